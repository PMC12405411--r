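category	value	count
Total	Case reports	3677
Gender	Female	1324
Gender	Male	1334
Gender	Unknown	1019
Age (year)	<5	585
Age (year)	5-18	1052
Age (year)	>18	620
Age (year)	Unknown	1420
Reporter	Consumer	2407
Reporter	Health Professional	226
Reporter	Physician	810
Reporter	Pharmacist	51
Reporter	Registered Nurse	3
Reporter	Unknown	25
Reporter country	United States	2710
Reporter country	Brazil	117
Reporter country	Others	850
Outcome	Hospitalization	1012
Outcome	Death	610
Outcome	Congenital Anomaly	5
Outcome	Life threatening	55
Outcome	Disability	69
Outcome	Other serious	785
Outcome	Unknown	1141
Reporting year	2004	81
Reporting year	2005	60
Reporting year	2006	28
Reporting year	2007	110
Reporting year	2008	58
Reporting year	2009	56
Reporting year	2010	50
Reporting year	2011	43
Reporting year	2012	69
Reporting year	2013	131
Reporting year	2014	127
Reporting year	2015	180
Reporting year	2016	201
Reporting year	2017	236
Reporting year	2018	295
Reporting year	2019	263
Reporting year	2020	274
Reporting year	2021	315
Reporting year	2022	387
Reporting year	2023	366
Reporting year	2024	347
Onset (days)	<=360	428
Onset (days)	>360	763
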