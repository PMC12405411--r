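# Shared fixture builders: tiny configs and hand-enumerable raw tables.

small_config <- function(n = 500, seed = 1, ...) {
  sim_config(
    n_reports = n,
    pt_catalog = default_pt_catalog(n_null = 20),
    seed = seed,
    ...
  )
}

# a hand-built raw dataset: n reports, explicit drug/PT assignments.
# pts is a list of character vectors, one per report.
hand_raw <- function(drugname, role = rep("PS", length(drugname)), pts,
                     fda_dt = rep(20240101L, length(drugname)),
                     caseid = as.character(seq_along(drugname)),
                     age = rep(NA_real_, length(drugname)),
                     age_cod = rep("YR", length(drugname)),
                     sex = rep("F", length(drugname)),
                     event_dt = rep(NA_integer_, length(drugname)),
                     start_dt = rep(NA_integer_, length(drugname))) {
  n <- length(drugname)
  pid <- as.character(seq_len(n) + 1000L)
  raw <- faersignal:::empty_raw_tables()
  raw$demo <- data.table::data.table(
    primaryid = pid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
    reporter_country = rep("US", n), occp_cod = rep("MD", n)
  )
  raw$drug <- data.table::data.table(
    primaryid = pid, caseid = caseid, drug_seq = 1L, role_cod = role,
    drugname = drugname, prod_ai = drugname
  )
  raw$reac <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    data.table::data.table(primaryid = pid[i], caseid = caseid[i],
                           pt = pts[[i]])
  }))
  raw$ther <- data.table::data.table(
    primaryid = pid, caseid = caseid, dsg_drug_seq = 1L,
    start_dt = start_dt
  )[!is.na(start_dt)]
  raw$outc <- raw$outc[0]
  raw
}

hand_map <- function(pts, socs) data.table::data.table(pt = pts, soc = socs)
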