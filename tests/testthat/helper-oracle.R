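# Independent scalar oracle for the four disproportionality statistics:
# a direct, unvectorized transcription of the printed formulas, kept
# separate from the package's implementation path.

oracle_ror <- function(a, b, c, d, z = 1.96) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}

oracle_prr <- function(a, b, c, d) {
  n <- a + b + c + d
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- (a * d - b * c)^2 * n /
    ((a + b) * (a + c) * (c + d) * (b + d))
  list(prr = prr, chi2 = chi2)
}

oracle_ebgm <- function(a, b, c, d, z = 1.64) {
  n <- a + b + c + d
  ebgm <- a * n / ((a + b) * (a + c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ebgm = ebgm, ebgm05 = exp(log(ebgm) - z * se))
}

oracle_bcpnn <- function(a, b, c, d, z = 1.96) {
  a1 <- 1; a2 <- 1; b1 <- 1; b2 <- 1; g11 <- 1
  al <- a1 + a2; be <- b1 + b2
  n <- a + b + c + d
  ic <- log2(a * n / ((a + b) * (a + c)))
  g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  eic <- log2((a + g11) * (n + al) * (n + be) /
                ((n + g) * (a + b + a1) * (a + c + b1)))
  vic <- (1 / log(2)^2) * (
    (n - a + g - g11) / ((a + g11) * (n + 1 + g)) +
      (n - a - b + al - a1) / ((a + b + a1) * (n + 1 + al)) +
      (n - a - c + be - b1) / ((a + c + b1) * (n + 1 + be))
  )
  list(ic = ic, eic = eic, vic = vic,
       ic025 = eic - z * sqrt(vic), ic975 = eic + z * sqrt(vic))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)

# random tables with all cells in [lo, hi]
random_tables <- function(n, lo = 1, hi = 1e6, seed = 1) {
  set.seed(seed)
  data.frame(
    a = floor(runif(n, lo, hi + 1)), b = floor(runif(n, lo, hi + 1)),
    c = floor(runif(n, lo, hi + 1)), d = floor(runif(n, lo, hi + 1))
  )
}
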