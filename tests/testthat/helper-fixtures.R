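# Small shared fixtures, built in code at test time.

# brute-force percentile: linear interpolation of the sorted sample
brute_pctl <- function(x, level) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n == 1) return(x)
  h <- (n - 1) * level / 100 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# a minimal daily series with fully controllable columns
toy_series <- function(n = 30, gpp = 5, qf = 1, par = 100, t_air = 20,
                       swc = 25, vpd = 10, co2 = 400, start = "2005-01-01",
                       site_id = "TOY", biome = "grasslands") {
  site_daily_series(data.frame(
    site_id = site_id, biome = biome,
    date = seq(as.Date(start), by = "day", length.out = n),
    gpp_obs = rep_len(gpp, n), quality_flag = rep_len(qf, n),
    par = rep_len(par, n), t_air = rep_len(t_air, n),
    swc = rep_len(swc, n), vpd = rep_len(vpd, n), co2 = rep_len(co2, n)))
}

# one seasonal cycle of semi-monthly NDVI following a double logistic
toy_ndvi_year <- function(year = 2005, base = 0.2, amp = 0.5, r1 = 1.2,
                          s1 = 8, r2 = 1.2, s2 = 18) {
  sm <- 1:24
  v <- base + amp * (1 / (1 + exp(-r1 * (sm - s1))) -
                     1 / (1 + exp(-r2 * (sm - s2))))
  ndvi_series(rep(year, 24), rep(1:12, each = 2), rep(1:2, 12), v)
}
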