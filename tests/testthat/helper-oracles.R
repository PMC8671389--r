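# Independent oracles used to pin expected values.  These deliberately do
# not share code with the package implementation.

# Plain bisection on the isobaric psychrometric balance
# e_s(Tw) - e(Td) = gamma * p * (Ta - Tw), with the same Magnus constants.
oracle_wet_bulb <- function(Ta, Td, p, iters = 60) {
  es <- function(T) 6.112 * exp(17.67 * T / (T + 243.5))
  f <- function(Tw) es(Tw) - es(Td) - 6.6e-4 * p * (Ta - Tw)
  lo <- Td; hi <- Ta
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Normal CDF through the error function (pracma), independent of pnorm
oracle_loss <- function(swbgt, mu = 32.47, sigma = 4.16) {
  0.5 * (1 + pracma::erf((swbgt - mu) / (sigma * sqrt(2))))
}

# Brute-force double-loop country aggregation
oracle_aggregate <- function(loss_grid, workers, cgrid) {
  sums <- list()
  for (i in seq_len(nrow(cgrid))) for (j in seq_len(ncol(cgrid))) {
    iso <- cgrid[i, j]
    if (is.na(iso)) next
    v <- loss_grid[i, j] * workers[i, j]
    if (is.na(v)) v <- 0
    sums[[iso]] <- (if (is.null(sums[[iso]])) 0 else sums[[iso]]) + v
  }
  unlist(sums)
}

# A synthetic 24-h diurnal cycle with a guaranteed coolest < hottest spread
random_diurnal <- function(base = 28, amp = NULL, noise = 0.3) {
  if (is.null(amp)) amp <- runif(1, 2, 6)
  h <- 0:23
  base + amp * cos(2 * pi * (h - 14) / 24) + rnorm(24, 0, noise)
}

# Small constant sWBGT field spanning whole days
constant_field <- function(value, n_days = 365, nlat = 2, nlon = 2) {
  time <- seq(as.POSIXct("2001-01-01 00:00:00", tz = "UTC"),
              by = "hour", length.out = n_days * 24)
  hourly_field(array(value, c(nlat, nlon, length(time))),
               lat = seq(-10, 10, length.out = nlat),
               lon = seq(0, 30, length.out = nlon), time = time)
}
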