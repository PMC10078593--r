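# shared fixtures, all generated in code

# small landscape reused across tests (deterministic)
tiny_landscape <- function(nx = 20, ny = 20, seed = 42, ...) {
  generate_landscape(nx = nx, ny = ny, cellsize = 1000, seed = seed, ...)
}

# perpendicular distances from a half-normal detection process truncated at w
rhalfnorm_trunc <- function(n, sigma, w) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- abs(stats::rnorm(2 * n, 0, sigma))
    out <- c(out, x[x <= w])
  }
  out[seq_len(n)]
}

# segment table with counts drawn from a known log-linear intensity, for
# direct GAM tests without the survey machinery
toy_segments <- function(n = 300, seed = 1, beta0 = log(5), area = 0.04,
                         theta = 2) {
  set.seed(seed)
  df <- data.frame(
    segment_id = sprintf("s%04d", seq_len(n)),
    transect_id = rep(sprintf("t%03d", seq_len(ceiling(n / 5))), each = 5)[seq_len(n)],
    year = rep(2010:2014, length.out = n),
    length_km = 0.4,
    x = runif(n, 0, 2e4), y = runif(n, 0, 2e4),
    temp_range = runif(n, 13, 21), elevation = runif(n, 900, 2500),
    dist_slope = runif(n, 0, 8000), dist_forest = runif(n, 0, 6000),
    hpd = exp(runif(n, log(0.5), log(300))),
    vegetation = factor(sample(veg_levels(), n, replace = TRUE), veg_levels())
  )
  df$area_km2 <- area
  df$log_area <- log(area)
  mu <- exp(beta0 + log(df$area_km2))
  df$count <- stats::rnbinom(n, size = theta, mu = mu)
  class(df) <- c("segment_table", "data.frame")
  df
}

# brute-force all-pairs Euclidean distance transform oracle (cell centres)
brute_force_edt <- function(mask, cellsize = 1000) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    out[r, c] <- sqrt(min((src[, 1] - r)^2 + (src[, 2] - c)^2)) * cellsize
  }
  out
}
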