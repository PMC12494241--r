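# Independent reference implementations and small fixture builders.
# These deliberately re-derive results with naive loops / dense algebra so
# the package's vectorised paths are checked against a second code path.

# Brute-force ordinary kriging: full bordered system over ALL points,
# assembled entry-by-entry and solved with qr.solve.
ok_oracle <- function(x, y, z, vm, tx, ty) {
  n <- length(x)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    A[i, j] <- model_gamma(vm, h)
  }
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  b <- numeric(n + 1)
  for (i in seq_len(n))
    b[i] <- model_gamma(vm, sqrt((x[i] - tx)^2 + (y[i] - ty)^2))
  b[n + 1] <- 1
  sol <- qr.solve(A, b)
  list(estimate = sum(sol[seq_len(n)] * z), weights = sol[seq_len(n)],
       variance = sum(sol * b))
}

# Loop-based metric references
rmse_percent_loop <- function(obs, est) {
  ss <- 0
  for (i in seq_along(obs)) ss <- ss + (obs[i] - est[i])^2
  100 * sqrt(ss / length(obs)) / (sum(obs) / length(obs))
}

pearson_r_loop <- function(obs, est) {
  mo <- mean(obs); me <- mean(est)
  num <- 0; do_ <- 0; de <- 0
  for (i in seq_along(obs)) {
    num <- num + (obs[i] - mo) * (est[i] - me)
    do_ <- do_ + (obs[i] - mo)^2
    de <- de + (est[i] - me)^2
  }
  num / sqrt(do_ * de)
}

# Naive Matheron estimator over explicit pair loops, one bin
matheron_loop <- function(x, y, v, lo, hi) {
  s <- 0; n <- 0L
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (j <= i) next
    h <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (h > lo && h <= hi) { s <- s + (v[i] - v[j])^2; n <- n + 1L }
  }
  if (n == 0L) NA_real_ else s / (2 * n)
}

square_area <- function(side = 120, crs = 32723) {
  study_area(list(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))),
             crs = crs)
}

tiny_samples <- function(crs = 32723) {
  sample_set(x = c(0, 10, 0, 10, 5, 2, 8, 3, 9, 6),
             y = c(0, 0, 10, 10, 5, 7, 2, 4, 8, 1),
             value = c(5, 6, 7, 8, 6.5, 7.2, 5.8, 6.1, 7.7, 5.9),
             treatment = rep(c("T1", "T2"), 5),
             crs = crs, variable_name = "yield")
}

# small deterministic grid with one masked cell
tiny_grid <- function(crs = 32723) {
  v <- matrix(as.numeric(1:12), 3, 4)
  v[2, 3] <- NA
  raster_grid(v, origin_x = 0, origin_y = 3, pixel = 1, crs = crs)
}
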