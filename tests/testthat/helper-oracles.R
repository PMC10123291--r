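# Analytic raster fixtures and independent brute-force oracles used
# across the suite.  Everything here is deliberately naive: fixtures are
# rasterized straight from the defining inequality, oracles enumerate or
# apply textbook formulas directly.

raster_disk <- function(r = 50, pad = 10) {
  n <- 2 * (r + pad)
  c0 <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), n), n)
  ((xs - c0)^2 + (t(xs) - c0)^2) <= r^2
}

raster_square <- function(side = 100, pad = 10) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

raster_ellipse <- function(a = 60, b = 20, angle = 0, pad = 10) {
  n <- 2 * (max(a, b) + pad)
  c0 <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), n), n) - c0
  ys <- t(matrix(rep(seq_len(n), n), n)) - c0
  u <- xs * cos(angle) + ys * sin(angle)
  v <- -xs * sin(angle) + ys * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

# two 100 x 20 bars crossing at the centre: area 3600, convex hull 6800
raster_cross <- function() {
  m <- matrix(FALSE, 140, 140)
  m[21:120, 61:80] <- TRUE
  m[61:80, 21:120] <- TRUE
  m
}

# Brute-force quartile-fence trimming: recompute fences with
# stats::quantile and test every element individually.
brute_trim_keep <- function(x, multiplier = 1.7) {
  q1 <- stats::quantile(x, 0.25, type = 7, names = FALSE)
  q3 <- stats::quantile(x, 0.75, type = 7, names = FALSE)
  iqr <- q3 - q1
  vapply(x, function(v) v >= q1 - multiplier * iqr &&
           v <= q3 + multiplier * iqr, logical(1))
}

# Textbook Kruskal-Wallis H with tie correction, from scratch.
brute_kw_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  Rsum <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / ns) - 3 * (N + 1)
  tie <- table(values)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# 2x2 Pearson chi-square closed form: n (ad - bc)^2 / (r1 r2 c1 c2).
brute_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# Welch t statistic and Satterthwaite df from the closed form.
brute_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# deterministic non-overlapping nucleus-blob raster (independent of the
# package's ROI generator): radial-falloff disks on a jittered grid
nuclei_fixture <- function(n_blobs = 200, dim_px = 1000, rad = 5,
                           seed = 99) {
  set.seed(seed)
  per_row <- ceiling(sqrt(n_blobs))
  spacing <- floor((dim_px - 40) / per_row)
  centers <- expand.grid(i = seq_len(per_row), j = seq_len(per_row))
  centers <- centers[seq_len(n_blobs), ]
  x <- 20 + (centers$i - 0.5) * spacing +
    stats::runif(n_blobs, -spacing / 6, spacing / 6)
  y <- 20 + (centers$j - 0.5) * spacing +
    stats::runif(n_blobs, -spacing / 6, spacing / 6)
  img <- matrix(0, dim_px, dim_px)
  for (k in seq_len(n_blobs)) {
    r1 <- floor(x[k] - rad - 1); r2 <- ceiling(x[k] + rad + 1)
    c1 <- floor(y[k] - rad - 1); c2 <- ceiling(y[k] + rad + 1)
    gx <- matrix(r1:r2, r2 - r1 + 1, c2 - c1 + 1)
    gy <- matrix(c1:c2, r2 - r1 + 1, c2 - c1 + 1, byrow = TRUE)
    d <- sqrt((gx - x[k])^2 + (gy - y[k])^2)
    img[r1:r2, c1:c2] <- pmax(img[r1:r2, c1:c2],
                              pmax(0, 0.85 * (1 - (d / rad)^2)))
  }
  img
}
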