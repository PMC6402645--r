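# Independent oracles and small fixture builders used across the suite.

# Unpenalized logistic regression by hand-rolled iteratively-reweighted
# least squares; independent of both glm() and mgcv.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(as.numeric(beta_new))
    beta <- as.numeric(beta_new)
  }
  as.numeric(beta)
}

# Random simple (convex) polygon: vertices at sorted angles.
random_convex_polygon <- function(n = 8, scale = 100) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.3, 1) * scale
  cbind(r * cos(th), r * sin(th))
}

# Tilted-plane DEM: z = y * tan(slope_deg), y increasing northward
# (row 1 = north holds the largest values).
plane_dem <- function(n = 12, cell = 20, slope_deg = 30, down = "south") {
  ys <- (n - seq_len(n) + 0.5) * cell
  z <- matrix(rep(ys * tan(slope_deg * pi / 180), n), n, n)
  if (down == "north") z <- z[n:1, ]
  dem_grid(z, cell_size = cell, origin = c(0, 0))
}

# Straight west coastline running the length of a synthetic strip, plus a
# single offshore hotspot; used by the absence-polygon tests.
strip_world <- function(len_km = 60) {
  list(coast = cbind(rep(0, 61), seq(0, len_km * 1000, length.out = 61)),
       hotspots = matrix(c(-5000, len_km * 500), 1, 2))
}
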