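# Shared fixtures, built in code at test time.

toy <- make_toy_fixture()

# a small but complete random contingency table (no all-zero margins)
random_contingency <- function(nr = NULL, nc = NULL, lambda = 4) {
  nr <- nr %||% sample(2:6, 1)
  nc <- nc %||% sample(2:6, 1)
  repeat {
    m <- matrix(rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) && sum(m) > 0) return(m)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force pseudo-F for Euclidean distances, computed from raw coordinates
# (classical sum-of-squares partition), independent of the package's
# distance-based route
coord_pseudo_F <- function(X, groups) {
  k <- length(unique(groups))
  N <- nrow(X)
  center <- colMeans(X)
  ss_total <- sum(sweep(X, 2, center)^2)
  ss_within <- 0
  for (g in unique(groups)) {
    Xi <- X[groups == g, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (N - k))
}
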