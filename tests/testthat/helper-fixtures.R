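# Shared fixtures, built in code at test time.

# Small deterministic expression profile with the standard design columns.
tiny_profile <- function(g = 40, seed = 42, weeks = c(1, 9, 18), per_cell = 3) {
  sim <- generate_profile(simulation_spec(
    n_genes = g, samples_per_cell = per_cell, weeks = weeks, seed = seed,
    planted_set_size = min(10, g)
  ))
  sim$profile
}

# Independent LTS oracle: exhaustive best h-subset search per knot candidate,
# ordinary least squares via normal equations (deliberately a different code
# path from the package's lm.fit-based implementation).
oracle_piecewise_lts <- function(x, y, coverage = 0.75,
                                 knot_probs = seq(0.1, 0.9, by = 0.1)) {
  n <- length(x)
  h <- ceiling(coverage * n)
  knots <- unique(as.numeric(quantile(x, probs = knot_probs, type = 7)))
  best <- list(obj = Inf)
  for (t in knots) {
    X <- cbind(1, x, pmax(x - t, 0))
    subsets <- combn(n, h)
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      Xi <- X[idx, , drop = FALSE]
      XtX <- crossprod(Xi)
      co <- tryCatch(solve(XtX, crossprod(Xi, y[idx])),
                     error = function(e) NULL)
      if (is.null(co)) next
      r2 <- (y - drop(X %*% co))^2
      obj <- sum(sort(r2)[seq_len(h)])
      if (obj < best$obj - 1e-12) {
        best <- list(obj = obj, coef = as.numeric(co), knot = t)
      }
    }
  }
  best
}

# Independent rank-sum enumeration oracle: exact one-sided p over all
# placements of m member ranks among g.
oracle_ranksum_p <- function(g, m, observed, end) {
  sums <- colSums(matrix(seq_len(g)[combn(g, m)], nrow = m))
  if (end == "low") mean(sums <= observed) else mean(sums >= observed)
}

# Chips realizing an exact additive probe + chip model on a small grid:
# one probeset per column of an 11-row grid.
additive_chips <- function(beta, alpha = NULL, n_sets = 4, seed = 99) {
  withr::with_seed(seed, {
    alpha <- alpha %||% rnorm(11, sd = 0.7)
    mu <- 8
    map <- matrix(rep(sprintf("S%02d", seq_len(n_sets)), each = 11),
                  11, n_sets)
    chips <- lapply(beta, function(b) {
      probe_chip(matrix(mu + alpha, 11, n_sets) + b, map)
    })
    names(chips) <- names(beta)
    chips
  })
}
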