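test_that("matching a decomposition against itself is the identity", {
  prof <- tiny_profile(g = 80, seed = 41)
  dec <- eigen_decompose(prof)
  m <- match_components(dec, dec, top_k = 4)
  expect_equal(m$control_component, 1:4)
  expect_equal(m$similarity, rep(1, 4), tolerance = 1e-10)
})

test_that("unrelated high-dimensional eigenvectors have near-zero similarity", {
  # E|cos| for two random unit vectors in dimension g is ~ sqrt(2/(pi*g))
  g <- 2000
  cosines <- withr::with_seed(42, {
    vapply(1:200, function(i) {
      a <- rnorm(g); b <- rnorm(g)
      abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
    }, numeric(1))
  })
  expect_lt(abs(mean(cosines) - sqrt(2 / (pi * g))), 0.005)
  expect_lt(max(cosines), 0.3)
})

test_that("the planted exogenous component disappears from the control SVD", {
  for (seed in 1:5) {
    sim <- generate_profile(simulation_spec(seed = seed))
    pooled <- eigen_decompose(sim$profile)
    control <- eigen_decompose(subset_samples(sim$profile, diet == "RC"))
    m <- match_components(pooled, control, top_k = 3)
    k_endo <- which.max(abs(crossprod(sim$truth$endo_u, pooled$u[, 1:3])))
    k_exo <- which.max(abs(crossprod(sim$truth$exo_u, pooled$u[, 1:3])))
    expect_gte(m$similarity[k_endo], 0.9)
    expect_equal(m$control_component[k_endo], 1L)
    expect_true(is.na(m$control_component[k_exo]))
    expect_lte(max(abs(crossprod(pooled$u[, k_exo], control$u))), 0.3)
  }
})

test_that("matching is symmetric and sign-invariant", {
  sim <- generate_profile(simulation_spec(n_genes = 500, seed = 43))
  pooled <- eigen_decompose(sim$profile)
  control <- eigen_decompose(subset_samples(sim$profile, diet == "RC"))
  ab <- match_components(pooled, control, top_k = 3)
  ba <- match_components(control, pooled, top_k = 3)
  pairs_ab <- stats::na.omit(ab[, c("pooled_component", "control_component")])
  pairs_ba <- stats::na.omit(ba[, c("pooled_component", "control_component")])
  expect_equal(
    pairs_ab[order(pairs_ab$pooled_component), ],
    setNames(pairs_ba[order(pairs_ba$control_component), 2:1],
             c("pooled_component", "control_component")),
    ignore_attr = TRUE
  )
  flipped <- control
  flipped$u <- -flipped$u
  flipped$v <- -flipped$v
  expect_equal(match_components(pooled, flipped, top_k = 3)$similarity,
               ab$similarity, tolerance = 1e-12)

  bad <- control
  rownames(bad$u)[1] <- "other_gene"
  expect_error(match_components(pooled, bad), "universes")
})

test_that("classification follows the match-then-association rule", {
  matches <- tibble::tibble(
    pooled_component = 1:3,
    control_component = c(1L, NA, NA),
    similarity = c(1, NA, NA),
    max_similarity = c(1, 0.05, 0.2)
  )
  assoc <- tibble::tibble(
    component = rep(1:3, each = 2),
    factor = rep(c("diet", "week"), 3),
    p_value = c(0.5, 1e-6, 1e-4, 0.4, 0.8, 0.9),
    p_adjusted = c(1, 2e-6, 2e-4, 0.8, 1, 1)
  )
  cls <- classify_components(matches, assoc)
  expect_equal(cls$classification,
               c("endogenous", "exogenous-candidate", "unclassified"))

  # monotone in the similarity threshold: endogenous can only drop to
  # unclassified, never jump to exogenous-candidate
  matches2 <- matches
  matches2$control_component[2] <- 2L
  matches2$similarity[2] <- 0.7
  prev <- NULL
  for (thr in seq(0, 1, by = 0.05)) {
    cls_t <- classify_components(matches2, assoc, sim_threshold = thr)$classification
    expect_false(any(cls_t == "exogenous-candidate" &
                       !is.na(matches2$control_component)))
    prev <- cls_t
  }
})

test_that("factor association uses exact rank-sum and Spearman tests", {
  sim <- generate_profile(simulation_spec(seed = 44))
  dec <- eigen_decompose(sim$profile)

  # perfectly separated diet groups: exact two-sided p = 2 / C(18, 9)
  sep <- dec
  hfd <- sim$profile$samples$diet == "HFD"
  sep$v[, 1] <- ifelse(hfd, 1, 0) + seq_len(18) * 1e-3
  a <- associate_factor(sep, "diet", 1)
  expect_equal(a$p_value, 2 / choose(18, 9), tolerance = 1e-12)
  expect_equal(a$direction, 1)

  # week-monotone loadings (ties within a week): Spearman rho = 1
  mono <- dec
  mono$v[, 1] <- sim$profile$samples$week / 20
  aw <- associate_factor(mono, "week", 1)
  expect_equal(aw$statistic, 1, tolerance = 1e-12)
  expect_lt(aw$p_value, 1e-6)

  # degenerate loadings
  flat <- dec
  flat$v[, 1] <- rep(0.2357, 18)
  expect_true(associate_factor(flat, "diet", 1)$degenerate)
  expect_equal(associate_factor(flat, "diet", 1)$p_value, 1)

  # AUC factors restrict to observed samples
  ag <- associate_factor(dec, "gtt_auc", 1)
  expect_equal(ag$n, sum(!is.na(sim$profile$samples$gtt_auc)))
})

test_that("diet association p-values are valid under the null", {
  # empirical rejection rate must match the discrete null's attained size
  n_rep <- 2000
  ps <- withr::with_seed(45, {
    vapply(seq_len(n_rep), function(i) {
      suppressWarnings(wilcox.test(rnorm(9), rnorm(9), exact = TRUE)$p.value)
    }, numeric(1))
  })
  pw <- pwilcox(0:81, 9, 9)
  attained <- 2 * pw[max(which(2 * pw <= 0.05))]
  expect_lt(abs(mean(ps <= 0.05) - attained), 0.015)
  for (alpha in c(0.01, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 0.02)
  }
})

test_that("associate_factors adjusts across factors within a component", {
  sim <- generate_profile(simulation_spec(seed = 46))
  dec <- fix_signs(eigen_decompose(sim$profile), "week", components = 1:3)
  tab <- associate_factors(dec, components = 1:2)
  expect_true(all(tab$p_adjusted >= tab$p_value))
  n_fac <- length(unique(tab$factor))
  expect_equal(tab$p_adjusted, pmin(1, tab$p_value * n_fac))
})
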