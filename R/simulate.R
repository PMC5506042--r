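#' Specify a synthetic study design
#'
#' Describes the simulated longitudinal diet study the generator emulates:
#' two diet arms (`RC` control, `HFD` treatment), samples collected at several
#' ages (weeks), a planted *endogenous* rank-1 component whose sample loadings
#' follow age in every animal, and a planted *exogenous* rank-1 component that
#' loads only on treated samples. Strengths are on the per-gene scale: a
#' component of strength `c` is planted with singular value `c * sqrt(n_genes)`
#' against i.i.d. Gaussian noise of standard deviation `noise_sd`, so `c /
#' noise_sd` is the per-gene signal-to-noise ratio of the component.
#'
#' @param n_genes number of genes.
#' @param samples_per_cell samples per diet-by-week cell (default 3, the
#'   design's three animals per group).
#' @param weeks ordered ages at sacrifice.
#' @param endo_strength,exo_strength per-gene strengths of the planted
#'   endogenous and exogenous components.
#' @param noise_sd standard deviation of the additive Gaussian noise (log2
#'   scale).
#' @param seed integer seed; fully determines the generated data.
#' @param planted_set_size size of the gene set planted at an eigenvector end.
#' @param planted_set_end which extreme of the sorted loadings carries the
#'   planted set, `"high"` or `"low"`.
#' @return A `simulation_spec` object (a validated list).
#' @export
simulation_spec <- function(n_genes = 2000,
                            samples_per_cell = 3,
                            weeks = c(1, 9, 18),
                            endo_strength = 8,
                            exo_strength = 5,
                            noise_sd = 1,
                            seed = 1,
                            planted_set_size = 50,
                            planted_set_end = c("high", "low")) {
  planted_set_end <- match.arg(planted_set_end)
  stopifnot(
    n_genes >= 2, samples_per_cell >= 1, length(weeks) >= 1,
    endo_strength >= 0, exo_strength >= 0, noise_sd >= 0,
    planted_set_size >= 1, planted_set_size <= n_genes
  )
  structure(
    list(
      n_genes = as.integer(n_genes),
      samples_per_cell = as.integer(samples_per_cell),
      weeks = sort(as.numeric(weeks)),
      endo_strength = endo_strength,
      exo_strength = exo_strength,
      noise_sd = noise_sd,
      seed = as.integer(seed),
      planted_set_size = as.integer(planted_set_size),
      planted_set_end = planted_set_end
    ),
    class = "simulation_spec"
  )
}

# Sample table for the factorial design; ids mirror the H4A-W18 / R17P-W9
# convention (diet letter, animal number, tissue letter, week).
design_samples <- function(spec, tissue = "L") {
  grid <- tidyr::expand_grid(
    diet = c("RC", "HFD"),
    week = spec$weeks,
    rep = seq_len(spec$samples_per_cell)
  )
  grid$animal <- seq_len(nrow(grid))
  grid$sample_id <- sprintf(
    "%s%d%s-W%d",
    ifelse(grid$diet == "HFD", "H", "R"), grid$animal, tissue, grid$week
  )
  grid[, c("sample_id", "diet", "week", "animal")]
}

#' Generate a synthetic expression profile with planted components
#'
#' Builds `E = rho_endo u_e v_e' + rho_exo u_x v_x' + noise` on the log2 scale.
#' The endogenous sample loading `v_e` is the centered week, monotone in age
#' across all samples; the exogenous loading `v_x` starts from the treatment
#' (HFD) indicator — exactly zero on control samples — and is Gram-Schmidt
#' orthogonalized against `v_e` (a no-op in the balanced default design, where
#' the two are already orthogonal). Restricting the matrix to control samples
#' therefore removes the exogenous component entirely: the computational
#' analogue of a treatment eigen-component disappearing from the control-only
#' decomposition. Gene eigenvectors are independent Gaussian directions,
#' orthogonalized and normalized.
#'
#' @param spec a [simulation_spec()].
#' @param tissue single letter used in sample names.
#' @return A list with `profile` (an [expression_profile()]) and `truth`
#'   (a `ground_truth` holding the planted unit vectors, the planted singular
#'   values `rho = strength * sqrt(n_genes)`, and the spec).
#' @examples
#' sim <- generate_profile(simulation_spec(n_genes = 200, seed = 42))
#' dim(sim$profile)
#' @export
generate_profile <- function(spec, tissue = "L") {
  stopifnot(inherits(spec, "simulation_spec"))
  samples <- design_samples(spec, tissue)
  n_s <- nrow(samples)
  g <- spec$n_genes

  v_endo <- samples$week - mean(samples$week)
  if (sqrt(sum(v_endo^2)) < 1e-12) {
    abort("degenerate sample layout: week has no variation, endogenous loading undefined.")
  }
  v_endo <- v_endo / sqrt(sum(v_endo^2))

  v_exo <- as.numeric(samples$diet == "HFD")
  v_exo <- v_exo - sum(v_exo * v_endo) * v_endo
  if (sqrt(sum(v_exo^2)) < 1e-12) {
    abort("degenerate sample layout: treatment indicator is collinear with the week trend.")
  }
  v_exo <- v_exo / sqrt(sum(v_exo^2))

  out <- withr::with_seed(spec$seed, {
    u_endo <- rnorm(g)
    u_endo <- u_endo / sqrt(sum(u_endo^2))
    u_exo <- rnorm(g)
    u_exo <- u_exo - sum(u_exo * u_endo) * u_endo
    u_exo <- u_exo / sqrt(sum(u_exo^2))

    rho_endo <- spec$endo_strength * sqrt(g)
    rho_exo <- spec$exo_strength * sqrt(g)
    E <- rho_endo * tcrossprod(u_endo, v_endo) +
      rho_exo * tcrossprod(u_exo, v_exo)
    if (spec$noise_sd > 0) {
      E <- E + matrix(rnorm(g * n_s, sd = spec$noise_sd), g, n_s)
    }
    phen <- simulate_phenotypes(samples)
    list(E = E, u_endo = u_endo, u_exo = u_exo,
         rho_endo = rho_endo, rho_exo = rho_exo, samples = phen)
  })

  gene_ids <- sprintf("g%05d", seq_len(g))
  dimnames(out$E) <- list(gene_ids, samples$sample_id)

  truth <- structure(
    list(
      endo_u = setNames(out$u_endo, gene_ids),
      endo_v = setNames(v_endo, samples$sample_id),
      exo_u = setNames(out$u_exo, gene_ids),
      exo_v = setNames(v_exo, samples$sample_id),
      endo_rho = out$rho_endo,
      exo_rho = out$rho_exo,
      spec = spec
    ),
    class = "ground_truth"
  )
  list(profile = expression_profile(out$E, out$samples), truth = truth)
}

# Diabetic-phenotype attributes for the oldest cohort: tolerance-test AUCs
# shifted upward under treatment, and a Gb/Gw split of the treated animals by
# their GTT result (better/worse half).
simulate_phenotypes <- function(samples) {
  samples <- as_tibble(samples)
  last_week <- max(samples$week)
  at_end <- samples$week == last_week
  n_end <- sum(at_end)
  samples$gtt_auc <- NA_real_
  samples$itt_auc <- NA_real_
  shift <- as.numeric(samples$diet[at_end] == "HFD")
  samples$gtt_auc[at_end] <- 1000 + 400 * shift + rnorm(n_end, sd = 100)
  samples$itt_auc[at_end] <- 500 + 200 * shift + rnorm(n_end, sd = 60)
  samples$subgroup <- NA_character_
  hfd_end <- which(at_end & samples$diet == "HFD")
  if (length(hfd_end) >= 2) {
    worse <- rank(samples$gtt_auc[hfd_end]) > length(hfd_end) / 2
    samples$subgroup[hfd_end] <- ifelse(worse, "Gw", "Gb")
  }
  samples[, c("sample_id", "diet", "week", "gtt_auc", "itt_auc", "subgroup")]
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d genes, %d samples; planted rho: endo %.1f, exo %.1f\n",
    length(x$endo_u), length(x$endo_v), x$endo_rho, x$exo_rho
  ))
  invisible(x)
}

#' Generate a reference/target probe chip pair with a spatial artifact
#'
#' Emulates the probe-level stage the spatial normalization addresses: a
#' reference chip of log2 intensities and a target chip equal to the reference
#' plus a smooth spatial distortion (uneven hybridization/washing) and noise.
#'
#' @param side chip side length in probes (the full-size array is 1002).
#' @param artifact `"gradient"` (additive shift increasing along rows),
#'   `"blotch"` (a localized Gaussian bump) or `"none"`.
#' @param noise_sd probe-level noise standard deviation (log2 scale).
#' @param magnitude peak artifact amplitude in log2 units.
#' @param probes_per_set probes per probeset in the generated map (11 for the
#'   arrays this emulates).
#' @param seed integer seed.
#' @return A list with `reference` and `target` (both [probe_chip()]) and
#'   `distortion`, the true artifact field.
#' @export
generate_probe_chip <- function(side = 1002,
                                artifact = c("gradient", "blotch", "none"),
                                noise_sd = 0.05,
                                magnitude = 1,
                                probes_per_set = 11,
                                seed = 1) {
  artifact <- match.arg(artifact)
  stopifnot(side >= 2)
  withr::with_seed(seed, {
    ref <- matrix(rnorm(side * side, mean = 8, sd = 1.5), side, side)
    dist <- switch(artifact,
      none = matrix(0, side, side),
      gradient = matrix(magnitude * (seq_len(side) - 1) / (side - 1),
                        side, side, byrow = FALSE),
      blotch = {
        cx <- runif(1, side / 4, 3 * side / 4)
        cy <- runif(1, side / 4, 3 * side / 4)
        r <- side / 6
        d2 <- outer((seq_len(side) - cx)^2, (seq_len(side) - cy)^2, "+")
        magnitude * exp(-d2 / (2 * r^2))
      }
    )
    tgt <- ref + dist
    if (noise_sd > 0) tgt <- tgt + matrix(rnorm(side * side, sd = noise_sd), side, side)
    ids <- sprintf("PS%06d", ceiling(seq_len(side * side) / probes_per_set))
    map <- matrix(ids, side, side)
    list(
      reference = probe_chip(ref, map),
      target = probe_chip(tgt, map),
      distortion = dist
    )
  })
}

#' Generate gene-set collections around a planted truth
#'
#' Draws one *planted* set from the designated extreme of a planted gene
#' eigenvector plus uniformly drawn null sets, for exercising the rank-scoring
#' enrichment stage.
#'
#' @param truth a `ground_truth` from [generate_profile()].
#' @param n_null_sets number of null sets drawn uniformly from the universe.
#' @param set_size genes per set.
#' @param component plant at an extreme of the exogenous (`"exo"`) or
#'   endogenous (`"endo"`) gene eigenvector.
#' @param end which extreme; defaults to the spec's `planted_set_end`.
#' @param seed integer seed.
#' @return A `gene_set_collection`; the planted set is named
#'   `"planted_<component>_<end>"` and recorded in `attr(, "planted")`.
#' @export
generate_genesets <- function(truth, n_null_sets = 100, set_size = 50,
                              component = c("exo", "endo"), end = NULL,
                              seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  component <- match.arg(component)
  end <- end %||% truth$spec$planted_set_end
  end <- match.arg(end, c("high", "low"))
  u <- if (component == "exo") truth$exo_u else truth$endo_u
  universe <- names(u)
  if (length(universe) == 0) abort("empty gene universe.")
  if (set_size < 1 || set_size > length(universe)) {
    abort("`set_size` must be between 1 and the universe size.")
  }
  ord <- order(u, decreasing = (end == "high"))
  planted <- universe[ord[seq_len(set_size)]]
  sets <- withr::with_seed(seed, {
    nulls <- purrr::map(seq_len(n_null_sets), function(i) sample(universe, set_size))
    names(nulls) <- sprintf("null_%03d", seq_len(n_null_sets))
    c(setNames(list(planted), sprintf("planted_%s_%s", component, end)), nulls)
  })
  out <- gene_set_collection(sets, universe)
  attr(out, "planted") <- list(
    name = sprintf("planted_%s_%s", component, end),
    members = planted, component = component, end = end
  )
  out
}

#' Generate promoter sequences with planted motif occurrences
#'
#' Produces one i.i.d.-uniform nucleotide sequence per gene and inserts the
#' motif consensus with a rank-dependent probability: genes at the designated
#' extreme of the sorted planted gene eigenvector receive occurrences with
#' elevated probability, so motif binding strength is correlated with the
#' loading by construction.
#'
#' @param truth a `ground_truth` from [generate_profile()].
#' @param pwm a [pwm()] whose consensus is inserted.
#' @param promoter_length upstream-region length in bases.
#' @param planting_rate_by_rank vector of insertion probabilities indexed by
#'   rank in the sorted (designated end first) gene order; genes beyond its
#'   length use `background_rate`. Default: probability 1 for the top 50.
#' @param background_rate insertion probability for all remaining genes.
#' @param component,end which planted eigenvector and which extreme define the
#'   ranking (defaults mirror [generate_genesets()]).
#' @param seed integer seed.
#' @return Named character vector of promoter sequences (one per gene).
#' @export
generate_promoters <- function(truth, pwm,
                               promoter_length = 500,
                               planting_rate_by_rank = rep(1, 50),
                               background_rate = 0.02,
                               component = c("exo", "endo"), end = NULL,
                               seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(pwm, "pwm"))
  component <- match.arg(component)
  end <- end %||% truth$spec$planted_set_end
  end <- match.arg(end, c("high", "low"))
  cons <- pwm_consensus(pwm)
  w <- nchar(cons)
  if (w > promoter_length) abort("motif longer than the promoter length.")
  if (any(planting_rate_by_rank < 0 | planting_rate_by_rank > 1) ||
      background_rate < 0 || background_rate > 1) {
    abort("planting rates must be probabilities.")
  }
  u <- if (component == "exo") truth$exo_u else truth$endo_u
  g <- length(u)
  rate <- rep(background_rate, g)
  k <- min(length(planting_rate_by_rank), g)
  ord <- order(u, decreasing = (end == "high"))
  rate[ord[seq_len(k)]] <- planting_rate_by_rank[seq_len(k)]

  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), g * promoter_length, replace = TRUE)
    seqmat <- matrix(chars, nrow = g)
    plant <- runif(g) < rate
    starts <- sample.int(promoter_length - w + 1, g, replace = TRUE)
    cons_chars <- strsplit(cons, "")[[1]]
    for (i in which(plant)) {
      seqmat[i, starts[i]:(starts[i] + w - 1)] <- cons_chars
    }
    seqs <- apply(seqmat, 1, paste0, collapse = "")
    attr(seqs, "planted") <- names(u)[plant]
    setNames(seqs, names(u))
  })
}
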