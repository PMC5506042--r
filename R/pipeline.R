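#' Pipeline configuration
#'
#' Collects every tunable of the dual eigen-analysis in one object: the
#' synthetic design, centering, matching and classification thresholds, the
#' enrichment and motif stage parameters, and a single global seed that is
#' propagated to every stochastic stage (simulation, null gene sets,
#' promoters, permutation null). The configuration round-trips losslessly
#' through its YAML representation ([write_config()] / [read_config()]).
#'
#' @param sim a [simulation_spec()] describing the synthetic inputs (its
#'   `seed` is overridden by the global `seed` below when the pipeline
#'   simulates).
#' @param centering SVD centering mode, see [eigen_decompose()].
#' @param top_k leading components carried through matching, association and
#'   enrichment.
#' @param match_min_similarity,sim_threshold,alpha matching and
#'   classification thresholds, see [match_components()] and
#'   [classify_components()].
#' @param anchor sample attribute used to fix eigenvector signs.
#' @param n_null_sets,set_size,min_size enrichment-stage parameters.
#' @param run_motif run the motif-association stage.
#' @param n_perm permutations of the motif null.
#' @param promoter_length simulated upstream-region length (bases).
#' @param seed mandatory global seed.
#' @return A `dual_eigen_config` list.
#' @export
dual_eigen_config <- function(sim = simulation_spec(),
                              centering = "gene",
                              top_k = 3,
                              match_min_similarity = 0.3,
                              sim_threshold = 0.6,
                              alpha = 0.05,
                              anchor = "week",
                              n_null_sets = 100,
                              set_size = NULL,
                              min_size = 5,
                              run_motif = TRUE,
                              n_perm = 999,
                              promoter_length = 500,
                              seed = 1) {
  structure(
    list(
      sim = sim, centering = centering, top_k = as.integer(top_k),
      match_min_similarity = match_min_similarity,
      sim_threshold = sim_threshold, alpha = alpha, anchor = anchor,
      n_null_sets = as.integer(n_null_sets),
      set_size = as.integer(set_size %||% sim$planted_set_size),
      min_size = as.integer(min_size),
      run_motif = isTRUE(run_motif), n_perm = as.integer(n_perm),
      promoter_length = as.integer(promoter_length),
      seed = as.integer(seed)
    ),
    class = "dual_eigen_config"
  )
}

#' @rdname dual_eigen_config
#' @param config a `dual_eigen_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "dual_eigen_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname dual_eigen_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(simulation_spec, x$sim)
  x$sim <- NULL
  do.call(dual_eigen_config, c(list(sim = sim), x))
}

#' Run the dual eigen-analysis pipeline
#'
#' Executes the full workflow: decompose the pooled profile and the
#' control-only profile, anchor signs, match gene eigenvectors across the two
#' decompositions, associate sample loadings with the design factors,
#' classify components as endogenous / exogenous-candidate, score gene sets
#' at both ends of each leading gene eigenvector, and (optionally) test
#' motif binding-affinity profiles against the sorted loadings. With no
#' inputs supplied, the synthetic generator provides profile, gene sets and
#' promoters according to `config$sim`, so the run is fully self-contained
#' and reproducible from `(config, seed)`.
#'
#' @param config a [dual_eigen_config()].
#' @param profile optional [expression_profile()]; simulated if `NULL`.
#' @param genesets optional [gene_set_collection()]; simulated from the
#'   planted truth if `NULL` and a simulation was run.
#' @param promoters optional named sequences; simulated likewise.
#' @param motifs optional named list of [pwm()]s; defaults to a planted
#'   direct-repeat motif plus an unrelated control motif.
#' @return A `dual_eigen_report` with fields `config`, `pooled`, `control`,
#'   `components` (classified matches), `associations`, `enrichment`,
#'   `motif`, and `truth` when simulated.
#' @export
run_dual_eigen <- function(config = dual_eigen_config(),
                           profile = NULL, genesets = NULL,
                           promoters = NULL, motifs = NULL) {
  stopifnot(inherits(config, "dual_eigen_config"))
  truth <- NULL
  if (is.null(profile)) {
    spec <- config$sim
    spec$seed <- config$seed
    sim <- generate_profile(spec)
    profile <- sim$profile
    truth <- sim$truth
  }
  if (!"diet" %in% names(profile$samples)) {
    abort("stage `dual`: profile has no `diet` attribute, cannot form the control-only SVD.")
  }

  k <- config$top_k
  pooled <- eigen_decompose(profile, config$centering)
  pooled <- fix_signs(pooled, config$anchor,
                      components = seq_len(min(k, length(pooled$rho))))
  control <- subset_samples(profile, .data$diet == "RC")
  control <- eigen_decompose(control, config$centering)
  control <- fix_signs(control, config$anchor,
                       components = seq_len(min(k, length(control$rho))))

  matches <- match_components(pooled, control, top_k = k,
                              min_similarity = config$match_min_similarity)
  associations <- associate_factors(pooled, components = seq_len(k))
  components <- classify_components(matches, associations,
                                    sim_threshold = config$sim_threshold,
                                    alpha = config$alpha)
  pct <- contribution_percentages(pooled$rho)
  components <- dplyr::mutate(
    components,
    rho = pooled$rho[.data$pooled_component],
    cum_percent = pct[.data$pooled_component],
    .after = "pooled_component"
  )

  if (is.null(genesets) && !is.null(truth)) {
    genesets <- generate_genesets(truth, n_null_sets = config$n_null_sets,
                                  set_size = config$set_size,
                                  seed = seed_stream(config$seed, 1))
  }
  enrichment <- NULL
  if (!is.null(genesets)) {
    enrichment <- purrr::map_dfr(seq_len(k), function(j) {
      u <- setNames(pooled$u[, j], rownames(pooled$u))
      dplyr::mutate(
        enrich_collection(u, genesets, min_size = config$min_size),
        component = j, .before = 1
      )
    })
  }

  motif <- NULL
  if (config$run_motif) {
    motifs <- motifs %||% list(
      planted = pwm_from_consensus("AGGTCAAAGGTCA", id = "SYN_DR1"),
      control = pwm_from_consensus("CACGTGTC", id = "SYN_EBOX")
    )
    if (is.null(promoters) && !is.null(truth)) {
      promoters <- generate_promoters(
        truth, motifs[[1]], promoter_length = config$promoter_length,
        seed = seed_stream(config$seed, 2)
      )
    }
    if (!is.null(promoters)) {
      motif <- purrr::map_dfr(motifs, function(mm) {
        aff <- scan_pwm_affinity(promoters, mm)
        purrr::map_dfr(seq_len(k), function(j) {
          u <- setNames(pooled$u[, j], rownames(pooled$u))
          dplyr::mutate(
            base_association(u, aff, n_perm = config$n_perm,
                             seed = seed_stream(config$seed, 3)),
            component = j, .before = 1
          )
        })
      })
      motif <- motif |>
        dplyr::group_by(.data$component) |>
        dplyr::mutate(p_bonferroni = pmin(1, .data$p_value * dplyr::n())) |>
        dplyr::ungroup()
    }
  }

  structure(
    list(config = config, pooled = pooled, control = control,
         components = components, associations = associations,
         enrichment = enrichment, motif = motif, truth = truth),
    class = "dual_eigen_report"
  )
}

# Derived sub-seeds for downstream stochastic stages; kept within 32-bit
# integer range.
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' @export
print.dual_eigen_report <- function(x, ...) {
  cat("<dual_eigen_report>\n")
  print(x$components)
  invisible(x)
}

#' @rdname run_dual_eigen
#' @param x a `dual_eigen_report`.
#' @param ... unused.
#' @export
tidy.dual_eigen_report <- function(x, ...) x$components

#' @rdname run_dual_eigen
#' @export
glance.dual_eigen_report <- function(x, ...) {
  cls <- x$components$classification
  tibble(
    n_components = nrow(x$components),
    n_endogenous = sum(cls == "endogenous"),
    n_exogenous_candidate = sum(cls == "exogenous-candidate"),
    n_unclassified = sum(cls == "unclassified"),
    top_set = if (is.null(x$enrichment)) NA_character_ else
      x$enrichment$set[which.min(x$enrichment$p_adjusted)],
    seed = x$config$seed
  )
}

#' Write all pipeline artifacts to a directory
#'
#' Emits the components report (singular value, cumulative percentage, match
#' similarity, classification, per-factor adjusted p-values), per-component
#' sorted sample-loading tables, enrichment and motif results, the eigen
#' decomposition TSVs and the resolved configuration YAML. Outputs are
#' byte-reproducible from `(inputs, config, seed)`.
#'
#' @param report a `dual_eigen_report`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dual_eigen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide_assoc <- report$associations |>
    dplyr::select("component", "factor", "p_adjusted") |>
    tidyr::pivot_wider(names_from = "factor", values_from = "p_adjusted",
                       names_prefix = "p_")
  readr::write_tsv(
    dplyr::left_join(report$components, wide_assoc,
                     by = c(pooled_component = "component")),
    file.path(dir, "components.tsv")
  )
  for (j in seq_len(nrow(report$components))) {
    tab <- tidy(report$pooled, "v", components = j) |>
      dplyr::arrange(.data$loading)
    readr::write_tsv(tab, file.path(dir, sprintf("sample_loadings_c%d.tsv", j)))
  }
  if (!is.null(report$enrichment)) {
    readr::write_tsv(report$enrichment, file.path(dir, "enrichment.tsv"))
  }
  if (!is.null(report$motif)) {
    readr::write_tsv(report$motif, file.path(dir, "motif.tsv"))
  }
  write_eigen_tsv(report$pooled, dir, "pooled",
                  components = seq_len(nrow(report$components)))
  write_eigen_tsv(report$control, dir, "control",
                  components = seq_len(min(nrow(report$components),
                                           length(report$control$rho))))
  write_config(report$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
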