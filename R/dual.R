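#' Match components across pooled and control-only decompositions
#'
#' The dual comparison: gene eigenvectors of the pooled (treatment + control)
#' decomposition are compared with those of the control-only decomposition by
#' absolute cosine similarity, and assigned greedily — largest similarity
#' first, each control component used at most once. Pairs below
#' `min_similarity` stay unmatched. Only gene eigenvectors are comparable
#' across the two fits (the sample sets differ), so matching is defined on
#' them; similarity is invariant to the sign ambiguity of either eigenvector.
#'
#' @param pooled,control [eigen_decompose()] results over the same genes in
#'   the same order (a differing gene universe is an error, not silently
#'   intersected).
#' @param top_k number of leading components considered on each side.
#' @param min_similarity smallest `|cos|` accepted as a match.
#' @return Tibble with one row per pooled component: `pooled_component`,
#'   `control_component` (`NA` when unmatched), `similarity` (of the matched
#'   pair) and `max_similarity` (largest `|cos|` against any considered
#'   control component, reported for unmatched components too).
#' @export
match_components <- function(pooled, control, top_k = 5, min_similarity = 0.3) {
  stopifnot(inherits(pooled, "eigen_decomposition"),
            inherits(control, "eigen_decomposition"))
  if (!identical(rownames(pooled$u), rownames(control$u))) {
    abort("gene universes of the two decompositions differ; align inputs first.")
  }
  kp <- min(top_k, ncol(pooled$u))
  kc <- min(top_k, ncol(control$u))
  S <- abs(crossprod(pooled$u[, seq_len(kp), drop = FALSE],
                     control$u[, seq_len(kc), drop = FALSE]))
  out <- tibble(
    pooled_component = seq_len(kp),
    control_component = NA_integer_,
    similarity = NA_real_,
    max_similarity = apply(S, 1, max)
  )
  S_work <- S
  repeat {
    m <- max(S_work)
    if (m < min_similarity || !is.finite(m)) break
    pos <- which(S_work == m, arr.ind = TRUE)[1, ]
    out$control_component[pos[1]] <- as.integer(pos[2])
    out$similarity[pos[1]] <- m
    S_work[pos[1], ] <- -Inf
    S_work[, pos[2]] <- -Inf
  }
  out
}

#' Associate a sample eigenvector with a design factor
#'
#' Binary factors (`diet`, `subgroup`) are tested by a two-sided Wilcoxon
#' rank-sum on the loadings (exact when both groups have at most 12 samples
#' and no ties; otherwise a tie-corrected normal approximation). Ordinal or
#' continuous factors (`week`, `gtt_auc`, `itt_auc`) use Spearman correlation
#' with a t-approximation p-value, restricted to samples with observed
#' values. Degenerate loadings (a single distinct value) give p = 1, flagged.
#'
#' @param decomposition an [eigen_decompose()] result.
#' @param factor one of `"diet"`, `"week"`, `"gtt_auc"`, `"itt_auc"`,
#'   `"subgroup"` (any attribute column works; character columns are treated
#'   as binary factors).
#' @param component which component's sample loadings to test.
#' @return One-row tibble: `component`, `factor`, `test`, `statistic`,
#'   `p_value`, `direction` (+1 when loadings increase with the factor or the
#'   treatment-like level), `n`, `degenerate`.
#' @export
associate_factor <- function(decomposition, factor, component = 1) {
  stopifnot(inherits(decomposition, "eigen_decomposition"))
  samples <- decomposition$samples
  if (!factor %in% names(samples)) {
    abort(sprintf("factor `%s` not present in the sample table.", factor))
  }
  v <- decomposition$v[, component]
  a <- samples[[factor]]
  ok <- !is.na(a)
  v <- v[ok]
  a <- a[ok]
  n <- length(v)
  binary <- is.character(a) || is.factor(a)

  if (length(unique(v)) < 2) {
    return(tibble(component = component, factor = factor,
                  test = if (binary) "wilcoxon" else "spearman",
                  statistic = NA_real_, p_value = 1, direction = 0,
                  n = n, degenerate = TRUE))
  }

  if (binary) {
    lev <- sort(unique(as.character(a)))
    if (length(lev) != 2) abort(sprintf("factor `%s` must have exactly 2 levels.", factor))
    hi <- if ("HFD" %in% lev) "HFD" else if ("Gw" %in% lev) "Gw" else lev[2]
    x <- v[a == hi]
    y <- v[a != hi]
    if (length(x) == 0 || length(y) == 0) abort("both factor groups must be nonempty.")
    exact <- length(x) <= 12 && length(y) <= 12 && !anyDuplicated(v)
    ht <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
    )
    tibble(component = component, factor = factor, test = "wilcoxon",
           statistic = unname(ht$statistic), p_value = ht$p.value,
           direction = sign(median(x) - median(y)), n = n, degenerate = FALSE)
  } else {
    rho <- cor(v, a, method = "spearman")
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- max(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
    tibble(component = component, factor = factor, test = "spearman",
           statistic = rho, p_value = p, direction = sign(rho),
           n = n, degenerate = FALSE)
  }
}

#' Associate several components with all available factors
#'
#' Runs [associate_factor()] for each requested component against every
#' factor present in the sample table, and Bonferroni-adjusts p-values across
#' the factors tested within each component.
#'
#' @param decomposition an [eigen_decompose()] result.
#' @param components components to test.
#' @param factors factor names; defaults to the study factors present.
#' @return Tibble of association rows with a `p_adjusted` column.
#' @export
associate_factors <- function(decomposition,
                              components = 1:3,
                              factors = NULL) {
  samples <- decomposition$samples
  factors <- factors %||% intersect(
    c("diet", "week", "gtt_auc", "itt_auc", "subgroup"), names(samples)
  )
  factors <- factors[purrr::map_lgl(factors, function(f) {
    a <- samples[[f]]
    sum(!is.na(a)) >= 3 && length(unique(a[!is.na(a)])) >= 2
  })]
  components <- components[components <= length(decomposition$rho)]
  purrr::map_dfr(components, function(k) {
    purrr::map_dfr(factors, function(f) associate_factor(decomposition, f, k)) |>
      dplyr::mutate(p_adjusted = pmin(1, .data$p_value * length(factors)))
  })
}

#' Classify matched components as endogenous or exogenous candidates
#'
#' A pooled component matched to a control component with similarity at or
#' above `sim_threshold` is *endogenous* (present with or without treatment).
#' An unmatched component whose sample loadings are treatment-associated
#' (adjusted diet p-value at most `alpha`) is an *exogenous candidate* — the
#' treatment-driven structure that vanishes from the control-only
#' decomposition. Everything else is *unclassified*. Classification is
#' monotone in `sim_threshold`: raising it can only move a component from
#' endogenous to unclassified, never directly to exogenous candidate (only
#' components unmatched at the matching stage are exogenous-eligible).
#'
#' @param matches output of [match_components()].
#' @param associations output of [associate_factors()] on the pooled
#'   decomposition (must include the `diet` factor).
#' @param sim_threshold similarity at or above which a match is endogenous.
#' @param alpha significance level on the Bonferroni-adjusted diet p-value.
#' @return `matches` with `diet_p_adjusted` and `classification` columns.
#' @export
classify_components <- function(matches, associations,
                                sim_threshold = 0.6, alpha = 0.05) {
  diet <- associations |>
    dplyr::filter(.data$factor == "diet") |>
    dplyr::select(pooled_component = "component",
                  diet_p_adjusted = "p_adjusted")
  out <- dplyr::left_join(matches, diet, by = "pooled_component")
  out$classification <- dplyr::case_when(
    !is.na(out$control_component) & out$similarity >= sim_threshold ~ "endogenous",
    is.na(out$control_component) &
      !is.na(out$diet_p_adjusted) & out$diet_p_adjusted <= alpha ~ "exogenous-candidate",
    TRUE ~ "unclassified"
  )
  out
}
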