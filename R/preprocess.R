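#' Configuration for sub-sub spatial normalization
#'
#' Parameters of the subarray decomposition and the robust piecewise fit:
#' 50 x 50 probe subarrays overlapping by 25 probes in both directions, a
#' one-knot piecewise-linear map per subarray estimated by least trimmed
#' squares (LTS) covering `lts_coverage` of the probes, with knot candidates
#' at the deciles of the target intensities inside the subarray.
#'
#' @param subarray_size side of a square subarray in probes.
#' @param overlap overlap between adjacent subarrays (probes); must satisfy
#'   `0 < overlap < subarray_size`.
#' @param lts_coverage fraction of probes the trimmed fit must cover
#'   (`h = ceiling(lts_coverage * n)`), in `[0.5, 1]`.
#' @param knot_probs quantile probabilities of the target intensities used as
#'   knot candidates.
#' @param exhaustive_n instances with `n <= exhaustive_n` points are solved by
#'   exact enumeration of all h-subsets; larger ones by deterministic
#'   concentration steps.
#' @param n_starts,max_csteps concentration-path controls for large instances.
#' @return A `subsub_config` list.
#' @export
subsub_config <- function(subarray_size = 50, overlap = 25,
                          lts_coverage = 0.75,
                          knot_probs = seq(0.1, 0.9, by = 0.1),
                          exhaustive_n = 20, n_starts = 5, max_csteps = 30) {
  if (!(overlap > 0 && overlap < subarray_size)) {
    abort("`overlap` must satisfy 0 < overlap < subarray_size.")
  }
  if (lts_coverage < 0.5 || lts_coverage > 1) {
    abort("`lts_coverage` must be in [0.5, 1].")
  }
  structure(
    list(
      subarray_size = as.integer(subarray_size),
      overlap = as.integer(overlap),
      lts_coverage = lts_coverage,
      knot_probs = knot_probs,
      exhaustive_n = as.integer(exhaustive_n),
      n_starts = as.integer(n_starts),
      max_csteps = as.integer(max_csteps)
    ),
    class = "subsub_config"
  )
}

#' Partition a probe grid into overlapping subarrays
#'
#' Window starts advance by `subarray_size - overlap`; if the last regular
#' window does not reach the grid edge, one extra edge-anchored window is
#' added at `length - size` so the union of windows covers every probe. On the
#' 1002-probe axis with size 50 and overlap 25 this yields starts
#' 0, 25, ..., 950, 952 — 40 per axis, 1600 windows.
#'
#' @param rows,cols grid dimensions.
#' @param config a [subsub_config()].
#' @return Tibble with 0-based `row_start`, `col_start` and `size`.
#' @export
partition_subarrays <- function(rows, cols, config = subsub_config()) {
  size <- config$subarray_size
  if (rows < size || cols < size) {
    abort("grid smaller than the configured subarray size.")
  }
  step <- size - config$overlap
  axis_starts <- function(len) {
    starts <- seq.int(0L, len - size, by = step)
    if (max(starts) + size < len) starts <- c(starts, len - size)
    starts
  }
  rs <- axis_starts(rows)
  cs <- axis_starts(cols)
  tidyr::expand_grid(row_start = rs, col_start = cs) |>
    dplyr::mutate(size = size)
}

#' One-knot piecewise-linear least trimmed squares fit
#'
#' Fits `y ~ b0 + b1 x + b2 (x - t)+` (continuous at the knot `t`) by least
#' trimmed squares: the objective is the sum of the `h` smallest squared
#' residuals, `h = ceiling(lts_coverage * n)`. Every knot candidate (deciles
#' of `x` by default) is scanned; for each, small instances
#' (`n <= exhaustive_n`) are solved exactly by enumerating all h-subsets
#' (the LTS optimum is the best h-subset least-squares fit), large instances
#' by deterministic concentration steps from several order-statistics starts.
#' The fit is deterministic given the inputs and the configuration.
#'
#' @param x target intensities (predictor, log2 scale).
#' @param y reference intensities (response, log2 scale).
#' @param config a [subsub_config()].
#' @return A `piecewise_fit` with elements `knot`, `coefficients`
#'   (`b0`, `b1`, `b2`), `segments` (per-segment slope and intercept),
#'   `trimmed_rss`, `h`, `n`, `degenerate` and `method`.
#' @export
fit_piecewise_lts <- function(x, y, config = subsub_config()) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have the same length.")
  h <- as.integer(ceiling(config$lts_coverage * n))

  if (diff(range(x)) < 1e-12) {
    # all-constant target: no slope is identifiable, fall back to a flat fit
    b <- c(mean(y), 0, 0)
    r <- y - b[1]
    trss <- sum(sort(r^2, partial = h)[seq_len(h)])
    return(new_piecewise_fit(NA_real_, b, trss, h, n,
                             degenerate = TRUE, method = "degenerate"))
  }
  if (n < 6) abort("need at least 6 points for a one-knot piecewise fit.")

  knots <- unique(as.numeric(quantile(x, probs = config$knot_probs, type = 7)))
  best <- NULL
  for (t in knots) {
    X <- cbind(1, x, pmax(x - t, 0))
    cand <- if (n <= config$exhaustive_n) {
      lts_exhaustive(X, y, h)
    } else {
      lts_concentrate(X, y, h, config$n_starts, config$max_csteps)
    }
    if (is.null(best) || cand$obj < best$obj - 1e-15) {
      best <- c(cand, list(knot = t))
    }
    if (best$obj < 1e-18) break  # perfect fit, no knot can improve on zero
  }
  new_piecewise_fit(best$knot, best$coef, best$obj, h, n,
                    degenerate = FALSE,
                    method = if (n <= config$exhaustive_n) "exhaustive" else "concentration")
}

ols_coef <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  co
}

trimmed_rss <- function(X, y, co, h) {
  r2 <- (y - drop(X %*% co))^2
  sum(sort(r2, partial = h)[seq_len(h)])
}

# Exact LTS: enumerate every h-subset, take the least-squares fit with the
# smallest subset RSS (equivalent to the trimmed objective at the optimum).
lts_exhaustive <- function(X, y, h) {
  n <- length(y)
  subsets <- combn(n, h)
  best_obj <- Inf
  best_co <- NULL
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    fit <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
    rss <- sum(fit$residuals^2)
    if (rss < best_obj - 1e-15) {
      co <- fit$coefficients
      co[is.na(co)] <- 0
      best_obj <- rss
      best_co <- co
    }
  }
  list(coef = best_co, obj = trimmed_rss(X, y, best_co, h))
}

# FAST-LTS style concentration with deterministic starts: the full
# least-squares fit plus elemental fits through fixed x-order quantile
# triples. Each C-step refits on the h smallest squared residuals until the
# objective stops improving.
lts_concentrate <- function(X, y, h, n_starts, max_csteps) {
  n <- length(y)
  ord <- order(X[, 2])
  triple_probs <- list(c(0.05, 0.5, 0.95), c(0.25, 0.5, 0.75),
                       c(0.1, 0.45, 0.9), c(0.15, 0.6, 0.85))
  starts <- list(ols_coef(X, y))
  for (p in triple_probs[seq_len(max(0, n_starts - 1))]) {
    idx <- ord[pmax(1, ceiling(p * n))]
    starts <- c(starts, list(ols_coef(X[idx, , drop = FALSE], y[idx])))
  }
  best_obj <- Inf
  best_co <- NULL
  for (co in starts) {
    obj_prev <- Inf
    for (step in seq_len(max_csteps)) {
      r2 <- (y - drop(X %*% co))^2
      H <- order(r2)[seq_len(h)]
      co <- ols_coef(X[H, , drop = FALSE], y[H])
      obj <- trimmed_rss(X, y, co, h)
      if (obj_prev - obj < 1e-12) break
      obj_prev <- obj
    }
    obj <- trimmed_rss(X, y, co, h)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best_co <- co
    }
    if (best_obj < 1e-20) break
  }
  list(coef = best_co, obj = best_obj)
}

new_piecewise_fit <- function(knot, coef, trss, h, n, degenerate, method) {
  coef <- setNames(as.numeric(coef), c("b0", "b1", "b2"))
  segments <- tibble(
    segment = c("left", "right"),
    intercept = c(coef[["b0"]],
                  coef[["b0"]] - coef[["b2"]] * (if (is.na(knot)) 0 else knot)),
    slope = c(coef[["b1"]], coef[["b1"]] + coef[["b2"]])
  )
  structure(
    list(knot = knot, coefficients = coef, segments = segments,
         trimmed_rss = trss, h = h, n = n,
         degenerate = degenerate, method = method),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "<piecewise_fit> knot %.4g; slopes %.4g / %.4g; trimmed RSS %.4g (h = %d of %d)%s\n",
    x$knot, x$segments$slope[1], x$segments$slope[2],
    x$trimmed_rss, x$h, x$n,
    if (x$degenerate) " [degenerate: flat fallback]" else ""
  ))
  invisible(x)
}

#' @export
predict.piecewise_fit <- function(object, newdata, ...) {
  co <- object$coefficients
  t <- if (is.na(object$knot)) 0 else object$knot
  co[["b0"]] + co[["b1"]] * newdata + co[["b2"]] * pmax(newdata - t, 0)
}

#' @export
tidy.piecewise_fit <- function(x, ...) x$segments

#' Spatially normalize a target chip against a reference
#'
#' For every overlapping subarray the reference intensities are regressed on
#' the target intensities with [fit_piecewise_lts()], and target probes are
#' mapped through the fitted piecewise function onto the reference scale.
#' A probe belonging to several subarrays receives the average of its
#' adjusted values. Normalizing a chip against itself returns the chip
#' unchanged (every window fit is the identity).
#'
#' @param target,reference [probe_chip()]s with identical geometry.
#' @param config a [subsub_config()].
#' @return A [probe_chip()] with adjusted intensities and the target's
#'   probeset map.
#' @export
subsub_normalize <- function(target, reference, config = subsub_config()) {
  stopifnot(inherits(target, "probe_chip"), inherits(reference, "probe_chip"))
  if (!identical(dim(target$intensity), dim(reference$intensity))) {
    abort("target and reference chips have different geometry.")
  }
  tm <- target$intensity
  rm_ <- reference$intensity
  windows <- partition_subarrays(nrow(tm), ncol(tm), config)
  acc <- matrix(0, nrow(tm), ncol(tm))
  cnt <- matrix(0L, nrow(tm), ncol(tm))
  for (i in seq_len(nrow(windows))) {
    ri <- windows$row_start[i] + seq_len(windows$size[i])
    ci <- windows$col_start[i] + seq_len(windows$size[i])
    xs <- as.vector(tm[ri, ci])
    ys <- as.vector(rm_[ri, ci])
    fit <- fit_piecewise_lts(xs, ys, config)
    acc[ri, ci] <- acc[ri, ci] + matrix(predict(fit, xs), length(ri), length(ci))
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  if (any(cnt == 0L)) abort("internal error: window union does not cover the grid.")
  probe_chip(acc / cnt, target$probeset)
}

#' Summarize normalized chips into an expression profile
#'
#' Per probeset, fits the additive model
#' `log2 I(probe p, chip j) = mu + alpha_p + beta_j` by median polish across
#' all chips (probe effects median-constrained to zero) and reports
#' `mu + beta_j` as the probeset's expression on chip `j`. Designated
#' reference chips participate in the fit — anchoring the scale — but are
#' excluded from the returned profile. Probesets observed on fewer than two
#' probes fall back to the per-chip mean and are flagged in
#' `attr(, "flagged_probesets")`.
#'
#' @param chips named list of normalized [probe_chip()]s sharing one probeset
#'   map.
#' @param references character names of the chips serving as references.
#' @return An [expression_profile()] over the non-reference chips (sample
#'   attributes reduced to `sample_id`; join study attributes afterwards).
#' @export
summarize_ptr <- function(chips, references) {
  if (is.null(names(chips)) || any(names(chips) == "")) {
    abort("`chips` must be a named list.")
  }
  if (length(references) < 1 || !all(references %in% names(chips))) {
    abort("designate at least one reference chip present in `chips`.")
  }
  maps <- purrr::map(chips, "probeset")
  if (any(purrr::map_lgl(maps, is.null))) abort("all chips need a probeset map.")
  for (m in maps[-1]) {
    if (!identical(m, maps[[1]])) abort("chips do not share the same probeset map.")
  }
  ps <- as.vector(maps[[1]])
  intens <- vapply(chips, function(ch) as.vector(ch$intensity),
                   numeric(length(ps)))
  groups <- split(seq_along(ps), ps)
  n_chip <- length(chips)
  expr <- matrix(NA_real_, length(groups), n_chip,
                 dimnames = list(names(groups), names(chips)))
  flagged <- character(0)
  for (k in seq_along(groups)) {
    Y <- intens[groups[[k]], , drop = FALSE]
    if (nrow(Y) < 2) {
      expr[k, ] <- colMeans(Y)
      flagged <- c(flagged, names(groups)[k])
    } else {
      mp <- medpolish(Y, trace.iter = FALSE, maxiter = 20L)
      expr[k, ] <- mp$overall + mp$col
    }
  }
  keep <- setdiff(names(chips), references)
  out <- expression_profile(
    expr[, keep, drop = FALSE],
    tibble(sample_id = keep)
  )
  attr(out, "flagged_probesets") <- flagged
  out
}
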