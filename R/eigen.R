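#' Singular value decomposition of an expression profile
#'
#' Decomposes the (optionally centered) log2 matrix as
#' `E = sum_k rho_k u_k v_k'` with nonincreasing singular values `rho_k`,
#' orthonormal gene eigenvectors `u_k` (length = number of genes) and
#' orthonormal sample eigenvectors `v_k` (length = number of samples). The
#' default centers each gene (row) at its mean so that the leading components
#' describe variation across samples rather than absolute expression level;
#' the centering mode is recorded in the result. Zero-variance genes under
#' gene centering are kept as all-zero rows, not dropped.
#'
#' The decomposition is deterministic (LAPACK, no random initialization), but
#' each component's sign is arbitrary; use [fix_signs()] to anchor signs
#' against a sample attribute.
#'
#' @param profile an [expression_profile()].
#' @param centering `"gene"` (default), `"none"`, `"sample"` or `"double"`.
#' @return An `eigen_decomposition` with fields `rho`, `u`, `v`, `centering`,
#'   `samples` and sign-anchor metadata (filled by [fix_signs()]).
#' @export
eigen_decompose <- function(profile,
                            centering = c("gene", "none", "sample", "double")) {
  stopifnot(inherits(profile, "expression_profile"))
  centering <- match.arg(centering)
  E <- profile$values
  if (centering %in% c("gene", "double")) E <- E - rowMeans(E)
  if (centering %in% c("sample", "double")) E <- sweep(E, 2, colMeans(E))
  sv <- svd(E)
  dimnames(sv$u) <- list(rownames(E), NULL)
  dimnames(sv$v) <- list(colnames(E), NULL)
  structure(
    list(
      rho = sv$d,
      u = sv$u,
      v = sv$v,
      centering = centering,
      samples = profile$samples,
      anchor = rep(NA_character_, length(sv$d)),
      anchor_flagged = rep(FALSE, length(sv$d))
    ),
    class = "eigen_decomposition"
  )
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat(sprintf(
    "<eigen_decomposition> %d genes x %d samples, centering = %s\n",
    nrow(x$u), nrow(x$v), x$centering
  ))
  k <- min(3L, length(x$rho))
  pct <- contribution_percentages(x$rho)
  cat(sprintf("  rho_%d = %.4g (cumulative %.2f%%)\n",
              seq_len(k), x$rho[seq_len(k)], pct[seq_len(k)]), sep = "")
  invisible(x)
}

#' Cumulative contribution percentages of singular values
#'
#' The contribution of the top `K` components is
#' `100 * sum(rho[1:K]) / sum(rho)` — linear in the singular values, not in
#' their squares. (Equal singular values `(1,1,1,1)` therefore contribute
#' 25, 50, 75, 100 percent.) The convention is scale-invariant.
#'
#' @param rho full nonnegative, nonincreasing singular value sequence.
#' @return Numeric vector of cumulative percentages, same length as `rho`.
#' @export
contribution_percentages <- function(rho) {
  if (length(rho) == 0 || any(rho < 0)) {
    abort("`rho` must be a nonempty nonnegative sequence.")
  }
  if (any(diff(rho) > 1e-8 * max(rho))) {
    abort("`rho` must be nonincreasing.")
  }
  tot <- sum(rho)
  if (tot == 0) abort("all singular values are zero; contributions undefined.")
  100 * cumsum(rho) / tot
}

#' Anchor eigenvector signs against sample attributes
#'
#' An SVD component is unchanged when `u_k` and `v_k` flip sign together; to
#' make loadings interpretable each sample eigenvector is flipped (with its
#' gene eigenvector) so that its Spearman correlation with an anchor
#' attribute — age in weeks, the treatment indicator, a tolerance-test AUC —
#' is nonnegative. If the correlation is exactly zero (or undefined) the
#' component is instead anchored by making its largest-magnitude sample
#' loading positive, and flagged. Singular values and the reconstruction
#' `sum_k rho_k u_k v_k'` are invariant.
#'
#' @param decomposition an [eigen_decompose()] result.
#' @param anchor character vector of attribute names, recycled over
#'   components (e.g. `c("week", "diet")` to anchor component 1 by age and
#'   component 2 by diet).
#' @param components which components to anchor (default all).
#' @return The decomposition with signs fixed and anchor metadata recorded.
#' @export
fix_signs <- function(decomposition, anchor = "week",
                      components = seq_along(decomposition$rho)) {
  stopifnot(inherits(decomposition, "eigen_decomposition"))
  anchor <- rep_len(anchor, length(components))
  for (i in seq_along(components)) {
    k <- components[i]
    a <- anchor_values(decomposition$samples, anchor[i])
    ok <- !is.na(a)
    if (sum(ok) < 2) abort(sprintf("anchor `%s` present for fewer than 2 samples.", anchor[i]))
    v <- decomposition$v[, k]
    rho_s <- suppressWarnings(cor(v[ok], a[ok], method = "spearman"))
    flagged <- is.na(rho_s) || rho_s == 0
    flip <- if (flagged) v[which.max(abs(v))] < 0 else rho_s < 0
    if (flip) {
      decomposition$v[, k] <- -decomposition$v[, k]
      decomposition$u[, k] <- -decomposition$u[, k]
    }
    decomposition$anchor[k] <- anchor[i]
    decomposition$anchor_flagged[k] <- flagged
  }
  decomposition
}

# Numeric encoding of an anchor attribute; binary factors map to 0/1 with the
# treatment-like level high (HFD, Gw).
anchor_values <- function(samples, attribute) {
  if (!attribute %in% names(samples)) {
    abort(sprintf("anchor attribute `%s` not found in the sample table.", attribute))
  }
  a <- samples[[attribute]]
  if (is.numeric(a)) return(a)
  if (attribute == "diet") return(as.numeric(a == "HFD"))
  if (attribute == "subgroup") return(as.numeric(a == "Gw"))
  as.numeric(factor(a))
}

#' @rdname eigen_decompose
#' @param x an `eigen_decomposition`.
#' @param matrix which part to tidy: `"d"` (singular values and contribution
#'   percentages), `"v"` (sample loadings, joined with sample attributes) or
#'   `"u"` (gene loadings).
#' @param components which components to return for `"u"`/`"v"`.
#' @param ... unused.
#' @export
tidy.eigen_decomposition <- function(x, matrix = c("d", "v", "u"),
                                     components = seq_along(x$rho), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "d") {
    return(tibble(
      component = seq_along(x$rho),
      rho = x$rho,
      percent = 100 * x$rho / sum(x$rho),
      cum_percent = contribution_percentages(x$rho)
    ))
  }
  m <- if (matrix == "v") x$v else x$u
  id_col <- if (matrix == "v") "sample_id" else "gene_id"
  out <- purrr::map_dfr(components, function(k) {
    tibble(
      !!id_col := rownames(m),
      component = k,
      loading = m[, k]
    )
  })
  if (matrix == "v") out <- dplyr::left_join(out, x$samples, by = "sample_id")
  out
}

#' @rdname eigen_decompose
#' @export
glance.eigen_decomposition <- function(x, ...) {
  pct <- contribution_percentages(x$rho)
  tibble(
    n_genes = nrow(x$u),
    n_samples = nrow(x$v),
    centering = x$centering,
    rho_1 = x$rho[1],
    cum_percent_3 = pct[min(3L, length(pct))]
  )
}

#' Write an eigen decomposition to TSV files
#'
#' Serializes the decomposition as three TSVs (singular values with
#' contribution percentages, gene loadings, sample loadings), each preceded
#' by `# centering` / `# anchor` metadata lines.
#'
#' @param decomposition an `eigen_decomposition`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param components how many components of loadings to write.
#' @return Invisibly, the paths written.
#' @export
write_eigen_tsv <- function(decomposition, dir, prefix = "eigen",
                            components = seq_along(decomposition$rho)) {
  stopifnot(inherits(decomposition, "eigen_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c(
    sprintf("# centering: %s", decomposition$centering),
    sprintf("# anchor: %s", paste(decomposition$anchor, collapse = ","))
  )
  write_one <- function(tab, name) {
    path <- file.path(dir, sprintf("%s_%s.tsv", prefix, name))
    writeLines(header, path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
    path
  }
  paths <- c(
    write_one(tidy(decomposition, "d"), "values"),
    write_one(tidy(decomposition, "u", components = components), "gene_loadings"),
    write_one(tidy(decomposition, "v", components = components), "sample_loadings")
  )
  invisible(paths)
}
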