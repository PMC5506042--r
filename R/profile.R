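#' Expression profile container
#'
#' An `expression_profile` couples a log2-scale gene-by-sample matrix with a
#' per-sample attribute table. Attributes follow the study design the package
#' targets: a binary diet factor (`RC` control vs `HFD` treatment), an ordinal
#' `week` (age at sacrifice), optional glucose/insulin tolerance AUC values
#' (`gtt_auc`, `itt_auc`) and an optional `subgroup` label (`Gb`/`Gw`).
#'
#' Missing expression values are refused outright: downstream eigen-analysis
#' assumes a complete matrix and silent imputation would change its meaning.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), log2 scale.
#' @param samples data frame with at least a `sample_id` column covering every
#'   column of `values`. Extra columns are kept as attributes.
#' @return An `expression_profile` object.
#' @export
expression_profile <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  if (anyNA(values)) {
    abort("expression matrix contains missing values; imputation is refused, fix the input.")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    abort(paste0("duplicated gene id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicated sample ids in expression matrix.")
  }
  samples <- as_tibble(samples)
  if (!"sample_id" %in% names(samples)) {
    abort("`samples` must have a `sample_id` column.")
  }
  missing <- setdiff(colnames(values), samples$sample_id)
  if (length(missing) > 0) {
    abort(paste0("attribute rows missing for sample(s): ", paste(missing, collapse = ", ")))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  structure(
    list(values = values, samples = samples),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf(
    "<expression_profile> %d genes x %d samples (log2 scale)\n",
    nrow(x$values), ncol(x$values)
  ))
  cat("sample attributes: ", paste(names(x$samples), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_profile <- function(x) dim(x$values)

#' Subset an expression profile by sample attributes
#'
#' Filters the samples of a profile with dplyr-style conditions evaluated on
#' the attribute table, e.g. `subset_samples(profile, diet == "RC")` for the
#' control-only profile of the dual analysis.
#'
#' @param profile an [expression_profile()].
#' @param ... conditions passed to [dplyr::filter()] on the attribute table.
#' @return A new `expression_profile` restricted to the matching samples.
#' @export
subset_samples <- function(profile, ...) {
  stopifnot(inherits(profile, "expression_profile"))
  kept <- dplyr::filter(profile$samples, ...)
  if (nrow(kept) == 0) abort("no samples left after filtering.")
  expression_profile(profile$values[, kept$sample_id, drop = FALSE], kept)
}

#' Read an expression profile from TSV files
#'
#' The expression file has a `gene_id` column followed by one numeric column
#' per sample; the attribute file has `sample_id`, `diet`, `week` and any
#' further per-sample columns. Values are expected on the log2 scale already.
#'
#' @param path TSV of expression values.
#' @param attr_path TSV of sample attributes.
#' @return An [expression_profile()].
#' @export
read_expression_tsv <- function(path, attr_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1] != "gene_id") abort("first column of the expression TSV must be `gene_id`.")
  genes <- tab$gene_id
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric expression cells found.")
  rownames(m) <- genes
  attrs <- readr::read_tsv(attr_path, show_col_types = FALSE)
  expression_profile(m, attrs)
}

#' Write an expression profile to TSV files
#'
#' @param profile an [expression_profile()].
#' @param path output TSV for the matrix.
#' @param attr_path output TSV for sample attributes.
#' @return `profile`, invisibly.
#' @export
write_expression_tsv <- function(profile, path, attr_path) {
  stopifnot(inherits(profile, "expression_profile"))
  tab <- dplyr::bind_cols(
    tibble(gene_id = rownames(profile$values)),
    as_tibble(profile$values)
  )
  readr::write_tsv(tab, path)
  readr::write_tsv(profile$samples, attr_path)
  invisible(profile)
}
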