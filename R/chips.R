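#' Probe chip container
#'
#' Holds a 2-D grid of probe intensities on the log2 scale together with an
#' optional probeset map (one probeset id per grid cell; the arrays this
#' package targets carry 11 probes per probeset on a 1002 x 1002 grid).
#'
#' @param intensity numeric matrix of log2 intensities.
#' @param probeset optional character matrix of probeset ids, same geometry.
#' @return A `probe_chip` object.
#' @export
probe_chip <- function(intensity, probeset = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric matrix.")
  }
  if (anyNA(intensity)) abort("probe intensities contain missing values.")
  if (!is.null(probeset)) {
    if (!is.matrix(probeset) || !identical(dim(probeset), dim(intensity))) {
      abort("`probeset` map must be a character matrix matching the intensity grid.")
    }
  }
  structure(list(intensity = intensity, probeset = probeset), class = "probe_chip")
}

#' @export
print.probe_chip <- function(x, ...) {
  cat(sprintf(
    "<probe_chip> %d x %d probes%s\n",
    nrow(x$intensity), ncol(x$intensity),
    if (is.null(x$probeset)) "" else
      sprintf(", %d probesets", length(unique(as.vector(x$probeset))))
  ))
  invisible(x)
}

#' @export
dim.probe_chip <- function(x) dim(x$intensity)

#' Read a probe chip from long-form TSV
#'
#' The file has columns `row`, `col` (0-based grid coordinates),
#' `probeset_id` and `intensity` (raw scale). Intensities are floored at 1.0
#' and log2-transformed at load; all downstream fitting is on the log2 scale.
#'
#' @param path TSV path.
#' @return A [probe_chip()].
#' @export
read_chip_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("row", "col", "probeset_id", "intensity")
  if (!all(need %in% names(tab))) {
    abort(paste0("chip TSV must have columns: ", paste(need, collapse = ", ")))
  }
  nr <- max(tab$row) + 1L
  nc <- max(tab$col) + 1L
  if (nrow(tab) != nr * nc) abort("chip TSV does not cover a full grid.")
  idx <- cbind(tab$row + 1L, tab$col + 1L)
  m <- matrix(NA_real_, nr, nc)
  m[idx] <- log2(pmax(tab$intensity, 1))
  ps <- matrix(NA_character_, nr, nc)
  ps[idx] <- tab$probeset_id
  probe_chip(m, ps)
}

#' Write a probe chip to long-form TSV
#'
#' Inverse of [read_chip_tsv()]: intensities are written back on the raw
#' scale (`2^log2`), coordinates 0-based.
#'
#' @param chip a [probe_chip()].
#' @param path output TSV path.
#' @return `chip`, invisibly.
#' @export
write_chip_tsv <- function(chip, path) {
  stopifnot(inherits(chip, "probe_chip"))
  nr <- nrow(chip$intensity)
  nc <- ncol(chip$intensity)
  ps <- chip$probeset %||% matrix(NA_character_, nr, nc)
  tab <- tibble(
    row = rep(seq_len(nr) - 1L, times = nc),
    col = rep(seq_len(nc) - 1L, each = nr),
    probeset_id = as.vector(ps),
    intensity = 2^as.vector(chip$intensity)
  )
  readr::write_tsv(tab, path)
  invisible(chip)
}
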