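#' Gene set collection
#'
#' Named gene sets scored against a fixed gene universe. Members are
#' deduplicated; scoring later intersects each set with the universe and
#' applies a minimum effective size.
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe character vector of all gene ids (the profile's genes).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(universe) == 0) abort("empty gene universe.")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("all gene sets must be named.")
  }
  if (anyDuplicated(names(sets))) abort("duplicated gene set names.")
  sets <- purrr::map(sets, unique)
  structure(list(sets = sets, universe = unique(universe)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited format: set name, description, then member ids.
#'
#' @param path GMT file path.
#' @param universe gene universe to attach.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- purrr::map_int(parts, length) < 3
  if (any(bad)) abort("malformed GMT line (need name, description, >= 1 member).")
  sets <- purrr::map(parts, function(p) p[-(1:2)])
  names(sets) <- purrr::map_chr(parts, 1)
  gene_set_collection(sets, universe)
}

#' Write gene sets to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param description description field written for every set.
#' @return Invisibly, `collection`.
#' @export
write_gmt <- function(collection, path, description = "synthetic") {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- purrr::imap_chr(collection$sets, function(members, name) {
    paste(c(name, description, members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(collection)
}

#' Wilcoxon rank-scoring of a gene set at one end of sorted loadings
#'
#' Ranks all gene loadings ascending (midranks for ties) and tests whether
#' the set's members concentrate at the requested end: `end = "low"` tests
#' for small ranks (one-sided p = probability of a rank-sum at most the
#' observed one under uniform placement), `end = "high"` the mirror image.
#' Because ranks simply reverse when the sort order flips, up-enrichment at
#' one end equals down-enrichment at the other: `p_low(u)` equals
#' `p_high(-u)` exactly. The p-value is exact (rank-sum null recursion) when
#' the set and universe are small and the loadings are tie-free; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' Only ranks matter, so any strictly monotone transform of the loadings
#' gives identical results.
#'
#' @param u named numeric vector of gene loadings (the universe).
#' @param members character vector of member gene ids, a nonempty proper
#'   subset of the universe.
#' @param end `"low"` or `"high"`.
#' @param exact_max_m,exact_max_g exact-path thresholds on set and universe
#'   size.
#' @return One-row tibble: `statistic` (member rank-sum), `p_value`, `end`,
#'   `m` (effective set size), `method`.
#' @export
wilcoxon_score <- function(u, members, end = c("high", "low"),
                           exact_max_m = 10, exact_max_g = 1000) {
  end <- match.arg(end)
  if (is.null(names(u))) abort("`u` must be named by gene id.")
  members <- unique(members)
  if (!all(members %in% names(u))) {
    abort("gene set members outside the loading universe.")
  }
  g <- length(u)
  m <- length(members)
  if (m == 0 || m == g) {
    abort("set must be a nonempty proper subset of the universe.")
  }
  r <- rank(u)  # ascending midranks
  S <- sum(r[members])
  n <- g - m
  ties <- anyDuplicated(u) > 0
  if (!ties && m <= exact_max_m && g <= exact_max_g) {
    W <- S - m * (m + 1) / 2
    p <- if (end == "low") {
      pwilcox(W, m, n)
    } else {
      # symmetry of the rank-sum null about m*n/2
      pwilcox(m * n - W, m, n)
    }
    method <- "exact"
  } else {
    mu <- m * (g + 1) / 2
    nties <- table(r)
    sigma <- sqrt((m * n / 12) * ((g + 1) - sum(nties^3 - nties) / (g * (g - 1))))
    z <- if (end == "low") (S + 0.5 - mu) / sigma else (mu - S + 0.5) / sigma
    p <- pnorm(z)
    method <- "normal"
  }
  tibble(statistic = S, p_value = min(max(p, 0), 1), end = end,
         m = m, method = method)
}

#' Score a gene-set collection at both ends of sorted loadings
#'
#' Applies [wilcoxon_score()] at both ends for every set whose effective size
#' (members present in the universe, deduplicated) reaches `min_size`. The
#' reported p-value per set is the better end, Bonferroni-adjusted by the
#' number of sets scored; rows are sorted by adjusted p, ties broken by set
#' name.
#'
#' @param u named numeric vector of gene loadings.
#' @param collection a [gene_set_collection()] over the same universe.
#' @param min_size smallest effective set size scored.
#' @param exact_max_m,exact_max_g passed to [wilcoxon_score()].
#' @return Tibble: `set`, `m`, `statistic`, `p_low`, `p_high`, `end`
#'   (better end), `p_value`, `p_adjusted`, `method`.
#' @export
enrich_collection <- function(u, collection, min_size = 5,
                              exact_max_m = 10, exact_max_g = 1000) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- purrr::map(collection$sets, function(s) intersect(s, names(u)))
  sets <- sets[purrr::map_int(sets, length) >= min_size]
  if (length(sets) == 0) abort("no gene set reaches `min_size` in this universe.")
  M <- length(sets)
  rows <- purrr::imap_dfr(sets, function(members, name) {
    lo <- wilcoxon_score(u, members, "low", exact_max_m, exact_max_g)
    hi <- wilcoxon_score(u, members, "high", exact_max_m, exact_max_g)
    better <- if (hi$p_value <= lo$p_value) hi else lo
    tibble(
      set = name, m = better$m, statistic = better$statistic,
      p_low = lo$p_value, p_high = hi$p_value,
      end = better$end, p_value = better$p_value,
      p_adjusted = min(1, better$p_value * M),
      method = better$method
    )
  })
  dplyr::arrange(rows, .data$p_adjusted, .data$set)
}
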