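#' Position weight matrix
#'
#' Wraps a position frequency (count) matrix over `{A, C, G, T}` with a
#' per-cell pseudocount and a background composition. Column frequencies are
#' normalized to sum to one after the pseudocount; scanning uses the log2
#' odds of frequency over background, floored at `score_floor` bits so a
#' zero-pseudocount matrix stays finite.
#'
#' @param counts 4-row numeric matrix, rows named `A`, `C`, `G`, `T`.
#' @param id motif identifier.
#' @param pseudocount added to every cell before normalization.
#' @param background length-4 background composition (sums to 1).
#' @param score_floor lower bound on a per-position log-odds (bits).
#' @return A `pwm` object with elements `id`, `counts`, `prob`, `log_odds`,
#'   `background`, `width`.
#' @export
pwm <- function(counts, id = "motif", pseudocount = 0.01,
                background = rep(0.25, 4), score_floor = -30) {
  if (!is.matrix(counts) || nrow(counts) != 4) {
    abort("`counts` must be a 4-row matrix (A, C, G, T).")
  }
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  if (!identical(rownames(counts), c("A", "C", "G", "T"))) {
    abort("rows must be named A, C, G, T in that order.")
  }
  if (any(counts < 0)) abort("counts must be nonnegative.")
  if (abs(sum(background) - 1) > 1e-8 || any(background <= 0)) {
    abort("`background` must be positive and sum to 1.")
  }
  prob <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  lo <- pmax(log2(prob / background), score_floor)
  structure(
    list(id = id, counts = counts, prob = prob, log_odds = lo,
         background = background, width = ncol(counts)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n",
              x$id, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x a [pwm()].
#' @return Single string of the per-column most probable bases.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste0(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = "")
}

#' Build a sharply peaked PWM from a consensus sequence
#'
#' @param consensus string over `ACGT`.
#' @param id motif identifier.
#' @param dominance fraction of counts on the consensus base per column.
#' @param total total counts per column.
#' @param ... passed to [pwm()].
#' @return A [pwm()].
#' @export
pwm_from_consensus <- function(consensus, id = consensus, dominance = 0.97,
                               total = 100, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) abort("consensus must be over ACGT.")
  counts <- matrix((1 - dominance) * total / 3, 4, length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, rownames(counts)), seq_along(bases))] <- dominance * total
  pwm(counts, id = id, ...)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the 4-row count format (`>id name` header, then `A [ ... ]` etc.,
#' brackets optional). Several motifs per file are supported.
#'
#' @param path PFM text file.
#' @param ... passed to [pwm()] (pseudocount, background).
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar_pfm <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort("no JASPAR header line (starting with `>`) found.")
  out <- purrr::map(seq_along(heads), function(i) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) < 4) abort("JASPAR record with fewer than 4 matrix rows.")
    rows <- purrr::map(block[1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    if (length(unique(purrr::map_int(rows, length))) != 1) {
      abort("JASPAR matrix rows have unequal lengths.")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    pwm(counts, id = id, ...)
  })
  names(out) <- purrr::map_chr(out, "id")
  out
}

#' Write PWMs in JASPAR text format
#'
#' @param pwms a [pwm()] or list of them.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- purrr::map(pwms, function(p) {
    c(paste0(">", p$id),
      purrr::map_chr(1:4, function(r) {
        sprintf("%s [ %s ]", rownames(p$counts)[r],
                paste(format(p$counts[r, ], trim = TRUE), collapse = " "))
      }))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write promoter sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_promoters_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# Exact null distribution of the per-position log-odds score under the
# background model, by column-wise convolution on a discretized (1e-3 bit)
# score grid. Returns a function giving P(score >= s).
pwm_null_tail <- function(x) {
  dist_key <- as.integer(round(x$log_odds[1:4, 1] * 1000))
  dist <- rowsum(x$background, dist_key)
  for (j in seq_len(x$width)[-1]) {
    add_key <- as.integer(round(x$log_odds[1:4, j] * 1000))
    new_key <- as.vector(outer(as.integer(rownames(dist)), add_key, "+"))
    new_p <- as.vector(outer(dist[, 1], x$background))
    dist <- rowsum(new_p, new_key)
  }
  scores <- as.numeric(rownames(dist)) / 1000
  o <- order(scores)
  scores <- scores[o]
  tailp <- rev(cumsum(rev(dist[o, 1])))
  function(s) {
    idx <- findInterval(s - 5e-4, scores) + 1
    ifelse(idx > length(scores), 0, tailp[pmin(idx, length(scores))])
  }
}

#' Scan promoters with a PWM and derive binding-affinity profiles
#'
#' For each gene the best log2-odds score over all positions on both strands
#' is found (`N` bases score as background, zero log-odds). The per-position
#' significance `P(null >= best)` is computed from the exact background null
#' of a single position, combined over the `2 * (L - W + 1)` scanned
#' positions as `1 - (1 - p)^n_pos`, and transformed to a binding strength
#' `-log10(combined)` — monotone decreasing in the combined significance.
#' Sequences shorter than the motif get strength 0 and are flagged.
#'
#' @param promoters named character vector of sequences over `ACGTN` (or a
#'   `DNAStringSet`).
#' @param x a [pwm()].
#' @return An `affinity_profile` tibble: `gene_id`, `best_score`,
#'   `p_position`, `p_combined`, `strength`, plus `motif_id` attribute.
#' @export
scan_pwm_affinity <- function(promoters, x) {
  stopifnot(inherits(x, "pwm"))
  if (!is.character(promoters)) {
    promoters <- setNames(as.character(promoters), names(promoters))
  }
  if (length(promoters) == 0) abort("no promoter sequences supplied.")
  if (is.null(names(promoters))) abort("promoters must be named by gene id.")
  seqs <- toupper(promoters)
  if (any(grepl("[^ACGTN]", seqs))) {
    abort("invalid alphabet: promoter sequences may only contain A, C, G, T, N.")
  }
  W <- x$width
  # 5-row lookup: ACGT log-odds plus an all-zero N row
  LO <- rbind(x$log_odds, N = 0)
  LO_rc <- rbind(x$log_odds[4:1, W:1, drop = FALSE], N = 0)
  tail_fun <- pwm_null_tail(x)

  lens <- nchar(seqs)
  best <- setNames(rep(-Inf, length(seqs)), names(seqs))
  npos <- setNames(2 * pmax(lens - W + 1, 0), names(seqs))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

  for (L in unique(lens[lens >= W])) {
    sel <- which(lens == L)
    mat <- matrix(code[unlist(strsplit(seqs[sel], ""), use.names = FALSE)],
                  nrow = length(sel), byrow = TRUE)
    n_off <- L - W + 1
    for (lo_mat in list(LO, LO_rc)) {
      acc <- matrix(0, length(sel), n_off)
      for (k in seq_len(W)) {
        block <- mat[, k:(k + n_off - 1), drop = FALSE]
        acc <- acc + matrix(lo_mat[cbind(as.vector(block), k)],
                            nrow = length(sel))
      }
      best[sel] <- pmax(best[sel], apply(acc, 1, max))
    }
  }
  short <- lens < W
  p_pos <- rep(1, length(seqs))
  p_pos[!short] <- tail_fun(best[!short])
  p_comb <- 1 - (1 - p_pos)^pmax(npos, 1)
  strength <- -log10(pmax(p_comb, 1e-300))
  strength[short] <- 0
  out <- tibble(
    gene_id = names(seqs),
    best_score = unname(ifelse(short, NA_real_, best)),
    p_position = unname(p_pos),
    p_combined = unname(p_comb),
    strength = unname(strength),
    flagged_short = unname(short)
  )
  attr(out, "motif_id") <- x$id
  class(out) <- c("affinity_profile", class(out))
  out
}

#' Maximum running-sum association between affinities and sorted loadings
#'
#' Orders genes by a per-gene statistic (descending), accumulates the
#' mean-centered binding affinities along that order, and takes the maximum
#' absolute running sum as the association score; the end (`head` or `tail`)
#' records where affinity concentrates. Significance is an add-one
#' permutation p-value over uniform shuffles of the affinity profile:
#' `p = (1 + #{permuted >= observed}) / (n_perm + 1)`, which is valid by
#' construction. Reversing the sort direction leaves the score unchanged and
#' swaps the end; a constant affinity profile scores 0 with p = 1.
#'
#' @param stat named numeric per-gene statistic (e.g. gene eigenvector
#'   loadings).
#' @param affinity an `affinity_profile` from [scan_pwm_affinity()] or a
#'   named numeric vector of strengths covering the same genes.
#' @param n_perm number of permutations (at least 99).
#' @param seed integer seed for the permutation null.
#' @return One-row tibble: `motif_id`, `score`, `position` (index of the
#'   maximum along the sorted list), `end`, `p_value`, `n_perm`.
#' @export
base_association <- function(stat, affinity, n_perm = 999, seed = 1) {
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  motif_id <- attr(affinity, "motif_id") %||% "affinity"
  if (is.data.frame(affinity)) {
    affinity <- setNames(affinity$strength, affinity$gene_id)
  }
  if (is.null(names(stat)) || is.null(names(affinity))) {
    abort("`stat` and `affinity` must be named by gene id.")
  }
  if (!setequal(names(stat), names(affinity))) {
    abort("affinity profile does not cover the gene universe of `stat`.")
  }
  w_all <- affinity[names(stat)]
  ord <- order(stat, decreasing = TRUE)
  w <- w_all[ord] - mean(w_all)
  if (max(abs(w)) < 1e-15) {
    return(tibble(motif_id = motif_id, score = 0, position = NA_integer_,
                  end = NA_character_, p_value = 1, n_perm = n_perm))
  }
  R <- cumsum(w)
  i_max <- which.max(abs(R))
  score <- abs(R[i_max])
  end <- if (R[i_max] >= 0) "head" else "tail"
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) max(abs(cumsum(sample(w)))),
           numeric(1))
  })
  p <- (1 + sum(perm >= score - 1e-12)) / (n_perm + 1)
  tibble(motif_id = motif_id, score = unname(score),
         position = as.integer(i_max), end = end,
         p_value = p, n_perm = n_perm)
}
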