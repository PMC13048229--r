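## Exact global pairwise alignment and a center-star MSA heuristic.
##
## This is the in-repo replacement for an external exact global aligner and
## for external MSA tools, so the whole evaluation pipeline runs without
## third-party binaries. Scoring is IUPAC-aware: identical codes score
## `match`, distinct-but-compatible codes (sets intersect, e.g. Y vs C)
## score `compatible`, disjoint codes score `mismatch`; gaps are linear.

#' Alignment scoring scheme
#'
#' Linear-gap scoring used by [global_align()] and [center_star_msa()].
#' `compatible` rewards pairings of distinct IUPAC codes that share a
#' nucleotide (so a consensus `Y` aligns onto a reference `C` rather than
#' being pushed into a gap); it must satisfy
#' `match >= compatible > mismatch` and `gap < 0`.
#'
#' @param match score for identical characters (default 2).
#' @param compatible score for distinct but intersecting IUPAC codes
#'   (default 1).
#' @param mismatch score for disjoint codes (default -1).
#' @param gap per-character gap penalty, negative (default -2).
#' @return an object of class `msab_scoring`.
#' @examples
#' scoring()
#' scoring(match = 3, gap = -4)
#' @export
scoring <- function(match = 2, compatible = 1, mismatch = -1, gap = -2) {
  stopifnot(match >= compatible, compatible > mismatch, gap < 0)
  structure(list(match = as.integer(match), compatible = as.integer(compatible),
                 mismatch = as.integer(mismatch), gap = as.integer(gap)),
            class = "msab_scoring")
}

as_scoring <- function(x) {
  if (inherits(x, "msab_scoring")) x else do.call(scoring, as.list(x))
}

# sequence string -> integer mask vector, with position-aware error message
seq_masks <- function(x, what = "sequence") {
  if (nchar(x) == 0L) return(integer(0))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  up <- toupper(chars)
  up[up == "U"] <- "T"
  m <- .IUPAC_MASK[up]
  if (anyNA(m)) {
    i <- which(is.na(m))[1L]
    stop(sprintf("non-IUPAC character %s at position %d of %s",
                 sQuote(chars[i]), i, what))
  }
  unname(m)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch alignment of two IUPAC sequences end to end, with a
#' linear gap penalty. The score is the global optimum under `scoring`;
#' traceback ties are broken deterministically (diagonal, then gap in `b`,
#' then gap in `a`). Either sequence may be empty.
#'
#' @param a,b sequences (single strings over the IUPAC alphabet).
#' @param sc a [scoring()] object.
#' @return a list of class `msab_alignment` with elements `gapped_a`,
#'   `gapped_b` (equal-length gapped strings), `score` and `columns`.
#' @examples
#' global_align("ACGT", "AGT")
#' @export
global_align <- function(a, b, sc = scoring()) {
  sc <- as_scoring(sc)
  am <- seq_masks(a, "first sequence")
  bm <- seq_masks(b, "second sequence")
  res <- .nw_align_masks(am, bm, sc$match, sc$compatible, sc$mismatch, sc$gap)
  ops <- res$ops
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  ga <- gb <- character(length(ops))
  ia <- ib <- 0L
  consume_a <- ops != 2L
  consume_b <- ops != 1L
  ga[consume_a] <- ac[seq_len(sum(consume_a))]
  ga[!consume_a] <- "-"
  gb[consume_b] <- bc[seq_len(sum(consume_b))]
  gb[!consume_b] <- "-"
  structure(list(gapped_a = paste(ga, collapse = ""),
                 gapped_b = paste(gb, collapse = ""),
                 score = res$score, columns = length(ops)),
            class = "msab_alignment")
}

#' @export
print.msab_alignment <- function(x, ...) {
  cat("Global alignment:", x$columns, "columns, score", x$score, "\n")
  cat(" ", x$gapped_a, "\n ", x$gapped_b, "\n", sep = "")
  invisible(x)
}

# number of gaps in `gapped` before each position of its ungapped sequence,
# slots 1..L+1 (slot L+1 = trailing gaps)
gap_slots <- function(gapped) {
  chars <- strsplit(gapped, "", fixed = TRUE)[[1]]
  L <- sum(chars != "-")
  slots <- integer(L + 1L)
  slot <- 1L
  for (ch in chars) {
    if (ch == "-") slots[slot] <- slots[slot] + 1L else slot <- slot + 1L
  }
  slots
}

#' Center-star multiple sequence alignment
#'
#' Built-in MSA heuristic standing in for external MSA tools: picks the
#' center sequence maximising the summed pairwise alignment score to all
#' others (exact all-pairs selection up to `max_exact_center` sequences,
#' first sequence beyond that), aligns every other sequence to the center
#' with [global_align()], and merges the pairwise alignments by the "once a
#' gap in the center, always a gap" rule.
#'
#' @param seqs character vector of at least 2 sequences (optionally named).
#' @param sc a [scoring()] object.
#' @param max_exact_center cap on the quadratic all-pairs center search
#'   (default 50).
#' @return an [msa()] object whose gap-stripped rows equal `seqs`.
#' @examples
#' center_star_msa(c("ACGT", "ACGT", "ACT"))
#' @export
center_star_msa <- function(seqs, sc = scoring(), max_exact_center = 50L) {
  if (length(seqs) < 2L) stop("center_star_msa needs at least 2 sequences")
  sc <- as_scoring(sc)
  n <- length(seqs)
  if (n <= max_exact_center) {
    tot <- numeric(n)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      s <- global_align(seqs[i], seqs[j], sc)$score
      tot[i] <- tot[i] + s
      tot[j] <- tot[j] + s
    }
    center <- which.max(tot)
  } else {
    center <- 1L
  }
  others <- setdiff(seq_len(n), center)
  alns <- lapply(seqs[others], function(s) global_align(seqs[center], s, sc))
  L <- nchar(seqs[center])
  ins <- lapply(alns, function(al) gap_slots(al$gapped_a))
  master <- Reduce(pmax, ins, integer(L + 1L))

  # re-space one gapped row (aligned against the center) onto the master
  # gap pattern: in each slot, pad missing gaps on the left
  respace <- function(gapped_other, slots) {
    chars <- strsplit(gapped_other, "", fixed = TRUE)[[1]]
    out <- character(0)
    k <- 0L
    for (slot in seq_len(L + 1L)) {
      take <- slots[slot] + (slot <= L)
      piece <- if (take > 0L) chars[k + seq_len(take)] else character(0)
      k <- k + take
      out <- c(out, rep("-", master[slot] - slots[slot]), piece)
    }
    paste(out, collapse = "")
  }

  rows <- character(n)
  rows[center] <- respace(seqs[center], integer(L + 1L))
  for (k in seq_along(others))
    rows[others[k]] <- respace(alns[[k]]$gapped_b, ins[[k]])
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(n))
  msa(rows, row_ids = ids)
}
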