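## Per-column IUPAC threshold consensus, and the metaconsensus of several
## tools' consensus sequences.
##
## Column rule: if the gap is strictly the most frequent character the
## column yields '-'. Otherwise nucleotides are taken in descending count
## order, whole tie-groups at a time (a tie never depends on an arbitrary
## order), until the accumulated count divided by the column total (gaps
## included in the denominator) reaches the threshold; the accumulated set
## is emitted as its IUPAC code. A diploid site covered 50/50 by two
## alleles thus becomes the 2-nucleotide ambiguity code at any threshold
## above 50% and up to 100%.

#' Consensus character of one MSA column
#'
#' Applies the threshold rule to a single column given its character
#' counts. Counts may be fractional (meta-MSA columns distribute each
#' ambiguity code's unit weight over its nucleotides).
#'
#' @param counts named numeric vector of non-negative counts over
#'   `A`,`C`,`G`,`T`,`-` (missing names count as zero).
#' @param threshold minimal appearance rate in `(0, 1]` for the accumulated
#'   nucleotides to be accepted (default 0.7).
#' @return a single character: an IUPAC code or `"-"`.
#' @examples
#' column_consensus(c(A = 3, C = 1, `-` = 1), 0.7)  # "M"
#' column_consensus(c(`-` = 3, A = 2), 0.7)         # "-"
#' @export
column_consensus <- function(counts, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (length(counts) == 0L || total <= 0) stop("empty column")
  bad <- setdiff(names(counts), c("A", "C", "G", "T", "-"))
  if (length(bad))
    stop("column counts must be over A,C,G,T,-; got ",
         paste(sQuote(bad), collapse = ", "))
  gapn <- if ("-" %in% names(counts)) counts[["-"]] else 0
  nuc <- counts[names(counts) != "-"]
  if (length(nuc) == 0L) return("-")
  if (gapn > max(nuc)) return("-")  # gap strictly most frequent
  acc <- character(0)
  cum <- 0
  for (v in sort(unique(unname(nuc)), decreasing = TRUE)) {
    grp <- names(nuc)[nuc == v]   # whole tie-group at once
    acc <- c(acc, grp)
    cum <- cum + v * length(grp)
    if (cum / total >= threshold) break
  }
  symbol_for_set(acc)
}

# per-column counts of an MSA as a 5 x n_cols matrix (rows A,C,G,T,-).
# Ambiguity codes in rows (meta-MSA) contribute 1/|set| to each of their
# nucleotides so every column still sums to n_rows.
msa_column_counts <- function(m) {
  cm <- msa_matrix(m)
  counts <- matrix(0, nrow = 5L, ncol = m$n_cols,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (ch in unique(as.vector(cm))) {
    hits <- colSums(cm == ch)
    if (ch == "-") {
      counts["-", ] <- counts["-", ] + hits
    } else {
      set <- iupac_set(ch)
      for (nt in set) counts[nt, ] <- counts[nt, ] + hits / length(set)
    }
  }
  counts
}

#' IUPAC threshold consensus of an MSA
#'
#' Applies [column_consensus()] to every column, left to right, and
#' returns both the gapped consensus (one character per MSA column) and
#' the ungapped consensus (gaps deleted; its length is the "consensus
#' size" metric).
#'
#' @param m an [msa()] object.
#' @param threshold minimal appearance rate in `(0, 1]` (default 0.7, the
#'   setting that lets a balanced diploid site surface as its ambiguity
#'   code).
#' @return an object of class `msab_consensus` with fields `gapped`,
#'   `ungapped` and `threshold`.
#' @examples
#' m <- msa(c("AC-T", "AC-T", "ACGT"))
#' msa_consensus(m, 0.7)
#' @export
msa_consensus <- function(m, threshold = 0.7) {
  stopifnot(inherits(m, "msab_msa"), threshold > 0, threshold <= 1)
  counts <- msa_column_counts(m)
  gapped <- vapply(seq_len(m$n_cols),
                   function(j) column_consensus(counts[, j], threshold),
                   character(1))
  gapped <- paste(gapped, collapse = "")
  structure(list(gapped = gapped,
                 ungapped = gsub("-", "", gapped, fixed = TRUE),
                 threshold = threshold,
                 n_rows = m$n_rows, n_cols = m$n_cols),
            class = "msab_consensus")
}

#' @export
print.msab_consensus <- function(x, ...) {
  cat(sprintf("Consensus (threshold %.0f%%, %d rows, %d columns):\n",
              100 * x$threshold, x$n_rows, x$n_cols))
  cat(" gapped:  ", x$gapped, "\n ungapped:", x$ungapped, "\n")
  invisible(x)
}

#' Metaconsensus of several consensus sequences
#'
#' Builds a "meta-MSA" of the (ungapped, possibly IUPAC-containing)
#' consensus sequences produced by different MSA tools and derives a
#' consensus of consensuses from it. Ambiguity codes in the inputs keep
#' their meaning: each contributes fractionally to its nucleotides during
#' column counting.
#'
#' @param consensi character vector of at least 2 ungapped IUPAC sequences.
#' @param threshold consensus threshold (default 0.7).
#' @param aligner function turning a character vector of sequences into an
#'   [msa()] (default the built-in [center_star_msa()]).
#' @param sc [scoring()] passed to the default aligner.
#' @return an object of class `msab_consensus`.
#' @examples
#' metaconsensus(c("ACGT", "ACGT", "ACAT"), 0.7)
#' @export
metaconsensus <- function(consensi, threshold = 0.7,
                          aligner = NULL, sc = scoring()) {
  if (length(consensi) < 2L)
    stop("metaconsensus needs at least 2 consensus sequences")
  if (is.null(aligner)) aligner <- function(s) center_star_msa(s, sc)
  msa_consensus(aligner(consensi), threshold)
}

#' Write a consensus as FASTA with a JSON sidecar
#'
#' Writes the ungapped consensus as a single-record FASTA and its metadata
#' (threshold, MSA dimensions) as a `.json` sidecar next to it.
#'
#' @param cons an `msab_consensus` object.
#' @param path output FASTA path.
#' @param id FASTA record id.
#' @export
write_consensus <- function(cons, path, id = "consensus") {
  write_fasta(stats::setNames(cons$ungapped, id), path)
  meta <- list(threshold = cons$threshold, n_rows = cons$n_rows,
               n_cols = cons$n_cols, consensus_size = nchar(cons$ungapped))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
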