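## Rectangular MSA container plus aligned-FASTA I/O (via Biostrings).

#' Multiple sequence alignment container
#'
#' A rectangular block of equal-length gapped rows over \{A,C,G,T,-\}.
#' IUPAC ambiguity codes are permitted in rows when the MSA is built from
#' consensus sequences (a meta-MSA). No row may be all gaps.
#'
#' @param rows character vector of equal-length gapped strings.
#' @param row_ids row identifiers (default `seq1`, `seq2`, ...).
#' @return an object of class `msab_msa` with fields `rows`, `row_ids`,
#'   `n_rows`, `n_cols`.
#' @examples
#' msa(c("AC-T", "ACGT"))
#' @export
msa <- function(rows, row_ids = NULL) {
  rows <- toupper(as.character(rows))
  if (length(rows) < 1L) stop("an MSA needs at least one row")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("MSA rows must all have the same length; got widths ",
         paste(unique(widths), collapse = ", "))
  if (widths[1L] == 0L) stop("MSA rows must be non-empty")
  if (any(vapply(rows, function(r) all(strsplit(r, "")[[1]] == "-"), TRUE)))
    stop("an MSA row is all gaps")
  bad <- setdiff(unique(unlist(strsplit(rows, ""))), c(iupac_codes(), "-"))
  if (length(bad))
    stop("invalid MSA character(s): ", paste(sQuote(bad), collapse = ", "))
  if (is.null(row_ids)) row_ids <- sprintf("seq%d", seq_along(rows))
  stopifnot(length(row_ids) == length(rows))
  structure(list(rows = unname(rows), row_ids = as.character(row_ids),
                 n_rows = length(rows), n_cols = widths[1L]),
            class = "msab_msa")
}

#' @export
print.msab_msa <- function(x, ...) {
  cat(sprintf("MSA: %d rows x %d columns\n", x$n_rows, x$n_cols))
  show <- utils::head(seq_len(x$n_rows), 8L)
  for (i in show)
    cat(sprintf(" %-12s %s\n", x$row_ids[i],
                if (x$n_cols > 60) paste0(substr(x$rows[i], 1, 57), "...")
                else x$rows[i]))
  if (x$n_rows > 8L) cat(" ...\n")
  invisible(x)
}

# character matrix view (n_rows x n_cols)
msa_matrix <- function(m) {
  matrix(unlist(strsplit(m$rows, "", fixed = TRUE), use.names = FALSE),
         nrow = m$n_rows, ncol = m$n_cols, byrow = TRUE)
}

#' Read and write MSAs / sequences as FASTA
#'
#' `read_msa_fasta()` reads an aligned FASTA (equal-length gapped records)
#' into an [msa()]; `write_msa_fasta()` writes one. `read_fasta()` /
#' `write_fasta()` handle plain (ungapped) sequence sets as named character
#' vectors.
#'
#' @param path file path.
#' @param m an [msa()] object.
#' @return `read_msa_fasta()`: an [msa()]; `read_fasta()`: a named
#'   character vector of sequences.
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  msa(as.character(x), row_ids = names(x))
}

#' @rdname read_msa_fasta
#' @export
write_msa_fasta <- function(m, path) {
  x <- Biostrings::BStringSet(stats::setNames(m$rows, m$row_ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_msa_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_msa_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
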