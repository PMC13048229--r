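## Evaluation of a consensus against a reference: the five rates
## (identity, ambiguity, match, error, size), read error-rate estimation,
## heterozygous-SNP recall/precision against an IUPAC diploid reference,
## and mean/sd aggregation over replicate regions.
##
## All primary rate denominators are the consensus size (the ungapped
## consensus length); error_rate can therefore exceed 1 when the reference
## is much longer than the consensus. Alignment-column-normalised variants
## are reported alongside under *_aln names.

aligned_cols <- function(aln) {
  list(a = strsplit(aln$gapped_a, "", fixed = TRUE)[[1]],
       b = strsplit(aln$gapped_b, "", fixed = TRUE)[[1]])
}

#' Score a consensus sequence against a reference
#'
#' Globally aligns the ungapped consensus to the reference and reports:
#' \describe{
#'   \item{identity_rate}{columns with strictly identical characters /
#'     consensus size.}
#'   \item{ambiguous_rate}{consensus characters other than A,C,G,T /
#'     consensus size.}
#'   \item{match_rate}{columns whose IUPAC codes share a nucleotide
#'     (Y matches S through C; R does not match Y) / consensus size.}
#'   \item{error_rate}{non-matching alignment columns, indel columns
#'     included / consensus size.}
#'   \item{consensus_size}{length of the ungapped consensus.}
#' }
#' `error_rate_aln` and `match_rate_aln` (same counts divided by alignment
#' columns) are included for reporting.
#'
#' @param consensus ungapped IUPAC sequence (string or `msab_consensus`).
#' @param reference reference sequence.
#' @param sc a [scoring()] object.
#' @return a one-row `data.frame` of class `msab_metrics`.
#' @examples
#' evaluate_consensus("AYGT", "ACGT")
#' @export
evaluate_consensus <- function(consensus, reference, sc = scoring()) {
  if (inherits(consensus, "msab_consensus")) consensus <- consensus$ungapped
  if (!nzchar(consensus)) stop("empty consensus")
  if (!nzchar(reference)) stop("empty reference")
  size <- nchar(consensus)
  aln <- global_align(consensus, reference, sc)
  cc <- aligned_cols(aln)
  both <- cc$a != "-" & cc$b != "-"
  n_ident <- sum(both & cc$a == cc$b)
  n_match <- sum(both)
  if (n_match > 0)
    n_match <- sum(codes_match(cc$a[both], cc$b[both]))
  n_amb <- sum(is_ambiguous(strsplit(consensus, "", fixed = TRUE)[[1]]))
  out <- data.frame(
    identity_rate = n_ident / size,
    ambiguous_rate = n_amb / size,
    match_rate = n_match / size,
    error_rate = (aln$columns - n_match) / size,
    consensus_size = size,
    match_rate_aln = n_match / aln$columns,
    error_rate_aln = (aln$columns - n_match) / aln$columns
  )
  class(out) <- c("msab_metrics", class(out))
  out
}

#' Mean per-read error rate against a reference segment
#'
#' Globally aligns each read to the reference and returns the mean, over
#' reads, of non-matching alignment columns (indels included) divided by
#' that read's alignment columns. This is how the sequencing error rate of
#' a read set is estimated from a trusted reference.
#'
#' @param reads character vector of at least one read.
#' @param reference reference (segment) sequence.
#' @param sc a [scoring()] object.
#' @return a single rate.
#' @examples
#' read_error_rate(c("ACGT", "ACGA"), "ACGT")
#' @export
read_error_rate <- function(reads, reference, sc = scoring()) {
  if (length(reads) < 1L) stop("empty read set")
  per_read <- vapply(reads, function(r) {
    aln <- global_align(r, reference, sc)
    cc <- aligned_cols(aln)
    both <- cc$a != "-" & cc$b != "-"
    n_match <- if (any(both)) sum(codes_match(cc$a[both], cc$b[both])) else 0L
    (aln$columns - n_match) / aln$columns
  }, numeric(1), USE.NAMES = FALSE)
  mean(per_read)
}

#' Heterozygous-SNP recall and precision of a consensus
#'
#' Aligns the consensus to the IUPAC-encoded diploid reference and counts:
#' `tp`, heterozygous sites whose aligned consensus character is exactly
#' the site's 2-nucleotide IUPAC code; `fn`, the remaining het sites
#' (collapsed to one allele, absent, or carrying a different code); `fp`,
#' ambiguity codes in the consensus that are not a `tp`. Recall is
#' `tp / (tp + fn)` — IUPAC symbols at het sites over all het SNPs — and
#' precision is `tp / (tp + fp)` — IUPAC symbols at het sites over all
#' IUPAC symbols in the consensus.
#'
#' @param consensus ungapped IUPAC sequence (string or `msab_consensus`).
#' @param diploid_ref a [build_diploid_reference()] object (or a list with
#'   `iupac_seq` and `het_sites`).
#' @param sc a [scoring()] object.
#' @return a list with `tp`, `fn`, `fp`, `recall`, `precision`
#'   (`NA` where a denominator is zero).
#' @export
het_eval <- function(consensus, diploid_ref, sc = scoring()) {
  if (inherits(consensus, "msab_consensus")) consensus <- consensus$ungapped
  ref <- diploid_ref$iupac_seq
  sites <- diploid_ref$het_sites
  aln <- global_align(consensus, ref, sc)
  cc <- aligned_cols(aln)
  refpos <- cumsum(cc$b != "-")          # 1-based ref coordinate per column
  refpos[cc$b == "-"] <- NA_integer_
  tp <- 0L
  if (nrow(sites) > 0L) {
    for (k in seq_len(nrow(sites))) {
      j <- which(refpos == sites$pos[k])
      if (length(j) == 1L && cc$a[j] == sites$code[k]) tp <- tp + 1L
    }
  }
  n_amb <- sum(is_ambiguous(strsplit(consensus, "", fixed = TRUE)[[1]]))
  fn <- nrow(sites) - tp
  fp <- n_amb - tp
  list(tp = tp, fn = fn, fp = fp,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Mean and standard deviation of metrics over replicates
#'
#' Aggregates evaluation records (e.g. the 10 regions of one
#' size-depth-tool combination) into per-metric mean and population
#' (n-denominator) standard deviation.
#'
#' @param records a `data.frame` of metric rows ([evaluate_consensus()]
#'   output rows bound together) or a list of such rows.
#' @return a `data.frame` with columns `metric`, `mean`, `sd`, `n`.
#' @examples
#' r <- rbind(evaluate_consensus("ACGT", "ACGT"),
#'            evaluate_consensus("ACAT", "ACGT"))
#' aggregate_metrics(r)
#' @export
aggregate_metrics <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (is.null(records) || nrow(records) < 1L) stop("no records to aggregate")
  num <- records[vapply(records, is.numeric, TRUE)]
  n <- nrow(num)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(metric = names(num),
             mean = vapply(num, mean, numeric(1)),
             sd = vapply(num, pop_sd, numeric(1)),
             n = n, row.names = NULL)
}
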