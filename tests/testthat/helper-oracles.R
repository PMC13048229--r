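# Independent oracles used for dual-route checks. These deliberately do
# not share code with the implementation paths they verify.

# Threshold-consensus oracle: enumerate the prefix tie-groups of the
# descending count ordering (for each distinct count v, the candidate set
# is every nucleotide occurring at least v times) and return the first
# candidate set whose cumulative rate reaches the threshold.
oracle_column_consensus <- function(counts, threshold) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  gap <- if ("-" %in% names(counts)) counts[["-"]] else 0
  nuc <- counts[setdiff(names(counts), "-")]
  if (length(nuc) == 0L) return("-")
  if (gap > max(nuc)) return("-")
  for (v in sort(unique(unname(nuc)), decreasing = TRUE)) {
    set <- names(nuc)[nuc >= v]
    if (sum(nuc[set]) / total >= threshold) return(symbol_for_set(set))
  }
  symbol_for_set(names(nuc))
}

# Exhaustive global-alignment score: recursive enumeration of every
# monotone alignment (no dynamic programming), feasible for lengths <= 6.
oracle_global_score <- function(a, b, sc = scoring()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  colscore <- function(x, y) {
    if (x == y) sc$match
    else if (length(intersect(iupac_set(x), iupac_set(y))) > 0) sc$compatible
    else sc$mismatch
  }
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) + colscore(A[i], B[j]))
    if (i > 0L) best <- max(best, rec(i - 1L, j) + sc$gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + sc$gap)
    best
  }
  rec(length(A), length(B))
}

# all compositions of n into 5 labelled parts (A,C,G,T,-)
count_compositions <- function(n) {
  out <- list()
  for (a in 0:n) for (c in 0:(n - a)) for (g in 0:(n - a - c))
    for (t in 0:(n - a - c - g)) {
      gap <- n - a - c - g - t
      out[[length(out) + 1L]] <- c(A = a, C = c, G = g, T = t, `-` = gap)
    }
  out
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Minimal coordinate-sorted SAM writer for fixtures: records is a
# data.frame with qname, pos (1-based), cigar, seq.
write_test_sam <- function(path, ref_len, records, seq_id = "ref") {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", seq_id, ref_len))
  records <- records[order(records$pos), , drop = FALSE]
  body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  records$qname, seq_id, records$pos, records$cigar,
                  records$seq)
  writeLines(c(header, body), path)
  path
}
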