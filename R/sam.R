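## Real-data mode: pull region-spanning reads out of a SAM/BAM file and
## clip them to region boundaries using their alignment (CIGAR)
## coordinates. Records are read with Rsamtools; CIGAR walking is done
## here because the clipping rule (keep the query bases laid over the
## region's reference interval, insertions included, deletions skipped)
## is specific to this pipeline.

# query substring of `seq` laid over reference interval [start, end)
# (0-based half-open), given POS (1-based) and a CIGAR string.
clip_read_to_region <- function(seq, pos, cigar, start, end) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  kinds <- sub("\\d+", "", ops)
  rpos <- pos - 1L  # 0-based reference cursor
  qpos <- 0L        # 0-based query cursor
  out <- character(0)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (k in seq_along(kinds)) {
    len <- lens[k]
    kind <- kinds[k]
    if (kind %in% c("M", "=", "X")) {
      # overlap of [rpos, rpos+len) with [start, end)
      lo <- max(rpos, start)
      hi <- min(rpos + len, end)
      if (hi > lo)
        out <- c(out, chars[qpos + (lo - rpos) + seq_len(hi - lo)])
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (kind %in% c("I", "S")) {
      # insertions inside the region are part of the read segment;
      # soft-clips are never inside the aligned span
      if (kind == "I" && rpos > start && rpos < end)
        out <- c(out, chars[qpos + seq_len(len)])
      qpos <- qpos + len
    } else if (kind %in% c("D", "N")) {
      rpos <- rpos + len
    }
    # H and P consume nothing we track
    if (rpos >= end) break
  }
  paste(out, collapse = "")
}

cigar_ref_span <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  kinds <- sub("\\d+", "", ops)
  sum(lens[kinds %in% c("M", "=", "X", "D", "N")])
}

#' Extract region-spanning reads from a SAM/BAM file
#'
#' Selects primary alignments that fully span the region, clips each read
#' to the region boundaries via its CIGAR, and uniformly samples `depth`
#' of them. SAM input is converted to BAM on the fly with Rsamtools.
#'
#' @param path SAM or BAM file of reads aligned to the reference.
#' @param region a list/row with `seq_id`, `start` (0-based), `length`.
#' @param depth number of reads to sample.
#' @param allow_fewer if `TRUE`, fewer spanning reads than `depth` is a
#'   warning and all spanning reads are returned; if `FALSE` (default) it
#'   is an error reporting the available count.
#' @return named character vector of clipped reads.
#' @export
extract_reads_from_sam <- function(path, region, depth, allow_fewer = FALSE) {
  if (depth < 1L) stop("depth must be >= 1")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "rname", "pos", "cigar", "seq"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(rec$pos) & as.character(rec$rname) == region$seq_id
  start <- region$start
  end <- region$start + region$length
  spans <- keep &
    (rec$pos - 1L) <= start &
    (rec$pos - 1L + vapply(rec$cigar, cigar_ref_span, integer(1))) >= end
  spans[is.na(spans)] <- FALSE
  idx <- which(spans)
  if (length(idx) < depth) {
    msg <- sprintf("only %d read(s) span region %s:%d-%d (depth %d requested)",
                   length(idx), region$seq_id, start, end, depth)
    if (!allow_fewer) stop(msg)
    warning(msg)
  } else {
    idx <- sort(sample(idx, depth))
  }
  seqs <- as.character(rec$seq[idx])
  out <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    clip_read_to_region(seqs[k], rec$pos[i], rec$cigar[i], start, end)
  }, character(1))
  stats::setNames(out, rec$qname[idx])
}
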