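## Synthetic read generation with controlled error profiles, region
## sampling, depth-constrained read sets, and artificial diploid (IUPAC)
## reference construction.
##
## Error model: each template base independently suffers at most one error
## event with probability `rate`; the event type is drawn from
## (p_sub, p_ins, p_del). A substitution replaces the base with a
## uniformly random different base; an insertion places one uniform random
## base immediately before the template base; a deletion drops the base.
## Every event is recorded in a truth log so realised rates and type
## compositions can be recovered exactly. Randomness comes from R's global
## RNG: call set.seed() (or use the seed fields of the bench module) for
## reproducibility.

.NUCS <- c("A", "C", "G", "T")

#' Error profile for read simulation
#'
#' An overall per-base error rate plus the composition of error types.
#' The named profiles mirror standard simulated long-read datasets:
#' `SUB` (substitutions only), `INS` (insertions only), `DEL` (deletions
#' only) and `MIX` with 23% substitutions, 31% insertions and 46%
#' deletions, an ONT-like composition.
#'
#' @param kind one of `"SUB"`, `"INS"`, `"DEL"`, `"MIX"`.
#' @param rate overall per-base error rate in `[0, 1]`.
#' @return an object of class `msab_profile` with fields `rate`, `p_sub`,
#'   `p_ins`, `p_del`.
#' @examples
#' make_profile("MIX", 0.10)
#' @export
make_profile <- function(kind, rate) {
  kind <- toupper(kind)
  p <- switch(kind,
              SUB = c(1, 0, 0),
              INS = c(0, 1, 0),
              DEL = c(0, 0, 1),
              MIX = c(0.23, 0.31, 0.46),
              stop("unknown error profile kind: ", sQuote(kind)))
  error_profile(rate, p[1], p[2], p[3])
}

#' @rdname make_profile
#' @param p_sub,p_ins,p_del fractions of errors by type; must sum to 1.
#' @export
error_profile <- function(rate, p_sub, p_ins, p_del) {
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop("error rate must be in [0, 1]")
  if (abs(p_sub + p_ins + p_del - 1) > 1e-9)
    stop("p_sub + p_ins + p_del must sum to 1")
  if (min(p_sub, p_ins, p_del) < 0) stop("type fractions must be >= 0")
  structure(list(rate = rate, p_sub = p_sub, p_ins = p_ins, p_del = p_del),
            class = "msab_profile")
}

#' Simulate one noisy read from a template
#'
#' Applies the error model above to `template` and returns the read along
#' with its truth-log entry: per-type event counts and the full edit
#' script (template position, operation, base involved).
#'
#' @param template non-empty template sequence.
#' @param profile an [error_profile()].
#' @return a list with `read` (string) and `truth`: a list with counts
#'   `n_sub`, `n_ins`, `n_del` and `edits`, a `data.frame` with columns
#'   `pos` (template position), `op` (`"S"`,`"I"`,`"D"`) and `base` (the
#'   substituted or inserted base; `NA` for deletions).
#' @examples
#' set.seed(1)
#' simulate_read("ACGTACGT", make_profile("MIX", 0.25))
#' @export
simulate_read <- function(template, profile) {
  stopifnot(inherits(profile, "msab_profile"))
  n <- nchar(template)
  if (n == 0L) stop("empty template")
  tchars <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  err <- stats::runif(n) < profile$rate
  k <- sum(err)
  ops <- rep("=", n)
  newbase <- rep(NA_character_, n)
  if (k > 0L) {
    ops[err] <- sample(c("S", "I", "D"), k, replace = TRUE,
                       prob = c(profile$p_sub, profile$p_ins, profile$p_del))
    is_sub <- ops == "S"
    if (any(is_sub)) {
      # uniform over the three non-template bases: rotate by 1..3
      idx <- match(tchars[is_sub], .NUCS)
      shift <- sample.int(3L, sum(is_sub), replace = TRUE)
      newbase[is_sub] <- .NUCS[((idx - 1L + shift) %% 4L) + 1L]
    }
    is_ins <- ops == "I"
    if (any(is_ins))
      newbase[is_ins] <- sample(.NUCS, sum(is_ins), replace = TRUE)
  }
  pieces <- tchars
  pieces[ops == "S"] <- newbase[ops == "S"]
  pieces[ops == "D"] <- ""
  pieces[ops == "I"] <- paste0(newbase[ops == "I"], tchars[ops == "I"])
  edits <- data.frame(pos = which(err), op = ops[err], base = newbase[err],
                      stringsAsFactors = FALSE)
  list(read = paste(pieces, collapse = ""),
       truth = list(n_sub = sum(ops == "S"), n_ins = sum(ops == "I"),
                    n_del = sum(ops == "D"), edits = edits))
}

#' Replay a truth-log edit script on its template
#'
#' Reconstructs the read from the template and an edit script; used to
#' check truth-log conservation.
#'
#' @param template the template sequence.
#' @param edits the `edits` data.frame of a [simulate_read()] truth entry.
#' @return the reconstructed read.
#' @export
apply_edits <- function(template, edits) {
  pieces <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  for (k in seq_len(nrow(edits))) {
    p <- edits$pos[k]
    pieces[p] <- switch(edits$op[k],
                        S = edits$base[k],
                        D = "",
                        I = paste0(edits$base[k], pieces[p]),
                        stop("unknown edit op ", edits$op[k]))
  }
  paste(pieces, collapse = "")
}

#' Random reference sequence
#'
#' Uniform i.i.d. nucleotide sequence, used as a stand-in reference for
#' simulated benchmarks.
#'
#' @param length sequence length in bases.
#' @return a string.
#' @export
random_reference <- function(length) {
  paste(sample(.NUCS, length, replace = TRUE), collapse = "")
}

#' Sample genomic regions of several sizes from shared start positions
#'
#' Draws `n_per_size` start positions uniformly such that every requested
#' size fits from each start, and returns the size-by-start cross product.
#' The defaults follow the standard benchmark grid: sizes 100-10,000 and
#' 10 random positions.
#'
#' @param ref_length reference length in bases.
#' @param sizes region lengths (default
#'   `c(100, 200, 500, 1000, 2000, 5000, 10000)`).
#' @param n_per_size number of start positions (default 10).
#' @param seq_id reference identifier recorded in each region.
#' @return a `data.frame` with columns `seq_id`, `start` (0-based),
#'   `length`, `region` (start index, 1..n_per_size).
#' @export
sample_regions <- function(ref_length,
                           sizes = c(100, 200, 500, 1000, 2000, 5000, 10000),
                           n_per_size = 10L, seq_id = "ref") {
  stopifnot(n_per_size >= 1L, length(sizes) >= 1L)
  if (max(sizes) > ref_length)
    stop("region size ", max(sizes), " exceeds reference length ", ref_length)
  max_start <- ref_length - max(sizes)   # every size must fit from any start
  starts <- if (max_start == 0L) rep(0L, n_per_size)
            else sample.int(max_start + 1L, n_per_size, replace = TRUE) - 1L
  out <- expand.grid(region = seq_len(n_per_size), length = sizes,
                     KEEP.OUT.ATTRS = FALSE)
  data.frame(seq_id = seq_id, start = starts[out$region],
             length = out$length, region = out$region)
}

region_template <- function(reference, region) {
  substr(reference, region$start + 1L, region$start + region$length)
}

#' Simulated read set for one region at a given depth
#'
#' Generates exactly `depth` reads by applying [simulate_read()] to the
#' region's template; depth is the number of rows the downstream MSA will
#' have. In diploid mode (a pair of colinear haplotype sequences), reads
#' are split 50/50 between the two haplotype templates (odd depth: the
#' extra read goes to a random haplotype), emulating an equal mix of two
#' strains; the truth log records each read's source haplotype.
#'
#' @param reference reference sequence (haploid mode).
#' @param region one row of [sample_regions()] (or a list with `start`,
#'   `length`).
#' @param depth number of reads (>= 1).
#' @param profile an [error_profile()].
#' @param haplotypes optional list of two equal-coordinate haplotype
#'   sequences for diploid mode; `reference` is ignored for templates.
#' @return a list with `reads` (character vector, named `read1`...) and
#'   `truth`: a `data.frame` with one row per read (`n_sub`, `n_ins`,
#'   `n_del`, `template_len`, `haplotype`) carrying the per-read edit
#'   scripts in `attr(truth, "edits")`.
#' @export
reads_for_region <- function(reference, region, depth, profile,
                             haplotypes = NULL) {
  if (depth < 1L) stop("depth must be >= 1")
  if (is.null(haplotypes)) {
    hap_of <- rep(1L, depth)
    templates <- region_template(reference, region)
  } else {
    stopifnot(length(haplotypes) == 2L)
    half <- depth %/% 2L
    hap_of <- c(rep(1L, half), rep(2L, half))
    if (depth %% 2L == 1L) hap_of <- c(hap_of, sample(1:2, 1L))
    templates <- vapply(haplotypes, function(h) region_template(h, region),
                        character(1))
  }
  sims <- lapply(hap_of, function(h) {
    tmpl <- if (is.null(haplotypes)) templates else templates[[h]]
    simulate_read(tmpl, profile)
  })
  reads <- vapply(sims, `[[`, character(1), "read")
  names(reads) <- sprintf("read%d", seq_len(depth))
  truth <- data.frame(
    read = names(reads),
    n_sub = vapply(sims, function(s) s$truth$n_sub, integer(1)),
    n_ins = vapply(sims, function(s) s$truth$n_ins, integer(1)),
    n_del = vapply(sims, function(s) s$truth$n_del, integer(1)),
    template_len = if (is.null(haplotypes)) nchar(templates)
                   else nchar(templates)[hap_of],
    haplotype = hap_of,
    stringsAsFactors = FALSE
  )
  attr(truth, "edits") <- lapply(sims, function(s) s$truth$edits)
  list(reads = reads, truth = truth)
}

#' Build an IUPAC diploid reference from two haplotypes
#'
#' Globally aligns the two haplotypes and encodes them as a single
#' reference in which heterozygous SNPs appear as 2-nucleotide IUPAC
#' codes: substitution columns become the code of the two alleles and are
#' recorded as het sites; columns where haplotype B has a gap keep the
#' haplotype-A base but are flagged as excluded from het accounting;
#' columns where haplotype A has a gap are dropped. Coordinates are
#' 1-based positions in the resulting sequence (the haplotype-A skeleton).
#'
#' @param hap_a,hap_b the two haplotype sequences.
#' @param sc a [scoring()] object.
#' @return an object of class `msab_diploid` with fields `iupac_seq`,
#'   `het_sites` (`data.frame` of `pos`, `code`), `excluded_sites`
#'   (integer positions) and `haplotype_ids`.
#' @examples
#' build_diploid_reference("ACGT", "ACAT")  # "ACRT", het site at 3
#' @export
build_diploid_reference <- function(hap_a, hap_b, sc = scoring()) {
  if (!nzchar(hap_a) || !nzchar(hap_b)) stop("empty haplotype")
  aln <- global_align(hap_a, hap_b, sc)
  cc <- aligned_cols(aln)
  keep <- cc$a != "-"                  # drop hap_b-insertion columns
  a <- cc$a[keep]
  b <- cc$b[keep]
  pos <- seq_along(a)                  # 1-based in the hap_a skeleton
  out <- a
  is_b_gap <- b == "-"
  het <- !is_b_gap & a != b
  codes <- vapply(which(het), function(i) symbol_for_set(c(a[i], b[i])),
                  character(1))
  out[het] <- codes
  structure(list(
    iupac_seq = paste(out, collapse = ""),
    het_sites = data.frame(pos = pos[het], code = codes,
                           stringsAsFactors = FALSE),
    excluded_sites = pos[is_b_gap],
    haplotype_ids = c("hap_a", "hap_b")
  ), class = "msab_diploid")
}

#' @export
print.msab_diploid <- function(x, ...) {
  cat(sprintf("Diploid reference: %d bases, %d het sites, %d excluded\n",
              nchar(x$iupac_seq), nrow(x$het_sites),
              length(x$excluded_sites)))
  invisible(x)
}

#' Plant heterozygous SNPs into a haplotype
#'
#' Convenience generator for diploid benchmarks: copies `hap_a` and
#' substitutes `n_snp` uniformly chosen positions with a different base,
#' yielding a colinear second haplotype with known het sites.
#'
#' @param hap_a haplotype sequence.
#' @param n_snp number of SNPs to plant.
#' @return a list with `hap_b` and `positions` (1-based SNP positions).
#' @export
mutate_haplotype <- function(hap_a, n_snp) {
  chars <- strsplit(hap_a, "", fixed = TRUE)[[1]]
  stopifnot(n_snp <= length(chars))
  at <- sort(sample.int(length(chars), n_snp))
  idx <- match(chars[at], .NUCS)
  shift <- sample.int(3L, n_snp, replace = TRUE)
  chars[at] <- .NUCS[((idx - 1L + shift) %% 4L) + 1L]
  list(hap_b = paste(chars, collapse = ""), positions = at)
}
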