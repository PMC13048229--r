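## IUPAC nucleotide-code algebra.
##
## Every IUPAC DNA code denotes a non-empty subset of {A,C,G,T}; internally
## each subset is a 4-bit mask (A=1, C=2, G=4, T=8) so that set intersection
## is a bitwAnd. The gap character '-' is deliberately NOT part of the
## alphabet: consensus and alignment code handle it as a separate state.

# masks indexed by code
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

# code indexed by mask 1..15
.IUPAC_CODE <- character(15L)
.IUPAC_CODE[.IUPAC_MASK] <- names(.IUPAC_MASK)

.NUC_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)

#' IUPAC DNA alphabet
#'
#' The 15 IUPAC nucleotide codes, each naming a non-empty subset of
#' \{A,C,G,T\}. `iupac_codes()` lists them; `iupac_set()` returns the
#' nucleotide set a code stands for.
#'
#' @return `iupac_codes()`: a character vector of the 15 codes.
#' @examples
#' iupac_codes()
#' iupac_set("Y")
#' @export
iupac_codes <- function() names(.IUPAC_MASK)

#' @rdname iupac_codes
#' @param code a single IUPAC code (case-insensitive; `"U"` is read as `"T"`).
#' @return `iupac_set()`: a character vector of the nucleotides the code
#'   can represent.
#' @export
iupac_set <- function(code) {
  m <- iupac_mask(code)
  names(.NUC_BIT)[bitwAnd(m, .NUC_BIT) > 0L]
}

# character vector of codes -> integer masks; errors on unknown characters.
# Gap is NOT accepted here.
iupac_mask <- function(codes) {
  codes <- toupper(codes)
  codes[codes == "U"] <- "T"
  m <- .IUPAC_MASK[codes]
  if (anyNA(m)) {
    bad <- unique(codes[is.na(m)])
    stop("unknown IUPAC character(s): ", paste(sQuote(bad), collapse = ", "))
  }
  unname(m)
}

#' IUPAC code for a nucleotide set
#'
#' Returns the unique IUPAC code whose nucleotide set equals the input set,
#' e.g. `{C,T}` maps to `Y` and the full set maps to `N`.
#'
#' @param nucleotides character vector of nucleotides among A, C, G, T
#'   (case-insensitive, duplicates ignored, `"U"` accepted for `"T"`).
#' @return a single uppercase IUPAC code.
#' @examples
#' symbol_for_set(c("C", "T"))  # "Y"
#' symbol_for_set("a")          # "A"
#' @export
symbol_for_set <- function(nucleotides) {
  if (length(nucleotides) == 0L)
    stop("no IUPAC code for empty set")
  nucleotides <- toupper(nucleotides)
  nucleotides[nucleotides == "U"] <- "T"
  bits <- .NUC_BIT[nucleotides]
  if (anyNA(bits))
    stop("not a nucleotide: ",
         paste(sQuote(unique(nucleotides[is.na(bits)])), collapse = ", "))
  .IUPAC_CODE[Reduce(bitwOr, bits)]
}

#' IUPAC compatibility ("match") relation
#'
#' Two IUPAC codes match when their nucleotide sets intersect: `Y` (C/T) and
#' `S` (C/G) match because both can represent C, while `R` (A/G) and `Y`
#' (C/T) do not. A gap only matches a gap. Vectorised over pairs, recycling
#' the shorter argument.
#'
#' @param a,b character vectors of IUPAC codes or `"-"`.
#' @return logical vector.
#' @examples
#' codes_match("Y", "S")  # TRUE
#' codes_match("R", "Y")  # FALSE
#' codes_match("-", "A")  # FALSE
#' @export
codes_match <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(toupper(a), n)
  b <- rep_len(toupper(b), n)
  ga <- a == "-"
  gb <- b == "-"
  out <- ga & gb
  both <- !ga & !gb
  if (any(both))
    out[both] <- bitwAnd(iupac_mask(a[both]), iupac_mask(b[both])) > 0L
  # a lone gap character on one side only: validate the other side anyway
  lone <- xor(ga, gb)
  if (any(lone)) invisible(iupac_mask(ifelse(ga[lone], b[lone], a[lone])))
  out
}

#' @rdname codes_match
#' @return `is_ambiguous()`: logical vector, `TRUE` where the character is an
#'   ambiguity code (an IUPAC code other than A, C, G or T; gaps are `FALSE`).
#' @export
is_ambiguous <- function(a) {
  a <- toupper(a)
  out <- logical(length(a))
  ng <- a != "-"
  if (any(ng)) out[ng] <- !(iupac_mask(a[ng]) %in% .NUC_BIT)
  out
}
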