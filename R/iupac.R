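# IUPAC nucleotide alphabet: degeneracy sets, complements and bitmask encoding.
# Masks use A=1, C=2, G=4, T=8; a degenerate letter is the OR of its bases, so
# "text letter t matches pattern letter p" is a single bitwAnd().

.IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_LETTERS <- names(.IUPAC_BASES)
.DEGENERATE_LETTERS <- setdiff(.IUPAC_LETTERS, c("A", "C", "G", "T"))

.BASE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_MASK <- vapply(.IUPAC_BASES, function(b) sum(.BASE_MASK[b]), integer(1))

# chartr() source/target for IUPAC-aware complement (A<->T, C<->G, R<->Y,
# K<->M, B<->V, D<->H; S, W, N self-complementary).
.COMP_FROM <- "ACGTRYSWKMBDHVN"
.COMP_TO   <- "TGCAYRSWMKVHDBN"

#' IUPAC degeneracy sets
#'
#' Returns the set of concrete bases denoted by each IUPAC nucleotide letter
#' (e.g. `R` = A/G, `N` = A/C/G/T).
#'
#' @param letters Character vector of single IUPAC letters; defaults to all 15.
#' @return Named list of character vectors of concrete bases.
#' @examples
#' iupac_bases("M")
#' @export
iupac_bases <- function(letters = .IUPAC_LETTERS) {
  letters <- toupper(letters)
  bad <- setdiff(letters, .IUPAC_LETTERS)
  if (length(bad) > 0)
    stop("not IUPAC nucleotide letters: ", paste(bad, collapse = ", "))
  .IUPAC_BASES[letters]
}

#' IUPAC letter for a base set
#'
#' Inverse of [iupac_bases()]: the unique IUPAC letter whose degeneracy set
#' equals the given set of concrete bases.
#'
#' @param bases Character vector of distinct bases from A/C/G/T.
#' @return A single IUPAC letter.
#' @examples
#' iupac_code(c("A", "C"))  # "M"
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0 || !all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be a non-empty subset of A/C/G/T")
  hit <- vapply(.IUPAC_BASES, function(b) identical(sort(b), bases), logical(1))
  names(.IUPAC_BASES)[hit][1]
}

# Split a string into single characters.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Uppercase and validate a sequence against an allowed alphabet; errors name
# the first offending character and its 1-based position.
.check_alphabet <- function(x, allowed, what = "sequence") {
  x <- toupper(x)
  ch <- .chars(x)
  bad <- which(!(ch %in% allowed))
  if (length(bad) > 0) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 ch[bad[1]], bad[1], what), call. = FALSE)
  }
  x
}

# Integer mask encoding of an IUPAC string (concrete DNA is the special case
# where every mask is a power of two).
.encode_iupac <- function(x) unname(.IUPAC_MASK[.chars(x)])

#' Reverse complement of a DNA or IUPAC string
#'
#' Watson-Crick complement of every letter (degeneracy-aware: R<->Y, K<->M,
#' B<->V, D<->H; S, W and N map to themselves), then reversal. The operation
#' is an involution.
#'
#' @param x A single string over the 15-letter IUPAC alphabet.
#' @return The reverse-complemented string, uppercase.
#' @examples
#' reverse_complement("ACGGA")   # "TCCGT"
#' reverse_complement("GAATTC")  # palindromic site
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- .check_alphabet(x, .IUPAC_LETTERS, "sequence")
  comp <- chartr(.COMP_FROM, .COMP_TO, x)
  paste(rev(.chars(comp)), collapse = "")
}

#' Expand a degenerate IUPAC pattern into concrete DNA strings
#'
#' Enumerates every concrete sequence over A/C/G/T whose letters lie in the
#' corresponding degeneracy sets of the pattern, in lexicographic order. The
#' count equals the product of per-position degeneracies.
#'
#' @param pattern IUPAC string.
#' @param cap Maximum number of expansions allowed (guards against e.g. long
#'   runs of `N`); exceeding it is an error naming the would-be count.
#' @return Character vector of concrete DNA strings, lexicographically sorted.
#' @examples
#' expand_iupac_pattern("AR")  # "AA" "AG"
#' @export
expand_iupac_pattern <- function(pattern, cap = 1024L) {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) > 0)
  pattern <- .check_alphabet(pattern, .IUPAC_LETTERS, "pattern")
  sets <- .IUPAC_BASES[.chars(pattern)]
  n <- prod(lengths(sets))
  if (n > cap) {
    stop(sprintf("pattern '%s' expands to %d concrete sequences (cap %d)",
                 pattern, n, cap), call. = FALSE)
  }
  out <- ""
  for (s in sets) out <- paste0(rep(out, each = length(s)), s)
  out
}
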