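# Recognition-site search: Boyer-Moore generalized to IUPAC-degenerate
# patterns (compatibility-set matching), a naive scanning oracle, and the
# catalog-level site finder used by the RFLP judgment layer.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build Boyer-Moore shift tables for a recognition pattern
#'
#' Preprocesses a (possibly degenerate) IUPAC pattern into the two classic
#' Boyer-Moore shift tables. The bad-character entry for a concrete text
#' letter is `M - 1 - r`, where `r` is the rightmost pattern position (over
#' positions 1..M-1, 0-based 0..M-2) whose degeneracy set contains the
#' letter, or `M` when none does; the shift applied at a mismatch is derived
#' from it in the scan. The good-suffix table implements the strong rule
#' (rightmost re-occurrence of the matched suffix preceded by a different
#' letter, else the longest pattern prefix that is a suffix of it). Because
#' letter compatibility is not transitive for degenerate letters, good-suffix
#' shifts are disabled for degenerate patterns and matching falls back to
#' bad-character shifts alone.
#'
#' @param pattern IUPAC recognition pattern.
#' @return An object of class `search_tables`: list with `pattern`, `length`,
#'   `degenerate`, `bad_character` (named integer vector over A/C/G/T, all
#'   entries in 1..M) and `good_suffix` (integer vector of length M indexed
#'   by 0-based mismatch position + 1; element 1 doubles as the shift after a
#'   full match; `NULL` for degenerate patterns).
#' @examples
#' build_tables("GAATTC")
#' @export
build_tables <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) > 0)
  pattern <- .check_alphabet(pattern, .IUPAC_LETTERS, "pattern")
  pm <- .encode_iupac(pattern)
  m <- length(pm)
  degenerate <- any(!(pm %in% c(1L, 2L, 4L, 8L)))

  bc <- vapply(c(A = 1L, C = 2L, G = 4L, T = 8L), function(mask) {
    compat <- which(bitwAnd(pm, mask) > 0L)
    compat <- compat[compat <= m - 1L]            # exclude final position
    if (length(compat) == 0) m else m - compat[length(compat)]
  }, integer(1))

  gs <- NULL
  if (!degenerate) {
    pat <- .chars(pattern)
    # suff[i]: length of the longest common suffix of pattern[1..i] and the
    # whole pattern (1-based i)
    suff <- vapply(seq_len(m), function(i) {
      l <- 0L
      while (l < i && pat[i - l] == pat[m - l]) l <- l + 1L
      l
    }, integer(1))
    gs <- rep.int(m, m)
    j <- 0L                                       # 0-based fill cursor
    for (i in seq(m - 1L, 0L)) {                  # 0-based position
      if (suff[i + 1L] == i + 1L) {               # prefix that is a suffix
        while (j < m - 1L - i) {
          if (gs[j + 1L] == m) gs[j + 1L] <- m - 1L - i
          j <- j + 1L
        }
      }
    }
    if (m >= 2) {
      for (i in 0L:(m - 2L)) gs[m - suff[i + 1L]] <- m - 1L - i
    }
  }

  structure(list(pattern = pattern, length = m, degenerate = degenerate,
                 bad_character = bc, good_suffix = gs),
            class = "search_tables")
}

#' @export
print.search_tables <- function(x, ...) {
  cat(sprintf("<search_tables> pattern %s (length %d, %s)\n", x$pattern,
              x$length, if (x$degenerate) "degenerate: bad-character shifts only"
                        else "concrete"))
  cat("  bad-character:", paste(names(x$bad_character), x$bad_character,
                                sep = "=", collapse = " "), "\n")
  if (!is.null(x$good_suffix))
    cat("  good-suffix:  ", paste(x$good_suffix, collapse = " "), "\n")
  invisible(x)
}

# scan with prebuilt tables against an already-encoded text
.bm_core <- function(tmask, tables, trace = FALSE) {
  if (tables$length > length(tmask)) {
    if (trace) return(list(starts = integer(0), alignments = integer(0)))
    return(integer(0))
  }
  res <- .bm_scan(tmask, .encode_iupac(tables$pattern),
                  unname(tables$bad_character),
                  tables$good_suffix %||% integer(0), trace)
  if (trace)
    return(list(starts = res$starts + 1L, alignments = res$alignments + 1L))
  res$starts + 1L
}

#' Boyer-Moore search for a recognition pattern in concrete DNA
#'
#' Finds every (possibly overlapping) occurrence of an IUPAC pattern in a
#' concrete DNA text: position `s` is reported when each text letter lies in
#' the degeneracy set of the aligned pattern letter. The text must be plain
#' A/C/G/T; expand variation-bearing templates into allele sequences first
#' (see [expand_alleles()]).
#'
#' @param text Concrete DNA string.
#' @param pattern IUPAC recognition pattern.
#' @param trace If `TRUE`, also return every alignment (window start) the
#'   scan visited, to inspect the shift sequence.
#' @return Integer vector of 1-based match start positions (sorted), or, with
#'   `trace = TRUE`, a list with `starts` and `alignments`.
#' @examples
#' bm_search("ACGGATTTTTT", "ACGGA")  # 1
#' @export
bm_search <- function(text, pattern, trace = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  text <- .check_alphabet(text, c("A", "C", "G", "T"), "text (degenerate letters: expand alleles first)")
  tables <- build_tables(pattern)
  .bm_core(.encode_iupac(text), tables, trace)
}

#' Naive scanning search (oracle and baseline)
#'
#' Same contract as [bm_search()], implemented by checking every window
#' position letter-by-letter against the IUPAC degeneracy sets. Kept as the
#' permanent correctness oracle and benchmark baseline for the Boyer-Moore
#' matcher; the two implementations share no search code.
#'
#' @inheritParams bm_search
#' @return Integer vector of 1-based match start positions (sorted).
#' @examples
#' naive_search("AAAA", "AA")  # 1 2 3
#' @export
naive_search <- function(text, pattern) {
  stopifnot(is.character(text), length(text) == 1)
  text <- .check_alphabet(text, c("A", "C", "G", "T"), "text (degenerate letters: expand alleles first)")
  pattern <- .check_alphabet(pattern, .IUPAC_LETTERS, "pattern")
  tch <- .chars(text)
  sets <- .IUPAC_BASES[.chars(pattern)]
  n <- length(tch); m <- length(sets)
  if (m > n) return(integer(0))
  cand <- seq_len(n - m + 1L)
  for (j in seq_len(m)) {
    cand <- cand[tch[cand + j - 1L] %in% sets[[j]]]
    if (length(cand) == 0) break
  }
  cand
}

.empty_hits <- function() {
  structure(data.frame(enzyme = character(0), strand = character(0),
                       start = integer(0), end = integer(0),
                       matched = character(0), pattern = character(0),
                       stringsAsFactors = FALSE),
            class = c("match_hits", "data.frame"))
}

#' Locate recognition sites of a catalog of enzymes on both strands
#'
#' Filters the catalog by recognition-sequence length, commercial
#' availability and composite-IUPAC status, then searches each surviving
#' enzyme's pattern on the plus strand and its reverse complement on the
#' minus strand (reported in plus-strand coordinates). Enzymes whose pattern
#' is longer than the text are skipped silently.
#'
#' @param text Concrete DNA string (plus strand).
#' @param catalog A `rebase_catalog`.
#' @param min_len,max_len Keep enzymes whose pattern length lies in
#'   `[min_len, max_len]`.
#' @param commercial_only Drop enzymes with an empty supplier set.
#' @param include_iupac Keep enzymes with degenerate recognition letters.
#' @return A data frame of class `match_hits` with columns `enzyme`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive), `matched` (text
#'   slice) and `pattern`, sorted by (start, enzyme, strand).
#' @examples
#' fx <- rebase_fixture(2, seed = 1)
#' find_sites("ACGGATTTTTT", fx$catalog)
#' @export
find_sites <- function(text, catalog, min_len = 1L, max_len = Inf,
                       commercial_only = FALSE, include_iupac = TRUE) {
  stopifnot(inherits(catalog, "rebase_catalog"), min_len <= max_len)
  text <- .check_alphabet(text, c("A", "C", "G", "T"), "text (degenerate letters: expand alleles first)")
  tmask <- .encode_iupac(text)

  plen <- nchar(catalog$pattern)
  keep <- plen >= min_len & plen <= max_len & plen <= length(tmask)
  if (commercial_only) keep <- keep & catalog$is_commercial
  if (!include_iupac) keep <- keep & !catalog$is_iupac
  cat_f <- catalog[keep, , drop = FALSE]
  if (nrow(cat_f) == 0) return(.empty_hits())

  out <- vector("list", nrow(cat_f))
  for (i in seq_len(nrow(cat_f))) {
    pat <- cat_f$pattern[i]
    m <- nchar(pat)
    fwd <- .bm_core(tmask, build_tables(pat))
    rcp <- reverse_complement(pat)
    rev <- .bm_core(tmask, build_tables(rcp))
    if (length(fwd) + length(rev) == 0) next
    starts <- c(fwd, rev)
    out[[i]] <- data.frame(
      enzyme = cat_f$name[i],
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      start = starts, end = starts + m - 1L,
      matched = substring(text, starts, starts + m - 1L),
      pattern = pat, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) return(.empty_hits())
  hits <- hits[order(hits$start, hits$enzyme, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("match_hits", "data.frame")
  hits
}

#' Export match hits as TSV, JSON or BED
#'
#' TSV and JSON carry the 1-based inclusive coordinates of the hit table;
#' BED output converts to the 0-based half-open browser convention, with the
#' enzyme name in the name column and the strand in column 6.
#'
#' @param hits A `match_hits` data frame from [find_sites()].
#' @param path Output path; `""` writes to stdout.
#' @param format One of `"tsv"`, `"json"`, `"bed"`.
#' @param seqname Sequence name used in the BED chrom column.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, format = c("tsv", "json", "bed"),
                       seqname = "seq") {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(hits), file = path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (format == "json") {
    json <- jsonlite::toJSON(as.data.frame(hits), dataframe = "rows",
                             auto_unbox = TRUE, pretty = TRUE)
    if (nzchar(path)) writeLines(json, path) else writeLines(json)
  } else {
    bed <- data.frame(chrom = seqname, start = hits$start - 1L,
                      end = hits$end, name = hits$enzyme, score = 0L,
                      strand = hits$strand, stringsAsFactors = FALSE)
    utils::write.table(bed, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
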