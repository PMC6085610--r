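# Variation-bearing input sequences: parsing of the three input dialects
# (plain DNA, IUPAC-coded variation, bracketed dNTP alleles incl. indels),
# dialect transformation, allele expansion, flanking windows.

.new_template <- function(segments, sites, dialect, name = NULL) {
  structure(list(segments = segments, sites = sites, dialect = dialect,
                 name = name),
            class = "variant_template")
}

#' Number of variation sites in a template
#' @param template A `variant_template`.
#' @return Integer count.
#' @export
n_sites <- function(template) {
  stopifnot(inherits(template, "variant_template"))
  length(template$sites)
}

# 1-based positions of the variation placeholders in the template string
# (each site counts as one position).
.site_positions <- function(template) {
  if (length(template$sites) == 0) return(integer(0))
  seg_len <- nchar(template$segments)
  cumsum(seg_len[-length(seg_len)] + 1L)
}

#' @export
as.character.variant_template <- function(x, ...) {
  k <- length(x$sites)
  if (k == 0) return(x$segments[1])
  groups <- vapply(x$sites, function(a) paste0("[", paste(a, collapse = "/"), "]"), "")
  paste0(paste0(x$segments[seq_len(k)], groups, collapse = ""),
         x$segments[k + 1L])
}

#' @export
print.variant_template <- function(x, ...) {
  cat(sprintf("<variant_template> %s dialect, %d variation site(s)\n",
              x$dialect, length(x$sites)))
  if (!is.null(x$name)) cat("  name:", x$name, "\n")
  cat(" ", as.character(x), "\n")
  invisible(x)
}

.parse_bracket_group <- function(content, group_text) {
  alleles <- strsplit(content, "/", fixed = TRUE)[[1]]
  bad <- function(msg) stop(sprintf("malformed variation group '%s': %s",
                                    group_text, msg), call. = FALSE)
  if (length(alleles) < 2) bad("fewer than 2 alleles")
  if (length(alleles) > 4) bad("more than 4 alleles")
  if (anyDuplicated(alleles)) bad("duplicate alleles")
  if (!all(grepl("^([ACGT]+|-)$", alleles)))
    bad("alleles must be runs of A/C/G/T or the deletion symbol '-'")
  if ("-" %in% alleles && length(alleles) != 2)
    bad("an indel site must be exactly [-/bases] or [bases/-]")
  alleles
}

#' Parse a sequence with variations into a template
#'
#' Accepts the three input dialects: `plain` DNA over A/C/G/T; `iupac`, where
#' every degenerate letter (R,Y,S,W,K,M,B,D,H,V,N) denotes a substitution
#' site whose alleles are the letter's base set; and `bracket`, where
#' `[X/Y]`, `[X/Y/Z]`, `[X/Y/Z/W]` denote substitution sites and `[-/XX]` /
#' `[XX/-]` denote indels. `auto` picks bracket if a `[` is present, else
#' iupac if any degenerate letter is present, else plain. Input is
#' uppercased; whitespace and digits (sequence-viewer line numbers) are
#' stripped first. Characters outside the chosen dialect's alphabet raise a
#' specification-nonconformance error naming the position and character.
#'
#' @param text The sequence text.
#' @param dialect One of `"auto"`, `"plain"`, `"iupac"`, `"bracket"`.
#' @param name Optional template name (e.g. a FASTA header), carried into
#'   reports.
#' @return An object of class `variant_template`.
#' @examples
#' parse_input("ACGG[A/C]TTTTTT")
#' parse_input("ACGGMTTTTTT", dialect = "iupac")
#' @export
parse_input <- function(text, dialect = c("auto", "plain", "iupac", "bracket"),
                        name = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(text), length(text) == 1)
  x <- toupper(gsub("[[:space:][:digit:]]", "", text))
  if (!nzchar(x)) stop("empty sequence input", call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("[", x, fixed = TRUE)) "bracket"
    else if (grepl("[RYSWKMBDHVN]", x)) "iupac"
    else "plain"
  }

  if (dialect == "plain") {
    x <- .check_alphabet(x, c("A", "C", "G", "T"), "plain DNA input")
    return(.new_template(segments = x, sites = list(), dialect = "plain",
                         name = name))
  }

  if (dialect == "iupac") {
    x <- .check_alphabet(x, .IUPAC_LETTERS, "IUPAC input")
    ch <- .chars(x)
    deg <- which(ch %in% .DEGENERATE_LETTERS)
    if (length(deg) == 0)
      return(.new_template(segments = x, sites = list(), dialect = "iupac",
                           name = name))
    bounds <- c(0L, deg, nchar(x) + 1L)
    segments <- vapply(seq_len(length(deg) + 1L), function(i) {
      lo <- bounds[i] + 1L; hi <- bounds[i + 1L] - 1L
      if (lo > hi) "" else substring(x, lo, hi)
    }, "")
    sites <- lapply(ch[deg], function(l) .IUPAC_BASES[[l]])
    return(.new_template(segments = segments, sites = sites,
                         dialect = "iupac", name = name))
  }

  # bracket dialect
  g <- gregexpr("\\[[^][]*\\]", x)[[1]]
  if (g[1] == -1) {
    if (grepl("[][]", x))
      stop("unbalanced '[' or ']' in bracketed input", call. = FALSE)
    x <- .check_alphabet(x, c("A", "C", "G", "T"), "bracketed input")
    return(.new_template(segments = x, sites = list(), dialect = "bracket",
                         name = name))
  }
  groups <- regmatches(x, gregexpr("\\[[^][]*\\]", x))[[1]]
  segments <- regmatches(x, gregexpr("\\[[^][]*\\]", x), invert = TRUE)[[1]]
  if (any(grepl("[][]", segments)))
    stop("unbalanced '[' or ']' in bracketed input", call. = FALSE)
  seg_starts <- c(1L, g + attr(g, "match.length"))
  for (i in seq_along(segments)) {
    ch <- .chars(segments[i])
    badpos <- which(!(ch %in% c("A", "C", "G", "T")))
    if (length(badpos) > 0)
      stop(sprintf("invalid character '%s' at position %d in bracketed input",
                   ch[badpos[1]], seg_starts[i] + badpos[1] - 1L),
           call. = FALSE)
  }
  sites <- lapply(seq_along(groups), function(i)
    .parse_bracket_group(substring(groups[i], 2, nchar(groups[i]) - 1L),
                         groups[i]))
  .new_template(segments = segments, sites = sites, dialect = "bracket",
                name = name)
}

#' Detect the variation sites of a template
#'
#' @param template A `variant_template`.
#' @return Data frame with one row per site: `site` (index), `position`
#'   (1-based position of the site in the template, each site counting as one
#'   position) and `alleles` (slash-separated). Zero rows for plain DNA.
#' @examples
#' detect_variations(parse_input("ACGG[A/C]TTTTTT"))
#' @export
detect_variations <- function(template) {
  stopifnot(inherits(template, "variant_template"))
  k <- length(template$sites)
  data.frame(site = seq_len(k),
             position = .site_positions(template),
             alleles = vapply(template$sites, paste, "", collapse = "/"),
             stringsAsFactors = FALSE)
}

#' Convert a bracketed template to composite-IUPAC text
#'
#' Every substitution site of single-base alleles becomes the unique IUPAC
#' letter whose base set equals the allele set. Indel sites and multi-base
#' alleles have no IUPAC code and raise an error.
#'
#' @param template A `variant_template`.
#' @return A single IUPAC string.
#' @examples
#' bracket_to_iupac(parse_input("ACGG[A/C]TTTTTT"))  # "ACGGMTTTTTT"
#' @export
bracket_to_iupac <- function(template) {
  stopifnot(inherits(template, "variant_template"))
  k <- length(template$sites)
  if (k == 0) return(template$segments[1])
  letters_ <- vapply(template$sites, function(a) {
    if (any(a == "-") || any(nchar(a) != 1))
      stop("no IUPAC code exists for indel or multi-base alleles: [",
           paste(a, collapse = "/"), "]", call. = FALSE)
    iupac_code(a)
  }, "")
  paste0(paste0(template$segments[seq_len(k)], letters_, collapse = ""),
         template$segments[k + 1L])
}

#' Convert composite-IUPAC text to a bracketed template
#'
#' Each degenerate letter becomes a substitution site whose alleles are the
#' letter's base set in canonical A<C<G<T order. Inverse of
#' [bracket_to_iupac()] up to allele ordering.
#'
#' @param text IUPAC sequence text.
#' @return A `variant_template` (bracket dialect).
#' @examples
#' as.character(iupac_to_bracket("ACGGMTTTTTT"))
#' @export
iupac_to_bracket <- function(text) {
  t <- parse_input(text, dialect = "iupac")
  t$dialect <- "bracket"
  t
}

#' Expand a template into its concrete allele sequences
#'
#' Realizes the Cartesian product of the per-site allele lists: one concrete
#' A/C/G/T sequence per combination, in lexicographic order of per-site
#' allele index (leftmost site most significant). Deletion alleles (`-`)
#' contribute the empty string and a zero-width span. A template without
#' sites yields itself.
#'
#' @param template A `variant_template`.
#' @param cap Maximum number of combinations (combinatorial guard).
#' @return A list of `allele_sequence` objects, each a list with `label`
#'   (chosen alleles joined with `/`), `alleles` (character vector, one per
#'   site), `sequence` (concrete DNA) and `spans` (data frame `site`,
#'   `start`, `end`, 1-based inclusive; deletion alleles have
#'   `end = start - 1`, `start` being the insertion point).
#' @examples
#' sapply(expand_alleles(parse_input("ACGG[A/C]TTTTTT")), `[[`, "sequence")
#' @export
expand_alleles <- function(template, cap = 256L) {
  stopifnot(inherits(template, "variant_template"))
  k <- length(template$sites)
  if (k == 0) {
    seq1 <- template$segments[1]
    return(list(structure(list(label = "", alleles = character(0),
                               sequence = seq1,
                               spans = data.frame(site = integer(0),
                                                  start = integer(0),
                                                  end = integer(0))),
                          class = "allele_sequence")))
  }
  counts <- lengths(template$sites)
  total <- prod(counts)
  if (total > cap)
    stop(sprintf("allele expansion would produce %d sequences (cap %d)",
                 total, cap), call. = FALSE)
  grid <- do.call(expand.grid, rev(lapply(counts, seq_len)))
  grid <- grid[, rev(seq_len(k)), drop = FALSE]  # site order, leftmost most significant
  segs <- template$segments
  lapply(seq_len(nrow(grid)), function(r) {
    choice <- as.integer(grid[r, ])
    alleles <- vapply(seq_len(k), function(i) template$sites[[i]][choice[i]], "")
    realized <- ifelse(alleles == "-", "", alleles)
    pieces <- character(2 * k + 1)
    pieces[seq(1, 2 * k + 1, by = 2)] <- segs
    pieces[seq(2, 2 * k, by = 2)] <- realized
    seqstr <- paste(pieces, collapse = "")
    lens <- nchar(pieces)
    offs <- cumsum(c(0L, lens))[seq_len(2 * k + 1)]  # 0-based start of each piece
    starts <- offs[seq(2, 2 * k, by = 2)] + 1L
    ends <- starts + nchar(realized) - 1L
    structure(list(label = paste(alleles, collapse = "/"), alleles = alleles,
                   sequence = seqstr,
                   spans = data.frame(site = seq_len(k), start = starts,
                                      end = ends)),
              class = "allele_sequence")
  })
}

#' @export
print.allele_sequence <- function(x, ...) {
  cat(sprintf("<allele_sequence> %s: %s\n",
              if (nzchar(x$label)) x$label else "(no variation)", x$sequence))
  invisible(x)
}

#' Extract the flanking window around a variation site
#'
#' Returns the sub-template covering `radius` template positions on each side
#' of the chosen site (sites count as one position; the window is truncated
#' at the sequence ends, never padded). Other sites falling inside the window
#' are retained with their alleles unchanged; positions are re-indexed to the
#' window.
#'
#' @param template A `variant_template` with at least one site.
#' @param radius Positive window half-width in template positions.
#' @param site_index Which site to center on (default the first).
#' @return A `variant_template`.
#' @examples
#' as.character(flanking(parse_input("ACGG[A/C]TTTTTT"), radius = 2))  # "GG[A/C]TT"
#' @export
flanking <- function(template, radius, site_index = 1L) {
  stopifnot(inherits(template, "variant_template"))
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1)
    stop("radius must be a positive integer", call. = FALSE)
  k <- length(template$sites)
  if (site_index < 1 || site_index > k)
    stop(sprintf("site_index %d out of range (template has %d sites)",
                 site_index, k), call. = FALSE)
  radius <- as.integer(radius)
  # tokenize: single characters, with each site one token
  tokens <- list()
  token_site <- integer(0)
  for (i in seq_len(k + 1L)) {
    seg <- template$segments[i]
    if (nzchar(seg)) {
      tokens <- c(tokens, as.list(.chars(seg)))
      token_site <- c(token_site, rep(0L, nchar(seg)))
    }
    if (i <= k) {
      tokens <- c(tokens, list(template$sites[[i]]))
      token_site <- c(token_site, i)
    }
  }
  p <- which(token_site == site_index)
  lo <- max(1L, p - radius); hi <- min(length(tokens), p + radius)
  sel <- lo:hi
  segs <- character(0); sites <- list(); cur <- ""
  for (j in sel) {
    if (token_site[j] == 0L) {
      cur <- paste0(cur, tokens[[j]])
    } else {
      segs <- c(segs, cur); cur <- ""
      sites <- c(sites, tokens[j])
    }
  }
  segs <- c(segs, cur)
  .new_template(segments = segs, sites = sites, dialect = template$dialect,
                name = template$name)
}

#' Reverse-complement a template
#'
#' Mirrors the whole template: segments are reverse-complemented and
#' reversed in order, site alleles are reverse-complemented individually
#' (the deletion allele is unchanged). Useful for strand-symmetry checks.
#'
#' @param template A `variant_template`.
#' @return A `variant_template`.
#' @export
reverse_complement_template <- function(template) {
  stopifnot(inherits(template, "variant_template"))
  segs <- vapply(rev(template$segments), function(s)
    if (nzchar(s)) reverse_complement(s) else "", "", USE.NAMES = FALSE)
  sites <- lapply(rev(template$sites), function(a)
    vapply(a, function(al) if (al == "-") "-" else reverse_complement(al), "",
           USE.NAMES = FALSE))
  .new_template(segments = segs, sites = sites, dialect = template$dialect,
                name = template$name)
}

#' Read templates from FASTA or line-per-template text
#'
#' FASTA (headers carried as template names; bracketed variation groups are
#' allowed inside sequence lines) or plain text with one template per line.
#'
#' @param path Input file.
#' @param format `"auto"` (FASTA when the first non-blank character is `>`),
#'   `"fasta"` or `"lines"`.
#' @param dialect Sequence dialect passed to [parse_input()].
#' @return A list of `variant_template` objects.
#' @export
read_templates <- function(path, format = c("auto", "fasta", "lines"),
                           dialect = "auto") {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0) stop("no sequences in ", path, call. = FALSE)
  if (format == "auto")
    format <- if (startsWith(trimws(nonblank[1]), ">")) "fasta" else "lines"
  if (format == "fasta") {
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("not FASTA: no '>' header in ", path, call. = FALSE)
    grp <- cumsum(hdr)
    keep <- grp > 0
    recs <- split(lines[keep], grp[keep])
    lapply(recs, function(rl) {
      nm <- sub("^>\\s*", "", rl[1])
      parse_input(paste(rl[-1], collapse = ""), dialect = dialect, name = nm)
    })
  } else {
    lapply(seq_along(nonblank), function(i)
      parse_input(nonblank[i], dialect = dialect,
                  name = sprintf("template_%d", i)))
  }
}
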