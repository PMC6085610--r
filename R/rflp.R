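# PCR-RFLP judgment: which enzymes discriminate the alleles of a variation.
# An enzyme is specific when some but not all alleles carry a recognition
# site overlapping the variation and the enzyme has no background site
# elsewhere in any allele (a repeated site would cut every genotype and
# carries no information, so such enzymes are excluded).

#' Options controlling RFLP judgment
#'
#' @param include_iupac Evaluate enzymes with composite-IUPAC (degenerate)
#'   recognition sequences; set `FALSE` to restrict to general A/C/G/T-only
#'   enzymes.
#' @param min_len,max_len Recognition-sequence length bounds.
#' @param commercial_only Restrict to enzymes with a non-empty supplier set.
#' @param flank_radius Optional window half-width applied around the judged
#'   site before judging (shorter sequences search faster; sites outside the
#'   window are ignored).
#' @param site_index Which variation site to judge when several exist; the
#'   others are held at their first allele.
#' @return An object of class `judge_options`.
#' @export
judge_options <- function(include_iupac = TRUE, min_len = 1L, max_len = Inf,
                          commercial_only = FALSE, flank_radius = NULL,
                          site_index = 1L) {
  if (min_len > max_len)
    stop("min_len must not exceed max_len", call. = FALSE)
  if (!is.null(flank_radius) && flank_radius < 1)
    stop("flank_radius must be >= 1", call. = FALSE)
  structure(list(include_iupac = isTRUE(include_iupac),
                 min_len = min_len, max_len = max_len,
                 commercial_only = isTRUE(commercial_only),
                 flank_radius = flank_radius,
                 site_index = as.integer(site_index)),
            class = "judge_options")
}

# Merge all sites except keep_index into the backbone at their first allele.
.freeze_sites <- function(template, keep_index) {
  k <- length(template$sites)
  segs <- character(0); cur <- ""
  sites <- list()
  for (i in seq_len(k)) {
    cur <- paste0(cur, template$segments[i])
    if (i == keep_index) {
      segs <- c(segs, cur); cur <- ""
      sites <- c(sites, template$sites[i])
    } else {
      first <- template$sites[[i]][1]
      if (first != "-") cur <- paste0(cur, first)
    }
  }
  cur <- paste0(cur, template$segments[k + 1L])
  segs <- c(segs, cur)
  .new_template(segments = segs, sites = sites, dialect = template$dialect,
                name = template$name)
}

# Does each hit (rows of `hits`) overlap the judged-site span? For a deletion
# allele the span is zero-width and a hit overlaps iff the insertion point
# lies strictly inside the hit (>= one matched base on each side).
.overlaps_span <- function(hits, span_start, span_end) {
  if (nrow(hits) == 0) return(logical(0))
  if (span_end >= span_start) {
    hits$start <= span_end & hits$end >= span_start
  } else {
    hits$start < span_start & hits$end >= span_start
  }
}

#' Judge which enzymes discriminate the alleles of a variation
#'
#' Implements the PCR-RFLP availability judgment. The template's judged
#' variation site is expanded into one concrete sequence per allele (other
#' sites, if any, held at their first allele); recognition sites of every
#' enzyme passing the option filters are located on both strands of each
#' allele sequence; hits are split into variation-overlapping versus
#' background. An enzyme is *specific* (usable for genotyping) when some but
#' not all alleles have a variation-overlapping hit and it has no background
#' hit in any allele.
#'
#' @param template A `variant_template` with at least one variation site.
#' @param catalog A non-empty `rebase_catalog`.
#' @param options A [judge_options()] object.
#' @return An object of class `rflp_judgment`: list with `verdicts` (data
#'   frame, one row per enzyme/pattern with any hit, sorted specific-first
#'   then by name: columns `enzyme`, `pattern`, `strand`, `cut_alleles`,
#'   `uncut_alleles`, `n_variation_hits`, `n_background_hits`, `specific`,
#'   `enzyme_class`, `availability`, plus list-columns `variation_hits` and
#'   `background_hits` of per-hit tables), `no_hit_enzymes`, `alleles`,
#'   `allele_sequences`, `template`, `options`.
#' @examples
#' fx <- rebase_fixture(2, seed = 1)
#' judge_rflp(parse_input("ACGG[A/C]TTTTTT"), fx$catalog)
#' @export
judge_rflp <- function(template, catalog, options = judge_options()) {
  stopifnot(inherits(template, "variant_template"),
            inherits(catalog, "rebase_catalog"))
  if (length(template$sites) == 0)
    stop("template has no variation site to judge", call. = FALSE)
  if (nrow(catalog) == 0)
    stop("empty enzyme catalog", call. = FALSE)
  if (!inherits(options, "judge_options"))
    stop("options must come from judge_options()", call. = FALSE)
  site_index <- options$site_index
  if (site_index < 1 || site_index > length(template$sites))
    stop("site_index out of range", call. = FALSE)

  work <- .freeze_sites(template, site_index)
  if (!is.null(options$flank_radius))
    work <- flanking(work, options$flank_radius, site_index = 1L)
  alleles <- work$sites[[1]]
  expanded <- expand_alleles(work)

  # hits per allele, split at the variation span; alleles tracked by index so
  # that the cut/uncut partition is well defined even for degenerate inputs
  per_allele <- lapply(expanded, function(al) {
    hits <- find_sites(al$sequence, catalog,
                       min_len = options$min_len, max_len = options$max_len,
                       commercial_only = options$commercial_only,
                       include_iupac = options$include_iupac)
    ov <- .overlaps_span(hits, al$spans$start[1], al$spans$end[1])
    list(label = al$label, variation = hits[ov, , drop = FALSE],
         background = hits[!ov, , drop = FALSE])
  })

  all_hits <- do.call(rbind, lapply(seq_along(per_allele), function(i) {
    pa <- per_allele[[i]]
    h <- rbind(cbind(pa$variation, at_variation = rep(TRUE, nrow(pa$variation))),
               cbind(pa$background, at_variation = rep(FALSE, nrow(pa$background))))
    h$allele <- rep(pa$label, nrow(h))
    h$allele_id <- rep(i, nrow(h))
    h
  }))

  n_alleles <- length(alleles)
  if (is.null(all_hits) || nrow(all_hits) == 0) {
    verdicts <- data.frame(enzyme = character(0), pattern = character(0),
                           strand = character(0), cut_alleles = character(0),
                           uncut_alleles = character(0),
                           n_variation_hits = integer(0),
                           n_background_hits = integer(0),
                           specific = logical(0), enzyme_class = character(0),
                           availability = character(0),
                           stringsAsFactors = FALSE)
    verdicts$variation_hits <- list()
    verdicts$background_hits <- list()
  } else {
    key <- paste(all_hits$enzyme, all_hits$pattern, sep = "\r")
    verdict_rows <- lapply(split(seq_len(nrow(all_hits)), key), function(idx) {
      h <- all_hits[idx, , drop = FALSE]
      vh <- h[h$at_variation, , drop = FALSE]
      bh <- h[!h$at_variation, , drop = FALSE]
      cut_ids <- sort(unique(vh$allele_id))
      cut <- alleles[cut_ids]
      uncut <- alleles[setdiff(seq_len(n_alleles), cut_ids)]
      strands <- unique(if (nrow(vh) > 0) vh$strand else bh$strand)
      crow <- match(paste(h$enzyme[1], h$pattern[1], sep = "\r"),
                    paste(catalog$name, catalog$pattern, sep = "\r"))
      df <- data.frame(
        enzyme = h$enzyme[1], pattern = h$pattern[1],
        strand = if (length(strands) > 1) "both" else strands,
        cut_alleles = paste(cut, collapse = ","),
        uncut_alleles = paste(uncut, collapse = ","),
        n_variation_hits = nrow(vh), n_background_hits = nrow(bh),
        specific = length(cut_ids) > 0 && length(cut_ids) < n_alleles &&
          nrow(bh) == 0,
        enzyme_class = if (catalog$is_iupac[crow]) "iupac" else "general",
        availability = if (catalog$is_commercial[crow]) "commercial"
                       else "non-commercial",
        stringsAsFactors = FALSE)
      df$variation_hits <- list(vh[, c("allele", "strand", "start", "end",
                                       "matched")])
      df$background_hits <- list(bh[, c("allele", "strand", "start", "end",
                                        "matched")])
      df
    })
    verdicts <- do.call(rbind, verdict_rows)
    verdicts <- verdicts[order(!verdicts$specific, verdicts$enzyme,
                               verdicts$pattern), , drop = FALSE]
    rownames(verdicts) <- NULL
  }

  searched <- catalog$name[nchar(catalog$pattern) >= options$min_len &
                           nchar(catalog$pattern) <= options$max_len &
                           (!options$commercial_only | catalog$is_commercial) &
                           (options$include_iupac | !catalog$is_iupac)]
  structure(list(verdicts = verdicts,
                 no_hit_enzymes = setdiff(searched, verdicts$enzyme),
                 alleles = alleles,
                 allele_sequences = expanded,
                 template = template, options = options,
                 site_index = site_index),
            class = "rflp_judgment")
}

#' @export
print.rflp_judgment <- function(x, ...) {
  v <- x$verdicts
  cat(sprintf("<rflp_judgment> %s | site %d, alleles %s\n",
              as.character(x$template), x$site_index,
              paste(x$alleles, collapse = "/")))
  cat(sprintf("  %d enzyme(s) with hits, %d specific, %d searched without hits\n",
              nrow(v), sum(v$specific), length(x$no_hit_enzymes)))
  if (nrow(v) > 0) {
    show <- v[, c("enzyme", "pattern", "strand", "cut_alleles",
                  "n_background_hits", "specific")]
    print.data.frame(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.rflp_judgment <- function(object, ...) {
  v <- object$verdicts
  structure(list(n_enzymes = nrow(v), n_specific = sum(v$specific),
                 specific = v$enzyme[v$specific],
                 classification = classify_results(object)),
            class = "summary.rflp_judgment")
}

#' @export
print.summary.rflp_judgment <- function(x, ...) {
  cat(sprintf("RFLP judgment: %d enzymes hit, %d specific (%s)\n",
              x$n_enzymes, x$n_specific,
              paste(x$specific, collapse = ", ")))
  invisible(x)
}

#' Classify judged enzymes into the four output categories
#'
#' Splits verdicts by recognition-sequence type (composite-IUPAC vs general)
#' and by commercial availability. Every verdict falls in exactly one class
#' of each pair.
#'
#' @param judgment An `rflp_judgment` (or its verdicts data frame).
#' @return List of four character vectors of enzyme names: `iupac`,
#'   `general`, `commercial`, `non_commercial`.
#' @export
classify_results <- function(judgment) {
  v <- if (inherits(judgment, "rflp_judgment")) judgment$verdicts else judgment
  list(iupac = v$enzyme[v$enzyme_class == "iupac"],
       general = v$enzyme[v$enzyme_class == "general"],
       commercial = v$enzyme[v$availability == "commercial"],
       non_commercial = v$enzyme[v$availability == "non-commercial"])
}

#' Join verdicts with full catalog records into a report table
#'
#' One row per verdict, carrying the judgment fields together with the seven
#' catalog fields (name, microorganism, source, recognition sequence,
#' methylation, commercial availability, references). Hit coordinates are
#' 1-based inclusive, collapsed as `allele:start-end(strand)`.
#'
#' @param judgment An `rflp_judgment`.
#' @param catalog The `rebase_catalog` the judgment was run against.
#' @return A data frame of class `rflp_report`.
#' @export
rflp_report <- function(judgment, catalog) {
  stopifnot(inherits(judgment, "rflp_judgment"),
            inherits(catalog, "rebase_catalog"))
  v <- judgment$verdicts
  idx <- match(paste(v$enzyme, v$pattern, sep = "\r"),
               paste(catalog$name, catalog$pattern, sep = "\r"))
  if (anyNA(idx))
    stop("verdict enzyme(s) not found in catalog: ",
         paste(v$enzyme[is.na(idx)], collapse = ", "), call. = FALSE)
  fmt_hits <- function(h) paste(sprintf("%s:%d-%d(%s)", h$allele, h$start,
                                        h$end, h$strand), collapse = ";")
  rep <- data.frame(
    template = rep(judgment$template$name %||% as.character(judgment$template),
                   nrow(v)),
    enzyme = v$enzyme,
    specific = v$specific,
    strand = v$strand,
    cut_alleles = v$cut_alleles,
    uncut_alleles = v$uncut_alleles,
    variation_hits = vapply(v$variation_hits, fmt_hits, ""),
    background_hits = vapply(v$background_hits, fmt_hits, ""),
    enzyme_class = v$enzyme_class,
    availability = v$availability,
    microorganism = catalog$microorganism[idx],
    source = catalog$source[idx],
    recognition = catalog$recognition_raw[idx],
    methylation = catalog$methylation[idx],
    suppliers = catalog$suppliers[idx],
    references = vapply(catalog$references[idx], paste, "", collapse = "; "),
    stringsAsFactors = FALSE)
  class(rep) <- c("rflp_report", "data.frame")
  rep
}

#' Write a report (or any package table) as TSV or JSON
#'
#' The two renderings are field-equal after parsing back.
#'
#' @param report A data frame.
#' @param path Output path; `""` writes to stdout.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(report), file = path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    json <- jsonlite::toJSON(as.data.frame(report), dataframe = "rows",
                             auto_unbox = TRUE, pretty = TRUE)
    if (nzchar(path)) writeLines(json, path) else writeLines(json)
  }
  invisible(path)
}

#' Batch RFLP judgment over many templates
#'
#' Applies [judge_rflp()] to each template, optionally across worker
#' processes. Results are returned in input order and are identical for any
#' worker count; a failing template yields an `rflp_error` record (with the
#' error message) in its slot instead of aborting the batch.
#'
#' @param templates Non-empty list of `variant_template` objects.
#' @param catalog A `rebase_catalog`.
#' @param options A [judge_options()].
#' @param workers Positive worker count; forked parallelism is used when
#'   `workers > 1` on Unix.
#' @return List of `rflp_judgment` / `rflp_error` objects, one per template.
#' @export
judge_rflp_batch <- function(templates, catalog, options = judge_options(),
                             workers = 1L) {
  stopifnot(is.list(templates), length(templates) > 0, workers >= 1)
  one <- function(i) {
    tryCatch(judge_rflp(templates[[i]], catalog, options),
             error = function(e)
               structure(list(message = conditionMessage(e), index = i,
                              template = templates[[i]]),
                         class = "rflp_error"))
  }
  idx <- seq_along(templates)
  if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, one, mc.cores = workers)
  } else {
    lapply(idx, one)
  }
}

#' Combined report for a batch run
#'
#' @param results Output of [judge_rflp_batch()].
#' @param catalog The catalog the batch was judged against.
#' @return A data frame: concatenated [rflp_report()] rows for successful
#'   templates and one `error` row per failed template (column `error`
#'   carries the message, empty otherwise).
#' @export
batch_report <- function(results, catalog) {
  parts <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (inherits(r, "rflp_error")) {
      df <- data.frame(template = r$template$name %||%
                         as.character(r$template),
                       enzyme = NA_character_, specific = NA,
                       error = r$message, stringsAsFactors = FALSE)
      return(df)
    }
    rep <- as.data.frame(rflp_report(r, catalog))
    if (nrow(rep) > 0) rep$error <- ""
    rep
  })
  all_cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(p) {
    for (cl in setdiff(all_cols, names(p))) p[[cl]] <- rep(NA, nrow(p))
    p[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
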