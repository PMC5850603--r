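# Variant-call post-processing for evolved isolates.
#
# Whole-genome variant callers randomly call spurious mutations inside an
# integrated reporter-fusion construct; those calls are excluded by genomic
# region before any downstream interpretation. Surviving calls are then used
# to classify each isolate by its suppressor locus: mutations in the
# catabolite-repression gene crc, mutations in (or immediately upstream of)
# the RNA-chaperone gene hfq, or neither. All coordinates are 1-based
# inclusive, the convention of Breseq-style call tables.

#' Define an excluded genomic region
#'
#' @param name region label (e.g. the reporter construct's name).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return data frame row of class `excluded_region`.
#' @export
excluded_region <- function(name, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 1) || any(end < 1)) stop("coordinates are 1-based (>= 1)", call. = FALSE)
  if (any(start > end)) stop("`start` must be <= `end`", call. = FALSE)
  out <- data.frame(name = as.character(name), start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("excluded_region", "data.frame")
  out
}

#' Remove reporter-fusion artifact calls
#'
#' Drops every variant call whose reported position falls inside any excluded
#' region (inclusive ends). Indels are judged by their reported position
#' alone. Idempotent: filtering twice equals filtering once.
#'
#' @param calls data frame with at least `isolate_id` and `position`
#'   (see [read_variant_calls()]).
#' @param regions an [excluded_region()] data frame (one or more rows).
#' @return the retained calls; attribute `n_removed` holds the removal count.
#' @export
filter_reporter_artifacts <- function(calls, regions) {
  stop_missing_cols(calls, c("isolate_id", "position"), "variant calls")
  stop_missing_cols(regions, c("start", "end"), "excluded regions")
  if (any(regions$start > regions$end)) stop("invalid region: start > end", call. = FALSE)
  if (!nrow(calls)) {
    attr(calls, "n_removed") <- 0L
    return(calls)
  }
  inside <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(regions))) {
    inside <- inside | (calls$position >= regions$start[i] &
                          calls$position <= regions$end[i])
  }
  out <- calls[!inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(inside)
  out
}

#' Classify isolates by suppressor locus
#'
#' Labels each isolate `"crc"` if any of its calls hits a crc locus label,
#' `"hfq"` if any call hits an hfq locus label or lies in the configured
#' window upstream of the hfq gene (promoter mutations reduce hfq
#' expression), and `"other"` otherwise. An isolate with hits in both loci is
#' labelled `"conflict"` and flagged — the study's observed pattern is strict
#' mutual exclusivity, so a conflict is surfaced, never silently resolved.
#' Isolates listed in `isolates` but carrying no calls are classified
#' `"other"` with a warning.
#'
#' @param calls filtered variant-call data frame (`isolate_id`, `position`,
#'   `gene`, ...).
#' @param crc_loci character vector of locus labels counted as crc.
#' @param hfq_loci character vector of locus labels counted as hfq.
#' @param hfq_gene_start optional 1-based start coordinate of the hfq gene;
#'   when given, calls with positions in
#'   `[hfq_gene_start - upstream_window, hfq_gene_start - 1]` also count as
#'   hfq (the promoter window).
#' @param upstream_window size of the upstream window in bp (default 300).
#' @param isolates optional full isolate roster (so isolates without any
#'   surviving call are still reported).
#' @return data frame of class `suppressor_classification`: `isolate_id`,
#'   `class` (`crc`/`hfq`/`other`/`conflict`), `conflict` (logical),
#'   `n_calls`.
#' @export
classify_suppressor <- function(calls, crc_loci, hfq_loci,
                                hfq_gene_start = NULL, upstream_window = 300,
                                isolates = NULL) {
  stop_missing_cols(calls, c("isolate_id", "position", "gene"), "variant calls")
  isolates <- as.character(isolates %||% unique(calls$isolate_id))
  gene <- as.character(calls$gene)
  crc_hit <- gene %in% crc_loci
  hfq_hit <- gene %in% hfq_loci
  if (!is.null(hfq_gene_start)) {
    hfq_hit <- hfq_hit | (calls$position >= hfq_gene_start - upstream_window &
                            calls$position <= hfq_gene_start - 1)
  }
  rows <- lapply(isolates, function(iso) {
    idx <- calls$isolate_id == iso
    n <- sum(idx)
    if (n == 0L) {
      warning("isolate ", iso, " has no variant calls; classified \"other\"",
              call. = FALSE)
      return(data.frame(isolate_id = iso, class = "other", conflict = FALSE,
                        n_calls = 0L, stringsAsFactors = FALSE))
    }
    has_crc <- any(crc_hit[idx])
    has_hfq <- any(hfq_hit[idx])
    cls <- if (has_crc && has_hfq) "conflict"
      else if (has_crc) "crc"
      else if (has_hfq) "hfq"
      else "other"
    data.frame(isolate_id = iso, class = cls, conflict = has_crc && has_hfq,
               n_calls = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("suppressor_classification", "data.frame")
  out
}

#' Read a loci/regions configuration from JSON
#'
#' The configuration carries the labels and coordinates that
#' [filter_reporter_artifacts()] and [classify_suppressor()] need:
#' ```json
#' {
#'   "excluded_regions": [{"name": "reporter", "start": 100, "end": 900}],
#'   "crc_loci": ["crc"],
#'   "hfq_loci": ["hfq"],
#'   "hfq_gene_start": 5000,
#'   "upstream_window": 300
#' }
#' ```
#'
#' @param path JSON file path.
#' @return list with `excluded_regions` (an [excluded_region()] frame),
#'   `crc_loci`, `hfq_loci`, `hfq_gene_start`, `upstream_window`.
#' @export
read_loci_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- NULL
  if (!is.null(cfg$excluded_regions)) {
    r <- as.data.frame(cfg$excluded_regions)
    regions <- excluded_region(r$name, r$start, r$end)
  }
  list(excluded_regions = regions,
       crc_loci = as.character(cfg$crc_loci %||% character()),
       hfq_loci = as.character(cfg$hfq_loci %||% character()),
       hfq_gene_start = cfg$hfq_gene_start,
       upstream_window = cfg$upstream_window %||% 300)
}
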