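# Readers for the plain-text formats the pipeline consumes. All are thin
# wrappers over utils::read.csv / read.delim that validate and rename into
# the column conventions the analysis functions expect.

#' Read a wide plate-reader export
#'
#' Wide layout: first column is time (minutes by default), remaining columns
#' are wells.
#'
#' @param path CSV path.
#' @param time_unit unit of the time column, `"min"` (default) or `"h"`.
#' @return long data frame `time_min`, `well`, `od`.
#' @export
read_plate_wide <- function(path, time_unit = c("min", "h")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("wide plate file needs a time column plus wells", call. = FALSE)
  t <- as.numeric(df[[1L]])
  if (time_unit == "h") t <- t * 60
  wells <- names(df)[-1L]
  out <- data.frame(
    time_min = rep(t, times = length(wells)),
    well = rep(wells, each = nrow(df)),
    od = as.numeric(unlist(df[-1L], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  out
}

#' Read a long plate-reader export
#'
#' Long layout with columns `time`, `well`, `value` (alternative names
#' `time_min`/`od` accepted).
#'
#' @param path CSV path.
#' @param time_unit unit of the time column.
#' @return long data frame `time_min`, `well`, `od`.
#' @export
read_plate_long <- function(path, time_unit = c("min", "h")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  tcol <- intersect(c("time_min", "time"), nm)[1L]
  vcol <- intersect(c("od", "value"), nm)[1L]
  if (is.na(tcol) || is.na(vcol) || !"well" %in% nm) {
    stop("long plate file needs columns time(+_min), well, od/value", call. = FALSE)
  }
  t <- as.numeric(df[[tcol]])
  if (time_unit == "h") t <- t * 60
  data.frame(time_min = t, well = as.character(df$well),
             od = as.numeric(df[[vcol]]), stringsAsFactors = FALSE)
}

#' Read a well -> strain plate map
#'
#' @param path CSV with columns `well`, `strain`.
#' @return data frame `well`, `strain`.
#' @export
read_platemap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_missing_cols(df, c("well", "strain"), "plate map")
  df
}

#' Read a CFU competition count sheet
#'
#' Expected columns: `assay_id`, `actor_id`, `recipient_id`, `stage`,
#' `strain_label`, `colony_count`, `dilution`, `volume_ml`, `bio_rep`,
#' `tech_rep`, `is_neutral_control`. CFU/ml is computed with
#' [cfu_estimate()]. A sheet that already carries `cfu_per_ml` is passed
#' through unchanged.
#'
#' @param path CSV path.
#' @return data frame in the layout [aggregate_assay()] expects.
#' @export
read_cfu_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cfu_per_ml" %in% names(df)) {
    stop_missing_cols(df, c("colony_count", "dilution", "volume_ml"), "CFU sheet")
    df$cfu_per_ml <- as.numeric(cfu_estimate(df$colony_count, df$dilution,
                                             df$volume_ml))
  }
  stop_missing_cols(df, c("assay_id", "actor_id", "recipient_id", "stage",
                          "strain_label", "cfu_per_ml", "bio_rep", "tech_rep",
                          "is_neutral_control"), "CFU sheet")
  df$is_neutral_control <- as.logical(df$is_neutral_control)
  df
}

#' Read an isolate phenotype table
#'
#' @param path CSV with columns `isolate`, `population`, plus numeric
#'   measurement channels.
#' @return data frame suitable for [hierarchical_clusters()].
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_missing_cols(df, c("isolate", "population"), "phenotype table")
  chan <- setdiff(names(df), c("isolate", "population"))
  if (!length(chan)) stop("phenotype table has no measurement channels", call. = FALSE)
  if (anyNA(df[chan])) stop("phenotype table contains missing values", call. = FALSE)
  df
}

#' Read a long-form metabolite peak-area table
#'
#' @param path CSV with columns `sample_id`, `mutant_id`, `experiment_id`,
#'   `replicate`, `metabolite_id`, `peak_area`.
#' @param drop_nonpositive drop records with missing or non-positive areas
#'   (default `TRUE`, with a message).
#' @return validated long metabolite table.
#' @export
read_peak_areas <- function(path, drop_nonpositive = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metabolite_table(df, drop_nonpositive = drop_nonpositive)
}

#' Read a simplified variant-call table
#'
#' Tab- or comma-separated with columns `isolate_id` (or `isolate`),
#' `position`, `gene`, and optionally `mutation_class`, `description`. This
#' is a documented simplification of Breseq-style output tables; coordinates
#' are 1-based.
#'
#' @param path CSV/TSV path (delimiter chosen by extension).
#' @return data frame `isolate_id`, `position`, `gene`, `mutation_class`,
#'   `description`.
#' @export
read_variant_calls <- function(path) {
  df <- if (grepl("\\.tsv$|\\.txt$", path)) {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if ("isolate" %in% names(df) && !"isolate_id" %in% names(df)) {
    names(df)[names(df) == "isolate"] <- "isolate_id"
  }
  stop_missing_cols(df, c("isolate_id", "position", "gene"), "variant calls")
  df$position <- as.numeric(df$position)
  if (any(df$position < 1, na.rm = TRUE)) stop("positions are 1-based (>= 1)", call. = FALSE)
  if (!"mutation_class" %in% names(df)) df$mutation_class <- "other"
  if (!"description" %in% names(df)) df$description <- ""
  df
}
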