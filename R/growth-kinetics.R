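#' Construct a growth curve
#'
#' A `growth_curve` holds one well's optical-density (OD 600 nm) time series
#' from a plate reader. Times are stored in minutes and must be strictly
#' increasing; OD values must be non-negative and finite.
#'
#' @param times numeric vector of measurement times. Interpreted in the unit
#'   given by `time_unit` and stored internally in minutes.
#' @param od numeric vector of optical densities, same length as `times`.
#' @param well_id,strain_id optional labels carried through to results.
#' @param time_unit `"min"` (default) or `"h"`.
#' @return An object of class `growth_curve`: a list with elements `times`
#'   (minutes), `od`, `well_id`, `strain_id`.
#' @examples
#' gc <- growth_curve(seq(0, 120, 10), 0.0025 * exp(0.01 * seq(0, 120, 10)))
#' @export
growth_curve <- function(times, od, well_id = NA_character_,
                         strain_id = NA_character_,
                         time_unit = c("min", "h")) {
  time_unit <- match.arg(time_unit)
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od)) {
    stop("`times` and `od` must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) stop("a growth curve needs at least 2 points", call. = FALSE)
  if (anyNA(times) || anyNA(od) || any(!is.finite(times)) || any(!is.finite(od))) {
    stop("times and OD must be finite and non-missing", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (any(od < 0)) stop("OD values must be non-negative", call. = FALSE)
  if (time_unit == "h") times <- times * 60
  structure(list(times = times, od = od,
                 well_id = as.character(well_id),
                 strain_id = as.character(strain_id)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> well %s, strain %s: %d points over %.1f h, OD %.4g-%.4g\n",
              x$well_id, x$strain_id, length(x$times),
              diff(range(x$times)) / 60, min(x$od), max(x$od)))
  invisible(x)
}

#' Estimate the exponential growth rate of a culture
#'
#' Implements the fixed-window rule used for plate-reader kinetics: the rate
#' is the slope of an ordinary-least-squares fit of `ln(OD)` against time (in
#' hours) over the first `n_points` measurements at or after the culture first
#' reaches `od_threshold`. With 10-minute sampling and the defaults this is
#' "the first 10 time points after OD 0.01".
#'
#' The threshold crossing is the first index with `OD >= od_threshold` (no
#' interpolation) and is included in the window by default
#' (`include_crossing = TRUE`). If fewer than `n_points` measurements remain
#' after the crossing, the fit uses what remains (at least 2 points) and the
#' result is flagged `truncated`. Blank subtraction is off by default; pass
#' `blank` to subtract a background OD before windowing.
#'
#' @param curve a [growth_curve()].
#' @param od_threshold OD that defines the start of the window (default 0.01).
#' @param n_points number of time points in the fit window (default 10).
#' @param include_crossing logical; include the crossing point itself
#'   (default `TRUE`).
#' @param blank background OD subtracted from the whole series before
#'   windowing (default 0, i.e. no correction).
#' @return An object of class `growth_rate_fit` with elements `rate` (per
#'   hour), `window_start_index`, `n_points_used`, `fit_r2` (`NA` and flagged
#'   when the windowed series is constant), `truncated`, `r2_undefined`,
#'   `intercept_log_od`, plus the window's times and OD.
#' @examples
#' t_min <- seq(0, 300, 10)
#' gc <- growth_curve(t_min, 0.0025 * exp(log(2) * t_min / 60))
#' exponential_growth_rate(gc)$rate  # doubling once per hour -> ~0.693 / h
#' @export
exponential_growth_rate <- function(curve, od_threshold = 0.01, n_points = 10L,
                                    include_crossing = TRUE, blank = 0) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.numeric(od_threshold) || od_threshold <= 0) {
    stop("`od_threshold` must be positive", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("`n_points` must be at least 2", call. = FALSE)
  od <- curve$od - blank
  cross <- which(od >= od_threshold)
  if (!length(cross)) {
    stop(sprintf("threshold not reached: max OD %.4g < threshold %.4g",
                 max(od), od_threshold), call. = FALSE)
  }
  start <- cross[1L]
  if (!include_crossing) start <- start + 1L
  end <- min(start + n_points - 1L, length(od))
  if (end - start + 1L < 2L) {
    stop("fewer than 2 usable points after the threshold crossing", call. = FALSE)
  }
  idx <- start:end
  w_od <- od[idx]
  if (any(w_od <= 0)) {
    stop("window contains non-positive OD values; cannot take logs", call. = FALSE)
  }
  t_h <- curve$times[idx] / 60
  y <- log(w_od)
  fit <- stats::lm.fit(cbind(1, t_h), y)
  rate <- unname(fit$coefficients[2L])
  ss_tot <- sum((y - mean(y))^2)
  r2_undefined <- ss_tot < .Machine$double.eps * length(y)
  if (r2_undefined) {
    rate <- 0
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
  }
  structure(list(rate = rate,
                 window_start_index = start,
                 n_points_used = length(idx),
                 fit_r2 = r2,
                 truncated = length(idx) < n_points,
                 r2_undefined = r2_undefined,
                 intercept_log_od = unname(fit$coefficients[1L]),
                 window_times_min = curve$times[idx],
                 window_od = w_od,
                 well_id = curve$well_id,
                 strain_id = curve$strain_id),
            class = "growth_rate_fit")
}

#' @export
print.growth_rate_fit <- function(x, ...) {
  cat(sprintf("<growth_rate_fit> rate %.4f / h (%d points from index %d%s)",
              x$rate, x$n_points_used, x$window_start_index,
              if (x$truncated) ", truncated" else ""))
  if (x$r2_undefined) cat("  [flat series: R^2 undefined]\n")
  else cat(sprintf("  R^2 = %.4f\n", x$fit_r2))
  invisible(x)
}

#' @export
coef.growth_rate_fit <- function(object, ...) {
  c(rate_per_h = object$rate, intercept_log_od = object$intercept_log_od)
}

#' Growth rates for every well of a plate
#'
#' Applies [exponential_growth_rate()] to each well of a long-format plate
#' table, optionally mapping wells to strains.
#'
#' @param plate data frame with columns `time_min`, `well`, `od` (see
#'   [read_plate_wide()] / [read_plate_long()]).
#' @param platemap optional data frame with columns `well`, `strain`.
#' @param ... passed to [exponential_growth_rate()].
#' @return data frame with one row per well: `well`, `strain`, `rate_per_h`,
#'   `fit_r2`, `n_points_used`, `window_start_index`, `truncated`, and `error`
#'   (message for wells whose fit failed, `NA` otherwise).
#' @export
plate_growth_rates <- function(plate, platemap = NULL, ...) {
  stop_missing_cols(plate, c("time_min", "well", "od"), "plate table")
  strains <- NULL
  if (!is.null(platemap)) {
    stop_missing_cols(platemap, c("well", "strain"), "plate map")
    strains <- stats::setNames(as.character(platemap$strain),
                               as.character(platemap$well))
  }
  wells <- unique(as.character(plate$well))
  rows <- lapply(wells, function(w) {
    sub <- plate[plate$well == w, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    strain <- if (!is.null(strains)) strains[w] else NA_character_
    res <- tryCatch({
      gc <- growth_curve(sub$time_min, sub$od, well_id = w, strain_id = strain)
      fit <- exponential_growth_rate(gc, ...)
      data.frame(well = w, strain = unname(strain), rate_per_h = fit$rate,
                 fit_r2 = fit$fit_r2, n_points_used = fit$n_points_used,
                 window_start_index = fit$window_start_index,
                 truncated = fit$truncated, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(well = w, strain = unname(strain), rate_per_h = NA_real_,
                 fit_r2 = NA_real_, n_points_used = NA_integer_,
                 window_start_index = NA_integer_, truncated = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
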