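# LC-MS peak-area normalization and differential-metabolite selection.
#
# Samples from different strains and batches differ in overall concentration.
# Under the assumption that the majority of metabolites are unchanged between
# strains, a single multiplicative scale factor per (strain, batch) group can
# be estimated jointly with per-metabolite abundances from the model
#
#     E[peakArea] = exp( mutant_id * experiment_id + metabolite_id )
#
# (Wilkinson notation: strain and batch main effects plus their interaction,
# plus a metabolite effect). Peak areas are divided by the fitted group scale
# factors, and metabolites that truly changed between strains are then picked
# out by per-metabolite one-way ANOVA with a Bonferroni family-wise
# correction (alpha / n over the metabolite family).

validate_metabolite_table <- function(table, drop_nonpositive = TRUE) {
  stop_missing_cols(table,
                    c("sample_id", "mutant_id", "experiment_id", "replicate",
                      "metabolite_id", "peak_area"),
                    "metabolite table")
  bad <- !is.finite(table$peak_area) | table$peak_area <= 0
  if (any(bad)) {
    if (!drop_nonpositive) stop("peak areas must be positive", call. = FALSE)
    message(sum(bad), " record(s) with missing/non-positive peak area dropped")
    table <- table[!bad, , drop = FALSE]
  }
  if (!nrow(table)) stop("no usable records in the metabolite table", call. = FALSE)
  table
}

#' Fit the concentration scaling model to a peak-area table
#'
#' Estimates one multiplicative concentration scale factor per
#' (`mutant_id`, `experiment_id`) group under the assumption that most
#' metabolites do not differ between groups. Two dialects are provided:
#'
#' * `"glm"` (default): a Gaussian generalized linear model with log link on
#'   the raw peak areas, `peak_area ~ mutant_id * experiment_id +
#'   metabolite_id`; group offsets are differences of linear predictors on
#'   the link (log) scale.
#' * `"ols"`: ordinary least squares on `log(peak_area)` with the same
#'   design; offsets are differences of fitted log means.
#'
#' On balanced noise-free data both dialects return offsets equal to
#' differences of group means of log peak area. `"ols"` is the default: the
#' formula's response is the log peak area, and under multiplicative
#' (log-normal) noise the raw-scale fit is dominated by the few most
#' abundant metabolites, which inflates the variance of the recovered
#' offsets severalfold.
#'
#' @param table long metabolite table (see [simulate_metabolome()] /
#'   [read_peak_areas()]).
#' @param dialect `"ols"` (default) or `"glm"`.
#' @param reference_strain strain whose groups anchor the offsets; default is
#'   the first strain in sort order. The reference group is
#'   (reference strain, first batch) and has offset 0.
#' @param exclude_metabolites metabolite ids left out of the fit (e.g. ones
#'   already known to change between strains, which would otherwise leak
#'   into the group offsets). The returned offsets still apply to the full
#'   table. See [fit_scaling_model_robust()].
#' @return object of class `scaling_model`: list with `group_log_offsets`
#'   (named `"mutant:experiment"`), `reference_group`, `dialect`, `family`,
#'   `link`, `metabolite_log_effects`, `converged`,
#'   `excluded_metabolites`.
#' @export
fit_scaling_model <- function(table, dialect = c("ols", "glm"),
                              reference_strain = NULL,
                              exclude_metabolites = NULL) {
  dialect <- match.arg(dialect)
  table <- validate_metabolite_table(table)
  if (length(exclude_metabolites)) {
    table <- table[!table$metabolite_id %in% exclude_metabolites, , drop = FALSE]
    if (!nrow(table)) stop("all metabolites excluded", call. = FALSE)
  }
  strains <- sort(unique(table$mutant_id))
  batches <- sort(unique(table$experiment_id))
  if (length(unique(paste(table$mutant_id, table$experiment_id))) < 2L) {
    stop("need at least 2 (mutant, experiment) groups", call. = FALSE)
  }
  if (length(unique(table$metabolite_id)) < 2L) {
    stop("need at least 2 metabolites", call. = FALSE)
  }
  reference_strain <- reference_strain %||% strains[1L]
  if (!reference_strain %in% strains) {
    stop("reference strain ", reference_strain, " absent from the table", call. = FALSE)
  }
  # every declared group must actually carry data
  combos <- expand.grid(mutant_id = strains, experiment_id = batches,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  present <- unique(paste(table$mutant_id, table$experiment_id, sep = ":"))
  missing_groups <- setdiff(paste(combos$mutant_id, combos$experiment_id, sep = ":"), present)
  if (length(missing_groups)) {
    stop("group(s) with no data: ", paste(missing_groups, collapse = ", "), call. = FALSE)
  }

  df <- data.frame(
    y = table$peak_area,
    mutant = factor(table$mutant_id, levels = c(reference_strain,
                                                setdiff(strains, reference_strain))),
    experiment = factor(table$experiment_id, levels = batches),
    metabolite = factor(table$metabolite_id)
  )
  converged <- TRUE
  if (dialect == "ols") {
    fit <- stats::lm(log(y) ~ mutant * experiment + metabolite, data = df)
  } else {
    # warm-start the IRLS from the OLS solution on the log scale: with a log
    # link the two parameterizations share a scale, and the default start
    # (mu = y) can diverge on strongly skewed areas
    start <- stats::coef(stats::lm(log(y) ~ mutant * experiment + metabolite, data = df))
    fit <- stats::glm(y ~ mutant * experiment + metabolite, data = df,
                      family = stats::gaussian(link = "log"),
                      start = start,
                      control = stats::glm.control(maxit = 200))
    converged <- fit$converged
  }

  grid <- data.frame(
    mutant = factor(combos$mutant_id, levels = levels(df$mutant)),
    experiment = factor(combos$experiment_id, levels = levels(df$experiment)),
    metabolite = factor(levels(df$metabolite)[1L], levels = levels(df$metabolite))
  )
  eta <- if (dialect == "ols") {
    stats::predict(fit, newdata = grid)
  } else {
    stats::predict(fit, newdata = grid, type = "link")
  }
  ref_key <- paste(reference_strain, batches[1L], sep = ":")
  keys <- paste(combos$mutant_id, combos$experiment_id, sep = ":")
  offsets <- stats::setNames(as.numeric(eta - eta[keys == ref_key]), keys)

  cf <- stats::coef(fit)
  met_eff <- cf[grepl("^metabolite", names(cf))]
  structure(list(group_log_offsets = offsets,
                 reference_group = ref_key,
                 reference_strain = reference_strain,
                 dialect = dialect,
                 family = if (dialect == "glm") "gaussian" else "gaussian (log response)",
                 link = if (dialect == "glm") "log" else "identity on log(peak_area)",
                 metabolite_log_effects = met_eff,
                 converged = converged,
                 excluded_metabolites = as.character(exclude_metabolites %||% character())),
            class = "scaling_model")
}

#' Two-stage scaling fit that excludes changed metabolites
#'
#' The one-pass scaling model is only unbiased "under the assumption that the
#' majority of metabolites are unchanged"; metabolites that truly differ
#' between strains leak their effects into the group offsets. This wrapper
#' makes the assumption operational: it fits the scaling model, normalizes,
#' flags changed metabolites with [select_changed_metabolites()], and refits
#' the scaling model on the unchanged majority only. The refined offsets
#' still normalize the full table.
#'
#' @inheritParams fit_scaling_model
#' @param alpha,n_tests,correction passed to [select_changed_metabolites()].
#' @return a `scaling_model` whose `excluded_metabolites` records the
#'   metabolites dropped in the second stage.
#' @export
fit_scaling_model_robust <- function(table, dialect = c("ols", "glm"),
                                     reference_strain = NULL,
                                     alpha = 0.01, n_tests = NULL,
                                     correction = "bonferroni") {
  dialect <- match.arg(dialect)
  first <- fit_scaling_model(table, dialect = dialect,
                             reference_strain = reference_strain)
  norm <- normalize_peak_areas(table, first)
  sel <- select_changed_metabolites(norm, alpha = alpha, n_tests = n_tests,
                                    reference_strain = reference_strain,
                                    correction = correction)
  changed <- sel$metabolite_id[sel$significant]
  if (!length(changed)) return(first)
  fit_scaling_model(table, dialect = dialect,
                    reference_strain = reference_strain,
                    exclude_metabolites = changed)
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("<scaling_model> dialect %s (%s family, %s link), reference group %s\n",
              x$dialect, x$family, x$link, x$reference_group))
  cat("group log offsets:\n")
  print(round(x$group_log_offsets, 4))
  if (!x$converged) cat("warning: IRLS did not converge\n")
  invisible(x)
}

#' @export
coef.scaling_model <- function(object, ...) object$group_log_offsets

#' Normalize peak areas by the fitted group scale factors
#'
#' Divides each record's peak area by `exp(group offset)`; records of the
#' reference group are unchanged.
#'
#' @param table long metabolite table.
#' @param model a [fit_scaling_model()] result.
#' @return the table with `peak_area` rescaled.
#' @export
normalize_peak_areas <- function(table, model) {
  stopifnot(inherits(model, "scaling_model"))
  table <- validate_metabolite_table(table)
  keys <- paste(table$mutant_id, table$experiment_id, sep = ":")
  unknown <- setdiff(unique(keys), names(model$group_log_offsets))
  if (length(unknown)) {
    stop("group(s) without a fitted offset: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  table$peak_area <- table$peak_area / exp(model$group_log_offsets[keys])
  table
}

# One-way ANOVA of log areas across strains for each metabolite, vectorized
# over metabolites (all tapply results align by factor level). Returns F, p,
# and a constant flag per metabolite.
anova_by_metabolite <- function(tbl) {
  y <- log(tbl$peak_area)
  met <- factor(tbl$metabolite_id)
  strain <- factor(tbl$mutant_id)
  n_cell <- unclass(base::table(met, strain))
  sum_cell <- tapply(y, list(met, strain), sum)       # NA where a cell is empty
  n_tot <- rowSums(n_cell)
  grand_mean <- as.numeric(tapply(y, met, sum)) / n_tot
  cell_mean <- sum_cell / ifelse(n_cell > 0, n_cell, NA)
  ss_tot <- as.numeric(tapply(y^2, met, sum)) - n_tot * grand_mean^2
  ss_between <- rowSums(n_cell * cell_mean^2, na.rm = TRUE) - n_tot * grand_mean^2
  ss_within <- pmax(ss_tot - ss_between, 0)
  k_present <- rowSums(n_cell > 0)
  df1 <- k_present - 1L
  df2 <- n_tot - k_present
  const <- ss_tot < 1e-12 * pmax(n_tot, 1)
  bad <- df1 < 1L | df2 < 1L
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[const | bad] <- 1
  f[const | bad] <- 0
  data.frame(metabolite_id = levels(met), F_statistic = unname(f),
             p_value = unname(p), constant = unname(const),
             stringsAsFactors = FALSE)
}

#' Select metabolites that changed between strains
#'
#' Per-metabolite one-way ANOVA of log (normalized) peak areas across
#' strains, with a family-wise Bonferroni correction: a metabolite is
#' significant when `p < alpha / n_tests`. `n_tests` defaults to the number
#' of metabolites in the table (the canonical family size here is 142).
#' Holm's step-down correction is available as an alternative. Metabolites
#' constant across all samples get `p = 1` and a `constant` flag.
#'
#' @param table long metabolite table, normally the output of
#'   [normalize_peak_areas()].
#' @param alpha family-wise significance level (default 0.01).
#' @param n_tests family size for the correction; default = number of
#'   metabolites present.
#' @param reference_strain strain against which per-strain mean log
#'   differences are reported; default = first strain in sort order.
#' @param correction `"bonferroni"` (default) or `"holm"`.
#' @return data frame of class `metabolite_diff`: `metabolite_id`,
#'   `F_statistic`, `p_value`, `corrected_alpha`, `significant`, `constant`,
#'   plus one `diff_<strain>` column of mean log differences vs the
#'   reference for each non-reference strain. Attributes `alpha`, `n_tests`,
#'   `correction`, `reference_strain`.
#' @export
select_changed_metabolites <- function(table, alpha = 0.01, n_tests = NULL,
                                       reference_strain = NULL,
                                       correction = c("bonferroni", "holm")) {
  correction <- match.arg(correction)
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  table <- validate_metabolite_table(table)
  strains <- sort(unique(table$mutant_id))
  if (length(strains) < 2L) stop("need at least 2 strains for ANOVA", call. = FALSE)
  reference_strain <- reference_strain %||% strains[1L]
  if (!reference_strain %in% strains) {
    stop("reference strain ", reference_strain, " absent from the table", call. = FALSE)
  }
  res <- anova_by_metabolite(table)
  n_tests <- as.integer(n_tests %||% nrow(res))
  if (n_tests < 1L) stop("`n_tests` must be >= 1", call. = FALSE)
  res$corrected_alpha <- alpha / n_tests
  if (correction == "bonferroni") {
    res$significant <- res$p_value < res$corrected_alpha
  } else {
    adj <- stats::p.adjust(res$p_value, method = "holm", n = max(n_tests, nrow(res)))
    res$significant <- adj < alpha
  }
  # per-strain mean log differences vs the reference strain
  y <- log(table$peak_area)
  means <- tapply(y, list(table$metabolite_id, table$mutant_id), mean)
  means <- means[res$metabolite_id, , drop = FALSE]
  for (s in setdiff(strains, reference_strain)) {
    res[[paste0("diff_", s)]] <- as.numeric(means[, s] - means[, reference_strain])
  }
  attr(res, "alpha") <- alpha
  attr(res, "n_tests") <- n_tests
  attr(res, "correction") <- correction
  attr(res, "reference_strain") <- reference_strain
  class(res) <- c("metabolite_diff", "data.frame")
  res
}

#' Row-standardize a matrix for heat-map display
#'
#' Rescales each row to mean 0 and (sample, n-1) standard deviation 1, the
#' convention used for clustergram heat maps. Constant rows map to all zeros
#' and are flagged in the `constant_rows` attribute.
#'
#' @param m numeric matrix with at least 2 columns (rows = metabolites,
#'   columns = samples).
#' @return matrix of the same shape; attribute `constant_rows` is a logical
#'   vector marking rows that were constant.
#' @export
row_standardize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 columns to standardize rows", call. = FALSE)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  const <- !is.finite(s) | s == 0
  out <- (m - mu) / ifelse(const, 1, s)
  out[const, ] <- 0
  attr(out, "constant_rows") <- unname(const)
  out
}

#' Build a clustergram (dual-dendrogram heat map ordering)
#'
#' Independently clusters the rows (metabolites) and columns (samples or
#' strains) of a matrix — conventionally row-standardized first — and returns
#' the two dendrograms and their leaf orders. Defaults: Euclidean distance,
#' average linkage on both axes.
#'
#' @param m numeric matrix, typically from [row_standardize()].
#' @param linkage_method agglomeration method (default `"average"`).
#' @param distance_metric distance (default `"euclidean"`).
#' @return object of class `clustergram`: list with `row_order`,
#'   `col_order`, `row_tree`, `col_tree` (`hclust` objects), `matrix`,
#'   `linkage_method`, `distance_metric`.
#' @export
clustergram <- function(m, linkage_method = "average",
                        distance_metric = "euclidean") {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("clustergram needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("matrix must be finite", call. = FALSE)
  row_tree <- stats::hclust(stats::dist(m, method = distance_metric),
                            method = linkage_method)
  col_tree <- stats::hclust(stats::dist(t(m), method = distance_metric),
                            method = linkage_method)
  structure(list(row_order = row_tree$order,
                 col_order = col_tree$order,
                 row_tree = row_tree,
                 col_tree = col_tree,
                 matrix = m,
                 linkage_method = linkage_method,
                 distance_metric = distance_metric),
            class = "clustergram")
}

#' @export
print.clustergram <- function(x, ...) {
  cat(sprintf("<clustergram> %d rows x %d columns (%s linkage, %s distance)\n",
              nrow(x$matrix), ncol(x$matrix), x$linkage_method, x$distance_metric))
  invisible(x)
}

#' @export
plot.clustergram <- function(x, col = grDevices::hcl.colors(64, "Green-Orange"),
                             ...) {
  m <- x$matrix[x$row_order, x$col_order, drop = FALSE]
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE], col = col,
                  axes = FALSE, ...)
  graphics::box()
  invisible(x)
}

#' Pivot a long metabolite table to a metabolite x sample matrix
#'
#' @param table long metabolite table.
#' @param log_scale take natural logs of the areas (default `TRUE`).
#' @return numeric matrix with metabolites as rows and samples as columns.
#' @export
metabolite_matrix <- function(table, log_scale = TRUE) {
  table <- validate_metabolite_table(table)
  v <- if (log_scale) log(table$peak_area) else table$peak_area
  m <- tapply(v, list(table$metabolite_id, table$sample_id), mean)
  if (anyNA(m)) stop("metabolite set is not identical across samples", call. = FALSE)
  m
}

#' Per-strain differences of significant metabolites vs a reference strain
#'
#' For every significant metabolite and every non-reference strain, the mean
#' log normalized area minus the reference strain's mean — the quantity shown
#' in per-strain "difference from wild type" panels.
#'
#' @param table normalized long metabolite table.
#' @param significant a [select_changed_metabolites()] result (or any data
#'   frame with `metabolite_id` and logical `significant`).
#' @param reference_strain the comparison baseline (e.g. the wild type).
#' @return long data frame `metabolite_id`, `strain`, `log_difference`
#'   (empty when nothing is significant).
#' @export
strain_difference_panel <- function(table, significant, reference_strain) {
  table <- validate_metabolite_table(table)
  strains <- sort(unique(table$mutant_id))
  if (!reference_strain %in% strains) {
    stop("reference strain ", reference_strain, " absent from the table", call. = FALSE)
  }
  sig_ids <- significant$metabolite_id[significant$significant]
  others <- setdiff(strains, reference_strain)
  if (!length(sig_ids)) {
    return(data.frame(metabolite_id = character(), strain = character(),
                      log_difference = numeric(), stringsAsFactors = FALSE))
  }
  sub <- table[table$metabolite_id %in% sig_ids, , drop = FALSE]
  y <- log(sub$peak_area)
  means <- tapply(y, list(sub$metabolite_id, sub$mutant_id), mean)
  out <- expand.grid(metabolite_id = sig_ids, strain = others,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$log_difference <- means[cbind(out$metabolite_id, out$strain)] -
    means[cbind(out$metabolite_id, rep(reference_strain, nrow(out)))]
  out
}
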