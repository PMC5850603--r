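# Generators for every input the pipeline consumes, with known ground truth.
# Distributional choices (logistic OD + additive Gaussian noise, multinomial
# plating, log-normal peak areas) are stand-ins chosen to match the downstream
# models; the methods vignette discusses what they do and do not emulate.

#' Simulate a plate-reader growth curve
#'
#' Logistic trajectory `OD(t) = K od0 e^{rt} / (K + od0 (e^{rt} - 1))` sampled
#' every `interval_min` minutes with additive Gaussian measurement noise
#' (floored at 0). With `carrying_capacity` much larger than the observed ODs
#' this reduces to clean exponential growth `od0 e^{rt}`.
#'
#' @param rate per-hour exponential rate; non-positive values give flat or
#'   declining curves.
#' @param od0 initial OD, must be positive and below `carrying_capacity`.
#' @param carrying_capacity saturation OD (default 1).
#' @param interval_min sampling interval in minutes (default 10, the usual
#'   plate-reader cadence).
#' @param duration_h total duration in hours (default 24).
#' @param noise_sd standard deviation of additive measurement noise in OD
#'   units (default 0).
#' @param seed integer seed; the generator is a pure function of it.
#' @param well_id,strain_id labels carried into the curve.
#' @return a [growth_curve()].
#' @export
simulate_growth_curve <- function(rate, od0, carrying_capacity = 1,
                                  interval_min = 10, duration_h = 24,
                                  noise_sd = 0, seed = 1L,
                                  well_id = "A1", strain_id = "sim") {
  if (!is.numeric(od0) || od0 <= 0) stop("`od0` must be positive", call. = FALSE)
  if (carrying_capacity <= 0) stop("`carrying_capacity` must be positive", call. = FALSE)
  if (od0 >= carrying_capacity) stop("`od0` must be below `carrying_capacity`", call. = FALSE)
  if (interval_min <= 0) stop("`interval_min` must be positive", call. = FALSE)
  if (duration_h <= 0) stop("`duration_h` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  t_min <- seq(0, duration_h * 60, by = interval_min)
  t_h <- t_min / 60
  e <- exp(rate * t_h)
  od <- carrying_capacity * od0 * e / (carrying_capacity + od0 * (e - 1))
  if (noise_sd > 0) {
    od <- with_seed(seed, od + stats::rnorm(length(od), sd = noise_sd))
    od <- pmax(od, 0)
  }
  growth_curve(t_min, od, well_id = well_id, strain_id = strain_id)
}

#' Ground truth for a simulated competition assay
#'
#' Describes one actor-recipient competition: the actor's starting frequency,
#' a per-generation selection coefficient `s`, the number of generations
#' elapsed, and the multinomial sampling depth that mimics dilution plating.
#' The default start fraction 25/26 is the 25:1 actor-to-recipient inoculum of
#' the swarming actor-recipient assay.
#'
#' @param start_fraction_actor actor frequency at inoculation, in (0, 1).
#' @param selection_coefficient per-generation selection coefficient of the
#'   actor (0 = neutral).
#' @param generations non-negative number of generations between the start
#'   and end samples (default 10, roughly a 24-h swarm expansion).
#' @param sampling_depth number of colonies counted per time point
#'   (default 1000).
#' @param seed integer seed.
#' @return object of class `competition_truth`.
#' @export
competition_truth <- function(start_fraction_actor = 25 / 26,
                              selection_coefficient = 0,
                              generations = 10,
                              sampling_depth = 1000L,
                              seed = 1L) {
  if (start_fraction_actor <= 0 || start_fraction_actor >= 1) {
    stop("`start_fraction_actor` must lie in (0, 1)", call. = FALSE)
  }
  if (generations < 0) stop("`generations` must be non-negative", call. = FALSE)
  sampling_depth <- as.integer(sampling_depth)
  if (sampling_depth < 1L) stop("`sampling_depth` must be >= 1", call. = FALSE)
  structure(list(start_fraction_actor = start_fraction_actor,
                 selection_coefficient = selection_coefficient,
                 generations = generations,
                 sampling_depth = sampling_depth,
                 seed = as.integer(seed)),
            class = "competition_truth")
}

#' Expected final actor frequency under selection
#'
#' Deterministic logistic frequency update
#' `p' = p e^{sg} / (p e^{sg} + (1 - p))` for start frequency `p`, selection
#' coefficient `s` per generation and `g` generations.
#'
#' @param p start frequency in `[0, 1]`.
#' @param s per-generation selection coefficient.
#' @param g generations.
#' @return expected final frequency.
#' @examples
#' expected_final_fraction(0.5, log(4), 1)  # 0.8
#' @export
expected_final_fraction <- function(p, s, g) {
  w <- p * exp(s * g)
  w / (w + (1 - p))
}

#' Simulate one actor-recipient competition observation
#'
#' Draws start colony counts multinomially at the true start frequency, moves
#' the frequency forward with [expected_final_fraction()], and draws end
#' counts multinomially at the updated frequency, mimicking CFU plating of the
#' mixed population before and after the competition.
#'
#' @param truth a [competition_truth()].
#' @param assay_id,actor_id,recipient_id labels for the output sheet.
#' @param bio_rep,tech_rep replicate indices.
#' @param is_neutral_control flag marking the neutral-competitor arm.
#' @param seed optional override of `truth$seed`.
#' @return data frame in the CFU-sheet layout: columns `assay_id`, `actor_id`,
#'   `recipient_id`, `stage` (`"start"`/`"end"`), `strain_label`, `cfu_per_ml`
#'   (here the raw colony counts), `bio_rep`, `tech_rep`,
#'   `is_neutral_control`; attribute `expected_final_fraction` holds the
#'   deterministic expectation.
#' @export
simulate_competition <- function(truth, assay_id = "assay1",
                                 actor_id = "actor", recipient_id = "recipient",
                                 bio_rep = 1L, tech_rep = 1L,
                                 is_neutral_control = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "competition_truth"))
  p0 <- truth$start_fraction_actor
  p1 <- expected_final_fraction(p0, truth$selection_coefficient, truth$generations)
  depth <- truth$sampling_depth
  counts <- with_seed(seed %||% truth$seed, {
    start <- stats::rmultinom(1, depth, c(p0, 1 - p0))[, 1]
    end <- stats::rmultinom(1, depth, c(p1, 1 - p1))[, 1]
    list(start = start, end = end)
  })
  out <- data.frame(
    assay_id = assay_id,
    actor_id = actor_id,
    recipient_id = recipient_id,
    stage = rep(c("start", "end"), each = 2L),
    strain_label = rep(c(actor_id, recipient_id), 2L),
    cfu_per_ml = as.numeric(c(counts$start, counts$end)),
    bio_rep = as.integer(bio_rep),
    tech_rep = as.integer(tech_rep),
    is_neutral_control = is_neutral_control,
    stringsAsFactors = FALSE
  )
  attr(out, "expected_final_fraction") <- p1
  out
}

#' Simulate a full actor-recipient assay with neutral controls
#'
#' Produces the standard replicated design: `n_bio` biological x `n_tech`
#' technical replicates of the actor arm plus a matched neutral-control arm
#' (selection coefficient 0) for every biological replicate, as required by
#' [aggregate_assay()].
#'
#' @param truth a [competition_truth()] for the actor arm.
#' @param n_bio,n_tech biological / technical replicate counts (defaults 3
#'   and 3, the assay's total n of 9).
#' @param assay_id,actor_id,recipient_id,neutral_id labels.
#' @param seed integer seed for the whole sheet.
#' @return CFU-sheet data frame (rows of [simulate_competition()] output).
#' @export
simulate_social_assay <- function(truth, n_bio = 3L, n_tech = 3L,
                                  assay_id = "assay1", actor_id = "actor",
                                  recipient_id = "recipient",
                                  neutral_id = "neutral", seed = 1L) {
  stopifnot(inherits(truth, "competition_truth"))
  neutral <- competition_truth(truth$start_fraction_actor, 0, truth$generations,
                               truth$sampling_depth, seed = truth$seed)
  sheets <- list()
  k <- 0L
  for (b in seq_len(n_bio)) {
    for (t in seq_len(n_tech)) {
      k <- k + 1L
      sheets[[length(sheets) + 1L]] <- simulate_competition(
        truth, assay_id, actor_id, recipient_id, b, t,
        is_neutral_control = FALSE, seed = seed * 10000L + k)
      sheets[[length(sheets) + 1L]] <- simulate_competition(
        neutral, assay_id, neutral_id, recipient_id, b, t,
        is_neutral_control = TRUE, seed = seed * 10000L + 5000L + k)
    }
  }
  out <- do.call(rbind, sheets)
  rownames(out) <- NULL
  out
}

#' Ground truth for a simulated metabolome
#'
#' Generative counterpart of the scaling model fitted downstream: peak areas
#' are `exp(baseline + strain effect + log scale factor + noise)`, with one
#' multiplicative concentration scale factor per (strain, batch) group and a
#' sparse set of truly changed metabolites. The reference strain's effects are
#' zero by construction. Defaults mirror the study design: 142 metabolites,
#' 5 strains, 2 batches, ~7% changed metabolites at a 4-fold effect.
#'
#' @param n_metabolites number of metabolites (default 142).
#' @param strains character vector of strain labels; the first is the
#'   reference (wild type) unless `reference_strain` says otherwise.
#' @param batches character vector of batch / experiment labels (default 2).
#' @param reference_strain label whose effects are fixed at 0.
#' @param n_changed number of truly changed metabolites (default 10).
#' @param effect_log_fold log fold change planted for each changed metabolite
#'   (default `log(4)`, a 4-fold effect); each changed metabolite is assigned
#'   to one randomly chosen non-reference strain.
#' @param scale_range range from which per-group scale factors are drawn
#'   uniformly (default `c(0.5, 2)`); the reference group's factor is set
#'   to 1 so true log offsets are simply `log` of the group factors.
#' @param baseline_mean,baseline_sd log-scale baseline abundance distribution
#'   (defaults 10 and 2, i.e. typical peak areas around e^10).
#' @param noise_sd_log standard deviation of Gaussian noise on the log scale
#'   (default 0.2, moderate LC-MS technical noise).
#' @param seed integer seed.
#' @return object of class `metabolome_truth` with fields
#'   `scale_factor_per_group` (named by `"strain:batch"`),
#'   `changed_metabolites`, `effect_log_fold` (matrix metabolite x strain),
#'   `baseline_log_abundance`, `noise_sd_log`, `seed`.
#' @export
metabolome_truth <- function(n_metabolites = 142L,
                             strains = c("WT", "dRhlA", "dCbrA", "crc_sup", "hfq_sup"),
                             batches = c("batch1", "batch2"),
                             reference_strain = strains[1L],
                             n_changed = 10L,
                             effect_log_fold = log(4),
                             scale_range = c(0.5, 2),
                             baseline_mean = 10, baseline_sd = 2,
                             noise_sd_log = 0.2,
                             seed = 1L) {
  if (!length(strains)) stop("`strains` must be non-empty", call. = FALSE)
  if (!reference_strain %in% strains) {
    stop("`reference_strain` must be one of `strains`", call. = FALSE)
  }
  n_metabolites <- as.integer(n_metabolites)
  n_changed <- as.integer(n_changed)
  if (n_changed > n_metabolites) stop("more changed metabolites than metabolites", call. = FALSE)
  if (any(scale_range <= 0)) stop("scale factors must be strictly positive", call. = FALSE)
  metabolites <- sprintf("m%03d", seq_len(n_metabolites))
  groups <- expand.grid(strain = strains, batch = batches,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  group_keys <- paste(groups$strain, groups$batch, sep = ":")
  truth <- with_seed(seed, {
    sf <- stats::runif(nrow(groups), scale_range[1L], scale_range[2L])
    names(sf) <- group_keys
    # pin the reference strain's groups at 1 so true offsets are log(sf)
    sf[groups$strain == reference_strain] <- 1
    baseline <- stats::rnorm(n_metabolites, baseline_mean, baseline_sd)
    names(baseline) <- metabolites
    changed <- sort(sample(metabolites, n_changed))
    eff <- matrix(0, n_metabolites, length(strains),
                  dimnames = list(metabolites, strains))
    non_ref <- setdiff(strains, reference_strain)
    if (length(non_ref) && n_changed > 0L) {
      hit <- sample(non_ref, n_changed, replace = TRUE)
      for (i in seq_len(n_changed)) eff[changed[i], hit[i]] <- effect_log_fold
    }
    list(sf = sf, baseline = baseline, changed = changed, eff = eff)
  })
  structure(list(scale_factor_per_group = truth$sf,
                 changed_metabolites = truth$changed,
                 effect_log_fold = truth$eff,
                 baseline_log_abundance = truth$baseline,
                 noise_sd_log = noise_sd_log,
                 strains = strains,
                 batches = batches,
                 reference_strain = reference_strain,
                 seed = as.integer(seed)),
            class = "metabolome_truth")
}

#' Simulate a long-form metabolite peak-area table
#'
#' Generates `replicates_per_cell` technical replicates for every
#' (strain, batch) group of `truth`:
#' `peakArea = exp(baseline + strain effect + log scale + N(0, noise_sd_log))`.
#' All areas are strictly positive by construction.
#'
#' @param truth a [metabolome_truth()].
#' @param replicates_per_cell technical replicates per (strain, batch) cell
#'   (default 3; with 2 batches this gives the study's 6 replicates/strain).
#' @param seed optional override of `truth$seed` for the noise draw.
#' @return list of class `metabolome_sim` with elements `table` (long data
#'   frame: `sample_id`, `mutant_id`, `experiment_id`, `replicate`,
#'   `metabolite_id`, `peak_area`) and `truth`.
#' @export
simulate_metabolome <- function(truth, replicates_per_cell = 3L, seed = NULL) {
  stopifnot(inherits(truth, "metabolome_truth"))
  replicates_per_cell <- as.integer(replicates_per_cell)
  if (replicates_per_cell < 1L) stop("`replicates_per_cell` must be >= 1", call. = FALSE)
  metabolites <- names(truth$baseline_log_abundance)
  design <- expand.grid(replicate = seq_len(replicates_per_cell),
                        strain = truth$strains, batch = truth$batches,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_m <- length(metabolites)
  n_s <- nrow(design)
  log_scale <- log(truth$scale_factor_per_group[paste(design$strain, design$batch, sep = ":")])
  # metabolite x sample matrix of noise-free log areas
  mu <- outer(truth$baseline_log_abundance, log_scale, `+`) +
    truth$effect_log_fold[, design$strain, drop = FALSE]
  noise <- if (truth$noise_sd_log > 0) {
    with_seed(seed %||% truth$seed,
              matrix(stats::rnorm(n_m * n_s, sd = truth$noise_sd_log), n_m, n_s))
  } else {
    matrix(0, n_m, n_s)
  }
  areas <- exp(mu + noise)
  sample_id <- sprintf("%s_%s_r%d", design$strain, design$batch, design$replicate)
  table <- data.frame(
    sample_id = rep(sample_id, each = n_m),
    mutant_id = rep(design$strain, each = n_m),
    experiment_id = rep(design$batch, each = n_m),
    replicate = rep(design$replicate, each = n_m),
    metabolite_id = rep(metabolites, times = n_s),
    peak_area = as.vector(areas),
    stringsAsFactors = FALSE
  )
  structure(list(table = table, truth = truth), class = "metabolome_sim")
}

#' Simulate an isolate phenotype panel with planted clusters
#'
#' Draws `n_populations * isolates_per_population` isolates around
#' `n_clusters` well-separated centroids in a 6-channel feature space (the
#' liquid-culture channels: absorbance 600/690/310 nm, GFP, pyoverdine and
#' 340/440 fluorescence). Centroid `k` sits at `separation` along axis `k`
#' (axes recycled when `n_clusters` exceeds the channel count, with an offset
#' to keep centroids distinct), so all centroid pairs are at least
#' `separation` apart. Isolates are assigned to clusters round-robin across
#' populations and the planted membership is recorded as ground truth.
#'
#' @param n_populations number of evolved populations (default 6).
#' @param isolates_per_population isolates sampled per population (default 8).
#' @param n_clusters number of planted phenotype clusters (>= 1).
#' @param separation centroid spacing in feature units.
#' @param noise_sd within-cluster Gaussian spread per channel.
#' @param seed integer seed.
#' @return data frame of class `phenotype_panel`: columns `isolate`,
#'   `population`, the 6 channels (`A600`, `A690`, `A310`, `GFP`, `PVD`,
#'   `F340`), and `true_cluster` (planted membership).
#' @export
simulate_phenotype_panel <- function(n_populations = 6L,
                                     isolates_per_population = 8L,
                                     n_clusters, separation, noise_sd,
                                     seed = 1L) {
  n_populations <- as.integer(n_populations)
  isolates_per_population <- as.integer(isolates_per_population)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) stop("`n_clusters` must be >= 1", call. = FALSE)
  n_iso <- n_populations * isolates_per_population
  if (n_clusters > n_iso) stop("`n_clusters` exceeds the total number of isolates", call. = FALSE)
  if (separation <= 0) stop("`separation` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  channels <- c("A600", "A690", "A310", "GFP", "PVD", "F340")
  p <- length(channels)
  centers <- matrix(0, n_clusters, p)
  for (k in seq_len(n_clusters)) {
    ax <- ((k - 1L) %% p) + 1L
    centers[k, ax] <- centers[k, ax] + separation * (1 + (k - 1L) %/% p)
  }
  cluster_of <- rep_len(seq_len(n_clusters), n_iso)
  population <- rep(seq_len(n_populations), each = isolates_per_population)
  x <- centers[cluster_of, , drop = FALSE]
  if (noise_sd > 0) {
    x <- x + with_seed(seed, matrix(stats::rnorm(n_iso * p, sd = noise_sd), n_iso, p))
  }
  colnames(x) <- channels
  out <- data.frame(isolate = sprintf("p%d_i%d", population,
                                      rep(seq_len(isolates_per_population), n_populations)),
                    population = population, x, true_cluster = cluster_of,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_panel", "data.frame")
  out
}

#' Write generator ground truth to a JSON sidecar
#'
#' Stores the parameters of a `metabolome_truth` or `competition_truth`
#' object next to a generated dataset so recovery tests can reload them.
#'
#' @param truth a truth object from this module.
#' @param path output file path (conventionally `truth.json`).
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  if (!is.null(x$effect_log_fold)) {
    x$effect_log_fold <- as.data.frame(x$effect_log_fold)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
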