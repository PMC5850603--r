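# Actor-recipient assay statistics from CFU counts.
#
# The assay mixes a helping "actor" strain with a non-producing "recipient"
# at a 25:1 inoculum, lets the mixture swarm for 24 h, and plates dilutions
# at the start and end. Two statistics summarise the outcome:
#   benefit to actor     = (starting actor fraction) - (final actor fraction)
#                          [the printed convention: positive when the actor
#                           LOSES frequency; a "gain" convention negates it]
#   benefit to recipient = recipient total with actor / recipient total with
#                          a neutral competitor (1 = no benefit)

#' CFU/ml from a dilution-plate colony count
#'
#' `colony_count / (dilution_factor * plated_volume_ml)`. A zero count
#' returns 0 flagged as below the detection limit.
#'
#' @param colony_count non-negative integer colony count(s).
#' @param dilution_factor plated dilution in (0, 1], e.g. `1e-6`.
#' @param plated_volume_ml plated volume in ml.
#' @return numeric CFU/ml, with logical attribute `below_detection`.
#' @examples
#' cfu_estimate(50, 1e-6, 0.1)  # 5e8 CFU/ml
#' @export
cfu_estimate <- function(colony_count, dilution_factor, plated_volume_ml) {
  if (any(colony_count < 0)) stop("`colony_count` must be non-negative", call. = FALSE)
  if (any(dilution_factor <= 0) || any(dilution_factor > 1)) {
    stop("`dilution_factor` must be in (0, 1]", call. = FALSE)
  }
  if (any(plated_volume_ml <= 0)) stop("`plated_volume_ml` must be positive", call. = FALSE)
  out <- colony_count / (dilution_factor * plated_volume_ml)
  attr(out, "below_detection") <- colony_count == 0
  out
}

#' Fraction of the actor strain in a mixed population
#'
#' @param actor_abundance actor CFU/ml (or count).
#' @param total_abundance total CFU/ml (or count), must be positive and at
#'   least the actor abundance.
#' @return fraction in `[0, 1]`.
#' @export
actor_fraction <- function(actor_abundance, total_abundance) {
  if (any(total_abundance <= 0)) stop("total abundance must be positive", call. = FALSE)
  if (any(actor_abundance < 0)) stop("actor abundance must be non-negative", call. = FALSE)
  if (any(actor_abundance > total_abundance)) {
    stop("actor abundance exceeds total abundance", call. = FALSE)
  }
  actor_abundance / total_abundance
}

#' Benefit to the actor strain
#'
#' The printed convention is `start - final` actor fraction, which is
#' POSITIVE when the actor declines in frequency (i.e. pays a cost). The
#' narrative convention (`sign_convention = "gain"`) returns `final - start`
#' so that a declining actor has a negative "net benefit". Both are exposed
#' because the two readings conflict; neither is silently preferred beyond
#' the printed default.
#'
#' @param start_fraction,final_fraction actor fractions in `[0, 1]`.
#' @param sign_convention `"printed"` (default, start - final) or `"gain"`
#'   (final - start).
#' @return real in `[-1, 1]`.
#' @export
benefit_to_actor <- function(start_fraction, final_fraction,
                             sign_convention = c("printed", "gain")) {
  sign_convention <- match.arg(sign_convention)
  if (any(start_fraction < 0 | start_fraction > 1) ||
      any(final_fraction < 0 | final_fraction > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  d <- start_fraction - final_fraction
  if (sign_convention == "gain") -d else d
}

#' Benefit to the recipient strain
#'
#' Ratio of the recipient's total cell number when mixed with the actor to
#' its total when mixed with a neutral (non-helping) competitor; 1 means no
#' benefit.
#'
#' @param recipient_total_with_actor recipient CFU/ml in the actor arm.
#' @param recipient_total_with_neutral recipient CFU/ml in the
#'   neutral-control arm; must be positive.
#' @return non-negative ratio.
#' @export
benefit_to_recipient <- function(recipient_total_with_actor,
                                 recipient_total_with_neutral) {
  if (any(recipient_total_with_neutral <= 0)) {
    stop("neutral-control recipient total must be positive", call. = FALSE)
  }
  if (any(recipient_total_with_actor < 0)) {
    stop("recipient total must be non-negative", call. = FALSE)
  }
  recipient_total_with_actor / recipient_total_with_neutral
}

#' Aggregate a replicated actor-recipient assay
#'
#' Computes per-replicate benefit statistics from a long CFU sheet and
#' aggregates them flat over all replicates (the design is 3 biological x 3
#' technical replicates, reported as a single n of 9). The 95% confidence
#' interval is t-based on the replicate values. Recipient benefit divides
#' each actor-arm replicate's recipient end total by the mean neutral-control
#' recipient end total of the same biological replicate when one exists, else
#' by the pooled control mean.
#'
#' @param observations data frame with columns `assay_id`, `actor_id`,
#'   `recipient_id`, `stage` (`"start"`/`"end"`), `strain_label`,
#'   `cfu_per_ml`, `bio_rep`, `tech_rep`, `is_neutral_control` (see
#'   [read_cfu_sheet()] / [simulate_social_assay()]).
#' @param sign_convention passed to [benefit_to_actor()].
#' @param conf_level confidence level (default 0.95).
#' @return object of class `social_benefit`: list with `per_replicate` data
#'   frame, `benefit_to_actor` / `benefit_to_recipient` means,
#'   `ci_benefit_to_actor` / `ci_benefit_to_recipient`, `n_replicates`,
#'   `sign_convention`.
#' @export
aggregate_assay <- function(observations,
                            sign_convention = c("printed", "gain"),
                            conf_level = 0.95) {
  sign_convention <- match.arg(sign_convention)
  stop_missing_cols(observations,
                    c("assay_id", "actor_id", "recipient_id", "stage",
                      "strain_label", "cfu_per_ml", "bio_rep", "tech_rep",
                      "is_neutral_control"),
                    "CFU sheet")
  obs <- observations
  if (!all(obs$stage %in% c("start", "end"))) {
    stop("`stage` must be \"start\" or \"end\"", call. = FALSE)
  }
  actor_arm <- obs[!obs$is_neutral_control, , drop = FALSE]
  control_arm <- obs[obs$is_neutral_control, , drop = FALSE]
  if (!nrow(actor_arm)) stop("no non-control observations", call. = FALSE)

  rep_stats <- function(arm) {
    keys <- unique(arm[, c("assay_id", "bio_rep", "tech_rep")])
    bad <- character()
    rows <- vector("list", nrow(keys))
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      sub <- arm[arm$assay_id == k$assay_id & arm$bio_rep == k$bio_rep &
                   arm$tech_rep == k$tech_rep, , drop = FALSE]
      key_lab <- sprintf("(assay %s, bio_rep %s, tech_rep %s)",
                         k$assay_id, k$bio_rep, k$tech_rep)
      for (st in c("start", "end")) {
        stage_sub <- sub[sub$stage == st, , drop = FALSE]
        if (nrow(stage_sub) < 2L ||
            !all(c(sub$actor_id[1L], sub$recipient_id[1L]) %in% stage_sub$strain_label)) {
          bad <- c(bad, paste(key_lab, "missing", st, "stage"))
        }
      }
      if (length(bad)) next
      get_cfu <- function(st, strain) {
        sum(sub$cfu_per_ml[sub$stage == st & sub$strain_label == strain])
      }
      actor_lab <- sub$actor_id[1L]
      recip_lab <- sub$recipient_id[1L]
      a0 <- get_cfu("start", actor_lab); r0 <- get_cfu("start", recip_lab)
      a1 <- get_cfu("end", actor_lab); r1 <- get_cfu("end", recip_lab)
      rows[[i]] <- data.frame(
        assay_id = k$assay_id, bio_rep = k$bio_rep, tech_rep = k$tech_rep,
        start_fraction = actor_fraction(a0, a0 + r0),
        final_fraction = actor_fraction(a1, a1 + r1),
        recipient_end_total = r1,
        stringsAsFactors = FALSE)
    }
    if (length(bad)) {
      stop("unpaired start/end observations: ", paste(unique(bad), collapse = "; "),
           call. = FALSE)
    }
    do.call(rbind, rows)
  }

  per_rep <- rep_stats(actor_arm)
  per_rep$benefit_to_actor <- benefit_to_actor(per_rep$start_fraction,
                                               per_rep$final_fraction,
                                               sign_convention)
  have_control <- nrow(control_arm) > 0L
  if (have_control) {
    ctrl <- rep_stats(control_arm)
    ctrl_by_bio <- tapply(ctrl$recipient_end_total, ctrl$bio_rep, mean)
    pooled <- mean(ctrl$recipient_end_total)
    ctrl_ref <- ctrl_by_bio[as.character(per_rep$bio_rep)]
    ctrl_ref[is.na(ctrl_ref)] <- pooled
    per_rep$benefit_to_recipient <- benefit_to_recipient(per_rep$recipient_end_total,
                                                         as.numeric(ctrl_ref))
  } else {
    per_rep$benefit_to_recipient <- NA_real_
  }

  t_ci <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 2L) return(c(NA_real_, NA_real_))
    m <- mean(x); se <- stats::sd(x) / sqrt(n)
    q <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L)
    c(m - q * se, m + q * se)
  }

  structure(list(
    per_replicate = per_rep,
    benefit_to_actor = mean(per_rep$benefit_to_actor),
    ci_benefit_to_actor = t_ci(per_rep$benefit_to_actor),
    benefit_to_recipient = if (have_control) mean(per_rep$benefit_to_recipient) else NA_real_,
    ci_benefit_to_recipient = if (have_control) t_ci(per_rep$benefit_to_recipient) else c(NA_real_, NA_real_),
    n_replicates = nrow(per_rep),
    sign_convention = sign_convention,
    conf_level = conf_level
  ), class = "social_benefit")
}

#' @export
print.social_benefit <- function(x, ...) {
  cat(sprintf("<social_benefit> n = %d replicates (%s sign convention)\n",
              x$n_replicates, x$sign_convention))
  cat(sprintf("  benefit to actor:     %.4f  [%.4f, %.4f]\n",
              x$benefit_to_actor, x$ci_benefit_to_actor[1L], x$ci_benefit_to_actor[2L]))
  if (is.finite(x$benefit_to_recipient)) {
    cat(sprintf("  benefit to recipient: %.4f  [%.4f, %.4f]\n",
                x$benefit_to_recipient, x$ci_benefit_to_recipient[1L],
                x$ci_benefit_to_recipient[2L]))
  } else {
    cat("  benefit to recipient: not computed (no neutral-control arm)\n")
  }
  invisible(x)
}
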