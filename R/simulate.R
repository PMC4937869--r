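# Seeded synthetic-data generators: a ground-truth potency landscape,
# participant-style model ensembles, a noisy multi-source literature corpus
# and HTS-style AUC training scores. Together they emulate the statistical
# structure of the real study inputs so the full pipeline is testable
# without downloads. Every generator takes an explicit seed and is
# bit-reproducible under (configuration, seed).

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline assumes: ~10% active
#' prevalence, active log10-AC50 uniform on \[-2, 3\] log10 micromolar
#' (spanning all five potency classes), a geometric literature source-count
#' distribution with mean 3 truncated at 20, and agonist/antagonist activity
#' nested inside binding activity (antagonists rarer, mirroring the highly
#' unbalanced antagonist sets).
#'
#' @param n_chemicals number of chemicals.
#' @param active_prevalence probability a chemical is an active binder.
#' @param log_ac50_range range of log10 AC50 (micromolar) for actives.
#' @param p_agonist,p_antagonist probability an active binder is an active
#'   agonist / antagonist.
#' @param n_models models per activity type in a simulated ensemble.
#' @param sens_range,spec_range,coverage_range per-model parameter ranges.
#' @param potency_grad detection-probability gradient across potency classes
#'   (see [simulate_model_predictions()]).
#' @param ad_model_fraction fraction of models that supply AD flags.
#' @param ad_fraction fraction of a model's covered chemicals inside its AD.
#' @param source_mean,source_max literature source-count distribution
#'   (geometric, truncated).
#' @param fp_rate,fn_rate per-source probability of reporting a true
#'   inactive as active / a true active as inactive.
#' @param source_log_sd lognormal (log10) spread of reported AC50s around
#'   the true value.
#' @param units unit mix for reported concentrations.
#' @param proliferation_fraction fraction of agonist records emitted as
#'   percent-proliferation assays.
#' @param decoy_fraction fraction of chemicals contributing an in vivo or
#'   cytotoxicity decoy record (dropped during harmonization).
#' @param seed master seed (mandatory).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chemicals = 2000, active_prevalence = 0.10,
                       log_ac50_range = c(-2, 3), p_agonist = 0.5,
                       p_antagonist = 0.25, n_models = 15,
                       sens_range = c(0.7, 0.9), spec_range = c(0.7, 0.9),
                       coverage_range = c(0.8, 1), potency_grad = 0.25,
                       ad_model_fraction = 0.4,
                       ad_fraction = 0.8, source_mean = 3, source_max = 20,
                       fp_rate = 0.10, fn_rate = 0.10, source_log_sd = 0.3,
                       units = c("uM", "nM", "mM", "M"),
                       proliferation_fraction = 0.10, decoy_fraction = 0.05,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  probs <- c(active_prevalence, p_agonist, p_antagonist, ad_model_fraction,
             ad_fraction, fp_rate, fn_rate, proliferation_fraction,
             decoy_fraction, sens_range, spec_range, coverage_range)
  stopifnot(all(probs >= 0 & probs <= 1), n_chemicals >= 1,
            source_mean >= 1, source_max >= 1, source_log_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# one independent stream per generator, derived from the master seed
.sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(stream)) %% 2147483629)
}

.synthetic_inchi <- function(i) {
  k <- i + 3L
  sprintf("InChI=1S/C%dH%d/c1-%d", k, 2L * k + 2L, k)
}

#' Generate a ground-truth activity landscape
#'
#' Binding activity is drawn at the configured prevalence; active binders
#' are active agonists/antagonists with the configured conditional
#' probabilities (so agonist or antagonist activity always implies binding
#' activity, which makes the correction rules non-trivial). Each active
#' endpoint receives an AC50 drawn log-uniformly over the configured range;
#' the binding AC50 is the most potent of the chemical's endpoint AC50s.
#' Inactive endpoints carry the 1 M sentinel.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` if given.
#' @return data.frame with per-activity-type columns `active_*`, `ac50_*`
#'   (micromolar) and `class_*`.
#' @export
generate_ground_truth <- function(config, seed = config$seed) {
  set.seed(.sub_seed(seed, 1L))
  n <- config$n_chemicals
  inchi <- .synthetic_inchi(seq_len(n))
  active_b <- stats::runif(n) < config$active_prevalence
  active_ag <- active_b & stats::runif(n) < config$p_agonist
  active_an <- active_b & stats::runif(n) < config$p_antagonist
  draw_ac50 <- function(active) {
    ifelse(active,
           10^stats::runif(length(active), config$log_ac50_range[1],
                           config$log_ac50_range[2]),
           INACTIVE_AC50_UM)
  }
  ac50_b <- draw_ac50(active_b)
  ac50_ag <- draw_ac50(active_ag)
  ac50_an <- draw_ac50(active_an)
  ac50_b <- pmin(ac50_b, ac50_ag, ac50_an)
  data.frame(inchi = inchi,
             active_binding = active_b, active_agonist = active_ag,
             active_antagonist = active_an,
             ac50_binding = ac50_b, ac50_agonist = ac50_ag,
             ac50_antagonist = ac50_an,
             class_binding = as.character(classify_potency(ac50_b)),
             class_agonist = as.character(classify_potency(ac50_ag)),
             class_antagonist = as.character(classify_potency(ac50_an)),
             stringsAsFactors = FALSE)
}

#' Simulate one model's predictions against a ground truth
#'
#' Each covered chemical is called active with probability `sens` if truly
#' active and `1 - spec` if truly inactive; uncovered chemicals are not
#' predicted. When `ad_fraction` is given, AD flags are assigned to that
#' fraction of covered chemicals. The continuous variant emits a lognormal
#' perturbation of the true log10 AC50 for its true-positive calls and a
#' log-uniform draw for its false positives.
#'
#' @param truth data.frame from [generate_ground_truth()].
#' @param activity_type binding / agonist / antagonist.
#' @param sens,spec,coverage model operating characteristics in \[0, 1\].
#' @param ad_fraction fraction of covered chemicals inside the AD, or `NULL`
#'   for a model without AD information.
#' @param potency_grad slope of the per-chemical detection probability in the
#'   potency class score, centered so the marginal sensitivity over actives
#'   stays `sens` (stronger actives are easier to detect, mirroring the
#'   higher model agreement observed for potent chemicals). Set 0 for a flat
#'   detection probability.
#' @param continuous emit potency predictions.
#' @param noise_sd log10 spread of predicted potencies around the truth.
#' @param log_ac50_range potency range for false-positive draws.
#' @param model_id identifier.
#' @param seed RNG seed.
#' @return a [prediction_set()].
#' @export
simulate_model_predictions <- function(truth, activity_type, sens, spec,
                                       coverage, ad_fraction = NULL,
                                       potency_grad = 0.25,
                                       continuous = FALSE, noise_sd = 0.5,
                                       log_ac50_range = c(-2, 3),
                                       model_id = "sim_model", seed = 1) {
  stopifnot(all(c(sens, spec, coverage) >= 0 & c(sens, spec, coverage) <= 1))
  set.seed(.sub_seed(seed, 2L))
  n <- nrow(truth)
  active <- truth[[paste0("active_", activity_type)]]
  ac50 <- truth[[paste0("ac50_", activity_type)]]
  covered <- stats::runif(n) < coverage
  p_detect <- rep(sens, n)
  if (potency_grad != 0 && any(active)) {
    s <- potency_score(classify_potency(ac50))
    dev <- s - mean(s[active])
    # shrink the gradient (never clamp) so probabilities stay in [0, 1] and
    # the marginal sensitivity over actives remains exactly `sens`
    up <- max(dev[active], 0); dn <- -min(dev[active], 0)
    g <- potency_grad * min(1,
                            if (up > 0) (1 - sens) / (potency_grad * up) else 1,
                            if (dn > 0) sens / (potency_grad * dn) else 1)
    p_detect <- sens + g * dev
  }
  p_active <- ifelse(active, p_detect, 1 - spec)
  call <- ifelse(covered, as.integer(stats::runif(n) < p_active), NA_integer_)
  in_ad <- NULL
  if (!is.null(ad_fraction)) {
    in_ad <- ifelse(covered, stats::runif(n) < ad_fraction, NA)
  }
  potency <- NULL
  if (continuous) {
    potency <- rep(NA_real_, n)
    tp <- !is.na(call) & call == 1 & active
    fp <- !is.na(call) & call == 1 & !active
    potency[tp] <- 10^(log10(ac50[tp]) + stats::rnorm(sum(tp), 0, noise_sd))
    potency[fp] <- 10^stats::runif(sum(fp), log_ac50_range[1], log_ac50_range[2])
    potency[!is.na(call) & call == 0] <- INACTIVE_AC50_UM
  }
  prediction_set(model_id, activity_type, truth$inchi, call,
                 in_ad = in_ad, potency_uM = potency,
                 is_continuous = continuous)
}

#' Simulate an ensemble of models
#'
#' Per-model sensitivity, specificity and coverage are drawn uniformly from
#' the configured ranges; a configured fraction of models supplies AD flags.
#'
#' @param truth data.frame from [generate_ground_truth()].
#' @param config a [sim_config()].
#' @param activity_type binding / agonist / antagonist.
#' @param continuous simulate continuous (potency) models.
#' @param seed overrides `config$seed`.
#' @return list of [prediction_set()]s; the drawn per-model parameters are
#'   attached as attribute `"params"`.
#' @export
simulate_model_ensemble <- function(truth, config, activity_type = "binding",
                                    continuous = FALSE, seed = config$seed) {
  set.seed(.sub_seed(seed, 3L))
  m <- config$n_models
  params <- data.frame(
    model_id = sprintf("%s_model_%02d", activity_type, seq_len(m)),
    sens = stats::runif(m, config$sens_range[1], config$sens_range[2]),
    spec = stats::runif(m, config$spec_range[1], config$spec_range[2]),
    coverage = stats::runif(m, config$coverage_range[1], config$coverage_range[2]),
    has_ad = stats::runif(m) < config$ad_model_fraction,
    stringsAsFactors = FALSE)
  preds <- lapply(seq_len(m), function(j) {
    simulate_model_predictions(
      truth, activity_type, params$sens[j], params$spec[j], params$coverage[j],
      ad_fraction = if (params$has_ad[j]) config$ad_fraction else NULL,
      potency_grad = config$potency_grad,
      continuous = continuous, log_ac50_range = config$log_ac50_range,
      model_id = params$model_id[j], seed = .sub_seed(seed, 100L + j))
  })
  attr(preds, "params") <- params
  preds
}

#' Simulate a multi-source literature corpus
#'
#' Per chemical and activity type, a source count is drawn from a truncated
#' geometric distribution; each source reports the true call flipped with
#' the configured false-positive/false-negative rates, with AC50 values
#' expressed in a random mix of molar units around the true potency. A
#' configured fraction of agonist records is emitted as percent-
#' proliferation assays, and in vivo / cytotoxicity decoy records are
#' appended (to be removed during harmonization).
#'
#' @param truth data.frame from [generate_ground_truth()].
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return raw activity-record data.frame suitable for
#'   [harmonize_entries()].
#' @export
simulate_literature <- function(truth, config, seed = config$seed) {
  set.seed(.sub_seed(seed, 4L))
  n <- nrow(truth)
  rows <- list()
  for (type in ACTIVITY_TYPES) {
    active <- truth[[paste0("active_", type)]]
    ac50 <- truth[[paste0("ac50_", type)]]
    k <- pmin(1L + stats::rgeom(n, 1 / config$source_mean), config$source_max)
    idx <- rep.int(seq_len(n), k)
    src <- unlist(lapply(k, function(m) sample.int(2L * config$source_max, m)))
    rep_active <- ifelse(active[idx],
                         stats::runif(length(idx)) >= config$fn_rate,
                         stats::runif(length(idx)) < config$fp_rate)
    true_uM <- ac50[idx]
    # false-positive reports invent a potency; true positives perturb it
    uM <- ifelse(active[idx], true_uM,
                 10^stats::runif(length(idx), config$log_ac50_range[1],
                                 config$log_ac50_range[2]))
    uM <- 10^(log10(uM) + stats::rnorm(length(idx), 0, config$source_log_sd))
    unit <- sample(config$units, length(idx), replace = TRUE)
    value <- ifelse(rep_active, uM / .UNIT_TO_UM[unit], NA_real_)
    unit[!rep_active] <- NA_character_
    assay <- if (type == "binding") "binding" else "transactivation"
    d <- data.frame(inchi = truth$inchi[idx], activity_type = type,
                    assay_class = assay, value = value, unit = unit,
                    active = rep_active,
                    source_ref = sprintf("SRC%03d", src),
                    stringsAsFactors = FALSE)
    if (type == "agonist" && config$proliferation_fraction > 0) {
      pr <- stats::runif(nrow(d)) < config$proliferation_fraction
      d$assay_class[pr] <- "proliferation"
      d$value[pr] <- ifelse(d$active[pr], stats::runif(sum(pr), 130, 250),
                            stats::runif(sum(pr), 50, 120))
      d$unit[pr] <- "%"
      d$active[pr] <- NA
    }
    rows[[type]] <- d
  }
  out <- do.call(rbind, rows)
  if (config$decoy_fraction > 0) {
    nd <- round(config$decoy_fraction * n)
    if (nd > 0) {
      di <- sample.int(n, nd)
      decoys <- data.frame(
        inchi = truth$inchi[di],
        activity_type = sample(ACTIVITY_TYPES, nd, replace = TRUE),
        assay_class = sample(c("in_vivo", "cytotoxicity"), nd, replace = TRUE),
        value = stats::runif(nd, 0.1, 100), unit = "uM",
        active = stats::runif(nd) < 0.5,
        source_ref = sprintf("SRC%03d", sample.int(2L * config$source_max, nd,
                                                   replace = TRUE)),
        stringsAsFactors = FALSE)
      out <- rbind(out, decoys)
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate HTS-style AUC training scores
#'
#' Inactive chemicals receive an AUC of zero (a flat concentration-response
#' carries no area); actives receive an AUC decreasing linearly in log10
#' AC50 from 1 (most potent) to 0.1, plus Gaussian noise clipped to
#' \[0, 1\]. A configured fraction of chemicals is forced into the ambiguous
#' \[0.01, 0.1) band.
#'
#' @param truth data.frame from [generate_ground_truth()].
#' @param noise_sd Gaussian noise on the AUC scale.
#' @param ambiguous_fraction fraction forced into the ambiguous band.
#' @param log_ac50_range potency range mapped onto the AUC scale.
#' @param seed RNG seed.
#' @return data.frame with `inchi`, `auc_binding`, `auc_agonist`,
#'   `auc_antagonist`.
#' @export
generate_training_auc <- function(truth, noise_sd = 0.02,
                                  ambiguous_fraction = 0.05,
                                  log_ac50_range = c(-2, 3), seed = 1) {
  stopifnot(noise_sd >= 0, ambiguous_fraction >= 0, ambiguous_fraction <= 1)
  set.seed(.sub_seed(seed, 5L))
  n <- nrow(truth)
  one <- function(type) {
    active <- truth[[paste0("active_", type)]]
    lac <- log10(truth[[paste0("ac50_", type)]])
    span <- diff(log_ac50_range)
    auc <- ifelse(active,
                  0.1 + 0.9 * (log_ac50_range[2] - lac) / span +
                    stats::rnorm(n, 0, noise_sd),
                  0)
    auc <- pmin(pmax(auc, 0), 1)
    amb <- stats::runif(n) < ambiguous_fraction
    auc[amb] <- stats::runif(sum(amb), 0.01, 0.0999)
    auc
  }
  data.frame(inchi = truth$inchi,
             auc_binding = one("binding"),
             auc_agonist = one("agonist"),
             auc_antagonist = one("antagonist"),
             stringsAsFactors = FALSE)
}
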