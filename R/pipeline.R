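# End-to-end orchestration: configuration with the study's policy defaults,
# a reproducible pipeline run over a seeded synthetic world, and the
# statistics report generator.

#' Pipeline run configuration
#'
#' Collects every numeric policy knob with its default: molecular weight
#' cutoff 1000 g/mol, 20% source-disagreement removal, potency class
#' boundaries 0.09 / 0.18 / 20 / 800 micromolar, ambiguous AUC band
#' \[0.01, 0.1), three-model threshold for correction rules 2/3, and a
#' 0-to-1-by-0.05 concordance sweep grid. Nothing numeric is hard-coded
#' elsewhere.
#'
#' @param sim a [sim_config()] describing the synthetic world.
#' @param max_mw curation molecular-weight cutoff (g/mol).
#' @param max_disagreement categorical reference removal threshold.
#' @param potency_thresholds potency class upper bounds (micromolar).
#' @param auc_band ambiguous training-AUC interval.
#' @param min_active_models raw active-call threshold for correction rules
#'   2 and 3.
#' @param sweep_thresholds concordance grid for [threshold_sweep()].
#' @param sweep_strata minimum literature source counts for stratified
#'   reporting.
#' @param n_continuous_models continuous models per activity type.
#' @param seed master seed for the run.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(seed = seed), max_mw = 1000,
                       max_disagreement = 0.20,
                       potency_thresholds = c(0.09, 0.18, 20, 800),
                       auc_band = c(0.01, 0.1), min_active_models = 3,
                       sweep_thresholds = seq(0, 1, by = 0.05),
                       sweep_strata = c(1L, 2L, 4L, 7L),
                       n_continuous_models = 3, seed = 42) {
  structure(as.list(environment()), class = "run_config")
}

# small stable polynomial text hash used to stamp outputs with their config
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full consensus pipeline on a seeded synthetic world
#'
#' Executes the stages in order: world simulation (ground truth, model
#' ensembles, literature corpus, training AUCs), record harmonization and
#' reference building, per-model scoring, categorical and potency consensus,
#' consistency corrections, the concordance threshold sweep, and the
#' statistics report. All stage outputs are returned and, if `out_dir` is
#' given, written as delimited text stamped with the configuration hash and
#' seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `truth`, `references`, `model_scores`, `consensus`
#'   (per activity type), `corrected`, `correction_log`, `sweep`, `report`
#'   and `stamp`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  sim <- config$sim
  truth <- generate_ground_truth(sim)
  training <- generate_training_auc(truth, seed = sim$seed)
  lit <- simulate_literature(truth, sim)
  entries <- harmonize_entries(lit)
  cat_ref <- build_categorical_reference(entries, config$max_disagreement)
  pot_ref <- build_potency_reference(entries, config$max_disagreement)

  ensembles <- list(); cont_ensembles <- list()
  scores <- list(); consensus <- list()
  for (type in ACTIVITY_TYPES) {
    ens <- simulate_model_ensemble(truth, sim, type,
                                   seed = .sub_seed(sim$seed, match(type, ACTIVITY_TYPES)))
    csim <- sim; csim$n_models <- config$n_continuous_models
    cens <- simulate_model_ensemble(truth, csim, type, continuous = TRUE,
                                    seed = .sub_seed(sim$seed, 10L + match(type, ACTIVITY_TYPES)))
    sc <- score_models(c(ens, cens), cat_ref$reference, pot_ref, training,
                       n_total = nrow(truth), auc_band = config$auc_band)
    cat_sc <- sc[!sc$is_continuous, , drop = FALSE]
    cont_sc <- sc[sc$is_continuous, , drop = FALSE]
    # a model whose score_2 is undefined cannot be weighted: exclude it
    if (anyNA(cat_sc$score_2)) {
      warning(sum(is.na(cat_sc$score_2)), " ", type,
              " categorical model(s) with undefined score_2 excluded",
              " from the consensus")
      cat_sc <- cat_sc[!is.na(cat_sc$score_2), , drop = FALSE]
    }
    if (anyNA(cont_sc$score_2)) {
      warning(sum(is.na(cont_sc$score_2)), " ", type,
              " continuous model(s) with undefined score_2 excluded",
              " from the consensus")
      cont_sc <- cont_sc[!is.na(cont_sc$score_2), , drop = FALSE]
    }
    calls_long <- do.call(rbind, lapply(ens, function(p) {
      data.frame(model_id = p$model_id, inchi = p$calls$inchi,
                 call = p$calls$call, stringsAsFactors = FALSE)
    }))
    calls_long <- calls_long[calls_long$model_id %in% cat_sc$model_id, ,
                             drop = FALSE]
    cc <- categorical_consensus(calls_long, cat_sc)
    pot_calls <- do.call(rbind, lapply(cens, function(p) {
      cls <- as.character(classify_potency(p$calls$potency_uM))
      cls[is.na(p$calls$call)] <- NA_character_
      data.frame(model_id = p$model_id, inchi = p$calls$inchi, class = cls,
                 stringsAsFactors = FALSE)
    }))
    pot_calls <- pot_calls[pot_calls$model_id %in% cont_sc$model_id, ,
                           drop = FALSE]
    cp <- consensus_potency_table(pot_calls, cont_sc)
    ensembles[[type]] <- ens; cont_ensembles[[type]] <- cens
    scores[[type]] <- sc
    consensus[[type]] <- list(categorical = cc, potency = cp)
  }
  corrected <- apply_corrections(consensus, config$min_active_models)

  bind_ref <- cat_ref$reference[cat_ref$reference$activity_type == "binding",
                                , drop = FALSE]
  sweep <- threshold_sweep(corrected$result$binding, bind_ref,
                           thresholds = config$sweep_thresholds,
                           strata = config$sweep_strata)
  report <- do.call(rbind, lapply(ACTIVITY_TYPES, function(type) {
    ref <- cat_ref$reference[cat_ref$reference$activity_type == type, ,
                             drop = FALSE]
    r <- report_metrics(corrected$result[[type]], ref,
                        strata = config$sweep_strata)
    cbind(activity_type = type, r)
  }))
  stamp <- list(config_hash = .config_hash(unclass(config)), seed = sim$seed)
  out <- list(truth = truth, training = training,
              references = list(categorical = cat_ref, potency = pot_ref,
                                entries = entries),
              model_scores = do.call(rbind, scores),
              consensus = consensus, corrected = corrected$result,
              correction_log = corrected$log, sweep = sweep, report = report,
              stamp = stamp)
  if (!is.null(out_dir)) .write_run(out, out_dir)
  out
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  w(run$model_scores, "model_scores.tsv")
  w(run$references$categorical$reference, "categorical_reference.tsv")
  w(run$references$potency, "potency_reference.tsv")
  for (type in names(run$corrected)) {
    w(run$corrected[[type]], sprintf("consensus_%s.tsv", type))
  }
  w(run$correction_log, "correction_log.tsv")
  w(run$sweep, "threshold_sweep.tsv")
  w(run$report, "report.tsv")
  writeLines(c(sprintf("config_hash\t%s", run$stamp$config_hash),
               sprintf("seed\t%d", run$stamp$seed)),
             file.path(out_dir, "run_stamp.tsv"))
  invisible(out_dir)
}

#' One report row from a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @param digits rounding for display (default 2, round-half-even as in R).
#' @return data.frame row with counts, sensitivity, specificity and
#'   balanced accuracy.
#' @export
metrics_row <- function(cm, digits = 2) {
  met <- classification_metrics(cm)
  data.frame(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
             sensitivity = round(met$sensitivity, digits),
             specificity = round(met$specificity, digits),
             balanced_accuracy = round(met$balanced_accuracy, digits))
}

#' Consensus statistics stratified by literature source count
#'
#' Emits, per stratum (chemicals with at least that many sources), the
#' confusion matrix of the consensus calls against the reference and the
#' derived sensitivity / specificity / balanced accuracy. Empty strata are
#' reported with undefined (`NA`) metrics, never zero.
#'
#' @param consensus_tab data.frame with `inchi` and `call` (a consensus or
#'   corrected consensus table).
#' @param reference data.frame with `inchi`, `active`, `n_sources`.
#' @param strata integer vector of minimum source counts.
#' @return data.frame with one row per stratum.
#' @export
report_metrics <- function(consensus_tab, reference, strata = 1L) {
  cc <- consensus_tab[consensus_tab$call %in% c("active", "inactive"), ,
                      drop = FALSE]
  m <- merge(cc[, c("inchi", "call")],
             reference[, c("inchi", "active", "n_sources")], by = "inchi")
  rows <- lapply(strata, function(s) {
    d <- m[m$n_sources >= s, , drop = FALSE]
    cm <- confusion(tp = sum(d$call == "active" & d$active),
                    fn = sum(d$call == "inactive" & d$active),
                    fp = sum(d$call == "active" & !d$active),
                    tn = sum(d$call == "inactive" & !d$active))
    cbind(data.frame(min_sources = s, n = nrow(d)), metrics_row(cm, digits = 4))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
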