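# Per-model evaluation: confusion matrices, sensitivity/specificity/balanced
# accuracy on six chemical subsets, and the two balanced-accuracy summary
# scores used to weight models in the consensus.

SUBSET_IDS <- c("toxcast", "lit_all", "lit_min2src", "lit_no_veryweak",
                "lit_in_ad", "lit_all_filters")

#' Construct a prediction set for one model
#'
#' @param model_id model identifier.
#' @param activity_type one of binding / agonist / antagonist.
#' @param inchi chemical keys.
#' @param call integer vector: 1 active, 0 inactive, `NA` not predicted.
#' @param in_ad optional logical vector: inside the model's applicability
#'   domain. `NULL` when the model supplied no AD information.
#' @param potency_uM optional numeric vector of predicted potencies
#'   (micromolar) for continuous models.
#' @param is_continuous whether the model is a continuous (potency) model.
#' @return an object of class `prediction_set`.
#' @export
prediction_set <- function(model_id, activity_type, inchi, call,
                           in_ad = NULL, potency_uM = NULL,
                           is_continuous = FALSE) {
  stopifnot(length(inchi) == length(call))
  activity_type <- match.arg(activity_type, ACTIVITY_TYPES)
  calls <- data.frame(inchi = inchi, call = as.integer(call),
                      stringsAsFactors = FALSE)
  calls$in_ad <- if (is.null(in_ad)) NA else as.logical(in_ad)
  calls$potency_uM <- if (is.null(potency_uM)) NA_real_ else as.numeric(potency_uM)
  structure(list(model_id = model_id, activity_type = activity_type,
                 calls = calls, has_ad = !is.null(in_ad),
                 is_continuous = is_continuous),
            class = "prediction_set")
}

#' Confusion matrix of calls against a binary reference
#'
#' Counts are taken over the intersection of predicted (non-`NA` call) and
#' referenced chemicals.
#'
#' @param calls data.frame with `inchi` and `call` (1/0/NA), or a
#'   `prediction_set`.
#' @param reference data.frame with `inchi` and logical `active`.
#' @return object of class `confusion_matrix` with fields `tp`, `fn`, `fp`,
#'   `tn`; an empty intersection is flagged via attribute `"empty"`.
#' @export
confusion_matrix <- function(calls, reference) {
  if (inherits(calls, "prediction_set")) calls <- calls$calls
  m <- merge(calls[!is.na(calls$call), c("inchi", "call")],
             reference[, c("inchi", "active")], by = "inchi")
  cm <- confusion(tp = sum(m$call == 1 & m$active),
                  fn = sum(m$call == 0 & m$active),
                  fp = sum(m$call == 1 & !m$active),
                  tn = sum(m$call == 0 & !m$active))
  attr(cm, "empty") <- nrow(m) == 0
  cm
}

#' Construct a confusion matrix from its four counts
#' @param tp,fn,fp,tn non-negative counts (true/false positives/negatives).
#' @return object of class `confusion_matrix`.
#' @export
confusion <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("            predicted active  predicted inactive\n"))
  cat(sprintf("  actives   %16d  %18d\n", x$tp, x$fn))
  cat(sprintf("  inactives %16d  %18d\n", x$fp, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and balanced accuracy
#'
#' Balanced accuracy is the mean of sensitivity and specificity. A metric
#' whose margin is zero (no actives, or no inactives) is undefined and
#' reported as `NA`, never coerced to a number.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
classification_metrics <- function(cm) {
  sens <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  spec <- if (cm$fp + cm$tn > 0) cm$tn / (cm$fp + cm$tn) else NA_real_
  ba <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  list(sensitivity = sens, specificity = spec, balanced_accuracy = ba)
}

#' Build the six evaluation chemical subsets for one model
#'
#' Subset 1 (`toxcast`): training-set chemicals excluding those whose
#' activity-type-relevant AUC lies in the ambiguous band. Subset 2
#' (`lit_all`): all literature reference chemicals for the activity type.
#' Subset 3: those with at least two literature sources. Subset 4: subset 2
#' minus very-weak actives. Subset 5: subset 2 restricted to the model's
#' applicability domain (identical to subset 2 when the model supplied no
#' AD). Subset 6: the intersection of subsets 3, 4 and 5.
#'
#' @param categorical_ref reference data.frame from
#'   [build_categorical_reference()] (the `reference` element).
#' @param potency_ref data.frame from [build_potency_reference()].
#' @param training data.frame with `inchi` and `auc_binding`, `auc_agonist`,
#'   `auc_antagonist` columns.
#' @param pred a `prediction_set` (supplies activity type and AD flags).
#' @param auc_band ambiguous AUC interval, default `[0.01, 0.1)`.
#' @return named list of six character vectors of chemical keys, with the
#'   binary training reference attached as attribute `"toxcast_reference"`.
#' @export
build_evaluation_subsets <- function(categorical_ref, potency_ref, training,
                                     pred, auc_band = c(0.01, 0.1)) {
  type <- pred$activity_type
  auc <- training[[paste0("auc_", type)]]
  ambiguous <- auc >= auc_band[1] & auc < auc_band[2]
  toxcast <- training$inchi[!ambiguous]
  tox_ref <- data.frame(inchi = toxcast,
                        active = auc[!ambiguous] >= auc_band[2],
                        stringsAsFactors = FALSE)

  ref <- categorical_ref[categorical_ref$activity_type == type, , drop = FALSE]
  lit_all <- ref$inchi
  lit_min2src <- ref$inchi[ref$n_sources >= 2]
  vw <- potency_ref$inchi[potency_ref$activity_type == type &
                            potency_ref$potency_class == "very_weak"]
  lit_no_veryweak <- setdiff(lit_all, vw)
  lit_in_ad <- if (pred$has_ad) {
    intersect(lit_all, pred$calls$inchi[!is.na(pred$calls$in_ad) & pred$calls$in_ad])
  } else lit_all
  lit_all_filters <- intersect(intersect(lit_min2src, lit_no_veryweak), lit_in_ad)

  out <- list(toxcast = toxcast, lit_all = lit_all,
              lit_min2src = lit_min2src, lit_no_veryweak = lit_no_veryweak,
              lit_in_ad = lit_in_ad, lit_all_filters = lit_all_filters)
  attr(out, "toxcast_reference") <- tox_ref
  out
}

#' Coverage- and accuracy-weighted model score (Score 1)
#'
#' `score_1 = (N_pred/N_total) * (1/n_filters) * sum_i BA_i *
#' (n_pred_in_subset_i / n_subset_i)` over the five literature subsets
#' (subsets 2-6). Favors models with wide applicability domains predicting
#' many chemicals. An undefined subset BA contributes zero.
#'
#' @param ba numeric vector of the five literature-subset balanced
#'   accuracies (subsets 2-6; `NA` allowed).
#' @param n_pred_in_subset,n_subset per-subset predicted and total counts.
#' @param n_pred,n_total chemicals predicted by the model and size of the
#'   prediction universe.
#' @param n_filters normalization constant (number of literature filters,
#'   default 5).
#' @return a number in \[0, 1\].
#' @export
score_1 <- function(ba, n_pred_in_subset, n_subset, n_pred, n_total,
                    n_filters = 5) {
  stopifnot(length(ba) == n_filters, length(n_pred_in_subset) == n_filters,
            length(n_subset) == n_filters)
  if (n_total == 0 || n_pred == 0) return(0)
  contrib <- ifelse(is.na(ba) | n_subset == 0, 0,
                    ba * n_pred_in_subset / n_subset)
  (n_pred / n_total) * sum(contrib) / n_filters
}

#' Accuracy-focused model score (Score 2)
#'
#' The arithmetic mean of the balanced accuracy on the HTS training data and
#' on the fully filtered literature subset. Not penalized for narrow
#' coverage.
#'
#' @param ba_toxcast,ba_all_filters the two balanced accuracies.
#' @return their mean, or `NA` if either is undefined.
#' @export
score_2 <- function(ba_toxcast, ba_all_filters) {
  if (is.na(ba_toxcast) || is.na(ba_all_filters)) return(NA_real_)
  (ba_toxcast + ba_all_filters) / 2
}

.subset_ba_categorical <- function(pred_calls, subset_inchi, reference) {
  sub_calls <- pred_calls[pred_calls$inchi %in% subset_inchi, , drop = FALSE]
  sub_ref <- reference[reference$inchi %in% subset_inchi, , drop = FALSE]
  cm <- confusion_matrix(sub_calls, sub_ref)
  met <- classification_metrics(cm)
  list(ba = met$balanced_accuracy, metrics = met, cm = cm,
       n_pred_in_subset = sum(!is.na(sub_calls$call) &
                                sub_calls$inchi %in% subset_inchi),
       n_subset = length(subset_inchi))
}

# mean one-vs-rest BA over the five potency classes; undefined classes are
# skipped (never coerced); all classes undefined -> NA
.subset_ba_multiclass <- function(pred_class, subset_inchi, ref_class) {
  pc <- pred_class[pred_class$inchi %in% subset_inchi, , drop = FALSE]
  rc <- ref_class[ref_class$inchi %in% subset_inchi, , drop = FALSE]
  m <- merge(pc[!is.na(pc$class), c("inchi", "class")],
             rc[, c("inchi", "class")], by = "inchi",
             suffixes = c("_pred", "_ref"))
  bas <- vapply(POTENCY_LEVELS, function(lv) {
    cm <- confusion(tp = sum(m$class_pred == lv & m$class_ref == lv),
                    fn = sum(m$class_pred != lv & m$class_ref == lv),
                    fp = sum(m$class_pred == lv & m$class_ref != lv),
                    tn = sum(m$class_pred != lv & m$class_ref != lv))
    classification_metrics(cm)$balanced_accuracy
  }, numeric(1))
  list(ba = if (all(is.na(bas))) NA_real_ else mean(bas, na.rm = TRUE),
       per_class = bas,
       n_pred_in_subset = nrow(m), n_subset = length(subset_inchi))
}

#' Evaluate one categorical model on the six subsets
#'
#' @param pred a `prediction_set`.
#' @param categorical_ref,potency_ref,training as in
#'   [build_evaluation_subsets()].
#' @param n_total size of the prediction universe (defaults to the number of
#'   chemicals the model was asked to predict).
#' @param auc_band ambiguous AUC interval.
#' @return one-row data.frame: model id, activity type, the six subset
#'   balanced accuracies, coverage counts, `score_1` and `score_2`.
#' @export
evaluate_categorical <- function(pred, categorical_ref, potency_ref, training,
                                 n_total = nrow(pred$calls),
                                 auc_band = c(0.01, 0.1)) {
  subsets <- build_evaluation_subsets(categorical_ref, potency_ref, training,
                                      pred, auc_band)
  tox_ref <- attr(subsets, "toxcast_reference")
  type <- pred$activity_type
  lit_ref <- categorical_ref[categorical_ref$activity_type == type,
                             c("inchi", "active"), drop = FALSE]
  evals <- lapply(SUBSET_IDS, function(sid) {
    ref <- if (sid == "toxcast") tox_ref else lit_ref
    .subset_ba_categorical(pred$calls, subsets[[sid]], ref)
  })
  names(evals) <- SUBSET_IDS
  ba <- vapply(evals, `[[`, numeric(1), "ba")
  nps <- vapply(evals, `[[`, numeric(1), "n_pred_in_subset")
  ns <- vapply(evals, `[[`, numeric(1), "n_subset")
  n_pred <- sum(!is.na(pred$calls$call))
  s1 <- score_1(ba[-1], nps[-1], ns[-1], n_pred, n_total)
  s2 <- score_2(ba[["toxcast"]], ba[["lit_all_filters"]])
  out <- data.frame(model_id = pred$model_id, activity_type = type,
                    is_continuous = FALSE,
                    ba_toxcast = ba[["toxcast"]],
                    ba_lit_all = ba[["lit_all"]],
                    ba_lit_min2src = ba[["lit_min2src"]],
                    ba_lit_no_veryweak = ba[["lit_no_veryweak"]],
                    ba_lit_in_ad = ba[["lit_in_ad"]],
                    ba_lit_all_filters = ba[["lit_all_filters"]],
                    n_pred = n_pred, n_total = n_total,
                    score_1 = s1, score_2 = s2, stringsAsFactors = FALSE)
  attr(out, "subset_evals") <- evals
  out
}

#' Evaluate one continuous (potency) model
#'
#' Predicted concentrations are mapped to the five potency classes. On
#' literature subsets the model is scored by the unweighted mean of the five
#' one-vs-rest balanced accuracies against the potency reference; on the HTS
#' subset, where only binary AUC-derived activity exists, by the binary
#' active/inactive balanced accuracy (predicted class not inactive). The
#' model score is Score 2. Predicted-active chemicals with no potency value
#' are treated as not predicted and logged.
#'
#' @inheritParams evaluate_categorical
#' @return one-row data.frame as in [evaluate_categorical()] with
#'   `is_continuous = TRUE`.
#' @export
evaluate_continuous <- function(pred, categorical_ref, potency_ref, training,
                                n_total = nrow(pred$calls),
                                auc_band = c(0.01, 0.1)) {
  stopifnot(pred$is_continuous)
  calls <- pred$calls
  cls <- as.character(classify_potency(calls$potency_uM))
  cls[!is.na(calls$call) & calls$call == 0] <- "inactive"
  missing_pot <- !is.na(calls$call) & calls$call == 1 & is.na(calls$potency_uM)
  if (any(missing_pot)) {
    warning(sum(missing_pot), " predicted-active chemical(s) without potency",
            " treated as not predicted")
    cls[missing_pot] <- NA_character_
  }
  pred_class <- data.frame(inchi = calls$inchi, class = cls,
                           stringsAsFactors = FALSE)
  # binary view for the HTS subset and for score_1 coverage accounting
  bin_calls <- data.frame(inchi = calls$inchi,
                          call = ifelse(is.na(cls), NA_integer_,
                                        as.integer(cls != "inactive")),
                          in_ad = calls$in_ad, stringsAsFactors = FALSE)
  bin_pred <- pred
  bin_pred$calls <- bin_calls
  subsets <- build_evaluation_subsets(categorical_ref, potency_ref, training,
                                      bin_pred, auc_band)
  tox_ref <- attr(subsets, "toxcast_reference")
  type <- pred$activity_type
  ref_class <- potency_ref[potency_ref$activity_type == type,
                           c("inchi", "potency_class"), drop = FALSE]
  names(ref_class)[2] <- "class"
  evals <- lapply(SUBSET_IDS, function(sid) {
    if (sid == "toxcast") {
      .subset_ba_categorical(bin_calls, subsets[[sid]], tox_ref)
    } else {
      .subset_ba_multiclass(pred_class, subsets[[sid]], ref_class)
    }
  })
  names(evals) <- SUBSET_IDS
  ba <- vapply(evals, `[[`, numeric(1), "ba")
  nps <- vapply(evals, `[[`, numeric(1), "n_pred_in_subset")
  ns <- vapply(evals, `[[`, numeric(1), "n_subset")
  n_pred <- sum(!is.na(bin_calls$call))
  s1 <- score_1(ba[-1], nps[-1], ns[-1], n_pred, n_total)
  s2 <- score_2(ba[["toxcast"]], ba[["lit_all_filters"]])
  out <- data.frame(model_id = pred$model_id, activity_type = type,
                    is_continuous = TRUE,
                    ba_toxcast = ba[["toxcast"]],
                    ba_lit_all = ba[["lit_all"]],
                    ba_lit_min2src = ba[["lit_min2src"]],
                    ba_lit_no_veryweak = ba[["lit_no_veryweak"]],
                    ba_lit_in_ad = ba[["lit_in_ad"]],
                    ba_lit_all_filters = ba[["lit_all_filters"]],
                    n_pred = n_pred, n_total = n_total,
                    score_1 = s1, score_2 = s2, stringsAsFactors = FALSE)
  attr(out, "subset_evals") <- evals
  out
}

#' Score a list of prediction sets
#'
#' @param preds list of `prediction_set` objects.
#' @param categorical_ref,potency_ref,training reference inputs.
#' @param n_total prediction universe size.
#' @param auc_band ambiguous AUC interval.
#' @return data.frame with one row per model (subset balanced accuracies,
#'   Score 1 and Score 2), mirroring a per-model score table.
#' @export
score_models <- function(preds, categorical_ref, potency_ref, training,
                         n_total = NULL, auc_band = c(0.01, 0.1)) {
  rows <- lapply(preds, function(p) {
    nt <- if (is.null(n_total)) nrow(p$calls) else n_total
    f <- if (p$is_continuous) evaluate_continuous else evaluate_categorical
    f(p, categorical_ref, potency_ref, training, nt, auc_band)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
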