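# Score-weighted consensus of model predictions: categorical calls,
# model concordance, weighted potency levels, post-hoc consistency
# corrections, and the positive-concordance threshold sweep.

#' Categorical consensus over a set of models
#'
#' For each chemical, the mean Score 2 of the models calling it active is
#' compared with the mean Score 2 of the models calling it inactive; the
#' larger mean wins (a tie is resolved as active, consistent with the
#' false-negative-averse prioritization goal). Models that did not predict
#' the chemical are excluded. Concordances are the fractions of predicting
#' models on each side and always sum to 1 when at least one model
#' predicted.
#'
#' @param calls data.frame with columns `model_id`, `inchi`, `call`
#'   (1 active / 0 inactive / `NA` not predicted).
#' @param model_scores data.frame with `model_id` and `score_2`.
#' @return data.frame with one row per chemical: `call` (active / inactive /
#'   not_predicted), `avg_score_active`, `avg_score_inactive`,
#'   `concordance_active`, `concordance_inactive`, `n_models`,
#'   `n_active_calls`.
#' @export
categorical_consensus <- function(calls, model_scores) {
  if (nrow(calls) == 0) {
    return(data.frame(inchi = character(0), call = character(0),
                      avg_score_active = numeric(0),
                      avg_score_inactive = numeric(0),
                      concordance_active = numeric(0),
                      concordance_inactive = numeric(0),
                      n_models = numeric(0), n_active_calls = numeric(0),
                      stringsAsFactors = FALSE))
  }
  s2 <- model_scores$score_2[match(calls$model_id, model_scores$model_id)]
  if (anyNA(s2[!is.na(calls$call)])) {
    stop("score_2 missing for a model that provided predictions")
  }
  chem <- factor(calls$inchi)
  pred <- !is.na(calls$call)
  act <- pred & calls$call == 1
  inact <- pred & calls$call == 0
  zero <- rep(0, length(chem))
  n_act <- rowsum(act + zero, chem)
  n_inact <- rowsum(inact + zero, chem)
  s_act <- rowsum(ifelse(act, s2, 0), chem)
  s_inact <- rowsum(ifelse(inact, s2, 0), chem)
  n_pred <- n_act + n_inact
  avg_act <- ifelse(n_act > 0, s_act / n_act, NA_real_)
  avg_inact <- ifelse(n_inact > 0, s_inact / n_inact, NA_real_)
  call_out <- ifelse(n_pred == 0, "not_predicted",
              ifelse(n_act == 0, "inactive",
              ifelse(n_inact == 0, "active",
              ifelse(avg_act >= avg_inact, "active", "inactive"))))
  out <- data.frame(inchi = rownames(n_act),
                    call = as.vector(call_out),
                    avg_score_active = as.vector(avg_act),
                    avg_score_inactive = as.vector(avg_inact),
                    concordance_active = as.vector(
                      ifelse(n_pred > 0, n_act / n_pred, NA_real_)),
                    concordance_inactive = as.vector(
                      ifelse(n_pred > 0, n_inact / n_pred, NA_real_)),
                    n_models = as.vector(n_pred),
                    n_active_calls = as.vector(n_act),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Concordance of model calls for one chemical
#'
#' Fractions of predicting models calling active and inactive; non-predicting
#' models are excluded; the two fractions sum to exactly 1.
#'
#' @param calls integer vector of calls (1/0/NA) for one chemical.
#' @return named numeric vector `c(active = ..., inactive = ...)`.
#' @export
concordance <- function(calls) {
  pred <- calls[!is.na(calls)]
  if (length(pred) == 0) stop("no predicting model")
  c(active = mean(pred == 1), inactive = mean(pred == 0))
}

#' Potency consensus weights from model scores
#'
#' Weights are proportional to the model scores of the predicting models,
#' normalized to sum 1. If all scores are zero, uniform weights are used
#' with a warning.
#'
#' @param scores numeric vector of (non-negative) model scores.
#' @return numeric vector of weights summing to 1.
#' @export
potency_weights <- function(scores) {
  stopifnot(length(scores) >= 1, all(scores >= 0))
  tot <- sum(scores)
  if (tot == 0) {
    warning("all model scores are zero; using uniform weights")
    return(rep(1 / length(scores), length(scores)))
  }
  scores / tot
}

# nearest potency class for a consensus level on the {0,.25,.5,.75,1} scale;
# a half-way level rounds toward the more potent class
.class_from_level <- function(C) {
  idx <- floor(round(C / 0.25, 9) + 0.5)
  idx <- pmin(pmax(idx, 0), 4)
  factor(POTENCY_LEVELS[idx + 1], levels = POTENCY_LEVELS, ordered = TRUE)
}

#' Weighted potency consensus for one chemical
#'
#' The consensus potency level is the weight-averaged class score
#' `C = sum_j w_j s(P_j)` on the scale inactive 0, very weak 0.25, weak 0.5,
#' moderate 0.75, strong 1; the consensus class is the nearest class score,
#' half-way levels rounding toward the more potent class.
#'
#' @param classes vector of predicted potency classes (one per model).
#' @param weights matching weights (normalized to sum 1; see
#'   [potency_weights()]).
#' @return list with `C` (consensus level) and `class` (ordered factor); an
#'   empty input yields `class = NA` ("not predicted").
#' @export
potency_consensus <- function(classes, weights) {
  if (length(classes) == 0) return(list(C = NA_real_, class = NA))
  stopifnot(length(classes) == length(weights))
  C <- sum(weights * potency_score(classes))
  list(C = C, class = .class_from_level(C))
}

#' Potency consensus table over a set of continuous models
#'
#' @param pot_calls data.frame with `model_id`, `inchi`, `class` (predicted
#'   potency class, `NA` = not predicted).
#' @param model_scores data.frame with `model_id` and `score_2`.
#' @return data.frame per chemical: `C`, `potency_class`, `n_models`.
#' @export
consensus_potency_table <- function(pot_calls, model_scores) {
  d <- pot_calls[!is.na(pot_calls$class), , drop = FALSE]
  if (nrow(d) == 0) {
    return(data.frame(inchi = character(0), C = numeric(0),
                      potency_class = character(0), n_models = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sc <- model_scores$score_2[match(d$model_id, model_scores$model_id)]
  if (anyNA(sc)) stop("score_2 missing for a continuous model")
  chem <- factor(d$inchi)
  zero <- rep(0, nrow(d))
  wsum <- rowsum(sc + zero, chem)
  lvl <- rowsum(sc * potency_score(d$class), chem) / wsum
  n <- rowsum(1 + zero, chem)
  out <- data.frame(inchi = rownames(wsum),
                    C = as.vector(lvl),
                    potency_class = as.character(.class_from_level(as.vector(lvl))),
                    n_models = as.vector(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Map positive concordance to a potency class
#'
#' Strong for concordance >= 0.9; moderate in \[0.75, 0.9); weak in
#' \[0.6, 0.75); very weak below 0.6. Used to assign a potency to chemicals
#' reclassified active by correction rule 1.
#'
#' @param concordance_active numeric vector in \[0, 1\].
#' @return ordered factor of potency classes.
#' @export
concordance_to_potency <- function(concordance_active) {
  stopifnot(all(concordance_active >= 0 & concordance_active <= 1, na.rm = TRUE))
  cls <- ifelse(concordance_active >= 0.9, "strong",
         ifelse(concordance_active >= 0.75, "moderate",
         ifelse(concordance_active >= 0.6, "weak", "very_weak")))
  factor(cls, levels = POTENCY_LEVELS, ordered = TRUE)
}

.merge_consensus_state <- function(categorical, potency) {
  st <- categorical[, c("inchi", "call", "concordance_active",
                        "n_active_calls"), drop = FALSE]
  if (is.null(potency) || nrow(potency) == 0) {
    st$potency_class <- rep(NA_character_, nrow(st))
  } else {
    st$potency_class <- potency$potency_class[match(st$inchi, potency$inchi)]
  }
  st
}

#' Apply the four consistency correction rules to consensus predictions
#'
#' One pass, agonist and antagonist first, then binding. Rule 1: a
#' categorical-active chemical becomes active in the quantitative consensus,
#' its potency set from the positive concordance via
#' [concordance_to_potency()]. Rule 2: a quantitative-active chemical with at
#' least `min_active_models` raw active categorical calls becomes
#' categorical-active. Rule 3: a quantitative-active chemical with fewer than
#' `min_active_models` active calls (and not categorical-active) becomes
#' quantitative-inactive. Rule 4 (binding only, last): an active agonist or
#' antagonist becomes an active categorical binder, its binding potency set
#' to its agonist/antagonist potency (the more potent of the two if both).
#' The pass is idempotent: re-applying it changes nothing.
#'
#' @param consensus named list with elements `agonist`, `antagonist`,
#'   `binding`; each a list with `categorical` (from
#'   [categorical_consensus()]) and `potency` (from
#'   [consensus_potency_table()], may be `NULL`).
#' @param min_active_models raw active-call threshold for rules 2 and 3
#'   (default 3).
#' @return list with `result` (per activity type: inchi, call,
#'   concordance_active, n_active_calls, potency_class, rules_applied) and
#'   `log` (one row per state change: inchi, activity_type, rule, field,
#'   before, after).
#' @export
apply_corrections <- function(consensus, min_active_models = 3) {
  stopifnot(all(c("agonist", "antagonist", "binding") %in% names(consensus)))
  log <- list()
  note <- function(inchi, type, rule, field, before, after) {
    log[[length(log) + 1]] <<- data.frame(
      inchi = inchi, activity_type = type, rule = rule, field = field,
      before = as.character(before), after = as.character(after),
      stringsAsFactors = FALSE)
  }
  states <- list()
  for (type in c("agonist", "antagonist", "binding")) {
    x <- consensus[[type]]
    # accept either a fresh consensus pair or this function's own output
    st <- if (is.data.frame(x)) x else
      .merge_consensus_state(x$categorical, x$potency)
    st$rules_applied <- rep("", nrow(st))
    mark <- function(i, r) {
      st$rules_applied[i] <<- ifelse(nzchar(st$rules_applied[i]),
                                     paste0(st$rules_applied[i], ";", r), r)
    }
    quant_active <- function() !is.na(st$potency_class) &
      st$potency_class != "inactive"
    # rule 1: categorical active => quantitative active
    r1 <- st$call == "active" & !quant_active()
    if (any(r1)) {
      new_pot <- as.character(concordance_to_potency(st$concordance_active[r1]))
      note(st$inchi[r1], type, 1L, "potency_class",
           ifelse(is.na(st$potency_class[r1]), "not_predicted",
                  st$potency_class[r1]), new_pot)
      st$potency_class[r1] <- new_pot
      mark(which(r1), "1")
    }
    # rule 2: quantitative active + enough active categorical calls
    r2 <- quant_active() & st$call != "active" &
      st$n_active_calls >= min_active_models
    if (any(r2)) {
      note(st$inchi[r2], type, 2L, "call", st$call[r2], "active")
      st$call[r2] <- "active"
      mark(which(r2), "2")
    }
    # rule 3: too few active categorical calls => quantitative inactive
    # (does not undo rule 1: categorical-active chemicals are exempt)
    r3 <- quant_active() & st$call != "active" &
      st$n_active_calls < min_active_models
    if (any(r3)) {
      note(st$inchi[r3], type, 3L, "potency_class", st$potency_class[r3],
           "inactive")
      st$potency_class[r3] <- "inactive"
      mark(which(r3), "3")
    }
    states[[type]] <- st
  }
  # rule 4: agonist/antagonist activity forces binding activity
  bind <- states$binding
  ag <- states$agonist; an <- states$antagonist
  ag_act <- ag$inchi[ag$call == "active"]
  an_act <- an$inchi[an$call == "active"]
  aa_act <- union(ag_act, an_act)
  r4 <- bind$inchi %in% aa_act & bind$call != "active"
  if (any(r4)) {
    pot_of <- function(tab, chems) {
      p <- tab$potency_class[match(chems, tab$inchi)]
      ifelse(tab$call[match(chems, tab$inchi)] == "active", p, NA_character_)
    }
    chems <- bind$inchi[r4]
    p_ag <- pot_of(ag, chems); p_an <- pot_of(an, chems)
    new_pot <- pmax(potency_score(p_ag), potency_score(p_an), na.rm = TRUE)
    new_cls <- as.character(.class_from_level(new_pot))
    note(chems, "binding", 4L, "call", bind$call[r4], "active")
    chg <- is.na(bind$potency_class[r4]) | bind$potency_class[r4] != new_cls
    if (any(chg)) {
      note(chems[chg], "binding", 4L, "potency_class",
           ifelse(is.na(bind$potency_class[r4][chg]), "not_predicted",
                  bind$potency_class[r4][chg]), new_cls[chg])
    }
    bind$call[r4] <- "active"
    bind$potency_class[r4] <- new_cls
    bind$rules_applied[r4] <- ifelse(nzchar(bind$rules_applied[r4]),
                                     paste0(bind$rules_applied[r4], ";4"), "4")
    states$binding <- bind
  }
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(inchi = character(0), activity_type = character(0),
               rule = integer(0), field = character(0),
               before = character(0), after = character(0))
  rownames(log_df) <- NULL
  list(result = states, log = log_df)
}

#' Positive-concordance threshold sweep
#'
#' A chemical counts as a potential active at threshold `t` iff its positive
#' concordance is at least `t` and at least one model called it active.
#' Sensitivity, specificity and balanced accuracy are computed against the
#' reference within each literature source-count stratum (chemicals with at
#' least `stratum` sources). The active count is non-increasing in the
#' threshold.
#'
#' @param consensus_cat data.frame from [categorical_consensus()].
#' @param reference data.frame with `inchi`, `active` and `n_sources`.
#' @param thresholds numeric vector of concordance thresholds (default 0 to
#'   1 by 0.05).
#' @param strata integer vector of minimum source counts (default 1).
#' @return data.frame (threshold, stratum, n, n_active, sensitivity,
#'   specificity, balanced_accuracy).
#' @export
threshold_sweep <- function(consensus_cat, reference,
                            thresholds = seq(0, 1, by = 0.05), strata = 1L) {
  cc <- consensus_cat[consensus_cat$call != "not_predicted", , drop = FALSE]
  m <- merge(cc, reference[, c("inchi", "active", "n_sources")], by = "inchi")
  rows <- list()
  for (s in strata) {
    d <- m[m$n_sources >= s, , drop = FALSE]
    for (t in thresholds) {
      pa <- d$concordance_active >= t & d$n_active_calls >= 1
      cm <- confusion(tp = sum(pa & d$active), fn = sum(!pa & d$active),
                      fp = sum(pa & !d$active), tn = sum(!pa & !d$active))
      met <- classification_metrics(cm)
      rows[[length(rows) + 1]] <- data.frame(
        threshold = t, stratum = s, n = nrow(d), n_active = sum(pa),
        sensitivity = met$sensitivity, specificity = met$specificity,
        balanced_accuracy = met$balanced_accuracy)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
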