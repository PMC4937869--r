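# Model evaluation: confusion matrices, subset construction and the two
# balanced-accuracy summary scores.

micro_refs <- function() {
  # ten literature chemicals: 3 actives (one very weak), mixed source counts
  cat_ref <- data.frame(
    inchi = sprintf("C%02d", 1:10), activity_type = "binding",
    active = c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
    n_sources = c(3, 1, 2, 2, 1, 2, 2, 1, 2, 2),
    provenance = "observed", stringsAsFactors = FALSE)
  pot_ref <- data.frame(
    inchi = c("C01", "C02", "C03"), activity_type = "binding",
    potency_class = c("strong", "weak", "very_weak"),
    avg_score = c(1, 0.5, 0.25), log10_median_uM = c(-2, 0, 2),
    n_sources = c(3, 1, 2), stringsAsFactors = FALSE)
  training <- data.frame(
    inchi = sprintf("T%02d", 1:6),
    auc_binding = c(0.5, 0.3, 0.005, 0.002, 0.05, 0.2),
    auc_agonist = 0.005, auc_antagonist = 0.005, stringsAsFactors = FALSE)
  list(cat_ref = cat_ref, pot_ref = pot_ref, training = training)
}

test_that("confusion matrices count over the predicted-and-referenced intersection", {
  ref <- data.frame(inchi = sprintf("C%02d", 1:10),
                    active = rep(c(TRUE, FALSE), c(3, 7)))
  perfect <- data.frame(inchi = ref$inchi, call = as.integer(ref$active))
  cm <- confusion_matrix(perfect, ref)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 3, fn = 0, fp = 0, tn = 7))
  all_inactive <- data.frame(inchi = ref$inchi, call = 0L)
  cm <- confusion_matrix(all_inactive, ref)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 0, fn = 3, fp = 0, tn = 7))
  partial <- data.frame(inchi = ref$inchi[1:5], call = c(1L, 0L, 1L, 0L, 0L))
  cm <- confusion_matrix(partial, ref)
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, 5)
  cm <- confusion_matrix(data.frame(inchi = "Z", call = 1L), ref)
  expect_true(attr(cm, "empty"))
})

test_that("metrics derive from the matrix and flag undefined margins", {
  m <- classification_metrics(confusion(1, 0, 0, 1))
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1,
                            balanced_accuracy = 1))
  # zero-actives margin: sensitivity undefined, not coerced to a number
  m <- classification_metrics(confusion(0, 0, 2, 8))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$balanced_accuracy))
  expect_equal(m$specificity, 0.8)
  # label swap symmetry: swapping classes swaps the two rates, BA unchanged
  a <- classification_metrics(confusion(40, 10, 20, 30))
  b <- classification_metrics(confusion(30, 20, 10, 40))
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$balanced_accuracy, b$balanced_accuracy)
})

test_that("the six evaluation subsets follow the filter definitions", {
  r <- micro_refs()
  pred <- prediction_set("m1", "binding", sprintf("C%02d", 1:10),
                         call = rep(1L, 10),
                         in_ad = c(rep(TRUE, 8), FALSE, FALSE))
  sub <- build_evaluation_subsets(r$cat_ref, r$pot_ref, r$training, pred)
  # ambiguous AUC band [0.01, 0.1) excluded from the HTS subset
  expect_setequal(sub$toxcast, c("T01", "T02", "T03", "T04", "T06"))
  tox_ref <- attr(sub, "toxcast_reference")
  expect_equal(tox_ref$active[tox_ref$inchi == "T06"], TRUE)
  expect_setequal(sub$lit_all, sprintf("C%02d", 1:10))
  # single-source chemicals leave the multi-source subset
  expect_setequal(sub$lit_min2src, c("C01", "C03", "C04", "C06", "C07", "C09", "C10"))
  # very-weak actives leave subset 4
  expect_setequal(sub$lit_no_veryweak, setdiff(sub$lit_all, "C03"))
  expect_setequal(sub$lit_in_ad, sprintf("C%02d", 1:8))
  expect_setequal(sub$lit_all_filters,
                  setdiff(intersect(sub$lit_min2src, sub$lit_in_ad), "C03"))
  # a model without AD: subset 5 collapses onto subset 2
  pred2 <- prediction_set("m2", "binding", sprintf("C%02d", 1:10), rep(1L, 10))
  sub2 <- build_evaluation_subsets(r$cat_ref, r$pot_ref, r$training, pred2)
  expect_setequal(sub2$lit_in_ad, sub2$lit_all)
  expect_setequal(sub2$lit_all_filters,
                  intersect(sub2$lit_min2src, sub2$lit_no_veryweak))
})

test_that("score_1 weights subset accuracy by coverage", {
  # no predictions -> 0; perfect coverage and accuracy -> 1
  expect_equal(score_1(rep(NA_real_, 5), rep(0, 5), rep(10, 5), 0, 100), 0)
  expect_equal(score_1(rep(1, 5), rep(10, 5), rep(10, 5), 100, 100), 1)
  # hand-computed mixed case: contributions 0.9, 0.5, 1.0, 0.7, 0.3
  s <- score_1(ba = c(0.9, 0.8, 1.0, 0.7, 0.6),
               n_pred_in_subset = c(10, 5, 4, 8, 2),
               n_subset = c(10, 8, 4, 8, 4), n_pred = 16, n_total = 20)
  expect_equal(s, (16 / 20) * (0.9 + 0.5 + 1.0 + 0.7 + 0.3) / 5)
  # an undefined subset BA contributes zero instead of poisoning the sum
  s2 <- score_1(ba = c(0.9, NA, 1.0, 0.7, 0.6),
                n_pred_in_subset = c(10, 5, 4, 8, 2),
                n_subset = c(10, 8, 4, 8, 4), n_pred = 16, n_total = 20)
  expect_equal(s2, (16 / 20) * (0.9 + 1.0 + 0.7 + 0.3) / 5)
})

test_that("score_2 is the mean of the HTS and filtered-literature accuracies", {
  expect_equal(score_2(0.92, 0.90), 0.91)
  expect_equal(score_2(1, 1), 1)
  expect_equal(score_2(0.8, 0.6), 0.7)
  expect_true(is.na(score_2(NA, 0.9)))
})

test_that("a perfect full-coverage categorical model scores 1 on both summaries", {
  chems <- sprintf("C%02d", 1:10)
  cat_ref <- data.frame(inchi = chems, activity_type = "binding",
                        active = rep(c(TRUE, FALSE), c(3, 7)),
                        n_sources = 2, provenance = "observed")
  pot_ref <- data.frame(inchi = chems[1:3], activity_type = "binding",
                        potency_class = c("strong", "weak", "moderate"),
                        avg_score = c(1, 0.5, 0.75), log10_median_uM = 0,
                        n_sources = 2)
  training <- data.frame(inchi = chems,
                         auc_binding = ifelse(cat_ref$active, 0.5, 0.005),
                         auc_agonist = 0.005, auc_antagonist = 0.005)
  pred <- prediction_set("perfect", "binding", chems,
                         call = as.integer(cat_ref$active))
  ms <- evaluate_categorical(pred, cat_ref, pot_ref, training, n_total = 10)
  expect_equal(ms$score_1, 1)
  expect_equal(ms$score_2, 1)
  expect_equal(ms$ba_lit_all, 1)
})

test_that("continuous models are scored on the five potency classes", {
  chems <- sprintf("C%02d", 1:8)
  classes <- c("strong", "moderate", "weak", "very_weak",
               rep("inactive", 4))
  ac50 <- c(0.05, 0.1, 1, 50, rep(INACTIVE_AC50_UM, 4))
  cat_ref <- data.frame(inchi = chems, activity_type = "binding",
                        active = classes != "inactive", n_sources = 2,
                        provenance = "observed")
  pot_ref <- data.frame(inchi = chems, activity_type = "binding",
                        potency_class = classes,
                        avg_score = potency_score(classes),
                        log10_median_uM = log10(ac50), n_sources = 2)
  training <- data.frame(inchi = chems,
                         auc_binding = ifelse(classes != "inactive", 0.5, 0.005),
                         auc_agonist = 0.005, auc_antagonist = 0.005)
  exact <- prediction_set("exact", "binding", chems,
                          call = as.integer(classes != "inactive"),
                          potency_uM = ac50, is_continuous = TRUE)
  ms <- evaluate_continuous(exact, cat_ref, pot_ref, training, n_total = 8)
  expect_equal(ms$ba_lit_all, 1)
  expect_equal(ms$score_2, 1)
  # 0.05 micromolar is compared as class strong
  ev <- attr(ms, "subset_evals")$lit_all
  expect_equal(unname(ev$per_class["strong"]), 1)
  # the constant inactive predictor gets inactive-class sensitivity 1,
  # zero sensitivity for every active class
  flat <- prediction_set("flat", "binding", chems, call = rep(0L, 8),
                         potency_uM = rep(INACTIVE_AC50_UM, 8),
                         is_continuous = TRUE)
  mf <- evaluate_continuous(flat, cat_ref, pot_ref, training, n_total = 8)
  pc <- attr(mf, "subset_evals")$lit_all$per_class
  expect_equal(unname(pc["inactive"]), 0.5)   # sens 1, spec 0 -> BA 0.5
})

test_that("restricting calls to a subset leaves that subset's matrix unchanged", {
  r <- micro_refs()
  set.seed(4)
  pred <- prediction_set("m", "binding", sprintf("C%02d", 1:10),
                         call = rbinom(10, 1, 0.4))
  sub <- sprintf("C%02d", c(1, 3, 5, 7, 9))
  full <- confusion_matrix(
    pred$calls[pred$calls$inchi %in% sub, ],
    r$cat_ref[r$cat_ref$inchi %in% sub, c("inchi", "active")])
  restricted_calls <- pred$calls[pred$calls$inchi %in% sub, ]
  again <- confusion_matrix(
    restricted_calls,
    r$cat_ref[r$cat_ref$inchi %in% sub, c("inchi", "active")])
  expect_equal(unlist(full[c("tp", "fn", "fp", "tn")]),
               unlist(again[c("tp", "fn", "fp", "tn")]))
})
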