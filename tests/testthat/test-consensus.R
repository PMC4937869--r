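# Consensus construction, concordance, weighted potency and correction rules.

cons_calls <- function(...) {
  # build a long call table: one row per model, for a single chemical "X"
  calls <- c(...)
  data.frame(model_id = sprintf("m%02d", seq_along(calls)), inchi = "X",
             call = calls, stringsAsFactors = FALSE)
}
scores_for <- function(s2) {
  data.frame(model_id = sprintf("m%02d", seq_along(s2)), score_2 = s2,
             stringsAsFactors = FALSE)
}

test_that("the higher average model score decides the categorical call", {
  # active callers' scores {0.8} beat inactive callers' {0.7, 0.6}
  cc <- categorical_consensus(cons_calls(1, 0, 0), scores_for(c(0.8, 0.7, 0.6)))
  expect_equal(cc$call, "active")
  expect_equal(cc$avg_score_active, 0.8)
  expect_equal(cc$avg_score_inactive, 0.65)
  # unanimous inactive
  cc <- categorical_consensus(cons_calls(0, 0, 0), scores_for(c(0.8, 0.7, 0.6)))
  expect_equal(cc$call, "inactive")
  expect_equal(cc$concordance_inactive, 1)
  # chemicals predicted by zero models are emitted, not omitted
  cc <- categorical_consensus(cons_calls(NA, NA, NA), scores_for(c(0.8, 0.7, 0.6)))
  expect_equal(cc$call, "not_predicted")
  # non-predicting models are excluded from the averages
  cc <- categorical_consensus(cons_calls(1, NA, 0), scores_for(c(0.6, 0.9, 0.5)))
  expect_equal(cc$concordance_active, 0.5)
  expect_equal(cc$avg_score_active, 0.6)
})

test_that("concordance splits predicting models and sums to one", {
  expect_equal(concordance(c(1, 1, 1, 0)), c(active = 0.75, inactive = 0.25))
  expect_equal(concordance(c(1, NA, 0)), c(active = 0.5, inactive = 0.5))
  expect_equal(concordance(c(1, 1, 1)), c(active = 1, inactive = 0))
  expect_error(concordance(c(NA, NA)), "no predicting model")
  # property: the pair sums to exactly one over random call patterns
  set.seed(9)
  for (i in 1:25) {
    calls <- sample(c(0L, 1L, NA), 8, replace = TRUE)
    if (all(is.na(calls))) next
    expect_equal(sum(concordance(calls)), 1)
  }
})

test_that("potency weights are score-proportional and normalized", {
  expect_equal(potency_weights(c(0.5, 0.5, 0.5)), rep(1 / 3, 3))
  expect_equal(potency_weights(0.7), 1)
  expect_equal(potency_weights(c(0.9, 0.45)), c(2 / 3, 1 / 3))
  expect_warning(w <- potency_weights(c(0, 0)), "zero")
  expect_equal(w, c(0.5, 0.5))
})

test_that("weighted potency levels round to the nearest class, half toward potent", {
  pc <- potency_consensus(c("weak", "weak"), c(0.5, 0.5))
  expect_equal(as.character(pc$class), "weak")
  pc <- potency_consensus("strong", 1)
  expect_equal(as.character(pc$class), "strong")
  # equal-weight weak + strong: level 0.75 -> moderate
  pc <- potency_consensus(c("weak", "strong"), c(0.5, 0.5))
  expect_equal(pc$C, 0.75)
  expect_equal(as.character(pc$class), "moderate")
  # half-way levels round toward the more potent class
  pc <- potency_consensus(c("moderate", "strong"), c(0.5, 0.5))
  expect_equal(pc$C, 0.875)
  expect_equal(as.character(pc$class), "strong")
  expect_equal(as.character(potency_consensus(c("inactive", "very_weak"),
                                              c(0.5, 0.5))$class), "very_weak")
  expect_true(is.na(potency_consensus(character(0), numeric(0))$class))
})

test_that("positive concordance maps onto potency classes at the stated cuts", {
  expect_equal(as.character(concordance_to_potency(c(0.95, 0.9, 0.8, 0.75,
                                                     0.7, 0.6, 0.5))),
               c("strong", "strong", "moderate", "moderate",
                 "weak", "weak", "very_weak"))
})

micro_consensus <- function() {
  chems <- sprintf("X%d", 1:5)
  bind_cat <- data.frame(
    inchi = chems,
    call = c("active", "inactive", "inactive", "inactive", "inactive"),
    concordance_active = c(0.8, 0.55, 0.4, 0.1, 0.0),
    n_active_calls = c(4L, 3L, 2L, 0L, 0L), stringsAsFactors = FALSE)
  bind_pot <- data.frame(
    inchi = chems,
    potency_class = c("inactive", "weak", "weak", "inactive", "inactive"),
    stringsAsFactors = FALSE)
  ag_cat <- data.frame(
    inchi = chems,
    call = c("inactive", "inactive", "inactive", "active", "inactive"),
    concordance_active = c(0, 0, 0, 0.95, 0),
    n_active_calls = c(0L, 0L, 0L, 5L, 0L), stringsAsFactors = FALSE)
  ag_pot <- data.frame(inchi = chems,
                       potency_class = c("inactive", "inactive", "inactive",
                                         "strong", "inactive"),
                       stringsAsFactors = FALSE)
  an_cat <- data.frame(inchi = chems, call = "inactive",
                       concordance_active = 0, n_active_calls = 0L,
                       stringsAsFactors = FALSE)
  an_pot <- data.frame(inchi = chems, potency_class = "inactive",
                       stringsAsFactors = FALSE)
  list(binding = list(categorical = bind_cat, potency = bind_pot),
       agonist = list(categorical = ag_cat, potency = ag_pot),
       antagonist = list(categorical = an_cat, potency = an_pot))
}

test_that("the four correction rules fire on constructed micro-cases", {
  res <- apply_corrections(micro_consensus())
  b <- res$result$binding
  # rule 1: categorical active, quantitative inactive, concordance 0.8 -> moderate
  expect_equal(b$potency_class[b$inchi == "X1"], "moderate")
  expect_equal(b$rules_applied[b$inchi == "X1"], "1")
  # rule 2: quantitative active with >= 3 active categorical calls
  expect_equal(b$call[b$inchi == "X2"], "active")
  expect_equal(b$rules_applied[b$inchi == "X2"], "2")
  # rule 3: quantitative active with < 3 active calls -> quantitative inactive
  expect_equal(b$potency_class[b$inchi == "X3"], "inactive")
  expect_equal(b$call[b$inchi == "X3"], "inactive")
  # rule 4: active agonist forces binding active at the agonist potency
  expect_equal(b$call[b$inchi == "X4"], "active")
  expect_equal(b$potency_class[b$inchi == "X4"], "strong")
  expect_match(b$rules_applied[b$inchi == "X4"], "4")
  # untouched chemical
  expect_equal(b$rules_applied[b$inchi == "X5"], "")
  # every state change has exactly one log row
  expect_equal(sort(unique(res$log$rule)), c(1L, 2L, 3L, 4L))
})

test_that("a second correction pass changes nothing", {
  res <- apply_corrections(micro_consensus())
  again <- apply_corrections(res$result)
  expect_equal(nrow(again$log), 0)
  for (type in names(res$result)) {
    expect_equal(again$result[[type]][, c("inchi", "call", "potency_class")],
                 res$result[[type]][, c("inchi", "call", "potency_class")])
  }
})

test_that("corrected consensus is internally consistent", {
  w <- tiny_world(250, seed = 21)
  cfg <- w$config
  consensus <- list()
  for (type in c("agonist", "antagonist", "binding")) {
    ens <- simulate_model_ensemble(w$truth, cfg, type)
    p <- attr(ens, "params")
    sc <- data.frame(model_id = p$model_id, score_2 = (p$sens + p$spec) / 2)
    cc <- categorical_consensus(calls_long(ens), sc)
    cens <- simulate_model_ensemble(w$truth, cfg, type, continuous = TRUE,
                                    seed = cfg$seed + 50)
    pot_calls <- do.call(rbind, lapply(cens, function(pp) {
      cls <- as.character(classify_potency(pp$calls$potency_uM))
      cls[is.na(pp$calls$call)] <- NA_character_
      data.frame(model_id = pp$model_id, inchi = pp$calls$inchi, class = cls)
    }))
    pc <- attr(cens, "params")
    cp <- consensus_potency_table(
      pot_calls, data.frame(model_id = pc$model_id,
                            score_2 = (pc$sens + pc$spec) / 2))
    consensus[[type]] <- list(categorical = cc, potency = cp)
  }
  res <- apply_corrections(consensus)
  # every active agonist/antagonist is an active binder after correction
  ag <- res$result$agonist; an <- res$result$antagonist; b <- res$result$binding
  forced <- union(ag$inchi[ag$call == "active"], an$inchi[an$call == "active"])
  expect_true(all(b$call[b$inchi %in% forced] == "active"))
  # categorical-active chemicals always carry a non-inactive potency
  act <- b$call == "active"
  expect_true(all(!is.na(b$potency_class[act]) &
                    b$potency_class[act] != "inactive"))
  # quantitative actives not categorical-active were all handled by rule 2 or 3
  qa <- !is.na(b$potency_class) & b$potency_class != "inactive" & !act
  expect_equal(sum(qa), 0)
  # and a second pass is silent
  expect_equal(nrow(apply_corrections(res$result)$log), 0)
})

test_that("the concordance threshold sweep is monotone with sensible endpoints", {
  set.seed(5)
  n <- 60
  cc <- data.frame(inchi = sprintf("C%02d", 1:n),
                   call = "active",
                   concordance_active = round(runif(n), 2),
                   n_active_calls = 0L, stringsAsFactors = FALSE)
  cc$n_active_calls <- as.integer(ifelse(cc$concordance_active > 0,
                                         pmax(1, round(cc$concordance_active * 10)), 0))
  cc$call <- ifelse(cc$n_active_calls > 0, "active", "inactive")
  ref <- data.frame(inchi = cc$inchi, active = runif(n) < 0.3,
                    n_sources = sample(1:8, n, replace = TRUE))
  sw <- threshold_sweep(cc, ref, thresholds = seq(0, 1, 0.1), strata = c(1, 3))
  for (s in c(1, 3)) {
    na <- sw$n_active[sw$stratum == s]
    expect_true(all(diff(na) <= 0))
  }
  # threshold 0 counts every chemical with at least one active call
  expect_equal(sw$n_active[sw$threshold == 0 & sw$stratum == 1],
               sum(cc$n_active_calls >= 1))
  # threshold 1 keeps only unanimous actives
  expect_equal(sw$n_active[sw$threshold == 1 & sw$stratum == 1],
               sum(cc$concordance_active == 1 & cc$n_active_calls >= 1))
})
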