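# Shared fixtures built in code.

# the 50-molecule curation fixture shipped with the package
fixture_smiles_path <- function() {
  system.file("extdata", "curation_fixture.smi", package = "erconsensus")
}

# a small deterministic synthetic world used across modules
tiny_world <- function(n = 300, seed = 11, ...) {
  cfg <- sim_config(n_chemicals = n, n_models = 6, seed = seed, ...)
  truth <- generate_ground_truth(cfg)
  list(config = cfg, truth = truth,
       training = generate_training_auc(truth, seed = seed),
       literature = simulate_literature(truth, cfg))
}

# long call table + score table from an ensemble, for consensus tests
calls_long <- function(preds) {
  do.call(rbind, lapply(preds, function(p) {
    data.frame(model_id = p$model_id, inchi = p$calls$inchi,
               call = p$calls$call, stringsAsFactors = FALSE)
  }))
}

# reference data.frame of truth for one activity type
truth_reference <- function(truth, type = "binding") {
  data.frame(inchi = truth$inchi, active = truth[[paste0("active_", type)]],
             stringsAsFactors = FALSE)
}

# binary consensus calls as a calls data.frame for confusion_matrix()
consensus_as_calls <- function(cc) {
  data.frame(inchi = cc$inchi,
             call = ifelse(cc$call == "active", 1L,
                           ifelse(cc$call == "inactive", 0L, NA_integer_)),
             stringsAsFactors = FALSE)
}
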