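# full-scale evaluation protocol, shared (and cached) across test files.
# problem sizes: default synthetic dataset (4 subjects, 292 sessions,
# 21 Hz), window ns = 21, exercise nets trained 40 epochs x 60 steps,
# anomaly nets 25 x 60, three protocol seeds for the headline medians.

.protocol_cache <- new.env(parent = emptyenv())

protocol_dataset <- function(variation = 1) {
  key <- paste0("ds_", variation)
  if (is.null(.protocol_cache[[key]])) {
    ds <- generate_dataset(variation = variation, seed = 1)
    feats <- lapply(ds$sessions, feature_matrix)
    .protocol_cache[[key]] <- list(ds = ds, feats = feats)
  }
  .protocol_cache[[key]]
}

protocol_config <- function(task, seed) {
  if (task == "exercise") {
    train_config(epochs = 40L, steps_per_epoch = 60L, seed = seed)
  } else {
    train_config(epochs = 25L, steps_per_epoch = 60L, seed = seed)
  }
}

protocol_accuracy <- function(variation, model_kind, task, scheme, seed,
                              ablation = "normal") {
  key <- paste("acc", variation, model_kind, task, scheme, seed, ablation,
               sep = "_")
  if (is.null(.protocol_cache[[key]])) {
    d <- protocol_dataset(variation)
    plan <- if (scheme == "loso") plan_loso(d$ds$manifest)
            else plan_five_fold(d$ds$manifest, seed = seed)
    rep <- run_experiment(
      d$ds, model_kind, task, ns = 21L, ablation = ablation, plan = plan,
      config = protocol_config(task, seed), seed = seed,
      features = if (model_kind == "cnn") d$feats else NULL)
    .protocol_cache[[key]] <- rep$aggregate$mean[
      rep$aggregate$metric == "accuracy"]
  }
  .protocol_cache[[key]]
}

protocol_seeds <- function() c(1L, 2L, 3L)

# median over the protocol seeds of the mean cross-validated accuracy
protocol_median <- function(model_kind, task, scheme, ablation = "normal",
                            seeds = protocol_seeds()) {
  median(vapply(seeds, function(s) {
    protocol_accuracy(1, model_kind, task, scheme, s, ablation)
  }, numeric(1)))
}
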