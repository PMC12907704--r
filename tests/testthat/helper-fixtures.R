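# Small shared builders for tests. Larger end-to-end artifacts (the trained
# model used by the fraction-recovery and monitoring scenarios) are built once
# and cached for the session.

tiny_beta <- function(n_probes = 6, n_samples = 4, seed = 1) {
  set.seed(seed)
  matrix(runif(n_probes * n_samples), n_probes, n_samples,
         dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                         paste0("s", seq_len(n_samples))))
}

tiny_reference <- function(n_probes = 30, seed = 2) {
  make_reference(fixture_spec(n_probes = n_probes, n_dmp = n_probes,
                              n_tissue_dmp = 0, n_tumor_tissue = 8,
                              n_plasma = 8, seed = seed))
}

tiny_model <- function(n_probes = 20, epochs = 3, seed = 1) {
  rf <- tiny_reference(n_probes)
  sim <- generate_simulated_data(rf$ref, samplenum = 60, random_state = 4)
  cfg <- suppressWarnings(model_config(n_features = n_probes, epochs = epochs,
                                       batch_size = 30, seed = seed))
  list(model = suppressWarnings(train_deconv(sim$x, sim$y, rf$ref, cfg)),
       sim = sim, rf = rf, cfg = cfg)
}

# session cache for the expensive trained model shared by acceptance checks
.cfdecon_cache <- new.env(parent = emptyenv())

recovery_experiment <- function() {
  if (!is.null(.cfdecon_cache$recovery)) {
    return(.cfdecon_cache$recovery)
  }
  rf <- make_reference(fixture_spec(n_probes = 200, n_dmp = 200, n_tissue_dmp = 0,
                                    n_tumor_tissue = 50, n_plasma = 60, seed = 11))
  train <- generate_simulated_data(rf$ref, samplenum = 1000, random_state = 11)
  heldout <- generate_simulated_data(rf$ref, samplenum = 200, random_state = 99)
  cfg <- model_config(n_features = 200, epochs = 256, seed = 1)
  model <- train_deconv(train$x, train$y, rf$ref, cfg)
  .cfdecon_cache$recovery <- list(rf = rf, train = train, heldout = heldout,
                                  model = model)
  .cfdecon_cache$recovery
}
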