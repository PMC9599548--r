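# Shared fixtures, generated once per test run. Reduced descriptor
# registries keep the unit tests fast while still spanning both feature
# families; the acceptance tests use the full registries.

.fixture_env <- new.env(parent = emptyenv())

small_physchem_registry <- function() {
  registry_subset(default_physchem_registry(), c("aac", "dpc", "ctdc"))
}

small_pssm_registry <- function() {
  registry_subset(default_pssm_registry(), c("aac_pssm", "dpc_pssm"))
}

# 50-sample planted dataset with cleaned reduced features, cached
small_planted <- function() {
  if (is.null(.fixture_env$small)) {
    ds <- gen_planted_dataset(planted_spec(n_pos = 20L, n_neg = 30L,
                                           length = 60L, effect = 3,
                                           noise = 0, seed = 11L))
    X <- clean_features(featurize(ds$records, ds$profiles,
                                  physchem_registry = small_physchem_registry(),
                                  pssm_registry = small_pssm_registry()))
    .fixture_env$small <- list(ds = ds, X = X, y = ds$labels)
  }
  .fixture_env$small
}

# hand-built linear classifier for ensemble tests: predicts sign of the
# first feature column
constant_direction_classifier <- function(columns, w, b = 0,
                                          algorithm = "ridge",
                                          test_mcc = 0.5, repeat_id = 1L) {
  structure(list(algorithm = algorithm,
                 hyper = list(lambda = 1),
                 cv_mcc = NA_real_,
                 feature_set = structure(list(method = "manual",
                                              dims = length(columns),
                                              target_dims = length(columns),
                                              columns = columns,
                                              family_counts = c(pssm = 0L,
                                                                physchem = 0L),
                                              label = "manual"),
                                         class = "feature_set"),
                 columns = columns,
                 center = stats::setNames(rep(0, length(columns)), columns),
                 scale = stats::setNames(rep(1, length(columns)), columns),
                 fit = list(w = w, b = b),
                 seed = 1L,
                 test_mcc = test_mcc,
                 repeat_id = repeat_id),
            class = "promisc_classifier")
}
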