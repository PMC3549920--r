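# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# The reference study condition: 11 + 11 subjects, 200 volumes. Built once
# (about a minute) and reused by the integration and acceptance tests.
default_study <- function() {
  if (is.null(.fixture_env$default)) {
    cfg <- cohort_config()
    cohort <- generate_cohort(cfg)
    feats <- study_features(cohort)
    .fixture_env$default <- list(cfg = cfg, cohort = cohort, feats = feats)
  }
  .fixture_env$default
}

# A toy cohort for cheap structural tests.
toy_cohort <- function() {
  if (is.null(.fixture_env$toy)) {
    cfg <- cohort_config(n_per_group = 2L, n_volumes = 60L,
                         n_per_condition = 3L, seed = 11L)
    .fixture_env$toy <- list(cfg = cfg, cohort = generate_cohort(cfg))
  }
  .fixture_env$toy
}

# A small bold_run with controllable series on a tiny grid.
tiny_bold <- function(series, nx = 4, ny = 1, nz = 1, tr = 2) {
  mask <- array(FALSE, dim = c(nx, ny, nz))
  mask[seq_len(nrow(series))] <- TRUE
  affine <- diag(c(10, 10, 10, 1))
  affine[1:3, 4] <- c(-25, -10, -10) # voxel (i,1,1) sits at (10i - 25, 0, 0) mm
  bold_run(series, mask, affine, tr)
}

# pure-noise feature table: n_subj subjects per group, 2 runs each
noise_table <- function(n_subj, n_feat, seed) {
  set.seed(seed)
  n <- 4 * n_subj # samples
  ids <- rep(c(sprintf("c%02d", seq_len(n_subj)), sprintf("p%02d", seq_len(n_subj))),
             each = 2)
  labels <- rep(c("control", "patient"), each = 2 * n_subj)
  feature_table(matrix(stats::rnorm(n * n_feat), n), labels, ids)
}
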