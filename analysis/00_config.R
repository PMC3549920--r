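# Shared settings for the analysis drivers. Every script sources this file,
# regenerates the cohort deterministically from MASTER_SEED, and writes its
# tables under results/.

suppressPackageStartupMessages(library(netfmri))

MASTER_SEED <- as.integer(Sys.getenv("NETFMRI_SEED", "1"))
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

study_config <- function() cohort_config(seed = MASTER_SEED)

# Feature extraction is the expensive step (about a minute); scripts 03-06
# share it through an on-disk cache keyed by the seed.
cached_features <- function() {
  cache <- file.path(RESULTS_DIR, sprintf("features_seed%d.rds", MASTER_SEED))
  if (file.exists(cache)) return(readRDS(cache))
  cohort <- generate_cohort(study_config())
  feats <- study_features(cohort)
  saveRDS(feats, cache)
  feats
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
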