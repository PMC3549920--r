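#!/usr/bin/env Rscript
# Build voxel-level functional networks (Pearson correlation, threshold 0.7)
# for every sample and extract the topological feature maps and the six
# global features.

source("analysis/00_config.R")

feats <- cached_features()
message(sprintf("%d samples x %d voxels; feature kinds: %s",
                nrow(feats$samples), ncol(feats$tables$degree_full$values),
                paste(names(feats$tables), collapse = ", ")))

globals <- cbind(feats$samples, feats$globals,
                 mean_abs_t_map8 = feats$mean_abs_t)
write_tsv(globals, "global_features.tsv")

by_group <- aggregate(feats$globals, list(group = feats$samples$label), mean)
write_tsv(by_group, "global_features_by_group.tsv")
message("group means of the global features:")
print(by_group)

# a sampled edge-weight feature set over a fixed random pair list
pairs <- sample_edges(ncol(feats$tables$degree_full$values), 20000,
                      seed = MASTER_SEED)
cohort <- generate_cohort(study_config())
edge_feats <- study_features(cohort, edge_pairs = pairs,
                             heavy_features = FALSE)$tables$edge_weights
res <- two_sample_ttest(edge_feats)
message(sprintf(
  "edge-weight features: %d of %d survive FDR at 0.05",
  sum(fdr_select(res$p, 0.05)), length(res$p)
))
write_tsv(
  data.frame(n_pairs = length(res$p),
             n_fdr = sum(fdr_select(res$p, 0.05)),
             n_bonferroni = sum(bonferroni_select(res$p, 0.05))),
  "edge_weight_stats.tsv"
)
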