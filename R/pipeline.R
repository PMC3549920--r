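#' Sample sheet of a cohort
#'
#' @param cohort list of `subject_record`s.
#' @return data frame with one row per (subject, run): `subject_id`, `run`,
#'   `label`.
#' @export
cohort_samples <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id, run = seq_along(s$runs),
               label = s$group, stringsAsFactors = FALSE)
  }))
}

#' Leave-one-subject-out folds
#'
#' One fold per subject; the test set is exactly that subject's two run
#' samples. Subjects are ordered lexicographically so folds are
#' reproducible.
#'
#' @param samples data frame with columns `subject_id`, `run`, `label`
#'   (e.g. [cohort_samples()]); every subject must have exactly 2 rows.
#' @return list of folds, each `list(subject_id, train, test)` with row
#'   indices into `samples`.
#' @export
make_losocv_folds <- function(samples) {
  counts <- table(samples$subject_id)
  if (any(counts != 2L)) {
    stop("subject without exactly 2 samples: ",
         paste(names(counts)[counts != 2L], collapse = ", "))
  }
  lab_per_subj <- tapply(samples$label, samples$subject_id,
                         function(x) length(unique(x)))
  if (any(lab_per_subj != 1L)) {
    stop("subject appears with more than one group label")
  }
  subjects <- sort(unique(samples$subject_id))
  folds <- lapply(subjects, function(sj) {
    test <- which(samples$subject_id == sj)
    list(subject_id = sj, train = setdiff(seq_len(nrow(samples)), test),
         test = test)
  })
  folds
}

#' Majority-class baseline accuracy
#'
#' @param labels vector of class labels.
#' @return the largest class frequency.
#' @export
baseline_accuracy <- function(labels) {
  if (!length(labels)) stop("labels must be nonempty")
  max(table(labels)) / length(labels)
}

subset_table <- function(table, rows, cols = NULL) {
  v <- table$values[rows, , drop = FALSE]
  ids <- table$feature_ids
  if (!is.null(cols)) {
    v <- v[, cols, drop = FALSE]
    ids <- ids[cols]
  }
  feature_table(v, table$labels[rows], table$subject_ids[rows], ids, table$kind)
}

#' Cross-validated classification with in-fold feature selection
#'
#' Leave-one-subject-out cross-validation: within each fold, features are
#' ranked by two-sample t-test p-values computed on the *training* rows
#' only, the top `k` are kept, the classifier is fitted on the training
#' rows and the held-out subject's two samples are predicted. Errors are
#' pooled over all held-out predictions per `k`. "patient" is the positive
#' class: FP is the fraction of control samples predicted patient, FN the
#' fraction of patient samples predicted control.
#'
#' @param table a [feature_table()] with two samples per subject.
#' @param kind classifier kind (see [fit_classifier()]).
#' @param k_grid numbers of selected features to sweep.
#' @param ... classifier parameters (e.g. `lambda`).
#' @return an `eval_result`: `results` data frame (`k`, `error`, `fp`,
#'   `fn`), `predictions` (per fold and k), `topk_sets` (per k, the list of
#'   per-fold selected feature positions).
#' @export
run_cv_experiment <- function(table, kind = "gnb", k_grid = c(10, 50, 100),
                              ...) {
  stopifnot(inherits(table, "feature_table"))
  nf <- ncol(table$values)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid > nf)) {
    stop("k_grid must lie within [1, ", nf, "]")
  }
  samples <- data.frame(subject_id = table$subject_ids,
                        run = stats::ave(seq_along(table$subject_ids),
                                         table$subject_ids, FUN = seq_along),
                        label = table$labels, stringsAsFactors = FALSE)
  folds <- make_losocv_folds(samples)

  topk_sets <- stats::setNames(
    lapply(k_grid, function(k) vector("list", length(folds))),
    paste0("k", k_grid)
  )
  preds <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    stopifnot(length(intersect(fold$train, fold$test)) == 0L)
    train_tab <- subset_table(table, fold$train)
    pv <- two_sample_ttest(train_tab)$p
    for (ki in seq_along(k_grid)) {
      k <- k_grid[ki]
      sel <- rank_topk(pv, k)
      topk_sets[[ki]][[fi]] <- sel
      model <- fit_classifier(subset_table(table, fold$train, sel), kind, ...)
      pred <- predict(model, table$values[fold$test, sel, drop = FALSE])
      preds[[length(preds) + 1L]] <- data.frame(
        fold = fi, subject_id = fold$subject_id, k = k,
        sample = fold$test, truth = table$labels[fold$test],
        predicted = pred, stringsAsFactors = FALSE
      )
    }
  }
  preds <- do.call(rbind, preds)
  results <- do.call(rbind, lapply(k_grid, function(k) {
    pk <- preds[preds$k == k, ]
    is_pat <- pk$truth == "patient"
    data.frame(
      k = k,
      error = mean(pk$predicted != pk$truth),
      fp = if (any(!is_pat)) mean(pk$predicted[!is_pat] == "patient") else NA_real_,
      fn = if (any(is_pat)) mean(pk$predicted[is_pat] == "control") else NA_real_
    )
  }))
  structure(
    list(results = results, predictions = preds, topk_sets = topk_sets,
         kind = kind, feature_kind = table$kind),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s on %s features\n", x$kind, x$feature_kind))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Selection stability of a CV experiment
#'
#' @param eval an `eval_result`.
#' @return data frame with `k` and `stability` (fraction of features common
#'   to all folds' top-k sets).
#' @export
cv_stability <- function(eval) {
  ks <- eval$results$k
  data.frame(
    k = ks,
    stability = vapply(seq_along(ks), function(i) {
      stability(eval$topk_sets[[i]], ks[i])
    }, numeric(1))
  )
}

#' Per-sample feature extraction over a cohort
#'
#' Runs the GLM and the network construction on every (subject, run) sample
#' and stacks the per-voxel features into [feature_table()]s. Degree maps
#' are spatially normalized per sample; activation t-maps are kept raw (use
#' [normalize_rows()] before classification, where normalized maps perform
#' better). Clustering and local efficiency are computed on the
#' absolute-threshold graph; degrees, global and distance features on the
#' raw-threshold graph.
#'
#' @param cohort list of `subject_record`s.
#' @param threshold correlation threshold (default 0.7).
#' @param contrasts activation contrast names to tabulate (default the
#'   eight maps).
#' @param edge_pairs optional fixed pair list from [sample_edges()] for
#'   edge-weight features.
#' @param min_dist long-distance degree cutoff (voxel-index units).
#' @param drift_cutoff GLM drift cutoff (Hz).
#' @param use_motion include motion regressors in the GLM design.
#' @param heavy_features compute clustering and local-efficiency maps
#'   (slower); default TRUE.
#' @return a `study_features` list: `samples`, `tables` (named
#'   feature_tables), `graphs` (raw-threshold `functional_graph` per
#'   sample), `globals` (data frame of six global features per sample),
#'   `mean_abs_t`, `motion_summary` (mean framewise displacement proxy),
#'   plus `mask`/`affine`.
#' @export
study_features <- function(cohort, threshold = 0.7, contrasts = NULL,
                           edge_pairs = NULL, min_dist = 5,
                           drift_cutoff = 1 / 128, use_motion = TRUE,
                           heavy_features = TRUE) {
  samples <- cohort_samples(cohort)
  n_samp <- nrow(samples)
  mask <- cohort[[1]]$runs[[1]]$mask
  affine <- cohort[[1]]$runs[[1]]$affine

  act_rows <- list()
  deg_rows <- list(full = list(), long = list(), inter = list())
  str_rows <- list(s = list(), a = list(), p = list())
  clu_rows <- list(); eff_rows <- list(); edge_rows <- list()
  graphs <- vector("list", n_samp)
  globals <- vector("list", n_samp)
  matv <- numeric(n_samp)
  motion_summary <- numeric(n_samp)

  si <- 0L
  for (subj in cohort) {
    for (r in seq_along(subj$runs)) {
      si <- si + 1L
      bold <- subj$runs[[r]]
      motion <- if (use_motion) subj$motion[[r]] else NULL
      maps <- activation_maps(bold, subj$paradigms[[r]], motion, drift_cutoff)
      act_rows[[si]] <- vapply(maps, function(m) m$values,
                               numeric(length(maps[[1]]$values)))
      matv[si] <- mean_abs_t(maps[["8_Silence"]])
      motion_summary[si] <- mean(abs(diff(subj$motion[[r]][, 1:3])))

      corr <- pairwise_correlations(bold)
      g_raw <- build_graph(corr, threshold, mode = "raw")
      degs <- degree_maps(g_raw, min_dist = min_dist)
      strs <- strength_maps(corr)
      deg_rows$full[[si]] <- normalize_map(degs$degree_full)$values
      deg_rows$long[[si]] <- normalize_map(degs$degree_long)$values
      deg_rows$inter[[si]] <- normalize_map(degs$degree_interhemi)$values
      str_rows$s[[si]] <- strs$strength$values
      str_rows$a[[si]] <- strs$strength_abs$values
      str_rows$p[[si]] <- strs$strength_pos$values
      if (heavy_features) {
        g_abs <- build_graph(corr, threshold, mode = "absolute")
        clu_rows[[si]] <- clustering_map(g_abs)$values
        eff_rows[[si]] <- local_efficiency_map(g_abs)$values
      }
      if (!is.null(edge_pairs)) {
        cc <- corr$full
        edge_rows[[si]] <- cc[cbind(edge_pairs[, 1], edge_pairs[, 2])]
      }
      graphs[[si]] <- g_raw
      globals[[si]] <- as.data.frame(global_features(g_raw))
    }
  }

  mk_tab <- function(rows, kind, ids = NULL) {
    feature_table(do.call(rbind, rows), samples$label, samples$subject_id,
                  feature_ids = ids, kind = kind)
  }
  act_mat <- do.call(rbind, lapply(act_rows, function(m) as.vector(m)))
  n_vox <- length(deg_rows$full[[1]])
  cnames <- names(activation_maps(cohort[[1]]$runs[[1]],
                                  cohort[[1]]$paradigms[[1]]))
  tables <- list()
  if (is.null(contrasts)) contrasts <- cnames
  for (cn in contrasts) {
    ci <- match(cn, cnames)
    tables[[paste0("activation_", cn)]] <- mk_tab(
      lapply(act_rows, function(m) m[, ci]), paste0("activation_", cn)
    )
  }
  tables$degree_full <- mk_tab(deg_rows$full, "degree_full")
  tables$degree_long <- mk_tab(deg_rows$long, "degree_long")
  tables$degree_interhemi <- mk_tab(deg_rows$inter, "degree_interhemi")
  tables$strength <- mk_tab(str_rows$s, "strength")
  tables$strength_abs <- mk_tab(str_rows$a, "strength_abs")
  tables$strength_pos <- mk_tab(str_rows$p, "strength_pos")
  if (heavy_features) {
    tables$clustering <- mk_tab(clu_rows, "clustering")
    tables$local_efficiency <- mk_tab(eff_rows, "local_efficiency")
  }
  if (!is.null(edge_pairs)) {
    tables$edge_weights <- mk_tab(
      edge_rows, "edge_weights",
      ids = paste(edge_pairs[, 1], edge_pairs[, 2], sep = "-")
    )
  }

  structure(
    list(samples = samples, tables = tables, graphs = graphs,
         globals = do.call(rbind, globals), mean_abs_t = matv,
         motion_summary = motion_summary, mask = mask, affine = affine),
    class = "study_features"
  )
}

#' Row-wise spatial normalization of a feature table
#'
#' Divides each sample's feature vector by its maximum absolute value
#' (per-sample map normalization applied at the table level).
#'
#' @param table a [feature_table()].
#' @return the normalized table.
#' @export
normalize_rows <- function(table) {
  v <- table$values
  m <- apply(abs(v), 1L, max)
  m[m == 0] <- 1
  table$values <- v / m
  table
}

#' Group comparison of distance-resolved connectivity
#'
#' Per group: the mean and standard deviation across samples of the per-bin
#' link probability, a power-law fit to the group-mean profile over the fit
#' range, and two-sample pooled-t comparisons of per-sample
#' inter-hemispheric link fractions (and, if ROIs are given, bilateral
#' ROI-pair link fractions). One-sided p-values test control > patient.
#'
#' @param graphs list of `functional_graph`s, one per sample.
#' @param groups group label per graph ("control"/"patient", >= 2 each).
#' @param bin_width distance bin width (mm).
#' @param fit_range length-2 fit range (mm) for the power law.
#' @param roi_a,roi_b optional disjoint voxel sets for the ROI-pair
#'   fraction.
#' @return a `distance_comparison` list.
#' @export
distance_group_comparison <- function(graphs, groups, bin_width = 5,
                                      fit_range = c(10, 150),
                                      roi_a = NULL, roi_b = NULL) {
  groups <- as.character(groups)
  if (length(graphs) != length(groups)) stop("one group label per graph")
  if (min(table(groups)) < 2L) stop("need at least 2 graphs per group")
  if (any(vapply(graphs, function(g) nrow(g$edges), integer(1)) == 0L)) {
    stop("a graph has no links")
  }

  profiles <- lapply(graphs, link_probability_by_distance, bin_width = bin_width)
  centers <- sort(unique(unlist(lapply(profiles, function(p) p$center))))
  prob_mat <- t(vapply(profiles, function(p) {
    p$probability[match(centers, p$center)]
  }, numeric(length(centers))))

  group_profile <- function(gname) {
    rows <- prob_mat[groups == gname, , drop = FALSE]
    prof <- data.frame(
      center = centers,
      probability = colMeans(rows, na.rm = TRUE),
      sd = apply(rows, 2L, stats::sd, na.rm = TRUE)
    )
    fit <- tryCatch(fit_power_law(prof, fit_range[1], fit_range[2]),
                    error = function(e) NULL)
    list(profile = prof, power_law = fit)
  }

  frac_test <- function(values) {
    res <- pooled_ttest_matrix(matrix(values, ncol = 1), groups == "control")
    means <- tapply(values, groups, mean)
    list(mean_control = unname(means["control"]),
         mean_patient = unname(means["patient"]),
         t = unname(res$t), p_two_sided = unname(res$p),
         p_control_greater = unname(stats::pt(res$t, df = res$df,
                                              lower.tail = FALSE)))
  }

  interhemi <- vapply(graphs, interhemispheric_fraction, numeric(1))
  out <- list(
    control = group_profile("control"),
    patient = group_profile("patient"),
    interhemispheric = c(list(values = interhemi), frac_test(interhemi))
  )
  if (!is.null(roi_a) && !is.null(roi_b)) {
    fr <- vapply(graphs, roi_pair_link_fraction, numeric(1),
                 roi_a = roi_a, roi_b = roi_b)
    out$roi_pair <- c(list(values = fr), frac_test(fr))
  }
  structure(out, class = "distance_comparison")
}

#' Run the full synthetic study end to end
#'
#' Generates (or accepts) a cohort, extracts activation and network
#' features, performs the mass-univariate group statistics with FDR and
#' Bonferroni correction, evaluates leave-one-subject-out classification
#' with in-fold selection, measures selection stability, and compares
#' distance-resolved connectivity between groups. Fully deterministic given
#' the configuration seed.
#'
#' @param config a [cohort_config()] (or an already generated cohort list).
#' @param threshold correlation threshold.
#' @param k_grid feature-selection sweep for cross-validation.
#' @param classifiers classifier kinds to evaluate.
#' @param lambda gmrf penalty.
#' @param cv_kinds feature-table names to cross-validate (default:
#'   normalized full-degree maps and the best-practice activation map 6).
#' @param heavy_features include clustering/local-efficiency maps.
#' @param out_dir optional directory; when given, writes `report.json` and
#'   TSV tables.
#' @return a `study_report` list with elements `samples`, `stats_table`,
#'   `cv`, `stability`, `distance`, `baseline`.
#' @export
run_full_study <- function(config = cohort_config(), threshold = 0.7,
                           k_grid = c(10, 50, 100), classifiers = "gnb",
                           lambda = 0.1, cv_kinds = NULL,
                           heavy_features = TRUE, out_dir = NULL) {
  cohort <- if (inherits(config, "cohort_config")) {
    generate_cohort(config)
  } else {
    config
  }
  feats <- study_features(cohort, threshold = threshold,
                          heavy_features = heavy_features)
  samples <- feats$samples

  stats_table <- do.call(rbind, lapply(names(feats$tables), function(nm) {
    res <- two_sample_ttest(feats$tables[[nm]])
    p <- res$p
    data.frame(
      map = nm,
      n_p001 = sum(p < 0.01), n_p0001 = sum(p < 0.001),
      n_fdr = sum(fdr_select(p, 0.05)),
      n_bonferroni = sum(bonferroni_select(p, 0.05)),
      n_features = length(p)
    )
  }))

  if (is.null(cv_kinds)) {
    cv_kinds <- c("degree_full", "activation_6_FrenchNative")
  }
  cv <- list(); stab <- list()
  for (nm in cv_kinds) {
    tab <- feats$tables[[nm]]
    if (startsWith(nm, "activation_")) tab <- normalize_rows(tab)
    for (cl in classifiers) {
      ev <- if (cl == "gmrf") {
        run_cv_experiment(tab, kind = cl, k_grid = k_grid, lambda = lambda)
      } else {
        run_cv_experiment(tab, kind = cl, k_grid = k_grid)
      }
      key <- paste(nm, cl, sep = ".")
      cv[[key]] <- ev
      stab[[key]] <- cv_stability(ev)
    }
  }

  distance <- distance_group_comparison(feats$graphs, samples$label)

  report <- structure(
    list(samples = samples, stats_table = stats_table, cv = cv,
         stability = stab, distance = distance,
         baseline = baseline_accuracy(samples$label),
         features = feats),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}
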