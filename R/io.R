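#' @title File interfaces
#' @description NIfTI-1 volumes (via RNifti), BIDS-style events TSV,
#'   whitespace-delimited motion text, ROI TSV, and JSON manifests.
#' @name io
NULL

# netfmri affines map 1-based voxel indices to mm; NIfTI sforms map 0-based
# indices. Shift the translation column when converting.
affine_to_nifti <- function(affine) {
  out <- affine
  out[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% rep(1, 3)
  out
}

affine_from_nifti <- function(xform) {
  out <- matrix(as.numeric(xform), 4, 4)
  out[1:3, 4] <- out[1:3, 4] - out[1:3, 1:3] %*% rep(1, 3)
  out
}

#' Write a bold_run (or any volume) as NIfTI-1
#'
#' @param bold a [bold_run()].
#' @param file output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_bold_nifti <- function(bold, file) {
  arr <- bold_array(bold)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(abs(diag(bold$affine)[1:3]), bold$tr)
  RNifti::sform(img) <- structure(affine_to_nifti(bold$affine), code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_bold_nifti
#' @param mask 3D logical array.
#' @param affine 1-based voxel-to-mm affine.
#' @export
write_mask_nifti <- function(mask, affine, file) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                         datatype = "uint8")
  RNifti::sform(img) <- structure(affine_to_nifti(affine), code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a BOLD run from NIfTI files
#'
#' @param bold_file 4D NIfTI path.
#' @param mask_file 3D mask NIfTI path (nonzero = in mask).
#' @param tr repetition time; `NULL` to take it from the NIfTI header.
#' @return a [bold_run()].
#' @export
read_bold_nifti <- function(bold_file, mask_file, tr = NULL) {
  img <- RNifti::readNifti(bold_file)
  msk <- RNifti::readNifti(mask_file)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  affine <- affine_from_nifti(RNifti::xform(img))
  bold_run(unclass(img)[, , , , drop = FALSE],
           array(unclass(msk) != 0, dim = dim(msk)[1:3]),
           affine, tr)
}

#' Write a feature map as a NIfTI-1 volume
#'
#' @param map a `feature_map` carrying `mask` and `affine`.
#' @param file output path.
#' @export
write_feature_map_nifti <- function(map, file) {
  if (is.null(map$mask) || is.null(map$affine)) {
    stop("feature map carries no geometry")
  }
  vol <- unmask(map$values, map$mask)
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(affine_to_nifti(map$affine), code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Events TSV round trip
#'
#' BIDS-style events table with columns `onset`, `duration`, `trial_type`.
#'
#' @param paradigm a `paradigm`.
#' @param file TSV path.
#' @export
write_events_tsv <- function(paradigm, file) {
  df <- data.frame(onset = paradigm$onset, duration = paradigm$duration,
                   trial_type = paradigm$condition)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_events_tsv
#' @param tr,n_volumes run timing (not stored in the TSV).
#' @export
read_events_tsv <- function(file, tr, n_volumes) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  new_paradigm(
    data.frame(onset = df$onset, duration = df$duration,
               condition = df$trial_type, stringsAsFactors = FALSE),
    tr = tr, n_volumes = as.integer(n_volumes)
  )
}

#' Motion parameter text files
#'
#' Six-column whitespace-delimited text (3 translations mm, 3 rotations
#' rad), one row per volume.
#'
#' @param motion `T x 6` matrix.
#' @param file path.
#' @export
write_motion_txt <- function(motion, file) {
  utils::write.table(motion, file, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_motion_txt
#' @export
read_motion_txt <- function(file) {
  m <- as.matrix(utils::read.table(file))
  if (ncol(m) != 6L) stop("motion file must have 6 columns")
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Read an ROI TSV (label, x, y, z, radius)
#'
#' @param file TSV path with columns `label`, `x`, `y`, `z`, `radius`
#'   (`radius_mm` accepted).
#' @return a [roi_set()].
#' @export
read_roi_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if ("radius_mm" %in% names(df) && !"radius" %in% names(df)) {
    df$radius <- df$radius_mm
  }
  roi_set(df)
}

#' Write a cohort to disk
#'
#' One directory per subject with per-run 4D NIfTI, events TSV and motion
#' text, a shared mask volume, and a JSON manifest listing files, groups and
#' the master seed.
#'
#' @param cohort list of `subject_record`s.
#' @param dir output directory.
#' @param seed master seed recorded in the manifest.
#' @return manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_file <- file.path(dir, "mask.nii.gz")
  write_mask_nifti(cohort[[1]]$runs[[1]]$mask, cohort[[1]]$runs[[1]]$affine,
                   mask_file)
  manifest <- list(seed = seed, mask = basename(mask_file), subjects = list())
  for (subj in cohort) {
    sdir <- file.path(dir, subj$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    runs <- list()
    for (r in seq_along(subj$runs)) {
      bf <- file.path(sdir, sprintf("run%d_bold.nii.gz", r))
      ef <- file.path(sdir, sprintf("run%d_events.tsv", r))
      mf <- file.path(sdir, sprintf("run%d_motion.txt", r))
      write_bold_nifti(subj$runs[[r]], bf)
      write_events_tsv(subj$paradigms[[r]], ef)
      write_motion_txt(subj$motion[[r]], mf)
      runs[[r]] <- list(bold = basename(bf), events = basename(ef),
                        motion = basename(mf))
    }
    manifest$subjects[[subj$subject_id]] <- list(group = subj$group,
                                                 runs = runs)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Write the tables of a study report
#'
#' Emits `stats_table.tsv`, per-experiment CV results and stability TSVs,
#' and a machine-readable `report.json` summary.
#'
#' @param report a `study_report` from [run_full_study()].
#' @param dir output directory.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$stats_table, file.path(dir, "stats_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cv_summary <- list()
  for (nm in names(report$cv)) {
    res <- report$cv[[nm]]$results
    utils::write.table(res, file.path(dir, paste0("cv_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cv_summary[[nm]] <- res
  }
  json <- list(
    n_samples = nrow(report$samples),
    baseline_accuracy = report$baseline,
    stats_table = report$stats_table,
    cv = cv_summary,
    stability = report$stability,
    interhemispheric = report$distance$interhemispheric[
      c("mean_control", "mean_patient", "t", "p_two_sided",
        "p_control_greater")
    ]
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
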