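#' Spherical ROI set
#'
#' @param spec data frame with columns `label`, `x`, `y`, `z` (mm) and
#'   `radius` (mm, > 0). Readable from TSV via [read_roi_tsv()].
#' @return a `roi_set` (validated data frame).
#' @export
roi_set <- function(spec) {
  need <- c("label", "x", "y", "z", "radius")
  if (!all(need %in% names(spec))) {
    stop("ROI spec needs columns: ", paste(need, collapse = ", "))
  }
  if (any(spec$radius <= 0)) stop("ROI radii must be positive")
  if (anyDuplicated(spec$label)) stop("duplicate ROI labels")
  structure(as.data.frame(spec)[need], class = c("roi_set", "data.frame"))
}

# Masked-voxel rows within each ROI sphere (mm distance via the affine;
# boundary voxels at exactly the radius are included).
roi_voxel_sets <- function(bold, rois) {
  xyz <- voxel_coords_mm(bold)
  sets <- lapply(seq_len(nrow(rois)), function(i) {
    d2 <- (xyz[, 1] - rois$x[i])^2 + (xyz[, 2] - rois$y[i])^2 +
      (xyz[, 3] - rois$z[i])^2
    which(d2 <= rois$radius[i]^2)
  })
  names(sets) <- rois$label
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    stop("ROI contains no masked voxel: ",
         paste(rois$label[empty], collapse = ", "))
  }
  sets
}

#' Extract detrended ROI mean time series
#'
#' Per ROI: the spatial mean over masked voxels within the sphere, then
#' residualised against the cosine drift basis (below `drift_cutoff`) plus
#' an intercept. Detrending is an orthogonal projection and hence
#' idempotent.
#'
#' @param bold a [bold_run()].
#' @param rois a [roi_set()].
#' @param drift_cutoff drift cutoff frequency (Hz); default 1/128.
#' @return `R x T` matrix, rows named by ROI label.
#' @export
extract_roi_timeseries <- function(bold, rois, drift_cutoff = 1 / 128) {
  sets <- roi_voxel_sets(bold, rois)
  nt <- n_volumes(bold)
  basis <- cbind(1, dct_drift_basis(nt, bold$tr, drift_cutoff))
  qb <- qr(basis)
  out <- t(vapply(sets, function(v) {
    m <- colMeans(bold$series[v, , drop = FALSE])
    qr.resid(qb, m)
  }, numeric(nt)))
  rownames(out) <- names(sets)
  out
}

#' ROI-to-ROI Pearson correlation
#'
#' @param roi_ts `R x T` matrix from [extract_roi_timeseries()].
#' @return symmetric `R x R` correlation matrix with unit diagonal.
#' @export
roi_correlation <- function(roi_ts) {
  if (ncol(roi_ts) < 3L) stop("need T >= 3")
  sds <- apply(roi_ts, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant ROI series: ",
         paste(rownames(roi_ts)[sds == 0], collapse = ", "))
  }
  cc <- stats::cor(t(roi_ts))
  diag(cc) <- 1
  cc
}

# Pearson correlation with nonnegative observation weights summing to 1.
weighted_correlation <- function(x, y, w) {
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(0)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Psycho-physiological interaction contrast
#'
#' For every ROI pair, the Pearson correlation weighted by condition `cond_a`
#' minus the correlation weighted by `cond_b`. Weights are the HRF-convolved
#' condition regressor clipped at zero and renormalised to sum to one, so
#' epochs where a condition's expected response is strong dominate its
#' correlation estimate.
#'
#' @param roi_ts `R x T` matrix.
#' @param design a `design_matrix` containing both condition regressors.
#' @param cond_a,cond_b condition names (e.g. `"FrenchNative"`, `"Silence"`).
#' @return symmetric `R x R` matrix of PPI contrasts (zero diagonal).
#' @export
ppi_contrast <- function(roi_ts, design, cond_a, cond_b) {
  get_w <- function(cond) {
    idx <- design$condition_idx[[cond]]
    if (is.null(idx) || is.na(idx)) stop("condition not in design: ", cond)
    w <- pmax(design$values[, idx], 0)
    if (sum(w) == 0) stop("all-zero weight vector for condition ", cond)
    w / sum(w)
  }
  wa <- get_w(cond_a)
  wb <- get_w(cond_b)
  if (ncol(roi_ts) != length(wa)) stop("roi_ts and design have different T")
  R <- nrow(roi_ts)
  out <- matrix(0, R, R, dimnames = list(rownames(roi_ts), rownames(roi_ts)))
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (j <= i) next
      d <- weighted_correlation(roi_ts[i, ], roi_ts[j, ], wa) -
        weighted_correlation(roi_ts[i, ], roi_ts[j, ], wb)
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  out
}
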