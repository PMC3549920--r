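#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF: a response gamma density with shape 6 and
#' rate 1 (mode at 5 s) minus an undershoot gamma with shape 16 and rate 1,
#' weighted 1/6, the whole curve scaled to unit peak. Returns 0 at `t = 0`
#' and for negative `t`.
#'
#' @param t time in seconds (vectorised).
#' @return numeric vector of HRF values, peak value 1.
#' @export
canonical_hrf <- function(t) {
  raw <- function(x) {
    stats::dgamma(x, shape = 6, rate = 1) -
      stats::dgamma(x, shape = 16, rate = 1) / 6
  }
  # unit-peak scaling; the undershoot shifts the peak marginally off t = 5
  peak <- stats::optimize(raw, c(3, 7), maximum = TRUE)$objective
  ifelse(t < 0, 0, raw(t) / peak)
}

.CONDITIONS <- c("FrenchNative", "Foreign", "Silence")

# HRF-convolved condition indicator regressors, sampled at volume onsets
# t_k = (k-1) * TR after construction on a 0.1 s grid.
condition_regressors <- function(paradigm) {
  tr <- attr(paradigm, "tr")
  nt <- attr(paradigm, "n_volumes")
  dt <- 0.1
  grid <- seq(0, nt * tr, by = dt)
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  out <- matrix(0, nrow = nt, ncol = length(.CONDITIONS),
                dimnames = list(NULL, .CONDITIONS))
  vol_idx <- round(((seq_len(nt) - 1) * tr) / dt) + 1L
  for (cond in .CONDITIONS) {
    ev <- paradigm[paradigm$condition == cond, , drop = FALSE]
    s <- numeric(length(grid))
    for (e in seq_len(nrow(ev))) {
      s[grid >= ev$onset[e] & grid < ev$onset[e] + ev$duration[e]] <- 1
    }
    conv <- stats::convolve(s, rev(hrf), type = "open")[seq_along(grid)] * dt
    out[, cond] <- conv[vol_idx]
  }
  out
}

#' Discrete-cosine drift basis
#'
#' Unit-norm DCT-II basis over `n` scans covering the `k = 1..K` components
#' with frequency `k / (2 n tr)` up to the cutoff, `K = floor(2 n tr cutoff)`.
#'
#' @param n number of scans.
#' @param tr repetition time (s).
#' @param cutoff drift cutoff frequency (Hz), e.g. `1/128`.
#' @return `n x K` matrix (0 columns if no component qualifies).
#' @export
dct_drift_basis <- function(n, tr, cutoff) {
  stopifnot(cutoff > 0)
  K <- floor(2 * n * tr * cutoff)
  K <- min(K, n - 1L)
  t_idx <- seq_len(n) - 1L
  out <- matrix(0, nrow = n, ncol = K)
  for (k in seq_len(K)) {
    col <- cos(pi * k * (2 * t_idx + 1) / (2 * n))
    out[, k] <- col / sqrt(sum(col^2))
  }
  if (K > 0) colnames(out) <- paste0("drift_", seq_len(K))
  out
}

#' Build a GLM design matrix
#'
#' Columns: the three HRF-convolved condition regressors, the cosine drift
#' set below `drift_cutoff`, the six motion parameters (if supplied), and an
#' intercept of ones.
#'
#' @param paradigm a [generate_paradigm()] output (or any `paradigm`).
#' @param motion optional `T x 6` motion-parameter matrix.
#' @param drift_cutoff drift cutoff frequency (Hz); default 1/128.
#' @return a `design_matrix`: list with `values` (`T x R`), `names`,
#'   `condition_idx`, `drift_idx`, `motion_idx`, `intercept_idx`.
#' @export
build_design_matrix <- function(paradigm, motion = NULL, drift_cutoff = 1 / 128) {
  stopifnot(inherits(paradigm, "paradigm"), drift_cutoff > 0)
  nt <- attr(paradigm, "n_volumes")
  conds <- condition_regressors(paradigm)
  drift <- dct_drift_basis(nt, attr(paradigm, "tr"), drift_cutoff)
  cols <- list(conds, drift)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nt || ncol(motion) != 6L) {
      stop("motion must be a T x 6 matrix matching the paradigm's volumes")
    }
    colnames(motion) <- paste0("motion_", 1:6)
    cols <- c(cols, list(motion))
  }
  intercept <- matrix(1, nrow = nt, ncol = 1, dimnames = list(NULL, "intercept"))
  X <- do.call(cbind, c(cols, list(intercept)))
  if (ncol(X) >= nt) stop("design has as many columns as scans; reduce regressors")

  # all-zero condition columns are legitimate (a paradigm may lack a
  # condition); the collinearity check applies to the nonzero columns
  nonzero <- colSums(X != 0) > 0
  qrX <- qr(X[, nonzero, drop = FALSE])
  if (qrX$rank < sum(nonzero)) {
    bad <- colnames(X)[nonzero][qrX$pivot[seq(qrX$rank + 1L, sum(nonzero))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(
      values = X, names = colnames(X),
      condition_idx = stats::setNames(match(.CONDITIONS, colnames(X)), .CONDITIONS),
      drift_idx = which(startsWith(colnames(X), "drift_")),
      motion_idx = which(startsWith(colnames(X), "motion_")),
      intercept_idx = which(colnames(X) == "intercept")
    ),
    class = "design_matrix"
  )
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares of every masked voxel's series on the design.
#'
#' @param bold a [bold_run()].
#' @param design a [build_design_matrix()] output.
#' @return a `glm_fit`: `beta` (`V x R`), `residual_variance` (length V,
#'   RSS / dof), `dof`, `xtx_inv`, and the originating `mask`/`affine`.
#' @export
fit_glm <- function(bold, design) {
  X <- design$values
  Y <- t(bold$series) # T x V
  if (nrow(Y) != nrow(X)) stop("design and BOLD run have different T")
  bad <- which(!apply(Y, 2L, function(y) all(is.finite(y))))
  if (length(bad)) stop("non-finite series at masked voxel ", bad[1L])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, Y) # R x V
  res <- Y - X %*% beta
  dof <- nrow(X) - ncol(X)
  rss <- colSums(res^2)
  structure(
    list(
      beta = t(beta), residual_variance = rss / dof, dof = dof,
      xtx_inv = chol2inv(chol(crossprod(X))),
      regressors = colnames(X), mask = bold$mask, affine = bold$affine
    ),
    class = "glm_fit"
  )
}

#' The eight activation contrasts
#'
#' Named contrast vectors over the condition regressors: 1 FrenchNative -
#' Silence, 2 FrenchNative - Foreign, 3 Silence - FrenchNative, 4 Foreign -
#' FrenchNative, 5 Foreign - Silence, and 6--8 the single-condition
#' amplitudes FrenchNative, Foreign, Silence versus baseline (the condition
#' regressors already measure response above the modelled intercept).
#'
#' @param design a `design_matrix`.
#' @return named list of length-R contrast vectors.
#' @export
activation_contrasts <- function(design) {
  R <- ncol(design$values)
  unit <- function(cond) {
    v <- numeric(R)
    v[design$condition_idx[[cond]]] <- 1
    v
  }
  fn <- unit("FrenchNative"); fo <- unit("Foreign"); si <- unit("Silence")
  list(
    "1_FrenchNative-Silence" = fn - si,
    "2_FrenchNative-Foreign" = fn - fo,
    "3_Silence-FrenchNative" = si - fn,
    "4_Foreign-FrenchNative" = fo - fn,
    "5_Foreign-Silence" = fo - si,
    "6_FrenchNative" = fn,
    "7_Foreign" = fo,
    "8_Silence" = si
  )
}

#' Contrast t-map
#'
#' Per-voxel `t = c'beta / sqrt(sigma2 * c' (X'X)^-1 c)`. Voxels with zero
#' residual variance get signed infinity when the numerator is nonzero and 0
#' when both are zero.
#'
#' @param fit a [fit_glm()] result.
#' @param design the matching design.
#' @param contrast length-R numeric contrast vector (not all zero), or the
#'   name/index of one of the eight [activation_contrasts()].
#' @return a `feature_map` with `kind = "activation"` and the contrast name.
#' @export
contrast_tmap <- function(fit, design, contrast) {
  cons <- activation_contrasts(design)
  cname <- "custom"
  if (is.character(contrast) && length(contrast) == 1L && contrast %in% names(cons)) {
    cname <- contrast
    contrast <- cons[[contrast]]
  } else if (is.numeric(contrast) && length(contrast) == 1L) {
    cname <- names(cons)[contrast]
    contrast <- cons[[contrast]]
  }
  contrast <- as.numeric(contrast)
  if (length(contrast) != ncol(fit$beta)) stop("contrast length must equal R")
  if (all(contrast == 0)) stop("contrast must not be all zero")
  num <- drop(fit$beta %*% contrast)
  cvc <- drop(t(contrast) %*% fit$xtx_inv %*% contrast)
  se <- sqrt(fit$residual_variance * cvc)
  tval <- ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * Inf))
  feature_map(tval, kind = "activation", name = cname,
              mask = fit$mask, affine = fit$affine)
}

#' Per-voxel feature map container
#'
#' @param values numeric vector, one value per masked voxel.
#' @param kind feature kind label (e.g. `"degree_full"`, `"activation"`).
#' @param name optional sub-label (e.g. contrast name).
#' @param mask,affine optional geometry for export.
#' @param normalized has [normalize_map()] been applied?
#' @return object of class `feature_map`.
#' @export
feature_map <- function(values, kind, name = NULL, mask = NULL, affine = NULL,
                        normalized = FALSE) {
  structure(
    list(values = as.numeric(values), kind = kind, name = name,
         mask = mask, affine = affine, normalized = normalized),
    class = "feature_map"
  )
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %s%s, %d voxels%s\n", x$kind,
              if (is.null(x$name)) "" else paste0(" (", x$name, ")"),
              length(x$values), if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Spatially normalize a map
#'
#' Divides by the maximum absolute value over voxels, so values land in
#' `[-1, 1]` (for nonnegative maps this equals division by the maximum).
#' All-zero maps are returned unchanged. Non-finite sentinel values are
#' ignored when locating the maximum.
#'
#' @param map a `feature_map`.
#' @return the normalized `feature_map`.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "feature_map"))
  v <- map$values
  m <- max(abs(v[is.finite(v)]), na.rm = TRUE)
  if (is.finite(m) && m > 0) map$values <- v / m
  map$normalized <- TRUE
  map
}

#' Mean absolute t-value of a map
#'
#' The global "mean activation" feature: mean over masked voxels of the
#' absolute t statistic (non-finite sentinels excluded).
#'
#' @param map a `feature_map`.
#' @return scalar.
#' @export
mean_abs_t <- function(map) {
  v <- map$values
  v <- v[is.finite(v)]
  if (!length(v)) stop("map has no finite values")
  mean(abs(v))
}

#' All eight activation t-maps for one run
#'
#' @param bold a [bold_run()].
#' @param paradigm the run's paradigm.
#' @param motion optional `T x 6` motion matrix.
#' @param drift_cutoff drift cutoff (Hz).
#' @return named list of eight `feature_map`s.
#' @export
activation_maps <- function(bold, paradigm, motion = NULL,
                            drift_cutoff = 1 / 128) {
  design <- build_design_matrix(paradigm, motion, drift_cutoff)
  fit <- fit_glm(bold, design)
  maps <- lapply(names(activation_contrasts(design)), function(cn) {
    contrast_tmap(fit, design, cn)
  })
  names(maps) <- names(activation_contrasts(design))
  maps
}
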