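#' @title Synthetic two-group fMRI cohort
#'
#' @description
#' The cohort generator emulates the statistical structure this package's
#' analyses assume: two groups ("control" and "patient") whose task-evoked
#' activation statistics are identical by construction, but whose inter-voxel
#' coupling differs — specifically in long-range, inter-hemispheric
#' connections. Each masked voxel's signal is
#'
#' \deqn{y_v(t) = \mu_0 + a_v (s \ast h)(t) + \sum_f L_{v,f} z_f(t) +
#'   \sigma \varepsilon_v(t)}
#'
#' where `s` are the auditory-condition indicator trains convolved with the
#' canonical HRF `h`, `a_v` are per-voxel activation amplitudes drawn once
#' per subject from the *same* distribution in both groups, `z_f` are AR(1)
#' latent series shared by all voxels in a factor's spatial support (with
#' group-specific loadings `L`), and the noise is white Gaussian. The latent
#' series model ongoing processes independent of the stimulus and are
#' realized orthogonal to each run's task regressors, so the coupling they
#' induce is invisible to activation statistics by construction.
#'
#' In the default configuration the groups are variance-matched: controls
#' load on one *bilateral* latent factor over a temporal-lobe-like support,
#' patients load equally strongly on two *unilateral* factors over the same
#' support, so per-voxel variance and within-hemisphere coupling coincide
#' across groups and only the inter-hemispheric coupling differs.
#'
#' @name synthetic_cohort
NULL

#' Derive a child seed from a master seed
#'
#' One master seed, children mixed per (subject, run, component) with a
#' Lehmer-style hash so adding subjects never perturbs existing ones. All
#' arithmetic stays below 2^53 (exact in doubles) and the result is below
#' 2^31 - 1. Component codes used by the generator: 1 paradigm, 2 amplitude,
#' 3 latent series, 4 noise, 5 motion.
#'
#' @param master integer master seed.
#' @param ... integer codes (subject index, run, component).
#' @return an integer seed.
#' @export
derive_seed <- function(master, ...) {
  codes <- c(master, ...)
  m <- 2147483647 # 2^31 - 1
  h <- 11
  for (code in codes) {
    h <- (h * 48271 + (code %% m) + 1) %% m
  }
  as.integer(h)
}

# component codes for derive_seed
.SEED_PARADIGM <- 1L
.SEED_AMPLITUDE <- 2L
.SEED_LATENT <- 3L
.SEED_NOISE <- 4L
.SEED_MOTION <- 5L

#' Stationary unit-variance AR(1) series
#'
#' @param n length.
#' @param phi autoregressive coefficient in `[0, 1)`.
#' @return numeric vector drawn from the current RNG state.
#' @export
ar1_series <- function(n, phi) {
  stopifnot(n >= 1, phi >= 0, phi < 1)
  e <- stats::rnorm(n)
  z <- numeric(n)
  z[1L] <- e[1L]
  s <- sqrt(1 - phi^2)
  for (t in seq_len(n)[-1L]) z[t] <- phi * z[t - 1L] + s * e[t]
  z
}

#' Generate a balanced three-condition event paradigm
#'
#' Builds a randomized rapid event design with equal numbers of
#' `FrenchNative`, `Foreign` and `Silence` trials. Each trial is an attention
#' tone (0.2 s), a stimulus epoch (3.5 s; silent for `Silence` trials), a
#' 0.75 s pause, a 0.5 s probe cue, and a uniform 0.5--1.5 s inter-trial
#' jitter. The event onset/duration recorded is the stimulus epoch.
#'
#' @param seed integer seed; the condition order and jitters are deterministic
#'   given the seed.
#' @param n_per_condition trials per condition (96-trial run: 32).
#' @param tr repetition time (s).
#' @param n_volumes number of volumes in the run.
#' @return a `paradigm`: data frame with columns `onset`, `duration`,
#'   `condition` and attributes `tr`, `n_volumes`.
#' @export
generate_paradigm <- function(seed, n_per_condition = 32L, tr = 2.0,
                              n_volumes = 416L) {
  stopifnot(n_per_condition >= 1, tr > 0, n_volumes >= 1)
  tone <- 0.2; stim <- 3.5; pause <- 0.75; probe <- 0.5
  jit_min <- 0.5; jit_max <- 1.5
  n_trials <- 3L * as.integer(n_per_condition)
  run_len <- tr * n_volumes
  min_len <- n_trials * (tone + stim + pause + probe + jit_min)
  if (min_len > run_len) {
    stop(sprintf(
      "run too short for %d trials: need at least %.1f s, have %.1f s",
      n_trials, min_len, run_len
    ))
  }

  set.seed(seed)
  conds <- sample(rep(c("FrenchNative", "Foreign", "Silence"), n_per_condition))
  jitters <- stats::runif(n_trials, jit_min, jit_max)
  trial_len <- tone + stim + pause + probe + jitters
  if (sum(trial_len) > run_len) {
    # jitter draw overflowed the run; shrink jitters uniformly to fit
    slack <- run_len - n_trials * (tone + stim + pause + probe)
    jitters <- jitters * (slack / sum(jitters))
    trial_len <- tone + stim + pause + probe + jitters
  }
  starts <- cumsum(c(0, trial_len[-n_trials]))
  events <- data.frame(
    onset = starts + tone,
    duration = stim,
    condition = conds,
    stringsAsFactors = FALSE
  )
  new_paradigm(events, tr = tr, n_volumes = as.integer(n_volumes))
}

new_paradigm <- function(events, tr, n_volumes) {
  stopifnot(all(c("onset", "duration", "condition") %in% names(events)))
  if (is.unsorted(events$onset, strictly = TRUE)) {
    stop("event onsets must be strictly increasing")
  }
  if (any(events$onset + events$duration > tr * n_volumes + 1e-9)) {
    stop("an event extends past the end of the run")
  }
  counts <- table(events$condition)
  if (length(unique(as.integer(counts))) != 1L) {
    stop("condition counts must be equal across conditions")
  }
  structure(events,
    tr = tr, n_volumes = n_volumes,
    class = c("paradigm", "data.frame")
  )
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf(
    "<paradigm> %d events (%s), TR %.3g s, %d volumes\n",
    nrow(x), paste(names(table(x$condition)), table(x$condition),
      sep = ":", collapse = ", "
    ),
    attr(x, "tr"), attr(x, "n_volumes")
  ))
  invisible(x)
}

#' Generate nuisance motion traces
#'
#' Six AR(1) traces (3 translations in mm, 3 rotations in radians), generated
#' from a random stream independent of every BOLD component, as a realistic
#' regressor and confound-check input. Slow drift-like dynamics
#' (autocorrelation 0.95); translation scale 0.1 mm, rotation scale 0.002 rad.
#'
#' @param seed integer seed.
#' @param n_volumes number of time points (>= 2).
#' @return `n_volumes x 6` numeric matrix.
#' @export
generate_motion <- function(seed, n_volumes) {
  stopifnot(n_volumes >= 2)
  set.seed(seed)
  scales <- c(0.1, 0.1, 0.1, 0.002, 0.002, 0.002)
  out <- vapply(
    scales,
    function(s) s * ar1_series(n_volumes, 0.95),
    numeric(n_volumes)
  )
  colnames(out) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  out
}

#' Default two-lobed mask geometry
#'
#' A 16 x 16 x 12 grid with 10 mm isotropic voxels; two ellipsoidal
#' "hemisphere" lobes (semi-axes 38 x 72 x 52 mm, centres at x = -40 and
#' +40 mm) separated at x = 0. No voxel sits exactly on the midline.
#'
#' @return list with `mask` (3D logical), `affine` (4x4).
#' @export
default_geometry <- function() {
  dims <- c(16L, 16L, 12L)
  # mm coordinate of 1-based index i along each axis
  affine <- diag(c(10, 10, 10, 1))
  affine[1:3, 4] <- c(-85, -85, -65)
  ijk <- as.matrix(expand.grid(
    i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3])
  ))
  xyz <- cbind(ijk, 1) %*% t(affine)
  in_lobe <- function(cx) {
    ((xyz[, 1] - cx) / 38)^2 + (xyz[, 2] / 72)^2 + (xyz[, 3] / 52)^2 <= 1
  }
  mask <- array(in_lobe(-40) | in_lobe(40), dim = dims)
  list(mask = mask, affine = affine)
}

#' Masked-voxel rows within a sphere (mm space)
#'
#' @param mask 3D logical array.
#' @param affine 1-based voxel-to-mm affine.
#' @param center length-3 mm centre.
#' @param radius mm radius (boundary included).
#' @return integer vector of masked-voxel row indices.
#' @export
sphere_voxels <- function(mask, affine, center, radius) {
  xyz <- voxel_coords_mm(list(mask = mask, affine = affine))
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  which(d2 <= radius^2)
}

#' Latent factor specification
#'
#' @param support integer vector of masked-voxel row indices the factor loads
#'   on (must be nonempty).
#' @param loading_control,loading_patient group-specific loadings.
#' @param ar temporal autocorrelation of the factor series, in `[0, 1)`.
#' @param name optional label.
#' @return a list of class `latent_factor`.
#' @export
latent_factor <- function(support, loading_control, loading_patient,
                          ar = 0.3, name = NULL) {
  support <- as.integer(support)
  if (length(support) == 0L) stop("latent factor support must be nonempty")
  stopifnot(ar >= 0, ar < 1)
  structure(
    list(
      support = support, loading_control = loading_control,
      loading_patient = loading_patient, ar = ar, name = name
    ),
    class = "latent_factor"
  )
}

#' Cohort configuration
#'
#' Assembles the full generative configuration for [generate_cohort()]. With
#' all arguments at default this is the package's reference study condition:
#' 11 + 11 subjects, 2 runs each, TR 2 s, 200 volumes, a bilateral
#' "auditory" activation blob with identical amplitude statistics in both
#' groups, and a variance-matched latent-factor set in which only controls
#' carry bilateral (inter-hemispheric) coupling.
#'
#' `n_volumes = 416` with `n_per_condition = 32` reproduces the acquisition
#' scale of a full 96-trial run; the 200-volume default keeps the end-to-end
#' demonstration fast while leaving every analysis unchanged.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_volumes volumes per run.
#' @param tr repetition time (s).
#' @param n_per_condition paradigm trials per condition per run.
#' @param activation_amplitude mean activation amplitude `mu_a`; per-subject
#'   amplitudes are `Normal(mu_a, 0.1 mu_a)`, identically in both groups.
#' @param activation_region integer voxel rows forming the activation blob;
#'   `NULL` for the default bilateral 22 mm spheres at (+-45, -20, 5) mm.
#' @param factors list of [latent_factor()]s; `NULL` for the variance-matched
#'   default: over the bilateral "auditory" support, controls load on one
#'   bilateral factor and patients on two unilateral factors of equal
#'   loading; in addition both groups share per-hemisphere "background"
#'   factors over a larger disjoint support, whose coupled component sets
#'   each sample's maximum degree so that per-sample degree normalization
#'   preserves the group difference inside the bilateral support.
#' @param noise_sd white-noise standard deviation (> 0).
#' @param baseline baseline signal intensity.
#' @param seed master seed; every random stream derives from it.
#' @param geometry list with `mask` and `affine`; default [default_geometry()].
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 11L, n_volumes = 200L, tr = 2.0,
                          n_per_condition = 20L, activation_amplitude = 1.0,
                          activation_region = NULL, factors = NULL,
                          noise_sd = 1.0, baseline = 100, seed = 1L,
                          geometry = default_geometry()) {
  stopifnot(n_per_group >= 2, noise_sd > 0, n_volumes >= 2)
  mask <- geometry$mask
  affine <- geometry$affine

  left_blob <- sphere_voxels(mask, affine, c(-45, -20, 5), 22)
  right_blob <- sphere_voxels(mask, affine, c(45, -20, 5), 22)
  left_bg <- sphere_voxels(mask, affine, c(-40, 30, -5), 28)
  right_bg <- sphere_voxels(mask, affine, c(40, 30, -5), 28)
  if (is.null(activation_region)) {
    activation_region <- c(left_blob, right_blob)
  }
  if (is.null(factors)) {
    factors <- list(
      latent_factor(c(left_blob, right_blob), 2.0, 0.0, name = "bilateral"),
      latent_factor(left_blob, 0.0, 2.0, name = "left_local"),
      latent_factor(right_blob, 0.0, 2.0, name = "right_local"),
      latent_factor(left_bg, 2.0, 2.0, name = "left_background"),
      latent_factor(right_bg, 2.0, 2.0, name = "right_background")
    )
  }
  xyz <- voxel_coords_mm(list(mask = mask, affine = affine))
  has_bilateral_diff <- any(vapply(factors, function(f) {
    spans <- any(xyz[f$support, 1] < 0) && any(xyz[f$support, 1] > 0)
    spans && (f$loading_control != f$loading_patient)
  }, logical(1)))
  if (!has_bilateral_diff) {
    warning(
      "no latent factor spans both hemispheres with differing loadings; ",
      "the cohort carries no inter-hemispheric group difference"
    )
  }

  structure(
    list(
      n_per_group = as.integer(n_per_group),
      n_volumes = as.integer(n_volumes), tr = tr,
      n_per_condition = as.integer(n_per_condition),
      activation_amplitude = activation_amplitude,
      activation_region = as.integer(activation_region),
      factors = factors, noise_sd = noise_sd, baseline = baseline,
      seed = as.integer(seed), mask = mask, affine = affine,
      regions = list(
        auditory_left = left_blob, auditory_right = right_blob,
        background_left = left_bg, background_right = right_bg
      )
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic two-group cohort
#'
#' Simulates every subject and run under a [cohort_config()]. Deterministic
#' given `config$seed`: each (subject, run, component) draws from its own
#' derived child stream, so enlarging the cohort leaves existing subjects'
#' data untouched.
#'
#' @param config a [cohort_config()].
#' @return list of `subject_record`s, each with `subject_id`, `group`,
#'   `runs` (2 [bold_run()]s), `motion` (2 `T x 6` matrices), `paradigms`
#'   (2 [generate_paradigm()] outputs).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  for (f in config$factors) {
    if (length(f$support) == 0L) stop("latent factor with empty support")
  }
  n <- config$n_per_group
  ids <- c(sprintf("control%02d", seq_len(n)), sprintf("patient%02d", seq_len(n)))
  groups <- rep(c("control", "patient"), each = n)
  lapply(seq_along(ids), function(s) {
    generate_subject(config, subject_index = s, subject_id = ids[s],
                     group = groups[s])
  })
}

generate_subject <- function(config, subject_index, subject_id, group) {
  V <- sum(config$mask)
  nt <- config$n_volumes

  # per-voxel activation amplitudes, drawn once per subject (shared by both
  # runs), from the same distribution for both groups
  set.seed(derive_seed(config$seed, subject_index, 0L, .SEED_AMPLITUDE))
  mu_a <- config$activation_amplitude
  a_v <- numeric(V)
  a_v[config$activation_region] <- stats::rnorm(
    length(config$activation_region), mean = mu_a, sd = 0.1 * abs(mu_a)
  )

  runs <- vector("list", 2L)
  motion <- vector("list", 2L)
  paradigms <- vector("list", 2L)
  for (r in 1:2) {
    paradigms[[r]] <- generate_paradigm(
      derive_seed(config$seed, subject_index, r, .SEED_PARADIGM),
      n_per_condition = config$n_per_condition,
      tr = config$tr, n_volumes = nt
    )
    motion[[r]] <- generate_motion(
      derive_seed(config$seed, subject_index, r, .SEED_MOTION), nt
    )
    # task response: auditory conditions only
    regs <- condition_regressors(paradigms[[r]])
    task <- regs[, "FrenchNative"] + regs[, "Foreign"]
    # ongoing processes are stimulus-independent: realize each latent series
    # orthogonal to the run's full design subspace (conditions, drift,
    # motion, intercept) so the injected coupling leaves no trace in
    # activation statistics, only in inter-voxel correlation
    design_basis <- cbind(1, regs,
                          dct_drift_basis(nt, config$tr, 1 / 128),
                          motion[[r]])
    task_qr <- qr(design_basis)

    set.seed(derive_seed(config$seed, subject_index, r, .SEED_LATENT))
    signal <- matrix(config$baseline, nrow = V, ncol = nt)
    signal <- signal + a_v %o% task
    load_field <- if (group == "control") "loading_control" else "loading_patient"
    for (f in config$factors) {
      z <- ar1_series(nt, f$ar)
      z <- qr.resid(task_qr, z)
      z <- z / stats::sd(z)
      L <- f[[load_field]]
      if (L != 0) {
        signal[f$support, ] <- signal[f$support, ] + L * rep(z, each = length(f$support))
      }
    }
    set.seed(derive_seed(config$seed, subject_index, r, .SEED_NOISE))
    signal <- signal + config$noise_sd * matrix(stats::rnorm(V * nt), V, nt)

    runs[[r]] <- bold_run(signal, config$mask, config$affine, config$tr)
  }
  structure(
    list(
      subject_id = subject_id, group = group, runs = runs,
      motion = motion, paradigms = paradigms
    ),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(
    "<subject_record> %s (%s), %d runs of %d volumes\n",
    x$subject_id, x$group, length(x$runs), ncol(x$runs[[1]]$series)
  ))
  invisible(x)
}

#' Latent factor series of a configured cohort
#'
#' Reconstructs the raw AR(1) latent draws for a given subject/run (before
#' the generator's projection orthogonal to the task regressors); useful for
#' independence checks against other random streams.
#'
#' @param config a [cohort_config()].
#' @param subject_index subject position (1-based, controls first).
#' @param run run number (1 or 2).
#' @return `T x n_factors` matrix.
#' @export
latent_series <- function(config, subject_index, run) {
  set.seed(derive_seed(config$seed, subject_index, run, .SEED_LATENT))
  vapply(config$factors, function(f) ar1_series(config$n_volumes, f$ar),
    numeric(config$n_volumes)
  )
}
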