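#' Pairwise voxel correlation structure
#'
#' Pearson correlations between masked voxel time series, either as the full
#' symmetric `V x V` matrix or as a fixed sampled edge list. Voxels with
#' constant series get correlation 0 to all partners and are flagged.
#'
#' @param bold a [bold_run()] with `T >= 3`.
#' @param pairs optional fixed pair list from [sample_edges()] (2-column
#'   `i < j` matrix); when supplied, only those correlations are computed.
#' @param full_cap refuse the full form above this voxel count.
#' @return a `correlation_structure`: `full` (matrix or NULL), `sampled`
#'   (data frame `i, j, r` or NULL), `xyz_vox`, `xyz_mm`, `constant` flags,
#'   `n` voxels.
#' @export
pairwise_correlations <- function(bold, pairs = NULL, full_cap = 5000L) {
  series <- bold$series
  V <- nrow(series)
  if (ncol(series) < 3L) stop("need T >= 3 for correlations")
  sds <- apply(series, 1L, stats::sd)
  constant <- sds == 0

  if (is.null(pairs)) {
    if (V > full_cap) {
      stop("V = ", V, " exceeds the full-form cap (", full_cap,
           "); supply a sampled pair list")
    }
    cc <- suppressWarnings(stats::cor(t(series)))
    cc[constant, ] <- 0
    cc[, constant] <- 0
    diag(cc) <- 1
    new_correlation_structure(full = cc, sampled = NULL, bold = bold,
                              constant = constant)
  } else {
    pairs <- as.matrix(pairs)
    if (any(pairs < 1L) || any(pairs > V)) stop("pair index out of mask")
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
    z <- series - rowMeans(series)
    denom <- sqrt(rowSums(z^2))
    denom[denom == 0] <- 1
    z <- z / denom
    r <- rowSums(z[pairs[, 1], , drop = FALSE] * z[pairs[, 2], , drop = FALSE])
    r[constant[pairs[, 1]] | constant[pairs[, 2]]] <- 0
    sampled <- data.frame(i = pairs[, 1], j = pairs[, 2], r = r)
    new_correlation_structure(full = NULL, sampled = sampled, bold = bold,
                              constant = constant)
  }
}

new_correlation_structure <- function(full, sampled, bold, constant) {
  structure(
    list(
      full = full, sampled = sampled,
      xyz_vox = voxel_coords(bold$mask), xyz_mm = voxel_coords_mm(bold),
      constant = constant, n = sum(bold$mask)
    ),
    class = "correlation_structure"
  )
}

#' Construct a correlation structure from a matrix
#'
#' Mainly for crafted inputs: wraps an explicit symmetric correlation matrix
#' with voxel coordinates so graph construction can be exercised directly.
#'
#' @param full symmetric `V x V` matrix, unit diagonal, values in `[-1, 1]`.
#' @param xyz_vox `V x 3` voxel-index coordinates.
#' @param xyz_mm `V x 3` mm coordinates (default: `xyz_vox` treated as mm).
#' @return a `correlation_structure`.
#' @export
correlation_structure <- function(full, xyz_vox, xyz_mm = xyz_vox) {
  full <- as.matrix(full)
  stopifnot(nrow(full) == ncol(full), nrow(xyz_vox) == nrow(full))
  if (max(abs(full - t(full))) > 1e-12) stop("correlation matrix must be symmetric")
  if (any(abs(full) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  structure(
    list(full = full, sampled = NULL, xyz_vox = as.matrix(xyz_vox),
         xyz_mm = as.matrix(xyz_mm), constant = rep(FALSE, nrow(full)),
         n = nrow(full)),
    class = "correlation_structure"
  )
}

#' Sample a fixed random edge list
#'
#' Uniform sample without replacement of unordered voxel pairs. Studies reuse
#' the *same* list for every subject and run so that edge features are
#' comparable across samples.
#'
#' @param n_voxels number of voxels.
#' @param n_pairs number of pairs to draw (at most `choose(n_voxels, 2)`).
#' @param seed integer seed.
#' @return integer `n_pairs x 2` matrix with `i < j`, ordered as drawn.
#' @export
sample_edges <- function(n_voxels, n_pairs, seed) {
  n_voxels <- as.numeric(n_voxels)
  total <- n_voxels * (n_voxels - 1) / 2
  if (n_pairs > total) stop("cannot sample ", n_pairs, " pairs from ", total)
  set.seed(seed)
  lin <- sample(total, n_pairs) # 1-based linear indices into i<j pairs
  # invert the row-major pair ordering: pairs (i, i+1..n) for i = 1..n-1
  # cumulative count after finishing row i is i*n - i*(i+1)/2
  i <- ceiling(n_voxels - 0.5 - sqrt((n_voxels - 0.5)^2 - 2 * lin))
  repeat {
    before <- (i - 1) * n_voxels - (i - 1) * i / 2
    too_high <- before >= lin
    too_low <- lin > before + (n_voxels - i)
    if (!any(too_high) && !any(too_low)) break
    i[too_high] <- i[too_high] - 1L
    i[too_low] <- i[too_low] + 1L
  }
  j <- i + (lin - before)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Build a thresholded functional graph
#'
#' Includes edge `(i, j)` when `r_ij` strictly exceeds `threshold`
#' (`mode = "raw"`) or when `|r_ij|` does (`mode = "absolute"`). Hemisphere
#' labels follow the sign of the mm x-coordinate; `x = 0` voxels are
#' midline.
#'
#' @param corr full-form `correlation_structure`.
#' @param threshold correlation threshold in `[0, 1)`; default 0.7.
#' @param mode `"raw"` or `"absolute"`.
#' @return a `functional_graph`: `edges` (`E x 2`, `i < j`), `n`, `xyz_vox`,
#'   `xyz_mm`, `hemisphere` (`"left"/"right"/"midline"`), `threshold`,
#'   `mode`.
#' @export
build_graph <- function(corr, threshold = 0.7, mode = c("raw", "absolute")) {
  mode <- match.arg(mode)
  if (is.null(corr$full)) stop("graph construction needs the full correlation form")
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  cc <- corr$full
  vals <- if (mode == "absolute") abs(cc) else cc
  vals[lower.tri(vals, diag = TRUE)] <- -Inf
  idx <- which(vals > threshold, arr.ind = TRUE)
  edges <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  functional_graph(edges, n = corr$n, xyz_vox = corr$xyz_vox,
                   xyz_mm = corr$xyz_mm, threshold = threshold, mode = mode)
}

#' @rdname build_graph
#' @param edges integer `E x 2` matrix of voxel row pairs (`i < j`).
#' @param n number of voxels.
#' @param xyz_vox,xyz_mm `n x 3` coordinate matrices.
#' @export
functional_graph <- function(edges, n, xyz_vox, xyz_mm = xyz_vox,
                             threshold = NA_real_, mode = "raw") {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges[, 1] >= edges[, 2])) stop("edges must satisfy i < j")
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    if (anyDuplicated(edges)) stop("duplicate edges")
  }
  x <- xyz_mm[, 1]
  hemisphere <- ifelse(x < 0, "left", ifelse(x > 0, "right", "midline"))
  structure(
    list(edges = edges, n = as.integer(n), xyz_vox = as.matrix(xyz_vox),
         xyz_mm = as.matrix(xyz_mm), hemisphere = hemisphere,
         threshold = threshold, mode = mode),
    class = "functional_graph"
  )
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d voxels, %d edges (threshold %s, %s)\n",
              x$n, nrow(x$edges), format(x$threshold), x$mode))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, t(graph$edges))
  }
  g
}

edge_mm_lengths <- function(graph) {
  if (!nrow(graph$edges)) return(numeric(0))
  d <- graph$xyz_mm[graph$edges[, 1], , drop = FALSE] -
    graph$xyz_mm[graph$edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Degree feature maps
#'
#' Three per-voxel neighbour counts: full degree; long-distance degree
#' (neighbours at Euclidean distance `>= min_dist` in voxel-index units, the
#' "5 or more voxels apart" rule); inter-hemispheric degree (neighbours in
#' the opposite left/right hemisphere — midline endpoints never count).
#'
#' @param graph a `functional_graph`.
#' @param min_dist minimum separation for the long-distance map (default 5).
#' @param distance_space `"voxel"` (index units, default) or `"mm"`.
#' @return named list of three `feature_map`s: `degree_full`, `degree_long`,
#'   `degree_interhemi`.
#' @export
degree_maps <- function(graph, min_dist = 5, distance_space = c("voxel", "mm")) {
  distance_space <- match.arg(distance_space)
  e <- graph$edges
  count_map <- function(keep) {
    tabulate(c(e[keep, 1], e[keep, 2]), nbins = graph$n)
  }
  all_e <- rep(TRUE, nrow(e))
  coords <- if (distance_space == "voxel") graph$xyz_vox else graph$xyz_mm
  if (nrow(e)) {
    d <- coords[e[, 1], , drop = FALSE] - coords[e[, 2], , drop = FALSE]
    far <- sqrt(rowSums(d^2)) >= min_dist
    h1 <- graph$hemisphere[e[, 1]]
    h2 <- graph$hemisphere[e[, 2]]
    cross <- (h1 == "left" & h2 == "right") | (h1 == "right" & h2 == "left")
  } else {
    far <- cross <- logical(0)
  }
  list(
    degree_full = feature_map(count_map(all_e), "degree_full"),
    degree_long = feature_map(count_map(far), "degree_long"),
    degree_interhemi = feature_map(count_map(cross), "degree_interhemi")
  )
}

#' Strength feature maps
#'
#' Node strengths over the *unthresholded* correlation matrix used as a
#' weighted adjacency: signed sum, sum of absolute values, and sum of
#' positive values of each voxel's off-diagonal correlations.
#'
#' @param corr full-form `correlation_structure`.
#' @return named list of `feature_map`s: `strength`, `strength_abs`,
#'   `strength_pos`.
#' @export
strength_maps <- function(corr) {
  if (is.null(corr$full)) stop("strength needs the full correlation form")
  cc <- corr$full
  diag(cc) <- 0
  list(
    strength = feature_map(rowSums(cc), "strength"),
    strength_abs = feature_map(rowSums(abs(cc)), "strength_abs"),
    strength_pos = feature_map(rowSums(pmax(cc, 0)), "strength_pos")
  )
}

#' Clustering-coefficient map
#'
#' Fraction of links among each voxel's neighbours relative to all possible;
#' voxels of degree < 2 get 0. Conventionally computed on the
#' absolute-threshold graph.
#'
#' @param graph a `functional_graph`.
#' @return a `feature_map` with values in `[0, 1]`.
#' @export
clustering_map <- function(graph) {
  g <- as_igraph(graph)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  feature_map(cl, "clustering")
}

#' Local-efficiency map
#'
#' Per voxel: the global efficiency (mean over ordered node pairs of the
#' inverse shortest-path length, 0 for disconnected pairs) of the subgraph
#' induced by the voxel's neighbours. Neighbourhoods smaller than 2 get 0.
#'
#' @param graph a `functional_graph`.
#' @return a `feature_map` with values in `[0, 1]`.
#' @export
local_efficiency_map <- function(graph) {
  g <- as_igraph(graph)
  vals <- vapply(seq_len(graph$n), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    d <- igraph::distances(sub)
    inv <- 1 / d[upper.tri(d)] # 1/Inf = 0 for disconnected pairs
    inv[!is.finite(inv)] <- 0
    sum(inv) / length(inv)
  }, numeric(1))
  feature_map(vals, "local_efficiency")
}

#' Global network features
#'
#' The six whole-graph summaries: mean degree, mean geodesic distance
#' (averaged over *connected* ordered pairs only; `NA` for an edgeless
#' graph), mean clustering coefficient, giant-component size and ratio, and
#' total link count.
#'
#' @param graph a `functional_graph`.
#' @return named list of six scalars.
#' @export
global_features <- function(graph) {
  g <- as_igraph(graph)
  deg <- igraph::degree(g)
  total_links <- nrow(graph$edges)
  comp <- igraph::components(g)
  giant <- max(comp$csize)
  if (total_links > 0) {
    d <- igraph::distances(g)
    vals <- d[upper.tri(d)]
    finite <- vals[is.finite(vals)]
    mean_geo <- if (length(finite)) mean(finite) else NA_real_
  } else {
    mean_geo <- NA_real_
  }
  list(
    mean_degree = mean(deg),
    mean_geodesic = mean_geo,
    mean_clustering = mean(clustering_map(graph)$values),
    giant_component_size = giant,
    giant_component_ratio = giant / graph$n,
    total_links = total_links
  )
}

#' Link probability as a function of distance
#'
#' Bins all voxel pairs by Euclidean mm distance and reports, per occupied
#' bin, the fraction of pairs that are linked. The per-bin `sd` is the
#' binomial standard deviation of that fraction.
#'
#' @param graph a `functional_graph` with >= 2 voxels.
#' @param bin_width bin width in mm (default 5, bins starting at 0).
#' @return a `distance_profile` data frame: `center`, `probability`, `sd`,
#'   `n_pairs`, `n_links`.
#' @export
link_probability_by_distance <- function(graph, bin_width = 5) {
  if (graph$n < 2L) stop("need at least 2 voxels")
  dd <- as.vector(stats::dist(graph$xyz_mm))
  bin <- floor(dd / bin_width)
  all_tab <- table(bin)
  link_bin <- floor(edge_mm_lengths(graph) / bin_width)
  link_tab <- table(factor(link_bin, levels = names(all_tab)))
  n_pairs <- as.integer(all_tab)
  n_links <- as.integer(link_tab)
  p <- n_links / n_pairs
  out <- data.frame(
    center = (as.integer(names(all_tab)) + 0.5) * bin_width,
    probability = p,
    sd = sqrt(pmax(p * (1 - p), 0) / n_pairs),
    n_pairs = n_pairs, n_links = n_links
  )
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Power-law fit to a distance profile
#'
#' Least-squares fit of `log p = log a - gamma * log d` over bins with
#' positive probability whose centres fall in `[d_min, d_max]`.
#'
#' @param profile a `distance_profile` (or data frame with `center`,
#'   `probability`).
#' @param d_min,d_max fit range in mm.
#' @return list with `a`, `gamma`, `d_min`, `d_max`, `n_bins`.
#' @export
fit_power_law <- function(profile, d_min = 10, d_max = 150) {
  keep <- profile$probability > 0 & profile$center >= d_min &
    profile$center <= d_max
  if (sum(keep) < 3L) stop("need at least 3 positive bins inside the fit range")
  x <- log(profile$center[keep])
  y <- log(profile$probability[keep])
  fit <- stats::lm(y ~ x)
  list(
    a = exp(unname(stats::coef(fit)[1])),
    gamma = -unname(stats::coef(fit)[2]),
    d_min = d_min, d_max = d_max, n_bins = sum(keep)
  )
}

#' Inter-hemispheric link fraction
#'
#' Number of left--right links divided by the total link count. Links with a
#' midline endpoint count in the denominator only.
#'
#' @param graph a `functional_graph` with at least one link.
#' @return scalar in `[0, 1]`.
#' @export
interhemispheric_fraction <- function(graph) {
  e <- graph$edges
  if (!nrow(e)) stop("graph has no links")
  h1 <- graph$hemisphere[e[, 1]]
  h2 <- graph$hemisphere[e[, 2]]
  cross <- (h1 == "left" & h2 == "right") | (h1 == "right" & h2 == "left")
  sum(cross) / nrow(e)
}

#' ROI-pair link fraction
#'
#' Fraction of all links with one endpoint in `roi_a` and the other in
#' `roi_b` (disjoint voxel sets).
#'
#' @param graph a `functional_graph` with at least one link.
#' @param roi_a,roi_b integer vectors of voxel rows.
#' @return scalar in `[0, 1]`.
#' @export
roi_pair_link_fraction <- function(graph, roi_a, roi_b) {
  if (length(intersect(roi_a, roi_b))) stop("ROIs must be disjoint")
  e <- graph$edges
  if (!nrow(e)) stop("graph has no links")
  ab <- (e[, 1] %in% roi_a & e[, 2] %in% roi_b) |
    (e[, 1] %in% roi_b & e[, 2] %in% roi_a)
  sum(ab) / nrow(e)
}
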