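# Independent brute-force oracles used to check the package's graph,
# regression and solver code. These deliberately share no code with the
# implementation: adjacency matrices, triple loops and Floyd-Warshall only.

adjacency_from_graph <- function(graph) {
  A <- matrix(0L, graph$n, graph$n)
  if (nrow(graph$edges)) {
    A[graph$edges] <- 1L
    A[graph$edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  A
}

# all-pairs shortest path lengths by Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

oracle_degree <- function(A) rowSums(A)

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) return(0)
    D <- oracle_distances(A[nb, nb, drop = FALSE])
    inv <- 1 / D[upper.tri(D)]
    inv[!is.finite(inv)] <- 0
    sum(inv) / length(inv)
  }, numeric(1))
}

oracle_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] == 1))))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

oracle_global <- function(A) {
  D <- oracle_distances(A)
  vals <- D[upper.tri(D)]
  finite <- vals[is.finite(vals) & vals > 0]
  comp <- oracle_components(A)
  list(
    mean_degree = mean(rowSums(A)),
    mean_geodesic = if (length(finite)) mean(finite) else NA_real_,
    mean_clustering = mean(oracle_clustering(A)),
    giant_component_size = max(table(comp)),
    giant_component_ratio = max(table(comp)) / nrow(A),
    total_links = sum(A) / 2
  )
}

# a random functional_graph with random 3D coordinates spanning x = 0
random_test_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p_edge)
  edges <- which(A == 1, arr.ind = TRUE)
  xyz <- cbind(stats::runif(n, -50, 50), stats::runif(n, -50, 50),
               stats::runif(n, -30, 30))
  functional_graph(edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
                   n = n, xyz_vox = xyz / 10, xyz_mm = xyz)
}

# explicit Benjamini-Hochberg step-up, written from the definition
oracle_bh_mask <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(n) * alpha / n)
  if (!length(below)) return(rep(FALSE, n))
  cutoff <- ps[max(below)]
  p <= cutoff
}

oracle_bonferroni_mask <- function(p, alpha) p <= alpha / length(p)

# ADMM solver for the l1-penalised inverse-covariance problem; an
# independent algorithm family from the package's proximal-gradient solver.
admm_sparse_precision <- function(S, lambda, penalize_diag = TRUE,
                                  rho = 1, iters = 2000L) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  for (i in seq_len(iters)) {
    eg <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (eg$values + sqrt(eg$values^2 + 4 * rho)) / (2 * rho)
    C <- eg$vectors %*% (d * t(eg$vectors))
    M <- C + U
    Znew <- sign(M) * pmax(abs(M) - lambda / rho, 0)
    if (!penalize_diag) diag(Znew) <- diag(M)
    U <- U + C - Znew
    if (max(abs(Znew - Z)) < 1e-10 && max(abs(C - Znew)) < 1e-10) {
      Z <- Znew
      break
    }
    Z <- Znew
  }
  (Z + t(Z)) / 2
}

glasso_objective <- function(C, S, lambda, penalize_diag = TRUE) {
  pen <- if (penalize_diag) sum(abs(C)) else sum(abs(C)) - sum(abs(diag(C)))
  -determinant(C, logarithm = TRUE)$modulus[1] + sum(S * C) + lambda * pen
}

# closed-form OLS through the normal equations
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
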