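#' Z-score a feature matrix
#'
#' Mean-centres and scales each column to unit variance. Constant columns
#' carry no ordering information and are dropped with a warning.
#'
#' @param x Numeric matrix or data frame of features (rows = patients).
#' @return Matrix of z-scores with attributes `center`, `scale` and
#'   `dropped` (names of constant columns).
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 rows to standardize")
  sds <- apply(x, 2, sd)
  bad <- sds < 1e-12 | !is.finite(sds)
  if (all(bad))
    stop("all feature columns are constant; nothing to embed")
  dropped <- if (is.null(colnames(x))) paste0("V", which(bad)) else colnames(x)[bad]
  if (any(bad))
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
  z <- scale(x[, !bad, drop = FALSE])
  out <- z[, , drop = FALSE]
  attr(out, "center") <- attr(z, "scaled:center")
  attr(out, "scale") <- attr(z, "scaled:scale")
  attr(out, "dropped") <- dropped
  out
}

#' Build the diffusion Markov operator
#'
#' Constructs a locally-scaled affinity on the union k-nearest-neighbour
#' graph: per-point scale \eqn{\sigma_i} is half the Euclidean distance to
#' the k-th neighbour, affinity
#' \eqn{W_{ij} = \exp(-d_{ij}^2 / (\sigma_i^2 + \sigma_j^2))} for neighbour
#' pairs (zero diagonal), optionally multiplied by the dimension-dependent
#' prefactor \eqn{(2\sigma_i\sigma_j/(\sigma_i^2+\sigma_j^2))^{p/2}} of some
#' locally-scaled kernels. Density is removed by the anisotropic
#' \eqn{\alpha = 1} normalization (division by the product of row sums)
#' before row-normalizing to a Markov operator.
#'
#' @param X Standardized matrix (rows = patients).
#' @param k Neighbourhood size, `1 <= k < n`.
#' @param prefactor Include the dimension-dependent kernel prefactor?
#' @param on_disconnected `"error"` (default) or `"largest"` to restrict to
#'   the largest connected component.
#' @return List of class `diffusion_operator`: `P` (row-stochastic matrix),
#'   `W`, `sigma`, `k`, `connected`, `keep` (row indices retained).
#' @export
build_diffusion_operator <- function(X, k = 20, prefactor = FALSE,
                                     on_disconnected = c("error", "largest")) {
  on_disconnected <- match.arg(on_disconnected)
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n (n = ", n, ")")
  d <- as.matrix(dist(X))
  # k-th neighbour distance per point (row includes self at distance 0)
  kth <- apply(d, 1, function(r) sort(r)[k + 1])
  sigma <- kth / 2
  sigma[sigma < 1e-12] <- 1e-12  # duplicated points
  nn <- apply(d, 1, function(r) order(r)[2:(k + 1)])  # k nearest, excl. self
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) A[i, nn[, i]] <- TRUE
  A <- A | t(A)  # union-kNN symmetrization
  diag(A) <- FALSE

  s2 <- outer(sigma^2, sigma^2, "+")
  W <- exp(-d^2 / s2)
  if (prefactor) {
    p <- ncol(X)
    W <- W * (2 * outer(sigma, sigma) / s2)^(p / 2)
  }
  W[!A] <- 0
  diag(W) <- 0

  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
  keep <- seq_len(n)
  connected <- comp$no == 1
  if (!connected) {
    if (on_disconnected == "error")
      stop("kNN graph is disconnected (", comp$no,
           " components); increase k or use on_disconnected = \"largest\"")
    keep <- which(comp$membership == which.max(comp$csize))
    W <- W[keep, keep, drop = FALSE]
    sigma <- sigma[keep]
  }

  q <- rowSums(W)
  W1 <- W / outer(q, q)          # alpha = 1 density normalization
  D <- rowSums(W1)
  P <- W1 / D
  structure(list(P = P, W = W1, sigma = sigma, k = k, connected = connected,
                 keep = keep, D = D), class = "diffusion_operator")
}

#' Eigendecompose the diffusion operator
#'
#' Solves the operator through its symmetric conjugate
#' \eqn{S = D^{1/2} P D^{-1/2}}, which shares eigenvalues with P; right
#' eigenvectors are recovered as \eqn{\psi = D^{-1/2}\phi}. The trivial pair
#' (eigenvalue 1, constant eigenvector) is excluded from the reported
#' components; DC1 is the eigenvector of the largest non-trivial eigenvalue.
#' Component signs are fixed deterministically (largest-magnitude entry
#' positive) but remain arbitrary by contract: downstream consumers must be
#' invariant to a global sign flip.
#'
#' @param op A `diffusion_operator`.
#' @param n_components Number of non-trivial components to return.
#' @return List of class `diffusion_embedding`: `eigenvalues` (descending,
#'   starting at the first non-trivial), `components` (n x m matrix, DC1,
#'   DC2, ...), `sigma`, `k`, `connected`, `keep`.
#' @export
diffusion_components <- function(op, n_components = 5) {
  stopifnot(inherits(op, "diffusion_operator"))
  n <- nrow(op$P)
  n_components <- min(n_components, n - 1)
  Dh <- sqrt(op$D)
  S <- op$W / outer(Dh, Dh)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  if (any(!is.finite(eig$values)))
    stop("defective eigendecomposition of the diffusion operator")
  # right eigenvectors of P
  psi <- eig$vectors / Dh
  # normalize and fix signs deterministically
  psi <- apply(psi, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  vals <- eig$values
  comps <- psi[, 2:(n_components + 1), drop = FALSE]
  colnames(comps) <- paste0("DC", seq_len(ncol(comps)))
  structure(list(eigenvalues = vals[2:(n_components + 1)],
                 trivial_eigenvalue = vals[1],
                 components = comps, sigma = op$sigma, k = op$k,
                 connected = op$connected, keep = op$keep),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat("Diffusion embedding: k =", x$k, "|",
      ncol(x$components), "components\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}
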