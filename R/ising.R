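#' Ising model with fields
#'
#' Parameters of a pairwise binary Markov network with energy
#' `U(x) = -(sum_i r_i x_i + sum_{i<j} w_ij x_i x_j)` over states
#' `x in {0,1}^n`. The probability of a configuration is proportional to
#' `exp(-beta * U(x))`; `beta` acts as an inverse-temperature multiplier
#' (pass `1/beta` to obtain the `exp(-U/beta)` convention instead).
#'
#' @param r numeric vector of field coefficients, length n.
#' @param W symmetric numeric n x n coupling matrix with zero diagonal;
#'   `W[i, j]` is the preference of nodes i and j to be in the same state.
#' @param beta positive scalar temperature parameter.
#' @return An object of class `ising_params`.
#' @export
ising_params <- function(r, W, beta = 1) {
  r <- as.numeric(r)
  W <- as.matrix(W)
  n <- length(r)
  if (!all(dim(W) == c(n, n))) stop("W must be ", n, " x ", n)
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a positive scalar")
  structure(list(r = r, W = W, beta = beta, n = n), class = "ising_params")
}

#' Ising energy of a configuration
#'
#' `U = -(sum_i r_i x_i + sum_{i<j} w_ij x_i x_j)`, each unordered pair
#' counted once (equivalently `-(r'x + x'Wx/2)` for symmetric `W`). Note the
#' temperature enters the distribution, not the energy.
#'
#' @param x binary vector of length `params$n`.
#' @param params an [ising_params()] object.
#' @return scalar energy.
#' @export
ising_energy <- function(x, params) {
  stopifnot(inherits(params, "ising_params"))
  x <- as.numeric(x)
  if (length(x) != params$n)
    stop("x has length ", length(x), ", expected ", params$n)
  if (!all(x == 0 | x == 1)) stop("x must be binary")
  -(sum(params$r * x) + 0.5 * drop(x %*% params$W %*% x))
}

#' Exact Ising distribution by enumeration
#'
#' Enumerates all `2^n` configurations and returns the normalized Gibbs
#' distribution `P(x) = exp(-beta * U(x)) / Z`. This is an oracle for testing
#' samplers and learners, not a sampler itself, so it refuses models with
#' more than 20 nodes.
#'
#' @param params an [ising_params()] object with `params$n <= 20`.
#' @return list with `states` (2^n x n binary matrix), `energy`, `prob`
#'   (normalized probabilities), and the partition function `Z`.
#' @export
ising_exact_distribution <- function(params) {
  stopifnot(inherits(params, "ising_params"))
  n <- params$n
  if (n > 20L)
    stop("exact enumeration is limited to 20 nodes (got ", n, ")")
  states <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- NULL
  U <- -(drop(states %*% params$r) +
           0.5 * rowSums((states %*% params$W) * states))
  w <- exp(-params$beta * U)
  Z <- sum(w)
  list(states = states, energy = U, prob = w / Z, Z = Z)
}

#' Gaussian Markov network parameters
#'
#' Mean and covariance of a multivariate normal viewed as a Markov network:
#' nodes i and j are adjacent exactly when the (i, j) entry of the precision
#' matrix `solve(sigma)` is nonzero. Helper accessors expose the precision and
#' the graph implied by it.
#'
#' @param mu numeric mean vector.
#' @param sigma symmetric positive-definite covariance matrix.
#' @param node_labels optional node names (default `V1..Vn`).
#' @return An object of class `gmn_params`.
#' @export
gaussian_mn_params <- function(mu, sigma, node_labels = NULL) {
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  n <- length(mu)
  if (!all(dim(sigma) == c(n, n))) stop("sigma must be ", n, " x ", n)
  if (max(abs(sigma - t(sigma))) > 1e-10) stop("sigma must be symmetric")
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("sigma must be positive definite")
  if (is.null(node_labels)) node_labels <- paste0("V", seq_len(n))
  node_labels <- as.character(node_labels)
  if (length(node_labels) != n || anyDuplicated(node_labels))
    stop("node_labels must be ", n, " unique labels")
  structure(list(mu = mu, sigma = sigma, node_labels = node_labels, n = n),
            class = "gmn_params")
}

#' Precision matrix of a Gaussian Markov network
#' @param params a [gaussian_mn_params()] object.
#' @return the precision matrix `solve(params$sigma)`.
#' @export
gmn_precision <- function(params) {
  stopifnot(inherits(params, "gmn_params"))
  K <- solve(params$sigma)
  dimnames(K) <- list(params$node_labels, params$node_labels)
  K
}

#' Conditional-independence graph of a Gaussian Markov network
#'
#' Edge (i, j) is present when `|precision[i, j]|` exceeds `tol` times the
#' largest absolute off-diagonal precision entry, which screens out entries
#' that are zero up to numerical inversion error.
#'
#' @param params a [gaussian_mn_params()] object.
#' @param tol relative tolerance for declaring a precision entry nonzero.
#' @return a [microcircuit()].
#' @export
gmn_structure <- function(params, tol = 1e-8) {
  K <- gmn_precision(params)
  off <- abs(K)
  diag(off) <- 0
  thr <- tol * max(off)
  A <- off > thr
  diag(A) <- FALSE
  microcircuit(params$node_labels, A | t(A))
}
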