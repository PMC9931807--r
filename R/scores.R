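#' Score configuration for Markov blanket search
#'
#' Bundles the family-score settings used by [find_markov_blanket()] and the
#' node-wise learner: the score family (BDeu for binary data, BIC for
#' continuous), the BDeu equivalent sample size, an optional cap on the
#' number of parents, and the variance floor guarding degenerate Gaussian
#' fits.
#'
#' @param score_type `"bdeu"` or `"bic"`.
#' @param ess positive BDeu equivalent sample size (ignored by BIC).
#' @param max_parents maximum blanket size explored by the search
#'   (default unlimited).
#' @param variance_floor lower bound for the residual variance in BIC fits.
#' @param eps minimum score improvement for a hill-climbing move to be
#'   accepted (floating-point guard).
#' @return An object of class `score_config`.
#' @export
score_config <- function(score_type = c("bdeu", "bic"), ess = 1,
                         max_parents = Inf, variance_floor = 1e-12,
                         eps = 1e-9) {
  score_type <- match.arg(score_type)
  if (!is.numeric(ess) || ess <= 0) stop("ess must be positive")
  if (max_parents < 0) stop("max_parents must be >= 0")
  if (variance_floor <= 0) stop("variance_floor must be positive")
  structure(list(score_type = score_type, ess = ess,
                 max_parents = max_parents,
                 variance_floor = variance_floor, eps = eps),
            class = "score_config")
}

.pow2 <- function(k) 2^(seq_len(k) - 1)

# Log marginal likelihood of a binary child given binary parent columns,
# Dirichlet hyperparameters ess/(2q) per cell, ess/q per parent configuration,
# q = 2^k. Unobserved configurations contribute exactly zero.
.bdeu_score <- function(y, Xp, ess) {
  n <- length(y)
  k <- if (is.null(Xp)) 0L else ncol(Xp)
  q <- 2^k
  a_j <- ess / q
  a_jk <- ess / (2 * q)
  if (k == 0L) {
    n1 <- sum(y)
    n0 <- n - n1
    return(lgamma(a_j) - lgamma(a_j + n) +
             lgamma(a_jk + n1) - lgamma(a_jk) +
             lgamma(a_jk + n0) - lgamma(a_jk))
  }
  if (q <= 2^20) {
    idx <- as.integer(Xp %*% .pow2(k))
    cnt <- tabulate(2L * idx + y + 1L, nbins = 2L * q)
    odd <- seq(1L, 2L * q, by = 2L)
    n0 <- cnt[odd]
    n1 <- cnt[odd + 1L]
    obs <- which(n0 + n1 > 0L)
    n0 <- n0[obs]; n1 <- n1[obs]
  } else {
    key <- drop(Xp %*% .pow2(k))
    n1 <- rowsum(as.numeric(y), key)[, 1L]
    tot <- rowsum(rep(1, n), key)[, 1L]
    n0 <- tot - n1
  }
  sum(lgamma(a_j) - lgamma(a_j + n0 + n1) +
        lgamma(a_jk + n1) - lgamma(a_jk) +
        lgamma(a_jk + n0) - lgamma(a_jk))
}

#' BDeu family score
#'
#' Log marginal likelihood of a binary child variable given a set of binary
#' parent columns under a Dirichlet prior with total equivalent sample size
#' `ess` spread uniformly over the `2^k` parent configurations and 2 child
#' states. Higher is better. The score is decomposable and satisfies
#' likelihood equivalence.
#'
#' @param child binary vector of child observations.
#' @param parents binary matrix with one column per parent (or NULL for no
#'   parents), rows aligned with `child`.
#' @param ess positive equivalent sample size.
#' @return scalar log score.
#' @export
bdeu_family_score <- function(child, parents = NULL, ess = 1) {
  child <- as.numeric(child)
  if (!all(child == 0 | child == 1)) stop("child must be binary")
  if (!is.null(parents)) {
    parents <- as.matrix(parents)
    if (ncol(parents) == 0L) parents <- NULL
  }
  if (!is.null(parents)) {
    if (nrow(parents) != length(child))
      stop("parents must have one row per child observation")
    if (!all(parents == 0 | parents == 1)) stop("parents must be binary")
  }
  if (ess <= 0) stop("ess must be positive")
  .bdeu_score(as.integer(child), parents, ess)
}

# Maximized Gaussian log-likelihood of y on an intercept plus columns Xp,
# minus (k/2) log n with k = n_parents + 2 (coefficients, intercept, variance).
# Collinear columns are dropped via the QR rank and reported.
.bic_score <- function(y, Xp, variance_floor) {
  n <- length(y)
  Z <- if (is.null(Xp)) matrix(1, n, 1) else cbind(1, Xp)
  dec <- qr(Z)
  res <- qr.resid(dec, y)
  sigma2 <- max(sum(res^2) / n, variance_floor)
  kpar <- (dec$rank - 1L) + 2L
  ll <- -0.5 * n * log(2 * pi * sigma2) - 0.5 * sum(res^2) / sigma2
  list(score = ll - 0.5 * kpar * log(n),
       dropped = ncol(Z) - dec$rank)
}

#' BIC family score for a linear-Gaussian child
#'
#' Maximized log-likelihood of `child` regressed linearly on `parents`
#' (ML residual variance, floored at `variance_floor`) penalized by
#' `(k/2) log(n)` with `k = n_parents + 2`. Higher is better. Collinear parent
#' columns are dropped with a warning and do not count towards `k`.
#'
#' @param child numeric child vector.
#' @param parents numeric matrix of parent columns (or NULL).
#' @param variance_floor small positive lower bound for the residual variance.
#' @return scalar score.
#' @export
bic_family_score <- function(child, parents = NULL, variance_floor = 1e-12) {
  child <- as.numeric(child)
  if (!is.null(parents)) {
    parents <- as.matrix(parents)
    if (ncol(parents) == 0L) parents <- NULL
  }
  if (!is.null(parents) && nrow(parents) != length(child))
    stop("parents must have one row per child observation")
  np <- if (is.null(parents)) 0L else ncol(parents)
  if (length(child) <= np + 2L)
    stop("need n_samples > n_parents + 2")
  out <- .bic_score(child, parents, variance_floor)
  if (out$dropped > 0L)
    warning(out$dropped, " collinear parent column(s) dropped from the fit")
  out$score
}
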