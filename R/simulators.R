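#' The benchmark 6-node Ising microcircuit
#'
#' Returns the 6-node Ising model used throughout the package's simulation
#' benchmarks: zero fields, temperature `beta = 2`, and couplings
#' `w12 = w14 = w23 = w34 = 0.5`, `w45 = -0.8`, `w56 = 0.9`, together with
#' the 6-edge ground-truth graph implied by the nonzero couplings (nodes
#' labelled `N1..N6`; 9 of the 15 node pairs are empty).
#'
#' @return list with `params` ([ising_params()]) and `graph`
#'   ([microcircuit()]).
#' @export
six_node_model <- function() {
  W <- matrix(0, 6, 6)
  couplings <- rbind(c(1, 2, 0.5), c(1, 4, 0.5), c(2, 3, 0.5),
                     c(3, 4, 0.5), c(4, 5, -0.8), c(5, 6, 0.9))
  for (k in seq_len(nrow(couplings))) {
    i <- couplings[k, 1]; j <- couplings[k, 2]
    W[i, j] <- W[j, i] <- couplings[k, 3]
  }
  labels <- paste0("N", 1:6)
  list(params = ising_params(r = rep(0, 6), W = W, beta = 2),
       graph = microcircuit(labels, W != 0))
}

#' Sample from an Ising model by Metropolis-Hastings
#'
#' Single-site flip proposals with acceptance `min(1, exp(-beta * dU))`. One
#' sweep proposes `n` flips at uniformly chosen sites; after `burn_in` sweeps
#' a configuration is recorded every `thin` sweeps. The chain starts from an
#' independent fair-coin configuration. Deterministic given `seed`.
#'
#' @param params an [ising_params()].
#' @param n_samples number of configurations to keep.
#' @param burn_in warm-up sweeps discarded before recording.
#' @param thin sweeps between recorded configurations.
#' @param seed optional integer seed.
#' @param node_labels labels for the sampled columns (default `N1..Nn`,
#'   matching [six_node_model()]).
#' @return a binary-mode [data_matrix()] with `n_samples` rows.
#' @export
sample_ising_mh <- function(params, n_samples, burn_in = 5000, thin = 10,
                            seed = NULL, node_labels = NULL) {
  stopifnot(inherits(params, "ising_params"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(node_labels)) node_labels <- paste0("N", seq_len(params$n))
  x0 <- rbinom(params$n, 1, 0.5)
  m <- mh_sample_cpp(as.integer(x0), params$r, params$W, params$beta,
                     as.integer(n_samples), as.integer(burn_in),
                     as.integer(thin))
  data_matrix(m, mode = "binary", node_labels = node_labels)
}

#' Random feed-forward wiring from group A to group B
#'
#' Each group-B neuron is assigned `parents_per_B` distinct group-A parents
#' drawn uniformly at random, the anatomical substrate whose shared inputs
#' define the ground-truth coherence graph of the biophysical simulation.
#'
#' @param n_A,n_B population sizes.
#' @param parents_per_B parents per B neuron (must not exceed `n_A`).
#' @return integer matrix `n_B x parents_per_B` of A indices; row names are
#'   the B labels `B1..Bn_B`, attribute `"A_labels"` carries `A1..An_A`.
#' @export
random_wiring <- function(n_A, n_B, parents_per_B = 2) {
  if (parents_per_B > n_A) stop("parents_per_B cannot exceed n_A")
  w <- t(vapply(seq_len(n_B),
                function(i) sort(sample.int(n_A, parents_per_B)),
                integer(parents_per_B)))
  rownames(w) <- paste0("B", seq_len(n_B))
  attr(w, "A_labels") <- paste0("A", seq_len(n_A))
  w
}

#' Shared-parent ground-truth graph
#'
#' Two group-B neurons are connected exactly when they share at least one
#' group-A parent — the coherence structure induced by common presynaptic
#' input.
#'
#' @param wiring a wiring matrix from [random_wiring()] (rows = B neurons,
#'   entries = A parent indices).
#' @param retained optional subset of B labels to keep (e.g. after excluding
#'   silent neurons); defaults to all rows.
#' @return a [microcircuit()] over `retained`.
#' @export
shared_parent_graph <- function(wiring, retained = NULL) {
  blab <- rownames(wiring)
  if (is.null(blab)) stop("wiring must have row names (B labels)")
  if (is.null(retained)) retained <- blab
  retained <- as.character(retained)
  missing <- setdiff(retained, blab)
  if (length(missing))
    stop("retained labels not in wiring: ", paste(missing, collapse = ", "))
  sub <- wiring[retained, , drop = FALSE]
  nA <- max(wiring)
  Mb <- matrix(FALSE, nrow(sub), nA)
  for (i in seq_len(nrow(sub))) Mb[i, sub[i, ]] <- TRUE
  share <- (Mb %*% t(Mb)) > 0
  diag(share) <- FALSE
  microcircuit(retained, share)
}

#' Configuration of the integrate-and-fire network simulation
#'
#' All tunables of the two-population feed-forward simulation. Defaults are
#' the benchmark conditions: 50 + 50 neurons, membrane time constants
#' `tau_A ~ N(20, 5)` ms (clipped below at 1 ms) and `tau_B = 100` ms, noise
#' scale `sigma = 0.2`, synaptic increment `a = 0.8` per parent spike, 5 ms
#' frames, firing threshold 1, resting potential 0, a global stimulus
#' presented every 3 or 4 frames (gap drawn uniformly), and 1200 frames.
#'
#' `stim_gain` is the potential increment every group-A neuron receives on a
#' stimulus frame. The default 1.0 sits exactly at the firing threshold, so
#' whether a given A neuron fires on a given stimulus frame is decided by its
#' accumulated membrane noise (approximately a fair coin, independent across
#' neurons). This keeps the stimulus a strong common drive while leaving
#' enough per-neuron variability for the shared-parent structure of group B
#' to be identifiable.
#'
#' @param n_A,n_B population sizes.
#' @param tau_A_mean,tau_A_sd mean and SD (ms) of group-A time constants.
#' @param tau_B group-B time constant (ms).
#' @param sigma noise scale; the per-frame noise term is
#'   `sigma * eps * tau^(-0.5)` with `eps ~ N(0, 1)`.
#' @param a synaptic increment per parent spike.
#' @param dt frame length (ms); also the Euler step.
#' @param threshold firing threshold.
#' @param v_rest resting (and reset, and initial) potential.
#' @param stim_gain stimulus increment for group-A neurons.
#' @param stim_gap possible gaps (in frames) between stimulus presentations.
#' @param parents_per_B group-A parents per group-B neuron.
#' @param n_frames number of simulated frames (= samples).
#' @param seed optional integer seed consumed by [simulate_lif()].
#' @return An object of class `lif_config`.
#' @export
lif_config <- function(n_A = 50, n_B = 50, tau_A_mean = 20, tau_A_sd = 5,
                       tau_B = 100, sigma = 0.2, a = 0.8, dt = 5,
                       threshold = 1, v_rest = 0, stim_gain = 1.0,
                       stim_gap = c(3, 4), parents_per_B = 2,
                       n_frames = 1200, seed = NULL) {
  stopifnot(tau_A_mean > 0, tau_B > 0, dt > 0, n_frames >= 1,
            parents_per_B <= n_A, all(stim_gap >= 1))
  structure(list(n_A = n_A, n_B = n_B, tau_A_mean = tau_A_mean,
                 tau_A_sd = tau_A_sd, tau_B = tau_B, sigma = sigma, a = a,
                 dt = dt, threshold = threshold, v_rest = v_rest,
                 stim_gain = stim_gain, stim_gap = stim_gap,
                 parents_per_B = parents_per_B, n_frames = n_frames,
                 seed = seed),
            class = "lif_config")
}

#' Simulate the two-population integrate-and-fire network
#'
#' Euler-integrates the membrane potential of every neuron one frame at a
#' time: leak towards `v_rest` with time constant `tau`, additive Gaussian
#' noise `sigma * eps * tau^(-0.5)`, the stimulus increment for group A on
#' stimulus frames, and `a` per parent that spiked on the previous frame for
#' group B. A neuron fires when its potential exceeds `threshold` and then
#' resets. Spikes are binarized per frame into the sample matrix.
#'
#' @param cfg a [lif_config()]; `cfg$seed`, when set, seeds the whole
#'   simulation (wiring, stimulus train, noise).
#' @return An object of class `lif_sim`: list with `data` (binary
#'   [data_matrix()], `n_frames x (n_A + n_B)`, labels `A1.. B1..`),
#'   `wiring`, `ground_truth` (shared-parent [microcircuit()] over the
#'   retained B neurons), `retained_b`, `silent_b` (labels of B neurons that
#'   never fired), `stim` (logical stimulus-frame vector), and `config`.
#' @export
simulate_lif <- function(cfg = lif_config()) {
  stopifnot(inherits(cfg, "lif_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tau <- c(pmax(rnorm(cfg$n_A, cfg$tau_A_mean, cfg$tau_A_sd), 1),
           rep(cfg$tau_B, cfg$n_B))
  wiring <- random_wiring(cfg$n_A, cfg$n_B, cfg$parents_per_B)
  gaps <- sample(cfg$stim_gap, size = ceiling(cfg$n_frames / min(cfg$stim_gap)) + 2L,
                 replace = TRUE)
  times <- cumsum(gaps)
  stim <- rep(FALSE, cfg$n_frames)
  stim[times[times <= cfg$n_frames]] <- TRUE
  spikes <- lif_sim_cpp(as.integer(cfg$n_frames), tau, as.integer(cfg$n_A),
                        wiring - 1L, stim, cfg$dt, cfg$sigma, cfg$a,
                        cfg$stim_gain, cfg$v_rest, cfg$threshold)
  labels <- c(attr(wiring, "A_labels"), rownames(wiring))
  dat <- data_matrix(spikes, mode = "binary", node_labels = labels)
  b_labels <- rownames(wiring)
  b_var <- apply(dat$values[, b_labels, drop = FALSE], 2L, var)
  retained <- b_labels[b_var > 0]
  silent <- setdiff(b_labels, retained)
  gt <- if (length(retained)) shared_parent_graph(wiring, retained) else NULL
  structure(list(data = dat, wiring = wiring, ground_truth = gt,
                 retained_b = retained, silent_b = silent, stim = stim,
                 config = cfg),
            class = "lif_sim")
}

#' @export
print.lif_sim <- function(x, ...) {
  cat(sprintf("<lif_sim> %d frames, %d+%d neurons, %d retained B, %d silent\n",
              x$config$n_frames, x$config$n_A, x$config$n_B,
              length(x$retained_b), length(x$silent_b)))
  invisible(x)
}

#' Sample from a Gaussian Markov network
#'
#' Multivariate-normal draws with the template's mean and covariance
#' (via [MASS::mvrnorm()]).
#'
#' @param params a [gaussian_mn_params()].
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return a continuous-mode [data_matrix()].
#' @export
sample_gaussian_mn <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "gmn_params"))
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(n, mu = params$mu, Sigma = params$sigma)
  if (n == 1L) x <- matrix(x, nrow = 1)
  data_matrix(x, mode = "continuous", node_labels = params$node_labels)
}

#' Gaussian chain with tridiagonal precision
#'
#' Convenience template: precision matrix with unit diagonal and `-partial`
#' on the first off-diagonal, so consecutive nodes have partial correlation
#' `partial` and the conditional-independence graph is the path
#' `1 - 2 - ... - n`.
#'
#' @param n_nodes chain length.
#' @param partial partial correlation between neighbors, `|partial| < 0.5`
#'   guarantees positive definiteness.
#' @param node_labels optional labels (default `V1..Vn`).
#' @return a [gaussian_mn_params()].
#' @export
chain_gmn_params <- function(n_nodes, partial = 0.45, node_labels = NULL) {
  K <- diag(n_nodes)
  for (i in seq_len(n_nodes - 1L)) K[i, i + 1L] <- K[i + 1L, i] <- -partial
  gaussian_mn_params(rep(0, n_nodes), solve(K), node_labels)
}

# Precision matrix with unit diagonal and -weight on the listed edges,
# shrunk towards the diagonal until positive definite.
.precision_from_edges <- function(n, edges, weight) {
  K <- diag(n)
  if (NROW(edges)) for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    K[i, j] <- K[j, i] <- -weight
  }
  for (it in 1:60) {
    ok <- tryCatch({ chol(K); TRUE }, error = function(e) FALSE)
    if (ok) return(K)
    K[row(K) != col(K)] <- K[row(K) != col(K)] * 0.95
  }
  stop("could not make the precision matrix positive definite")
}
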