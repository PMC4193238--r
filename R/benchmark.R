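#' Build a benchmark network
#'
#' Random balanced network: `0.8 N` excitatory then `0.2 N` inhibitory
#' neurons (GIDs in creation order); every neuron receives exactly the
#' set's excitatory and inhibitory in-degrees from sources drawn
#' uniformly with replacement (multapses and autapses allowed -- the
#' connectivity law assumed throughout the package).
#' Excitatory-excitatory synapses are plastic (syn type 1), all others
#' static (type 0).  The synapse array is laid out per target (block of
#' `K` sources, the excitatory ones first) with a by-source index for
#' delivery.
#'
#' @param set a [benchmark_set()] (or 1/2).
#' @param N total neurons.
#' @param n_vp number of virtual processes neurons are assigned to,
#'   round-robin by `gid %% n_vp`.
#' @param seed RNG seed; identical `(set, N, n_vp, seed)` give identical
#'   networks.
#' @param max_elements refuse to build more than this many synapses
#'   (guards desk-scale use; raise explicitly for larger runs).
#' @return object of class `spikemem_network`.
#' @export
build_network <- function(set, N, n_vp = 1, seed = 1,
                          max_elements = 5e7) {
  if (!inherits(set, "benchmark_set")) set <- benchmark_set(set)
  if (N < 1) stop("N must be >= 1")
  if (as.double(N) * set$K > max_elements)
    stop("network would hold ", format(N * set$K, big.mark = ","),
         " synapses, above max_elements = ", format(max_elements),
         "; reduce N or raise max_elements explicitly")
  n_exc <- as.integer(round(set$beta * N))
  n_inh <- N - n_exc
  if (n_exc < 1 || n_inh < 1)
    stop("N too small to hold both populations")
  K <- set$K
  K_E <- set$K_E
  K_I <- set$K_I
  set.seed(seed)
  sources <- integer(N * K)
  dim(sources) <- c(K, N)
  sources[seq_len(K_E), ] <- sample.int(n_exc, N * K_E, replace = TRUE)
  sources[K_E + seq_len(K_I), ] <-
    n_exc + sample.int(n_inh, N * K_I, replace = TRUE)
  dim(sources) <- NULL

  weights <- rep(-set$g * set$J_E, N * K)
  weights[sources <= n_exc] <- set$J_E

  csr_idx <- order(sources, method = "radix")
  csr_ptr <- c(0L, cumsum(tabulate(sources, nbins = N)))

  structure(list(set = set, N = as.integer(N), n_exc = n_exc,
                 K = K, K_E = K_E, K_I = K_I,
                 n_vp = as.integer(n_vp), seed = seed,
                 sources = sources, weights = weights,
                 csr_idx = csr_idx, csr_ptr = as.integer(csr_ptr)),
            class = "spikemem_network")
}

#' Assemble a network from explicit connectivity
#'
#' Low-level constructor for small, hand-specified networks (tests,
#' worked examples).  `sources` is the per-target in-degree array: a
#' `K x N` matrix (or vector of length `N K`) whose column `i` lists the
#' source GIDs of neuron `i`, the first `K_E` rows excitatory.
#'
#' @param sources source GID array (see above); may be empty for `K = 0`.
#' @param N number of neurons.
#' @param n_exc number of excitatory neurons (GIDs `1..n_exc`).
#' @param K_E excitatory in-degree.
#' @param set a [benchmark_set()] supplying neuron and weight parameters.
#' @param weights optional per-synapse weights (defaults to `J_E` /
#'   `-g J_E` by source type).
#' @param n_vp virtual processes.
#' @return object of class `spikemem_network`.
#' @export
manual_network <- function(sources, N, n_exc, K_E = 0,
                           set = benchmark_set(2), weights = NULL,
                           n_vp = 1) {
  sources <- as.integer(sources)
  if (length(sources) %% N != 0) stop("length(sources) must be a multiple of N")
  K <- length(sources) %/% N
  if (K_E > K) stop("K_E cannot exceed K")
  if (length(sources) && (min(sources) < 1 || max(sources) > N))
    stop("source GIDs must lie in [1, N]")
  if (is.null(weights)) {
    weights <- rep(-set$g * set$J_E, length(sources))
    weights[sources <= n_exc] <- set$J_E
  }
  if (length(weights) != length(sources))
    stop("weights must match sources in length")
  csr_idx <- if (length(sources)) order(sources, method = "radix") else integer(0)
  csr_ptr <- c(0L, cumsum(tabulate(sources, nbins = N)))
  structure(list(set = set, N = as.integer(N), n_exc = as.integer(n_exc),
                 K = as.integer(K), K_E = as.integer(K_E),
                 K_I = as.integer(K - K_E),
                 n_vp = as.integer(n_vp), seed = NA,
                 sources = sources, weights = as.numeric(weights),
                 csr_idx = csr_idx, csr_ptr = as.integer(csr_ptr)),
            class = "spikemem_network")
}

#' Dry run: memory plan for a machine partition
#'
#' Mimics a full-machine run on the desk: predicts the maximum network
#' size fitting the per-process budget, the memory breakdown at that
#' size, and the expected target-list census per virtual process.
#'
#' @param grid a [machine_grid()].
#' @param set a [benchmark_set()] (or 1/2) supplying `K` and `beta`.
#' @param budget a [machine_budget()].
#' @param generation kernel generation, `"4g"` or `"3g"`.
#' @return object of class `dry_run_report`: `N_max`, `breakdown`
#'   (a `memory_breakdown` at `N_max`), `list_census`
#'   (a `target_list_stats`), plus the inputs.
#' @export
dry_run <- function(grid, set, budget = machine_budget(),
                    generation = c("4g", "3g")) {
  if (!inherits(set, "benchmark_set")) set <- benchmark_set(set)
  generation <- match.arg(generation)
  params <- memory_params(generation, beta = set$beta)
  N_max <- max_network_size(grid, set$K, params, budget)
  if (N_max == 0) {
    return(structure(list(N_max = 0, breakdown = NULL, list_census = NULL,
                          grid = grid, set = set, budget = budget,
                          generation = generation),
                     class = "dry_run_report"))
  }
  shape <- network_shape(N_max, set$K, grid)
  structure(list(N_max = N_max,
                 breakdown = total_memory(grid, shape, params, budget),
                 list_census = expected_list_counts(grid, shape),
                 grid = grid, set = set, budget = budget,
                 generation = generation),
            class = "dry_run_report")
}

#' Empirical target-list census of a built network
#'
#' Counts, for each virtual process, how many source neurons have 0, 1
#' or more local targets, and compares the totals with the closed-form
#' expectations (z-scores use the binomial standard error of the
#' theoretical proportion over `n_vp * N` source-VP pairs).
#'
#' @param network a [build_network()] result.
#' @param grid optional [machine_grid()]; defaults to
#'   `machine_grid(network$n_vp, 1)`.
#' @return list with `empirical` (mean per-VP counts of
#'   empty/one/multi lists), `expected` (a `target_list_stats`),
#'   `z` (named z-scores) and `per_vp` (counts matrix).
#' @export
verify_combinatorics <- function(network, grid = NULL) {
  stopifnot(inherits(network, "spikemem_network"))
  if (is.null(grid)) grid <- machine_grid(network$n_vp, 1)
  n_vp <- grid$VP
  N <- network$N
  # per-(source, vp) local target counts; target vp = gid %% n_vp
  tgt <- rep(seq_len(N), each = network$K)
  vp <- tgt %% n_vp
  counts <- matrix(0L, nrow = 3, ncol = n_vp,
                   dimnames = list(c("empty", "one", "multi"), NULL))
  for (v in seq_len(n_vp) - 1L) {
    len <- tabulate(network$sources[vp == v], nbins = N)
    counts[, v + 1L] <- c(sum(len == 0), sum(len == 1), sum(len > 1))
  }
  emp <- rowMeans(counts)
  exp_st <- expected_list_counts(grid, network_shape(N, network$K, grid))
  p <- c(exp_st$p_empty, exp_st$p_one, exp_st$p_multi)
  tot <- as.double(n_vp) * N
  z <- (rowSums(counts) - p * tot) / sqrt(pmax(p * (1 - p) * tot, 1e-300))
  names(z) <- rownames(counts)
  list(empirical = emp, expected = exp_st, z = z, per_vp = counts)
}
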