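#' Memory-model parameter set for one kernel generation
#'
#' Per-object sizes and per-neuron infrastructure overheads of the
#' simulator's data structures, for the 3rd-generation ("3g") and
#' 4th-generation ("4g") kernel designs.  All values in bytes:
#'
#' * `m_n`: one neuron object (1100 B, both generations)
#' * `m0_n`: neuron-infrastructure overhead per neuron in the whole
#'   network (1/3 B for 3g -- one sparse-table bit plus group overhead --
#'   and 0 for 4g, where the sparse node array eliminates it)
#' * `mplus_n`: overhead per *local* neuron (16 B / 24 B)
#' * `mempty_n`: overhead per non-local neuron (0)
#' * `m_stat_c`, `m_stdp_c`: one static / STDP synapse object
#'   (48/48 B for 3g, 16/24 B for 4g condensed objects)
#' * `m0_c`: connection-infrastructure overhead per neuron (sparse
#'   presence table, 1/3 B per neuron per thread)
#' * `m1_c`: overhead per source neuron with exactly one local target
#'   (96 B / 24 B)
#' * `mgt1_c`: overhead per source neuron with more than one local target
#'   (160 B / 128 B, a worst-case uniform value)
#' * `mempty_c`: overhead per source without local targets (0)
#'
#' The nominal 0.33 B table entries are represented as exactly 1/3 B
#' (one bit per neuron plus 16 B bookkeeping per 48-entry group).
#'
#' @param generation `"3g"` or `"4g"`.
#' @param beta excitatory fraction of the network (default 0.8), used to
#'   split synapses into STDP (excitatory-excitatory, fraction `beta^2`)
#'   and static.
#' @return object of class `memory_params`.
#' @export
memory_params <- function(generation = c("4g", "3g"), beta = 0.8) {
  generation <- match.arg(generation)
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  third <- 1 / 3
  p <- if (generation == "3g") {
    list(m_n = 1100, m0_n = third, mplus_n = 16, mempty_n = 0,
         m_stat_c = 48, m_stdp_c = 48,
         m0_c = third, m1_c = 96, mgt1_c = 160, mempty_c = 0)
  } else {
    list(m_n = 1100, m0_n = 0, mplus_n = 24, mempty_n = 0,
         m_stat_c = 16, m_stdp_c = 24,
         m0_c = third, m1_c = 24, mgt1_c = 128, mempty_c = 0)
  }
  structure(c(list(generation = generation), p, list(beta = beta)),
            class = "memory_params")
}

#' Read a memory-model parameter table from a key-value file
#'
#' The built-in tables are shipped as editable `key = value` files under
#' `inst/extdata/` (one per kernel generation); values may be simple
#' fractions such as `1/3`.  Unknown keys are rejected.
#'
#' @param path path to a config file; by default the packaged table for
#'   `generation` is read.
#' @param generation `"3g"` or `"4g"`, used to locate the packaged file
#'   when `path` is `NULL`.
#' @return a [memory_params()] object.
#' @export
memory_params_from_file <- function(path = NULL, generation = c("4g", "3g")) {
  generation <- match.arg(generation)
  if (is.null(path))
    path <- system.file("extdata",
                        paste0("memory_params_", generation, ".conf"),
                        package = "spikemem", mustWork = TRUE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  parse_num <- function(x) {
    if (grepl("/", x, fixed = TRUE)) {
      parts <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
      parts[1] / parts[2]
    } else as.numeric(x)
  }
  p <- memory_params(vals[keys == "generation"],
                     beta = parse_num(vals[keys == "beta"]))
  numeric_keys <- setdiff(keys, c("generation", "beta"))
  bad <- setdiff(numeric_keys, names(p))
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  for (k in numeric_keys) p[[k]] <- parse_num(vals[keys == k])
  p
}

#' Per-process memory budget and base footprint
#'
#' @param budget_bytes usable memory per MPI process.  Default is the
#'   13.81 GiB of the 16 GiB per node actually available to a user
#'   program on the K computer.
#' @param base_bytes start-up footprint of the simulator including
#'   external libraries (default 268 MiB, the K-computer measurement).
#' @param buffer_entries size of the outgoing MPI spike buffer in entries
#'   (default 1000, a worst case; measured full-machine runs used 568).
#' @param buffer_entry_bytes bytes per buffer entry (default 4).
#' @return object of class `machine_budget`.
#' @export
machine_budget <- function(budget_bytes = 13.81 * 2^30,
                           base_bytes = 268 * 2^20,
                           buffer_entries = 1000,
                           buffer_entry_bytes = 4) {
  structure(list(budget_bytes = budget_bytes, base_bytes = base_bytes,
                 buffer_entries = buffer_entries,
                 buffer_entry_bytes = buffer_entry_bytes),
            class = "machine_budget")
}

#' Base memory per MPI process
#'
#' Start-up footprint plus the incoming spike-communication buffer, which
#' grows linearly with the number of processes `M` because collective
#' exchange concatenates one outgoing buffer per process.
#'
#' @param M number of MPI processes.
#' @param budget a [machine_budget()].
#' @return bytes: `base_bytes + M * buffer_entries * buffer_entry_bytes`.
#' @export
base_memory <- function(M, budget = machine_budget()) {
  stopifnot(inherits(budget, "machine_budget"))
  if (M < 1) stop("M must be >= 1")
  budget$base_bytes + M * budget$buffer_entries * budget$buffer_entry_bytes
}

#' Memory for neuron objects and neuron infrastructure per MPI process
#'
#' Objects: `(N/M) * m_n`.  Infrastructure: `N * m0_n + (N/M) * mplus_n`;
#' the term proportional to the *total* network size `N` (the per-neuron
#' sparse-table bits of the 3g design) is the component that the sparse
#' node array of the 4g design eliminates (`m0_n = 0`).
#'
#' @param N total neurons.
#' @param M MPI processes.
#' @param params a [memory_params()].
#' @return named numeric `c(objects = ..., infra = ...)` in bytes.
#' @export
neuron_memory <- function(N, M, params) {
  stopifnot(inherits(params, "memory_params"))
  if (N < 0) stop("N must be >= 0")
  c(objects = (N / M) * params$m_n,
    infra = N * params$m0_n + (N / M) * params$mplus_n)
}

new_memory_breakdown <- function(base, buffer, neuron_objects, neuron_infra,
                                 sparse_table, infra_singleton, infra_multi,
                                 synapses_static, synapses_stdp) {
  parts <- c(base = base, buffer = buffer,
             neuron_objects = neuron_objects, neuron_infra = neuron_infra,
             sparse_table = sparse_table,
             infra_singleton = infra_singleton, infra_multi = infra_multi,
             synapses_static = synapses_static, synapses_stdp = synapses_stdp)
  structure(as.list(c(parts, total = sum(parts))), class = "memory_breakdown")
}

#' Connection memory per MPI process
#'
#' Synapse objects are split into STDP (`K_M beta^2`, the
#' excitatory-excitatory fraction) and static; infrastructure comprises
#' the sparse presence table replicated per thread (`T N m0_c`) and the
#' per-source container overheads weighted by the expected number of
#' singleton (`m1_c`) and longer (`mgt1_c`) target lists per virtual
#' process, from [expected_list_counts()].
#'
#' @param grid a [machine_grid()].
#' @param shape a [network_shape()].
#' @param params a [memory_params()].
#' @param mode probability mode passed to [expected_list_counts()].
#' @return a `memory_breakdown` with only the connection fields non-zero.
#' @export
connection_memory <- function(grid, shape, params, mode = "exact") {
  stopifnot(inherits(grid, "machine_grid"), inherits(shape, "network_shape"),
            inherits(params, "memory_params"))
  N <- shape$N
  K_M <- (N / grid$M) * shape$K
  n_stdp <- K_M * params$beta^2
  if (shape$N < 2 && mode == "exact") mode <- "poisson_limit"
  if (shape$K == 0) {
    sparse_table <- 0
    n1 <- 0
    ngt1 <- 0
  } else {
    st <- expected_list_counts(grid, shape, mode)
    sparse_table <- grid$T * N * params$m0_c
    n1 <- st$n_one
    ngt1 <- N - st$n_empty - st$n_one
  }
  new_memory_breakdown(
    base = 0, buffer = 0, neuron_objects = 0, neuron_infra = 0,
    sparse_table = sparse_table,
    infra_singleton = grid$T * n1 * params$m1_c,
    infra_multi = grid$T * ngt1 * params$mgt1_c,
    synapses_static = (K_M - n_stdp) * params$m_stat_c,
    synapses_stdp = n_stdp * params$m_stdp_c)
}

#' Total predicted memory per MPI process
#'
#' Sum of the base, neuron and connection components,
#' `M(M,T,N,K) = M_0(M) + M_n(M,N) + M_c(M,T,N,K)`.
#'
#' @inheritParams connection_memory
#' @param budget a [machine_budget()].
#' @return a `memory_breakdown`; field `total` is the per-process
#'   prediction in bytes.
#' @examples
#' g <- machine_grid(80000, 8)
#' s <- network_shape(1e9, 11250, g)
#' total_memory(g, s, memory_params("4g"), machine_budget())$total / 2^30
#' @export
total_memory <- function(grid, shape, params, budget = machine_budget(),
                         mode = "exact") {
  conn <- connection_memory(grid, shape, params, mode)
  neu <- neuron_memory(shape$N, grid$M, params)
  new_memory_breakdown(
    base = budget$base_bytes,
    buffer = grid$M * budget$buffer_entries * budget$buffer_entry_bytes,
    neuron_objects = unname(neu["objects"]),
    neuron_infra = unname(neu["infra"]),
    sparse_table = conn$sparse_table,
    infra_singleton = conn$infra_singleton,
    infra_multi = conn$infra_multi,
    synapses_static = conn$synapses_static,
    synapses_stdp = conn$synapses_stdp)
}

#' Largest network that fits a per-process memory budget
#'
#' Integer bisection on `N` of the monotone total-memory prediction.
#' Returns the largest integer `N` with
#' `total_memory(N) <= budget_bytes`, so that
#' `total(N_max) <= budget < total(N_max + 1)`.
#'
#' @param grid a [machine_grid()].
#' @param K mean in-degree.
#' @param params a [memory_params()].
#' @param budget a [machine_budget()].
#' @return `N_max` (integer-valued numeric; 0 if not even one neuron
#'   fits).
#' @export
max_network_size <- function(grid, K, params, budget = machine_budget()) {
  tot <- function(N) {
    if (N == 0) return(base_memory(grid$M, budget))
    total_memory(grid, network_shape(N, K, grid), params, budget)$total
  }
  if (tot(0) > budget$budget_bytes)
    stop("infeasible: budget below base memory")
  lo <- 0
  hi <- 1
  while (tot(hi) <= budget$budget_bytes) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e15) stop("budget admits implausibly large N; check parameters")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (tot(mid) <= budget$budget_bytes) lo <- mid else hi <- mid
  }
  lo
}
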