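#' Partition a network into emulated virtual processes
#'
#' Assigns neurons round-robin (`gid %% n_vp`) and builds, for each VP,
#' the thread-local data structures a distributed simulator would hold:
#' a [sparse_node_array()] of the local nodes and a [connection_store()]
#' of the VP-local target lists, with targets stored as thread-local
#' indices.  Intended for small networks (the per-record R containers are
#' semantic models, not bulk storage).
#'
#' @param network a `spikemem_network`.
#' @param n_vp number of virtual processes (>= 1).
#' @param delay_steps delay stored in each record (default 15, i.e.
#'   1.5 ms at 0.1 ms resolution).
#' @param max_elements guard on `N * K`.
#' @return list of length `n_vp`; each element has `vp`, `gids`,
#'   `sna` and `store`.
#' @export
emulate_vps <- function(network, n_vp = network$n_vp, delay_steps = 15,
                        max_elements = 1e6) {
  stopifnot(inherits(network, "spikemem_network"))
  if (n_vp < 1) stop("n_vp must be >= 1")
  if (length(network$sources) > max_elements)
    stop("network too large for the per-record VP emulation")
  N <- network$N
  K <- network$K
  lapply(seq_len(n_vp) - 1L, function(v) {
    gids <- which(seq_len(N) %% n_vp == v)
    sna <- sparse_node_array(gids, max_gid = N)
    store <- connection_store(n_sources = N)
    local_index <- integer(N)
    local_index[gids] <- seq_along(gids)
    for (tgt in gids) {
      if (K == 0) next
      block <- (tgt - 1L) * K + seq_len(K)
      for (k in seq_len(K)) {
        j <- block[k]
        src <- network$sources[j]
        syn_id <- if (src <= network$n_exc && tgt <= network$n_exc &&
                      k <= network$K_E) 1 else 0
        store <- add_connection(store, src,
          connection_record(target = local_index[tgt], syn_id = syn_id,
                            delay_steps = delay_steps,
                            weight = network$weights[j]))
      }
    }
    list(vp = v, gids = gids, sna = sna, store = store)
  })
}

#' Reference simulation through the per-VP data structures
#'
#' A deliberately plain R re-implementation of the simulation loop that
#' routes every spike through the emulated per-VP connection stores and
#' resolves targets through each VP's sparse node array.  Static synapses
#' only (plasticity is ignored); external input is drawn from the same
#' per-neuron streams as the fast path, so for a static configuration the
#' spike output is identical to [simulate_network()] for any `n_vp`.
#'
#' @param network a small `spikemem_network`.
#' @param config a [sim_config()] (its `stdp` is ignored; weights stay
#'   fixed).
#' @param n_vp number of emulated virtual processes.
#' @return list with `spikes`, `rates`, `mean_rate` as in
#'   [simulate_network()].
#' @export
simulate_reference <- function(network, config = sim_config(), n_vp = 1) {
  stopifnot(inherits(network, "spikemem_network"))
  set <- network$set
  np <- set$neuron
  h <- config$h
  n <- network$N
  n_steps <- as.integer(round(config$duration_ms / h))
  delay_steps <- as.integer(round(config$delay_ms / h))
  ref_steps <- as.integer(round(np$t_ref / h))
  prop <- lif_propagator(np, h)
  nu_ext <- if (is.null(config$nu_ext)) external_rate(set, "ms") else config$nu_ext

  vps <- emulate_vps(network, n_vp, delay_steps = delay_steps)

  set.seed(config$seed)
  lo <- stats::pnorm(np$v_reset, set$vm_init_mean, set$vm_init_sd)
  V <- stats::qnorm(stats::runif(n, lo, 1), set$vm_init_mean, set$vm_init_sd)

  # external counts, n x n_steps (same layout the fast path consumes)
  ext <- if (!is.null(config$ext_counts)) config$ext_counts
  else if (nu_ext > 0)
    t(vapply(seq_len(n), function(g)
      ext_poisson_counts(n_steps, nu_ext * h, config$seed, g),
      integer(n_steps)))
  else matrix(0L, n, n_steps)
  have_ext <- nu_ext > 0 || !is.null(config$ext_counts)

  y1 <- numeric(n)
  y2 <- numeric(n)
  input <- numeric(n)
  refr <- integer(n)
  qlen <- delay_steps + 1L
  queue <- replicate(qlen, integer(0), simplify = FALSE)
  spike_gid <- integer(0)
  spike_step <- integer(0)

  for (t in seq_len(n_steps)) {
    slot <- ((t - 1L) %% qlen) + 1L
    arrivals <- queue[[slot]]
    queue[slot] <- list(integer(0))
    for (src in arrivals) {
      for (vp in vps) {
        for (rec in deliver(vp$store, src)) {
          tgt <- vp$gids[rec$target]
          input[tgt] <- input[tgt] + rec$weight
        }
      }
    }
    if (have_ext)
      input <- input + ext[, t] * set$J_E

    v_new <- prop$e_m * V + prop$p31 * y1 + prop$p32 * y2
    y2 <- prop$e_s * y2 + prop$hs * y1
    y1 <- prop$e_s * y1 + prop$psc_norm * input
    input[] <- 0
    in_ref <- refr > 0
    refr[in_ref] <- refr[in_ref] - 1L
    V[in_ref] <- np$v_reset
    V[!in_ref] <- v_new[!in_ref]
    sp <- integer(0)
    if (config$threshold) {
      sp <- which(!in_ref & V >= np$v_th)
      if (length(sp)) {
        V[sp] <- np$v_reset
        refr[sp] <- ref_steps
        spike_gid <- c(spike_gid, sp)
        spike_step <- c(spike_step, rep(t, length(sp)))
        dst <- ((t - 1L + delay_steps) %% qlen) + 1L
        queue[[dst]] <- c(queue[[dst]], sp)
      }
    }
  }
  counts <- tabulate(spike_gid, nbins = n)
  list(spikes = data.frame(gid = spike_gid, time_ms = spike_step * h),
       rates = counts / (config$duration_ms / 1000),
       mean_rate = mean(counts) / (config$duration_ms / 1000))
}
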