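#' Neuron parameters of the benchmark integrate-and-fire model
#'
#' Leaky integrate-and-fire neuron with alpha-shaped post-synaptic
#' currents.  Defaults are the benchmark values: threshold 20 mV,
#' membrane time constant 10 ms, capacitance 250 pF, synaptic time
#' constant 0.3258 ms; resting and reset potential 0 mV and a 0.5 ms
#' refractory period follow the benchmark-script conventions.
#'
#' @param v_th spike threshold (mV).
#' @param tau_m membrane time constant (ms).
#' @param c_m membrane capacitance (pF).
#' @param tau_syn synaptic (alpha-kernel) time constant (ms).
#' @param e_l resting potential (mV).
#' @param v_reset post-spike reset potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @return object of class `neuron_params`.
#' @export
neuron_params <- function(v_th = 20, tau_m = 10, c_m = 250,
                          tau_syn = 0.3258, e_l = 0, v_reset = 0,
                          t_ref = 0.5) {
  if (tau_m <= 0 || tau_syn <= 0 || c_m <= 0) stop("time constants and c_m must be > 0")
  if (v_th <= v_reset) stop("v_th must exceed v_reset")
  structure(list(v_th = v_th, tau_m = tau_m, c_m = c_m, tau_syn = tau_syn,
                 e_l = e_l, v_reset = v_reset, t_ref = t_ref),
            class = "neuron_params")
}

#' Exact one-step propagator of the subthreshold dynamics
#'
#' The subthreshold system (y1, y2, V) with
#' `y1' = -y1/tau_syn`, `y2' = y1 - y2/tau_syn`,
#' `V' = -V/tau_m + y2/C_m` is linear, so the state after one step `h`
#' follows from the matrix exponential in closed form.  A spike of weight
#' `J` increments `y1` by `J e / tau_syn`, which makes the resulting
#' current `y2(t) = J e (t/tau_syn) exp(-t/tau_syn)` peak at exactly `J`
#' a time `tau_syn` after arrival.  The confluent case
#' `tau_m = tau_syn` is handled by its closed-form limit.
#'
#' @param params a [neuron_params()].
#' @param h step size (ms).
#' @return list with entries `e_s = exp(-h/tau_syn)`,
#'   `hs = h exp(-h/tau_syn)`, `e_m = exp(-h/tau_m)`, and the
#'   current-to-voltage couplings `p31`, `p32`, plus
#'   `psc_norm = e/tau_syn`.
#' @export
lif_propagator <- function(params, h) {
  stopifnot(inherits(params, "neuron_params"))
  if (h <= 0) stop("h must be > 0")
  a <- 1 / params$tau_m
  b <- 1 / params$tau_syn
  e_m <- exp(-a * h)
  e_s <- exp(-b * h)
  C <- params$c_m
  d <- b - a
  if (abs(d) < 1e-12) {
    p32 <- h * e_m / C
    p31 <- h^2 * e_m / (2 * C)
  } else {
    p32 <- e_m * (1 - exp(-d * h)) / (C * d)
    p31 <- e_m * (1 - (1 + d * h) * exp(-d * h)) / (C * d^2)
  }
  list(e_s = e_s, hs = h * e_s, e_m = e_m, p31 = p31, p32 = p32,
       psc_norm = exp(1) / params$tau_syn)
}

#' Benchmark network parameter sets
#'
#' The balanced random network of 80% excitatory and 20% inhibitory
#' neurons used for all measurements.  Set 1: in-degree `K = 11250`
#' (9000 excitatory, 2250 inhibitory), `J_E = 45.61` pA, `g = 5`,
#' `eta = 1.685`.  Set 2: `K = 6000` (4800/1200), `J_E = 50` pA,
#' `g = 7`, `eta = 1.2`, tuned to an irregular state of about 4.5
#' spikes/s.  Inhibitory weights are `-g J_E`; all
#' excitatory-excitatory synapses are plastic (STDP), all others static.
#'
#' @param set 1 or 2.
#' @return object of class `benchmark_set`.
#' @export
benchmark_set <- function(set = c(1, 2)) {
  set <- match.arg(as.character(set[1]), c("1", "2"))
  p <- if (set == "1")
    list(id = 1L, K = 11250L, K_E = 9000L, K_I = 2250L,
         J_E = 45.61, g = 5, eta = 1.685)
  else
    list(id = 2L, K = 6000L, K_E = 4800L, K_I = 1200L,
         J_E = 50, g = 7, eta = 1.2)
  p$beta <- 0.8
  p$delay_ms <- 1.5
  p$vm_init_mean <- 9.5
  p$vm_init_sd <- 5.0
  p$neuron <- neuron_params()
  stopifnot(p$K_E + p$K_I == p$K)
  structure(p, class = "benchmark_set")
}

#' External Poisson drive rate
#'
#' Rate of the summed external excitatory input that raises the mean
#' free membrane potential to `eta * V_th`:
#' `nu_ext = eta V_th C_m / (e tau_syn J_E tau_m)`.  The factor `e`
#' reflects the weight convention that `J_E` is the peak of the alpha
#' current, whose time integral is `J_E e tau_syn`.
#'
#' @param set a [benchmark_set()].
#' @param per what to return the rate per: `"s"` (default) or `"ms"`.
#' @return spikes per second (or per ms) summed over all external inputs
#'   to one neuron; about 20856/s for set 1.
#' @export
external_rate <- function(set, per = c("s", "ms")) {
  stopifnot(inherits(set, "benchmark_set"))
  per <- match.arg(per)
  np <- set$neuron
  nu_ms <- set$eta * np$v_th * np$c_m /
    (exp(1) * np$tau_syn * set$J_E * np$tau_m)
  if (per == "ms") nu_ms else nu_ms * 1000
}

#' External input spike counts
#'
#' Poisson-distributed number of external spikes per update step with
#' mean `nu_ext * h`, drawn from the per-neuron counter-seeded stream the
#' simulator itself uses (so a given `(seed, gid)` pair reproduces the
#' simulator's drive exactly).
#'
#' @param nu_ext external rate (per ms).
#' @param h step size (ms).
#' @param n_steps number of steps.
#' @param seed simulation seed.
#' @param gid neuron GID selecting the stream.
#' @return integer vector of length `n_steps`.
#' @export
external_input <- function(nu_ext, h, n_steps, seed = 1, gid = 1) {
  if (nu_ext < 0) stop("nu_ext must be >= 0")
  ext_poisson_counts(n_steps, nu_ext * h, seed, gid)
}

#' STDP parameters
#'
#' Power-law potentiation and multiplicative depression with
#' pre-/post-synaptic trace time constants.  `lambda = 0` disables
#' plasticity (weights are then bit-identical to a static run).
#'
#' The reference weight `w0` defaults to 1 pA, i.e. weights enter the
#' potentiation rule in units of pA.  Under uncorrelated pre/post firing
#' this puts the stationary weight of the rule at
#' `(tau_plus / (alpha tau_minus))^(1/(1-mu)) ~ 44.5 pA`, consistent
#' with the benchmark's excitatory weight of 45.61 pA; a reference
#' weight of the order of the operating weight itself would move the
#' fixed point far above it and destabilise the network.
#'
#' @param lambda learning rate.
#' @param mu weight exponent of the power-law potentiation.
#' @param alpha relative strength of depression.
#' @param tau_plus presynaptic trace time constant (ms).
#' @param tau_minus postsynaptic trace time constant (ms).
#' @param w0 reference weight (pA).
#' @return object of class `stdp_params`.
#' @export
stdp_params <- function(lambda = 0.1, mu = 0.4, alpha = 0.0513,
                        tau_plus = 15, tau_minus = 30, w0 = 1) {
  structure(list(lambda = lambda, mu = mu, alpha = alpha,
                 tau_plus = tau_plus, tau_minus = tau_minus, w0 = w0),
            class = "stdp_params")
}

#' Single STDP weight updates
#'
#' `stdp_potentiate` applies the power-law facilitation
#' `w + lambda w0^(1-mu) w^mu x_pre` triggered by a postsynaptic spike;
#' `stdp_depress` applies the multiplicative depression
#' `w (1 - lambda alpha x_post)` (clipped at 0) triggered by a
#' presynaptic spike arrival.
#'
#' @param w current weight (> 0 for plastic synapses).
#' @param x_pre,x_post value of the respective trace at the triggering
#'   event.
#' @param params an [stdp_params()] with concrete `w0`.
#' @return updated weight.
#' @export
stdp_potentiate <- function(w, x_pre, params) {
  stopifnot(inherits(params, "stdp_params"), is.finite(params$w0))
  w + params$lambda * params$w0^(1 - params$mu) * w^params$mu * x_pre
}

#' @rdname stdp_potentiate
#' @export
stdp_depress <- function(w, x_post, params) {
  stopifnot(inherits(params, "stdp_params"))
  pmax(0, w * (1 - params$lambda * params$alpha * x_post))
}

#' Simulation configuration
#'
#' @param duration_ms biological time to simulate (ms).
#' @param h state-update step (ms), default 0.1.
#' @param delay_ms synaptic delay, an integer multiple of `h`; spikes are
#'   exchanged in intervals of the delay (1.5 ms default).
#' @param seed integer seed; drives membrane-potential initialisation and
#'   the per-neuron external-input streams.
#' @param threshold set `FALSE` to disable spiking (free membrane
#'   potential).
#' @param stdp an [stdp_params()]; `stdp_params(lambda = 0)` for a fully
#'   static run.
#' @param nu_ext external drive per neuron in spikes/ms; `NULL` derives
#'   it from the network's parameter set via [external_rate()].
#' @param record_vm record the full membrane-potential trajectory
#'   (n x steps matrix; small networks only).
#' @param vm_warmup_ms initial interval excluded from the reported
#'   time-averaged membrane potential.
#' @param return_weights return the final synaptic weight vector.
#' @param ext_counts optional pre-drawn external spike-count matrix
#'   (n x steps), overriding the internal streams.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(duration_ms = 1000, h = 0.1, delay_ms = 1.5,
                       seed = 1, threshold = TRUE, stdp = stdp_params(),
                       nu_ext = NULL, record_vm = FALSE, vm_warmup_ms = 0,
                       return_weights = FALSE, ext_counts = NULL) {
  steps_per_delay <- delay_ms / h
  if (abs(steps_per_delay - round(steps_per_delay)) > 1e-9)
    stop("delay_ms must be an integer multiple of h")
  structure(list(duration_ms = duration_ms, h = h, delay_ms = delay_ms,
                 seed = seed, threshold = threshold, stdp = stdp,
                 nu_ext = nu_ext, record_vm = record_vm,
                 vm_warmup_ms = vm_warmup_ms,
                 return_weights = return_weights, ext_counts = ext_counts),
            class = "sim_config")
}

#' Run the reference simulation
#'
#' Advances all neurons in steps of `h` with the exact propagator,
#' delivers every spike exactly one synaptic delay after emission, and
#' applies STDP to excitatory-excitatory synapses.  Deterministic given
#' the network and `config$seed`; independent of the number of virtual
#' processes the network is partitioned into, because external input is
#' drawn from per-neuron streams.
#'
#' @param network a network from [build_network()] or
#'   [manual_network()].
#' @param config a [sim_config()].
#' @return list with `spikes` (data frame `gid`, `time_ms`), `rates`
#'   (per-neuron spikes/s), `mean_rate`, `vm_mean` (per-neuron
#'   time-averaged potential), `n_steps`, `seed`, and optionally `vm`
#'   and `weights`.
#' @export
simulate_network <- function(network, config = sim_config()) {
  stopifnot(inherits(network, "spikemem_network"),
            inherits(config, "sim_config"))
  set <- network$set
  np <- set$neuron
  h <- config$h
  n_steps <- as.integer(round(config$duration_ms / h))
  delay_steps <- as.integer(round(config$delay_ms / h))
  ref_steps <- as.integer(round(np$t_ref / h))
  prop <- lif_propagator(np, h)
  nu_ext <- if (is.null(config$nu_ext)) external_rate(set, "ms") else config$nu_ext

  stdp <- config$stdp
  w0 <- stdp$w0

  set.seed(config$seed)
  lo <- stats::pnorm(np$v_reset, set$vm_init_mean, set$vm_init_sd)
  v_init <- stats::qnorm(stats::runif(network$N, lo, 1),
                         set$vm_init_mean, set$vm_init_sd)

  res <- simulate_core(
    n = network$N, n_exc = network$n_exc, K = network$K, K_E = network$K_E,
    sources = network$sources, weight_in = network$weights,
    csr_ptr = network$csr_ptr, csr_idx = network$csr_idx,
    n_steps = n_steps, delay_steps = delay_steps, ref_steps = ref_steps,
    prop = c(prop$e_s, prop$hs, prop$e_m, prop$p31, prop$p32),
    psc_norm = prop$psc_norm, v_th = np$v_th, v_reset = np$v_reset,
    v_init = v_init, nu_h = nu_ext * h, j_ext = set$J_E,
    stdp_lambda = stdp$lambda, stdp_mu = stdp$mu, stdp_alpha = stdp$alpha,
    stdp_tau_plus = stdp$tau_plus, stdp_tau_minus = stdp$tau_minus,
    stdp_w0 = w0, h = h, seed = config$seed,
    threshold_on = config$threshold,
    record_vm = config$record_vm,
    vm_warmup_steps = as.integer(round(config$vm_warmup_ms / h)),
    return_weights = config$return_weights,
    ext_counts_in = config$ext_counts)

  out <- list(
    spikes = data.frame(gid = res$spike_gid,
                        time_ms = res$spike_step * h),
    rates = res$counts / (config$duration_ms / 1000),
    mean_rate = mean(res$counts) / (config$duration_ms / 1000),
    vm_mean = res$vm_mean,
    n_steps = n_steps,
    seed = config$seed)
  if (config$record_vm) out$vm <- res$vm
  if (config$return_weights) out$weights <- res$weights
  out
}
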