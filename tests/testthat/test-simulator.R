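# deterministic-initialisation variant of a parameter set (V(0) = 0)
quiet_set <- function(set = benchmark_set(2)) {
  set$vm_init_mean <- 0
  set$vm_init_sd <- 1e-12
  set
}

test_that("exact propagator matches an adaptive ODE oracle to 1e-9", {
  np <- neuron_params()
  h <- 0.1
  pr <- lif_propagator(np, h)
  state <- c(y1 = 3.7, y2 = -1.2, V = 5.4)
  n_steps <- 1000  # 100 ms
  traj <- matrix(0, n_steps, 3)
  s <- state
  for (t in seq_len(n_steps)) {
    v <- pr$e_m * s["V"] + pr$p31 * s["y1"] + pr$p32 * s["y2"]
    s <- c(y1 = unname(pr$e_s * s["y1"]),
           y2 = unname(pr$e_s * s["y2"] + pr$hs * s["y1"]),
           V = unname(v))
    traj[t, ] <- s
  }
  rhs <- function(t, y, p) {
    list(c(-y[1] / np$tau_syn,
           y[1] - y[2] / np$tau_syn,
           -y[3] / np$tau_m + y[2] / np$c_m))
  }
  sol <- deSolve::lsoda(state, seq(0, n_steps * h, by = h), rhs, NULL,
                        rtol = 1e-13, atol = 1e-13)
  ref <- sol[-1, c("y1", "y2", "V")]
  scale <- max(abs(state))
  expect_lt(max(abs(traj - ref)) / scale, 1e-9)

  # h -> 0: the one-step map approaches the identity
  pr0 <- lif_propagator(np, 1e-9)
  expect_equal(pr0$e_s, 1, tolerance = 1e-8)
  expect_equal(pr0$e_m, 1, tolerance = 1e-8)
  expect_lt(abs(pr0$p31) + abs(pr0$p32), 1e-8)

  # confluent case tau_m = tau_syn has a finite closed form
  npc <- neuron_params(tau_m = 2, tau_syn = 2)
  prc <- lif_propagator(npc, h)
  expect_true(all(is.finite(unlist(prc))))
  expect_equal(prc$p32, h * exp(-h / 2) / npc$c_m)
})

test_that("a single spike produces an alpha current peaking at the weight", {
  np <- neuron_params()
  h <- 0.001
  pr <- lif_propagator(np, h)
  J <- 45.61
  y1 <- J * pr$psc_norm  # spike of weight J enters y1 as J*e/tau_syn
  y2 <- 0
  n <- 3000
  cur <- numeric(n)
  for (t in seq_len(n)) {
    y2 <- pr$e_s * y2 + pr$hs * y1
    y1 <- pr$e_s * y1
    cur[t] <- y2
  }
  tt <- seq_len(n) * h
  closed <- J * exp(1) * (tt / np$tau_syn) * exp(-tt / np$tau_syn)
  expect_lt(max(abs(cur - closed)) / J, 1e-3)
  expect_equal(max(cur), J, tolerance = 1e-3)
  expect_equal(tt[which.max(cur)], np$tau_syn, tolerance = 5e-3)
})

test_that("no input and resting initialisation produce no spikes", {
  net <- manual_network(integer(0), N = 20, n_exc = 16, set = quiet_set())
  r <- simulate_network(net, sim_config(duration_ms = 100, nu_ext = 0,
                                        stdp = stdp_params(lambda = 0)))
  expect_equal(nrow(r$spikes), 0)
  expect_equal(max(abs(r$vm_mean)), 0)
})

test_that("free membrane potential settles at eta * V_th under set-1 drive", {
  set <- benchmark_set(1)
  net <- manual_network(integer(0), N = 300, n_exc = 240, set = set)
  r <- simulate_network(net, sim_config(duration_ms = 1000, threshold = FALSE,
                                        vm_warmup_ms = 200, seed = 5,
                                        stdp = stdp_params(lambda = 0)))
  target <- set$eta * set$neuron$v_th  # 33.7 mV
  se <- stats::sd(r$vm_mean) / sqrt(length(r$vm_mean))
  expect_lt(abs(mean(r$vm_mean) - target), 3 * se + 0.01 * target)
})

test_that("external Poisson streams have the right moments and reproduce", {
  counts <- external_input(nu_ext = 2.0, h = 0.1, n_steps = 1e5,
                           seed = 3, gid = 17)
  lam <- 0.2
  se <- sqrt(lam / 1e5)
  expect_lt(abs(mean(counts) - lam), 3 * se)
  expect_lt(abs(stats::var(counts) - lam), 5 * se)
  expect_identical(counts,
                   external_input(2.0, 0.1, 1e5, seed = 3, gid = 17))
  expect_false(identical(counts,
                         external_input(2.0, 0.1, 1e5, seed = 3, gid = 18)))
  expect_equal(sum(external_input(0, 0.1, 100)), 0)
  # set-1 drive: eta*V_th*C_m/(e*tau_syn*J_E*tau_m) ~ 20856 spikes/s
  expect_equal(external_rate(benchmark_set(1)), 20856, tolerance = 1e-3)
})

# two-neuron pairing protocol: zero initial state, zero background drive,
# long refractory period so each external kick elicits exactly one spike
pair_set <- function() {
  s <- quiet_set()
  s$neuron <- neuron_params(t_ref = 3)
  s
}

test_that("spikes are delivered exactly one synaptic delay after emission", {
  # neuron 1 -> neuron 2 with a strong synapse; drive only neuron 1
  set <- pair_set()
  net <- manual_network(sources = c(2, 1), N = 2, n_exc = 2, K_E = 1,
                        set = set, weights = c(0.01, 10000))
  n_steps <- 400
  ext <- matrix(0L, 2, n_steps)
  ext[1, 50] <- 200L  # kick -> neuron 1 spikes once shortly after step 50
  cfg <- sim_config(duration_ms = n_steps * 0.1, nu_ext = 0,
                    stdp = stdp_params(lambda = 0), record_vm = TRUE,
                    ext_counts = ext)
  r <- simulate_network(net, cfg)
  s1 <- r$spikes[r$spikes$gid == 1, "time_ms"]
  expect_length(s1, 1)
  pre_step <- round(s1 / 0.1)
  # target potential deviates first at pre_step + delay + 1 (input enters
  # y1 at the arrival step, the voltage one step later)
  v2 <- r$vm[2, ]
  first_dev <- which(abs(v2) > 1e-9)[1]
  expect_equal(first_dev, pre_step + 15 + 1)
  # and the strong weight makes neuron 2 fire shortly after arrival
  s2 <- r$spikes[r$spikes$gid == 2, "time_ms"]
  expect_gte(min(s2), s1 + 1.5)
  expect_lt(min(s2), s1 + 1.5 + 1)
})

test_that("STDP weight changes match the scalar update formulas", {
  set <- pair_set()
  p <- stdp_params(lambda = 0.05, mu = 0.4, alpha = 0.0513,
                   tau_plus = 15, tau_minus = 30, w0 = set$J_E)
  # 1 -> 2 plastic (both excitatory); drive pre then post externally
  net <- manual_network(sources = c(2, 1), N = 2, n_exc = 2, K_E = 1,
                        set = set, weights = c(1e-3, 10))
  n_steps <- 600
  ext <- matrix(0L, 2, n_steps)
  ext[1, 100] <- 200L   # pre spike
  ext[2, 300] <- 200L   # post spike, long after the pre arrival
  cfg <- sim_config(duration_ms = n_steps * 0.1, nu_ext = 0, stdp = p,
                    return_weights = TRUE, ext_counts = ext)
  r <- simulate_network(net, cfg)
  expect_equal(sum(r$spikes$gid == 1), 1)
  expect_equal(sum(r$spikes$gid == 2), 1)
  pre_step <- round(r$spikes$time_ms[r$spikes$gid == 1][1] / 0.1)
  post_step <- round(r$spikes$time_ms[r$spikes$gid == 2][1] / 0.1)
  arrival <- pre_step + 15
  expect_gt(post_step, arrival)
  # presynaptic trace at the post spike: one arrival, decayed since
  x_pre <- exp(-(post_step - arrival) * 0.1 / p$tau_plus)
  expect_equal(r$weights[2], stdp_potentiate(10, x_pre, p),
               tolerance = 1e-12)
  # reverse synapse 2 -> 1: neuron 2's spike arrives after neuron 1
  # spiked, so it is depressed by the decayed postsynaptic trace
  arr_rev <- post_step + 15
  x_post1 <- exp(-(arr_rev - pre_step) * 0.1 / p$tau_minus)
  expect_equal(r$weights[1], stdp_depress(1e-3, x_post1, p),
               tolerance = 1e-12)

  # depression leg: post fires first, then the pre spike arrives
  ext2 <- matrix(0L, 2, n_steps)
  ext2[2, 100] <- 200L
  ext2[1, 120] <- 200L
  r2 <- simulate_network(net, sim_config(duration_ms = n_steps * 0.1,
                                         nu_ext = 0, stdp = p,
                                         return_weights = TRUE,
                                         ext_counts = ext2))
  t_post2 <- r2$spikes$time_ms[r2$spikes$gid == 2][1]
  t_pre2 <- r2$spikes$time_ms[r2$spikes$gid == 1][1]
  arr2 <- round(t_pre2 / 0.1) + 15
  x_post <- exp(-(arr2 - round(t_post2 / 0.1)) * 0.1 / p$tau_minus)
  expect_equal(r2$weights[2], stdp_depress(10, x_post, p), tolerance = 1e-12)
})

test_that("lambda = 0 leaves weights untouched and output identical to static", {
  set.seed(1)
  set <- benchmark_set(2)
  srcs <- matrix(0L, 5, 40)
  srcs[1:4, ] <- sample.int(32, 160, replace = TRUE)
  srcs[5, ] <- 32L + sample.int(8, 40, replace = TRUE)
  net <- manual_network(srcs, N = 40, n_exc = 32, K_E = 4, set = set)
  cfg0 <- sim_config(duration_ms = 300, seed = 11, stdp = stdp_params(lambda = 0),
                     return_weights = TRUE)
  r0 <- simulate_network(net, cfg0)
  expect_identical(r0$weights, net$weights)
  # plasticity switched on changes exc-exc weights but (small lambda) not spikes
  cfgp <- sim_config(duration_ms = 300, seed = 11, stdp = stdp_params(lambda = 0.1),
                     return_weights = TRUE)
  rp <- simulate_network(net, cfgp)
  expect_false(identical(rp$weights, net$weights))
  # inhibitory and exc->inh weights never move
  plastic <- rep(seq_len(40), each = 5) <= 32 & net$sources <= 32 &
    rep(1:5, 40) <= 4
  expect_identical(rp$weights[!plastic], net$weights[!plastic])
})

test_that("simulation is deterministic given the seed", {
  net <- build_network(2, N = 120, seed = 99, max_elements = 1e6)
  r1 <- simulate_network(net, sim_config(duration_ms = 200, seed = 4))
  r2 <- simulate_network(net, sim_config(duration_ms = 200, seed = 4))
  expect_identical(r1$spikes, r2$spikes)
  r3 <- simulate_network(net, sim_config(duration_ms = 200, seed = 5))
  expect_false(identical(r1$spikes, r3$spikes))
})
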