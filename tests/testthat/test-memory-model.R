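test_that("table parameter sets carry the published byte values", {
  p3 <- memory_params("3g")
  p4 <- memory_params("4g")
  expect_equal(unname(unlist(p3[c("m_n", "m0_n", "mplus_n", "mempty_n",
                                  "m_stat_c", "m_stdp_c", "m0_c", "m1_c",
                                  "mgt1_c", "mempty_c")])),
               c(1100, 1/3, 16, 0, 48, 48, 1/3, 96, 160, 0))
  expect_equal(unname(unlist(p4[c("m_n", "m0_n", "mplus_n", "mempty_n",
                                  "m_stat_c", "m_stdp_c", "m0_c", "m1_c",
                                  "mgt1_c", "mempty_c")])),
               c(1100, 0, 24, 0, 16, 24, 1/3, 24, 128, 0))
  # the condensed singleton infrastructure is far leaner than the old one
  expect_lt(p4$m1_c, p3$m1_c)
})

test_that("packaged parameter files reproduce the built-in tables", {
  for (gen in c("3g", "4g")) {
    from_file <- memory_params_from_file(generation = gen)
    expect_equal(unclass(from_file), unclass(memory_params(gen)))
  }
  # edited values are honoured
  tmp <- tempfile(fileext = ".conf")
  writeLines(c("generation = 4g", "beta = 0.5", "m1_c = 40"), tmp)
  p <- memory_params_from_file(tmp)
  expect_equal(p$m1_c, 40)
  expect_equal(p$beta, 0.5)
  expect_equal(p$m_stat_c, 16)  # untouched keys keep generation defaults
  writeLines(c("generation = 4g", "beta = 0.8", "nonsense = 1"), tmp)
  expect_error(memory_params_from_file(tmp), "unknown parameter")
})

test_that("base memory adds the M-proportional communication buffer", {
  b <- machine_budget(base_bytes = 268 * 2^20, buffer_entries = 1000,
                      buffer_entry_bytes = 4)
  expect_equal(base_memory(1, machine_budget(base_bytes = 5, buffer_entries = 0)), 5)
  expect_equal(base_memory(1e5, b) - b$base_bytes, 4e8)  # 1e5 * 1000 * 4 B
  expect_error(base_memory(0, b))
})

test_that("neuron memory splits objects and infrastructure as designed", {
  p3 <- memory_params("3g")
  p4 <- memory_params("4g")
  expect_equal(unname(neuron_memory(0, 10, p3)), c(0, 0))
  # N-proportional sparse-table term: 1/3 B * 1e9 = 318 binary MB
  nm <- neuron_memory(1e9, 1e6, p3)
  expect_equal((1e9 / 3) / 2^20, 318, tolerance = 5e-3)
  expect_gt(nm["infra"], 1e9 / 3)
  # 4g: no N-proportional term; 1000 local neurons cost 24 kB
  nm4 <- neuron_memory(1e6, 1000, p4)
  expect_equal(unname(nm4["infra"]), 1000 * 24)
  expect_equal(unname(nm4["objects"]), 1000 * 1100)
})

test_that("connection memory agrees with direct enumeration of random realizations", {
  # small instance: N = 100, M = 2, T = 2, K = 8
  N <- 100; M <- 2; T_ <- 2; K <- 8
  g <- machine_grid(M, T_)
  s <- network_shape(N, K, g)
  p <- memory_params("4g", beta = 0.8)
  cm <- connection_memory(g, s, p)

  set.seed(303)
  reps <- 2000
  draws_per_vp <- round(s$K_vp)
  # per-VP infrastructure cost of one realization, summed over T threads
  infra <- replicate(reps, {
    lens <- mc_list_lengths(N, draws_per_vp)
    T_ * (sum(lens == 1) * p$m1_c + sum(lens > 1) * p$mgt1_c)
  })
  model_infra <- cm$infra_singleton + cm$infra_multi
  se <- stats::sd(infra) / sqrt(reps)
  expect_lt(abs(mean(infra) - model_infra), 3 * se)

  # synapse-object bytes are deterministic given the counts
  K_M <- N / M * K
  expect_equal(cm$synapses_stdp, K_M * 0.64 * 24)
  expect_equal(cm$synapses_static, K_M * 0.36 * 16)
  expect_equal(cm$sparse_table, T_ * N / 3)
})

test_that("total memory is additive and monotone in N", {
  g <- machine_grid(100, 8)
  p <- memory_params("4g")
  b <- machine_budget()
  tot <- function(N) total_memory(g, network_shape(N, 5000, g), p, b)
  t1 <- tot(1e5)
  parts <- unlist(t1[setdiff(names(t1), "total")])
  expect_equal(t1$total, sum(parts))
  expect_equal(t1$base + t1$buffer, base_memory(100, b))
  expect_gt(tot(2e5)$total, t1$total)
  nm <- neuron_memory(1e5, 100, p)
  cm <- connection_memory(g, network_shape(1e5, 5000, g), p)
  expect_equal(t1$total,
               base_memory(100, b) + sum(nm) + cm$total)
})

test_that("max_network_size brackets the budget and matches a linear scan", {
  g <- machine_grid(8, 4)
  p <- memory_params("4g")
  K <- 500
  b <- machine_budget(budget_bytes = 60e6, base_bytes = 1e6,
                      buffer_entries = 100)
  nmax <- max_network_size(g, K, p, b)
  tot <- function(N) total_memory(g, network_shape(N, K, g), p, b)$total
  expect_lte(tot(nmax), b$budget_bytes)
  expect_gt(tot(nmax + 1), b$budget_bytes)
  # coarse-then-fine scan oracle
  Ns <- seq(32, nmax + 64, by = 32)
  feas <- vapply(Ns, function(N) tot(N) <= b$budget_bytes, logical(1))
  coarse <- max(Ns[feas])
  fine <- coarse
  while (tot(fine + 1) <= b$budget_bytes) fine <- fine + 1
  expect_equal(nmax, fine)

  # budget at base memory leaves room for nothing
  b0 <- machine_budget(budget_bytes = base_memory(8, b), base_bytes = 1e6,
                       buffer_entries = 100)
  expect_equal(max_network_size(g, K, p, b0), 0)
  expect_error(max_network_size(g, K, p,
    machine_budget(budget_bytes = 10, base_bytes = 1e6)), "infeasible")
})

test_that("solver responds correctly to in-degree and budget", {
  g <- machine_grid(16, 8)
  p <- memory_params("4g")
  b1 <- machine_budget(budget_bytes = 1e9)
  b2 <- machine_budget(budget_bytes = 2e9)
  n_k1 <- max_network_size(g, 1000, p, b1)
  n_k2 <- max_network_size(g, 4000, p, b1)
  expect_gte(n_k1, n_k2)                 # nonincreasing in K
  expect_gte(max_network_size(g, 1000, p, b2), n_k1)  # nondecreasing in budget
})

test_that("per-process growth with machine size is confined to buffer and sparse table (4g)", {
  p <- memory_params("4g")
  b <- machine_budget()
  N_vp <- 2000
  K <- 5000
  tots <- lapply(c(64, 256, 1024), function(M) {
    g <- machine_grid(M, 8)
    total_memory(g, network_shape(N_vp * g$VP, K, g), p, b)
  })
  # neuron objects and synapse bytes per process stay constant
  for (f in c("neuron_objects", "neuron_infra", "synapses_static", "synapses_stdp")) {
    vals <- vapply(tots, `[[`, numeric(1), f)
    expect_equal(max(vals) / min(vals), 1, tolerance = 1e-6)
  }
  # buffer and sparse table grow
  expect_true(all(diff(vapply(tots, `[[`, numeric(1), "buffer")) > 0))
  expect_true(all(diff(vapply(tots, `[[`, numeric(1), "sparse_table")) > 0))
})
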