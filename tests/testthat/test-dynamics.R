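test_that("chemical activation is a bounded increasing sigmoid", {
  expect_equal(chemical_activation(-0.25), 0.5)
  expect_equal(chemical_activation(0), 1 / (1 + exp(-2.5)), tolerance = 1e-12)
  expect_equal(chemical_activation(1e3), 1)
  expect_equal(chemical_activation(-1e3), 0)
  p <- seq(-2, 2, 0.05)
  expect_true(all(diff(chemical_activation(p)) > 0))
  expect_true(all(chemical_activation(p) > 0 & chemical_activation(p) < 1))
})

test_that("uncoupled vector field reduces to independent single neurons", {
  # hand arithmetic at the origin
  net1 <- connectome(matrix(0, 1, 1))
  expect_equal(hr_vector_field(c(0, 0, 0, 0), net1),
               c(3.25, 1, 0.032, 0))
  # g_n = g_l = 0 on a coupled graph equals N independent copies
  set.seed(1)
  net <- ring_of_clusters(3, 4, k_ring = 2)
  st <- initial_state(net)
  f_coupled <- hr_vector_field(st, net, syn = synapse_params(g_n = 0, g_l = 0))
  f_single <- vapply(seq_len(net$n), function(i) {
    hr_vector_field(st[i + net$n * 0:3], net1)
  }, numeric(4))
  expect_equal(f_coupled, c(t(f_single)), tolerance = 1e-12)
})

test_that("electrical coupling vanishes on the synchronization manifold", {
  set.seed(2)
  net <- electrical_only_net(8)
  st <- c(rep(-1.1, 8), rep(-6.9, 8), rep(3.1, 8), rep(0, 8))
  f0 <- hr_vector_field(st, net, syn = synapse_params(g_l = 0))
  f1 <- hr_vector_field(st, net, syn = synapse_params(g_l = 1.7))
  expect_equal(f0, f1, tolerance = 1e-12)  # Laplacian rows sum to zero
})

test_that("initial state uses the printed base point with U[0, 0.5] jitter", {
  set.seed(3)
  st <- initial_state(10000)
  p <- st[1:10000]; q <- st[10001:20000]; n <- st[20001:30000]
  eta <- p + 1.30784489
  expect_true(all(eta >= 0 & eta <= 0.5))
  expect_equal(mean(eta), 0.25, tolerance = 0.01)
  # shared jitter: same draw on all three variables
  expect_equal(q + 7.32183132, eta, tolerance = 1e-9)
  expect_equal(n - 3.35299859, eta, tolerance = 1e-9)
  expect_equal(st[30001:40000], rep(0, 10000))
  # determinism
  set.seed(3)
  expect_identical(initial_state(10000), st)
})

test_that("compiled Euler step matches the R vector field exactly", {
  set.seed(4)
  net <- ring_of_clusters(3, 4, k_ring = 2)
  st <- initial_state(net)
  cfg <- sim_config(dt = 0.01, t_f = 1, t_t = 0.5, record_stride = 1)
  sim <- simulate_bdn(net, syn = synapse_params(g_n = 0.7, g_l = 1.2),
                      cfg = cfg, state = st)
  one <- st + cfg$dt * hr_vector_field(st, net, syn = synapse_params(g_n = 0.7, g_l = 1.2))
  N <- net$n
  expect_equal(sim$p[2, ], one[1:N], tolerance = 1e-14)
  expect_equal(sim$q[2, ], one[N + 1:N], tolerance = 1e-14)
  expect_equal(sim$n_slow[2, ], one[2 * N + 1:N], tolerance = 1e-14)
  expect_equal(sim$phi[2, ], one[3 * N + 1:N], tolerance = 1e-14)
})

test_that("simulations are deterministic and stay on the bounded attractor", {
  set.seed(5)
  net1 <- connectome(matrix(0, 1, 1))
  st <- initial_state(1)
  sim <- simulate_bdn(net1, cfg = sim_config(t_f = 1000, t_t = 300),
                      state = st)
  expect_lt(sim$max_abs_p, 2)
  expect_true(all(is.finite(sim$p)))
  # excitatory sign condition: (p - V_syn) < 0 after the transient
  expect_true(all(sim$p[!sim$transient, ] - 2 < 0))
  sim2 <- simulate_bdn(net1, cfg = sim_config(t_f = 1000, t_t = 300),
                       state = st)
  expect_identical(sim$p, sim2$p)
})

test_that("halving the step shrinks the trajectory error first-order", {
  set.seed(6)
  net <- ring_of_clusters(3, 4, k_ring = 2)
  st <- initial_state(net)
  syn <- synapse_params(g_n = 0.5, g_l = 0.5)
  p_at_end <- function(dt) {
    cfg <- sim_config(dt = dt, t_f = 5, t_t = 2.5,
                      record_stride = round(5 / dt))
    sim <- simulate_bdn(net, syn = syn, cfg = cfg, state = st)
    sim$p[nrow(sim$p), ]
  }
  ref <- p_at_end(0.000625)
  e1 <- max(abs(p_at_end(0.01) - ref))
  e2 <- max(abs(p_at_end(0.005) - ref))
  e3 <- max(abs(p_at_end(0.0025) - ref))
  expect_gt(e1 / e2, 1.5)  # ~2 for a first-order method
  expect_lt(e1 / e2, 3)
  expect_gt(e2 / e3, 1.5)
  expect_lt(e2 / e3, 3)
})

test_that("strong electrical coupling raises the order parameter", {
  set.seed(7)
  net <- electrical_only_net(12)
  st <- initial_state(net)
  cfg <- sim_config(t_f = 700, t_t = 300)
  rho_of <- function(gl) {
    simulate_bdn(net, syn = synapse_params(g_n = 0, g_l = gl),
                 cfg = cfg, state = st)$rho
  }
  r <- c(rho_of(0.01), rho_of(0.5), rho_of(2))
  expect_gt(r[3], r[1])
  # monotone tendency: allow estimator noise but no large decrease
  expect_gt(r[2], r[1] - 0.05)
  expect_gt(r[3], r[2] - 0.05)
})
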