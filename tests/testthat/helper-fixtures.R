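# Shared fixtures and independent oracles used across test files.

# a single-cluster electrical network (B empty) for coupling-sweep tests
electrical_only_net <- function(n = 12, k_ring = 4, p_rewire = 0.1) {
  A <- sw_cluster(n, k_ring, p_rewire)
  net <- connectome(A, B = matrix(0, n, n))
  net$labels <- rep(1L, n)
  net
}

# adjacency of two K4 cliques joined by a single edge (nodes 1-4 and 5-8)
two_cliques_adj <- function(clique_size = 4) {
  n <- 2 * clique_size
  A <- matrix(0, n, n)
  idx1 <- seq_len(clique_size)
  idx2 <- clique_size + idx1
  A[idx1, idx1] <- 1
  A[idx2, idx2] <- 1
  diag(A) <- 0
  A[clique_size, clique_size + 1] <- A[clique_size + 1, clique_size] <- 1
  A
}

# brute-force Newman-Girvan modularity: explicit sum over the e/a table
modularity_bruteforce <- function(A, labels) {
  m <- sum(A) / 2
  cls <- unique(labels)
  q <- 0
  for (cl in cls) {
    idx <- which(labels == cl)
    e_c <- sum(A[idx, idx]) / 2 / m
    a_c <- sum(A[idx, ]) / (2 * m)
    q <- q + e_c - a_c^2
  }
  q
}

# adjusted Rand index between two labelings (closed-form pair counting)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(length(a), 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# independent R reimplementation of the Benettin estimator for the coupled
# network, using a finite-difference Jacobian of hr_vector_field; mirrors
# the compiled schedule (renormalize every `ri` steps, discard the interval
# straddling the transient cutoff)
benettin_fd <- function(net, hr, syn, state0, dt, n_steps, n_trans, ri) {
  N <- net$n
  x <- state0
  m <- 3 * N
  u1 <- numeric(m); u1[1] <- 1
  u2 <- numeric(m); u2[min(2, m)] <- 1
  fd_jac_apply <- function(x, u) {
    eps <- 1e-6
    up <- c(u, rep(0, N))  # phi components do not feed back
    (hr_vector_field(x + eps * up, net, hr, syn)[1:m] -
       hr_vector_field(x - eps * up, net, hr, syn)[1:m]) / (2 * eps)
  }
  s1 <- s2 <- 0; t0 <- NA; t_acc <- 0
  started <- FALSE
  for (step in seq_len(n_steps)) {
    dx <- hr_vector_field(x, net, hr, syn)
    u1 <- u1 + dt * fd_jac_apply(x, u1)
    u2 <- u2 + dt * fd_jac_apply(x, u2)
    x <- x + dt * dx
    if (step %% ri == 0 || step == n_steps) {
      n1 <- sqrt(sum(u1^2)); u1 <- u1 / n1
      u2 <- u2 - sum(u2 * u1) * u1
      n2 <- sqrt(sum(u2^2)); u2 <- u2 / n2
      if (step > n_trans) {
        if (!started) {
          started <- TRUE; t0 <- step * dt
        } else {
          s1 <- s1 + log(n1); s2 <- s2 + log(n2)
          t_acc <- step * dt - t0
        }
      }
    }
  }
  l <- sort(c(s1, s2) / t_acc, decreasing = TRUE)
  list(lambda1 = l[1], lambda2 = l[2])
}

# synthetic evolution trace for slope/classification tests
fake_trace <- function(rho, cluster_mat) {
  structure(list(
    accepted_links = matrix(seq_len(2 * (length(rho) - 1)), ncol = 2),
    ic_history = seq(0.01, by = 0.001, length.out = length(rho)),
    rho_history = rho,
    cluster_sync_history = cluster_mat,
    n_candidates_tested = 10L,
    mMIR = 0.01 + 0.001 * (length(rho) - 1)),
    class = "bdn_evolution")
}
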