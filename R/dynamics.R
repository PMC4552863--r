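#' Hindmarsh-Rose single-neuron parameters
#'
#' Constants of the three-variable Hindmarsh-Rose model: `p` is the membrane
#' potential, `q` the fast (Na+/K+) current and `n` the slow (Ca2+) current.
#' The defaults put each neuron in the multi-scale chaotic spike-bursting
#' regime; `r` sets the slow timescale and must be positive.
#'
#' @param a,b,c,d,s dimensionless model constants.
#' @param p0 resting-potential offset.
#' @param I_ext external current.
#' @param r slow-timescale modulator (> 0).
#' @return a list of class `hr_params`.
#' @export
hr_params <- function(a = 1, b = 3, c = 1, d = 5, s = 4,
                      p0 = -1.6, I_ext = 3.25, r = 0.005) {
  if (r <= 0) stop("r must be positive")
  structure(list(a = a, b = b, c = c, d = d, s = s, p0 = p0,
                 I_ext = I_ext, r = r), class = "hr_params")
}

#' Synaptic coupling parameters
#'
#' The chemical synapse acts through the sigmoidal activation
#' `S(p) = 1 / (1 + exp(-lambda_sig (p - theta_syn)))` and enters the
#' membrane equation as `-g_n (p_i - V_syn) sum_j B_ij S(p_j)`; with the
#' default `V_syn = 2` and bounded potentials (`|p| < 2`) the coupling is
#' excitatory.  The electrical synapse is diffusive:
#' `-g_l sum_j G_ij p_j` with `G = K - A` the graph Laplacian of the
#' electrical adjacency.
#'
#' @param theta_syn sigmoid threshold.
#' @param lambda_sig sigmoid slope.
#' @param V_syn chemical reversal potential.
#' @param g_n chemical coupling strength (>= 0).
#' @param g_l electrical coupling strength (>= 0).
#' @return a list of class `synapse_params`.
#' @export
synapse_params <- function(theta_syn = -0.25, lambda_sig = 10, V_syn = 2,
                           g_n = 0, g_l = 0) {
  if (g_n < 0 || g_l < 0) stop("coupling strengths must be nonnegative")
  structure(list(theta_syn = theta_syn, lambda_sig = lambda_sig,
                 V_syn = V_syn, g_n = g_n, g_l = g_l),
            class = "synapse_params")
}

#' Simulation configuration
#'
#' Forward-Euler integration protocol: step `dt` (reference value 0.01),
#' final time `t_f`, and transient time `t_t` after which all statistics
#' (order parameter, Lyapunov accumulation, bounds) are computed.
#' `record_stride` controls how often samples are stored.
#'
#' @param dt integration step (> 0).
#' @param t_f final time.
#' @param t_t transient time (0 < t_t < t_f).
#' @param record_stride steps between stored samples.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, t_f = 2500, t_t = 300, record_stride = 10) {
  if (dt <= 0) stop("dt must be positive")
  if (!(t_t > 0 && t_t < t_f)) stop("need 0 < t_t < t_f")
  structure(list(dt = dt, t_f = t_f, t_t = t_t,
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}

#' Sigmoidal chemical synapse activation
#'
#' `S(p) = 1 / (1 + exp(-lambda_sig (p - theta_syn)))`, a continuous
#' activation/deactivation mechanism for the chemical synapses: strictly
#' increasing in `p`, bounded in (0, 1), with `S(theta_syn) = 1/2`.
#'
#' @param p membrane potential(s).
#' @param params a [synapse_params()] object.
#' @return activation value(s) in (0, 1).
#' @examples
#' chemical_activation(-0.25)  # 0.5 at the threshold
#' @export
chemical_activation <- function(p, params = synapse_params()) {
  1 / (1 + exp(-params$lambda_sig * (p - params$theta_syn)))
}

#' Seeded initial state near the attractor
#'
#' Each neuron starts at the base point `p = -1.30784489`,
#' `q = -7.32183132`, `n = 3.35299859` offset by a per-neuron jitter
#' `eta_i ~ U[0, 0.5]`; phases start at 0.  By default the same draw
#' `eta_i` is added to all three variables of neuron `i`
#' (`jitter = "shared"`); `jitter = "independent"` draws separately per
#' variable.  These initial conditions land close to the chaotic attractor,
#' keeping the needed transient short.
#'
#' @param n_neurons number of neurons (or a [connectome]).
#' @param jitter `"shared"` or `"independent"`.
#' @return numeric vector `c(p, q, n, phi)` of length `4 * n_neurons`.
#' @export
initial_state <- function(n_neurons, jitter = c("shared", "independent")) {
  jitter <- match.arg(jitter)
  if (inherits(n_neurons, "connectome")) n_neurons <- n_neurons$n
  base <- c(p = -1.30784489, q = -7.32183132, n = 3.35299859)
  if (jitter == "shared") {
    eta <- runif(n_neurons, 0, 0.5)
    ep <- eq <- en <- eta
  } else {
    ep <- runif(n_neurons, 0, 0.5)
    eq <- runif(n_neurons, 0, 0.5)
    en <- runif(n_neurons, 0, 0.5)
  }
  c(base["p"] + ep, base["q"] + eq, base["n"] + en, rep(0, n_neurons))
}

#' Coupled network vector field
#'
#' Time derivatives of the full state `(p, q, n, phi)` of the coupled
#' Hindmarsh-Rose network.  The electrical term is `-g_l G p` with
#' `G = K - A`; the chemical term is `-g_n (p_i - V_syn) sum_j B_ij S(p_j)`;
#' the phase obeys `phi_i' = (q_i' p_i - p_i' q_i) / (p_i^2 + q_i^2)`
#' (set to 0 where the denominator vanishes).  This reference R
#' implementation backs tests and cross-checks of the compiled integrator.
#'
#' @param state numeric vector `c(p, q, n, phi)` of length `4 N`.
#' @param net a [connectome].
#' @param hr [hr_params()].
#' @param syn [synapse_params()].
#' @return derivative vector of the same length/layout as `state`.
#' @export
hr_vector_field <- function(state, net, hr = hr_params(),
                            syn = synapse_params()) {
  N <- net$n
  stopifnot(length(state) == 4 * N)
  p <- state[1:N]; q <- state[N + 1:N]; nn <- state[2 * N + 1:N]
  Sp <- chemical_activation(p, syn)
  kA <- rowSums(net$A)
  dp <- q - hr$a * p^3 + hr$b * p^2 - nn + hr$I_ext -
    syn$g_n * (p - syn$V_syn) * drop(net$B %*% Sp) -
    syn$g_l * (kA * p - drop(net$A %*% p))
  dq <- hr$c - hr$d * p^2 - q
  dn <- hr$r * (hr$s * (p - hr$p0) - nn)
  denom <- p^2 + q^2
  dphi <- ifelse(denom > 0, (dq * p - dp * q) / denom, 0)
  c(dp, dq, dn, dphi)
}

#' Simulate a brain dynamical network
#'
#' Forward-Euler integration of the coupled Hindmarsh-Rose network.
#' Samples with `time < t_t` are flagged transient and excluded from all
#' downstream statistics.
#'
#' @param net a [connectome].
#' @param hr [hr_params()].
#' @param syn [synapse_params()].
#' @param cfg [sim_config()].
#' @param state optional initial state (default: [initial_state()] drawn
#'   from the current RNG).
#' @return an object of class `bdn_sim` with elements `times`, matrices
#'   `p`, `q`, `n_slow`, `phi` (samples x neurons), logical `transient`,
#'   `rho` (post-transient time-averaged order parameter), `max_abs_p`
#'   (post-transient bound, evaluated every step) and the configuration.
#' @examples
#' set.seed(1)
#' net <- ring_of_clusters(3, 5)
#' sim <- simulate_bdn(net, cfg = sim_config(t_f = 400, t_t = 300))
#' sim$max_abs_p < 2
#' @export
simulate_bdn <- function(net, hr = hr_params(), syn = synapse_params(),
                         cfg = sim_config(), state = NULL) {
  if (is.null(state)) state <- initial_state(net)
  n_steps <- round(cfg$t_f / cfg$dt)
  n_trans <- round(cfg$t_t / cfg$dt)
  res <- hr_run_cpp(net$A, net$B, state, unclass(hr), unclass(syn),
                    cfg$dt, n_steps, n_trans,
                    stride = cfg$record_stride, want_lyap = FALSE,
                    renorm_interval = 10L)
  structure(
    list(times = res$times, p = res$p, q = res$q, n_slow = res$n_slow,
         phi = res$phi, transient = res$times < cfg$t_t,
         rho = res$rho, max_abs_p = res$max_abs_p,
         net = net, hr = hr, syn = syn, cfg = cfg),
    class = "bdn_sim")
}

#' @export
print.bdn_sim <- function(x, ...) {
  cat("BDN simulation:", x$net$n, "neurons,",
      length(x$times), "recorded samples (dt =", x$cfg$dt,
      ", t_f =", x$cfg$t_f, ", transient", x$cfg$t_t, ")\n")
  cat("  post-transient order parameter rho =", signif(x$rho, 4), "\n")
  cat("  post-transient max |p| =", signif(x$max_abs_p, 4), "\n")
  invisible(x)
}

#' @export
plot.bdn_sim <- function(x, neurons = 1, ...) {
  keep <- !x$transient
  graphics::matplot(x$times[keep], x$p[keep, neurons, drop = FALSE],
                    type = "l", lty = 1, xlab = "time",
                    ylab = "membrane potential p", ...)
  invisible(x)
}

# post-transient phase matrix of a simulation
post_transient_phases <- function(sim) {
  sim$phi[!sim$transient, , drop = FALSE]
}
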