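#' Two largest Lyapunov exponents of a brain dynamical network
#'
#' Tangent-space (Benettin) estimation: two tangent vectors in the
#' `3 N`-dimensional `(p, q, n)` space are evolved under the analytic
#' Jacobian of the coupled system alongside the trajectory, and
#' re-orthonormalized (Gram-Schmidt) every `renorm_interval` Euler steps.
#' Exponents are the time-averaged log stretch factors accumulated after the
#' transient.  Phases are excluded from the variational system — they never
#' feed back into `(p, q, n)` and would only contribute a spurious neutral
#' direction.
#'
#' @param net a [connectome].
#' @param hr [hr_params()].
#' @param syn [synapse_params()].
#' @param cfg [sim_config()].
#' @param state optional initial state (default drawn from the current RNG).
#' @param renorm_interval Gram-Schmidt cadence in Euler steps.
#' @param record_phases if `TRUE`, strided post-hoc phases are returned so
#'   synchronization measures can be computed from the same run.
#' @return an object of class `bdn_lyapunov`: `lambda1 >= lambda2`, the
#'   information flow capacity `ic = lambda1 - lambda2`, the running-estimate
#'   `history` data frame, the post-transient order parameter `rho`, and
#'   (optionally) recorded `phi` / `times`.
#' @examples
#' set.seed(1)
#' net <- connectome(matrix(0, 1, 1))  # single uncoupled neuron
#' est <- lyapunov_exponents(net, cfg = sim_config(t_f = 600, t_t = 300))
#' est$ic >= 0
#' @export
lyapunov_exponents <- function(net, hr = hr_params(), syn = synapse_params(),
                               cfg = sim_config(), state = NULL,
                               renorm_interval = 10, record_phases = FALSE) {
  if (is.null(state)) state <- initial_state(net)
  n_steps <- round(cfg$t_f / cfg$dt)
  n_trans <- round(cfg$t_t / cfg$dt)
  res <- hr_run_cpp(net$A, net$B, state, unclass(hr), unclass(syn),
                    cfg$dt, n_steps, n_trans,
                    stride = if (record_phases) cfg$record_stride else 0L,
                    want_lyap = TRUE,
                    renorm_interval = as.integer(renorm_interval))
  if (res$n_degenerate > 0)
    warning("reinitialized a degenerate tangent vector ",
            res$n_degenerate, " time(s)")
  structure(
    list(lambda1 = res$lambda1, lambda2 = res$lambda2,
         ic = info_capacity(res$lambda1, res$lambda2),
         history = res$history, rho = res$rho,
         max_abs_p = res$max_abs_p,
         times = res$times, phi = res$phi,
         cfg = cfg, renorm_interval = renorm_interval),
    class = "bdn_lyapunov")
}

#' Information flow capacity from the two largest exponents
#'
#' The mutual information rate between any two nodes of a connected network
#' is bounded above by `Ic = lambda1 - lambda2` (`lambda1 >= lambda2`), the
#' network's information flow capacity.
#'
#' @param lambda1 largest Lyapunov exponent.
#' @param lambda2 second largest exponent (must not exceed `lambda1`).
#' @return nonnegative scalar `lambda1 - lambda2`.
#' @examples
#' info_capacity(0.03, 0.01)  # 0.02
#' @export
info_capacity <- function(lambda1, lambda2) {
  if (any(lambda2 > lambda1 + 1e-15))
    stop("lambda1 must be >= lambda2 (arguments in the wrong order?)")
  lambda1 - lambda2
}

#' @export
print.bdn_lyapunov <- function(x, ...) {
  cat("Lyapunov estimate (tangent-space method):\n")
  cat("  lambda1 =", signif(x$lambda1, 5),
      " lambda2 =", signif(x$lambda2, 5), "\n")
  cat("  information flow capacity Ic =", signif(x$ic, 5), "\n")
  if (!is.null(x$rho) && is.finite(x$rho))
    cat("  order parameter rho =", signif(x$rho, 4), "\n")
  invisible(x)
}

#' @export
plot.bdn_lyapunov <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$time, cbind(h$lambda1, h$lambda2), type = "l",
                    lty = 1, col = c("black", "grey50"),
                    xlab = "time", ylab = "running exponent estimate", ...)
  graphics::legend("topright", c("lambda1", "lambda2"), lty = 1,
                   col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Export a convergence history to CSV
#' @param x a `bdn_lyapunov` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lyapunov_history <- function(x, path) {
  write.table(x$history, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Benettin exponents of a constant-coefficient linear system
#'
#' Runs the same Euler + Gram-Schmidt tangent machinery on `x' = M x`,
#' whose two largest Lyapunov exponents equal the two largest real parts of
#' the eigenvalues of `M`.  Used to validate the estimator against a
#' closed-form oracle.
#'
#' @param M square coefficient matrix (dimension >= 2).
#' @param dt Euler step.
#' @param t_f total integration time.
#' @param t_t transient discarded before accumulating (lets the tangent
#'   vectors align with the dominant directions first).
#' @param renorm_interval Gram-Schmidt cadence in steps.
#' @return list with `lambda1 >= lambda2`.
#' @examples
#' lyapunov_linear(diag(c(0.1, -0.05, -0.2)))
#' @export
lyapunov_linear <- function(M, dt = 0.001, t_f = 100, t_t = t_f / 10,
                            renorm_interval = 10) {
  M <- as.matrix(M)
  res <- lyap_linear_cpp(M, dt, as.integer(round(t_f / dt)),
                         as.integer(round(t_t / dt)),
                         as.integer(renorm_interval))
  list(lambda1 = res$lambda1, lambda2 = res$lambda2)
}
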