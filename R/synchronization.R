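#' Kuramoto order parameter of a phase record
#'
#' The population phasor `z(t) = (1/N) sum_j exp(i phi_j(t))` has modulus
#' `rho(t)` in `[0, 1]`: 1 means complete phase synchronization, 0 complete
#' desynchronization.  The scalar order parameter `rho` is the time average
#' of `rho(t)` over the supplied (post-transient) samples.
#'
#' @param phases matrix of unwrapped phases (samples x neurons), or a
#'   `bdn_sim` object (post-transient samples are used).
#' @return list with `rho_t` (instantaneous series), `rho` (time average)
#'   and `Phi_t` (mean-phase series).
#' @examples
#' ph <- matrix(rep(seq(0, 10, 0.1), 3), ncol = 3)  # identical phases
#' order_parameter(ph)$rho  # exactly 1
#' @export
order_parameter <- function(phases) {
  phases <- phase_matrix(phases)
  if (length(phases) == 0) stop("empty phase series")
  z <- rowMeans(exp(1i * phases))
  list(rho_t = Mod(z), rho = mean(Mod(z)), Phi_t = Arg(z))
}

phase_matrix <- function(phases) {
  if (inherits(phases, "bdn_sim")) phases <- post_transient_phases(phases)
  if (is.null(dim(phases))) phases <- matrix(phases, ncol = 1)
  phases
}

#' Pairwise phase synchronization matrix
#'
#' For each connected pair (`C_ij = 1`) the synchronization level is the
#' modulus of the time-averaged phasor of the phase difference,
#' `rho_ij = |<exp(i (phi_i - phi_j))>_t|`, a finite-window surrogate for
#' the infinite-window average.  Unconnected pairs are masked to 0 by the
#' combined adjacency.
#'
#' @param phases matrix of unwrapped phases (samples x neurons) or `bdn_sim`.
#' @param net a [connectome] (supplies the combined adjacency mask `C`).
#' @return symmetric `N x N` matrix with entries in `[0, 1]`, zero wherever
#'   `C_ij = 0`.
#' @export
pairwise_sync <- function(phases, net) {
  phases <- phase_matrix(phases)
  if (nrow(phases) < 10)
    stop("averaging window shorter than 10 recorded samples")
  if (ncol(phases) != net$n)
    stop("phase record and connectome disagree on neuron count")
  E <- exp(1i * phases)
  # mean_t exp(i(phi_i - phi_j)) for all pairs via one crossproduct
  Z <- crossprod(Conj(E), E) / nrow(phases)
  out <- Mod(Z) * net$C
  diag(out) <- 0
  out
}

#' Per-cluster mean pairwise synchronization
#'
#' Average of `rho_ij` over connected intra-cluster pairs (`i < j`,
#' `C_ij = 1`) for each cluster.  A cluster with no internal links gets
#' `NA` (undefined, not zero).
#'
#' @param rho_pair matrix from [pairwise_sync()].
#' @param labels integer cluster label per neuron.
#' @param C combined adjacency used to select connected pairs (defaults to
#'   `rho_pair > 0`, which reproduces the mask applied by
#'   [pairwise_sync()]).
#' @return named numeric vector of per-cluster means `<rho_ij>_cl`.
#' @export
cluster_mean_sync <- function(rho_pair, labels, C = NULL) {
  if (length(labels) != nrow(rho_pair))
    stop("labels must cover all neurons")
  if (is.null(C)) C <- (rho_pair > 0) * 1
  cls <- sort(unique(labels))
  out <- vapply(cls, function(cl) {
    idx <- which(labels == cl)
    sub <- rho_pair[idx, idx, drop = FALSE]
    msk <- C[idx, idx, drop = FALSE] * upper.tri(sub)
    if (sum(msk) == 0) return(NA_real_)
    sum(sub[msk == 1]) / sum(msk)
  }, numeric(1))
  names(out) <- paste0("cluster_", cls)
  out
}

#' Export a pairwise synchronization matrix
#'
#' Writes either the dense matrix or a long-format `(i, j, value)` table
#' suitable for heatmap plotting.
#'
#' @param rho_pair matrix from [pairwise_sync()].
#' @param path output CSV path.
#' @param long if `TRUE`, write long format (upper triangle only).
#' @return `path`, invisibly.
#' @export
write_pairwise_sync <- function(rho_pair, path, long = FALSE) {
  if (long) {
    ij <- which(upper.tri(rho_pair), arr.ind = TRUE)
    df <- data.frame(i = ij[, 1], j = ij[, 2], value = rho_pair[ij])
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    write.table(rho_pair, path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
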