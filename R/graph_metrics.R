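#' Small-worldness against degree-preserving surrogates
#'
#' Computes `mu = L / <L_r>` and `gamma = C / <C_r>` where `C` is the mean
#' local clustering coefficient, `L` the mean shortest path length, and the
#' reference values are averaged over `n_random` random graphs with the
#' same degree sequence (connected configuration-model draws, with a
#' degree-preserving rewiring fallback).  The small-worldness measure is
#' `sigma_sw = gamma / mu`; values above 1 indicate small-world structure.
#'
#' @param adj adjacency matrix or [connectome] (combined adjacency);
#'   must be connected.
#' @param n_random number of surrogate graphs (default 100).
#' @return list with `mu`, `gamma`, `sigma_sw`, `C`, `L`, `C_rand`,
#'   `L_rand`.
#' @export
small_worldness <- function(adj, n_random = 100) {
  g <- as_igraph(adj)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  C <- mean_local_clustering(g)
  L <- igraph::mean_distance(g)
  deg <- igraph::degree(g)
  Cr <- Lr <- numeric(n_random)
  for (i in seq_len(n_random)) {
    gr <- degree_matched_surrogate(g, deg)
    Cr[i] <- mean_local_clustering(gr)
    Lr[i] <- igraph::mean_distance(gr)  # largest component if disconnected
  }
  mu <- L / mean(Lr)
  gamma <- C / mean(Cr)
  list(mu = mu, gamma = gamma, sigma_sw = gamma / mu,
       C = C, L = L, C_rand = mean(Cr), L_rand = mean(Lr))
}

mean_local_clustering <- function(g) {
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

# random graph with the same degree sequence; "vl" draws connected simple
# graphs, rewiring is the fallback for degree sequences it cannot handle
degree_matched_surrogate <- function(g, deg, max_tries = 20) {
  for (i in seq_len(max_tries)) {
    gr <- tryCatch(
      igraph::sample_degseq(deg, method = "vl"),
      error = function(e) NULL)
    if (!is.null(gr)) return(gr)
  }
  igraph::rewire(g, igraph::keeping_degseq(niter = 20 * igraph::ecount(g)))
}

#' Walktrap community detection
#'
#' Agglomerative community detection driven by short random walks (walk
#' length `steps`, default 6), with the dendrogram cut at maximum
#' modularity.  Singleton communities are reported so callers can exclude
#' them from cluster-level statistics as trivial.
#'
#' @param adj adjacency matrix or [connectome].
#' @param steps random-walk length.
#' @return list with integer `membership`, `n_communities`, `modularity`
#'   of the cut, and indices of `singletons`.
#' @export
detect_communities <- function(adj, steps = 6) {
  g <- as_igraph(adj)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  wt <- igraph::cluster_walktrap(g, steps = steps)
  mem <- igraph::membership(wt)
  sizes <- table(mem)
  list(membership = as.integer(mem),
       n_communities = length(sizes),
       modularity = igraph::modularity(g, mem),
       singletons = as.integer(names(sizes)[sizes == 1]))
}

#' Newman-Girvan modularity of a partition
#'
#' Standard modularity `Q = sum_c (e_c - a_c^2)` of the given node
#' partition: the fraction of edges inside each community minus the
#' expectation under the degree-preserving null model.
#'
#' @param adj adjacency matrix or [connectome].
#' @param labels community label per node.
#' @return scalar `Q` in `[-0.5, 1]`.
#' @export
graph_modularity <- function(adj, labels) {
  g <- as_igraph(adj)
  if (length(labels) != igraph::vcount(g))
    stop("labels must cover all nodes")
  igraph::modularity(g, labels)
}

#' Smallest positive eigenvalue of the electrical Laplacian
#'
#' `omega_m`, the smallest nonzero eigenvalue of `G = K - A`, used to
#' rescale the electrical coupling across networks with different spectra.
#'
#' @param A electrical adjacency matrix or [connectome] (its `A`).
#' @param tol eigenvalues below `tol` are treated as zero.
#' @return scalar `omega_m`.
#' @export
electrical_spectral_gap <- function(A, tol = 1e-9) {
  if (inherits(A, "connectome")) A <- A$A
  A <- as_binary_adj(A)
  G <- diag(rowSums(A)) - A
  ev <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  pos <- ev[ev > tol]
  if (length(pos) == 0) stop("Laplacian has no positive eigenvalue")
  pos[1]
}

#' Rescale maximum coupling strengths between networks
#'
#' Transfers a reference parameter-space extent to a new network: the
#' maximum chemical coupling scales with the ratio of average chemical
#' degrees, `g_n^max = (dbar_ref / dbar_target) g_n_ref`, and the maximum
#' electrical coupling with the ratio of the smallest positive electrical
#' Laplacian eigenvalues, `g_l^max = (omega_ref / omega_target) g_l_ref`.
#'
#' @param g_n_ref,g_l_ref reference maximum couplings.
#' @param dbar_ref,dbar_target average chemical degrees.
#' @param omega_ref,omega_target smallest positive electrical Laplacian
#'   eigenvalues.
#' @return list with `g_n_max` and `g_l_max` for the target network.
#' @examples
#' rescale_couplings(0.3, 2, dbar_ref = 7, dbar_target = 14,
#'                   omega_ref = 1, omega_target = 1)
#' @export
rescale_couplings <- function(g_n_ref, g_l_ref, dbar_ref, dbar_target,
                              omega_ref, omega_target) {
  vals <- c(g_n_ref, g_l_ref, dbar_ref, dbar_target, omega_ref,
            omega_target)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rescaling inputs must be positive")
  list(g_n_max = (dbar_ref / dbar_target) * g_n_ref,
       g_l_max = (omega_ref / omega_target) * g_l_ref)
}

#' Degree-resolved structural profiles
#'
#' Profiles over the normalized degree `kbar = k / k_max` (exact rational
#' degree classes, no histogram binning): the degree distribution
#' `pdf(kbar)`, the mean local clustering coefficient `CC(kbar)`, and the
#' mean normalized neighbor degree `knn(kbar)`.
#'
#' @param adj adjacency matrix or [connectome].
#' @return data frame with columns `kbar`, `pdf`, `cc`, `knn`.
#' @export
degree_profiles <- function(adj) {
  g <- as_igraph(adj)
  deg <- igraph::degree(g)
  if (length(deg) == 0) stop("empty graph")
  kmax <- max(deg)
  kbar <- deg / kmax
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  knn_node <- vapply(seq_along(deg), function(i) {
    nb <- as.integer(igraph::neighbors(g, i))
    if (length(nb) == 0) return(NA_real_)
    mean(deg[nb]) / kmax
  }, numeric(1))
  classes <- sort(unique(kbar))
  data.frame(
    kbar = classes,
    pdf = vapply(classes, function(k) mean(kbar == k), numeric(1)),
    cc = vapply(classes, function(k) mean(cc[kbar == k]), numeric(1)),
    knn = vapply(classes, function(k) mean(knn_node[kbar == k]),
                 numeric(1)))
}

#' Full structural characterization of a network
#'
#' Bundles small-worldness, walktrap communities, modularity and the
#' degree-resolved profiles into one report.
#'
#' @param adj adjacency matrix or [connectome].
#' @param n_random surrogates for the small-worldness null model.
#' @param walktrap_steps random-walk length for community detection.
#' @return object of class `structure_report`.
#' @export
structure_report <- function(adj, n_random = 100, walktrap_steps = 6) {
  sw <- small_worldness(adj, n_random)
  com <- detect_communities(adj, walktrap_steps)
  structure(
    list(C = sw$C, L = sw$L, mu = sw$mu, gamma = sw$gamma,
         sigma_sw = sw$sigma_sw,
         modularity = com$modularity,
         community_labels = com$membership,
         n_communities = com$n_communities,
         singletons = com$singletons,
         profiles = degree_profiles(adj)),
    class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("Structural report:\n")
  cat("  mean local clustering C =", signif(x$C, 4),
      "| mean shortest path L =", signif(x$L, 4), "\n")
  cat("  small-worldness sigma =", signif(x$sigma_sw, 4),
      "(gamma =", signif(x$gamma, 4), ", mu =", signif(x$mu, 4), ")\n")
  cat("  walktrap communities:", x$n_communities,
      "| modularity Q =", signif(x$modularity, 4), "\n")
  if (length(x$singletons))
    cat("  singleton communities (excluded as trivial):",
        paste(x$singletons, collapse = ", "), "\n")
  invisible(x)
}

#' Write a structure report to disk
#'
#' Flat key-value text file for the scalars plus a CSV for the
#' degree-resolved profiles and a node,label CSV for communities.
#'
#' @param x a `structure_report`.
#' @param path base path; `<path>.txt`, `<path>_profiles.csv` and
#'   `<path>_communities.csv` are written.
#' @return `path`, invisibly.
#' @export
write_structure_report <- function(x, path) {
  keys <- c(C = x$C, L = x$L, mu = x$mu, gamma = x$gamma,
            sigma_sw = x$sigma_sw, modularity = x$modularity,
            n_communities = x$n_communities)
  writeLines(paste(names(keys), keys, sep = " = "),
             paste0(path, ".txt"))
  write.table(x$profiles, paste0(path, "_profiles.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write.table(
    data.frame(node = seq_along(x$community_labels),
               label = x$community_labels),
    paste0(path, "_communities.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}
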