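#' Connectome objects
#'
#' A connectome couples a brain dynamical network through two symmetric
#' binary adjacency matrices: `A` for electrical (gap-junction, diffusive)
#' synapses and `B` for chemical (excitatory) synapses.  The combined
#' adjacency `C = A + B` (binarized, i.e. elementwise max) defines the graph
#' used for synchronization masks and structural analysis.  Model-generated
#' connectomes restrict `A` to intra-cluster links and `B` to inter-cluster
#' links; empirical connectomes typically use `A = B =` the loaded adjacency.
#'
#' @param A symmetric binary electrical adjacency matrix (zero diagonal).
#' @param B symmetric binary chemical adjacency matrix; defaults to `A`.
#' @param labels optional integer cluster label per neuron.
#' @param node_names optional character vector of original node identifiers.
#' @return An object of class `connectome`: a list with elements `n`, `A`,
#'   `B`, `C` and `labels`.
#' @examples
#' net <- ring_of_clusters(3, 5)
#' net
#' @export
connectome <- function(A, B = A, labels = NULL, node_names = NULL) {
  A <- as_binary_adj(A, "A")
  B <- as_binary_adj(B, "B")
  if (!all(dim(A) == dim(B))) stop("A and B must have identical dimensions")
  n <- nrow(A)
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels must have one entry per neuron")
    labels <- as.integer(labels)
  }
  structure(
    list(n = n, A = A, B = B, C = pmax(A, B), labels = labels,
         node_names = node_names),
    class = "connectome")
}

# validate / coerce an adjacency matrix: symmetric, binary, zero diagonal
as_binary_adj <- function(M, name = "adjacency") {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop(name, " must be square")
  if (any(M != 0 & M != 1)) stop(name, " must be binary (entries 0/1)")
  if (any(M != t(M))) stop(name, " must be symmetric")
  if (any(diag(M) != 0)) stop(name, " must have zero diagonal")
  storage.mode(M) <- "double"
  unname(M)
}

#' @export
print.connectome <- function(x, ...) {
  cat("Connectome:", x$n, "neurons\n")
  cat("  electrical links:", sum(x$A) / 2,
      "| chemical links:", sum(x$B) / 2, "\n")
  if (!is.null(x$labels))
    cat("  clusters:", length(unique(x$labels)),
        "(sizes:", paste(table(x$labels), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
plot.connectome <- function(x, ...) {
  g <- igraph::graph_from_adjacency_matrix(x$C, mode = "undirected")
  col <- if (is.null(x$labels)) "grey70" else x$labels + 1L
  igraph::plot.igraph(g, vertex.color = col, vertex.size = 6,
                      vertex.label = NA, ...)
  invisible(x)
}

#' Coerce a connectome (or adjacency) to an igraph graph of its combined links
#' @param x a `connectome` or a square adjacency matrix.
#' @return an undirected igraph graph.
#' @export
as_igraph <- function(x) {
  adj <- if (inherits(x, "connectome")) x$C else as.matrix(x)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

adjacency_of <- function(x) {
  if (inherits(x, "connectome")) x$C else as_binary_adj(x)
}

#' Generate one small-world (Watts-Strogatz) cluster
#'
#' Ring lattice of even degree `k_ring` with each edge rewired with
#' probability `p_rewire`, conditioned on connectivity (redrawn up to
#' `max_tries` times).  Edge count is conserved at `n * k_ring / 2`.
#'
#' @param n number of nodes (`n > k_ring`).
#' @param k_ring even ring degree.
#' @param p_rewire rewiring probability in `[0, 1]`.
#' @param max_tries connectivity retries before failing.
#' @return binary adjacency matrix.
#' @export
sw_cluster <- function(n, k_ring = 4, p_rewire = 0.1, max_tries = 100) {
  if (k_ring %% 2 != 0) stop("k_ring must be even")
  if (k_ring < 2) stop("k_ring must be >= 2")
  if (n <= k_ring) stop("need n > k_ring")
  for (i in seq_len(max_tries)) {
    g <- igraph::sample_smallworld(1, n, k_ring / 2, p_rewire,
                                   loops = FALSE, multiple = FALSE)
    if (igraph::is_connected(g)) return(graph_to_adj(g))
  }
  stop("failed to generate a connected small-world cluster after ",
       max_tries, " tries")
}

graph_to_adj <- function(g) {
  unname(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
}

#' Generate an alternative cluster topology
#'
#' Cluster families used as alternative starting communities: Erdos-Renyi
#' `G(n, p)`, Barabasi-Albert preferential attachment seeded with an
#' `m`-clique, or a star perturbed by rewiring a fraction `f` of its edges
#' to uniformly random non-star pairs (edge count preserved).
#'
#' @param kind one of `"erdos_renyi"`, `"barabasi_albert"`, `"perturbed_star"`.
#' @param n number of nodes (>= 3).
#' @param p Erdos-Renyi edge probability.
#' @param m Barabasi-Albert attachments per new node.
#' @param f fraction of star edges rewired (default 0.2).
#' @param max_tries connectivity retries before failing.
#' @return binary adjacency matrix of a connected graph.
#' @export
alt_cluster <- function(kind = c("erdos_renyi", "barabasi_albert",
                                 "perturbed_star"),
                        n, p = 0.3, m = 2, f = 0.2, max_tries = 100) {
  kind <- match.arg(kind)
  if (n < 3) stop("need n >= 3")
  for (i in seq_len(max_tries)) {
    g <- switch(kind,
      erdos_renyi = igraph::sample_gnp(n, p),
      barabasi_albert = igraph::sample_pa(
        n, m = m, directed = FALSE,
        start.graph = igraph::make_full_graph(min(m, n))),
      perturbed_star = perturbed_star_graph(n, f))
    if (igraph::is_connected(g)) return(graph_to_adj(g))
  }
  stop("failed to generate a connected ", kind, " cluster after ",
       max_tries, " tries")
}

# star on n nodes (hub = 1) with round(f * (n-1)) edges rewired to uniformly
# random non-star pairs, keeping the graph simple and the edge count fixed
perturbed_star_graph <- function(n, f) {
  g <- igraph::make_star(n, mode = "undirected", center = 1)
  n_rewire <- round(f * (n - 1))
  if (n_rewire == 0) return(g)
  victims <- sample(igraph::E(g), n_rewire)
  g <- igraph::delete_edges(g, victims)
  # candidate non-star pairs: both endpoints are leaves
  for (i in seq_len(n_rewire)) {
    for (try in 1:200) {
      uv <- sample(2:n, 2)
      if (!igraph::are_adjacent(g, uv[1], uv[2])) {
        g <- igraph::add_edges(g, uv)
        break
      }
    }
  }
  g
}

#' Build the evolution model's starting topology: a ring of clusters
#'
#' `N_c` equally sized clusters of electrically coupled neurons arranged in a
#' closed ring.  Within each cluster all links are electrical; each cluster's
#' hub (maximum-degree node, ties broken by smallest index) is linked to the
#' hub of each neighboring cluster by a chemical excitatory synapse, so the
#' chemical adjacency starts as a single cycle of `N_c` links.
#'
#' @param n_clusters number of clusters (>= 3).
#' @param n_per_cluster neurons per cluster (>= 3, and > `k_ring` for
#'   small-world clusters).
#' @param kind cluster family: `"small_world"` (default), `"erdos_renyi"`,
#'   `"barabasi_albert"` or `"perturbed_star"`.
#' @param k_ring,p_rewire small-world cluster parameters.
#' @param p,m,f alternative-cluster parameters (see [alt_cluster()]).
#' @return a [connectome] with block-diagonal `A`, cyclic hub-to-hub `B`,
#'   and cluster labels `1..n_clusters`.
#' @examples
#' net <- ring_of_clusters(6, 10, k_ring = 4, p_rewire = 0.1)
#' net$n            # 60 neurons
#' sum(net$B) / 2   # 6 chemical hub links
#' @export
ring_of_clusters <- function(n_clusters, n_per_cluster,
                             kind = c("small_world", "erdos_renyi",
                                      "barabasi_albert", "perturbed_star"),
                             k_ring = 4, p_rewire = 0.1,
                             p = 0.3, m = 2, f = 0.2) {
  kind <- match.arg(kind)
  if (n_clusters < 3) stop("need at least 3 clusters")
  if (n_per_cluster < 3) stop("need at least 3 neurons per cluster")
  n <- n_clusters * n_per_cluster
  A <- matrix(0, n, n)
  hubs <- integer(n_clusters)
  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  for (cl in seq_len(n_clusters)) {
    adj <- switch(kind,
      small_world = sw_cluster(n_per_cluster, k_ring, p_rewire),
      alt_cluster(kind, n_per_cluster, p = p, m = m, f = f))
    idx <- which(labels == cl)
    A[idx, idx] <- adj
    deg <- colSums(adj)
    hubs[cl] <- idx[which.max(deg)]  # which.max breaks ties at smallest index
  }
  B <- matrix(0, n, n)
  for (cl in seq_len(n_clusters)) {
    nxt <- hubs[if (cl == n_clusters) 1L else cl + 1L]
    B[hubs[cl], nxt] <- B[nxt, hubs[cl]] <- 1
  }
  out <- connectome(A, B, labels)
  out$hubs <- hubs
  out
}

#' Read a connectome from disk
#'
#' Supports whitespace/comma-separated edge lists (optionally with `#`
#' comments), dense CSV matrices (square, optional header) and GraphML.
#' The loaded adjacency is symmetrized and binarized, self-loops are dropped
#' with a warning, and isolated nodes are removed (mirroring the
#' preprocessing applied to empirical connectomes).  By default both the
#' electrical and chemical matrices are set to the loaded adjacency; supply
#' `chemical_path` to load `B` from a second file.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"edge_list"`, `"csv_matrix"` or
#'   `"graphml"`.
#' @param chemical_path optional second file providing the chemical adjacency.
#' @param labels_path optional node,label CSV assigning cluster labels.
#' @return a [connectome].
#' @export
read_connectome <- function(path,
                            format = c("auto", "edge_list", "csv_matrix",
                                       "graphml"),
                            chemical_path = NULL, labels_path = NULL) {
  format <- match.arg(format)
  adj <- read_adjacency(path, format)
  if (!is.null(chemical_path)) {
    B <- read_adjacency(chemical_path, format)
    if (nrow(B$adj) != nrow(adj$adj))
      stop("electrical and chemical files disagree on node count")
  } else {
    B <- adj
  }
  keep <- which(colSums(adj$adj) + colSums(B$adj) > 0)
  if (length(keep) < nrow(adj$adj)) {
    message("removed ", nrow(adj$adj) - length(keep), " isolated node(s)")
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- read.table(labels_path, header = TRUE, sep = ",")
    labels <- lab[[2]][match(adj$names, lab[[1]])]
  }
  connectome(adj$adj[keep, keep, drop = FALSE],
             B$adj[keep, keep, drop = FALSE],
             labels = if (is.null(labels)) NULL else labels[keep],
             node_names = adj$names[keep])
}

read_adjacency <- function(path, format) {
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      graphml = "graphml", csv = "csv_matrix",
      "edge_list")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    nm <- if ("name" %in% igraph::vertex_attr_names(g))
      igraph::V(g)$name else as.character(seq_len(igraph::vcount(g)))
    M <- graph_to_adj(igraph::simplify(g))
    return(list(adj = clean_adj(M), names = nm))
  }
  if (format == "csv_matrix") {
    first <- readLines(path, n = 1)
    has_header <- grepl("[A-Za-z]", first)
    M <- as.matrix(read.table(path, header = has_header, sep = ","))
    if (nrow(M) != ncol(M))
      stop("CSV matrix in ", path, " is not square (",
           nrow(M), "x", ncol(M), ")")
    nm <- if (has_header) colnames(M) else as.character(seq_len(ncol(M)))
    return(list(adj = clean_adj(M), names = nm))
  }
  # edge list
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no edges found in ", path)
  parts <- strsplit(lines, "[,[:space:]]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("malformed edge list in ", path, " at line ", bad[1])
  u <- vapply(parts, `[`, "", 1)
  v <- vapply(parts, `[`, "", 2)
  nodes <- sort(unique(c(u, v)))
  suppressWarnings({
    num <- as.numeric(nodes)
  })
  if (!anyNA(num)) nodes <- nodes[order(num)]
  M <- matrix(0, length(nodes), length(nodes))
  iu <- match(u, nodes); iv <- match(v, nodes)
  for (e in seq_along(iu)) {
    M[iu[e], iv[e]] <- 1
    M[iv[e], iu[e]] <- 1
  }
  list(adj = clean_adj(M), names = nodes)
}

# symmetrize + binarize, drop self loops with a warning
clean_adj <- function(M) {
  M <- (M + t(M)) > 0
  storage.mode(M) <- "double"
  if (any(diag(M) != 0)) {
    warning("dropping ", sum(diag(M) != 0), " self-loop(s)")
    diag(M) <- 0
  }
  unname(M)
}

#' Write a connectome to disk
#'
#' Writes the combined adjacency `C` (or a chosen matrix) as an edge list,
#' dense CSV matrix or GraphML file; cluster labels can be written alongside
#' as a `node,label` CSV.
#'
#' @param x a [connectome].
#' @param path output file.
#' @param format `"edge_list"`, `"csv_matrix"` or `"graphml"`.
#' @param which which matrix to write: `"C"` (default), `"A"` or `"B"`.
#' @param labels_path optional path for the cluster-label CSV.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path,
                             format = c("edge_list", "csv_matrix", "graphml"),
                             which = c("C", "A", "B"), labels_path = NULL) {
  format <- match.arg(format)
  which <- match.arg(which)
  M <- x[[which]]
  nm <- x$node_names %||% as.character(seq_len(x$n))
  if (format == "csv_matrix") {
    # digit-only names would be indistinguishable from a data row
    header <- any(grepl("[A-Za-z]", nm))
    if (header) colnames(M) <- nm
    write.table(M, path, sep = ",", row.names = FALSE, col.names = header,
                quote = FALSE)
  } else if (format == "graphml") {
    g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected")
    igraph::V(g)$name <- nm
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ij <- which(M == 1 & upper.tri(M), arr.ind = TRUE)
    writeLines(paste(nm[ij[, 1]], nm[ij[, 2]]), path)
  }
  if (!is.null(labels_path) && !is.null(x$labels)) {
    write.table(data.frame(node = nm, label = x$labels), labels_path,
                sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
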