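#' Scan the chemical/electrical coupling parameter space
#'
#' Evaluates a rectangular grid of `(g_n, g_l)` coupling pairs.  In
#' `"static"` mode each cell computes the order parameter and information
#' flow capacity of the fixed network; in `"evolve"` mode each cell runs
#' the full network-growth process and records the final `rho` and `mMIR`
#' together with the number of retained links.  Cells are independent and
#' individually seeded as `base_seed + cell_index`, so partial scans are
#' reproducible and resumable; a failing cell is recorded in `status`
#' without aborting the scan.
#'
#' @param net a [connectome] (with cluster labels for `"evolve"` mode).
#' @param g_n_values,g_l_values coupling values defining the grid.
#' @param hr [hr_params()].
#' @param cfg [sim_config()].
#' @param mode `"static"` or `"evolve"`.
#' @param base_seed integer seed base for per-cell seeding.
#' @param syn_template [synapse_params()] supplying the non-coupling
#'   synapse constants.
#' @param shared_state if `TRUE` (static mode), one initial condition is
#'   drawn from `base_seed` and reused for every cell, so that cell-to-cell
#'   comparisons of `rho` and `ic` are not confounded by initial-condition
#'   noise (the same device the evolution procedure uses for candidate
#'   comparisons).
#' @param ... passed to [evolve_bdn()] in `"evolve"` mode.
#' @return a data frame of class `bdn_scan` with columns `g_n`, `g_l`,
#'   `rho`, `ic`, `n_links` (evolve mode), `seed`, `status`.  Cells are
#'   enumerated in canonical (sorted `g_n` within sorted `g_l`) order and
#'   seeded `base_seed + cell_index`, so results do not depend on the order
#'   in which the coupling values are supplied.
#' @export
scan_parameter_space <- function(net, g_n_values, g_l_values,
                                 hr = hr_params(), cfg = sim_config(),
                                 mode = c("static", "evolve"),
                                 base_seed = 1,
                                 syn_template = synapse_params(),
                                 shared_state = FALSE, ...) {
  mode <- match.arg(mode)
  grid <- expand.grid(g_n = sort(unique(g_n_values)),
                      g_l = sort(unique(g_l_values)),
                      KEEP.OUT.ATTRS = FALSE)
  shared <- NULL
  if (shared_state) {
    set.seed(base_seed)
    shared <- initial_state(net)
  }
  out <- data.frame(grid, rho = NA_real_, ic = NA_real_,
                    n_links = NA_integer_,
                    seed = base_seed + seq_len(nrow(grid)),
                    status = "ok", stringsAsFactors = FALSE)
  for (cell in seq_len(nrow(grid))) {
    syn <- syn_template
    syn$g_n <- grid$g_n[cell]
    syn$g_l <- grid$g_l[cell]
    set.seed(out$seed[cell])
    res <- tryCatch({
      if (mode == "static") {
        est <- lyapunov_exponents(net, hr, syn, cfg, state = shared)
        list(rho = est$rho, ic = est$ic, n_links = NA_integer_)
      } else {
        ev <- evolve_bdn(net, hr, syn, cfg, ...)
        list(rho = ev$rho_history[length(ev$rho_history)],
             ic = ev$mMIR, n_links = nrow(ev$accepted_links))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status[cell] <- conditionMessage(res)
    } else {
      out$rho[cell] <- res$rho
      out$ic[cell] <- res$ic
      out$n_links[cell] <- res$n_links
    }
  }
  class(out) <- c("bdn_scan", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' @export
plot.bdn_scan <- function(x, what = c("rho", "ic"), ...) {
  what <- match.arg(what)
  gn <- sort(unique(x$g_n)); gl <- sort(unique(x$g_l))
  z <- matrix(x[[what]][order(x$g_l, x$g_n)], nrow = length(gn))
  graphics::image(gn, gl, z, xlab = "g_n (chemical)",
                  ylab = "g_l (electrical)",
                  main = if (what == "rho") "order parameter"
                         else "information flow capacity",
                  col = grDevices::hcl.colors(32, "viridis"), ...)
  invisible(x)
}

#' Write a scan result as long-format CSV
#' @param x a `bdn_scan`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(x, path) {
  write.table(as.data.frame(x), path, sep = ",", row.names = FALSE,
              quote = TRUE)
  invisible(path)
}

#' Run a complete analysis from a flat key-value configuration file
#'
#' The configuration is a plain text file of `key = value` lines (`#`
#' comments allowed).  Recognized keys: `mode` (`static`/`evolve`),
#' topology (`n_clusters`, `n_per_cluster`, `cluster_kind`, `k_ring`,
#' `p_rewire`) or `topology_file`; couplings (`g_n`, `g_l`, or ranges
#' `g_n_min`/`g_n_max`/`g_n_count` and likewise for `g_l`); protocol
#' (`dt`, `t_f`, `t_t`, `record_stride`, `candidate_t_f`); `seed`; and
#' `out_dir`.  Writes the scan table, a structure report and spectral
#' density of the (final) network, and a provenance record echoing the
#' configuration and seeds.
#'
#' @param path configuration file.
#' @return the scan result, invisibly; artifacts are written to `out_dir`.
#' @export
run_from_config <- function(path) {
  cfg <- read_flat_config(path)
  need <- function(key) {
    if (is.null(cfg[[key]]))
      stop("configuration is missing required field '", key, "'")
    cfg[[key]]
  }
  num <- function(key, default = NULL) {
    v <- cfg[[key]]
    if (is.null(v)) {
      if (is.null(default)) stop("configuration field '", key,
                                 "' is required")
      return(default)
    }
    as.numeric(v)
  }
  out_dir <- need("out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(num("seed", 1))
  set.seed(seed)

  net <- if (!is.null(cfg$topology_file)) {
    read_connectome(cfg$topology_file)
  } else {
    ring_of_clusters(as.integer(num("n_clusters", 6)),
                     as.integer(num("n_per_cluster", 10)),
                     kind = cfg$cluster_kind %||% "small_world",
                     k_ring = num("k_ring", 4),
                     p_rewire = num("p_rewire", 0.1))
  }
  sim_cfg <- sim_config(dt = num("dt", 0.01), t_f = num("t_f", 2500),
                        t_t = num("t_t", 300),
                        record_stride = num("record_stride", 10))
  coupling_axis <- function(prefix) {
    if (!is.null(cfg[[prefix]])) return(as.numeric(cfg[[prefix]]))
    lo <- num(paste0(prefix, "_min"))
    hi <- num(paste0(prefix, "_max"))
    n <- as.integer(num(paste0(prefix, "_count"), 2))
    seq(lo, hi, length.out = n)
  }
  gn <- coupling_axis("g_n")
  gl <- coupling_axis("g_l")
  mode <- cfg$mode %||% "static"

  scan <- scan_parameter_space(net, gn, gl, cfg = sim_cfg, mode = mode,
                               base_seed = seed)
  write_scan(scan, file.path(out_dir, "scan.csv"))
  rep <- structure_report(net)
  write_structure_report(rep, file.path(out_dir, "structure"))
  dens <- spectral_density(normalized_laplacian(net))
  write_spectral_density(dens, file.path(out_dir, "spectral_density.csv"))
  writeLines(
    c(paste0("# bdnflow ", as.character(utils::packageVersion("bdnflow"))),
      paste0("date = ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      paste0("seed = ", seed),
      paste0("config_file = ", normalizePath(path)),
      paste(names(cfg), unlist(cfg), sep = " = ")),
    file.path(out_dir, "provenance.txt"))
  invisible(scan)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines)
  if (any(bad))
    stop("malformed configuration line: '", lines[which(bad)[1]], "'")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  setNames(as.list(vals), keys)
}
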