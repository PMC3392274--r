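#' Cooperator fraction of a population state
#'
#' @param state a population-state tibble.
#' @return Fraction of players currently cooperating, in \[0, 1\].
#' @export
cooperator_fraction <- function(state) {
  mean(state$strategy == "C")
}

#' Stationary average of a cooperator-fraction trajectory
#'
#' Arithmetic mean and (population) standard deviation of `rho_c` over the
#' final `window` entries of a trajectory.
#'
#' @param trajectory a trajectory tibble with a `rho_c` column (or a bare
#'   numeric vector of cooperator fractions).
#' @param window number of trailing entries to average over.
#' @return A one-row tibble with columns `mean` and `sd`.
#' @export
stationary_average <- function(trajectory, window) {
  x <- if (is.data.frame(trajectory)) trajectory$rho_c else trajectory
  window <- assert_count(window, "window", min = 1L)
  if (window > length(x)) {
    abort("`window` exceeds the trajectory length.")
  }
  tail_x <- x[(length(x) - window + 1L):length(x)]
  tibble(mean = mean(tail_x), sd = sd_pop(tail_x))
}

#' Donor-selection statistics per Monte Carlo step
#'
#' From the per-MCS counters (`n_h`: imitation events whose donor came from
#' the highest-reputation branch, `n_hc`: those donors that were cooperators,
#' `n_rc`: randomly chosen donors that were cooperators) computes two ratios
#' tracking how often cooperators with high reputation act as strategy
#' sources:
#'
#' * `f_h = n_hc / n_h` — cooperator share among reputation-selected donors;
#' * `f_share = n_hc / (n_hc + n_rc)` — reputation-selected share among all
#'   cooperator donors.
#'
#' Ratios with a zero denominator are reported as `NA`, not 0.
#'
#' @param trajectory a trajectory tibble with columns `mcs`, `n_h`, `n_hc`,
#'   `n_rc` (as produced by [run_simulation()]).
#' @return A tibble with columns `mcs`, `f_h`, `f_share`.
#' @export
donor_statistics <- function(trajectory) {
  tibble(
    mcs = trajectory$mcs,
    f_h = ifelse(!is.na(trajectory$n_h) & trajectory$n_h > 0L,
                 trajectory$n_hc / trajectory$n_h, NA_real_),
    f_share = ifelse(!is.na(trajectory$n_hc) &
                       (trajectory$n_hc + trajectory$n_rc) > 0L,
                     trajectory$n_hc / (trajectory$n_hc + trajectory$n_rc),
                     NA_real_))
}

#' Cooperator cluster structure
#'
#' Connected components of the cooperators under the network adjacency
#' (von Neumann 4-neighbourhood on the lattice, i.e. the game adjacency).
#' On lattices the boundary geometry is reported as well: a cooperator is a
#' boundary site iff it has at least one defector neighbour. High/low
#' reputation labels come from [classify_reputation_rank()].
#'
#' @param state a population-state tibble.
#' @param network an `interaction_network`.
#' @return A list with `clusters` (tibble: `cluster_id`, `size`, `n_high`,
#'   `n_low`, `n_boundary`; the boundary column is `NA` off-lattice) and
#'   `summary` (one-row tibble: `n_cooperators`, `n_clusters`,
#'   `largest_cluster_fraction`).
#' @export
cluster_statistics <- function(state, network) {
  stopifnot(inherits(network, "interaction_network"))
  is_lattice <- network$topology == "square_lattice"
  coop <- which(state$strategy == "C")
  n_coop <- length(coop)

  if (n_coop == 0L) {
    return(list(
      clusters = tibble(cluster_id = integer(0), size = integer(0),
                        n_high = integer(0), n_low = integer(0),
                        n_boundary = integer(0)),
      summary = tibble(n_cooperators = 0L, n_clusters = 0L,
                       largest_cluster_fraction = NA_real_)))
  }

  edges <- network_edges(network)
  coop_set <- logical(network$n_nodes)
  coop_set[coop] <- TRUE
  keep <- coop_set[edges$from] & coop_set[edges$to]
  remap <- integer(network$n_nodes)
  remap[coop] <- seq_len(n_coop)
  g <- igraph::make_empty_graph(n = n_coop, directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(remap[edges$from[keep]],
                                    remap[edges$to[keep]]))
  }
  comp <- igraph::components(g)

  ranked <- classify_reputation_rank(state, network)
  is_high <- ranked$reputation_rank[coop] == "high"
  boundary <- if (is_lattice) {
    vapply(coop, function(i) {
      any(state$strategy[network$neighbors[[i]]] == "D")
    }, logical(1))
  } else rep(NA, n_coop)

  clusters <- tibble(cluster_id = seq_len(comp$no)) %>%
    mutate(size = as.integer(comp$csize),
           n_high = vapply(.data$cluster_id, function(k)
             sum(is_high[comp$membership == k]), integer(1)),
           n_low = .data$size - .data$n_high,
           n_boundary = if (is_lattice)
             vapply(.data$cluster_id, function(k)
               sum(boundary[comp$membership == k]), integer(1))
           else NA_integer_)

  list(clusters = clusters,
       summary = tibble(n_cooperators = n_coop,
                        n_clusters = comp$no,
                        largest_cluster_fraction =
                          max(comp$csize) / n_coop))
}

#' Write cluster summaries as CSV
#'
#' Columns `(cluster_id, size, n_high, n_low, n_boundary)`.
#'
#' @param cluster_stats output of [cluster_statistics()].
#' @param path file path.
#' @export
write_cluster_csv <- function(cluster_stats, path) {
  readr::write_csv(cluster_stats$clusters, path)
  invisible(path)
}

#' Export a lattice snapshot as a character grid
#'
#' Writes one line per lattice row (row-major, matching the node indexing
#' convention). In `"strategy"` mode sites are `C`/`D`; in
#' `"reputation_rank"` mode cooperators appear as `H` (high reputation) or
#' `L` (low), defectors as `D`.
#'
#' @param state a population-state tibble.
#' @param network an `interaction_network` with `square_lattice` topology.
#' @param path file path.
#' @param coloring `"strategy"` or `"reputation_rank"`.
#' @export
export_snapshot <- function(state, network, path,
                            coloring = c("strategy", "reputation_rank")) {
  stopifnot(inherits(network, "interaction_network"))
  coloring <- match.arg(coloring)
  if (network$topology != "square_lattice") {
    abort("snapshots are defined on the square lattice only.")
  }
  side <- network$lattice_side
  chars <- if (coloring == "strategy") {
    state$strategy
  } else {
    ranked <- classify_reputation_rank(state, network)
    ifelse(state$strategy == "D", "D",
           ifelse(ranked$reputation_rank == "high", "H", "L"))
  }
  rows <- vapply(seq_len(side), function(r) {
    paste0(chars[((r - 1L) * side + 1L):(r * side)], collapse = "")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname export_snapshot
#' @return `read_snapshot()` returns a tibble with columns `node` and
#'   `symbol` (the grid character), in node-id order.
#' @export
read_snapshot <- function(path) {
  rows <- readLines(path)
  symbols <- unlist(strsplit(rows, ""), use.names = FALSE)
  tibble(node = seq_along(symbols), symbol = symbols)
}
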