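#' Interaction networks with (mean) degree four
#'
#' The simulator runs on three undirected topologies, all with four neighbours
#' per player on average: a periodic square lattice with von Neumann
#' neighbourhoods, a random 4-regular graph, and a Watts-Strogatz small world
#' grown from a degree-4 ring. An `interaction_network` stores the node count,
#' an ordered neighbour list per node, and a topology label; adjacency is
#' validated on construction (symmetric, no self-loops, no duplicates).
#'
#' Node ids are 1-based inside R. The on-disk edge-list format
#' (see [write_edge_list()]) uses 0-based ids, one undirected edge per line.
#' Lattice nodes are indexed row-major: 0-based id = row * side + column.
#'
#' @param side_length lattice side; the lattice has `side_length^2` nodes.
#'   Must be at least 3 (below that the periodic degree-4 construction
#'   degenerates into self-loops or duplicate edges).
#' @param n_nodes number of nodes.
#' @param rewire_fraction probability that each ring edge is rewired to a
#'   uniformly chosen non-duplicate, non-self target.
#' @param seed integer seed making the random constructions reproducible.
#'
#' @return An object of class `interaction_network`: a list with elements
#'   `n_nodes`, `neighbors` (list of sorted integer vectors), `topology`
#'   (one of `"square_lattice"`, `"random_regular"`, `"small_world"`) and,
#'   for lattices, `lattice_side`.
#'
#' @examples
#' net <- build_square_lattice(4)
#' net$n_nodes        # 16
#' neighbors_of(net, 1)
#'
#' rrg <- build_random_regular(50, seed = 1)
#' table(network_degrees(rrg)) # all 4
#' @name topologies
NULL

new_interaction_network <- function(n_nodes, neighbors, topology,
                                    lattice_side = NULL) {
  net <- structure(
    list(n_nodes = n_nodes,
         neighbors = neighbors,
         topology = topology,
         lattice_side = lattice_side),
    class = "interaction_network"
  )
  validate_network(net)
  net
}

validate_network <- function(net) {
  nb <- net$neighbors
  n <- net$n_nodes
  if (length(nb) != n) abort("neighbor list length must equal n_nodes")
  for (i in seq_len(n)) {
    v <- nb[[i]]
    if (any(v == i)) abort("self-loop detected in interaction network")
    if (anyDuplicated(v)) abort("duplicate neighbor entry detected")
    if (any(v < 1L | v > n)) abort("neighbor id out of range")
  }
  # symmetry
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]])) abort("adjacency is not symmetric")
    }
  }
  deg <- lengths(nb)
  if (net$topology %in% c("square_lattice", "random_regular")) {
    if (!all(deg == 4L)) abort("degree must be exactly 4 on this topology")
  } else if (abs(mean(deg) - 4) > 1e-12) {
    abort("mean degree must be exactly 4 on the small-world topology")
  }
  invisible(net)
}

#' @rdname topologies
#' @export
build_square_lattice <- function(side_length) {
  side_length <- assert_count(side_length, "side_length", min = 3L)
  n <- side_length * side_length
  id <- 0:(n - 1L) # 0-based, row-major
  row <- id %/% side_length
  col <- id %% side_length
  up    <- ((row - 1L) %% side_length) * side_length + col
  down  <- ((row + 1L) %% side_length) * side_length + col
  left  <- row * side_length + (col - 1L) %% side_length
  right <- row * side_length + (col + 1L) %% side_length
  neighbors <- lapply(seq_len(n), function(i) {
    sort(c(up[i], down[i], left[i], right[i]) + 1L)
  })
  new_interaction_network(n, neighbors, "square_lattice",
                          lattice_side = side_length)
}

#' @rdname topologies
#' @export
build_random_regular <- function(n_nodes, seed) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 6L)
  seed <- assert_count(seed, "seed")
  g <- withr::with_seed(seed, igraph::sample_k_regular(n_nodes, 4L))
  el <- igraph::as_edgelist(g, names = FALSE)
  neighbors <- edgelist_to_neighbors(el, n_nodes)
  new_interaction_network(n_nodes, neighbors, "random_regular")
}

#' @rdname topologies
#' @export
build_small_world <- function(n_nodes, rewire_fraction, seed) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 10L)
  assert_scalar_number(rewire_fraction, "rewire_fraction")
  if (rewire_fraction < 0 || rewire_fraction > 1) {
    abort("`rewire_fraction` must lie in [0, 1].")
  }
  seed <- assert_count(seed, "seed")

  # degree-4 ring: each node linked to the two nearest neighbours on each side
  ring_edges <- rbind(
    cbind(seq_len(n_nodes), (seq_len(n_nodes) %% n_nodes) + 1L),
    cbind(seq_len(n_nodes), ((seq_len(n_nodes) + 1L) %% n_nodes) + 1L)
  )

  withr::with_seed(seed, {
    adj <- lapply(seq_len(n_nodes), function(i) integer(0))
    for (k in seq_len(nrow(ring_edges))) {
      i <- ring_edges[k, 1L]; j <- ring_edges[k, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    edges <- ring_edges
    rewire <- runif(nrow(edges)) < rewire_fraction
    for (k in which(rewire)) {
      i <- edges[k, 1L]; j <- edges[k, 2L]
      # keep endpoint i, move the far endpoint to a fresh uniform target
      forbidden <- c(i, adj[[i]])
      candidates <- setdiff(seq_len(n_nodes), forbidden)
      if (length(candidates) == 0L) next # saturated node: keep the edge
      new_j <- candidates[sample.int(length(candidates), 1L)]
      adj[[i]] <- c(setdiff(adj[[i]], j), new_j)
      adj[[j]] <- setdiff(adj[[j]], i)
      adj[[new_j]] <- c(adj[[new_j]], i)
      edges[k, 2L] <- new_j
    }
  })

  neighbors <- lapply(adj, function(v) sort(as.integer(v)))
  new_interaction_network(n_nodes, neighbors, "small_world")
}

edgelist_to_neighbors <- function(el, n_nodes) {
  adj <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) adj[[i]] <- integer(0)
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1L]; j <- el[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(as.integer(v)))
}

#' Query neighbours and degrees
#'
#' @param network an `interaction_network`.
#' @param node a node id (1-based).
#' @return `neighbors_of()` returns the sorted integer vector of neighbour
#'   ids; `network_degrees()` the integer degree of every node.
#' @export
neighbors_of <- function(network, node) {
  stopifnot(inherits(network, "interaction_network"))
  node <- assert_count(node, "node", min = 1L)
  if (node > network$n_nodes) abort("`node` out of range.")
  network$neighbors[[node]]
}

#' @rdname neighbors_of
#' @export
network_degrees <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  lengths(network$neighbors)
}

#' Edge list of an interaction network
#'
#' Each undirected edge appears once, with `from < to`, as a tibble of
#' 1-based ids.
#'
#' @param network an `interaction_network`.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  from <- rep.int(seq_len(network$n_nodes), lengths(network$neighbors))
  to <- unlist(network$neighbors, use.names = FALSE)
  keep <- from < to
  tibble(from = from[keep], to = to[keep])
}

#' @export
as_tibble.interaction_network <- function(x, ...) network_edges(x)

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network: %s, %d nodes, %d edges, mean degree %.2f>\n",
              x$topology, x$n_nodes, nrow(network_edges(x)),
              mean(network_degrees(x))))
  invisible(x)
}

#' Plain-text edge-list export and import
#'
#' One undirected edge per line as two whitespace-separated 0-based node ids,
#' each edge listed once.
#'
#' @param network an `interaction_network`.
#' @param path file path.
#' @param topology label to attach on import (the file does not record it).
#' @param lattice_side lattice side on import when `topology` is
#'   `"square_lattice"`.
#' @export
write_edge_list <- function(network, path) {
  edges <- network_edges(network)
  writeLines(sprintf("%d %d", edges$from - 1L, edges$to - 1L), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, topology = "random_regular",
                           lattice_side = NULL) {
  el <- as.matrix(utils::read.table(path, col.names = c("from", "to")))
  n_nodes <- max(el) + 1L
  neighbors <- edgelist_to_neighbors(el + 1L, n_nodes)
  new_interaction_network(n_nodes, neighbors, topology,
                          lattice_side = lattice_side)
}

# CSR (0-based) adjacency for the C++ engine
network_csr <- function(network) {
  deg <- lengths(network$neighbors)
  list(ptr = c(0L, cumsum(deg)),
       idx = unlist(network$neighbors, use.names = FALSE) - 1L)
}
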