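# Small deterministic fixtures shared across tests.

# population state with explicitly chosen fields (defaults: all-C, rep 1, p 0)
make_state <- function(n, strategy = rep("C", n), reputation = rep(1, n),
                       infer_p = rep(0, n)) {
  tibble::tibble(node = seq_len(n), strategy = strategy,
                 reputation = reputation, infer_p = infer_p)
}

# a tiny config that runs in milliseconds
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(game = "weak_pd", parameter = 1.05,
                   topology = "square_lattice", side_or_n = 10L,
                   K = 0.1, relaxation_mcs = 50L, measurement_mcs = 20L,
                   seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# brute-force payoff oracle: enumerate the focal player's pairwise games
payoff_oracle <- function(focal, strategies, network, matrix) {
  total <- 0
  for (j in neighbors_of(network, focal)) {
    s_f <- strategies[focal]
    s_j <- strategies[j]
    total <- total + if (s_f == "C" && s_j == "C") matrix$R
    else if (s_f == "C" && s_j == "D") matrix$S
    else if (s_f == "D" && s_j == "C") matrix$T
    else matrix$P
  }
  total
}

# random simple connected-ish graph on n nodes as an interaction_network-like
# neighbour structure is not needed: tests use the built topologies, plus this
# arbitrary-degree graph built from an Erdos-Renyi draw for payoff oracles
random_graph_network <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p_edge) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  })
  # ensure no isolated node (give it one partner deterministically)
  for (i in seq_len(n)) {
    if (length(adj[[i]]) == 0L) {
      j <- if (i < n) i + 1L else 1L
      adj[[i]] <- j
      adj[[j]] <- sort(unique(c(adj[[j]], i)))
    }
  }
  structure(list(n_nodes = n,
                 neighbors = lapply(adj, sort),
                 topology = "random_regular", # label only; degree unchecked
                 lattice_side = NULL),
            class = "interaction_network")
}
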