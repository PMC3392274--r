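#' Reputation update rules
#'
#' Reputation rewards cooperative acts: at each full Monte Carlo step every
#' player's reputation is updated from its current strategy, with increment
#' `dR = 1` if the player currently cooperates and `dR = 0` otherwise.
#' Two modes exist:
#'
#' * `"accumulative"`: `new = old + dR`. With the initial reputation of 1,
#'   a player's reputation equals 1 plus its lifetime count of cooperative
#'   steps, and is non-decreasing.
#' * `"weighted"`: `new = (1 - w) * old + w * dR`, with evaluation factor
#'   `w` in \[0, 1\] interpolating between pure historical memory (`w -> 0`,
#'   reputation frozen) and pure present behaviour (`w = 1`, reputation is
#'   the cooperation indicator).
#'
#' The default timing applies the increment to every player once per full
#' Monte Carlo step, synchronously, from end-of-step strategies — the only
#' timing under which all reputations advance at the same rate. The
#' alternative `"per_event_focal"` timing instead updates only the focal
#' player's reputation at each elementary event, from its post-event
#' strategy. [run_simulation()] always uses the default; the alternative is
#' available through [monte_carlo_step()].
#'
#' @param mode `"accumulative"` or `"weighted"`.
#' @param w evaluation factor in \[0, 1\]; required for (and only used by)
#'   the weighted mode.
#' @param timing `"per_mcs"` (default) or `"per_event_focal"`.
#' @return A `reputation_rule` object.
#' @examples
#' reputation_rule("accumulative")
#' reputation_rule("weighted", w = 0.5)
#' @export
reputation_rule <- function(mode = c("accumulative", "weighted"), w = NULL,
                            timing = c("per_mcs", "per_event_focal")) {
  mode <- match.arg(mode)
  timing <- match.arg(timing)
  if (mode == "weighted") {
    if (is.null(w)) abort("the weighted rule requires an evaluation factor `w`.")
    assert_scalar_number(w, "w")
    if (w < 0 || w > 1) abort("`w` must lie in [0, 1].")
  } else {
    w <- NA_real_
  }
  structure(list(mode = mode, w = w, timing = timing),
            class = "reputation_rule")
}

#' @export
print.reputation_rule <- function(x, ...) {
  if (x$mode == "accumulative") {
    cat("<reputation_rule: accumulative (new = old + dR)>\n")
  } else {
    cat(sprintf("<reputation_rule: weighted, w = %g (new = (1-w)*old + w*dR)>\n",
                x$w))
  }
  invisible(x)
}

#' Initialise a population on a network
#'
#' Every player starts as cooperator or defector with equal probability,
#' with reputation 1, and with a personal inferring ability `p` drawn once
#' from the uniform distribution on \[0, 1). `p` never changes during a run:
#' it is the probability that the player identifies (and targets) its
#' highest-reputation neighbour when choosing a strategy donor, the
#' complement `1 - p` falling back to a uniformly random neighbour.
#'
#' @param network an `interaction_network`.
#' @param seed integer seed; the draw is reproducible.
#' @param traditional_baseline if `TRUE`, all `p` are set to 0, which reduces
#'   the dynamics to the traditional spatial game with uniformly random donor
#'   choice (the comparison baseline).
#' @return A population-state tibble with columns `node`, `strategy`
#'   (`"C"`/`"D"`), `reputation`, `infer_p`.
#' @examples
#' net <- build_square_lattice(5)
#' init_population(net, seed = 1)
#' @export
init_population <- function(network, seed, traditional_baseline = FALSE) {
  stopifnot(inherits(network, "interaction_network"))
  seed <- assert_count(seed, "seed")
  n <- network$n_nodes
  withr::with_seed(seed, {
    strategy <- ifelse(runif(n) < 0.5, "C", "D")
    infer_p <- runif(n)
  })
  if (isTRUE(traditional_baseline)) infer_p <- rep(0, n)
  tibble(node = seq_len(n),
         strategy = strategy,
         reputation = rep(1, n),
         infer_p = infer_p)
}

#' Apply a reputation rule to every player
#'
#' Updates the `reputation` column of a population state from each player's
#' current strategy, once, as done at the end of every full Monte Carlo step.
#'
#' @param state a population-state tibble (see [init_population()]).
#' @param rule a [reputation_rule()].
#' @return The state with updated reputations.
#' @export
update_reputations <- function(state, rule) {
  stopifnot(inherits(rule, "reputation_rule"))
  dR <- as.numeric(state$strategy == "C")
  if (rule$mode == "accumulative") {
    state$reputation <- state$reputation + dR
  } else {
    state$reputation <- (1 - rule$w) * state$reputation + rule$w * dR
  }
  state
}

#' Reputation-guided donor selection
#'
#' With probability `p` (the focal player's inferring ability) the donor is a
#' neighbour of maximal reputation, ties broken uniformly at random;
#' otherwise the donor is a uniformly random neighbour. Uses R's RNG: seed
#' with [set.seed()] for reproducibility.
#'
#' @param focal focal node id.
#' @param state a population-state tibble.
#' @param network an `interaction_network`.
#' @return A list with `donor` (node id) and `branch` (`"highest_reputation"`
#'   or `"random"`), the branch being needed by the donor-selection
#'   observables.
#' @export
select_donor <- function(focal, state, network) {
  stopifnot(inherits(network, "interaction_network"))
  focal <- assert_count(focal, "focal", min = 1L)
  nb <- network$neighbors[[focal]]
  if (length(nb) < 1L) abort("focal player has no neighbours.")
  if (runif(1) < state$infer_p[focal]) {
    reps <- state$reputation[nb]
    best <- nb[reps == max(reps)]
    donor <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    list(donor = donor, branch = "highest_reputation")
  } else {
    list(donor = nb[sample.int(length(nb), 1L)], branch = "random")
  }
}

#' Classify cooperators as high- or low-reputation
#'
#' A cooperator holds high reputation if its reputation strictly exceeds that
#' of every neighbour; any tie with a neighbour makes it low. Defectors are
#' not classified (`NA`).
#'
#' @param state a population-state tibble.
#' @param network an `interaction_network`.
#' @return The state with an added `reputation_rank` column
#'   (`"high"`/`"low"` for cooperators, `NA` for defectors).
#' @export
classify_reputation_rank <- function(state, network) {
  stopifnot(inherits(network, "interaction_network"))
  rep_v <- state$reputation
  rank <- vapply(seq_len(network$n_nodes), function(i) {
    if (state$strategy[i] != "C") return(NA_character_)
    nb <- network$neighbors[[i]]
    if (all(rep_v[i] > rep_v[nb])) "high" else "low"
  }, character(1))
  state$reputation_rank <- rank
  state
}

#' Read/write population-state snapshots as CSV
#'
#' Per-node records `(node, strategy, reputation, infer_p)` with a header
#' line.
#'
#' @param state a population-state tibble.
#' @param path file path.
#' @export
write_state_csv <- function(state, path) {
  readr::write_csv(state[, c("node", "strategy", "reputation", "infer_p")],
                   path)
  invisible(path)
}

#' @rdname write_state_csv
#' @export
read_state_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    node = readr::col_integer(),
                    strategy = readr::col_character(),
                    reputation = readr::col_double(),
                    infer_p = readr::col_double()))
}
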