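#' Configure a simulation run
#'
#' Bundles every parameter of one Monte Carlo run. The dynamics are
#' asynchronous (random sequential): a full Monte Carlo step (MCS) consists
#' of `n_nodes` elementary events, each picking a focal player uniformly at
#' random (with replacement), selecting a strategy donor by reputation
#' inference, and applying the Fermi adoption rule at noise `K`. Reputations
#' advance once per MCS for all players simultaneously.
#'
#' @param game `"weak_pd"` or `"snowdrift"`.
#' @param parameter temptation `b` (weak PD, `1 < b <= 2`) or cost-to-benefit
#'   ratio `r` (snowdrift, `0 < r < 1`).
#' @param topology `"square_lattice"`, `"random_regular"` or `"small_world"`.
#' @param side_or_n lattice side (for `square_lattice`; population is its
#'   square) or node count (other topologies). Default gives 10^4 players.
#' @param rewire_fraction Watts-Strogatz rewiring probability (small world
#'   only). Default 0.1.
#' @param K Fermi noise amplitude; default 0.1, the customary value at which
#'   the traditional square-lattice extinction threshold sits at b = 1.066.
#' @param reputation_mode `"accumulative"` or `"weighted"`.
#' @param w evaluation factor for the weighted rule.
#' @param relaxation_mcs MCS discarded before measuring; default 30000.
#' @param measurement_mcs MCS over which the stationary cooperator fraction
#'   is averaged; default 5000.
#' @param seed integer seed controlling network construction, the initial
#'   population and the Monte Carlo stream.
#' @param traditional_baseline if `TRUE`, all inferring abilities are 0 and
#'   donors are chosen uniformly at random (the traditional spatial game).
#' @return A validated `sim_config` object.
#' @examples
#' cfg <- sim_config("weak_pd", 1.05, side_or_n = 50, seed = 1,
#'                   relaxation_mcs = 500, measurement_mcs = 100)
#' @export
sim_config <- function(game = c("weak_pd", "snowdrift"),
                       parameter,
                       topology = c("square_lattice", "random_regular",
                                    "small_world"),
                       side_or_n = 100L,
                       rewire_fraction = 0.1,
                       K = 0.1,
                       reputation_mode = c("accumulative", "weighted"),
                       w = NA_real_,
                       relaxation_mcs = 30000L,
                       measurement_mcs = 5000L,
                       seed = 1L,
                       traditional_baseline = FALSE) {
  game <- match.arg(game)
  topology <- match.arg(topology)
  reputation_mode <- match.arg(reputation_mode)
  payoff_matrix(game, parameter) # validates the parameter range
  assert_scalar_number(K, "K")
  if (K <= 0) abort("`K` must be strictly positive.")
  relaxation_mcs <- assert_count(relaxation_mcs, "relaxation_mcs", min = 0L)
  measurement_mcs <- assert_count(measurement_mcs, "measurement_mcs", min = 1L)
  side_or_n <- assert_count(side_or_n, "side_or_n", min = 3L)
  seed <- assert_count(seed, "seed")
  if (reputation_mode == "weighted") {
    assert_scalar_number(w, "w")
    if (w < 0 || w > 1) abort("`w` must lie in [0, 1].")
  }
  if (topology == "small_world") {
    assert_scalar_number(rewire_fraction, "rewire_fraction")
    if (rewire_fraction < 0 || rewire_fraction > 1) {
      abort("`rewire_fraction` must lie in [0, 1].")
    }
  }
  structure(
    list(game = game, parameter = parameter, topology = topology,
         side_or_n = side_or_n, rewire_fraction = rewire_fraction, K = K,
         reputation_mode = reputation_mode, w = w,
         relaxation_mcs = relaxation_mcs, measurement_mcs = measurement_mcs,
         seed = seed,
         traditional_baseline = isTRUE(traditional_baseline)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config: %s (%s = %g), %s (%d), K = %g, %s%s,\n",
                     "  %d + %d MCS, seed %d%s>\n"),
              x$game, if (x$game == "weak_pd") "b" else "r", x$parameter,
              x$topology, x$side_or_n, x$K, x$reputation_mode,
              if (x$reputation_mode == "weighted") sprintf(" (w = %g)", x$w)
              else "",
              x$relaxation_mcs, x$measurement_mcs, x$seed,
              if (x$traditional_baseline) ", traditional baseline" else ""))
  invisible(x)
}

build_network_from_config <- function(config) {
  switch(config$topology,
         square_lattice = build_square_lattice(config$side_or_n),
         random_regular = build_random_regular(config$side_or_n,
                                               seed = config$seed),
         small_world = build_small_world(config$side_or_n,
                                         config$rewire_fraction,
                                         seed = config$seed))
}

#' Run one seeded Monte Carlo simulation
#'
#' Builds the interaction network and the initial population from the
#' config's seed, runs `relaxation_mcs + measurement_mcs` full Monte Carlo
#' steps, and returns the cooperator-fraction trajectory together with
#' per-MCS donor-selection counters and the stationary summary over the
#' measurement window. Identical configs give bit-identical results.
#'
#' Once the population is absorbed (all-cooperator or all-defector) the run
#' stops early; the absorbing cooperator fraction is extended through the
#' remaining trajectory and the donor counters are recorded as missing from
#' that point on.
#'
#' @param config a [sim_config()].
#' @param keep_state if `TRUE` (default) the final population state and the
#'   network are attached to the result (needed for snapshots and cluster
#'   observables).
#' @return A `sim_result`: list with `trajectory` (tibble: `mcs`, `rho_c`,
#'   `n_h`, `n_hc`, `n_rc`), `stationary_mean`, `stationary_sd`,
#'   `absorbed_at` (MCS of absorption or `NA`), `final_state`, `network`,
#'   `config`.
#' @examples
#' cfg <- sim_config("weak_pd", 1.05, side_or_n = 20, seed = 1,
#'                   relaxation_mcs = 200, measurement_mcs = 50)
#' res <- run_simulation(cfg)
#' glance(res)
#' @export
run_simulation <- function(config, keep_state = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  network <- build_network_from_config(config)
  state <- init_population(network, seed = config$seed,
                           traditional_baseline = config$traditional_baseline)
  matrix <- payoff_matrix(config$game, config$parameter)
  csr <- network_csr(network)
  rep_mode <- if (config$reputation_mode == "accumulative") 0L else 1L
  w <- if (is.na(config$w)) 0 else config$w

  out <- .cpp_run_simulation(
    csr$ptr, csr$idx,
    strategy_codes(state$strategy), state$reputation, state$infer_p,
    payoff_lookup(matrix), config$K, rep_mode, w,
    config$relaxation_mcs, config$measurement_mcs,
    as.numeric(config$seed), TRUE)

  total <- config$relaxation_mcs + config$measurement_mcs
  trajectory <- tibble(mcs = seq_len(total),
                       rho_c = out$rho,
                       n_h = out$n_h, n_hc = out$n_hc, n_rc = out$n_rc)
  window <- trajectory$rho_c[(total - config$measurement_mcs + 1L):total]

  final_state <- NULL
  if (isTRUE(keep_state)) {
    final_state <- state
    final_state$strategy <- ifelse(out$strategy == 0L, "C", "D")
    final_state$reputation <- out$reputation
  }

  structure(
    list(trajectory = trajectory,
         stationary_mean = mean(window),
         stationary_sd = sd_pop(window),
         absorbed_at = out$absorbed_at,
         final_state = final_state,
         network = if (isTRUE(keep_state)) network else NULL,
         config = config),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sim_result: %s (%s = %g), %s, n = %d>\n",
              cfg$game, if (cfg$game == "weak_pd") "b" else "r",
              cfg$parameter, cfg$topology,
              if (cfg$topology == "square_lattice") cfg$side_or_n^2
              else cfg$side_or_n))
  cat(sprintf("  stationary rho_c = %.4f (sd %.4f) over final %d MCS%s\n",
              x$stationary_mean, x$stationary_sd, cfg$measurement_mcs,
              if (!is.na(x$absorbed_at))
                sprintf("; absorbed at MCS %d", x$absorbed_at) else ""))
  invisible(x)
}

#' @describeIn run_simulation `tidy()` returns the per-MCS trajectory tibble.
#' @param x a `sim_result`.
#' @param ... unused.
#' @export
tidy.sim_result <- function(x, ...) x$trajectory

#' @describeIn run_simulation `glance()` returns a one-row summary tibble.
#' @export
glance.sim_result <- function(x, ...) {
  cfg <- x$config
  tibble(game = cfg$game, parameter = cfg$parameter, topology = cfg$topology,
         n_nodes = if (cfg$topology == "square_lattice") cfg$side_or_n^2
                   else cfg$side_or_n,
         K = cfg$K, reputation_mode = cfg$reputation_mode, w = cfg$w,
         traditional_baseline = cfg$traditional_baseline, seed = cfg$seed,
         stationary_mean = x$stationary_mean,
         stationary_sd = x$stationary_sd,
         absorbed_at = if (is.null(x$absorbed_at) || is.na(x$absorbed_at))
           NA_integer_ else as.integer(x$absorbed_at))
}

#' @describeIn run_simulation `autoplot()` draws the cooperator-fraction
#'   trajectory on a log time axis.
#' @param object a `sim_result`.
#' @export
autoplot.sim_result <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$mcs, y = .data$rho_c)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Monte Carlo step", y = "cooperator fraction",
                  title = sprintf("%s, %s = %g, K = %g",
                                  object$config$game,
                                  if (object$config$game == "weak_pd") "b"
                                  else "r",
                                  object$config$parameter,
                                  object$config$K)) +
    ggplot2::theme_minimal()
}

#' Write a trajectory as CSV
#'
#' Columns `(mcs, rho_c, n_h, n_hc, n_rc)`.
#'
#' @param result a `sim_result`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(result, path) {
  readr::write_csv(result$trajectory, path)
  invisible(path)
}

#' Advance a population by full Monte Carlo steps
#'
#' Runs `n_mcs` full Monte Carlo steps (each: `n_nodes` elementary imitation
#' events followed by one synchronous reputation update) starting from an
#' explicit population state, and returns the updated state together with
#' the per-MCS donor-selection counters. This is the building block that
#' [run_simulation()] iterates; exposing it allows stepping the dynamics
#' under outside bookkeeping.
#'
#' @param state a population-state tibble.
#' @param network an `interaction_network`.
#' @param matrix a [payoff_matrix()].
#' @param K Fermi noise amplitude.
#' @param rule a [reputation_rule()].
#' @param seed integer seed for this stretch of the Monte Carlo stream.
#' @param n_mcs number of full steps to run (default 1).
#' @return A list with `state` (updated tibble) and `counters` (tibble:
#'   `mcs`, `rho_c`, `n_h`, `n_hc`, `n_rc`).
#' @export
monte_carlo_step <- function(state, network, matrix, K, rule, seed,
                             n_mcs = 1L) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(matrix, "payoff_matrix"),
            inherits(rule, "reputation_rule"))
  n_mcs <- assert_count(n_mcs, "n_mcs", min = 1L)
  seed <- assert_count(seed, "seed")
  csr <- network_csr(network)
  out <- .cpp_run_simulation(
    csr$ptr, csr$idx, strategy_codes(state$strategy),
    state$reputation, state$infer_p, payoff_lookup(matrix), K,
    if (rule$mode == "accumulative") 0L else 1L,
    if (is.na(rule$w)) 0 else rule$w,
    0L, n_mcs, as.numeric(seed), FALSE,
    if (identical(rule$timing, "per_event_focal")) 1L else 0L)
  new_state <- state
  new_state$strategy <- ifelse(out$strategy == 0L, "C", "D")
  new_state$reputation <- out$reputation
  list(state = new_state,
       counters = tibble(mcs = seq_len(n_mcs), rho_c = out$rho,
                         n_h = out$n_h, n_hc = out$n_hc, n_rc = out$n_rc))
}

#' Run elementary imitation events from a frozen state
#'
#' Exposes the event-level dynamics (focal choice, donor selection, Fermi
#' adoption) without the per-MCS reputation bookkeeping, for inspection and
#' testing. Reputations stay frozen at their input values throughout.
#'
#' @param state a population-state tibble.
#' @param network an `interaction_network`.
#' @param matrix a [payoff_matrix()].
#' @param K Fermi noise amplitude.
#' @param n_events number of elementary events to run.
#' @param seed integer seed for the event stream.
#' @return A list with `events` (tibble: `focal`, `donor`, `high_branch`,
#'   `adopted`) and `state` (the strategy vector after the events).
#' @export
run_elementary_steps <- function(state, network, matrix, K, n_events, seed) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(matrix, "payoff_matrix"))
  n_events <- assert_count(n_events, "n_events", min = 1L)
  seed <- assert_count(seed, "seed")
  csr <- network_csr(network)
  out <- .cpp_elementary_steps(
    csr$ptr, csr$idx, strategy_codes(state$strategy),
    state$reputation, state$infer_p, payoff_lookup(matrix),
    K, n_events, as.numeric(seed))
  new_state <- state
  new_state$strategy <- ifelse(out$strategy == 0L, "C", "D")
  list(events = tibble(focal = out$focal, donor = out$donor,
                       high_branch = as.logical(out$high_branch),
                       adopted = as.logical(out$adopted)),
       state = new_state)
}
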