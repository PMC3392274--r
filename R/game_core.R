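#' Two-player game payoff matrices
#'
#' Two social-dilemma games are supported. The weak prisoner's dilemma is
#' parameterised by the temptation to defect `b`: `T = b`, `R = 1`,
#' `P = S = 0`, with `1 < b <= 2`, so the payoff ranking is `T > R > P = S`.
#' The snowdrift game is parameterised by the cost-to-benefit ratio `r` with
#' `0 < r < 1`, using the standard lattice convention `T = 1 + r`, `R = 1`,
#' `S = 1 - r`, `P = 0`, which satisfies `T > R > S > P`.
#'
#' @param game one of `"weak_pd"` or `"snowdrift"`.
#' @param parameter the temptation `b` (weak PD) or the cost-to-benefit
#'   ratio `r` (snowdrift).
#'
#' @return A `payoff_matrix`: list with entries `T`, `R`, `S`, `P`, plus
#'   `game` and `parameter`.
#' @examples
#' payoff_matrix("weak_pd", 1.1)
#' payoff_matrix("snowdrift", 0.5)
#' @export
payoff_matrix <- function(game = c("weak_pd", "snowdrift"), parameter) {
  game <- match.arg(game)
  assert_scalar_number(parameter, "parameter")
  if (game == "weak_pd") {
    # b = 1 (T = R, a degenerate boundary of the dilemma) is admitted so
    # that sweeps and phase scans can anchor their grids at it
    if (parameter < 1 || parameter > 2) {
      abort("weak prisoner's dilemma requires a temptation b with 1 <= b <= 2.")
    }
    m <- list(T = parameter, R = 1, S = 0, P = 0)
  } else {
    if (parameter <= 0 || parameter >= 1) {
      abort("snowdrift requires a cost-to-benefit ratio r with 0 < r < 1.")
    }
    m <- list(T = 1 + parameter, R = 1, S = 1 - parameter, P = 0)
  }
  structure(c(m, list(game = game, parameter = parameter)),
            class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("<payoff_matrix: %s (%s = %g)>  T=%g R=%g S=%g P=%g\n",
              x$game, if (x$game == "weak_pd") "b" else "r", x$parameter,
              x$T, x$R, x$S, x$P))
  invisible(x)
}

# 2x2 matrix indexed [own, other] with strategies ordered (C, D);
# the engine receives it flattened row-major: c(R, S, T, P)
payoff_lookup <- function(matrix) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  c(matrix$R, matrix$S, matrix$T, matrix$P)
}

#' Payoff of one player against all its neighbours
#'
#' Sums the pairwise game payoff of the focal player against each of its
#' network neighbours under the current strategy assignment. Payoffs carry no
#' memory: every call evaluates the current neighbourhood from scratch.
#'
#' @param focal focal node id (1-based).
#' @param strategies character vector of `"C"`/`"D"`, one entry per node.
#' @param network an `interaction_network`.
#' @param matrix a [payoff_matrix()].
#' @return The focal player's payoff (a single number).
#' @examples
#' net <- build_square_lattice(3)
#' strat <- rep("C", 9)
#' accumulate_payoff(1, strat, net, payoff_matrix("weak_pd", 1.5)) # 4 * R = 4
#' @export
accumulate_payoff <- function(focal, strategies, network, matrix) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(matrix, "payoff_matrix"))
  focal <- assert_count(focal, "focal", min = 1L)
  if (length(strategies) != network$n_nodes) {
    abort("`strategies` must have one entry per node.")
  }
  codes <- strategy_codes(strategies)
  M <- matrix(payoff_lookup(matrix), nrow = 2, byrow = TRUE)
  nb <- network$neighbors[[focal]]
  sum(M[cbind(codes[focal] + 1L, codes[nb] + 1L)])
}

#' Fermi strategy-adoption probability
#'
#' Probability that the focal player adopts the donor's strategy:
#' `1 / (1 + exp((payoff_focal - payoff_donor) / K))`. The noise amplitude
#' `K` acts as a temperature: small `K` makes imitation of better-performing
#' donors nearly deterministic, large `K` approaches a coin toss. Exponents
#' are clipped at +/- 700 so extreme payoff gaps saturate to 0/1 instead of
#' overflowing.
#'
#' @param payoff_focal,payoff_donor payoffs of the focal and donor players
#'   (vectorised).
#' @param K noise amplitude, strictly positive.
#' @return Adoption probabilities in (0, 1).
#' @examples
#' fermi_probability(0, 1, K = 0.1)  # ~0.99995
#' fermi_probability(1, 1, K = 0.5)  # 0.5 exactly
#' @export
fermi_probability <- function(payoff_focal, payoff_donor, K) {
  assert_scalar_number(K, "K")
  if (K <= 0) abort("`K` must be strictly positive.")
  z <- (payoff_focal - payoff_donor) / K
  z <- pmin(pmax(z, -700), 700)
  1 / (1 + exp(z))
}
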