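# internal helpers shared across modules

# Deterministic derived seeds for replicate runs and grid points.
# Values stay within 1..2^31-2 so they remain valid R integer seeds.
derive_seed <- function(base_seed, i, j = 0L) {
  as.integer((as.numeric(base_seed) + 7919 * i + 104729 * j) %% 2147483645) + 1L
}

# population (not sample) standard deviation; the alternating-trajectory
# arithmetic of stationary_average() relies on the 1/n normalisation
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name)
  if (x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

strategy_codes <- function(strategy) {
  if (is.factor(strategy)) strategy <- as.character(strategy)
  if (!all(strategy %in% c("C", "D"))) {
    abort("strategies must be \"C\" or \"D\"")
  }
  as.integer(strategy == "D") # 0 = C, 1 = D, the engine's coding
}
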