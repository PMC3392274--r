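#' Sweep a game parameter (or the evaluation factor) over a grid
#'
#' Runs `runs_per_point` independently seeded simulations at every grid value
#' and summarises the stationary cooperator fraction. Sweeps can range over
#' the game parameter (`b` for the weak prisoner's dilemma, `r` for the
#' snowdrift game) or, at fixed game parameter, over the evaluation factor
#' `w` of the weighted reputation rule. Replicate seeds are derived
#' deterministically from the base config's seed.
#'
#' @param base_config a [sim_config()] supplying every non-swept parameter.
#' @param grid sorted numeric vector of parameter values.
#' @param runs_per_point independent runs per grid value (1 to 40; results
#'   in this literature are customarily averaged over up to 40 runs).
#' @param sweep_over `"parameter"` (the game parameter) or `"w"`.
#' @return A `sweep_result` tibble with columns `value`, `rho_mean`,
#'   `rho_sd`, `rho_se`, `n_runs`, `n_absorbed`; the base config is attached
#'   as an attribute.
#' @examples
#' cfg <- sim_config("weak_pd", 1.05, side_or_n = 20, seed = 1,
#'                   relaxation_mcs = 100, measurement_mcs = 50)
#' sweep_parameter(cfg, grid = c(1.02, 1.05), runs_per_point = 2)
#' @export
sweep_parameter <- function(base_config, grid, runs_per_point = 10L,
                            sweep_over = c("parameter", "w")) {
  stopifnot(inherits(base_config, "sim_config"))
  sweep_over <- match.arg(sweep_over)
  if (length(grid) < 1L) abort("`grid` must be non-empty.")
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be sorted and free of duplicates.")
  }
  runs_per_point <- assert_count(runs_per_point, "runs_per_point", min = 1L)
  if (runs_per_point > 40L) {
    abort("`runs_per_point` is capped at 40.")
  }

  rows <- purrr::map(seq_along(grid), function(i) {
    cfg <- base_config
    if (sweep_over == "parameter") {
      cfg$parameter <- grid[i]
    } else {
      cfg$reputation_mode <- "weighted"
      cfg$w <- grid[i]
    }
    stats <- purrr::map_dbl(seq_len(runs_per_point), function(j) {
      cfg$seed <- derive_seed(base_config$seed, i, j)
      run_simulation(do.call(sim_config, unclass(cfg)),
                     keep_state = FALSE)$stationary_mean
    })
    tibble(value = grid[i],
           rho_mean = mean(stats),
           rho_sd = sd_pop(stats),
           rho_se = sd_pop(stats) / sqrt(runs_per_point),
           n_runs = runs_per_point,
           n_absorbed = sum(stats %in% c(0, 1)))
  })

  out <- bind_rows(rows)
  attr(out, "base_config") <- base_config
  attr(out, "sweep_over") <- sweep_over
  class(out) <- c("sweep_result", class(out))
  out
}

#' @describeIn sweep_parameter plot the sweep with +/- 2 s.e. ribbons.
#' @param object a `sweep_result`.
#' @param ... unused.
#' @export
autoplot.sweep_result <- function(object, ...) {
  xlab <- if (attr(object, "sweep_over") == "w") "evaluation factor w"
  else if (attr(object, "base_config")$game == "weak_pd") "temptation b"
  else "cost-to-benefit ratio r"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$rho_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$rho_mean -
                                                    2 * .data$rho_se),
                                      ymax = pmin(1, .data$rho_mean +
                                                    2 * .data$rho_se)),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = xlab, y = "stationary cooperator fraction") +
    ggplot2::theme_minimal()
}

#' Estimate the cooperator-extinction threshold
#'
#' Scans the temptation `b` over a regular grid and classifies each grid
#' point as extinct iff every one of its runs ends with a stationary
#' cooperator fraction below `epsilon` (with the default early-absorption
#' detection this is literal fixation to all-defector for almost every run;
#' `epsilon` guards the rare non-absorbed stragglers). The threshold `b_c`
#' is the midpoint between the last surviving and the first extinct grid
#' point. If survival re-enters above the first extinction the scan is
#' flagged as non-monotone. A scan with no extinction (or no survival) gives
#' a censored bound instead of a value.
#'
#' @param base_config a [sim_config()]; its `parameter` is overridden by the
#'   scan.
#' @param b_low,b_high scan interval (must satisfy `b_low < b_high`).
#' @param resolution grid spacing; default 0.005.
#' @param runs_per_point independent runs per grid point; default 10.
#' @param epsilon extinction cutoff on the stationary cooperator fraction;
#'   default 1e-3.
#' @param simulate_fn function taking a `sim_config` and returning an object
#'   with a `stationary_mean` element. Defaults to [run_simulation()];
#'   injectable so the scanner can be verified against noise-free surrogate
#'   dynamics with a planted threshold.
#' @return A `threshold_result`: list with `b_c`, `censored` (`NA`,
#'   `"lower"` or `"upper"`), `bracket` (last surviving / first extinct
#'   values), `monotone` flag, `resolution`, `runs_per_point`, and the
#'   per-point `grid` tibble.
#' @export
estimate_extinction_threshold <- function(base_config, b_low, b_high,
                                          resolution = 0.005,
                                          runs_per_point = 10L,
                                          epsilon = 1e-3,
                                          simulate_fn = run_simulation) {
  stopifnot(inherits(base_config, "sim_config"))
  assert_scalar_number(b_low, "b_low")
  assert_scalar_number(b_high, "b_high")
  if (b_low >= b_high) abort("`b_low` must be smaller than `b_high`.")
  assert_scalar_number(resolution, "resolution")
  if (resolution <= 0) abort("`resolution` must be positive.")
  runs_per_point <- assert_count(runs_per_point, "runs_per_point", min = 1L)

  b_grid <- seq(b_low, b_high, by = resolution)
  rows <- purrr::map(seq_along(b_grid), function(i) {
    cfg <- base_config
    cfg$parameter <- b_grid[i]
    finals <- purrr::map_dbl(seq_len(runs_per_point), function(j) {
      cfg$seed <- derive_seed(base_config$seed, i, j)
      simulate_fn(do.call(sim_config, unclass(cfg)))$stationary_mean
    })
    tibble(b = b_grid[i],
           mean_rho = mean(finals),
           n_extinct = sum(finals < epsilon),
           all_extinct = all(finals < epsilon))
  })
  grid_tbl <- bind_rows(rows)

  extinct <- grid_tbl$all_extinct
  first_ext <- if (any(extinct)) which(extinct)[1L] else NA_integer_
  last_surv <- if (any(!extinct)) max(which(!extinct)) else NA_integer_

  monotone <- TRUE
  b_c <- NA_real_
  censored <- NA_character_
  bracket <- c(NA_real_, NA_real_)
  if (is.na(first_ext)) {
    censored <- "upper" # cooperators survive across the whole scan
  } else if (!any(!extinct[seq_len(first_ext - 1L)]) && first_ext == 1L) {
    censored <- "lower" # already extinct at b_low
  } else {
    if (last_surv > first_ext) monotone <- FALSE
    below <- first_ext - 1L
    bracket <- c(grid_tbl$b[below], grid_tbl$b[first_ext])
    b_c <- mean(bracket)
  }

  structure(list(b_c = b_c, censored = censored,
                 bracket = bracket, monotone = monotone,
                 resolution = resolution, runs_per_point = runs_per_point,
                 epsilon = epsilon, grid = grid_tbl,
                 base_config = base_config),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (!is.na(x$b_c)) {
    cat(sprintf("<threshold_result: b_c = %.4g (bracket %.4g..%.4g, resolution %g)%s>\n",
                x$b_c, x$bracket[1], x$bracket[2], x$resolution,
                if (!x$monotone) ", NON-MONOTONE scan" else ""))
  } else if (identical(x$censored, "upper")) {
    cat(sprintf("<threshold_result: censored, b_c >= %.4g>\n", max(x$grid$b)))
  } else {
    cat(sprintf("<threshold_result: censored, b_c <= %.4g>\n", min(x$grid$b)))
  }
  invisible(x)
}

#' @describeIn estimate_extinction_threshold `tidy()` returns the per-point
#'   scan grid.
#' @param x a `threshold_result`.
#' @param ... unused.
#' @export
tidy.threshold_result <- function(x, ...) x$grid

#' @describeIn estimate_extinction_threshold `glance()` returns a one-row
#'   summary.
#' @export
glance.threshold_result <- function(x, ...) {
  tibble(b_c = x$b_c, censored = x$censored,
         bracket_low = x$bracket[1], bracket_high = x$bracket[2],
         monotone = x$monotone, resolution = x$resolution,
         runs_per_point = x$runs_per_point)
}

#' Map a temptation-noise phase diagram
#'
#' Classifies every `(b, K)` grid point into one of three stationary phases:
#' `pure_C` iff every run fixates to all-cooperator, `pure_D` iff every run
#' fixates to all-defector, `mixed` otherwise. Runs are independently seeded
#' per grid point.
#'
#' @param base_config a [sim_config()]; `parameter` and `K` are overridden.
#' @param b_grid sorted temptation values.
#' @param K_grid sorted noise values.
#' @param runs_per_point independent runs per grid point.
#' @param epsilon fixation cutoff on the stationary cooperator fraction.
#' @return A `phase_diagram` tibble with columns `b`, `K`, `phase`,
#'   `mean_rho`.
#' @export
map_phase_diagram <- function(base_config, b_grid, K_grid,
                              runs_per_point = 5L, epsilon = 1e-3) {
  stopifnot(inherits(base_config, "sim_config"))
  if (length(b_grid) < 1L || length(K_grid) < 1L) {
    abort("`b_grid` and `K_grid` must be non-empty.")
  }
  runs_per_point <- assert_count(runs_per_point, "runs_per_point", min = 1L)

  rows <- purrr::map(seq_along(K_grid), function(ki) {
    purrr::map(seq_along(b_grid), function(bi) {
      cfg <- base_config
      cfg$parameter <- b_grid[bi]
      cfg$K <- K_grid[ki]
      finals <- purrr::map_dbl(seq_len(runs_per_point), function(j) {
        cfg$seed <- derive_seed(base_config$seed, 1000L * ki + bi, j)
        run_simulation(do.call(sim_config, unclass(cfg)),
                       keep_state = FALSE)$stationary_mean
      })
      phase <- if (all(finals > 1 - epsilon)) "pure_C"
      else if (all(finals < epsilon)) "pure_D"
      else "mixed"
      tibble(b = b_grid[bi], K = K_grid[ki], phase = phase,
             mean_rho = mean(finals))
    }) %>% bind_rows()
  }) %>% bind_rows()

  attr(rows, "base_config") <- base_config
  class(rows) <- c("phase_diagram", class(rows))
  rows
}

#' Phase boundaries of a mapped phase diagram
#'
#' For every noise value `K`, locates the two transition lines along the
#' temptation axis as midpoints between adjacent grid values: the boundary
#' between the pure-cooperator and mixed phases, and between the mixed and
#' pure-defector phases. A boundary that does not fall inside the scanned
#' grid for some `K` is omitted for that `K`.
#'
#' @param diagram a `phase_diagram` tibble.
#' @return A tibble with columns `K`, `boundary`
#'   (`"pure_C_mixed"`/`"mixed_pure_D"`) and `b`.
#' @export
phase_boundaries <- function(diagram) {
  stopifnot(inherits(diagram, "phase_diagram"))
  purrr::map(sort(unique(diagram$K)), function(k) {
    sl <- diagram %>% filter(.data$K == k) %>% arrange(.data$b)
    out <- list()
    # last pure_C before a non-pure_C point
    idx_c <- which(sl$phase == "pure_C")
    if (length(idx_c) > 0 && max(idx_c) < nrow(sl)) {
      i <- max(idx_c)
      out$pc <- tibble(K = k, boundary = "pure_C_mixed",
                       b = mean(sl$b[c(i, i + 1L)]))
    }
    idx_d <- which(sl$phase == "pure_D")
    if (length(idx_d) > 0 && min(idx_d) > 1L) {
      i <- min(idx_d)
      out$pd <- tibble(K = k, boundary = "mixed_pure_D",
                       b = mean(sl$b[c(i - 1L, i)]))
    }
    bind_rows(out)
  }) %>% bind_rows()
}

#' @describeIn map_phase_diagram plot the phase diagram as a tile map.
#' @param object a `phase_diagram`.
#' @param ... unused.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$K, y = .data$b,
                                       fill = .data$phase)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(pure_C = "#2166ac",
                                          mixed = "#fddbc7",
                                          pure_D = "#b2182b")) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "noise K", y = "temptation b") +
    ggplot2::theme_minimal()
}
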