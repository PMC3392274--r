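# Experiment drivers: sweeps, threshold scanning, phase classification, CLI.
# Monte Carlo protocols here are deliberately tiny; the statistical
# reproduction checks live in test-acceptance.R.

test_that("a one-point sweep reduces to replicated simulation runs", {
  cfg <- tiny_config(seed = 31)
  sw <- sweep_parameter(cfg, grid = 1.05, runs_per_point = 3)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$n_runs, 3L)
  # reproduce by hand with the same derived seeds
  by_hand <- vapply(1:3, function(j) {
    cfg2 <- cfg
    cfg2$seed <- inferrep:::derive_seed(cfg$seed, 1L, j)
    run_simulation(do.call(sim_config, unclass(cfg2)))$stationary_mean
  }, numeric(1))
  expect_equal(sw$rho_mean, mean(by_hand))
})

test_that("sweeps validate their grid and honour the 40-run cap", {
  cfg <- tiny_config()
  expect_error(sweep_parameter(cfg, grid = numeric(0)))
  expect_error(sweep_parameter(cfg, grid = c(1.1, 1.05)), "sorted")
  expect_error(sweep_parameter(cfg, grid = 1.05, runs_per_point = 41),
               "capped")
  w_sw <- sweep_parameter(tiny_config(seed = 32), grid = c(0.2, 0.5, 0.8),
                          runs_per_point = 2, sweep_over = "w")
  expect_equal(nrow(w_sw), 3L)
  expect_true(all(w_sw$rho_mean >= 0 & w_sw$rho_mean <= 1))
  expect_s3_class(autoplot(w_sw), "ggplot")
})

test_that("the threshold scanner recovers a planted extinction point", {
  # noise-free surrogate dynamics: cooperators survive at rho = 0.4 strictly
  # below the planted threshold, are extinct at or above it
  planted <- 1.0815
  fake_sim <- function(config) {
    list(stationary_mean = if (config$parameter < planted) 0.4 else 0)
  }
  cfg <- tiny_config()
  res <- estimate_extinction_threshold(cfg, 1.02, 1.12, resolution = 0.005,
                                       runs_per_point = 3,
                                       simulate_fn = fake_sim)
  expect_true(res$monotone)
  expect_lt(abs(res$b_c - planted), 0.005) # within one resolution step
  expect_equal(res$bracket, c(1.080, 1.085))
  expect_true(is.na(res$censored))
  g <- glance(res)
  expect_equal(g$b_c, res$b_c)
  expect_equal(nrow(tidy(res)), length(seq(1.02, 1.12, by = 0.005)))
})

test_that("threshold scans report censored bounds when nothing crosses", {
  alive <- function(config) list(stationary_mean = 0.5)
  dead <- function(config) list(stationary_mean = 0)
  cfg <- tiny_config()
  up <- estimate_extinction_threshold(cfg, 1.02, 1.06, resolution = 0.01,
                                      runs_per_point = 1, simulate_fn = alive)
  expect_true(is.na(up$b_c))
  expect_equal(up$censored, "upper")
  low <- estimate_extinction_threshold(cfg, 1.02, 1.06, resolution = 0.01,
                                       runs_per_point = 1, simulate_fn = dead)
  expect_equal(low$censored, "lower")
  expect_error(estimate_extinction_threshold(cfg, 1.1, 1.0))
})

test_that("re-entrant survival above the first extinction is flagged", {
  flaky <- function(config) {
    b <- config$parameter
    list(stationary_mean = if (b < 1.04 || (b > 1.055 && b < 1.065)) 0.3 else 0)
  }
  res <- estimate_extinction_threshold(tiny_config(), 1.0, 1.1,
                                       resolution = 0.01, runs_per_point = 1,
                                       simulate_fn = flaky)
  expect_false(res$monotone)
})

test_that("phase classification is exhaustive, exclusive and boundary-aware", {
  # the classification rule itself, on a cheap grid: maximal temptation under
  # the traditional baseline must land in pure_D
  cfg <- sim_config("weak_pd", 1.5, side_or_n = 12L, seed = 41,
                    relaxation_mcs = 300L, measurement_mcs = 100L,
                    traditional_baseline = TRUE)
  pd <- map_phase_diagram(cfg, b_grid = c(1.01, 2.0), K_grid = c(0.1, 0.5),
                          runs_per_point = 2)
  expect_equal(nrow(pd), 4L)
  expect_true(all(pd$phase %in% c("pure_C", "mixed", "pure_D")))
  expect_true(all(pd$phase[pd$b == 2.0] == "pure_D"))
  expect_s3_class(autoplot(pd), "ggplot")

  # boundary midlines from a hand-built diagram
  hand <- tibble::tibble(b = rep(c(1.0, 1.05, 1.1, 1.15), 2),
                         K = rep(c(0.1, 0.5), each = 4),
                         phase = c("pure_C", "mixed", "mixed", "pure_D",
                                   "mixed", "mixed", "pure_D", "pure_D"),
                         mean_rho = 0.5)
  class(hand) <- c("phase_diagram", class(hand))
  bounds <- phase_boundaries(hand)
  expect_equal(bounds$b[bounds$K == 0.1 & bounds$boundary == "pure_C_mixed"],
               1.025)
  expect_equal(bounds$b[bounds$K == 0.1 & bounds$boundary == "mixed_pure_D"],
               1.125)
  expect_equal(bounds$b[bounds$K == 0.5 & bounds$boundary == "mixed_pure_D"],
               1.075)
  expect_false(any(bounds$boundary[bounds$K == 0.5] == "pure_C_mixed"))
})

test_that("config files round-trip and reject malformed input", {
  cfg <- sim_config("snowdrift", 0.4, topology = "small_world",
                    side_or_n = 50L, rewire_fraction = 0.2, K = 0.3,
                    reputation_mode = "weighted", w = 0.6,
                    relaxation_mcs = 10L, measurement_mcs = 5L, seed = 77)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("game = weak_pd\nbogus_key = 1", path)
  expect_error(read_sim_config(path), "unknown config key")
  writeLines("game weak_pd", path)
  expect_error(read_sim_config(path), "key = value")
})

test_that("the CLI runs subcommands, is deterministic, and signals errors", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg_path <- file.path(out1, "run.cfg")
  write_sim_config(tiny_config(seed = 55, side_or_n = 8L), cfg_path)

  st <- suppressMessages(
    run_cli(c("simulate", "--config", cfg_path, "--out-dir", out1)))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(out1, "trajectory.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))

  # identical invocations give identical outputs
  st2 <- suppressMessages(
    run_cli(c("simulate", "--config", cfg_path, "--out-dir", out2)))
  expect_identical(readLines(file.path(out1, "trajectory.csv")),
                   readLines(file.path(out2, "trajectory.csv")))

  sw_dir <- withr::local_tempdir()
  st3 <- suppressMessages(
    run_cli(c("sweep", "--config", cfg_path, "--grid", "1.02,1.06",
              "--runs", "2", "--out-dir", sw_dir)))
  expect_equal(st3, 0L)
  sweep_csv <- readr::read_csv(file.path(sw_dir, "sweep.csv"),
                               show_col_types = FALSE)
  expect_equal(nrow(sweep_csv), 2L) # one row per grid value

  snap_dir <- withr::local_tempdir()
  st4 <- suppressMessages(
    run_cli(c("snapshot", "--config", cfg_path, "--out-dir", snap_dir,
              "--coloring", "reputation_rank")))
  expect_equal(st4, 0L)
  grid <- readLines(file.path(snap_dir, "snapshot.txt"))
  expect_equal(length(grid), 8L)
  expect_true(all(nchar(grid) == 8L))

  # failure modes: unknown subcommand, bad flag, inverted threshold interval
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(run_cli(c("simulate", "--wat", "1"))), 2L)
  expect_equal(suppressMessages(
    run_cli(c("threshold", "--config", cfg_path,
              "--b-low", "1.2", "--b-high", "1.1"))), 2L)
  expect_equal(suppressMessages(run_cli(character())), 2L)
})
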