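# virtual experiment runner and CLI

two_arm_config <- function(seed = 1, ...)
  experiment_config(
    conditions = list(
      condition_arm("medium control",
                    scenario_spec("control-exponential"), control = TRUE),
      condition_arm("empty PACA 32", scenario_spec("lysis"), 32)),
    seed = seed, ...)

test_that("a minimal run completes with the expected course length", {
  cfg <- experiment_config(
    conditions = list(condition_arm("medium control",
                                    scenario_spec("arrest"),
                                    control = TRUE)),
    n_positions = 1, n_experiments = 1, times_h = c(0, 12, 24),
    measurement_sd_ng = 0, seed = 1)
  res <- run_virtual_experiment(cfg)
  expect_equal(nrow(res$courses), 3)
  expect_equal(res$increments$increment_ng, 0, tolerance = 1e-9)
})

test_that("identical seeds give byte-identical result files", {
  d1 <- tempfile(); d2 <- tempfile()
  run_virtual_experiment(two_arm_config(42, outdir = d1))
  run_virtual_experiment(two_arm_config(42, outdir = d2))
  for (f in c("courses.csv", "increments.csv", "stats.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # the manifest reproduces the run
  man <- jsonlite::fromJSON(file.path(d1, "manifest.json"),
                            simplifyDataFrame = FALSE)
  cfg3 <- config_from_list(man$config)
  cfg3$outdir <- NULL
  r3 <- run_virtual_experiment(cfg3)
  written <- read.csv(file.path(d1, "courses.csv"))
  expect_equal(r3$courses, written, tolerance = 1e-12)
})

test_that("control-vs-lysis runs end with a starred lysis arm", {
  res <- run_virtual_experiment(two_arm_config(7))
  st <- res$stats[res$stats$condition == "empty PACA 32", ]
  expect_lt(st$mean_ng, 0)
  expect_lt(st$p_adj, 0.005)
  expect_equal(st$stars, "***")
  ctrl <- res$stats[res$stats$condition == "medium control", ]
  expect_gt(ctrl$mean_ng, 0)
  expect_equal(nrow(res$increments), 2 * 3 * 4)  # 2 arms x N=3 x n=4
})

test_that("full-fidelity mode writes hologram and phase stacks", {
  out <- tempfile()
  cfg <- experiment_config(
    conditions = list(condition_arm("medium control",
                                    scenario_spec("arrest"),
                                    control = TRUE)),
    n_positions = 1, n_experiments = 1, times_h = c(0, 24),
    mode = "full", grid = scene_grid(128, 96), n_cells = 6,
    optical = optical_config(frames_per_timepoint = 2),
    background = background_params(30),
    seed = 2, outdir = out, write_holograms = TRUE)
  res <- run_virtual_experiment(cfg)
  holos <- list.files(file.path(out, "holograms"))
  expect_length(holos, 2)
  stk <- read_stack(file.path(out, "holograms", holos[1]))
  expect_length(stk$images, 2)
  phases <- list.files(file.path(out, "phase"))
  expect_length(phases, 1)
  # arrest: increment ~0 relative to the population mass
  m0 <- res$courses$dry_mass_ng[1]
  expect_lt(abs(res$increments$increment_ng), 0.05 * m0)
})

test_that("an unseparable carrier triggers the separation warning", {
  sc <- random_scene(6, tiny_grid(), seed = 1)
  cfg <- optical_config(carrier_cpp = c(0.03, 0.03))
  expect_warning(acquire_timepoint(sc, optical_config(
    carrier_cpp = c(0.03, 0.03), frames_per_timepoint = 1),
    check_separation = TRUE), "separate")
  expect_silent(invisible(acquire_timepoint(sc, optical_config(
    frames_per_timepoint = 1), check_separation = TRUE)))
})

test_that("layout validation demands exactly one control arm", {
  arm <- condition_arm("a", scenario_spec("arrest"))
  expect_error(experiment_config(conditions = list(arm)),
               "exactly one", class = "holomass_config_error")
  two_ctrl <- list(condition_arm("a", scenario_spec("arrest"),
                                 control = TRUE),
                   condition_arm("b", scenario_spec("arrest"),
                                 control = TRUE))
  expect_error(experiment_config(conditions = two_ctrl), "exactly one")
})

test_that("the CLI verbs chain on real files with correct exit codes", {
  dir <- tempfile(); dir.create(dir)
  cfg_path <- file.path(dir, "cfg.json")
  save_config(two_arm_config(5), cfg_path)
  out <- file.path(dir, "run")
  expect_equal(holomass_cli(c("run-all", "--config", cfg_path,
                              "--out", out, "--seed", "9")), 0L)
  expect_true(all(file.exists(file.path(out, c("courses.csv",
                                               "increments.csv",
                                               "stats.csv")))))

  holo <- file.path(dir, "holo.tif")
  phase <- file.path(dir, "phase.tif")
  dmcsv <- file.path(dir, "dm.csv")
  expect_equal(holomass_cli(c("simulate", "--out", holo, "--seed", "3",
                              "--n-cells", "15", "--frames", "2")), 0L)
  expect_equal(holomass_cli(c("reconstruct", "--in", holo,
                              "--out", phase)), 0L)
  expect_equal(holomass_cli(c("drymass", "--in", phase,
                              "--out", dmcsv)), 0L)
  expect_gt(read.csv(dmcsv)$dry_mass_ng[1], 0)
  expect_equal(holomass_cli(c("stats", "--in",
                              file.path(out, "increments.csv"),
                              "--out", file.path(dir, "st.csv"))), 0L)

  # exit codes: 2 for config problems, 3 for data problems
  expect_equal(holomass_cli(c("run-all", "--config", "does_not_exist.json",
                              "--out", out)), 2L)
  bad_csv <- file.path(dir, "bad.csv")
  write.csv(data.frame(x = 1:3), bad_csv, row.names = FALSE)
  expect_equal(holomass_cli(c("stats", "--in", bad_csv,
                              "--out", file.path(dir, "y.csv"))), 3L)
})
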