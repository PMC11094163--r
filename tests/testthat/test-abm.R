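# Agent-based simulation: schedules, hazard calibration, trajectories.

test_that("schedules split the PDT time into two equal phases in order", {
  s1 <- build_schedule("405-580", 60)
  expect_identical(s1$wavelength_nm, c(405, 580))
  expect_identical(s1$duration_min, c(30, 30))
  expect_identical(attr(s1, "kill_phase"), 2L)

  s2 <- build_schedule("580-405", 60)
  expect_identical(s2$wavelength_nm, c(580, 405))
  expect_identical(attr(s2, "kill_phase"), 1L)

  s3 <- build_schedule("405-580", 2, dt = 1)
  expect_identical(s3$duration_min, c(1, 1))

  expect_error(build_schedule("405-580", 5, dt = 2), "whole number")
  expect_error(build_schedule("both", 60), "protocol")
})

test_that("per-step hazard calibrates expected survival", {
  expect_equal(hazard_per_step(0.25, 2), 0.5)
  expect_identical(hazard_per_step(1, 30), 0)
  expect_equal(hazard_per_step(0.45, 30), 1 - 0.45^(1 / 30))
  expect_equal(round(hazard_per_step(0.45, 30), 5), 0.02627)
  # survival after kill_steps trials has the target expectation
  for (target in c(0.1, 0.45, 0.9)) {
    p <- hazard_per_step(target, 30)
    expect_equal((1 - p)^30, target, tolerance = 1e-12)
  }
  expect_warning(h0 <- hazard_per_step(0, 10), "saturates")
  expect_identical(h0, 1)
  expect_error(hazard_per_step(-0.1, 10), ">=")
  expect_error(hazard_per_step(1.1, 10), "<=")
  expect_error(hazard_per_step(0.5, 0), ">=")
})

test_that("trajectories conserve cells, start at 1, and only fall in the kill phase", {
  fit <- default_fit()
  cfg <- simulation_config(n_cells = 400, seed = 11, replicates = 4)
  for (prot in pdt_protocols()) {
    res <- run_simulation(fit, 1.5, prot, 60, 400, cfg)
    traj <- res$replicate_trajectories
    expect_identical(dim(traj), c(4L, 61L))
    expect_true(all(traj[, 1] == 1))
    expect_true(all(diff(t(traj)) <= 0)) # monotone non-increasing
    # counts are multiples of 1/n_cells: ACTIVE + DEAD = n_cells
    expect_true(all(abs(traj * 400 - round(traj * 400)) < 1e-9))
    kill_first <- attr(res$schedule, "kill_phase") == 1L
    outside <- if (kill_first) 32:61 else 1:31
    expect_true(all(traj[, outside] == traj[, outside[1]]))
    expect_identical(res$final_viability, mean(traj[, 61]))
    expect_identical(res$trajectory[61], res$final_viability)
  }
})

test_that("photosensitizer agents activate to the protocol state at light onset", {
  fit <- default_fit()
  cfg <- simulation_config(n_cells = 50, seed = 1, replicates = 1)
  r1 <- run_simulation(fit, 2, "405-580", 60, 400, cfg)
  expect_identical(r1$photosensitizers$n_agents, 200)
  expect_identical(r1$photosensitizers$initial_state, "INACTIVE")
  expect_identical(r1$photosensitizers$activated_state, "ACTIVATED_405_580")
  r2 <- run_simulation(fit, 2, "580-405", 60, 400, cfg)
  expect_identical(r2$photosensitizers$activated_state, "ACTIVATED_580_405")
})

test_that("mean final viability is calibrated to the surrogate prediction", {
  fit <- default_fit()
  cfg <- simulation_config(n_cells = 1000, seed = 7, replicates = 20)
  for (prot in pdt_protocols()) {
    res <- run_simulation(fit, 2, prot, 60, 400, cfg)
    target <- res$target_viability
    n <- cfg$n_cells * cfg$replicates
    ci_half <- qnorm(0.995) * sqrt(target * (1 - target) / n)
    expect_lt(abs(res$final_viability - target), ci_half + 1e-12)
  }
})

test_that("an inert surface (target survival 1) leaves the trajectory flat", {
  # hand-built network with all-zero weights and output bias 2: the clipped
  # prediction is exactly 1 everywhere
  inert <- default_fit()
  inert$theta <- c(rep(0, length(inert$theta) - 1), 2)
  cfg <- simulation_config(n_cells = 200, seed = 2, replicates = 2)
  res <- run_simulation(inert, 2, "580-405", 60, 400, cfg)
  expect_identical(res$target_viability, 1)
  expect_true(all(res$replicate_trajectories == 1))
  expect_identical(res$final_viability, 1)
})

test_that("simulations are deterministic given the config", {
  fit <- default_fit()
  cfg <- simulation_config(n_cells = 300, seed = 9, replicates = 3)
  r1 <- run_simulation(fit, 2, "405-580", 60, 400, cfg)
  r2 <- run_simulation(fit, 2, "405-580", 60, 400, cfg)
  expect_identical(r1$replicate_trajectories, r2$replicate_trajectories)
  r3 <- run_simulation(fit, 2, "405-580", 60, 400,
                       simulation_config(n_cells = 300, seed = 10,
                                         replicates = 3))
  expect_false(identical(r1$replicate_finals, r3$replicate_finals))
})

test_that("protocol comparison pairs seeds and reports the 580-405 advantage gap", {
  fit <- default_fit()
  cfg <- simulation_config(n_cells = 500, seed = 7, replicates = 5)
  cmp <- compare_protocols(fit, 2, 60, 400, cfg)
  expect_equal(cmp$difference,
               cmp$result_580_405$final_viability -
                 cmp$result_405_580$final_viability)
  expect_identical(cmp$result_405_580$config$seed,
                   cmp$result_580_405$config$seed)
  expect_gt(cmp$difference, 0)

  # equal protocol effects -> difference vanishes within Monte-Carlo error
  cmp0 <- compare_protocols(inert_fit(), 2, 60, 400, cfg)
  expect_lt(abs(cmp0$difference), 0.03)
})

test_that("simulated protocol advantage is non-negative across the grid", {
  fit <- default_fit()
  cfg <- simulation_config(n_cells = 500, seed = 7, replicates = 5)
  for (conc in seq(0.25, 2.25, by = 0.5)) {
    cmp <- compare_protocols(fit, conc, 60, 400, cfg)
    expect_gte(cmp$difference, -0.02)
  }
})

test_that("unfitted models and bad configs are rejected", {
  expect_error(run_simulation(structure(list(), class = "surrogate_model"),
                              2, "405-580", 60, 400), "fitted")
  expect_error(simulation_config(replicates = 0), ">=")
  expect_error(simulation_config(n_cells = 0), ">=")
})

test_that("simulation JSON carries trajectory, finals and seeds", {
  fit <- default_fit()
  res <- run_simulation(fit, 2, "405-580", 60, 400,
                        simulation_config(n_cells = 100, seed = 7,
                                          replicates = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_simulation_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$trajectory, res$trajectory)
  expect_equal(back$replicate_finals, res$replicate_finals)
  expect_identical(back$seed, 7L)
  expect_identical(back$n_cells, 100L)
})
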