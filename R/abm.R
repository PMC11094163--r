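# Agent-based simulation of PDT cell kill under a sequential two-phase light
# schedule. Cell agents are ACTIVE or DEAD (absorbing); photosensitizer
# agents flip from INACTIVE to the protocol's activated state at first light
# onset. Cytotoxicity is confined to the 580 nm (photoactivation) phase and
# is calibrated so the expected surviving fraction equals the surrogate's
# predicted viability at the simulated condition.

#' Build a two-phase light schedule for a sequential protocol
#'
#' Splits the total PDT time into two equal phases in protocol order. The
#' kill phase is the 580 nm phase, where the released photosensitizer is
#' photoactivated: second for 405-580, first for 580-405.
#'
#' @param protocol One of [pdt_protocols()].
#' @param pdt_time Total PDT time, minutes; each phase (`pdt_time / 2`) must
#'   be a whole multiple of `dt`.
#' @param dt Simulation step, minutes per step.
#' @return A `pdt_schedule`: data frame of phases (`wavelength_nm`,
#'   `duration_min`) with attributes `kill_phase` (index) and `dt`.
#' @export
#' @examples
#' build_schedule("405-580", 60)
build_schedule <- function(protocol, pdt_time, dt = 1) {
  check_protocol(protocol)
  check_number(pdt_time, "pdt_time", min = 0, strict = TRUE)
  check_number(dt, "dt", min = 0, strict = TRUE)
  half <- pdt_time / 2
  if (abs(half / dt - round(half / dt)) > 1e-9) {
    stop_invalid("`pdt_time`/2 (", half, " min) is not a whole number of ",
                 "dt = ", dt, " min steps")
  }
  order_nm <- if (protocol == "405-580") c(405, 580) else c(580, 405)
  phases <- data.frame(wavelength_nm = order_nm,
                       duration_min = c(half, half))
  structure(phases, kill_phase = which(order_nm == 580), dt = dt,
            protocol = protocol, class = c("pdt_schedule", "data.frame"))
}

#' @export
print.pdt_schedule <- function(x, ...) {
  cat(sprintf("PDT light schedule (%s), dt = %g min:\n",
              attr(x, "protocol"), attr(x, "dt")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  phase %d: %d nm for %g min%s\n", i, x$wavelength_nm[i],
                x$duration_min[i],
                if (i == attr(x, "kill_phase")) "  [photoactivation]" else ""))
  }
  invisible(x)
}

#' Per-step death probability realizing a target survival
#'
#' With `kill_steps` independent Bernoulli death trials per cell, a per-step
#' hazard `p = 1 - s^(1/kill_steps)` makes the expected surviving fraction
#' equal the target `s`.
#'
#' @param target_survival Target surviving fraction in \eqn{(0, 1]}; a target
#'   of exactly 0 returns hazard 1 with a warning.
#' @param kill_steps Number of kill-phase steps (>= 1).
#' @return Per-step death probability.
#' @export
#' @examples
#' hazard_per_step(0.25, 2) # 0.5
#' hazard_per_step(0.45, 30)
hazard_per_step <- function(target_survival, kill_steps) {
  check_number(target_survival, "target_survival", min = 0)
  kill_steps <- check_count(kill_steps, "kill_steps", min = 1L)
  if (target_survival > 1) stop_invalid("`target_survival` must be <= 1")
  if (target_survival == 0) {
    warning("target survival of 0: hazard saturates at 1", call. = FALSE)
    return(1)
  }
  1 - target_survival^(1 / kill_steps)
}

#' Simulation configuration
#'
#' @param n_cells Number of cell agents per replicate (>= 1).
#' @param dt Minutes per simulation step (> 0).
#' @param seed Integer base seed; replicate `k` uses `seed + k - 1`.
#' @param replicates Number of independent replicates (>= 1).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cells = 1000L, dt = 1, seed = 7L,
                              replicates = 20L) {
  n_cells <- check_count(n_cells, "n_cells", min = 1L)
  check_number(dt, "dt", min = 0, strict = TRUE)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  replicates <- check_count(replicates, "replicates", min = 1L)
  structure(list(n_cells = n_cells, dt = dt, seed = seed,
                 replicates = replicates), class = "simulation_config")
}

#' Run the agent-based PDT simulation at one treatment condition
#'
#' Simulates `config$n_cells` cell agents over the two-phase light schedule
#' of the condition's protocol. At the first light step all photosensitizer
#' agents (bookkeeping agents, 100 per mg/mL of concentration) switch from
#' INACTIVE to the protocol's activated state. During each step of the
#' 580 nm phase every ACTIVE cell dies independently with the constant
#' hazard that calibrates the expected final surviving fraction to
#' `predict_viability(model, condition)`; no deaths occur outside the kill
#' phase. Replicate `k` is seeded with `config$seed + k - 1`, so results are
#' deterministic given `(model, condition, config)`.
#'
#' @param model A fitted [fit_surrogate()] model.
#' @param concentration,protocol,pdt_time,input_power Treatment condition.
#' @param config A [simulation_config()].
#' @return A `simulation_result`: mean `trajectory` (viability per step,
#'   starting at 1), per-replicate trajectories and finals, `final_viability`
#'   (mean over replicates), the target viability queried from the surrogate,
#'   photosensitizer agent bookkeeping, and the condition.
#' @export
run_simulation <- function(model, concentration, protocol, pdt_time,
                           input_power, config = simulation_config()) {
  if (!inherits(model, "surrogate_model") || is.null(model$theta)) {
    stop_invalid("`model` must be a fitted surrogate_model")
  }
  stopifnot(inherits(config, "simulation_config"))
  check_condition(concentration, protocol, pdt_time, input_power)
  schedule <- build_schedule(protocol, pdt_time, dt = config$dt)

  target <- predict_viability(model, concentration, protocol, pdt_time,
                              input_power)
  steps_per_phase <- round(schedule$duration_min / config$dt)
  n_steps <- sum(steps_per_phase)
  kill_phase <- attr(schedule, "kill_phase")
  kill_steps_idx <- seq_len(steps_per_phase[kill_phase]) +
    if (kill_phase == 1L) 0L else steps_per_phase[1L]
  p <- hazard_per_step(target, length(kill_steps_idx))

  traj <- matrix(NA_real_, nrow = config$replicates, ncol = n_steps + 1L)
  for (k in seq_len(config$replicates)) {
    traj[k, ] <- with_seed(config$seed + k - 1L, {
      active <- config$n_cells
      v <- numeric(n_steps + 1L)
      v[1L] <- 1
      for (s in seq_len(n_steps)) {
        if (s %in% kill_steps_idx && active > 0L) {
          active <- active - rbinom(1L, active, p)
        }
        v[s + 1L] <- active / config$n_cells
      }
      v
    })
  }
  finals <- traj[, n_steps + 1L]
  activated_state <- paste0("ACTIVATED_", gsub("-", "_", protocol))
  structure(
    list(
      condition = list(concentration = concentration, protocol = protocol,
                       pdt_time = pdt_time, input_power = input_power),
      schedule = schedule,
      target_viability = target,
      hazard = p,
      time_min = seq(0, n_steps) * config$dt,
      trajectory = colMeans(traj),
      replicate_trajectories = traj,
      replicate_finals = finals,
      final_viability = mean(finals),
      final_sd = if (length(finals) > 1L) sd(finals) else 0,
      photosensitizers = list(n_agents = round(100 * concentration),
                              initial_state = "INACTIVE",
                              activated_state = activated_state,
                              activation_step = 1L),
      config = config
    ),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "PDT agent-based simulation: %g mg/mL, %s, %g min, %g mW\n",
    x$condition$concentration, x$condition$protocol, x$condition$pdt_time,
    x$condition$input_power))
  cat(sprintf("  %d cells x %d replicates; surrogate target %.4f\n",
              x$config$n_cells, x$config$replicates, x$target_viability))
  cat(sprintf("  mean final viability %.4f (SD %.4f)\n",
              x$final_viability, x$final_sd))
  invisible(x)
}

#' Compare the two sequential protocols at a common condition
#'
#' Runs [run_simulation()] under both protocols with identical replicate
#' seeds and returns the paired results with the difference in mean final
#' viability (580-405 minus 405-580) — positive when the
#' release-before-activation order kills more cells.
#'
#' @inheritParams run_simulation
#' @return A `protocol_comparison` list: `result_405_580`, `result_580_405`,
#'   and `difference`.
#' @export
compare_protocols <- function(model, concentration, pdt_time, input_power,
                              config = simulation_config()) {
  r1 <- run_simulation(model, concentration, "405-580", pdt_time,
                       input_power, config)
  r2 <- run_simulation(model, concentration, "580-405", pdt_time,
                       input_power, config)
  structure(
    list(result_405_580 = r1, result_580_405 = r2,
         difference = r2$final_viability - r1$final_viability),
    class = "protocol_comparison"
  )
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat(sprintf(
    "Protocol comparison at %g mg/mL, %g min, %g mW:\n",
    x$result_405_580$condition$concentration,
    x$result_405_580$condition$pdt_time,
    x$result_405_580$condition$input_power))
  cat(sprintf("  405-580 mean final viability: %.4f\n",
              x$result_405_580$final_viability))
  cat(sprintf("  580-405 mean final viability: %.4f\n",
              x$result_580_405$final_viability))
  cat(sprintf("  difference (580-405 minus 405-580): %.4f\n", x$difference))
  invisible(x)
}

#' Serialize a simulation result as JSON
#'
#' Writes the trajectory, per-replicate finals, mean and SD, condition and
#' seeds to a JSON file.
#'
#' @param result A `simulation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_json <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  payload <- list(
    condition = result$condition,
    target_viability = result$target_viability,
    hazard_per_step = result$hazard,
    time_min = result$time_min,
    trajectory = result$trajectory,
    replicate_finals = result$replicate_finals,
    final_viability = result$final_viability,
    final_sd = result$final_sd,
    n_cells = result$config$n_cells,
    replicates = result$config$replicates,
    seed = result$config$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
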