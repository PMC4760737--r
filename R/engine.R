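#' Run the gut community simulation
#'
#' Executes the full tick loop: scheduled nutrient/mucus/antibiotic entry,
#' gut-mediated feedback emissions, bacterial actions in randomized order
#' (search, movement, substrate conversion, division, starvation/toxin/drug
#' death), then passive-particle transport with wall absorption and
#' excretion. Runs are fully reproducible: the RNG is seeded from
#' `params$rng_seed` (or the `seed` argument) before the loop starts.
#'
#' @param params a `gut_params` object.
#' @param ticks number of ticks to simulate (`ticks * params$tick_hours`
#'   hours of model time).
#' @param record_every record a trajectory row every this many ticks.
#' @param snapshot_every if > 0, store a bacteria snapshot every this many
#'   ticks.
#' @param snapshot_particles also return the final particle table.
#' @param seed optional override of `params$rng_seed`.
#' @return An object of class `gut_sim`: a list with `trajectory` (one row
#'   per recorded tick: counts of sensitive/resistant bacteria per type,
#'   particle pools per kind, cumulative birth/death ledgers by cause,
#'   cumulative per-kind mass ledgers, feedback event counts),
#'   `final_bacteria` (agent table), `snapshots`, and `params`.
#' @examples
#' p <- gut_params(initial_bacteria_1 = 20, initial_bacteria_2 = 20,
#'                 initial_ps = 100, initial_acetate = 0,
#'                 initial_propionate = 0, initial_butyrate = 0,
#'                 gut_length_L = 20000, gut_width_D = 6000)
#' sim <- run_simulation(p, ticks = 50)
#' tail(sim$trajectory[, c("hours", "n1_sens", "n2_sens", "ps")], 3)
#' @export
run_simulation <- function(params, ticks = 10000, record_every = 1,
                           snapshot_every = 0, snapshot_particles = FALSE,
                           seed = NULL) {
  stopifnot(inherits(params, "gut_params"), ticks > 0)
  if (!is.null(seed)) params$rng_seed <- as.integer(seed)
  set.seed(params$rng_seed)
  raw <- .abm_run(unclass(params), as.integer(ticks),
                  as.integer(record_every), as.integer(snapshot_every),
                  isTRUE(snapshot_particles))
  traj <- as.data.frame(raw$trajectory)
  out <- list(
    trajectory = traj,
    final_bacteria = raw$final_bacteria,
    snapshots = raw$snapshots,
    snapshot_ticks = raw$snapshot_ticks,
    final_particles = raw$final_particles,
    params = params
  )
  class(out) <- "gut_sim"
  out
}

#' @export
print.gut_sim <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat("Gut ABM run: ", last$tick, " ticks (", round(last$hours, 2),
      " h)\n", sep = "")
  cat("  final counts: type 1 = ", last$n1_sens + last$n1_res,
      " (", last$n1_res, " resistant), type 2 = ",
      last$n2_sens + last$n2_res, " (", last$n2_res, " resistant)\n",
      sep = "")
  cat("  particles: ps = ", last$ps, ", acetate = ", last$acetate,
      ", propionate = ", last$propionate, ", butyrate = ", last$butyrate,
      "\n", sep = "")
  invisible(x)
}

#' Per-type bacterial counts from a trajectory
#'
#' @param traj a trajectory data frame from [run_simulation()].
#' @return The data frame with added `n1`, `n2` total-count columns and an
#'   `r_frac` community-wide resistant fraction column (NA where the
#'   community is empty).
#' @export
with_totals <- function(traj) {
  traj$n1 <- traj$n1_sens + traj$n1_res
  traj$n2 <- traj$n2_sens + traj$n2_res
  tot <- traj$n1 + traj$n2
  res <- traj$n1_res + traj$n2_res
  traj$r_frac <- ifelse(tot > 0, res / tot, NA_real_)
  traj
}

#' Check the per-kind mass ledger of a trajectory
#'
#' For every particle kind and every recorded tick the pool count must
#' equal `injected + produced + released - consumed - wall_absorbed -
#' excreted - decayed - uptaken` (all in quanta). This is an exact
#' accounting identity of the engine, exposed for testing and diagnostics.
#'
#' @param traj a trajectory data frame from [run_simulation()].
#' @return Maximum absolute discrepancy over all kinds and ticks (0 for a
#'   conserving run).
#' @export
ledger_discrepancy <- function(traj) {
  kinds <- c("ps", "ps_gut", "acetate", "propionate", "butyrate",
             "toxin1", "toxin2", "antibiotic")
  worst <- 0
  for (k in kinds) {
    bal <- traj[[paste0("led_", k, "_injected")]] +
      traj[[paste0("led_", k, "_produced")]] +
      traj[[paste0("led_", k, "_released")]] -
      traj[[paste0("led_", k, "_consumed")]] -
      traj[[paste0("led_", k, "_wall_absorbed")]] -
      traj[[paste0("led_", k, "_excreted")]] -
      traj[[paste0("led_", k, "_decayed")]] -
      traj[[paste0("led_", k, "_uptaken")]]
    worst <- max(worst, max(abs(traj[[k]] - bal)))
  }
  worst
}

#' Drug-mass ledger discrepancy
#'
#' Antibiotic conservation: quanta that entered the gut must equal the
#' luminal pool plus the load inside living bacteria plus everything
#' excreted, minus nothing else (dead bacteria re-release their load).
#'
#' @param traj a trajectory data frame from [run_simulation()].
#' @return Maximum absolute discrepancy over recorded ticks.
#' @export
drug_ledger_discrepancy <- function(traj) {
  in_bact <- traj$led_antibiotic_uptaken - traj$led_antibiotic_released
  bal <- traj$led_antibiotic_injected - in_bact -
    traj$led_antibiotic_excreted - traj$led_antibiotic_wall_absorbed
  max(abs(traj$antibiotic - bal), abs(traj$drug_in_bacteria - in_bact))
}
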