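## Experiment harness: derived seeds, initial-condition sweeps, the
## feedback stability screen and the resistance-outcome parameter map.

#' Desk-scale experiment profile
#'
#' The published geometry scaled to a single-workstation setting: a
#' 150 x 30 mm gut section at a 0.02 h tick, with every kinetic constant,
#' agent-behavior parameter and initial count left at its default. All
#' feedback screens, sweeps and treatment experiments in the package
#' documentation run on this profile; runs of 10^4 to 10^5 ticks take
#' seconds to a couple of minutes each.
#'
#' @param ... named overrides passed on to [gut_params()].
#' @return A `gut_params` object.
#' @export
desk_params <- function(...) {
  gut_params(gut_length_L = 150000, gut_width_D = 30000,
             tick_hours = 0.02, ...)
}

#' Derive a per-run seed
#'
#' Deterministic, collision-avoiding child seeds from a base seed, kept
#' inside the 32-bit integer range.
#'
#' @param base_seed integer base seed.
#' @param index run index (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 48271 + index * 65537) %% 2147483629 + 1)
}

#' Sweep over initial bacterial counts
#'
#' Runs the model across a grid of initial (type 1, type 2) counts with
#' several replicates per cell — the protocol behind the bistability
#' analysis (full scale: initial counts from 200 up to 3000 in steps of
#' 200, 14 x 14 cells, 3 replicates = 588 runs) — and records each run's
#' long-run mean state.
#'
#' @param params base `gut_params`.
#' @param grid vector of initial counts applied to both types.
#' @param replicates runs per grid cell.
#' @param ticks ticks per run.
#' @param base_seed seed from which per-run seeds are derived.
#' @return Data frame with `n1_init`, `n2_init`, `replicate`, `seed`,
#'   `n1`, `n2` (long-run means) and `coexist`.
#' @export
sweep_initial_conditions <- function(params, grid = seq(200, 2800, by = 200),
                                     replicates = 3, ticks = 10000,
                                     base_seed = params$rng_seed) {
  cells <- expand.grid(n1_init = grid, n2_init = grid,
                       replicate = seq_len(replicates))
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- params
    p$initial_bacteria_1 <- cells$n1_init[i]
    p$initial_bacteria_2 <- cells$n2_init[i]
    seed <- derive_seed(base_seed, i)
    sim <- run_simulation(p, ticks = ticks, record_every = 10, seed = seed)
    st <- long_run_state(sim$trajectory)
    res[[i]] <- data.frame(cells[i, ], seed = seed, n1 = st[["n1"]],
                           n2 = st[["n2"]],
                           coexist = sustains_coexistence(sim$trajectory))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Stability screen over feedback networks
#'
#' Runs each listed feedback configuration across several seeds and
#' reports how often it sustains coexistence of both types — the screen
#' that classifies single feedbacks as stabilizing or not.
#'
#' @param params base `gut_params` (its `feedbacks_enabled` is replaced
#'   per network).
#' @param networks named list of feedback sets, e.g.
#'   `list(basic = character(0), FB1 = "FB1")`.
#' @param seeds vector of seeds per network.
#' @param ticks ticks per run.
#' @param floor_count coexistence floor for [sustains_coexistence()].
#' @return Data frame with `network`, `seed`, `coexist`, `n1`, `n2`.
#' @export
feedback_screen <- function(params, networks, seeds = 1:5, ticks = 20000,
                            floor_count = 10) {
  res <- list()
  for (nm in names(networks)) {
    p <- params
    p$feedbacks_enabled <- toupper(as.character(networks[[nm]]))
    for (s in seeds) {
      sim <- run_simulation(p, ticks = ticks, record_every = 10, seed = s)
      st <- long_run_state(sim$trajectory)
      res[[length(res) + 1]] <- data.frame(
        network = nm, seed = s,
        coexist = sustains_coexistence(sim$trajectory, floor_count),
        n1 = st[["n1"]], n2 = st[["n2"]])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Resistance-outcome parameter map
#'
#' For each (Rc, alpha) cell runs replicated antibiotic courses,
#' classifies each run with [classify_outcome()] and reports the modal
#' class — the phase portrait of resistance outcomes over fitness cost
#' and mutation pressure.
#'
#' @param params base `gut_params` with an antibiotic course configured.
#' @param rc_grid retardation constants (>= 1).
#' @param alpha_grid mutation-rate scales.
#' @param replicates runs per cell.
#' @param ticks ticks per run.
#' @param window classification window, hours (default 10 x course
#'   length).
#' @param base_seed seed from which per-run seeds are derived.
#' @return Data frame with `Rc`, `alpha`, `modal_class` and per-class
#'   vote counts.
#' @export
resistance_parameter_map <- function(params, rc_grid, alpha_grid,
                                     replicates = 3, ticks = 30000,
                                     window = NULL,
                                     base_seed = params$rng_seed) {
  course_end <- params$ant_course_start + params$ant_course_days * 24
  if (is.null(window)) window <- 10 * params$ant_course_days * 24
  cells <- expand.grid(Rc = rc_grid, alpha = alpha_grid)
  out <- cells
  out$modal_class <- NA_integer_
  out$votes_1 <- out$votes_2 <- out$votes_3 <- 0L
  idx <- 0
  for (i in seq_len(nrow(cells))) {
    p <- params
    p$retardation_constant_Rc <- cells$Rc[i]
    p$mutation_rate_scale_alpha <- cells$alpha[i]
    cls <- integer(replicates)
    for (r in seq_len(replicates)) {
      idx <- idx + 1
      sim <- run_simulation(p, ticks = ticks, record_every = 10,
                            seed = derive_seed(base_seed, idx))
      cls[r] <- classify_outcome(sim$trajectory, course_end, window)
    }
    tab <- tabulate(cls, nbins = 3)
    out$votes_1[i] <- tab[1]; out$votes_2[i] <- tab[2]
    out$votes_3[i] <- tab[3]
    out$modal_class[i] <- which.max(tab)
  }
  out
}
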