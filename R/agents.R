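## Reference semantics of the per-bacterium behavior cycle.
##
## These pure R functions state the decision rules one agent follows in a
## single tick — the same rules the compiled engine applies to the whole
## population. They exist so the rules can be unit-tested and read in
## isolation; the engine is the production path.

#' Create a bacterium record
#'
#' @param type bacterial type, 1 or 2.
#' @param x,y position, um.
#' @param energy mmol of substrate converted since the last division.
#' @param hunger_clock hours since last feeding.
#' @param starvation_limit hours the bacterium survives without food.
#' @param resistant logical, antibiotic resistance state.
#' @param accumulated_antibiotic absorbed drug quanta.
#' @return A list of class `gut_bacterium`.
#' @export
bacterium <- function(type, x = 0, y = 0, energy = 0, hunger_clock = 0,
                      starvation_limit = 24, resistant = FALSE,
                      accumulated_antibiotic = 0) {
  stopifnot(type %in% c(1, 2))
  structure(list(type = type, x = x, y = y, energy = energy,
                 hunger_clock = hunger_clock,
                 starvation_limit = starvation_limit,
                 resistant = resistant,
                 accumulated_antibiotic = accumulated_antibiotic),
            class = "gut_bacterium")
}

#' Substrate kinds a bacterium can eat
#'
#' Type 1 ferments dietary and host polysaccharides to acetate; type 2
#' ferments dietary polysaccharide to acetate and propionate; the
#' acetate-to-butyrate conversion belongs to `p$acetate_consumer_type`
#' (the exploitation link: by default the dominant type 2 consumes the
#' partner's acetate). A type also "eats" the toxin kind it detoxifies.
#'
#' @param type bacterial type, 1 or 2.
#' @param p a `gut_params` object.
#' @return Character vector of particle kinds.
#' @export
edible_kinds <- function(type, p = gut_params()) {
  ace_owner <- p$acetate_consumer_type
  kinds <- character(0)
  if (type == 1) {
    if (p$k_ps_to_acetate_1 > 0 || p$k_ps_to_propionate_1 > 0)
      kinds <- c(kinds, "ps")
    if (p$k_psgut_to_acetate_1 > 0) kinds <- c(kinds, "ps_gut")
    kinds <- c(kinds, "toxin1")
  } else {
    if (p$k_ps_to_acetate_2 > 0 || p$k_ps_to_propionate_2 > 0)
      kinds <- c(kinds, "ps")
    if (p$k_psgut_to_acetate_2 > 0) kinds <- c(kinds, "ps_gut")
    kinds <- c(kinds, "toxin2")
  }
  if (ace_owner == type &&
      max(p$k_acetate_to_butyrate_1, p$k_acetate_to_butyrate_2) > 0)
    kinds <- c(kinds, "acetate")
  kinds
}

#' Choose the next action of a bacterium
#'
#' The behavior cycle: a bacterium past its starvation limit dies; one with
#' enough converted substrate divides; otherwise it converts substrate in
#' contact range, moves toward the nearest edible particle inside the
#' search radius, or performs a random-walk search step.
#'
#' @param b a [bacterium()].
#' @param particles data frame with columns `kind`, `x`, `y` (the local
#'   particle field).
#' @param p a `gut_params` object.
#' @return One of `"dying"`, `"dividing"`, `"converting"`, `"moving"`,
#'   `"searching"`.
#' @export
choose_action <- function(b, particles, p = gut_params()) {
  if (b$hunger_clock > b$starvation_limit) return("dying")
  if (b$energy >= p$division_threshold) return("dividing")
  if (nrow(particles) == 0) return("searching")
  ed <- particles[particles$kind %in% edible_kinds(b$type, p), , drop = FALSE]
  if (nrow(ed) == 0) return("searching")
  d <- sqrt((ed$x - b$x)^2 + (ed$y - b$y)^2)
  if (any(d <= p$contact_radius)) return("converting")
  if (any(d <= p$search_radius_R)) return("moving")
  "searching"
}

#' Displace a bacterium one tick
#'
#' Moves by `bacterial_speed * dt` along the unit vector toward `target`
#' (landing on it if closer than one step), or in a uniform-random
#' direction when no target is given, reflecting at the gut boundaries.
#'
#' @param b a [bacterium()].
#' @param target optional `c(x, y)` to move toward.
#' @param p a `gut_params` object.
#' @param dt tick length in hours (default `p$tick_hours`).
#' @return The displaced bacterium.
#' @export
move_bacterium <- function(b, target = NULL, p = gut_params(),
                           dt = p$tick_hours) {
  step <- p$bacterial_speed * dt
  if (is.null(target)) {
    ang <- stats::runif(1, 0, 2 * pi)
    nx <- b$x + cos(ang) * step
    ny <- b$y + sin(ang) * step
  } else {
    d <- sqrt((target[1] - b$x)^2 + (target[2] - b$y)^2)
    if (d <= step || d == 0) {
      nx <- target[1]; ny <- target[2]
    } else {
      nx <- b$x + (target[1] - b$x) / d * step
      ny <- b$y + (target[2] - b$y) / d * step
    }
  }
  refl <- function(v, lo, hi) {
    if (v < lo) v <- 2 * lo - v
    if (v > hi) v <- 2 * hi - v
    min(max(v, lo), hi)
  }
  b$x <- refl(nx, 0, p$gut_length_L)
  b$y <- refl(ny, 0, p$gut_width_D)
  b
}

#' Divide a bacterium
#'
#' Two daughters at the parent position (small random offset), energy reset
#' to zero, starvation limits redrawn independently from
#' `U(0, n * eat_period]`; type and resistance state are inherited. Each
#' sensitive daughter mutates to resistant with probability
#' `min(1, alpha * C / Rc)` where `C` is the local antibiotic level in
#' quanta.
#'
#' @param b a [bacterium()] with `energy >= p$division_threshold`.
#' @param p a `gut_params` object.
#' @param local_antibiotic antibiotic quanta within contact range.
#' @return A list of two daughter bacteria.
#' @export
divide_bacterium <- function(b, p = gut_params(), local_antibiotic = 0) {
  stopifnot(b$energy >= p$division_threshold)
  pmut <- mutation_probability(local_antibiotic,
                               p$mutation_rate_scale_alpha,
                               p$retardation_constant_Rc)
  mk <- function() {
    d <- b
    d$energy <- 0
    d$hunger_clock <- 0
    d$starvation_limit <- stats::runif(1, 0, p$eat_range_multiplier_n *
                                         p$eat_period)
    d$x <- d$x + stats::runif(1, -p$contact_radius, p$contact_radius)
    d$y <- d$y + stats::runif(1, -p$contact_radius, p$contact_radius)
    if (!d$resistant && stats::runif(1) < pmut) d$resistant <- TRUE
    d
  }
  list(mk(), mk())
}

#' Resistance mutation probability
#'
#' `min(1, alpha * C / Rc)`: linear in the local antibiotic level, damped
#' by the fitness cost (a costly resistance is also harder to fix).
#'
#' @param C local antibiotic level, quanta.
#' @param alpha mutation-rate scale, 1/quanta.
#' @param Rc retardation constant (>= 1).
#' @return Probability in `[0, 1]` (vectorized over `C`).
#' @export
mutation_probability <- function(C, alpha, Rc) {
  stopifnot(Rc >= 1, alpha >= 0, all(C >= 0))
  pmin(1, alpha * C / Rc)
}

#' Apply contacted toxin quanta to a bacterium
#'
#' The detoxifying type (type 1 for toxin 1, type 2 for toxin 2) consumes
#' the quanta harmlessly as nutrient; a sensitive type accumulates them and
#' dies once the accumulated dose reaches its lethal threshold; a type with
#' the `Inf` sentinel threshold ignores the toxin.
#'
#' @param b a [bacterium()].
#' @param toxin_kind `"toxin1"` or `"toxin2"`.
#' @param n_quanta contacted quanta.
#' @param accumulated previously accumulated dose of this toxin.
#' @param p a `gut_params` object.
#' @return A list with `fate` (`"detoxified"`, `"unharmed"`, `"accumulating"`
#'   or `"dead"`), `accumulated`, and `consumed` (quanta removed from the
#'   pool).
#' @export
apply_toxins <- function(b, toxin_kind = c("toxin1", "toxin2"),
                         n_quanta = 1, accumulated = 0, p = gut_params()) {
  toxin_kind <- match.arg(toxin_kind)
  detox_type <- if (toxin_kind == "toxin1") 1 else 2
  thr <- p[[paste0("sensitive_", toxin_kind, "_", b$type)]]
  if (b$type == detox_type)
    return(list(fate = "detoxified", accumulated = accumulated,
                consumed = n_quanta))
  if (!is.finite(thr))
    return(list(fate = "unharmed", accumulated = accumulated, consumed = 0))
  acc <- accumulated + n_quanta
  list(fate = if (acc >= thr) "dead" else "accumulating",
       accumulated = acc, consumed = n_quanta)
}
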