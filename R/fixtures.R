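## Deterministic synthetic agent configurations and trajectories.
##
## These generators exercise the observable definitions (segregation,
## recovery, resilience, outcome classes) without running a simulation;
## they emulate snapshot regimes and crossing times, not ecological
## dynamics.

with_fixture_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                            envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Generate a synthetic agent snapshot
#'
#' Deterministic placements for testing the spatial observables:
#' `layered` puts type 1 in the wall mucin zones and type 2 in the lumen;
#' `checkerboard` alternates types on a lattice (locally well mixed);
#' `uniform-mixed` scatters both types uniformly; `two-cluster` separates
#' the types along the gut axis; `custom` passes `positions` through.
#'
#' @param pattern placement pattern.
#' @param n1,n2 bacteria per type.
#' @param L,D gut dimensions, um.
#' @param seed RNG seed (same spec + seed gives an identical table).
#' @param positions for `pattern = "custom"`: data frame with `type`,
#'   `x`, `y`.
#' @return Data frame with columns `type`, `x`, `y`.
#' @export
make_snapshot <- function(pattern = c("layered", "checkerboard",
                                      "uniform-mixed", "two-cluster",
                                      "custom"),
                          n1 = 100, n2 = 100, L = 60000, D = 60000,
                          seed = 1, positions = NULL) {
  pattern <- match.arg(pattern)
  if (pattern == "custom") {
    stopifnot(!is.null(positions),
              all(c("type", "x", "y") %in% names(positions)))
    return(positions)
  }
  with_fixture_seed(seed, {
    if (pattern == "layered") {
      side <- rep(c(0, 1), length.out = n1)
      y1 <- ifelse(side == 0, stats::runif(n1, 0, D / 5),
                   stats::runif(n1, 4 * D / 5, D))
      df <- data.frame(
        type = c(rep(1, n1), rep(2, n2)),
        x = stats::runif(n1 + n2, 0, L),
        y = c(y1, stats::runif(n2, D / 5, 4 * D / 5)))
    } else if (pattern == "checkerboard") {
      # lattice sized so each parity class can hold its type
      g <- max(2, ceiling(sqrt(2 * max(n1, n2))), ceiling(sqrt(n1 + n2)))
      gx <- g; gy <- g
      if (L / gx < 1 || D / gy < 1) stop("counts exceed lattice packing")
      ij <- expand.grid(i = seq_len(gx), j = seq_len(gy))
      ij$par <- (ij$i + ij$j) %% 2
      even <- ij[ij$par == 0, ]
      odd <- ij[ij$par == 1, ]
      if (nrow(even) < n1 || nrow(odd) < n2)
        stop("counts exceed lattice packing")
      pick <- rbind(cbind(even[seq_len(n1), c("i", "j")], type = 1),
                    cbind(odd[seq_len(n2), c("i", "j")], type = 2))
      df <- data.frame(type = pick$type,
                       x = (pick$i - 0.5) * L / gx,
                       y = (pick$j - 0.5) * D / gy)
    } else if (pattern == "uniform-mixed") {
      df <- data.frame(type = c(rep(1, n1), rep(2, n2)),
                       x = stats::runif(n1 + n2, 0, L),
                       y = stats::runif(n1 + n2, 0, D))
    } else {  # two-cluster
      df <- data.frame(
        type = c(rep(1, n1), rep(2, n2)),
        x = c(stats::runif(n1, 0, L / 4), stats::runif(n2, 3 * L / 4, L)),
        y = stats::runif(n1 + n2, 0, D))
    }
    rownames(df) <- NULL
    df
  })
}

#' Generate a synthetic trajectory with a named crossing
#'
#' Piecewise count series that place a recovery, critical-threshold or
#' resistant-fraction event exactly at time `T`, for unit-testing
#' [recovery_time()], [resilience_time()] and [classify_outcome()].
#'
#' Templates: `recovery-at-T` (both types regain 80% of baseline exactly
#' `T` hours after the course ends), `never-recover` (pinned at half the
#' baseline), `hit-100-at-T` (linear decline reaching 100 at hour `T`),
#' `rising-R-fraction` (plateau 0.9 after the course), `decaying-R-fraction`
#' (resistant strains vanish), `oscillating-R-fraction` (fraction cycles
#' between 0.3 and 0.7).
#'
#' @param template trajectory shape.
#' @param T event time, hours (meaning depends on the template).
#' @param course_start,course_end antibiotic course boundaries, hours.
#' @param total_hours series length.
#' @param baseline pre-treatment count per type.
#' @return Data frame with `tick`, `hours`, `n1_sens`, `n1_res`,
#'   `n2_sens`, `n2_res` (1 h sampling).
#' @export
make_trajectory <- function(template = c("recovery-at-T", "never-recover",
                                         "hit-100-at-T",
                                         "oscillating-R-fraction",
                                         "decaying-R-fraction",
                                         "rising-R-fraction"),
                            T = 37, course_start = 100, course_end = 172,
                            total_hours = 1500, baseline = 400) {
  template <- match.arg(template)
  hours <- 0:total_hours
  n <- length(hours)
  zero <- numeric(n)
  df <- data.frame(tick = seq_len(n) - 1, hours = hours,
                   n1_sens = zero, n1_res = zero,
                   n2_sens = zero, n2_res = zero)
  in_course <- hours >= course_start & hours < course_end
  post <- hours >= course_end
  if (template == "recovery-at-T") {
    stopifnot(course_end + T <= total_hours)
    counts <- rep(baseline, n)
    counts[in_course] <- baseline / 4
    counts[post & hours < course_end + T] <- baseline / 4
    counts[hours >= course_end + T] <- baseline
    df$n1_sens <- df$n2_sens <- counts
  } else if (template == "never-recover") {
    counts <- rep(baseline, n)
    counts[hours >= course_start] <- baseline / 2
    df$n1_sens <- df$n2_sens <- counts
  } else if (template == "hit-100-at-T") {
    stopifnot(T > 0, T <= total_hours)
    start <- 10 * 100
    counts <- pmax(start - (start - 100) * hours / T, 60)
    df$n1_sens <- counts
    df$n2_sens <- rep(start, n)
  } else {
    stopifnot(course_end + T <= total_hours)
    frac <- rep(0, n)
    if (template == "rising-R-fraction") {
      frac[post] <- 0.9
    } else if (template == "decaying-R-fraction") {
      frac[in_course] <- 0.5
      frac[post] <- 0.5 * exp(-(hours[post] - course_end) / (T / 4))
      frac[hours >= course_end + T] <- 0
    } else {  # oscillating
      frac[post] <- 0.5 + 0.2 * sin(2 * pi * (hours[post] - course_end) / T)
      frac[in_course] <- 0.5
    }
    df$n1_res <- round(baseline * frac)
    df$n1_sens <- baseline - df$n1_res
    df$n2_res <- round(baseline * frac)
    df$n2_sens <- baseline - df$n2_res
  }
  df
}
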