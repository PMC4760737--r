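#' Gut zone partition
#'
#' The three analysis zones of the virtual gut cross-section: mucin layer
#' (outer fifths, `(0, D/5)` and `(4D/5, D)`), lumen (`(D/5, 4D/5)`), and
#' the border bands between them (`(2D/15, 4D/15)` and `(11D/15, 13D/15)`).
#' The border bands deliberately overlap the mucin/lumen split at `D/5`,
#' exactly as the zone list is defined.
#'
#' @param D gut width, um.
#' @return A data frame with columns `zone`, `y_min`, `y_max`.
#' @export
gut_zones <- function(D) {
  data.frame(
    zone = c("mucin_wall_low", "mucin_wall_high", "lumen",
             "border_low", "border_high"),
    y_min = c(0, 4 * D / 5, D / 5, 2 * D / 15, 11 * D / 15),
    y_max = c(D / 5, D, 4 * D / 5, 4 * D / 15, 13 * D / 15),
    stringsAsFactors = FALSE
  )
}

#' Per-bacterium segregation fractions
#'
#' For each bacterium, the fraction of same-type neighbors among all
#' bacteria within distance `r` (the bacterium itself excluded). Bacteria
#' with no neighbor within `r` get `NA` and are excluded from zone
#' averages.
#'
#' @param snapshot data frame with columns `type`, `x`, `y`.
#' @param r neighborhood radius, um (default 30000).
#' @return Numeric vector, one fraction (or `NA`) per bacterium.
#' @export
per_cell_segregation <- function(snapshot, r = 30000) {
  stopifnot(all(c("type", "x", "y") %in% names(snapshot)))
  .seg_fractions(as.numeric(snapshot$x), as.numeric(snapshot$y),
                 as.integer(snapshot$type), r)
}

#' Zone segregation index
#'
#' Mean per-bacterium segregation fraction over bacteria of one type lying
#' in one zone of the gut cross-section. Neighbors are counted over the
#' whole snapshot (the neighborhood is not clipped to the zone); an index
#' of 1 means fully layered, about 0.5 means well-mixed equal populations.
#'
#' @param snapshot data frame with columns `type`, `x`, `y`.
#' @param zone zone name from [gut_zones()], or `"all"`.
#' @param bac_type 1 or 2.
#' @param D gut width, um (needed to resolve the zone boundaries).
#' @param r neighborhood radius, um.
#' @return The index in `[0, 1]`, or `NA` if the zone holds no bacteria of
#'   that type with defined fractions.
#' @export
zone_segregation <- function(snapshot, zone = "all", bac_type = 1,
                             D, r = 30000) {
  seg <- per_cell_segregation(snapshot, r)
  sel <- snapshot$type == bac_type
  if (zone != "all") {
    z <- gut_zones(D)
    z <- z[z$zone == zone, ]
    if (nrow(z) != 1) stop("unknown zone: ", zone)
    sel <- sel & snapshot$y >= z$y_min & snapshot$y <= z$y_max
  }
  vals <- seg[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Bacterial density profile
#'
#' Histogram of bacterial positions per type along (`x`) or across (`y`)
#' the gut. Bin counts per type sum to the type's population.
#'
#' @param snapshot data frame with columns `type`, `x`, `y`.
#' @param axis `"along"` (x) or `"across"` (y).
#' @param bins number of bins (>= 2).
#' @param limit domain upper bound (gut length or width); defaults to the
#'   data maximum.
#' @return Data frame with `bin_mid`, `type`, `count`.
#' @export
density_profile <- function(snapshot, axis = c("along", "across"),
                            bins = 20, limit = NULL) {
  axis <- match.arg(axis)
  stopifnot(bins >= 2)
  v <- if (axis == "along") snapshot$x else snapshot$y
  if (is.null(limit)) limit <- if (length(v)) max(v) else 1
  breaks <- seq(0, limit, length.out = bins + 1)
  out <- expand.grid(bin_mid = (breaks[-1] + breaks[-(bins + 1)]) / 2,
                     type = c(1, 2))
  out$count <- 0
  for (ty in c(1, 2)) {
    vv <- v[snapshot$type == ty]
    if (!length(vv)) next
    h <- hist(pmin(pmax(vv, 0), limit), breaks = breaks, plot = FALSE)
    out$count[out$type == ty] <- h$counts
  }
  out
}

#' Recovery time after an antibiotic course
#'
#' Hours from the end of the course until both bacterial types have
#' regained at least `frac` (default 80%) of their pre-treatment baseline,
#' where the baseline is each type's mean count over the `baseline_hours`
#' before the course started.
#'
#' @param traj trajectory data frame from [run_simulation()].
#' @param course_start,course_end course boundaries, hours.
#' @param frac recovery fraction of baseline (default 0.8).
#' @param baseline_hours length of the pre-course baseline window.
#' @return Recovery time in hours (0 if never depressed), or `NA` if the
#'   trajectory never recovers (censored).
#' @export
recovery_time <- function(traj, course_start, course_end, frac = 0.8,
                          baseline_hours = 100) {
  traj <- with_totals(traj)
  if (course_end > max(traj$hours) || course_end < min(traj$hours))
    stop("course_end lies outside the trajectory")
  base_win <- traj$hours >= (course_start - baseline_hours) &
    traj$hours < course_start
  if (!any(base_win)) stop("no samples in the baseline window")
  b1 <- mean(traj$n1[base_win])
  b2 <- mean(traj$n2[base_win])
  post <- traj[traj$hours >= course_end, ]
  ok <- post$n1 >= frac * b1 & post$n2 >= frac * b2
  if (!any(ok)) return(NA_real_)
  post$hours[which(ok)[1]] - course_end
}

#' Resilience time under continuous treatment
#'
#' First time either bacterial type's count falls to the critical
#' threshold (default 100) — beyond that point a rebound is improbable, so
#' longer times mean a more resilient community.
#'
#' @param traj trajectory data frame from [run_simulation()].
#' @param critical critical count (default 100).
#' @return Hours until first crossing, or `NA` if never reached (censored).
#' @export
resilience_time <- function(traj, critical = 100) {
  traj <- with_totals(traj)
  hit <- traj$n1 <= critical | traj$n2 <= critical
  if (!any(hit)) return(NA_real_)
  traj$hours[which(hit)[1]]
}

#' Classify the post-treatment resistance outcome
#'
#' Three community structures after an antibiotic course, read from the
#' resistant fraction R/(R+S): class 1 — resistant strains dominate (mean
#' fraction over the post-course window > 0.7); class 3 — sensitive strains
#' recover and resistant strains disappear (mean < 0.1 and no resistant
#' bacteria at the end); class 2 — sustained fluctuation in the ratio
#' (everything else).
#'
#' @param traj trajectory data frame from [run_simulation()] (or any frame
#'   with `hours`, `n1_res`, `n2_res`, `n1_sens`, `n2_sens`).
#' @param course_end end of the course, hours.
#' @param window classification window after `course_end`, hours; the
#'   trajectory must extend at least that far.
#' @return Integer class 1, 2 or 3.
#' @export
classify_outcome <- function(traj, course_end, window) {
  traj <- with_totals(traj)
  if (max(traj$hours) < course_end + window)
    stop("insufficient data: trajectory must extend ", window,
         " h past course_end")
  post <- traj[traj$hours > course_end &
                 traj$hours <= course_end + window, ]
  rf <- post$r_frac[!is.na(post$r_frac)]
  if (!length(rf)) return(3L)  # community extinct: no resistant survivors
  m <- mean(rf)
  final_res <- traj$n1_res[nrow(traj)] + traj$n2_res[nrow(traj)]
  if (m > 0.7) return(1L)
  if (m < 0.1 && final_res == 0) return(3L)
  2L
}

#' Count modes of a final-state distribution
#'
#' Kernel-smoothed 2D histogram of long-run (N1, N2) states from an
#' initial-condition sweep; the mode count is the number of local maxima
#' whose density exceeds `prominence` times the global maximum. One mode
#' means a single attractor, two modes means bistability.
#'
#' @param final_states data frame with columns `n1`, `n2` (one row per
#'   run; at least 30 required).
#' @param gridsize kernel density grid resolution per axis.
#' @param prominence fraction of the global density maximum a local
#'   maximum must reach to count as a mode (default 0.15).
#' @param saddle_ratio a local maximum is a separate mode only if every
#'   path to higher density crosses a valley below this fraction of its
#'   own height (default 0.5, the half-height prominence convention);
#'   shoulders and sampling ripples of a larger peak are merged into it.
#' @param bandwidth optional kernel bandwidth (one number or two); default
#'   is the normal-reference bandwidth, floored at 5% of the data range.
#' @return A list with `n_modes`, `modes` (data frame of mode
#'   coordinates), and `density` (the `MASS::kde2d` result).
#' @export
bistability_histogram <- function(final_states, gridsize = 41,
                                  prominence = 0.15, saddle_ratio = 0.5,
                                  bandwidth = NULL) {
  stopifnot(all(c("n1", "n2") %in% names(final_states)))
  if (nrow(final_states) < 30)
    stop("insufficient data: need at least 30 final states")
  x <- final_states$n1
  y <- final_states$n2
  if (is.null(bandwidth)) {
    bw1 <- max(MASS::bandwidth.nrd(x), 0.05 * diff(range(x)), 1e-6)
    bw2 <- max(MASS::bandwidth.nrd(y), 0.05 * diff(range(y)), 1e-6)
    bandwidth <- c(bw1, bw2)
  }
  pad <- c(-1, 1)
  dens <- MASS::kde2d(x, y, h = bandwidth, n = gridsize,
                      lims = c(range(x) + pad * bandwidth[1],
                               range(y) + pad * bandwidth[2]))
  z <- dens$z
  floor_z <- prominence * max(z)
  nx <- nrow(z); ny <- ncol(z)

  # grid-local maxima above the prominence floor
  cand <- NULL
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      zij <- z[i, j]
      if (zij < floor_z) next
      nb <- z[max(1, i - 1):min(nx, i + 1), max(1, j - 1):min(ny, j + 1)]
      if (zij >= max(nb) && sum(nb == zij) == 1)
        cand <- rbind(cand, data.frame(i = i, j = j, density = zij))
    }
  }
  # saddle test: flood-fill above saddle_ratio * height; a candidate that
  # reaches strictly higher density without descending is a shoulder
  is_separate <- function(i0, j0, h) {
    lvl <- saddle_ratio * h
    seen <- matrix(FALSE, nx, ny)
    queue <- list(c(i0, j0))
    seen[i0, j0] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny || seen[ii, jj]) next
        if (z[ii, jj] <= lvl) next
        if (z[ii, jj] > h) return(FALSE)  # connected upslope: a shoulder
        seen[ii, jj] <- TRUE
        queue[[length(queue) + 1]] <- c(ii, jj)
      }
    }
    TRUE
  }
  modes <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(-cand$density), ]
    for (k in seq_len(nrow(cand))) {
      if (k == 1 || is_separate(cand$i[k], cand$j[k], cand$density[k]))
        modes <- rbind(modes, data.frame(n1 = dens$x[cand$i[k]],
                                         n2 = dens$y[cand$j[k]],
                                         density = cand$density[k]))
    }
  }
  if (is.null(modes))
    modes <- data.frame(n1 = numeric(0), n2 = numeric(0),
                        density = numeric(0))
  list(n_modes = nrow(modes), modes = modes, density = dens)
}

#' Long-run mean state of a trajectory
#'
#' Mean (N1, N2) over the final third of the run — the summary each sweep
#' run contributes to the bistability histogram.
#'
#' @param traj trajectory data frame from [run_simulation()].
#' @return Named vector `c(n1, n2)`.
#' @export
long_run_state <- function(traj) {
  traj <- with_totals(traj)
  tail_third <- traj[traj$hours >= max(traj$hours) * 2 / 3, ]
  c(n1 = mean(tail_third$n1), n2 = mean(tail_third$n2))
}

#' Coexistence check
#'
#' A run sustains coexistence when both types keep a positive long-run
#' average (final third of the run) above a floor and are still present at
#' the end.
#'
#' @param traj trajectory data frame from [run_simulation()].
#' @param floor_count minimum long-run mean count per type.
#' @return Logical.
#' @export
sustains_coexistence <- function(traj, floor_count = 10) {
  st <- long_run_state(traj)
  last <- with_totals(traj)[nrow(traj), ]
  all(st > floor_count) && last$n1 > 0 && last$n2 > 0
}
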