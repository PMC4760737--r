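test_that("per-bacterium segregation counts same-type neighbor fractions", {
  # four neighbors of the same type within r
  snap <- data.frame(type = c(1, 1, 1, 1, 1),
                     x = c(0, 10, 20, 30, 40), y = 0)
  expect_equal(per_cell_segregation(snap, r = 100), rep(1, 5))
  # 2 same + 2 other at equal distance: 0.5 for the center bacterium
  snap <- data.frame(type = c(1, 1, 1, 2, 2),
                     x = c(0, 10, -10, 20, -20), y = 0)
  expect_equal(per_cell_segregation(snap, r = 100)[1], 0.5)
  # isolated bacterium: undefined
  snap <- data.frame(type = c(1, 2), x = c(0, 1e6), y = c(0, 0))
  expect_true(all(is.na(per_cell_segregation(snap, r = 100))))
})

test_that("zone segregation equals the all-pairs brute-force oracle", {
  D <- 60000
  set.seed(202)
  cases <- list()
  for (i in 1:40)
    cases[[length(cases) + 1]] <-
      make_snapshot("uniform-mixed", n1 = sample(20:120, 1),
                    n2 = sample(20:120, 1), L = 90000, D = D, seed = i)
  for (i in 1:20) {
    cases[[length(cases) + 1]] <-
      make_snapshot("layered", n1 = 60, n2 = 60, L = 90000, D = D,
                    seed = 100 + i)
    cases[[length(cases) + 1]] <-
      make_snapshot("checkerboard", n1 = 50, n2 = 50, L = 90000, D = D,
                    seed = 200 + i)
    cases[[length(cases) + 1]] <-
      make_snapshot("two-cluster", n1 = 40, n2 = 80, L = 90000, D = D,
                    seed = 300 + i)
  }
  zones <- c("all", gut_zones(D)$zone)
  for (r in c(5000, 30000)) {
    for (snap in cases) {
      expect_equal(per_cell_segregation(snap, r),
                   brute_force_segregation(snap, r))
    }
  }
  # zone means agree too (spot-check a subset across zones and types)
  for (snap in cases[seq(1, length(cases), by = 10)])
    for (z in zones)
      for (ty in 1:2)
        expect_equal(zone_segregation(snap, z, ty, D = D, r = 30000),
                     brute_force_zone_segregation(snap, z, ty, D, 30000))
})

test_that("segregation index separates layered from mixed configurations", {
  D <- 60000
  # fully separated by more than r: each type sees only itself
  snap <- data.frame(
    type = rep(c(1, 2), each = 50),
    x = c(runif(50, 0, 10000), runif(50, 200000, 210000)),
    y = runif(100, 0, D))
  expect_equal(zone_segregation(snap, "all", 1, D = D, r = 30000), 1)
  expect_equal(zone_segregation(snap, "all", 2, D = D, r = 30000), 1)
  # checkerboard mixing: near 0.5 by the neighbor-fraction definition
  snap <- make_snapshot("checkerboard", n1 = 200, n2 = 200,
                        L = 60000, D = D, seed = 4)
  expect_equal(zone_segregation(snap, "all", 1, D = D, r = 30000), 0.5,
               tolerance = 0.05)
  # type-swap symmetry on a mirrored configuration
  snap <- make_snapshot("two-cluster", n1 = 80, n2 = 80, L = 120000, D = D,
                        seed = 9)
  mirrored <- snap
  mirrored$type <- 3 - snap$type
  mirrored$x <- 120000 - snap$x
  s1 <- zone_segregation(snap, "all", 1, D = D, r = 30000)
  s2 <- zone_segregation(mirrored, "all", 2, D = D, r = 30000)
  expect_equal(s1, s2)
})

test_that("gut zones partition the width as defined", {
  z <- gut_zones(60000)
  expect_equal(z$y_max[z$zone == "mucin_wall_low"], 12000)
  expect_equal(z$y_min[z$zone == "mucin_wall_high"], 48000)
  expect_equal(unname(unlist(z[z$zone == "lumen", c("y_min", "y_max")])),
               c(12000, 48000))
  expect_equal(unname(unlist(z[z$zone == "border_low", c("y_min", "y_max")])),
               c(8000, 16000))
  expect_equal(unname(unlist(z[z$zone == "border_high", c("y_min", "y_max")])),
               c(44000, 52000))
})

test_that("density profiles conserve population counts", {
  snap <- make_snapshot("uniform-mixed", n1 = 137, n2 = 89,
                        L = 90000, D = 60000, seed = 3)
  for (axis in c("along", "across")) {
    prof <- density_profile(snap, axis, bins = 13,
                            limit = if (axis == "along") 90000 else 60000)
    expect_equal(sum(prof$count[prof$type == 1]), 137)
    expect_equal(sum(prof$count[prof$type == 2]), 89)
  }
  # layered fixture: all type-1 mass in the wall fifths of the width
  snap <- make_snapshot("layered", n1 = 100, n2 = 100, L = 90000,
                        D = 60000, seed = 5)
  prof <- density_profile(snap, "across", bins = 10, limit = 60000)
  p1 <- prof[prof$type == 1, ]
  wall_bins <- p1$bin_mid < 12000 | p1$bin_mid > 48000
  expect_equal(sum(p1$count[wall_bins]), 100)
  # empty snapshot: all-zero profile
  empty <- data.frame(type = numeric(0), x = numeric(0), y = numeric(0))
  expect_true(all(density_profile(empty, "along", 5, limit = 100)$count == 0))
})

test_that("recovery time reads the 80% crossing from the trajectory", {
  tr <- make_trajectory("recovery-at-T", T = 37)
  expect_equal(recovery_time(tr, 100, 172), 37)
  # untreated flat run recovers immediately
  flat <- make_trajectory("recovery-at-T", T = 37)
  flat$n1_sens <- flat$n2_sens <- 400
  expect_equal(recovery_time(flat, 100, 172), 0)
  # pinned at half the baseline: censored
  expect_true(is.na(recovery_time(make_trajectory("never-recover"),
                                  100, 172)))
  expect_error(recovery_time(tr, 100, 1e6), "outside")
  # loosening the recovery fraction can only shorten the time
  t80 <- recovery_time(tr, 100, 172, frac = 0.8)
  t70 <- recovery_time(tr, 100, 172, frac = 0.7)
  expect_lte(t70, t80)
})

test_that("resilience time finds the critical-count crossing", {
  tr <- make_trajectory("hit-100-at-T", T = 412, total_hours = 1500)
  expect_equal(resilience_time(tr), 412)
  tr0 <- make_trajectory("hit-100-at-T", T = 412)
  tr0$n1_sens <- 80  # already past critical at t = 0
  expect_equal(resilience_time(tr0), 0)
  stable <- make_trajectory("never-recover")
  expect_true(is.na(resilience_time(stable)))
})

test_that("outcome classes follow the resistant-fraction regimes", {
  W <- 720
  expect_equal(classify_outcome(make_trajectory("rising-R-fraction", T = 100),
                                172, W), 1L)
  expect_equal(classify_outcome(make_trajectory("decaying-R-fraction",
                                                T = 100), 172, W), 3L)
  expect_equal(classify_outcome(make_trajectory("oscillating-R-fraction",
                                                T = 200), 172, W), 2L)
  expect_error(classify_outcome(make_trajectory("rising-R-fraction"),
                                172, 5000), "insufficient")
})

test_that("mode counting distinguishes one attractor from two", {
  set.seed(77)
  one <- data.frame(n1 = rnorm(120, 500, 30), n2 = rnorm(120, 300, 30))
  expect_equal(bistability_histogram(one)$n_modes, 1)
  two <- data.frame(
    n1 = c(rnorm(60, 200, 20), rnorm(60, 800, 20)),
    n2 = c(rnorm(60, 700, 20), rnorm(60, 150, 20)))
  expect_equal(bistability_histogram(two)$n_modes, 2)
  expect_error(bistability_histogram(one[1:10, ]), "insufficient")
})
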