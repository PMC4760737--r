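# drug-schedule worlds without bacteria isolate the dosing arithmetic
dose_world <- function(...) {
  gut_params(gut_length_L = 30000, gut_width_D = 10000,
             initial_bacteria_1 = 0, initial_bacteria_2 = 0,
             initial_ps = 0, initial_acetate = 0, initial_propionate = 0,
             initial_butyrate = 0, k_intake = 0, k_ps_mucus = 0, ...)
}

test_that("gavage windows deliver the scheduled drug mass", {
  # 10 mmol/h for 1 h once a day, 3-day course
  p <- dose_world(k_ant_intake = 10, ant_gavages_per_day = 1,
                  ant_course_days = 3, ant_course_start = 0,
                  ant_gavage_duration = 1)
  sim <- run_simulation(p, ticks = 4 * 24 * 100, record_every = 100, seed = 1)
  tr <- sim$trajectory
  # 30 quanta scheduled; at most one can sit in the fractional accumulator
  expect_lte(abs(tr$led_antibiotic_injected[nrow(tr)] - 30), 1)
  # exactly 3 distinct gavage windows
  bursts <- rle(diff(tr$led_antibiotic_injected) > 0)
  expect_equal(sum(bursts$values), 3)
  # entries happen only inside the course
  after <- tr$hours > 3 * 24 + 1
  expect_equal(diff(range(tr$led_antibiotic_injected[after])), 0)

  # the same daily dose split over 3 gavages delivers the same mass
  p3 <- dose_world(k_ant_intake = 10, ant_gavages_per_day = 3,
                   ant_course_days = 3, ant_course_start = 0,
                   ant_gavage_duration = 1 / 3)
  sim3 <- run_simulation(p3, ticks = 4 * 24 * 100, record_every = 100,
                         seed = 1)
  expect_lte(abs(sim3$trajectory$led_antibiotic_injected[nrow(sim3$trajectory)]
                 - 30), 1)

  # no entries before the course starts
  p$ant_course_start <- 1000
  sim <- run_simulation(p, ticks = 100, seed = 1)
  expect_equal(sim$trajectory$led_antibiotic_injected[101], 0)
})

test_that("drug uptake kills at the lethal threshold and resistance shields", {
  cfg <- function(...) {
    gut_params(gut_length_L = 20000, gut_width_D = 8000,
               initial_bacteria_1 = 80, initial_bacteria_2 = 80,
               initial_ps = 600, initial_acetate = 100,
               initial_propionate = 0, initial_butyrate = 0,
               k_intake = 0, k_ps_mucus = 0,
               k_ant_intake = 400, ant_course_days = 2,
               ant_course_start = 0.2, ant_gavage_duration = 2, ...)
  }
  sim <- run_simulation(cfg(), ticks = 3000, record_every = 10, seed = 2)
  tr <- sim$trajectory
  last <- tr[nrow(tr), ]
  expect_gt(last$deaths_antibiotic_1 + last$deaths_antibiotic_2, 10)
  expect_equal(drug_ledger_discrepancy(tr), 0)
  expect_equal(ledger_discrepancy(tr), 0)

  # the Inf sentinel makes a type immune to the drug
  sim <- run_simulation(cfg(sensitive_antibiotic_1 = Inf,
                            sensitive_antibiotic_2 = Inf),
                        ticks = 3000, record_every = 10, seed = 2)
  last <- sim$trajectory[nrow(sim$trajectory), ]
  expect_equal(last$deaths_antibiotic_1 + last$deaths_antibiotic_2, 0)
  expect_gt(last$led_antibiotic_uptaken, 0)  # still absorbed and carried
})

test_that("lower lethal thresholds cannot raise the treatment trough", {
  trough <- function(thr, s) {
    p <- gut_params(gut_length_L = 20000, gut_width_D = 8000,
                    initial_bacteria_1 = 80, initial_bacteria_2 = 80,
                    initial_ps = 800, initial_acetate = 100,
                    initial_propionate = 0, initial_butyrate = 0,
                    k_ant_intake = 300, ant_course_days = 2,
                    ant_course_start = 0.2, ant_gavage_duration = 2,
                    sensitive_antibiotic_1 = thr)
    sim <- run_simulation(p, ticks = 3000, record_every = 10, seed = s)
    min(with_totals(sim$trajectory)$n1)
  }
  lo <- vapply(1:3, function(s) trough(1, s), numeric(1))
  hi <- vapply(1:3, function(s) trough(Inf, s), numeric(1))
  expect_true(all(lo <= hi))
})

test_that("the outcome map labels each parameter cell with a class", {
  p <- gut_params(gut_length_L = 20000, gut_width_D = 8000,
                  initial_bacteria_1 = 50, initial_bacteria_2 = 50,
                  initial_ps = 800, initial_acetate = 100,
                  initial_propionate = 0, initial_butyrate = 0,
                  k_ant_intake = 150, ant_course_days = 1,
                  ant_course_start = 10, ant_gavage_duration = 2,
                  mutation_rate_scale_alpha = 1)
  m <- resistance_parameter_map(p, rc_grid = 1, alpha_grid = 1,
                                replicates = 1, ticks = 10000,
                                window = 50, base_seed = 5L)
  expect_equal(nrow(m), 1)
  expect_true(m$modal_class %in% 1:3)
  expect_equal(m$votes_1 + m$votes_2 + m$votes_3, 1L)
})

test_that("resistance arises only under drug exposure and is heritable", {
  cfg <- function(alpha) {
    gut_params(gut_length_L = 20000, gut_width_D = 8000,
               initial_bacteria_1 = 60, initial_bacteria_2 = 60,
               initial_ps = 1500, initial_acetate = 200,
               initial_propionate = 0, initial_butyrate = 0,
               k_ant_intake = 200, ant_course_days = 3,
               ant_course_start = 0.2, ant_gavage_duration = 2,
               mutation_rate_scale_alpha = alpha,
               retardation_constant_Rc = 1)
  }
  sim <- run_simulation(cfg(1), ticks = 4000, record_every = 10, seed = 5)
  tr <- sim$trajectory
  expect_gt(max(tr$n1_res + tr$n2_res), 0)
  # without mutation pressure no resistant bacterium ever appears
  sim0 <- run_simulation(cfg(0), ticks = 4000, record_every = 10, seed = 5)
  expect_equal(max(sim0$trajectory$n1_res + sim0$trajectory$n2_res), 0)
})
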