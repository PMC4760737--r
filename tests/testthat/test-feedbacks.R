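# particle-only world: gut rules can be observed without bacteria
gut_only <- function(...) {
  gut_params(gut_length_L = 30000, gut_width_D = 10000,
             initial_bacteria_1 = 0, initial_bacteria_2 = 0,
             initial_ps = 0, initial_acetate = 0, initial_propionate = 0,
             initial_butyrate = 0, k_intake = 0, k_ps_mucus = 0,
             k_antitoxin1 = 0, k_antitoxin2 = 0, ...)
}

test_that("the toxin-antitoxin branch splits the acetate flux by percentage", {
  mk <- function(pct, seed) {
    p <- gut_params(gut_length_L = 30000, gut_width_D = 10000,
                    initial_bacteria_1 = 0, initial_bacteria_2 = 150,
                    initial_ps = 0, initial_acetate = 4000,
                    initial_propionate = 0, initial_butyrate = 0,
                    k_intake = 0, k_ps_mucus = 0,
                    feedbacks_enabled = "FB1", fb1_toxin_percentage = pct)
    sim <- run_simulation(p, ticks = 1500, record_every = 1500, seed = seed)
    last <- sim$trajectory[nrow(sim$trajectory), ]
    c(tox = last$led_toxin1_produced, but = last$led_butyrate_produced,
      conv = last$fb1_events)
  }
  # percentage 0: every converted acetate quantum becomes butyrate
  r <- mk(0, 1)
  expect_equal(r[["tox"]], 0)
  expect_gt(r[["but"]], 100)
  # percentage 100: only toxin, never butyrate
  r <- mk(100, 2)
  expect_equal(r[["but"]], 0)
  expect_gt(r[["tox"]], 100)
  # intermediate percentage: binomial fraction of the conversion flux
  r <- mk(30, 3)
  n <- r[["tox"]] + r[["but"]]
  expect_gt(n, 1000)
  frac <- r[["tox"]] / n
  expect_lt(abs(frac - 0.30), 3 * sqrt(0.3 * 0.7 / n) + 0.01)
})

test_that("gut toxin production follows the SCFA-difference rule", {
  # sensed difference above threshold: emission occurs
  p <- gut_only(feedbacks_enabled = "FB4", initial_propionate = 400,
                initial_butyrate = 250)
  sim <- run_simulation(p, ticks = 20, seed = 1)
  expect_gt(sim$trajectory$fb4_events[21], 0)
  expect_gt(sim$trajectory$toxin1[21], 0)
  # below threshold: no emission
  p <- gut_only(feedbacks_enabled = "FB4", initial_propionate = 300,
                initial_butyrate = 250)
  sim <- run_simulation(p, ticks = 20, seed = 1)
  expect_equal(sim$trajectory$fb4_events[21], 0)
  # the printed literal orientation senses butyrate - propionate
  p <- gut_only(feedbacks_enabled = "FB4", fb4_difference = "but-pro",
                initial_butyrate = 400, initial_propionate = 250)
  sim <- run_simulation(p, ticks = 20, seed = 1)
  expect_gt(sim$trajectory$fb4_events[21], 0)
  p <- gut_only(feedbacks_enabled = "FB4", fb4_difference = "but-pro",
                initial_butyrate = 300, initial_propionate = 250)
  sim <- run_simulation(p, ticks = 20, seed = 1)
  expect_equal(sim$trajectory$fb4_events[21], 0)
})

test_that("the gut feeds type 1 only while butyrate is scarce", {
  p <- gut_only(feedbacks_enabled = "FB7", fb7_ps_rate = 1)
  sim <- run_simulation(p, ticks = 50, seed = 1, snapshot_particles = TRUE)
  last <- sim$trajectory[51, ]
  expect_equal(last$led_ps_gut_produced, 50)  # 1 quantum per triggered tick
  expect_true(all(sim$final_particles$kind == "ps_gut"))
  # emitted at the walls
  expect_true(all(sim$final_particles$y < 2000 |
                    sim$final_particles$y > 8000))
  p <- gut_only(feedbacks_enabled = "FB7", fb7_ps_rate = 1,
                initial_butyrate = 3000)
  sim <- run_simulation(p, ticks = 50, seed = 1)
  expect_equal(sim$trajectory$led_ps_gut_produced[51], 0)
  # host polysaccharide is digestible only by type 1
  expect_true("ps_gut" %in% edible_kinds(1, gut_params()))
  expect_false("ps_gut" %in% edible_kinds(2, gut_params()))
})

test_that("bacterial toxin co-emission requires the abundance condition", {
  # pseudocode orientation: type 1 emits when type 2 dominates by > threshold
  p <- gut_params(gut_length_L = 30000, gut_width_D = 10000,
                  initial_bacteria_1 = 40, initial_bacteria_2 = 200,
                  initial_ps = 2000, initial_acetate = 0,
                  initial_propionate = 0, initial_butyrate = 0,
                  k_intake = 0, k_ps_mucus = 0,
                  feedbacks_enabled = "FB2", fb2_source_type = 1,
                  fb2_abundance_threshold = 100)
  sim <- run_simulation(p, ticks = 500, record_every = 500, seed = 4)
  expect_gt(sim$trajectory$fb2_events[2], 0)
  expect_gt(sim$trajectory$led_toxin1_produced[2], 0)
  # equal abundances: inactive (short horizon so counts stay near equal)
  p$initial_bacteria_1 <- 120; p$initial_bacteria_2 <- 120
  sim <- run_simulation(p, ticks = 100, record_every = 100, seed = 4)
  expect_equal(sim$trajectory$fb2_events[2], 0)
  # FB2 disabled: no toxin particles ever exist in the basic network
  p$feedbacks_enabled <- character(0)
  sim <- run_simulation(p, ticks = 500, record_every = 500, seed = 4)
  last <- sim$trajectory[2, ]
  expect_equal(last$led_toxin1_produced + last$led_toxin2_produced, 0)
})

test_that("toxin particles decay at the antitoxin rate", {
  # FB4 keeps producing toxin 1; with a fast degradation constant the
  # decay ledger fills while the pool stays bounded
  p <- gut_only(feedbacks_enabled = "FB4", initial_propionate = 400,
                initial_butyrate = 0, k_antitoxin1 = 2)
  sim <- run_simulation(p, ticks = 400, record_every = 400, seed = 1)
  last <- sim$trajectory[2, ]
  expect_gt(last$led_toxin1_decayed, 0)
  expect_equal(last$toxin1 + last$led_toxin1_decayed +
                 last$led_toxin1_excreted, last$led_toxin1_produced)
  # without the degradation channel nothing decays
  p$k_antitoxin1 <- 0
  sim <- run_simulation(p, ticks = 400, record_every = 400, seed = 1)
  expect_equal(sim$trajectory$led_toxin1_decayed[2], 0)
})
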