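## Independent oracles and small run configurations shared across tests.

# All-pairs brute-force segregation index: same sigma and neighbor rule as
# the production path, written as a plain double loop over bacteria.
brute_force_segregation <- function(snapshot, r) {
  n <- nrow(snapshot)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    same <- 0L
    tot <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- (snapshot$x[i] - snapshot$x[j])^2 +
        (snapshot$y[i] - snapshot$y[j])^2
      if (d2 <= r^2) {
        tot <- tot + 1L
        if (snapshot$type[i] == snapshot$type[j]) same <- same + 1L
      }
    }
    if (tot > 0) out[i] <- same / tot
  }
  out
}

brute_force_zone_segregation <- function(snapshot, zone, bac_type, D, r) {
  seg <- brute_force_segregation(snapshot, r)
  sel <- snapshot$type == bac_type
  if (zone != "all") {
    z <- gut_zones(D)
    z <- z[z$zone == zone, ]
    sel <- sel & snapshot$y >= z$y_min & snapshot$y <= z$y_max
  }
  vals <- seg[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# small, fast world for engine unit tests (not the calibrated screen setup)
tiny_params <- function(...) {
  gut_params(gut_length_L = 30000, gut_width_D = 10000,
             initial_bacteria_1 = 30, initial_bacteria_2 = 30,
             initial_ps = 200, initial_acetate = 50,
             initial_propionate = 0, initial_butyrate = 0, ...)
}
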