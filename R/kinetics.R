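#' Michaelis-Menten conversion rate
#'
#' Rate of a bacterial conversion reaction (polysaccharide to acetate or
#' propionate, acetate to butyrate) as a function of the local substrate
#' concentration: `100 * k * S / (Km + S)` mmol/h, monotone in `S` and
#' saturating at `100 * k`.
#'
#' @param substrate_conc substrate concentration, mM (vectorized).
#' @param k reaction rate constant, mmol/h.
#' @param km Michaelis constant, mM (> 0).
#' @return Rate in mmol/h.
#' @examples
#' conversion_rate(15, k = 0.16, km = 15)  # half-saturation: 8 mmol/h
#' @export
conversion_rate <- function(substrate_conc, k, km) {
  if (any(km <= 0)) stop("km must be > 0")
  if (any(substrate_conc < 0)) stop("substrate_conc must be >= 0")
  100 * k * substrate_conc / (km + substrate_conc)
}

#' SCFA wall-absorption rate through the MCT transporter
#'
#' Saturable competitive transport of one short-chain fatty acid across the
#' gut wall: `k_trans_mct * (C_s / Km_s) / D` where
#' `D = 1 + sum_j C_j / Km_j` runs over acetate, propionate and butyrate.
#' Because the three species compete for the same carrier, the summed flux
#' over all species is strictly below `k_trans_mct`.
#'
#' @param concentrations named numeric vector with elements `acetate`,
#'   `propionate`, `butyrate` (mM, all >= 0).
#' @param species which SCFA's flux to return.
#' @param p a `gut_params` object supplying `k_trans_mct` and the
#'   transport Michaelis constants.
#' @return Absorption rate, mmol/h.
#' @examples
#' p <- gut_params()
#' wall_absorption_rate(c(acetate = 15, propionate = 0, butyrate = 0),
#'                      "acetate", p)  # 8.3 * 1 / 2 = 4.15
#' @export
wall_absorption_rate <- function(concentrations,
                                 species = c("acetate", "propionate",
                                             "butyrate"),
                                 p = gut_params()) {
  species <- match.arg(species)
  need <- c("acetate", "propionate", "butyrate")
  if (!all(need %in% names(concentrations)))
    stop("concentrations must be named with acetate, propionate, butyrate")
  conc <- concentrations[need]
  if (any(conc < 0)) stop("concentrations must be >= 0")
  km <- c(acetate = p$km_acetate_mct, propionate = p$km_propionate_mct,
          butyrate = p$km_butyrate_mct)
  d <- 1 + sum(conc / km)
  unname(p$k_trans_mct * (conc[species] / km[species]) / d)
}

#' Total SCFA wall-absorption flux
#'
#' Sum of [wall_absorption_rate()] over the three SCFAs. The analytic
#' supremum over all concentrations is `k_trans_mct` (reached only in the
#' saturating limit), so the summed flux never exceeds the transporter's
#' binding rate constant.
#'
#' @inheritParams wall_absorption_rate
#' @return Total absorption rate, mmol/h.
#' @export
total_absorption_flux <- function(concentrations, p = gut_params()) {
  sum(vapply(c("acetate", "propionate", "butyrate"),
             function(s) wall_absorption_rate(concentrations, s, p),
             numeric(1)))
}

#' Axial flow velocity across the gut section
#'
#' Luminal transport profile: particles at lateral position `y` advance
#' along the gut at `k_gut_out * L * (1 - |y - D/2| * 2/D)^2` um/h -
#' maximal on the centerline, vanishing at the walls where material clings
#' to the mucus.
#'
#' @param y lateral coordinate, um, in `[0, D]` (vectorized).
#' @param p a `gut_params` object supplying `k_gut_out`, `gut_length_L`
#'   and `gut_width_D`.
#' @return Axial velocity, um/h.
#' @examples
#' p <- gut_params()
#' axial_velocity(p$gut_width_D / 2, p)  # centerline: 0.02 * 600000
#' @export
axial_velocity <- function(y, p = gut_params()) {
  D <- p$gut_width_D
  if (any(y < 0 | y > D)) stop("y must lie in [0, D]")
  p$k_gut_out * p$gut_length_L * (1 - abs(y - D / 2) * 2 / D)^2
}
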