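#' Default simulation parameters
#'
#' Builds the full parameter set of the model: reaction rate constants of
#' the SCFA cross-feeding scheme, transport and clearance constants, agent
#' behavior parameters, gut geometry, feedback-network configuration,
#' antibiotic dosing schedule and the resistance model. Values not
#' overridden take the published defaults of the two-species model
#' (rates in mmol/h, Michaelis constants in mM, lengths in micrometers,
#' times in hours).
#'
#' Sensitivity thresholds (`sensitive_*`) are lethal doses in substance
#' quanta; the sentinel `Inf` encodes a fully resistant type.
#'
#' @param ... named overrides of any default field.
#' @return An object of class `gut_params` (a named list).
#' @examples
#' p <- gut_params(k_gut_out = 0.08, rng_seed = 42)
#' p$k_intake
#' @export
gut_params <- function(...) {
  p <- list(
    ## conversion rate constants, mmol/h (type 1 / type 2)
    k_ps_to_acetate_1      = 0.16,
    k_ps_to_acetate_2      = 0.16,
    k_psgut_to_acetate_1   = 0.16,  # equals k_ps_to_acetate for type 1
    k_psgut_to_acetate_2   = 0.0,
    k_ps_to_propionate_1   = 0.0,
    k_ps_to_propionate_2   = 0.26,
    k_acetate_to_butyrate_1 = 0.31,
    k_acetate_to_butyrate_2 = 0.0,
    k_toxin1               = 0.31,  # network-dependent; toxin branch of the acetate flux
    k_antitoxin1           = 0.05,  # toxin-1 degradation, 1/h
    k_antitoxin2           = 0.05,  # toxin-2 degradation, 1/h
    ## lethal-dose thresholds, substance quanta (Inf = resistant)
    sensitive_toxin1_1     = Inf,   # type 1 detoxifies toxin 1
    sensitive_toxin1_2     = 2,
    sensitive_toxin2_1     = 2,
    sensitive_toxin2_2     = Inf,   # type 2 detoxifies toxin 2
    sensitive_antibiotic_1 = 2,
    sensitive_antibiotic_2 = 2,
    ## transport / supply
    k_gut_out              = 0.02,  # clearance, 1/h
    k_intake               = 40,    # dietary polysaccharide intake, mmol/h
    k_ps_mucus             = 1,     # host polysaccharide production, mmol/h
    k_trans_mct            = 8.3,   # MCT binding rate constant, mmol/h
    km_acetate_mct         = 15.0,  # mM
    km_propionate_mct      = 15.0,  # mM
    km_butyrate_mct        = 21.3,  # mM
    km_acetate_conv        = 15.0,  # mM (conversion reactions; see vignette)
    km_propionate_conv     = 15.0,
    km_butyrate_conv       = 21.3,
    ## bacterial behavior
    search_radius_R        = 3500,  # um
    bacterial_speed        = 7000,  # um/h
    eat_period             = 8,     # h between meals
    eat_range_multiplier_n = 3,     # starvation limit ~ U(0, n * eat_period]
    contact_radius         = 100,   # um, ingestion/contact distance
    division_threshold     = 4,     # mmol of converted substrate per division
    ## initial agent counts
    initial_bacteria_1     = 400,
    initial_bacteria_2     = 400,
    initial_ps             = 1200,
    initial_acetate        = 200,
    initial_propionate     = 200,
    initial_butyrate       = 200,
    ## geometry and discretization
    gut_length_L           = 600000, # um
    gut_width_D            = 60000,  # um
    tick_hours             = 0.01,
    particle_quantum       = 1,      # mmol represented by one passive agent
    jitter_step            = 50,     # um lateral jitter per tick
    conc_grid_nx           = 20,
    conc_grid_ny           = 10,
    conc_per_quantum       = 1.0,    # mM contributed by one quantum in a grid cell
    ## network orientation: which type performs the acetate conversion
    ## (and is FB1's self-limiting toxin producer)
    acetate_consumer_type  = 2,
    ## feedback network
    feedbacks_enabled      = character(0),
    fb1_toxin_percentage   = 50,    # % of the acetate flux diverted to toxin
    fb2_abundance_threshold = 100,
    fb2_source_type        = 2,     # type emitting the toxin when the other dominates
    fb3_abundance_threshold = 100,
    fb4_scfa_difference_threshold = 100,
    fb4_difference         = "pro-but",  # which SCFA difference is sensed
    fb5_butyrate_threshold = 300,
    fb6_propionate_threshold = 300,
    fb7_butyrate_threshold = 2500,
    gut_toxin_rate         = 1,     # toxin quanta emitted per triggered tick
    fb7_ps_rate            = 0.3,   # host PS quanta emitted per triggered tick
    toxin_dispersal_radius = 2000,  # um; bacterial toxins diffuse this far
    ## antibiotic course
    k_ant_intake           = 0,     # mmol/h during a gavage (0 = no treatment)
    ant_gavages_per_day    = 1,
    ant_course_days        = 3,
    ant_course_start       = 0,     # h
    ant_gavage_duration    = 1,     # h
    ant_continuous         = FALSE,
    ## resistance model
    retardation_constant_Rc = 1,    # fitness cost; conversion rates divided by Rc
    mutation_rate_scale_alpha = 0,  # p_mut = min(1, alpha * C / Rc)
    initial_resistant_fraction = 0, # fraction of each type resistant at t = 0
    rng_seed               = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$feedbacks_enabled <- toupper(as.character(p$feedbacks_enabled))
  class(p) <- "gut_params"
  err <- validate_params(p)
  if (length(err))
    stop("invalid parameters:\n  ", paste(err, collapse = "\n  "))
  p
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set: non-negative
#' rates and thresholds, positive geometry and time step, the fixed zero
#' constants of the reaction table (type 1 makes no propionate, type 2
#' makes no butyrate and eats no host polysaccharide), `Rc >= 1` and a
#' known feedback set.
#'
#' @param p a `gut_params` object (or plain named list with the same fields).
#' @return A character vector of violations, empty when `p` is valid.
#' @export
validate_params <- function(p) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  nonneg <- c(
    "k_ps_to_acetate_1", "k_ps_to_acetate_2", "k_psgut_to_acetate_1",
    "k_psgut_to_acetate_2", "k_ps_to_propionate_1", "k_ps_to_propionate_2",
    "k_acetate_to_butyrate_1", "k_acetate_to_butyrate_2", "k_toxin1",
    "k_antitoxin1", "k_antitoxin2", "sensitive_toxin1_1",
    "sensitive_toxin1_2", "sensitive_toxin2_1", "sensitive_toxin2_2",
    "sensitive_antibiotic_1", "sensitive_antibiotic_2", "k_gut_out",
    "k_intake", "k_ps_mucus", "k_trans_mct", "search_radius_R",
    "bacterial_speed", "contact_radius", "jitter_step", "gut_toxin_rate",
    "toxin_dispersal_radius", "fb7_ps_rate",
    "k_ant_intake", "mutation_rate_scale_alpha", "fb2_abundance_threshold",
    "fb3_abundance_threshold", "fb4_scfa_difference_threshold",
    "fb5_butyrate_threshold", "fb6_propionate_threshold",
    "fb7_butyrate_threshold", "initial_bacteria_1", "initial_bacteria_2",
    "initial_ps", "initial_acetate", "initial_propionate", "initial_butyrate"
  )
  for (f in nonneg) {
    val <- p[[f]]
    chk(is.numeric(val) && length(val) == 1 && !is.na(val) && val >= 0,
        sprintf("%s = %s violates: must be a non-negative number",
                f, paste(p[[f]], collapse = ",")))
  }
  pos <- c("km_acetate_mct", "km_propionate_mct", "km_butyrate_mct",
           "km_acetate_conv", "km_propionate_conv", "km_butyrate_conv",
           "gut_length_L", "gut_width_D", "tick_hours", "particle_quantum",
           "eat_period", "eat_range_multiplier_n", "division_threshold",
           "ant_gavage_duration")
  for (f in pos) {
    val <- p[[f]]
    chk(is.numeric(val) && length(val) == 1 && is.finite(val) && val > 0,
        sprintf("%s = %s violates: must be > 0",
                f, paste(p[[f]], collapse = ",")))
  }
  chk(is.numeric(p$retardation_constant_Rc) &&
        p$retardation_constant_Rc >= 1,
      sprintf("retardation_constant_Rc = %s violates: Rc >= 1",
              paste(p$retardation_constant_Rc, collapse = ",")))
  chk(p$k_ps_to_propionate_1 == 0,
      "k_ps_to_propionate_1 violates: fixed at 0 for type 1")
  chk(p$k_acetate_to_butyrate_2 == 0,
      "k_acetate_to_butyrate_2 violates: fixed at 0 for type 2")
  chk(p$k_psgut_to_acetate_2 == 0,
      "k_psgut_to_acetate_2 violates: fixed at 0 for type 2")
  chk(is.numeric(p$initial_resistant_fraction) &&
        p$initial_resistant_fraction >= 0 &&
        p$initial_resistant_fraction <= 1,
      sprintf("initial_resistant_fraction = %s violates: must be in [0, 1]",
              paste(p$initial_resistant_fraction, collapse = ",")))
  chk(is.numeric(p$fb1_toxin_percentage) &&
        p$fb1_toxin_percentage >= 0 && p$fb1_toxin_percentage <= 100,
      sprintf("fb1_toxin_percentage = %s violates: must be in [0, 100]",
              paste(p$fb1_toxin_percentage, collapse = ",")))
  chk(all(p$feedbacks_enabled %in% paste0("FB", 1:7)),
      sprintf("feedbacks_enabled = {%s} violates: subset of FB1..FB7",
              paste(p$feedbacks_enabled, collapse = ",")))
  chk(p$acetate_consumer_type %in% c(1, 2),
      "acetate_consumer_type violates: 1 or 2")
  chk(p$fb4_difference %in% c("pro-but", "but-pro"),
      "fb4_difference violates: 'pro-but' or 'but-pro'")
  chk(p$fb2_source_type %in% c(1, 2), "fb2_source_type violates: 1 or 2")
  chk(p$ant_gavages_per_day >= 1,
      "ant_gavages_per_day violates: must be >= 1")
  chk(isTRUE(p$ant_continuous) || isFALSE(p$ant_continuous) ||
        p$ant_course_days > 0,
      "ant_course_days violates: must be > 0 unless ant_continuous")
  chk(p$conc_grid_nx >= 1 && p$conc_grid_ny >= 1,
      "concentration grid violates: at least 1 cell per axis")
  v
}

## fields serialized as comma-separated sets / booleans / plain strings
.set_fields <- "feedbacks_enabled"
.flag_fields <- "ant_continuous"
.string_fields <- "fb4_difference"

#' Read a parameter file
#'
#' Parses a flat `key = value` text file (one assignment per line, `#`
#' comments allowed). Omitted keys keep their defaults; `feedbacks_enabled`
#' is a comma-separated subset of `FB1..FB7`; `Inf` is accepted for the
#' resistance sentinel thresholds.
#'
#' @param path path to the configuration file.
#' @return A validated `gut_params` object.
#' @seealso [write_run_manifest()] for the inverse operation.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("configuration error: line is not a key = value assignment: '",
           ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (key %in% .set_fields) {
      parsed <- if (nzchar(val)) trimws(strsplit(val, ",")[[1]]) else character(0)
    } else if (key %in% .flag_fields) {
      parsed <- toupper(val) %in% c("TRUE", "1", "YES")
    } else if (key %in% .string_fields) {
      parsed <- val
    } else if (key == "rng_seed") {
      parsed <- suppressWarnings(as.integer(val))
      if (is.na(parsed)) stop("configuration error: bad value for key 'rng_seed'")
    } else {
      parsed <- suppressWarnings(as.numeric(val))
      if (is.na(parsed)) stop("configuration error: bad value for key '", key, "'")
    }
    overrides[[key]] <- parsed
  }
  bad <- setdiff(names(overrides), names(gut_params()))
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(gut_params, overrides)
}

#' Write a run manifest
#'
#' Serializes a parameter set to the same flat `key = value` schema read by
#' [load_params()], so that a run is fully reproducible from its manifest:
#' `load_params(f)` after `write_run_manifest(p, f)` equals `p` field for
#' field, including the RNG seed.
#'
#' @param p a `gut_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(p, path) {
  stopifnot(inherits(p, "gut_params"))
  fmt <- function(key) {
    val <- p[[key]]
    if (key %in% .set_fields) return(paste(val, collapse = ","))
    if (key %in% .flag_fields) return(if (isTRUE(val)) "TRUE" else "FALSE")
    if (key %in% .string_fields) return(as.character(val))
    format(val, digits = 17, scientific = FALSE, trim = TRUE)
  }
  keys <- names(unclass(p))
  writeLines(paste(keys, "=", vapply(keys, fmt, character(1))), path)
  invisible(path)
}

#' @export
print.gut_params <- function(x, ...) {
  cat("Gut ABM parameter set\n")
  cat("  gut: ", x$gut_length_L, " x ", x$gut_width_D, " um, tick ",
      x$tick_hours, " h\n", sep = "")
  cat("  initial bacteria: ", x$initial_bacteria_1, " (type 1) + ",
      x$initial_bacteria_2, " (type 2)\n", sep = "")
  fb <- if (length(x$feedbacks_enabled)) paste(x$feedbacks_enabled,
                                               collapse = ", ") else "none"
  cat("  feedbacks:", fb, "\n")
  if (x$k_ant_intake > 0)
    cat("  antibiotic: ", x$k_ant_intake, " mmol/h, ",
        x$ant_gavages_per_day, "x/day, ",
        if (isTRUE(x$ant_continuous)) "continuous"
        else paste0(x$ant_course_days, " days"),
        " from t = ", x$ant_course_start, " h\n", sep = "")
  cat("  seed:", x$rng_seed, "\n")
  invisible(x)
}
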