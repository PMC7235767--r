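# Stoichiometric and operational accounting for anaerobic digestion
# experiments: Buswell-Boyle theoretical methane potentials, organic
# loading rates, retention time, digestion efficiency, gas normalisation
# and stressor molarity.

#' Molar volume of an ideal gas at 273 K and 1013 hPa (L/mol)
#'
#' Standard conditions used for biogas normalisation (VDI 4630
#' convention: 0 degrees C, 1013 hPa).
#' @export
MOLAR_VOLUME <- 22.414

.atomic_masses <- c(c = 12.011, h = 1.008, o = 15.999, n = 14.007)

#' Define a chemical species
#'
#' A substrate or stressor with its C/H/O/N elemental composition and
#' molar mass.  The composition drives Buswell-Boyle stoichiometry; for
#' species containing other elements (e.g. trisodium phosphate) set
#' `chon_only = FALSE` — such species cannot be fed to [buswell_yield()]
#' but are still usable for molarity and loading arithmetic.
#'
#' @param name species label.
#' @param c,h,o,n non-negative integer atom counts.
#' @param molar_mass molar mass in g/mol; must be consistent with the
#'   composition within 1% when `chon_only = TRUE`.
#' @param chon_only logical; `TRUE` if the species contains only
#'   C, H, O and N.
#' @return An object of class `chemical_species`.
#' @examples
#' glucose <- chemical_species("glucose", c = 6, h = 12, o = 6, molar_mass = 180.16)
#' buswell_yield(glucose)
#' @export
chemical_species <- function(name, c = 0, h = 0, o = 0, n = 0,
                             molar_mass, chon_only = TRUE) {
  comp <- c(c = c, h = h, o = o, n = n)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp != round(comp))) {
    abort("atom counts must be non-negative integers",
          "digestor_composition_error")
  }
  check_number(molar_mass, "molar_mass", lower = 0, allow_zero_lower = FALSE)
  if (isTRUE(chon_only)) {
    implied <- sum(comp * .atomic_masses)
    if (implied <= 0) {
      abort(sprintf("'%s': empty composition for a C/H/O/N-only species", name),
            "digestor_composition_error")
    }
    if (abs(implied - molar_mass) / molar_mass > 0.01) {
      abort(sprintf(
        "'%s': molar mass %.2f inconsistent with composition (implies %.2f)",
        name, molar_mass, implied), "digestor_composition_error")
    }
  }
  structure(
    list(name = name, c = c, h = h, o = o, n = n,
         molar_mass = molar_mass, chon_only = isTRUE(chon_only)),
    class = "chemical_species")
}

#' @export
print.chemical_species <- function(x, ...) {
  frm <- paste0(
    if (x$c > 0) paste0("C", x$c) else "",
    if (x$h > 0) paste0("H", x$h) else "",
    if (x$o > 0) paste0("O", x$o) else "",
    if (x$n > 0) paste0("N", x$n) else "")
  cat(sprintf("<chemical_species> %s  %s  M = %.2f g/mol%s\n",
              x$name, if (nzchar(frm)) frm else "(non-CHON)",
              x$molar_mass, if (x$chon_only) "" else "  [contains other elements]"))
  invisible(x)
}

#' Built-in species database
#'
#' The substrates and stressors of the four-reactor stress experiment:
#' glucose (substrate), nalidixic acid and gamma-aminobutyric acid
#' (organic stressors) and anhydrous trisodium phosphate (inorganic
#' stressor, Na3PO4, M = 163.94 g/mol).
#'
#' @return Named list of [chemical_species()] objects.
#' @export
species_db <- function() {
  list(
    glucose         = chemical_species("glucose", c = 6, h = 12, o = 6,
                                       molar_mass = 180.16),
    nalidixic_acid  = chemical_species("nalidixic acid", c = 12, h = 12,
                                       o = 3, n = 2, molar_mass = 232.24),
    gaba            = chemical_species("gamma-aminobutyric acid", c = 4,
                                       h = 9, o = 2, n = 1,
                                       molar_mass = 103.12),
    sodium_phosphate = chemical_species("trisodium phosphate", c = 0, h = 0,
                                        o = 4, n = 0, molar_mass = 163.94,
                                        chon_only = FALSE))
}

#' Buswell-Boyle specific theoretical methane potential
#'
#' For a fully degradable substrate CcHhOoNn, complete anaerobic
#' conversion yields `c/2 + h/8 - o/4 - 3n/8` mol CH4 per mol substrate.
#' The specific potential is that molar yield times the molar gas volume
#' at 273 K / 1013 hPa, divided by the molar mass.  Fully oxidised
#' substrates (non-positive methane moles) are clamped to zero and
#' flagged via the `non_methanogenic` attribute rather than erroring, so
#' batch tables stay totally ordered.
#'
#' @param species a [chemical_species()] with complete C/H/O/N
#'   composition and at least one carbon.
#' @return Specific methane potential in L CH4 (STP) per g, with
#'   attribute `non_methanogenic`.
#' @examples
#' db <- species_db()
#' round(buswell_yield(db$nalidixic_acid), 2)  # 0.58
#' round(buswell_yield(db$gaba), 2)            # 0.49
#' @export
buswell_yield <- function(species) {
  stopifnot(inherits(species, "chemical_species"))
  if (!species$chon_only) {
    abort(sprintf(
      "'%s' contains elements beyond C/H/O/N; Buswell stoichiometry undefined",
      species$name), "digestor_composition_error")
  }
  if (species$c < 1) {
    abort(sprintf("'%s' has no carbon; no methane can form", species$name),
          "digestor_composition_error")
  }
  mol_ch4 <- species$c / 2 + species$h / 8 - species$o / 4 - 3 * species$n / 8
  clamped <- mol_ch4 <= 0
  y <- max(0, mol_ch4) * MOLAR_VOLUME / species$molar_mass
  structure(y, non_methanogenic = clamped)
}

#' Theoretical methane potential of an applied load
#'
#' Volume of methane (per litre working volume) expected from complete
#' degradation of `load` g/L of a substrate.  By default the per-gram
#' yield is rounded half-up to `yield_digits = 2` decimals before
#' multiplying, which is how the study's printed chain works (21.11 g/L
#' x 0.58 L/g = 12.24 L); set `yield_digits = NULL` for full precision.
#' Alternatively pass a per-gram `yield` directly, e.g. when an
#' empirical conversion basis rather than the Buswell value is wanted.
#'
#' @param load applied load in g per L working volume (>= 0).
#' @param species a [chemical_species()]; ignored when `yield` is given.
#' @param yield optional specific methane potential, L/g.
#' @param yield_digits decimals to which the per-gram yield is rounded
#'   before multiplication, or `NULL` for no rounding.
#' @return Theoretical methane potential, L CH4 per L working volume.
#' @examples
#' theoretical_methane(21.11, species_db()$nalidixic_acid)  # 12.24
#' @export
theoretical_methane <- function(load, species = NULL, yield = NULL,
                                yield_digits = 2) {
  check_number(load, "load", lower = 0)
  if (is.null(yield)) {
    if (is.null(species)) {
      abort("supply either `species` or `yield`", "digestor_domain_error")
    }
    yield <- as.numeric(buswell_yield(species))
  }
  if (!is.null(yield_digits)) yield <- round_half_up(yield, yield_digits)
  load * yield
}

#' Define a feeding event
#'
#' @param day non-negative integer experiment day.
#' @param substrate_load substrate in gVS per L working volume.
#' @param stressor_load stressor in g per L working volume.
#' @param stressor_is_organic does the stressor contribute volatile
#'   solids (organic carbon)?  Inorganic stressors (e.g. sodium
#'   phosphate) do not enter the loading rate.
#' @return A one-row `data.frame`.
#' @export
feeding_event <- function(day, substrate_load = 0, stressor_load = 0,
                          stressor_is_organic = FALSE) {
  check_number(day, "day", lower = 0)
  check_number(substrate_load, "substrate_load", lower = 0)
  check_number(stressor_load, "stressor_load", lower = 0)
  data.frame(day = day, substrate_load = substrate_load,
             stressor_load = stressor_load,
             stressor_is_organic = isTRUE(stressor_is_organic))
}

#' Organic loading rate over one week of feeding events
#'
#' Daily flow of volatile solids: the week's summed VS divided by 7.
#' Glucose counts fully as VS; organic stressors add their load;
#' inorganic stressors contribute nothing.
#'
#' @param events a `data.frame` of feeding events (see
#'   [feeding_event()]); all days must fall within one 7-day window.
#' @return OLR in gVS per L per day (full precision; round for reports).
#' @examples
#' wk <- do.call(rbind, lapply(c(0, 2, 4), feeding_event, substrate_load = 1))
#' round(organic_loading_rate(wk), 2)  # 0.43
#' @export
organic_loading_rate <- function(events) {
  if (is.null(events) || NROW(events) == 0L) return(0)
  stopifnot(is.data.frame(events))
  if (diff(range(events$day)) >= 7) {
    abort("feeding events span more than one 7-day window",
          "digestor_domain_error")
  }
  vs <- sum(events$substrate_load) +
    sum(events$stressor_load[events$stressor_is_organic])
  vs / 7
}

#' Weekly organic loading rates for a whole schedule
#'
#' Splits a feeding schedule into consecutive 7-day windows (week 1 =
#' days 0-6) and computes [organic_loading_rate()] per window.
#'
#' @param schedule `data.frame` of feeding events over the experiment.
#' @return `data.frame` with columns `week` and `olr`.
#' @export
olr_by_week <- function(schedule) {
  stopifnot(is.data.frame(schedule))
  if (nrow(schedule) == 0L) {
    return(data.frame(week = integer(), olr = numeric()))
  }
  wk <- schedule$day %/% 7 + 1L
  weeks <- seq_len(max(wk))
  olr <- vapply(weeks, function(w) {
    organic_loading_rate(schedule[wk == w, , drop = FALSE])
  }, numeric(1))
  data.frame(week = weeks, olr = olr)
}

#' Define a reactor configuration
#'
#' @param working_volume working volume in L.
#' @param exchange_volume volume removed and replaced per feeding, L.
#' @param feedings_per_week number of feeding events per week.
#' @return An object of class `reactor_config`.
#' @export
reactor_config <- function(working_volume, exchange_volume,
                           feedings_per_week) {
  check_number(working_volume, "working_volume", lower = 0,
               allow_zero_lower = FALSE)
  check_number(exchange_volume, "exchange_volume", lower = 0,
               upper = working_volume)
  check_number(feedings_per_week, "feedings_per_week", lower = 0)
  structure(list(working_volume = working_volume,
                 exchange_volume = exchange_volume,
                 feedings_per_week = feedings_per_week),
            class = "reactor_config")
}

#' Hydraulic retention time
#'
#' Working volume divided by the mean daily throughput
#' (`exchange_volume * feedings_per_week / 7`).  A 3 L working volume
#' with 150 mL exchanged thrice weekly gives 46.66... days (reports
#' conventionally truncate to 2 decimals).
#'
#' @param config a [reactor_config()].
#' @return Retention time in days, full precision.
#' @export
hydraulic_retention_time <- function(config) {
  stopifnot(inherits(config, "reactor_config"))
  if (config$exchange_volume <= 0 || config$feedings_per_week <= 0) {
    abort("no throughput: exchange volume and feedings per week must be > 0",
          "digestor_no_throughput_error")
  }
  config$working_volume /
    (config$exchange_volume * config$feedings_per_week / 7)
}

#' Digestion efficiency
#'
#' Produced methane as a percentage of the theoretical potential.
#'
#' @param produced methane produced, L (>= 0).
#' @param theoretical theoretical methane potential, L (> 0).
#' @return Efficiency in percent.
#' @examples
#' round(digestion_efficiency(16.66, 28.96), 2)  # 57.53
#' @export
digestion_efficiency <- function(produced, theoretical) {
  check_number(produced, "produced", lower = 0)
  check_number(theoretical, "theoretical", lower = 0,
               allow_zero_lower = FALSE)
  100 * produced / theoretical
}

#' Expected methane surplus from a stressor
#'
#' Additional methane expected over the control if the stressor's
#' theoretical potential were converted at the observed digestion
#' efficiency.
#'
#' @param theoretical_stressor theoretical potential of the stressor, L.
#' @param efficiency digestion efficiency in percent, within \[0, 100\].
#' @return Expected surplus, L.
#' @export
expected_surplus <- function(theoretical_stressor, efficiency) {
  check_number(theoretical_stressor, "theoretical_stressor", lower = 0)
  check_number(efficiency, "efficiency", lower = 0, upper = 100)
  theoretical_stressor * efficiency / 100
}

#' Define a gas measurement
#'
#' @param volume measured gas volume, L.
#' @param temperature gas temperature, K.
#' @param pressure gas pressure, hPa.
#' @return An object of class `gas_measurement`.
#' @export
gas_measurement <- function(volume, temperature, pressure) {
  check_number(volume, "volume", lower = 0)
  check_number(temperature, "temperature", lower = 0,
               allow_zero_lower = FALSE)
  check_number(pressure, "pressure", lower = 0, allow_zero_lower = FALSE)
  structure(list(volume = volume, temperature = temperature,
                 pressure = pressure), class = "gas_measurement")
}

#' Normalise a gas volume to standard conditions
#'
#' Ideal-gas correction to 273 K and 1013 hPa:
#' `V * (273 / T) * (p / 1013)`.
#'
#' @param m a [gas_measurement()], or a volume in L when `temperature`
#'   and `pressure` are given.
#' @param temperature,pressure alternative scalar inputs (K, hPa).
#' @return Volume in L at 273 K / 1013 hPa.
#' @export
normalize_gas_volume <- function(m, temperature = NULL, pressure = NULL) {
  if (!inherits(m, "gas_measurement")) {
    m <- gas_measurement(m, temperature, pressure)
  }
  m$volume * (273 / m$temperature) * (m$pressure / 1013)
}

#' Molar concentration of an applied load
#'
#' @param load load in g per L (>= 0).
#' @param species a [chemical_species()].
#' @return Concentration in mM.
#' @examples
#' round(molar_concentration(20.5, species_db()$sodium_phosphate))  # 125
#' @export
molar_concentration <- function(load, species) {
  check_number(load, "load", lower = 0)
  stopifnot(inherits(species, "chemical_species"))
  1000 * load / species$molar_mass
}
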