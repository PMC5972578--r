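# Experiment-design utilities: thermal-time-equivalent sampling days for
# aligning grain development between post-anthesis temperature regimes, and
# nutrient-solution nitrogen supply from a recipe.

MG_N_PER_MMOL <- 14.0067  # atomic mass of nitrogen, mg per mmol

#' Describe a day/night temperature regime
#'
#' Square-wave profile: `day_temp` for `day_hours` of each 24 h and
#' `night_temp` for the rest. Symmetric day/night transition ramps leave
#' the daily mean unchanged and are ignored.
#'
#' @param day_temp,night_temp daytime and night temperatures, deg C.
#' @param day_hours photoperiod, hours per 24 (default 16).
#' @param base_temp base temperature for thermal time, deg C (default 4.1,
#'   the standard base for wheat development).
#' @return object of class `thermal_regime`.
#' @export
thermal_regime <- function(day_temp, night_temp, day_hours = 16,
                           base_temp = 4.1) {
  if (day_hours <= 0 || day_hours >= 24)
    stop("day_hours must be strictly between 0 and 24", call. = FALSE)
  if (day_temp < night_temp)
    stop("day_temp must be >= night_temp", call. = FALSE)
  reg <- structure(list(day_temp = day_temp, night_temp = night_temp,
                        day_hours = day_hours, base_temp = base_temp),
                   class = "thermal_regime")
  if (daily_thermal_time(reg) <= 0)
    stop("mean daily temperature does not exceed the base temperature",
         call. = FALSE)
  reg
}

#' Daily thermal time of a regime
#'
#' Photoperiod-weighted daily mean temperature minus the base temperature,
#' in degree-days per day.
#'
#' @param regime a [thermal_regime()].
#' @return degree-days accumulated per day.
#' @export
daily_thermal_time <- function(regime) {
  stopifnot(inherits(regime, "thermal_regime"))
  mean_t <- (regime$day_temp * regime$day_hours +
             regime$night_temp * (24 - regime$day_hours)) / 24
  mean_t - regime$base_temp
}

#' Thermal-time-equivalent sampling day under another regime
#'
#' The day count under `target` that accumulates the same thermal time as
#' `reference_days` under `reference`, rounded to the nearest whole day
#' (halves away from zero).
#'
#' @param reference regime the stated days refer to.
#' @param reference_days days after anthesis under `reference`.
#' @param target regime to convert to.
#' @return integer day count.
#' @export
equivalent_day <- function(reference, reference_days, target) {
  dd_ref <- daily_thermal_time(reference)
  dd_tgt <- daily_thermal_time(target)
  if (dd_tgt <= 0) stop("target regime accumulates no thermal time",
                        call. = FALSE)
  x <- reference_days * dd_ref / dd_tgt
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Describe a nutrient-solution recipe
#'
#' @param components data.frame with columns `compound`, `mmol_per_l`
#'   (molarity, mM), `n_atoms` (nitrogen atoms per formula unit) and
#'   optionally `chelator` (logical; chelator-bound nitrogen such as
#'   FeNaEDTA, excluded from default totals).
#' @param volume_per_application litres per application.
#' @param n_applications number of applications.
#' @return object of class `nutrient_recipe`.
#' @export
nutrient_recipe <- function(components, volume_per_application,
                            n_applications) {
  stopifnot(is.data.frame(components),
            all(c("compound", "mmol_per_l", "n_atoms") %in%
                  names(components)))
  if (any(components$mmol_per_l < 0) ||
      any(components$n_atoms < 0) ||
      any(components$n_atoms != round(components$n_atoms)))
    stop("molarity must be >= 0 and n_atoms a non-negative integer",
         call. = FALSE)
  if (volume_per_application < 0 || n_applications < 0)
    stop("volume and application count must be non-negative", call. = FALSE)
  if (is.null(components$chelator)) components$chelator <- FALSE
  structure(list(components = components,
                 volume_per_application = volume_per_application,
                 n_applications = n_applications),
            class = "nutrient_recipe")
}

#' Total nitrogen supplied by a recipe
#'
#' Sum over components of molarity (mmol/l) x nitrogen atoms x 14.0067
#' mg/mmol x litres per application x applications. Chelator-bound
#' nitrogen (e.g. FeNaEDTA) is excluded by default since it is not a plant
#' nitrogen source in the usual accounting.
#'
#' @param recipe a [nutrient_recipe()].
#' @param include_chelator count chelator-bound nitrogen too (default
#'   FALSE).
#' @return total nitrogen in mg.
#' @export
nitrogen_mass <- function(recipe, include_chelator = FALSE) {
  stopifnot(inherits(recipe, "nutrient_recipe"))
  comp <- recipe$components
  if (!include_chelator) comp <- comp[!comp$chelator, , drop = FALSE]
  sum(comp$mmol_per_l * comp$n_atoms) * MG_N_PER_MMOL *
    recipe$volume_per_application * recipe$n_applications
}

#' Nutrient-solution recipes for the high- and low-nitrogen treatments
#'
#' The liquid feeds used in the controlled-environment trial: calcium
#' nitrate supplies the nitrogen (4 mM high, 0.4 mM low, the low treatment
#' balanced with CaCl2), with a common macro/micronutrient background.
#' Nine 0.5-l applications per pot.
#'
#' @param level "high" or "low".
#' @return a [nutrient_recipe()].
#' @export
trial_nutrient_recipe <- function(level = c("high", "low")) {
  level <- match.arg(level)
  base <- data.frame(
    compound = c("KH2PO4", "KOH", "MgSO4.7H2O", "CaCl2", "FeNaEDTA",
                 "H3BO3", "MnSO4.4H2O", "ZnCl2.7H2O", "CuSO4.5H2O",
                 "Na2MoO2.2H2O"),
    mmol_per_l = c(0.25, 0.5, 0.75, 0.03, 0.1, 0.03, 0.01, 0.001, 0.003,
                   0.0005),
    n_atoms = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    chelator = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, FALSE))
  nsource <- if (level == "high") {
    data.frame(compound = "Ca(NO3)2.4H2O", mmol_per_l = 4, n_atoms = 2L,
               chelator = FALSE)
  } else {
    data.frame(compound = c("Ca(NO3)2.4H2O", "CaCl2"),
               mmol_per_l = c(0.4, 3.6), n_atoms = c(2L, 0L),
               chelator = c(FALSE, FALSE))
  }
  nutrient_recipe(rbind(nsource, base), volume_per_application = 0.5,
                  n_applications = 9)
}

#' Difference between two treatment-level means of a harvest trait
#'
#' Convenience for recomputing printed treatment contrasts from a table of
#' level means (e.g. thousand grain weight by temperature level).
#'
#' @param means data.frame with columns `factor`, `level`, and the trait.
#' @param factor_name which factor to contrast.
#' @param trait trait column name.
#' @param higher,lower level names; `higher - lower` is returned. Defaults
#'   to the first and second level in table order.
#' @return numeric difference in the trait's units.
#' @export
trait_difference <- function(means, factor_name, trait,
                             higher = NULL, lower = NULL) {
  rows <- means[means$factor == factor_name, , drop = FALSE]
  if (nrow(rows) < 2L) stop("need two levels for factor '", factor_name,
                            "'", call. = FALSE)
  if (is.null(higher)) higher <- rows$level[1]
  if (is.null(lower)) lower <- rows$level[2]
  rows[rows$level == higher, trait] - rows[rows$level == lower, trait]
}
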