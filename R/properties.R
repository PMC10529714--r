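#' Component thermophysical property constants
#'
#' Density, specific heat and thermal conductivity of the five proximate
#' food components (water, protein, fat, carbohydrate, ash), evaluated at
#' 20 degrees C from the standard Choi-Okos polynomial correlations used
#' throughout food engineering. Properties are treated as
#' temperature-independent during simulation; 20 degrees C is a mid-process
#' reference.
#'
#' @return A data.frame with row names `water`, `protein`, `fat`,
#'   `carbohydrate`, `ash` and columns `rho` (kg/m^3), `cp` (J/(kg K)),
#'   `k` (W/(m K)).
#' @export
#' @examples
#' component_property_table()
component_property_table <- function() {
  data.frame(
    rho = c(995.74, 1319.53, 917.24, 1592.89, 2418.19),
    cp  = c(4177.6, 2031.86, 2011.70, 1585.71, 1128.94),
    k   = c(0.60363, 0.20157, 0.17487, 0.22741, 0.35553),
    row.names = c("water", "protein", "fat", "carbohydrate", "ash")
  )
}

.components <- c("water", "protein", "fat", "carbohydrate", "ash")

#' Proximate composition of a food product
#'
#' Mass fractions of the five proximate components. Fractions must each lie
#' in \[0, 1\] and sum to 1 (tolerance 1e-9).
#'
#' @param water,protein,fat,carbohydrate,ash Mass fractions (dimensionless).
#' @return A named numeric vector of class `"composition"`.
#' @export
#' @examples
#' composition(water = 0.75, protein = 0.2, fat = 0.05)
composition <- function(water, protein = 0, fat = 0, carbohydrate = 0,
                        ash = 0) {
  x <- c(water = water, protein = protein, fat = fat,
         carbohydrate = carbohydrate, ash = ash)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("composition: each mass fraction must lie in [0, 1]", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-9)
    stop(sprintf("composition: mass fractions sum to %.12f, not 1", sum(x)),
         call. = FALSE)
  structure(x, class = "composition")
}

#' Default cured pork loin composition
#'
#' A proximate composition representative of salted (cured) pork loin,
#' calibrated once (see `scripts/calibrate_composition.R`) so that the three
#' property estimators applied to [component_property_table()] with the
#' default conductivity weight g = 0.5 reproduce the packaged typical
#' product properties (1064.5 kg/m^3, 3535.5 J/(kg K), 0.47 W/(m K))
#' to within 0.5 percent. The elevated ash fraction reflects the curing salt.
#'
#' @return A `"composition"` object.
#' @export
default_composition <- function() {
  composition(water = 0.726, protein = 0.182, fat = 0.043,
              carbohydrate = 0.006, ash = 0.043)
}

.check_comp_props <- function(comp_props, cols = c("rho", "cp", "k")) {
  if (!is.data.frame(comp_props) ||
      !all(.components %in% rownames(comp_props)))
    stop("comp_props must be a data.frame with rows ",
         paste(.components, collapse = ", "), call. = FALSE)
  for (cc in cols)
    if (any(!is.finite(comp_props[.components, cc]) |
            comp_props[.components, cc] <= 0))
      stop("comp_props: all ", cc, " values must be strictly positive",
           call. = FALSE)
  comp_props[.components, , drop = FALSE]
}

.check_comp <- function(comp) {
  if (!inherits(comp, "composition"))
    comp <- do.call(composition, as.list(comp[.components]))
  comp
}

#' Effective density from composition
#'
#' Harmonic mass-fraction mixture rule: `rho_m = 1 / sum(x_i / rho_i)`.
#'
#' @param comp A [composition()].
#' @param comp_props Component property table, see
#'   [component_property_table()].
#' @return Effective density (kg/m^3).
#' @export
#' @examples
#' estimate_density(default_composition())
estimate_density <- function(comp, comp_props = component_property_table()) {
  comp <- .check_comp(comp)
  comp_props <- .check_comp_props(comp_props, "rho")
  1 / sum(comp / comp_props$rho)
}

#' Effective specific heat from composition
#'
#' Mass-fraction-weighted arithmetic mean: `cp_m = sum(cp_i * x_i)`.
#'
#' @inheritParams estimate_density
#' @return Effective specific heat (J/(kg K)).
#' @export
estimate_heat_capacity <- function(comp,
                                   comp_props = component_property_table()) {
  comp <- .check_comp(comp)
  comp_props <- .check_comp_props(comp_props, "cp")
  sum(comp * comp_props$cp)
}

#' Component volume fractions
#'
#' `eps_i = (x_i / rho_i) / sum(x_j / rho_j)`.
#'
#' @inheritParams estimate_density
#' @return Named numeric vector of volume fractions summing to 1.
#' @export
volume_fractions <- function(comp, comp_props = component_property_table()) {
  comp <- .check_comp(comp)
  comp_props <- .check_comp_props(comp_props, "rho")
  sv <- comp / comp_props$rho
  tot <- sum(sv)
  if (tot <= 0) stop("volume_fractions: zero total specific volume",
                     call. = FALSE)
  stats::setNames(as.numeric(sv / tot), .components)
}

#' Effective thermal conductivity from composition
#'
#' Weighted blend of the parallel (arithmetic, volume-weighted) and
#' perpendicular (harmonic, volume-weighted) conductivity mixture bounds:
#' `k_m = g * k_per + (1 - g) * k_par` with
#' `k_par = sum(eps_i * k_i)` and `k_per = 1 / sum(eps_i / k_i)`.
#'
#' @inheritParams estimate_density
#' @param g Weight of the perpendicular model, in \[0, 1\]. The default 0.5
#'   is the midpoint of the two bounds.
#' @return Effective conductivity (W/(m K)).
#' @export
estimate_thermal_conductivity <- function(comp,
                                          comp_props =
                                            component_property_table(),
                                          g = 0.5) {
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g < 0 || g > 1)
    stop("g must be a single value in [0, 1]", call. = FALSE)
  comp_props <- .check_comp_props(comp_props, c("rho", "k"))
  eps <- volume_fractions(comp, comp_props)
  k_par <- sum(eps * comp_props$k)
  k_per <- 1 / sum(eps / comp_props$k)
  g * k_per + (1 - g) * k_par
}

#' Bundle of effective product properties
#'
#' @param rho Density (kg/m^3).
#' @param cp Specific heat (J/(kg K)).
#' @param k Thermal conductivity (W/(m K)).
#' @return List of class `"thermo_props"` with elements `rho`, `cp`, `k` and
#'   the derived thermal diffusivity `alpha = k / (rho * cp)` (m^2/s).
#' @export
thermo_props <- function(rho, cp, k) {
  v <- c(rho = rho, cp = cp, k = k)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("thermo_props: rho, cp and k must be strictly positive",
         call. = FALSE)
  structure(list(rho = rho, cp = cp, k = k, alpha = k / (rho * cp)),
            class = "thermo_props")
}

#' Effective properties from a composition
#'
#' @inheritParams estimate_thermal_conductivity
#' @return A [thermo_props()] object.
#' @export
#' @examples
#' props_from_composition(default_composition())
props_from_composition <- function(comp,
                                   comp_props = component_property_table(),
                                   g = 0.5) {
  thermo_props(estimate_density(comp, comp_props),
               estimate_heat_capacity(comp, comp_props),
               estimate_thermal_conductivity(comp, comp_props, g))
}

#' @export
#' @method print thermo_props
print.thermo_props <- function(x, ...) {
  cat(sprintf(
    "thermo_props: rho = %.1f kg/m^3, cp = %.1f J/(kg K), k = %.3f W/(m K)\n",
    x$rho, x$cp, x$k))
  invisible(x)
}
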