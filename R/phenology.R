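#' Phenology parameters for a simulated field
#'
#' Describes the noise-free seasonal NDVI trajectory of a field and the
#' corresponding cross-polarised (VH) backscatter levels. The NDVI curve is a
#' normalised double-logistic bump between `ndvi_base` (bare soil) and
#' `ndvi_peak` (full canopy); with `n_cycles = 2` the growing season is split
#' into two successive bumps (e.g. a double vegetable crop).
#'
#' @param ndvi_base bare-soil NDVI level (dimensionless).
#' @param ndvi_peak full-canopy NDVI level; must exceed `ndvi_base`.
#' @param green_up_doy,senescence_doy start and end (day of year) of the
#'   growing season. `green_up_doy` may be negative to model winter crops that
#'   are already green on January 1st.
#' @param n_cycles 1 or 2 growth cycles within the season.
#' @param vh_soil_db,vh_canopy_db VH backscatter (dB) over bare soil and full
#'   canopy; vegetation volume scattering raises VH, so typically
#'   `vh_canopy_db > vh_soil_db`.
#' @param vh_metal_boost_db additive VH increase (dB) caused by metal support
#'   structures under a plastic cover above vegetation; must be non-negative.
#' @return an object of class `phenology_params`.
#' @export
phenology_params <- function(ndvi_base = 0.15, ndvi_peak = 0.80,
                             green_up_doy = 120, senescence_doy = 260,
                             n_cycles = 1,
                             vh_soil_db = -20, vh_canopy_db = -14,
                             vh_metal_boost_db = 4) {
  if (ndvi_base >= ndvi_peak) {
    abort("`ndvi_base` must be smaller than `ndvi_peak`",
          class = "plasticmapr_config_error")
  }
  if (vh_metal_boost_db < 0) {
    abort("`vh_metal_boost_db` must be >= 0", class = "plasticmapr_config_error")
  }
  if (!n_cycles %in% c(1, 2)) {
    abort("`n_cycles` must be 1 or 2", class = "plasticmapr_config_error")
  }
  if (senescence_doy <= green_up_doy) {
    abort("`green_up_doy` must precede `senescence_doy`",
          class = "plasticmapr_config_error")
  }
  structure(list(ndvi_base = ndvi_base, ndvi_peak = ndvi_peak,
                 green_up_doy = green_up_doy, senescence_doy = senescence_doy,
                 n_cycles = n_cycles, vh_soil_db = vh_soil_db,
                 vh_canopy_db = vh_canopy_db,
                 vh_metal_boost_db = vh_metal_boost_db),
            class = "phenology_params")
}

# Normalised double-logistic bump over [a, b]: ~0 outside, 1 at the midpoint.
logistic_bump <- function(doy, a, b) {
  w <- b - a
  rate <- 0.04 * w
  up <- stats::plogis((doy - (a + 0.25 * w)) / rate)
  down <- stats::plogis(((b - 0.25 * w) - doy) / rate)
  mid <- (a + b) / 2
  norm <- stats::plogis((mid - (a + 0.25 * w)) / rate) *
    stats::plogis(((b - 0.25 * w) - mid) / rate)
  up * down / norm
}

#' Vegetation fraction implied by the phenology curve
#'
#' The normalised (0 = bare, 1 = full canopy) seasonal development used by
#' both [phenology_ndvi()] and the backscatter model of the scene simulator.
#'
#' @param doy day(s) of year, 1-366.
#' @param params a [phenology_params()] object.
#' @return numeric vector in \eqn{[0, 1]}.
#' @export
phenology_fraction <- function(doy, params) {
  if (any(doy < 1 | doy > 366)) {
    abort("`doy` must lie in 1..366", class = "plasticmapr_domain_error")
  }
  a <- params$green_up_doy
  b <- params$senescence_doy
  if (params$n_cycles == 1) {
    g <- logistic_bump(doy, a, b)
  } else {
    mid <- (a + b) / 2
    g <- pmax(logistic_bump(doy, a, mid), logistic_bump(doy, mid, b))
  }
  clamp(g, 0, 1)
}

#' Seasonal NDVI curve
#'
#' Smooth, noise-free NDVI as a function of day of year: `ndvi_base` outside
#' the growing season, `ndvi_peak` at mid-season, a normalised double-logistic
#' transition in between. With `n_cycles = 2` the curve shows two local
#' maxima, one per growth cycle.
#'
#' @inheritParams phenology_fraction
#' @return NDVI value(s), dimensionless.
#' @examples
#' p <- phenology_params()
#' phenology_ndvi(c(20, 190, 350), p)
#' @export
phenology_ndvi <- function(doy, params) {
  g <- phenology_fraction(doy, params)
  params$ndvi_base + g * (params$ndvi_peak - params$ndvi_base)
}

#' Noise-free VH backscatter implied by the phenology curve
#'
#' Linear interpolation between the bare-soil and full-canopy VH levels with
#' the vegetation fraction of [phenology_fraction()].
#'
#' @inheritParams phenology_fraction
#' @return VH backscatter in dB.
#' @export
phenology_vh <- function(doy, params) {
  g <- phenology_fraction(doy, params)
  params$vh_soil_db + g * (params$vh_canopy_db - params$vh_soil_db)
}
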