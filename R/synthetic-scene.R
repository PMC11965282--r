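#' Field specification for the scene simulator
#'
#' A rectangular field with a truth class, plastic-management attributes and
#' phenology. The generative rules follow the contrasts that distinguish the
#' three land uses in fused optical/radar time series: black mulching films
#' raise NDVI over bare soil while leaving backscatter at the soil level;
#' plastic covers above vegetation flatten the NDVI series and raise VH
#' through their metal support structures; plastic-free farmland simply
#' follows its crop phenology.
#'
#' @param rows,cols integer ranges `c(first, last)` of the field rectangle in
#'   grid coordinates.
#' @param truth_class one of `"PFF"`, `"PMF"`, `"PCV"`.
#' @param cover_window optional `c(start_doy, end_doy)` during which the
#'   plastic cover is present; required for PMF (mulch is seasonal here),
#'   ignored for permanent PCV.
#' @param film_type `"black"`, `"transparent_white"` or `"none"`.
#' @param permanence `"seasonal"` or `"permanent"` (PCV only).
#' @param phenology a [phenology_params()] object.
#' @param film_ndvi apparent NDVI of the film-covered surface (black films
#'   suppress red reflectance more than NIR, so this sits well above the
#'   bare-soil NDVI).
#' @param confounder logical; if `TRUE` the field is plastic-free but its
#'   soil, when bare, mimics the optical signature of a mulching film (the
#'   bright-soil false-positive mechanism the spatial QC is designed to
#'   catch).
#' @param role `"train"`, `"validation"` or `"none"` (e.g. QC-only regions).
#' @param id optional field identifier.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(rows, cols, truth_class = c("PFF", "PMF", "PCV"),
                       cover_window = NULL,
                       film_type = c("none", "black", "transparent_white"),
                       permanence = c("seasonal", "permanent"),
                       phenology = phenology_params(),
                       film_ndvi = phenology$ndvi_base + 0.35,
                       confounder = FALSE,
                       role = c("train", "validation", "none"),
                       id = NULL) {
  truth_class <- match.arg(truth_class)
  film_type <- match.arg(film_type)
  permanence <- match.arg(permanence)
  role <- match.arg(role)
  if (length(rows) != 2 || length(cols) != 2 || rows[1] > rows[2] || cols[1] > cols[2]) {
    abort("`rows` and `cols` must each be c(first, last) with first <= last",
          class = "plasticmapr_config_error")
  }
  if (truth_class == "PFF" && (film_type != "none" || !is.null(cover_window))) {
    abort("a PFF field cannot have a film type or a cover window",
          class = "plasticmapr_config_error")
  }
  if (truth_class == "PMF") {
    if (is.null(cover_window)) {
      abort("a PMF field requires a `cover_window` (mulch is seasonal)",
            class = "plasticmapr_config_error")
    }
    if (film_type == "none") film_type <- "black"
  }
  if (truth_class == "PCV" && permanence == "seasonal" && is.null(cover_window)) {
    abort("a seasonal PCV field requires a `cover_window`",
          class = "plasticmapr_config_error")
  }
  if (!is.null(cover_window) &&
      (length(cover_window) != 2 || cover_window[1] >= cover_window[2] ||
       cover_window[1] < 1 || cover_window[2] > 366)) {
    abort("`cover_window` must be c(start_doy, end_doy) within 1..366",
          class = "plasticmapr_config_error")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 truth_class = truth_class, cover_window = cover_window,
                 film_type = film_type, permanence = permanence,
                 phenology = phenology, film_ndvi = film_ndvi,
                 confounder = confounder, role = role, id = id),
            class = "field_spec")
}

#' Scene simulator configuration
#'
#' @param grid_size `c(rows, cols)` in pixels; at least 16 x 16.
#' @param pixel_size pixel edge length in metres.
#' @param n_optical_dates,n_radar_dates number of optical / radar acquisitions
#'   spread over the year.
#' @param field_layout list of [field_spec()] objects.
#' @param cloud_fraction_mean mean per-date scene cloud fraction in
#'   \eqn{[0, 1]}; per-date fractions are drawn uniformly within 0.25 of it.
#' @param speckle_looks equivalent number of looks of the multiplicative
#'   gamma speckle applied to the radar bands in the linear power domain.
#' @param clear_doys days of year whose optical acquisitions are kept
#'   cloud-free (reference dates for single-date classifier training).
#' @param seed integer seed making the whole scene reproducible.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(grid_size = c(192, 128), pixel_size = 10,
                         n_optical_dates = 24, n_radar_dates = 36,
                         field_layout = list(),
                         cloud_fraction_mean = 0.3, speckle_looks = 5,
                         clear_doys = c(85, 120), seed = 1) {
  if (length(grid_size) != 2 || any(grid_size < 16)) {
    abort("`grid_size` must be c(rows, cols) with both >= 16",
          class = "plasticmapr_config_error")
  }
  if (cloud_fraction_mean < 0 || cloud_fraction_mean > 1) {
    abort("`cloud_fraction_mean` must lie in [0, 1]",
          class = "plasticmapr_config_error")
  }
  if (speckle_looks <= 0) {
    abort("`speckle_looks` must be positive", class = "plasticmapr_config_error")
  }
  for (f in field_layout) {
    if (!inherits(f, "field_spec")) {
      abort("`field_layout` must contain field_spec objects",
            class = "plasticmapr_config_error")
    }
    if (f$rows[2] > grid_size[1] || f$cols[2] > grid_size[2]) {
      abort(sprintf("field [%s] extends beyond the grid", f$id %||% "?"),
            class = "plasticmapr_config_error")
    }
  }
  structure(list(grid_size = as.integer(grid_size), pixel_size = pixel_size,
                 n_optical_dates = as.integer(n_optical_dates),
                 n_radar_dates = as.integer(n_radar_dates),
                 field_layout = field_layout,
                 cloud_fraction_mean = cloud_fraction_mean,
                 speckle_looks = speckle_looks,
                 clear_doys = as.integer(clear_doys),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Default field layout of the synthetic study area
#'
#' Lays fields on a regular lattice of 16 x 16-pixel cells, in three
#' horizontal bands from the top of the grid:
#' \enumerate{
#'   \item a mixed farming band with `n_per_class` fields per land-use class
#'     (alternating train / validation roles, variable sizes between 0.36 and
#'     1 ha on a 10 m grid, per-field jittered phenology);
#'   \item a clean plastic-free band of `n_clean` additional PFF fields (no
#'     plasticulture, no soil confounding) serving as the control region for
#'     the spatial QC;
#'   \item a confounder band of `n_confounder` plastic-free fields whose
#'     bright soil mimics mulching film when bare — the false-hotspot
#'     fixture.
#' }
#' Roughly 40% of the plastic-free fields follow a winter-crop phenology
#' (green in early spring), so that single-date training data contain both
#' bare and vegetated plastic-free surfaces.
#'
#' @param n_per_class fields per class in the mixed band.
#' @param n_clean number of clean control fields (0 to disable).
#' @param n_confounder number of confounder fields (0 to disable).
#' @param cell pixel size of a layout cell.
#' @param layout_cols number of cells per lattice row.
#' @param seed integer seed for the per-field jitter.
#' @return list of [field_spec()] objects.
#' @export
default_field_layout <- function(n_per_class = 20, n_clean = 16,
                                 n_confounder = 16,
                                 cell = 16, layout_cols = 8, seed = 1) {
  local_rng(seed)
  classes <- rep(c("PFF", "PMF", "PCV"), each = n_per_class)
  classes <- classes[sample.int(length(classes))]
  n_mixed <- length(classes)
  # clean band starts on a fresh cell row; confounder band likewise
  clean_start <- ceiling(n_mixed / layout_cols) * layout_cols
  conf_start <- clean_start +
    ceiling(n_clean / layout_cols) * layout_cols
  slots <- c(seq_len(n_mixed),
             clean_start + seq_len(n_clean),
             conf_start + seq_len(n_confounder))
  kinds <- c(rep("mixed", n_mixed), rep("clean", n_clean),
             rep("confounder", n_confounder))
  n_total <- length(slots)
  fields <- vector("list", n_total)
  role_counter <- c(PFF = 0L, PMF = 0L, PCV = 0L)
  for (k in seq_len(n_total)) {
    slot <- slots[k]
    cell_row <- (slot - 1) %/% layout_cols
    cell_col <- (slot - 1) %% layout_cols
    conf <- kinds[k] == "confounder"
    cls <- if (kinds[k] == "mixed") classes[k] else "PFF"
    side <- sample(6:10, 1)
    r0 <- cell_row * cell + sample.int(cell - side - 1, 1) + 1
    c0 <- cell_col * cell + sample.int(cell - side - 1, 1) + 1
    winter <- !conf && cls == "PFF" && runif(1) < 0.4
    phen <- phenology_params(
      ndvi_base = clamp(rnorm(1, 0.15, 0.01), 0.08, 0.25),
      ndvi_peak = clamp(rnorm(1, 0.80, 0.03), 0.6, 0.92),
      green_up_doy = if (winter) rnorm(1, -80, 10) else rnorm(1, 120, 12),
      senescence_doy = if (winter) rnorm(1, 175, 10) else rnorm(1, 268, 12),
      n_cycles = if (!conf && runif(1) < 0.3) 2 else 1,
      vh_soil_db = rnorm(1, -20, 0.4),
      vh_canopy_db = rnorm(1, -14, 0.4)
    )
    window <- NULL
    permanence <- "seasonal"
    film <- "none"
    if (cls == "PMF") {
      film <- "black"
      start <- round(clamp(rnorm(1, 60, 8), 30, 80))
      window <- c(start, start + round(clamp(rnorm(1, 90, 12), 60, 130)))
    } else if (cls == "PCV") {
      if (runif(1) < 0.7) {
        permanence <- "permanent"
        film <- "transparent_white"
      } else {
        film <- "transparent_white"
        start <- round(clamp(rnorm(1, 50, 10), 20, 80))
        window <- c(start, start + round(clamp(rnorm(1, 200, 20), 150, 260)))
      }
    }
    role <- if (kinds[k] != "mixed") "none" else {
      role_counter[cls] <- role_counter[cls] + 1L
      if (role_counter[cls] %% 2L == 1L) "train" else "validation"
    }
    fields[[k]] <- field_spec(
      rows = c(r0, r0 + side - 1), cols = c(c0, c0 + side - 1),
      truth_class = cls, cover_window = window, film_type = film,
      permanence = permanence, phenology = phen, confounder = conf,
      role = role, id = sprintf("F%03d", k)
    )
  }
  fields
}

# Seed the RNG locally and restore the caller's state when `envir` exits.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  invisible(seed)
}

#' Noise-free simulated NDVI of a field
#'
#' The deterministic part of the generative model for one field: crop
#' phenology, overridden by the film signature during the cover window (PMF),
#' pinned at the mid value while a cover above vegetation is active (PCV), or
#' mimicking the film when a confounder field is bare.
#'
#' @param doy day(s) of year.
#' @param field a [field_spec()].
#' @return numeric vector of noise-free NDVI values.
#' @export
simulated_ndvi <- function(doy, field) {
  p <- field$phenology
  value <- phenology_ndvi(doy, p)
  active <- cover_active_doy(field, doy)
  if (field$truth_class == "PMF") {
    value[active] <- pmax(field$film_ndvi, value[active])
  } else if (field$truth_class == "PCV") {
    value[active] <- (p$ndvi_base + p$ndvi_peak) / 2
  } else if (field$confounder) {
    bare <- phenology_fraction(doy, p) < 0.2
    value[bare] <- field$film_ndvi
  }
  value
}

#' Noise-free simulated VH backscatter of a field
#'
#' Companion to [simulated_ndvi()]: vegetation-driven VH, held at the soil
#' level under a mulching film (radar is insensitive to the film itself) and
#' raised by the metal-structure boost while a cover above vegetation is
#' active.
#'
#' @inheritParams simulated_ndvi
#' @return numeric vector of noise-free VH values in dB.
#' @export
simulated_vh <- function(doy, field) {
  p <- field$phenology
  value <- phenology_vh(doy, p)
  active <- cover_active_doy(field, doy)
  if (field$truth_class == "PMF") {
    value[active] <- p$vh_soil_db
  } else if (field$truth_class == "PCV") {
    value[active] <- (p$vh_soil_db + p$vh_canopy_db) / 2 + p$vh_metal_boost_db
  } else if (field$confounder) {
    bare <- phenology_fraction(doy, p) < 0.2
    value[bare] <- p$vh_soil_db
  }
  value
}

cover_active_doy <- function(field, doy) {
  if (field$truth_class == "PCV" && field$permanence == "permanent") {
    return(rep(TRUE, length(doy)))
  }
  if (is.null(field$cover_window)) return(rep(FALSE, length(doy)))
  doy >= field$cover_window[1] & doy <= field$cover_window[2]
}

# Spatially correlated standard-normal field: smoothed white noise, rescaled.
smooth_noise_field <- function(nr, nc, radius_px) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  s <- focal_disc_mean(z, radius_px)
  (s - mean(s)) / sd(as.vector(s))
}

#' Generate a synthetic annual optical + radar scene
#'
#' Builds co-registered optical and radar time series over the labelled field
#' layout of `config`, together with the truth class map and a field table.
#' The per-pixel generative rules encode the class contrasts the mapping
#' method exploits:
#' \itemize{
#'   \item PFF follows its crop phenology in both NDVI and VH.
#'   \item PMF with a black film: during the cover window, red reflectance is
#'     suppressed more than NIR, so apparent NDVI sits well above the
#'     bare-soil level while VH stays at the soil level.
#'   \item PCV: NDVI is pinned near the mid-seasonal value with shrunk
#'     variance (the flattened series of a permanent cover) and VH is raised
#'     by `vh_metal_boost_db` over the mid-vegetation level for the cover
#'     duration.
#'   \item Confounder fields are PFF whose bare-soil dates mimic the film
#'     signature.
#' }
#' Clouds are drawn per optical date as spatially correlated blobs whose
#' scene fraction varies uniformly around `cloud_fraction_mean`; speckle is
#' applied to the radar bands as multiplicative gamma noise in the linear
#' power domain before conversion to dB. The whole scene is a deterministic
#' function of `(config, config$seed)`.
#'
#' @param config a [scene_config()].
#' @return list with `optical` (list of [optical_acquisition()]), `radar`
#'   (list of [radar_acquisition()]), `truth` (a [class_map()]) and `fields`
#'   (a tibble with id, class, geometry, area, role and cover attributes).
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) {
    abort("`config` must be a scene_config", class = "plasticmapr_config_error")
  }
  local_rng(config$seed)
  nr <- config$grid_size[1]; nc <- config$grid_size[2]
  ps <- config$pixel_size

  optical_doys <- unique(round(seq(10, 360, length.out = config$n_optical_dates)))
  for (d in config$clear_doys) {
    optical_doys[which.min(abs(optical_doys - d))] <- d
  }
  optical_doys <- sort(unique(optical_doys))
  radar_doys <- unique(round(seq(5, 362, length.out = config$n_radar_dates)))

  # --- per-pixel static attributes -------------------------------------------
  truth <- matrix(NA_integer_, nr, nc)
  field_id_map <- matrix(NA_integer_, nr, nc)
  for (k in seq_along(config$field_layout)) {
    f <- config$field_layout[[k]]
    truth[f$rows[1]:f$rows[2], f$cols[1]:f$cols[2]] <-
      match(f$truth_class, plastic_classes())
    field_id_map[f$rows[1]:f$rows[2], f$cols[1]:f$cols[2]] <- k
  }

  # Background (unlabelled) pixels: generic grassland phenology.
  background <- phenology_params(ndvi_base = 0.2, ndvi_peak = 0.7,
                                 green_up_doy = 100, senescence_doy = 290)
  brightness <- 0.5 + 0.05 * smooth_noise_field(nr, nc, 8)
  # Per-pixel probability that a bare confounder pixel mimics the film
  # signature on a given date: a smooth spatial field, so that detection
  # frequency varies across the confounder region the way soil brightness
  # varies across a real soil unit.
  mimic_p <- clamp(0.55 + 0.35 * smooth_noise_field(nr, nc, 6), 0.05, 1)

  # --- optical series --------------------------------------------------------
  optical <- vector("list", length(optical_doys))
  for (t in seq_along(optical_doys)) {
    doy <- optical_doys[t]
    ndvi <- matrix(phenology_ndvi(doy, background), nr, nc)
    noise_sd <- matrix(0.03, nr, nc)
    for (k in seq_along(config$field_layout)) {
      f <- config$field_layout[[k]]
      idx <- which(field_id_map == k)
      ndvi[idx] <- simulated_ndvi(doy, f)
      if (f$truth_class == "PCV" && cover_active_doy(f, doy)) {
        noise_sd[idx] <- 0.01                    # flattened series: shrunk variance
      }
      if (f$confounder && phenology_fraction(doy, f$phenology) < 0.2) {
        # only a pixel-wise random subset mimics the film on this date
        mim <- runif(length(idx)) < mimic_p[idx]
        ndvi[idx][!mim] <- phenology_ndvi(doy, f$phenology)
      }
    }
    ndvi <- clamp(ndvi + rnorm(nr * nc, 0, 1) * noise_sd, -0.2, 0.98)

    # Reflectance pair consistent with the target NDVI: nir + red = brightness.
    nir <- clamp(brightness * (1 + ndvi) / 2 + rnorm(nr * nc, 0, 0.01), 0, 1)
    red <- clamp(brightness * (1 - ndvi) / 2 + rnorm(nr * nc, 0, 0.01), 0, 1)
    green <- clamp(0.9 * (nir + red) / 2 + rnorm(nr * nc, 0, 0.01), 0, 1)
    blue <- clamp(0.75 * green + rnorm(nr * nc, 0, 0.01), 0, 1)

    if (doy %in% config$clear_doys) {
      frac <- 0
    } else {
      frac <- runif(1, max(0, config$cloud_fraction_mean - 0.25),
                    min(1, config$cloud_fraction_mean + 0.25))
    }
    if (frac > 0) {
      fld <- smooth_noise_field(nr, nc, 6)
      thr <- quantile(fld, 1 - frac, names = FALSE)
      cloudy <- fld >= thr
    } else {
      cloudy <- matrix(FALSE, nr, nc)
    }
    cloud_prob <- matrix(clamp(rnorm(nr * nc, 5, 3), 0, 100), nr, nc)
    cloud_prob[cloudy] <- clamp(rnorm(sum(cloudy), 92, 4), 0, 100)
    # clouds are bright in all optical bands
    for (b in c("blue", "green", "red", "nir")) {
      m <- get(b)
      m[cloudy] <- clamp(rnorm(sum(cloudy), 0.85, 0.05), 0, 1)
      assign(b, m)
    }
    optical[[t]] <- optical_acquisition(doy, blue, green, red, nir, cloud_prob)
  }

  # --- radar series ----------------------------------------------------------
  radar <- vector("list", length(radar_doys))
  for (t in seq_along(radar_doys)) {
    doy <- radar_doys[t]
    vh <- matrix(phenology_vh(doy, background), nr, nc)
    for (k in seq_along(config$field_layout)) {
      f <- config$field_layout[[k]]
      idx <- which(field_id_map == k)
      vh[idx] <- simulated_vh(doy, f)
    }
    vv <- vh + 7  # typical co-pol offset over agricultural surfaces
    looks <- config$speckle_looks
    vh <- 10 * log10(10^(vh / 10) * rgamma(nr * nc, shape = looks, rate = looks))
    vv <- 10 * log10(10^(vv / 10) * rgamma(nr * nc, shape = looks, rate = looks))
    orbit <- if (t %% 2 == 0) "descending" else "ascending"
    radar[[t]] <- radar_acquisition(doy, matrix(vv, nr, nc), matrix(vh, nr, nc),
                                    orbit)
  }

  fields <- purrr::imap_dfr(config$field_layout, function(f, k) {
    tibble::tibble(
      id = f$id %||% sprintf("F%03d", k),
      truth_class = f$truth_class,
      row_min = f$rows[1], row_max = f$rows[2],
      col_min = f$cols[1], col_max = f$cols[2],
      centroid_row = floor((f$rows[1] + f$rows[2]) / 2),
      centroid_col = floor((f$cols[1] + f$cols[2]) / 2),
      area_ha = diff(f$rows + c(0, 1)) * diff(f$cols + c(0, 1)) * ps^2 / 1e4,
      film_type = f$film_type, permanence = f$permanence,
      cover_start = if (is.null(f$cover_window)) NA_real_ else f$cover_window[1],
      cover_end = if (is.null(f$cover_window)) NA_real_ else f$cover_window[2],
      confounder = f$confounder, role = f$role
    )
  })

  list(optical = optical, radar = radar,
       truth = class_map(truth, pixel_size = ps),
       fields = fields)
}
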