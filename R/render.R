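# Rendering of synthetic sensor data: LiDAR-like point clouds, an RGB
# orthophoto and a 15-band hyperspectral reflectance raster. Rendering is a
# pure function of (trial, flight_gdd, seed).

# Wavelengths (nm) needed by all supported vegetation indices.
HYPERSPECTRAL_WAVELENGTHS <- c(420, 445, 500, 531, 550, 570, 670, 680, 695,
                               700, 705, 720, 740, 750, 800)

# Fixed endmember spectra; per-pixel reflectance is a linear mixture of the
# two, with the vegetation NIR plateau scaled by local vigor.
SOIL_SPECTRUM <- c(0.120, 0.130, 0.150, 0.160, 0.170, 0.180, 0.220, 0.222,
                   0.228, 0.230, 0.232, 0.238, 0.246, 0.250, 0.270)
VEG_SPECTRUM <- c(0.030, 0.030, 0.040, 0.060, 0.090, 0.070, 0.035, 0.035,
                  0.060, 0.080, 0.120, 0.220, 0.360, 0.420, 0.480)

SOIL_RGB <- c(0.45, 0.36, 0.25) # hue ~33 deg: outside the vegetation hue band
VEG_RGB <- c(0.15, 0.45, 0.12)  # hue ~115 deg

field_extent <- function(trial, margin = 0.5) {
  cfg <- trial$config
  n_ranges <- max(trial$plots$range)
  n_cols <- max(trial$plots$col)
  c(
    xmin = -margin,
    xmax = (n_ranges - 1) * (cfg$row_length_m + cfg$alley_m) +
      cfg$row_length_m + margin,
    ymin = -margin,
    ymax = n_cols * cfg$rows_per_plot * cfg$row_spacing_m + margin
  )
}

clip_plants <- function(trial, extent) {
  p <- trial$plants
  if (is.null(extent)) return(p)
  p[p$x >= extent["xmin"] & p$x <= extent["xmax"] &
      p$y >= extent["ymin"] & p$y <= extent["ymax"], , drop = FALSE]
}

#' Render a synthetic LiDAR-like point cloud for one flight
#'
#' Emits ground returns on a regular grid (z near 0 with small noise) and
#' canopy returns around every plant. Plant height is
#' `canopy_max_height_m * growth_fraction(flight_gdd) * vigor` and the number
#' of canopy returns per plant grows with the same growth fraction and with
#' the plant's vigor (bigger canopies intercept more returns), so both height
#' and point density increase with thermal time. Canopy points are
#' confined laterally to the plant's row strip. Every point carries a truth
#' label (`ground` / `canopy`) plus its plot and row of origin, so ground
#' classification can be tested against truth.
#'
#' @param trial a [simulate_trial()] result.
#' @param flight_gdd cumulative GDD of the flight, `>= 0`.
#' @param extent optional named vector `c(xmin, xmax, ymin, ymax)` to render
#'   only part of the field (default: whole field plus a 0.5 m margin).
#' @param points_per_plant canopy returns per plant at full growth.
#' @param ground_spacing_m ground-return grid spacing, meters.
#' @param seed integer seed (default derived from the trial seed).
#' @return Data frame with columns `x`, `y`, `z`, `label`, `plot_id`,
#'   `row_index` (`NA` for ground returns).
#' @export
render_point_cloud <- function(trial, flight_gdd, extent = NULL,
                               points_per_plant = 60,
                               ground_spacing_m = 0.15,
                               seed = trial$config$rng_seed) {
  stopifnot(inherits(trial, "field_trial"))
  if (!is.numeric(flight_gdd) || length(flight_gdd) != 1 || flight_gdd < 0) {
    stop("flight_gdd must be a single number >= 0", call. = FALSE)
  }
  cfg <- trial$config
  if (is.null(extent)) extent <- field_extent(trial)
  g <- growth_fraction(flight_gdd)

  with_seed(derive_seed(seed, paste0("cloud:", flight_gdd)), {
    gx <- seq(extent["xmin"], extent["xmax"], by = ground_spacing_m)
    gy <- seq(extent["ymin"], extent["ymax"], by = ground_spacing_m)
    ground <- data.frame(
      x = rep(gx, times = length(gy)),
      y = rep(gy, each = length(gx)),
      z = stats::rnorm(length(gx) * length(gy), 0, 0.005),
      label = "ground",
      plot_id = NA_character_,
      row_index = NA_integer_,
      stringsAsFactors = FALSE
    )

    plants <- clip_plants(trial, extent)
    n_pts <- round(points_per_plant * g * pmax(0, plants$vigor))
    if (nrow(plants) > 0 && sum(n_pts) > 0) {
      h <- pmax(0, cfg$canopy_max_height_m * g * plants$vigor)
      total <- sum(n_pts)
      px <- rep(plants$x, n_pts) + stats::rnorm(total, 0, 0.06)
      py <- rep(plants$y, n_pts) + stats::rnorm(total, 0, 0.06)
      # confine to the row's lateral strip
      pidx <- match(rep(plants$plot_id, n_pts), trial$plots$plot_id)
      row_c <- trial$plots$y0[pidx] +
        (rep(plants$row_index, n_pts) - 0.5) * cfg$row_spacing_m
      half <- cfg$row_spacing_m / 2 - 1e-6
      py <- pmin(pmax(py, row_c - half), row_c + half)
      # z ~ h * sqrt(U): top-weighted so the 95th percentile tracks h
      pz <- rep(h, n_pts) * sqrt(stats::runif(total))
      canopy <- data.frame(
        x = px, y = py, z = pz, label = "canopy",
        plot_id = rep(plants$plot_id, n_pts),
        row_index = rep(plants$row_index, n_pts),
        stringsAsFactors = FALSE
      )
      rbind(ground, canopy)
    } else {
      ground
    }
  })
}

#' A simple in-memory georeferenced raster
#'
#' Row `i` of `values` spans `y` in `[ymin + (i-1)*res, ymin + i*res)` and
#' column `j` spans `x` in `[xmin + (j-1)*res, xmin + j*res)`; pixel centers
#' are used for box membership.
#'
#' @param values numeric array `[ny, nx, nbands]`.
#' @param res pixel size, meters.
#' @param xmin,ymin field coordinates of the raster's lower-left corner.
#' @param bands band labels: `c("R","G","B")` or numeric wavelengths in nm.
#' @return An object of class `field_raster`.
#' @export
field_raster <- function(values, res, xmin, ymin, bands) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(bands))
  structure(list(values = values, res = res, xmin = xmin, ymin = ymin,
                 bands = bands),
            class = "field_raster")
}

#' @export
print.field_raster <- function(x, ...) {
  cat(sprintf("<field_raster> %d x %d px, %d band(s), res %.3f m, origin (%.2f, %.2f)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$res, x$xmin, x$ymin))
  invisible(x)
}

# pixel-center coordinate vectors
raster_x <- function(r) r$xmin + (seq_len(dim(r$values)[2]) - 0.5) * r$res
raster_y <- function(r) r$ymin + (seq_len(dim(r$values)[1]) - 0.5) * r$res

# Paint circular canopy footprints onto a binary cover matrix [ny, nx].
paint_cover <- function(extent, res, cx, cy, radius) {
  nx <- max(1L, ceiling((extent["xmax"] - extent["xmin"]) / res))
  ny <- max(1L, ceiling((extent["ymax"] - extent["ymin"]) / res))
  cover <- matrix(FALSE, ny, nx)
  if (length(cx) == 0) return(cover)
  xs <- extent["xmin"] + (seq_len(nx) - 0.5) * res
  ys <- extent["ymin"] + (seq_len(ny) - 0.5) * res
  for (k in seq_along(cx)) {
    r <- radius[k]
    if (r <= 0) next
    jr <- which(abs(xs - cx[k]) <= r)
    ir <- which(abs(ys - cy[k]) <= r)
    if (!length(jr) || !length(ir)) next
    dx2 <- (xs[jr] - cx[k])^2
    dy2 <- (ys[ir] - cy[k])^2
    hit <- outer(dy2, dx2, "+") <= r^2
    cover[ir, jr] <- cover[ir, jr] | hit
  }
  cover
}

#' Render synthetic RGB and hyperspectral orthophotos for one flight
#'
#' Vegetation is modeled as circular canopy footprints around each plant
#' whose radius grows with [growth_fraction()] and the plant's vigor.
#' RGB pixels covered by canopy take a green color inside the default HSV
#' vegetation thresholds; soil pixels take a brown color outside them.
#' Hyperspectral pixels are a linear mixture of a fixed soil spectrum and a
#' vegetation spectrum whose near-infrared plateau (bands >= 740 nm) is
#' scaled by the local vigor, so the red/NIR (and red-edge) contrast tracks
#' the latent trait mean; bands on or below the red edge are left unscaled so
#' ratio indices against them do not cancel the signal. The 15 bands cover every wavelength used by the supported
#' vegetation indices.
#'
#' @inheritParams render_point_cloud
#' @param rgb_res,hyp_res ground sampling distance, meters (defaults 0.01 and
#'   0.04, the typical UAV RGB and VNIR resolutions).
#' @param max_radius_m canopy footprint radius of a vigor-1 plant at full
#'   growth, meters.
#' @return List with elements `rgb` and `hyperspectral`, both
#'   [field_raster()] objects.
#' @export
render_rasters <- function(trial, flight_gdd, extent = NULL,
                           rgb_res = 0.01, hyp_res = 0.04,
                           max_radius_m = 0.30,
                           seed = trial$config$rng_seed) {
  stopifnot(inherits(trial, "field_trial"))
  if (!is.numeric(flight_gdd) || length(flight_gdd) != 1 || flight_gdd < 0) {
    stop("flight_gdd must be a single number >= 0", call. = FALSE)
  }
  cfg <- trial$config
  if (is.null(extent)) extent <- field_extent(trial)
  g <- growth_fraction(flight_gdd)
  plants <- clip_plants(trial, extent)
  radius <- pmin(0.48 * cfg$row_spacing_m, pmax(0, max_radius_m * g * plants$vigor))

  with_seed(derive_seed(seed, paste0("raster:", flight_gdd)), {
    # --- RGB ---
    cov_rgb <- paint_cover(extent, rgb_res, plants$x, plants$y, radius)
    ny <- nrow(cov_rgb); nx <- ncol(cov_rgb)
    rgb_arr <- array(0, c(ny, nx, 3))
    for (b in 1:3) {
      base <- ifelse(cov_rgb, VEG_RGB[b], SOIL_RGB[b])
      rgb_arr[, , b] <- pmin(1, pmax(0, base + stats::rnorm(ny * nx, 0, 0.015)))
    }
    rgb <- field_raster(rgb_arr, rgb_res, unname(extent["xmin"]),
                        unname(extent["ymin"]), c("R", "G", "B"))

    # --- hyperspectral ---
    cov_h <- paint_cover(extent, hyp_res, plants$x, plants$y, radius)
    nyh <- nrow(cov_h); nxh <- ncol(cov_h)
    # local vigor per hyperspectral pixel: the covering plant's vigor
    # (where footprints overlap, the later-painted plant wins)
    vig <- matrix(1, nyh, nxh)
    if (nrow(plants) > 0) {
      xs <- extent["xmin"] + (seq_len(nxh) - 0.5) * hyp_res
      ys <- extent["ymin"] + (seq_len(nyh) - 0.5) * hyp_res
      for (k in seq_len(nrow(plants))) {
        r <- radius[k]
        if (r <= 0) next
        jr <- which(abs(xs - plants$x[k]) <= r)
        ir <- which(abs(ys - plants$y[k]) <= r)
        if (length(jr) && length(ir)) vig[ir, jr] <- plants$vigor[k]
      }
    }
    nir_scale <- matrix(1, nyh, nxh)
    nir_scale[cov_h] <- pmax(0.5, 0.75 + 0.35 * vig[cov_h])
    nb <- length(HYPERSPECTRAL_WAVELENGTHS)
    hyp_arr <- array(0, c(nyh, nxh, nb))
    for (b in seq_len(nb)) {
      veg_b <- VEG_SPECTRUM[b] *
        if (HYPERSPECTRAL_WAVELENGTHS[b] >= 740) nir_scale else 1
      base <- ifelse(cov_h, veg_b, SOIL_SPECTRUM[b])
      hyp_arr[, , b] <- pmin(1, pmax(0, base + stats::rnorm(nyh * nxh, 0, 0.004)))
    }
    hyp <- field_raster(hyp_arr, hyp_res, unname(extent["xmin"]),
                        unname(extent["ymin"]), HYPERSPECTRAL_WAVELENGTHS)

    list(rgb = rgb, hyperspectral = hyp)
  })
}
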