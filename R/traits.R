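# Trait extraction from point clouds and rasters over row-segment boxes.
# All traits pool points/pixels across the supplied boxes (not averages of
# per-row values); boxes are half-open [min, max).

in_box <- function(x, y, b) {
  x >= b$x_min & x < b$x_max & y >= b$y_min & y < b$y_max
}

points_in_boxes <- function(points, boxes) {
  boxes <- boxes[!boxes$missing, , drop = FALSE]
  keep <- rep(FALSE, nrow(points))
  for (i in seq_len(nrow(boxes))) {
    keep <- keep | in_box(points$x, points$y, boxes[i, ])
  }
  keep
}

# logical matrix [ny, nx]: pixel centers inside any box
pixels_in_boxes <- function(raster, boxes) {
  xs <- raster_x(raster)
  ys <- raster_y(raster)
  boxes <- boxes[!boxes$missing, , drop = FALSE]
  m <- matrix(FALSE, length(ys), length(xs))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    jr <- which(xs >= b$x_min & xs < b$x_max)
    ir <- which(ys >= b$y_min & ys < b$y_max)
    if (length(jr) && length(ir)) m[ir, jr] <- TRUE
  }
  m
}

#' Canopy cover from an RGB orthophoto (HSV thresholding)
#'
#' Classifies pixels inside the boxes as vegetation when their HSV
#' coordinates fall strictly inside the vegetation thresholds (defaults: hue
#' in (60, 180) degrees, saturation > 0.15, value > 0.10; ties count as
#' non-vegetation) and returns the vegetation fraction pooled over all
#' supplied boxes.
#'
#' @param raster an RGB [field_raster()] (bands `R`, `G`, `B` in `[0, 1]`).
#' @param boxes row-segment boxes.
#' @param hsv_thresholds list with `hue_deg` (length-2), `s_min`, `v_min`.
#' @return Vegetation fraction in `[0, 1]`.
#' @export
canopy_cover_rgb <- function(raster, boxes,
                             hsv_thresholds = list(hue_deg = c(60, 180),
                                                   s_min = 0.15,
                                                   v_min = 0.10)) {
  stopifnot(inherits(raster, "field_raster"), dim(raster$values)[3] == 3)
  sel <- pixels_in_boxes(raster, boxes)
  n <- sum(sel)
  if (n == 0) stop("no pixels fall inside the supplied boxes", call. = FALSE)
  rgb <- rbind(raster$values[, , 1][sel],
               raster$values[, , 2][sel],
               raster$values[, , 3][sel])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  veg <- hue > hsv_thresholds$hue_deg[1] & hue < hsv_thresholds$hue_deg[2] &
    hsv[2, ] > hsv_thresholds$s_min & hsv[3, ] > hsv_thresholds$v_min
  sum(veg) / n
}

#' Classify point-cloud returns as ground or nonground
#'
#' Estimates the local ground elevation as the minimum `z` within square
#' cells of `cell_m` and labels points within `h0` above that minimum as
#' ground. Synthetic clouds carrying truth labels can bypass this by using
#' their `label` column directly.
#'
#' @param points data frame with `x`, `y`, `z`.
#' @param cell_m ground-estimation cell size, meters.
#' @param h0 height threshold above the local minimum, meters.
#' @return Character vector, `"ground"` or `"nonground"`, one per point.
#' @export
classify_ground <- function(points, cell_m = 0.5, h0 = 0.10) {
  if (nrow(points) == 0) return(character(0))
  cx <- floor((points$x - min(points$x)) / cell_m)
  cy <- floor((points$y - min(points$y)) / cell_m)
  cell <- paste(cx, cy)
  zmin <- stats::ave(points$z, cell, FUN = min)
  ifelse(points$z < zmin + h0, "ground", "nonground")
}

# nonground mask from either truth labels or the classifier
nonground_mask <- function(points, use_labels = TRUE, ...) {
  if (use_labels && "label" %in% names(points)) {
    points$label != "ground"
  } else {
    classify_ground(points, ...) == "nonground"
  }
}

#' LiDAR canopy cover (CC10)
#'
#' Computes the height threshold as the 10th percentile (linear
#' interpolation) of the nonground returns inside the boxes and returns the
#' fraction of all returns (ground + nonground) strictly above it. Setting
#' `percentile_population = "all"` instead takes the percentile over every
#' return, the alternative reading of the statistic.
#'
#' @param points point cloud with `x`, `y`, `z` and optionally a truth
#'   `label` column.
#' @param boxes row-segment boxes; points are pooled across them.
#' @param probs percentile defining the threshold (default 0.10).
#' @param percentile_population `"nonground"` (default) or `"all"`.
#' @param use_labels use the `label` column when present instead of
#'   [classify_ground()].
#' @return Fraction in `[0, 1]`, or `NA` (flagged missing) when the boxes
#'   contain no nonground return.
#' @export
canopy_cover_lidar <- function(points, boxes, probs = 0.10,
                               percentile_population = c("nonground", "all"),
                               use_labels = TRUE) {
  percentile_population <- match.arg(percentile_population)
  keep <- points_in_boxes(points, boxes)
  if (!any(keep)) stop("no points fall inside the supplied boxes", call. = FALSE)
  pts <- points[keep, , drop = FALSE]
  ng <- nonground_mask(pts, use_labels)
  if (!any(ng)) return(NA_real_)
  pop <- if (percentile_population == "nonground") pts$z[ng] else pts$z
  z_star <- pctl(pop, probs)
  sum(pts$z > z_star) / nrow(pts)
}

#' 95th-percentile canopy height
#'
#' Linear-interpolation percentile of the nonground return heights pooled
#' over the boxes. Ground returns never enter the computation.
#'
#' @inheritParams canopy_cover_lidar
#' @param probs percentile (default 0.95).
#' @return Height in meters, or `NA` when no nonground return is inside.
#' @export
height_p95 <- function(points, boxes, probs = 0.95, use_labels = TRUE) {
  keep <- points_in_boxes(points, boxes)
  if (!any(keep)) stop("no points fall inside the supplied boxes", call. = FALSE)
  pts <- points[keep, , drop = FALSE]
  ng <- nonground_mask(pts, use_labels)
  if (!any(ng)) return(NA_real_)
  pctl(pts$z[ng], probs)
}

#' Canopy volume from gridded point heights
#'
#' Tiles each box with `cell_m` x `cell_m` cells (edge cells clipped to the
#' box); every cell holding at least one nonground return contributes
#' `cell area x (p95(z) + min(z)) / 2` using the nonground heights in that
#' cell; empty cells contribute zero. The result is summed over cells and
#' boxes.
#'
#' @inheritParams canopy_cover_lidar
#' @param cell_m grid cell size, meters (default 0.08).
#' @return Volume in cubic meters (0 for empty boxes).
#' @export
plot_volume <- function(points, boxes, cell_m = 0.08, use_labels = TRUE) {
  boxes <- boxes[!boxes$missing, , drop = FALSE]
  total <- 0
  ng_all <- nonground_mask(points, use_labels)
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    keep <- in_box(points$x, points$y, b) & ng_all
    if (!any(keep)) next
    px <- points$x[keep]; py <- points$y[keep]; pz <- points$z[keep]
    nx <- ceiling((b$x_max - b$x_min) / cell_m - 1e-9)
    ny <- ceiling((b$y_max - b$y_min) / cell_m - 1e-9)
    ix <- pmin(floor((px - b$x_min) / cell_m), nx - 1)
    iy <- pmin(floor((py - b$y_min) / cell_m), ny - 1)
    cell <- ix * ny + iy
    groups <- split(pz, cell)
    ids <- as.numeric(names(groups))
    h <- vapply(groups, function(z) (pctl(z, 0.95) + min(z)) / 2, numeric(1))
    # clipped cell area at the box edges
    cw <- pmin(cell_m, b$x_max - b$x_min - (ids %/% ny) * cell_m)
    ch <- pmin(cell_m, b$y_max - b$y_min - (ids %% ny) * cell_m)
    total <- total + sum(h * cw * ch)
  }
  total
}

# reflectance matrix for the band nearest to `wavelength_nm` (within tol_nm)
band_reflectance <- function(raster, wavelength_nm, tol_nm = 3) {
  stopifnot(is.numeric(raster$bands))
  d <- abs(raster$bands - wavelength_nm)
  b <- which.min(d)
  if (d[b] > tol_nm) {
    stop(sprintf("no band within %g nm of %g nm", tol_nm, wavelength_nm),
         call. = FALSE)
  }
  raster$values[, , b]
}

# index name -> required wavelengths and per-pixel formula
index_registry <- function() {
  list(
    Carte1   = list(wl = c(695, 420),
                    fun = function(r) r[["695"]] / r[["420"]]),
    GNDVI    = list(wl = c(750, 550),
                    fun = function(r) (r[["750"]] - r[["550"]]) / (r[["750"]] + r[["550"]])),
    mRENDVI  = list(wl = c(750, 705, 445),
                    fun = function(r) (r[["750"]] - r[["705"]]) /
                      (r[["750"]] + r[["705"]] - 2 * r[["445"]])),
    NDVI     = list(wl = c(750, 705),
                    fun = function(r) (r[["750"]] - r[["705"]]) / (r[["750"]] + r[["705"]])),
    OSAVI    = list(wl = c(800, 670),
                    fun = function(r) 1.16 * (r[["800"]] - r[["670"]]) /
                      (r[["800"]] + r[["670"]] + 0.16)),
    PRI      = list(wl = c(531, 570),
                    fun = function(r) (r[["531"]] - r[["570"]]) / (r[["531"]] + r[["570"]])),
    PSRI     = list(wl = c(680, 500, 750),
                    fun = function(r) (r[["680"]] - r[["500"]]) / r[["750"]]),
    SR800680 = list(wl = c(800, 680),
                    fun = function(r) r[["800"]] / r[["680"]]),
    SR700670 = list(wl = c(700, 670),
                    fun = function(r) r[["700"]] / r[["670"]]),
    VOG1     = list(wl = c(740, 720),
                    fun = function(r) r[["740"]] / r[["720"]])
  )
}

#' Supported hyperspectral vegetation indices
#' @return Character vector of index names.
#' @export
vegetation_index_names <- function() names(index_registry())

index_image <- function(raster, index_name) {
  reg <- index_registry()[[index_name]]
  if (is.null(reg)) {
    stop(sprintf("unknown vegetation index '%s'", index_name), call. = FALSE)
  }
  r <- lapply(reg$wl, function(w) band_reflectance(raster, w))
  names(r) <- as.character(reg$wl)
  reg$fun(r)
}

#' Vegetation mask for a hyperspectral raster
#'
#' Pixels whose vegetation index exceeds the threshold (strictly) are kept as
#' vegetation; everything else — soil in particular — is masked out.
#'
#' @param raster hyperspectral [field_raster()] with numeric wavelengths.
#' @param index_name masking index (default `"NDVI"`).
#' @param threshold mask threshold (default 0.5).
#' @return Logical matrix `[ny, nx]`, `TRUE` for vegetation.
#' @export
mask_ground_hyperspectral <- function(raster, index_name = "NDVI",
                                      threshold = 0.5) {
  img <- index_image(raster, index_name)
  is.finite(img) & img > threshold
}

#' Mean vegetation index over the vegetation pixels of row-segment boxes
#'
#' Computes the index per pixel (bands located by nearest-wavelength lookup
#' within 3 nm) over pixels that are inside the boxes and inside the
#' vegetation mask, then averages. Pixels with non-finite values (division by
#' zero) are excluded with a message.
#'
#' @param raster hyperspectral [field_raster()].
#' @param boxes row-segment boxes.
#' @param index_name one of [vegetation_index_names()].
#' @param mask optional precomputed logical mask (from
#'   [mask_ground_hyperspectral()]); computed with defaults when `NULL`.
#' @return Mean index value, or `NA` (flagged missing) when no vegetation
#'   pixel lies inside the boxes.
#' @export
vegetation_index <- function(raster, boxes, index_name, mask = NULL) {
  if (is.null(mask)) mask <- mask_ground_hyperspectral(raster)
  sel <- pixels_in_boxes(raster, boxes) & mask
  if (!any(sel)) return(NA_real_)
  img <- index_image(raster, index_name)
  vals <- img[sel]
  bad <- !is.finite(vals)
  if (any(bad)) {
    message(sprintf("%s: excluded %d pixel(s) with undefined value",
                    index_name, sum(bad)))
    vals <- vals[!bad]
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Extract all traits for every (plot, selection, trim) combination
#'
#' Drives the per-trait extractors over a grid of row selections and
#' trimming variants, pooling points/pixels across each selection's member
#' boxes. Supply whichever sensor products are available; traits whose
#' sensor is absent are skipped.
#'
#' @param boxes untrimmed row-segment boxes from [build_grid()].
#' @param cloud optional point cloud (for `CC10`, `Height95`, `PlotVolume`).
#' @param rgb optional RGB [field_raster()] (for `CC`).
#' @param hyperspectral optional hyperspectral [field_raster()] (for the
#'   vegetation indices in `indices`).
#' @param flight_id,gdd flight identifier and thermal time stamped on every
#'   observation.
#' @param selections row-selection names to evaluate.
#' @param trims logical vector of trim variants.
#' @param trim_m trim length per end, meters.
#' @param indices vegetation indices to compute (default `"NDVI"`).
#' @param use_labels use truth labels for ground classification when present.
#' @return Long data frame `(plot_id, selection, trimmed, flight_id, gdd,
#'   trait, value)`.
#' @export
extract_traits <- function(boxes, cloud = NULL, rgb = NULL,
                           hyperspectral = NULL,
                           flight_id = "F01", gdd = NA_real_,
                           selections = names(row_selections()),
                           trims = c(FALSE, TRUE), trim_m = 0.40,
                           indices = "NDVI", use_labels = TRUE) {
  plot_ids <- unique(boxes$plot_id)
  variants <- list(`FALSE` = boxes)
  if (any(trims)) variants$`TRUE` <- trim_box(boxes, trim_m)
  hyp_mask <- if (!is.null(hyperspectral)) {
    mask_ground_hyperspectral(hyperspectral)
  }
  rows <- list()
  add <- function(plot, sel, tm, trait, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      plot_id = plot, selection = sel, trimmed = tm,
      flight_id = flight_id, gdd = gdd, trait = trait, value = value,
      stringsAsFactors = FALSE)
  }
  for (tm in trims) {
    bx <- variants[[as.character(tm)]]
    for (plot in plot_ids) {
      for (sel in selections) {
        member <- select_rows(bx, plot, sel)
        if (!is.null(rgb)) {
          add(plot, sel, tm, "CC", canopy_cover_rgb(rgb, member))
        }
        if (!is.null(cloud)) {
          add(plot, sel, tm, "CC10",
              canopy_cover_lidar(cloud, member, use_labels = use_labels))
          add(plot, sel, tm, "Height95",
              height_p95(cloud, member, use_labels = use_labels))
          add(plot, sel, tm, "PlotVolume",
              plot_volume(cloud, member, use_labels = use_labels))
        }
        if (!is.null(hyperspectral)) {
          for (ix in indices) {
            add(plot, sel, tm, ix,
                vegetation_index(hyperspectral, member, ix, mask = hyp_mask))
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
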