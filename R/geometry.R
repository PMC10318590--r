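#' Row-selection schemes
#'
#' The seven row-wise subsets of a four-row plot used throughout the
#' analysis: all rows (`RS1234`), the inner rows (`RS23`), the outer rows
#' (`RS14`), and each individual row (`RS1`-`RS4`).
#'
#' @return Named list mapping selection name to member row indices.
#' @export
#' @examples
#' row_selections()$RS23
row_selections <- function() {
  list(RS1234 = 1:4, RS23 = 2:3, RS14 = c(1L, 4L),
       RS1 = 1L, RS2 = 2L, RS3 = 3L, RS4 = 4L)
}

new_boxes <- function(plot_id, row_index, x_min, x_max, y_min, y_max,
                      trimmed = FALSE, missing = FALSE) {
  data.frame(plot_id = plot_id, row_index = as.integer(row_index),
             x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
             trimmed = trimmed, missing = missing, stringsAsFactors = FALSE)
}

#' Build the grid of row-segment bounding boxes from plant positions
#'
#' One axis-aligned box per (plot, row): the lateral extent is the full row
#' spacing centered on the row line, and the longitudinal extent runs from
#' the proximal-most to the terminal-most plant of the row segment, so boxes
#' differ in length with emergence. Rows must run parallel to the `x` axis.
#' Boxes are half-open intervals `[min, max)` for point/pixel membership, so
#' adjacent boxes never double-count. A row segment with fewer than two
#' plants cannot define a box and is flagged missing (with a message), not an
#' error; flagged rows are excluded downstream.
#'
#' The grid is intended to be built once from an early-season snapshot and
#' reused for every later flight; canopy material outside the early boxes is
#' then excluded from trait extraction.
#'
#' @param plants data frame with columns `plot_id`, `row_index`, `x`, `y`
#'   (one row per plant), e.g. `simulate_trial(...)$plants`.
#' @param row_spacing_m lateral box width, meters.
#' @return Data frame of boxes with columns `plot_id`, `row_index`, `x_min`,
#'   `x_max`, `y_min`, `y_max`, `trimmed`, `missing`.
#' @export
build_grid <- function(plants, row_spacing_m = 0.76) {
  req <- c("plot_id", "row_index", "x", "y")
  if (!all(req %in% names(plants))) {
    stop("plants must have columns plot_id, row_index, x, y", call. = FALSE)
  }
  key <- interaction(plants$plot_id, plants$row_index, drop = TRUE)
  groups <- split(plants, key)
  half <- row_spacing_m / 2
  out <- lapply(groups, function(gr) {
    if (nrow(gr) < 2) {
      message(sprintf("row segment %s row %d has < 2 plants; flagged missing",
                      gr$plot_id[1], gr$row_index[1]))
      return(new_boxes(gr$plot_id[1], gr$row_index[1],
                       NA_real_, NA_real_, NA_real_, NA_real_,
                       missing = TRUE))
    }
    yc <- mean(gr$y)
    new_boxes(gr$plot_id[1], gr$row_index[1],
              min(gr$x), max(gr$x), yc - half, yc + half)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$plot_id, out$row_index), , drop = FALSE]
  rownames(out) <- NULL
  # lateral jitter in plant positions can make adjacent rows' nominal strips
  # overlap by a few millimeters; clip shared boundaries to the midpoint so
  # boxes within a plot never overlap (and never double-count points)
  for (p in unique(out$plot_id)) {
    idx <- which(out$plot_id == p & !out$missing)
    idx <- idx[order(out$y_min[idx])]
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]; b <- idx[k + 1]
      if (out$y_max[a] > out$y_min[b]) {
        mid <- (out$y_max[a] + out$y_min[b]) / 2
        out$y_max[a] <- mid
        out$y_min[b] <- mid
      }
    }
  }
  out
}

#' Trim a fixed length from both ends of row-segment boxes
#'
#' Shrinks the longitudinal extent of each box by `trim_m` at each end (40 cm
#' by default); the lateral extent is unchanged and the `trimmed` flag is set
#' even when `trim_m = 0`. Flagged-missing boxes pass through unchanged.
#'
#' @param boxes data frame from [build_grid()].
#' @param trim_m length removed from each end, meters.
#' @param min_length_m smallest admissible trimmed length; shorter results
#'   are an error naming the plot.
#' @return The boxes with updated `x_min`, `x_max`, `trimmed`.
#' @export
trim_box <- function(boxes, trim_m = 0.40, min_length_m = 0.5) {
  if (trim_m < 0) stop("trim_m must be >= 0", call. = FALSE)
  ok <- !boxes$missing
  new_len <- boxes$x_max[ok] - boxes$x_min[ok] - 2 * trim_m
  if (any(new_len < min_length_m)) {
    bad <- boxes[ok, ][which(new_len < min_length_m)[1], ]
    stop(sprintf(
      "trimming %.2f m per end leaves plot %s row %d below the %.2f m minimum",
      trim_m, bad$plot_id, bad$row_index, min_length_m), call. = FALSE)
  }
  boxes$x_min[ok] <- boxes$x_min[ok] + trim_m
  boxes$x_max[ok] <- boxes$x_max[ok] - trim_m
  boxes$trimmed <- TRUE
  boxes
}

#' Resolve a row selection to its member boxes for one plot
#'
#' @param boxes data frame from [build_grid()] (optionally trimmed).
#' @param plot_id plot identifier.
#' @param selection selection name (see [row_selections()]) or an integer
#'   vector of member rows.
#' @return The member rows' boxes in row-index order.
#' @export
select_rows <- function(boxes, plot_id, selection) {
  rows <- if (is.character(selection)) {
    sel <- row_selections()[[selection]]
    if (is.null(sel)) stop(sprintf("unknown row selection '%s'", selection),
                           call. = FALSE)
    sel
  } else {
    as.integer(selection)
  }
  sub <- boxes[boxes$plot_id == plot_id & boxes$row_index %in% rows, , drop = FALSE]
  found <- sub$row_index[!sub$missing]
  absent <- setdiff(rows, found)
  if (length(absent)) {
    stop(sprintf("plot %s: member row(s) %s missing from grid",
                 plot_id, paste(absent, collapse = ", ")), call. = FALSE)
  }
  sub <- sub[order(sub$row_index), , drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Write row-segment boxes as GeoJSON polygons
#'
#' Each box becomes a `Polygon` feature with `plot_id`, `row_index` and
#' `trimmed` properties; flagged-missing boxes are skipped.
#'
#' @param boxes data frame of boxes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
boxes_to_geojson <- function(boxes, path) {
  keep <- boxes[!boxes$missing, , drop = FALSE]
  features <- lapply(seq_len(nrow(keep)), function(i) {
    b <- keep[i, ]
    ring <- list(
      c(b$x_min, b$y_min), c(b$x_max, b$y_min),
      c(b$x_max, b$y_max), c(b$x_min, b$y_max), c(b$x_min, b$y_min)
    )
    list(
      type = "Feature",
      properties = list(plot_id = b$plot_id, row_index = b$row_index,
                        trimmed = b$trimmed),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read row-segment boxes from GeoJSON
#'
#' @param path a GeoJSON file written by [boxes_to_geojson()] (axis-aligned
#'   rectangle polygons with `plot_id`, `row_index`, `trimmed` properties).
#' @return Data frame of boxes as produced by [build_grid()].
#' @export
geojson_to_boxes <- function(path) {
  fc <- jsonlite::read_json(path)
  out <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    new_boxes(f$properties$plot_id, f$properties$row_index,
              min(xs), max(xs), min(ys), max(ys),
              trimmed = isTRUE(f$properties$trimmed))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
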