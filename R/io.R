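# Plain-text (and optionally TIFF) readers/writers for the pipeline's
# intermediate artifacts, so any stage can be run standalone.

#' Write / read a point cloud as XYZ + label CSV
#'
#' Columns `x`, `y`, `z`, `label` (plus any extra columns such as the truth
#' `plot_id` / `row_index`) in plain CSV.
#'
#' @param points point cloud data frame.
#' @param path file path.
#' @return `path` (write) or the point cloud data frame (read).
#' @export
write_point_cloud <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a raster as per-band TIFF files with a world file
#'
#' Each band is written as `<basename>_band<k>.tif` (values clipped to
#' `[0, 1]`), georeferencing as an ESRI world file `<basename>.wld`, and band
#' labels/wavelengths as `<basename>_bands.csv`. Requires the `tiff`
#' package.
#'
#' @param raster a [field_raster()].
#' @param basename output path prefix (no extension).
#' @return `basename` (write) or a [field_raster()] (read).
#' @export
write_raster <- function(raster, basename) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write rasters", call. = FALSE)
  }
  nb <- dim(raster$values)[3]
  ny <- dim(raster$values)[1]
  for (b in seq_len(nb)) {
    img <- pmin(pmax(raster$values[ny:1, , b], 0), 1) # TIFF rows start at top
    tiff::writeTIFF(img, sprintf("%s_band%02d.tif", basename, b),
                    bits.per.sample = 16L)
  }
  # world file: pixel size, rotations, center of the upper-left pixel
  wld <- c(raster$res, 0, 0, -raster$res,
           raster$xmin + raster$res / 2,
           raster$ymin + (ny - 0.5) * raster$res)
  writeLines(format(wld, digits = 12), paste0(basename, ".wld"))
  utils::write.csv(data.frame(band = seq_len(nb), label = raster$bands),
                   paste0(basename, "_bands.csv"), row.names = FALSE)
  invisible(basename)
}

#' @rdname write_raster
#' @export
read_raster <- function(basename) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read rasters", call. = FALSE)
  }
  bands <- utils::read.csv(paste0(basename, "_bands.csv"),
                           stringsAsFactors = FALSE)
  imgs <- lapply(seq_len(nrow(bands)), function(b) {
    img <- tiff::readTIFF(sprintf("%s_band%02d.tif", basename, b))
    img[nrow(img):1, , drop = FALSE]
  })
  ny <- nrow(imgs[[1]]); nx <- ncol(imgs[[1]])
  arr <- array(unlist(imgs), c(ny, nx, length(imgs)))
  wld <- as.numeric(readLines(paste0(basename, ".wld")))
  res <- wld[1]
  xmin <- wld[5] - res / 2
  ymin <- wld[6] + res / 2 - ny * res
  lab <- bands$label
  if (!anyNA(suppressWarnings(as.numeric(lab)))) lab <- as.numeric(lab)
  field_raster(arr, res, xmin, ymin, lab)
}

#' Write / read a pipeline run configuration as YAML
#'
#' The configuration round-trips losslessly: reading a written file
#' reconstructs an identical [run_config()].
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path` (write) or a [run_config()] (read).
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$trial <- do.call(trial_config, raw$trial)
  do.call(run_config, raw)
}
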