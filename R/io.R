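# File-format adapters: multi-page 16-bit TIFF fields with a JSON channel
# sidecar, label-mask TIFFs, and CSV tables (UTF-8, comma, header, '.'
# decimal).

TIFF_MAX <- 65535

#' Write rendered fields to TIFF + JSON sidecar
#'
#' Each field becomes one multi-page 16-bit TIFF (one page per channel,
#' values in ADU, clamped to the 16-bit range) plus `field_<i>.json` naming
#' the channels and pixel size; label masks (if given) are written as
#' single-page 16-bit TIFFs; ground truth as CSV.
#'
#' @param scene A `scene` from [simulate_scene()], or a list with `fields`,
#'   and optionally `masks` and `cells`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of TIFF paths written.
#' @export
write_fields <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fields <- scene$fields
  paths <- character(length(fields))
  for (i in seq_along(fields)) {
    fld <- fields[[i]]
    stack <- lapply(fld$channels, function(m)
      pmin(pmax(round(m), 0), TIFF_MAX) / TIFF_MAX)
    path <- file.path(dir, sprintf("field_%03d.tif", i))
    tiff::writeTIFF(unname(stack), path, bits.per.sample = 16)
    sidecar <- list(channels = names(fld$channels),
                    pixel_size_um = fld$pixel_size, field_id = fld$field_id,
                    seed = scene$seed)
    if (!is.null(scene$scene)) sidecar$scene <- unclass(scene$scene)
    jsonlite::write_json(sidecar, sub("\\.tif$", ".json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(scene$masks))
      tiff::writeTIFF(scene$masks[[i]] / TIFF_MAX,
                      file.path(dir, sprintf("mask_%03d.tif", i)),
                      bits.per.sample = 16)
    paths[i] <- path
  }
  if (!is.null(scene$cells))
    write_table(scene$cells, file.path(dir, "ground_truth.csv"))
  invisible(paths)
}

#' Read TIFF fields written with a JSON channel sidecar
#'
#' @param dir Directory containing `field_*.tif` + `field_*.json` pairs
#'   (any multi-page TIFF with a sidecar listing `channels` works).
#' @return List of `field_image` objects, intensities in ADU.
#' @export
read_fields <- function(dir) {
  tifs <- sort(list.files(dir, pattern = "^field_.*\\.tif$",
                          full.names = TRUE))
  if (!length(tifs)) stop("no field TIFFs in ", dir, call. = FALSE)
  lapply(tifs, function(path) {
    meta <- jsonlite::read_json(sub("\\.tif$", ".json", path),
                                simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != length(meta$channels))
      stop("page/channel count mismatch in ", path, call. = FALSE)
    channels <- lapply(pages, function(p) p * TIFF_MAX)
    names(channels) <- meta$channels
    field_image(channels, pixel_size = meta$pixel_size_um,
                field_id = meta$field_id)
  })
}

#' Write a table as CSV
#'
#' UTF-8, comma separator, header row, `.` decimal mark, no row names.
#' @param table Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
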