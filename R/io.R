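# Readers and writers for the pipeline's standard formats: multi-page
# TIFF volumes with a JSON geometry sidecar, float TIFF en-face images,
# and full-precision CSV study tables. All round-trips are lossless at the
# declared precision and every artifact records the seed that produced it.

#' Write / read an OCT volume as multi-page TIFF + JSON sidecar
#'
#' Pages are B-scans `[depth, fast]` ordered repeat-major: all slow-axis
#' locations of repeat 1, then repeat 2, and so on. Pixels are stored as
#' 32-bit floats normalized by the volume maximum, which is recorded in
#' the sidecar (`<path>.json`) together with the grid dimensions, the
#' per-axis spacing and the provenance seed. Reading without the sidecar
#' is an error: spacing is never silently defaulted.
#'
#' @param volume an [oct_volume()].
#' @param path TIFF file path; the sidecar goes to `paste0(path, ".json")`.
#' @param seed provenance seed recorded in the sidecar.
#' @return `read_volume` returns an [oct_volume()].
#' @export
write_volume <- function(volume, path, seed = NA) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensity)   # [repeat, slow, depth, fast]
  # normalize by a power of two: dividing by 2^k only changes the float
  # exponent, so integer (and any float32-representable) intensities
  # survive the TIFF round trip bit-exactly
  mx <- max(volume$intensity)
  mx <- if (mx <= 0) 1 else 2^ceiling(log2(mx))
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      pages[[k]] <- matrix(volume$intensity[t, y, , ] / mx, d[3], d[4])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    n_repeats = d[1], n_slow = d[2], n_depth = d[3], n_fast = d[4],
    spacing_um = as.list(volume$spacing),
    intensity_max = mx,
    integer_data = all(volume$intensity == round(volume$intensity)),
    seed = seed, format = "rpcsvoct-volume-v1")
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    stop("missing geometry sidecar '", sc_path,
         "': volumes without explicit spacing are not readable")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  expected <- sc$n_repeats * sc$n_slow
  if (length(pages) != expected)
    stop(sprintf("volume/sidecar mismatch: expected %d pages, found %d",
                 expected, length(pages)))
  if (!all(dim(pages[[1]]) == c(sc$n_depth, sc$n_fast)))
    stop(sprintf("page size mismatch: expected %d x %d, found %s",
                 sc$n_depth, sc$n_fast,
                 paste(dim(pages[[1]]), collapse = " x ")))
  vol <- array(0, c(sc$n_repeats, sc$n_slow, sc$n_depth, sc$n_fast))
  k <- 1L
  for (t in seq_len(sc$n_repeats)) {
    for (y in seq_len(sc$n_slow)) {
      vol[t, y, , ] <- pages[[k]] * sc$intensity_max
      k <- k + 1L
    }
  }
  # integer intensities round-trip exactly: sample quantization errors are
  # far below one count
  if (isTRUE(sc$integer_data)) vol <- round(vol)
  spacing <- unlist(sc$spacing_um)
  oct_volume(vol, spacing = spacing)
}

#' Write / read an en-face image (float TIFF + JSON sidecar, PNG preview)
#'
#' The quantitative image goes to a 32-bit float TIFF normalized by its
#' recorded maximum; a 16-bit PNG preview is written alongside when
#' `png_preview` is `TRUE`.
#'
#' @param enface an [enface_image()].
#' @param path TIFF path; sidecar at `paste0(path, ".json")`.
#' @param seed provenance seed recorded in the sidecar.
#' @param png_preview also write `<path>.png`.
#' @return `read_enface` returns an [enface_image()].
#' @export
write_enface <- function(enface, path, seed = NA, png_preview = FALSE) {
  stopifnot(inherits(enface, "enface_image"))
  mx <- max(enface$pixels)
  mx <- if (mx <= 0) 1 else 2^ceiling(log2(mx))
  tiff::writeTIFF(enface$pixels / mx, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_um = enface$pixel_um, slab = enface$slab,
                            intensity_max = mx, seed = seed,
                            format = "rpcsvoct-enface-v1"),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  if (png_preview)
    png::writePNG(enface$pixels / mx, paste0(path, ".png"))
  invisible(path)
}

#' @rdname write_enface
#' @export
read_enface <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    stop("missing sidecar '", sc_path, "'")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  px <- tiff::readTIFF(path)
  enface_image(px * sc$intensity_max, pixel_um = sc$pixel_um,
               slab = sc$slab %||% "")
}

#' Write / read a study-record table as CSV
#'
#' Numeric columns are written with 15 significant digits so that a
#' write-read round trip preserves values to full double precision for
#' practical purposes; files are byte-stable for identical inputs.
#'
#' @param records study-record data.frame.
#' @param path CSV path.
#' @return `read_records` returns the data.frame.
#' @export
write_records <- function(records, path) {
  out <- records
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]))
      out[[cl]] <- vapply(out[[cl]], function(v)
        if (is.na(v)) "" else format(v, digits = 15), character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num_cols <- intersect(c("icd_um", "density_per_100um", "diameter_um",
                          "rnfl_um", "n_crossings", "seed"), names(df))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  df
}
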