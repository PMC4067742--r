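# File formats: photon counts travel as 16-bit multi-page TIFF with a JSON
# sidecar (<path>.json) for metadata that TIFF cannot carry (channel width,
# bin size, origin); tables travel as CSV.

write_tiff_pages <- function(pages, path) {
  mx <- max(1, max(vapply(pages, max, 0)))
  if (mx > 65535) stopf("counts exceed 16-bit TIFF range")
  tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                  bits.per.sample = 16L)
}

read_tiff_pages <- function(path) {
  pg <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pg)) pg <- list(pg)
  pg
}

sidecar <- function(path) paste0(path, ".json")

#' Write / read a TCSPC decay cube as multi-page TIFF
#'
#' One page per time channel, 16-bit counts; channel width stored in a JSON
#' sidecar.
#'
#' @param cube A `decay_cube`.
#' @param path Output TIFF path.
#' @return `path`, invisibly (writer); a `decay_cube` (reader).
#' @export
write_decay_cube <- function(cube, path) {
  stopifnot(inherits(cube, "decay_cube"))
  pages <- lapply(seq_len(dim(cube)[3L]), function(ch) cube[, , ch])
  write_tiff_pages(pages, path)
  jsonlite::write_json(list(channel_width = attr(cube, "channel_width"),
                            kind = "decay_cube"),
                       sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decay_cube
#' @export
read_decay_cube <- function(path) {
  meta <- jsonlite::read_json(sidecar(path))
  pages <- read_tiff_pages(path)
  cube <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (ch in seq_along(pages)) cube[, , ch] <- pages[[ch]]
  decay_cube(cube, meta$channel_width)
}

#' Write / read a movie stack as multi-page TIFF
#'
#' Frames are rounded to integer counts for 16-bit storage.
#'
#' @param movie A `frame_stack`.
#' @param path TIFF path.
#' @param camera Camera model to attach on read.
#' @return `path` invisibly / a `frame_stack`.
#' @export
write_movie <- function(movie, path) {
  pages <- lapply(seq_len(dim(movie)[3L]), function(f) round(movie[, , f]))
  write_tiff_pages(pages, path)
  cam <- attr(movie, "camera")
  jsonlite::write_json(list(kind = "frame_stack", camera = unclass(cam)),
                       sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path, camera = NULL) {
  pages <- read_tiff_pages(path)
  stack <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]]
  if (is.null(camera) && file.exists(sidecar(path))) {
    meta <- jsonlite::read_json(sidecar(path))
    if (!is.null(meta$camera)) camera <- do.call(camera_model, meta$camera)
  }
  structure(stack, camera = camera, class = "frame_stack")
}

#' Write / read an IRF as two-column CSV (time_ns, amplitude)
#'
#' @param x An `irf`.
#' @param path CSV path.
#' @return `path` invisibly / an `irf`.
#' @export
write_irf_csv <- function(x, path) {
  stopifnot(inherits(x, "irf"))
  t_mid <- (seq_len(x$n_channels) - 0.5) * x$channel_width
  utils::write.csv(data.frame(time_ns = t_mid, amplitude = x$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_irf_csv
#' @export
read_irf_csv <- function(path) {
  df <- utils::read.csv(path)
  irf(df$amplitude, channel_width = df$time_ns[2L] - df$time_ns[1L])
}

#' Write / read a localization table as CSV
#'
#' Columns `frame, x_nm, y_nm, photons, sigma_nm, background, precision_nm`,
#' the common SMLM table convention.
#'
#' @param table A `localization_table`.
#' @param path CSV path.
#' @param pixel_size Pixel size in nm (reader; default from sidecar-free
#'   header comment is not used — pass explicitly or accept NA).
#' @return `path` invisibly / a `localization_table`.
#' @export
write_localizations_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations_csv
#' @export
read_localizations_csv <- function(path, pixel_size = NA_real_) {
  localization_table(utils::read.csv(path), pixel_size = pixel_size)
}

#' Write / read a super-resolution image (16-bit TIFF + JSON metadata)
#'
#' @param sr An `sr_image`.
#' @param path TIFF path.
#' @return `path` invisibly / an `sr_image`.
#' @export
write_sr_image <- function(sr, path) {
  write_tiff_pages(list(unclass(sr)), path)
  jsonlite::write_json(list(kind = "sr_image", bin_size = attr(sr, "bin_size"),
                            origin = attr(sr, "origin")),
                       sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sr_image
#' @export
read_sr_image <- function(path) {
  meta <- jsonlite::read_json(sidecar(path))
  counts <- read_tiff_pages(path)[[1L]]
  structure(counts, bin_size = meta$bin_size,
            origin = unlist(meta$origin), n_rendered = sum(counts),
            class = "sr_image")
}

#' Write / read a kinetic trace as CSV (time_hr, value, sem, kind)
#'
#' @param trace A `kinetic_trace`.
#' @param path CSV path.
#' @return `path` invisibly / a `kinetic_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  if (is.null(df$sem)) df$sem <- NA_real_
  df$kind <- attr(trace, "kind")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  err <- if (all(is.na(df$sem))) NULL else df$sem
  kinetic_trace(df$time_hr, df$value, errors = err, kind = df$kind[1L])
}

#' Write statistics results as CSV
#'
#' @param x A `stat_result` data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a lifetime map (float TIFF in ns + per-pixel CSV)
#'
#' @param map A `lifetime_map`.
#' @param path TIFF path; the CSV lands at `<path>.csv`.
#' @return `path`, invisibly.
#' @export
write_lifetime_map <- function(map, path) {
  z <- map$tau
  z[is.na(z)] <- 0
  tiff::writeTIFF(z / max(z, 1), path, bits.per.sample = 32L)
  utils::write.csv(as.data.frame(map), paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
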