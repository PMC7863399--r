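#' Read and write study input tables
#'
#' Plain-CSV readers and writers for the pipeline's three input tables:
#' GPS relocations (`id, species, timestamp, x, y, error_sd`; ISO-8601
#' timestamps, projected meters), accelerometer summaries
#' (`id, species, interval_start, summed_accel`), and long-format scat records
#' (`id, date, diameter_mm, track_species, item, volume_fraction`).
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @name study_io
NULL

#' @rdname study_io
#' @export
write_gps <- function(x, path) {
  x <- dplyr::mutate(
    x, timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_gps <- function(path) {
  d <- dplyr::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  if (anyNA(d$timestamp)) stop("unparseable timestamps in ", path)
  d
}

#' @rdname study_io
#' @export
write_activity <- function(x, path) {
  x <- dplyr::mutate(
    x,
    interval_start = format(.data$interval_start, "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  )
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_activity <- function(path) {
  d <- dplyr::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  d$interval_start <- as.POSIXct(d$interval_start,
                                 format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(d$interval_start)) stop("unparseable interval starts in ", path)
  d
}

#' @rdname study_io
#' @export
write_scats <- function(x, path) {
  x <- dplyr::mutate(x, date = format(as.Date(.data$date)))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_scats <- function(path) {
  d <- dplyr::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  d$date <- as.Date(d$date)
  d
}

#' Write an occurrence distribution as CSV
#'
#' One row per cell: grid indices, center coordinates, height, and the
#' availability-mask flag.
#'
#' @param od An `occurrence_dist`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_od <- function(od, path) {
  utils::write.csv(tidy(od), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
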