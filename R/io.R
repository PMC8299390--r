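# Format round-tripping: ASCII count matrices (the export format of the
# instrument pipeline), 16-bit TIFF via the tiff package, and JSON
# summaries via jsonlite. All round trips are bit-exact for integer counts.

#' Write / read a plain-text ASCII count matrix
#'
#' Tab-separated numbers, one scan line per row, no header: the plain-text
#' export format for scans and kymographs.
#'
#' @param mat Numeric matrix.
#' @param path File path.
#' @return `write_ascii_matrix` returns `path` invisibly;
#'   `read_ascii_matrix` returns the matrix.
#' @export
write_ascii_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat))
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_matrix
#' @export
read_ascii_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file: ", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (any(ncols != ncols[1]))
    stop("ragged matrix in ", path, ": line ",
         which(ncols != ncols[1])[1], " has ", ncols[ncols != ncols[1]][1],
         " fields, expected ", ncols[1])
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("non-numeric field in ", path, " at line ",
         (bad - 1) %/% ncols[1] + 1, ", field ", (bad - 1) %% ncols[1] + 1)
  }
  matrix(vals, nrow = length(rows), byrow = TRUE)
}

#' Write / read a kymograph with its JSON sidecar
#'
#' The count matrix goes to `path` as ASCII text (or 16-bit TIFF with
#' `format = "tiff"`); line times, pixel positions and the optics echo go
#' to `<path>.json`. Counts round-trip exactly.
#'
#' @param kymo A `kymograph_image`.
#' @param path File path.
#' @param format `"ascii"` or `"tiff"`.
#' @return `write_kymograph` returns `path` invisibly; `read_kymograph`
#'   returns a `kymograph_image`.
#' @export
write_kymograph <- function(kymo, path, format = c("ascii", "tiff")) {
  stopifnot(inherits(kymo, "kymograph_image"))
  format <- match.arg(format)
  if (format == "ascii") {
    write_ascii_matrix(kymo$counts, path)
  } else {
    if (any(kymo$counts < 0) || any(kymo$counts > 65535))
      stop("counts outside the 16-bit range")
    tiff::writeTIFF(kymo$counts / 65535, path, bits.per.sample = 16,
                    compression = "none")
  }
  meta <- list(format = format, line_times_s = kymo$line_times_s,
               pixel_centers_nm = kymo$pixel_centers_nm,
               optics = unclass(kymo$optics))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  counts <- if (identical(meta$format, "tiff")) {
    round(tiff::readTIFF(path) * 65535)
  } else {
    read_ascii_matrix(path)
  }
  structure(list(counts = counts, line_times_s = meta$line_times_s,
                 pixel_centers_nm = meta$pixel_centers_nm,
                 optics = do.call(optics_config, as.list(meta$optics))),
            class = "kymograph_image")
}

#' Write a multi-frame 16-bit TIFF stack of scan frames
#'
#' @param frames List of `scan_image` objects (or count matrices).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scan_stack_tiff <- function(frames, path) {
  mats <- lapply(frames, function(f)
    if (inherits(f, "scan_image")) f$counts else f)
  for (m in mats)
    if (any(m < 0) || any(m > 65535)) stop("counts outside the 16-bit range")
  tiff::writeTIFF(lapply(mats, function(m) m / 65535), path,
                  bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_scan_stack_tiff
#' @export
read_scan_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  lapply(frames, function(m) round(m * 65535))
}
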