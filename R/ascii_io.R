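# ESRI ASCII grid I/O.  The format: a 5-6 line header (ncols, nrows,
# xllcorner, yllcorner, cellsize, optional NODATA_value) followed by a
# whitespace-separated integer body, row 1 = top row.

#' Read an ESRI ASCII grid as a landscape grid
#'
#' @param path path to an \code{.asc} file with an integer body.
#' @param codebook \code{lulc_codebook} used to validate cell values.
#' @return A \code{landscape_grid}; the header's NODATA_value cells become
#'   \code{NA} and the value is kept for lossless rewriting.
#' @seealso [write_ascii_grid()]
#' @export
read_ascii_grid <- function(path, codebook = default_codebook()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  body_start <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) == 2L &&
        tolower(toks[1]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                "cellsize", "nodata_value")) {
      v <- suppressWarnings(as.numeric(toks[2]))
      if (is.na(v)) stop("malformed header line: ", lines[i], call. = FALSE)
      hdr[[tolower(toks[1])]] <- v
    } else {
      body_start <- i
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ESRI ASCII header; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  if (is.na(body_start)) stop("grid body is empty", call. = FALSE)
  vals <- scan(text = paste(lines[body_start:length(lines)], collapse = "\n"),
               what = integer(), quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop(sprintf("body has %d values; header promises %d x %d = %d",
                 length(vals), nrows, ncols, nrows * ncols), call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999L else as.integer(hdr$nodata_value)
  cells <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  cells[cells == nodata] <- NA_integer_
  landscape_grid(cells, cell_size = hdr$cellsize, codebook = codebook,
                 xll = hdr$xllcorner, yll = hdr$yllcorner,
                 nodata_value = nodata)
}

#' Write a landscape grid as an ESRI ASCII grid
#'
#' Round-trips losslessly with [read_ascii_grid()] on cell values, cell size
#' and nodata.
#'
#' @param grid a \code{landscape_grid}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "landscape_grid"))
  m <- grid$cells
  m[is.na(m)] <- grid$nodata_value
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %s", format(grid$xll, scientific = FALSE)),
           sprintf("yllcorner %s", format(grid$yll, scientific = FALSE)),
           sprintf("cellsize %s", format(grid$cell_size, scientific = FALSE)),
           sprintf("NODATA_value %d", grid$nodata_value))
  body <- apply(m, 1L, paste, collapse = " ")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

# Zone masks share the raster dialect: zones are encoded as small integers.
zone_codes <- function() c(NONE = 0L, WEST = 1L, EAST = 2L, CORRIDOR = 3L)

#' Read / write a zone mask as an ESRI ASCII grid
#'
#' Zones are encoded NONE=0, WEST=1, EAST=2, CORRIDOR=3.
#'
#' @param path file path.
#' @return \code{read_zone_mask}: a \code{zone_mask}.
#' @export
read_zone_mask <- function(path) {
  cb <- lulc_codebook(unname(zone_codes()), names(zone_codes()))
  g <- read_ascii_grid(path, codebook = cb)
  z <- matrix(names(zone_codes())[match(g$cells, zone_codes())], nrow(g$cells))
  z[is.na(z)] <- "NONE"
  zone_mask(z)
}

#' @rdname read_zone_mask
#' @param mask a \code{zone_mask}.
#' @param cell_size cell size written in the header.
#' @export
write_zone_mask <- function(mask, path, cell_size = 100) {
  stopifnot(inherits(mask, "zone_mask"))
  cb <- lulc_codebook(unname(zone_codes()), names(zone_codes()))
  cells <- matrix(zone_codes()[mask$cells], nrow(mask$cells))
  write_ascii_grid(landscape_grid(cells, cell_size = cell_size, codebook = cb),
                   path)
}
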