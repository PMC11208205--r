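#' Categorical landscape grid
#'
#' A \code{landscape_grid} is an integer matrix of LULC class ids with a cell
#' size in meters and an attached codebook.  \code{NA} cells are nodata
#' (outside the study area); land conversion never creates or destroys
#' non-nodata cells.
#'
#' @param cells integer matrix of class ids (\code{NA} = nodata).
#' @param cell_size cell edge length in meters (> 0).
#' @param codebook a \code{lulc_codebook}; every non-nodata cell value must be
#'   one of its class ids.
#' @param xll,yll lower-left corner coordinates (kept for file round-trips).
#' @param nodata_value integer written for nodata cells in ASCII output.
#' @return An object of class \code{landscape_grid}.
#' @export
landscape_grid <- function(cells, cell_size = 100, codebook = default_codebook(),
                           xll = 0, yll = 0, nodata_value = -9999L) {
  if (!is.matrix(cells)) stop("cells must be a matrix", call. = FALSE)
  storage.mode(cells) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  stopifnot(inherits(codebook, "lulc_codebook"))
  vals <- cells[!is.na(cells)]
  bad <- which(!(vals %in% codebook$class_id))
  if (length(bad)) {
    idx <- which(!is.na(cells))[bad[1L]]
    rc <- arrayInd(idx, dim(cells))
    stop(sprintf("cell value %d at (row %d, col %d) is not in the codebook",
                 vals[bad[1L]], rc[1], rc[2]), call. = FALSE)
  }
  structure(list(cells = cells, cell_size = cell_size, codebook = codebook,
                 xll = xll, yll = yll, nodata_value = as.integer(nodata_value)),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  n <- sum(!is.na(x$cells))
  cat(sprintf("landscape_grid: %d x %d cells (%d non-nodata), cell size %g m\n",
              nrow(x$cells), ncol(x$cells), n, x$cell_size))
  cat(sprintf("area: %.1f km^2; classes: %s\n",
              n * (x$cell_size / 1000)^2,
              paste(x$codebook$name, collapse = ", ")))
  invisible(x)
}

#' @export
summary.landscape_grid <- function(object, ...) {
  area_shares(object)
}

#' @export
plot.landscape_grid <- function(x, col = NULL, main = "Land cover", ...) {
  ids <- sort(x$codebook$class_id)
  if (is.null(col))
    col <- grDevices::hcl.colors(length(ids), "Spectral")
  z <- matrix(match(x$cells, ids), nrow(x$cells))
  # image() draws column 1 at the bottom; flip rows so row 1 is on top
  graphics::image(t(z[nrow(z):1, , drop = FALSE]), col = col, axes = FALSE,
                  main = main, ...)
  graphics::legend("topright",
                   legend = x$codebook$name[match(ids, x$codebook$class_id)],
                   fill = col, cex = 0.6, bg = "white")
  invisible(x)
}

#' Zone mask
#'
#' A \code{zone_mask} labels each grid cell with one of \code{"WEST"},
#' \code{"EAST"}, \code{"CORRIDOR"} or \code{"NONE"}.  Transition rules are
#' restricted to subsets of these zones.  The corridor is the road band inside
#' the eastern part of the landscape.
#'
#' @param cells character matrix with values in
#'   \code{c("WEST","EAST","CORRIDOR","NONE")}.
#' @return An object of class \code{zone_mask}.
#' @export
zone_mask <- function(cells) {
  if (!is.matrix(cells)) stop("cells must be a matrix", call. = FALSE)
  cells[] <- as.character(cells)
  bad <- setdiff(unique(as.vector(cells)), zone_levels())
  if (length(bad))
    stop("unknown zone labels: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(cells = cells), class = "zone_mask")
}

#' @rdname zone_mask
#' @export
zone_levels <- function() c("NONE", "WEST", "EAST", "CORRIDOR")

#' @export
print.zone_mask <- function(x, ...) {
  tab <- table(factor(x$cells, levels = zone_levels()))
  cat("zone_mask:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                          collapse = " "), "\n")
  invisible(x)
}

check_aligned <- function(grid, mask) {
  if (!identical(dim(grid$cells), dim(mask$cells)))
    stop("grid and zone mask shapes differ", call. = FALSE)
  invisible(TRUE)
}

#' Area shares of a landscape grid
#'
#' Percentage of the non-nodata area covered by each codebook class.
#'
#' @param grid a \code{landscape_grid}.
#' @return An \code{area_share_table}: data frame with columns
#'   \code{class_id}, \code{name}, \code{share} (percent, summing to 100).
#' @examples
#' cb <- lulc_codebook(1:2, c("A", "B"))
#' g <- landscape_grid(matrix(c(1, 1, 2, 2), 2), codebook = cb)
#' area_shares(g)
#' @export
area_shares <- function(grid) {
  stopifnot(inherits(grid, "landscape_grid"))
  n <- sum(!is.na(grid$cells))
  if (n == 0L) stop("grid has no non-nodata cells", call. = FALSE)
  ids <- grid$codebook$class_id
  counts <- vapply(ids, function(id) sum(grid$cells == id, na.rm = TRUE), 0L)
  out <- data.frame(class_id = ids, name = grid$codebook$name,
                    share = 100 * counts / n, stringsAsFactors = FALSE)
  class(out) <- c("area_share_table", "data.frame")
  out
}

#' Count Moore-neighborhood cells of a target class
#'
#' Number of cells of class \code{target} among the 8 neighbors of
#' \code{(row, col)}.  Off-grid and nodata neighbors count as non-target.
#'
#' @param grid a \code{landscape_grid}.
#' @param row,col cell index (1-based).
#' @param target class id to count.
#' @return Integer in 0..8.
#' @export
count_target_neighbors <- function(grid, row, col, target) {
  m <- grid$cells
  if (row < 1 || row > nrow(m) || col < 1 || col > ncol(m))
    stop("cell index out of bounds", call. = FALSE)
  cnt <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r <- row + dr; c <- col + dc
    if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
        !is.na(m[r, c]) && m[r, c] == target) cnt <- cnt + 1L
  }
  cnt
}

# internal: matrix of Moore-neighbor counts of `target` for every cell,
# computed by summing the 8 shifted indicator matrices (zero-padded border).
moore_counts <- function(cells, target) {
  nr <- nrow(cells); nc <- ncol(cells)
  ind <- !is.na(cells) & cells == target
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- ind
  out <- matrix(0L, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1L && dc == 1L) next
    out <- out + p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  }
  out
}
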