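# Synthetic baseline landscapes.  The generator emulates the study mosaic:
# rubber concentrated in the rural west, settlement in the peri-urban east
# with the highest density along a road corridor, one contiguous forest
# reserve, and wetland/waterbody along the southern coast.  Only composition
# and this qualitative geography are fixed; spatial detail is seeded region
# growing.

# run `expr` under a temporary RNG state so generators do not disturb the
# caller's stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default landscape composition (percent of area per class)
#'
#' Settlement 7.61, rubber 27.35, palm 19.67, cropland 22.26, forest 9.09,
#' shrubland 11.46, waterbody 0.55, wetland 2.00 — the 2020 composition of
#' the municipal study landscape the fixtures emulate.
#'
#' @param codebook a \code{lulc_codebook}; must be the default 8-class book.
#' @return Named numeric vector (names = class ids as character), summing to 100.
#' @export
default_composition <- function(codebook = default_codebook()) {
  shares <- c("Settlement" = 7.61, "Rubber plantations" = 27.35,
              "Palm vegetation" = 19.67, "Cropland" = 22.26,
              "Forest" = 9.09, "Shrubland" = 11.46,
              "Waterbody" = 0.55, "Wetlands" = 2.00)
  ids <- vapply(names(shares), function(nm) class_id_by_name(codebook, nm), 0L)
  if (anyNA(ids))
    stop("codebook lacks one of the default class names", call. = FALSE)
  stats::setNames(as.numeric(shares), as.character(ids))
}

#' Specification of a synthetic landscape
#'
#' @param rows,cols grid dimensions.
#' @param cell_size cell edge in meters (default 100 m; a 243 x 243 grid then
#'   covers about 590 km^2).
#' @param composition named numeric vector, class id -> target share in
#'   percent; must sum to 100 (within 0.01).
#' @param west_fraction fraction of columns assigned to the WEST zone
#'   (strictly between 0 and 1).
#' @param corridor_rows integer vector of row indices forming the road
#'   corridor band inside the EAST zone; default: a central band of about 6
#'   percent of the rows.
#' @param patch_cohesion number in [0, 1]; larger values grow fewer, larger
#'   patches (more clumped landscapes).
#' @param seed integer seed; identical spec + seed gives identical output.
#' @param codebook the \code{lulc_codebook} the composition refers to.
#' @return An object of class \code{landscape_spec}.
#' @export
landscape_spec <- function(rows = 243, cols = 243, cell_size = 100,
                           composition = default_composition(codebook),
                           west_fraction = 0.5, corridor_rows = NULL,
                           patch_cohesion = 0.9, seed = 1L,
                           codebook = default_codebook()) {
  if (abs(sum(composition) - 100) > 0.01)
    stop("composition shares must sum to 100", call. = FALSE)
  if (is.null(names(composition)))
    stop("composition must be named by class id", call. = FALSE)
  if (!all(as.integer(names(composition)) %in% codebook$class_id))
    stop("composition names must be codebook class ids", call. = FALSE)
  if (west_fraction <= 0 || west_fraction >= 1)
    stop("west_fraction must be strictly between 0 and 1", call. = FALSE)
  if (patch_cohesion < 0 || patch_cohesion > 1)
    stop("patch_cohesion must be in [0, 1]", call. = FALSE)
  if (is.null(corridor_rows)) {
    h <- max(2L, round(rows * 0.06))
    mid <- round(rows / 2)
    corridor_rows <- seq.int(max(1L, mid - h %/% 2L),
                             min(rows, mid - h %/% 2L + h - 1L))
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size, composition = composition,
                 west_fraction = west_fraction,
                 corridor_rows = as.integer(corridor_rows),
                 patch_cohesion = patch_cohesion, seed = as.integer(seed),
                 codebook = codebook),
            class = "landscape_spec")
}

# largest-remainder apportionment of N cells to composition shares
quota_cells <- function(composition, n) {
  raw <- composition / 100 * n
  q <- floor(raw)
  rem <- n - sum(q)
  if (rem > 0) {
    # shares may sum to slightly under 100 (within tolerance), so the
    # remainder can exceed the class count; cycle through by remainder rank
    idx <- rep(order(raw - q, decreasing = TRUE), length.out = rem)
    for (i in idx) q[i] <- q[i] + 1
  }
  stats::setNames(as.integer(q), names(composition))
}

# Region-growing allocator.  `state` is a mutable environment holding the
# assignment vector (0 = free) and grid dims; cells are linear column-major
# indices.  Patches grow by repeatedly popping a random frontier cell.
alloc_state <- function(rows, cols) {
  e <- new.env(parent = emptyenv())
  e$assign <- integer(rows * cols)   # 0 = free
  e$rows <- rows; e$cols <- cols
  e
}

free_neighbors <- function(state, idx) {
  rows <- state$rows
  r <- (idx - 1L) %% rows + 1L
  c <- (idx - 1L) %/% rows + 1L
  out <- integer(0)
  for (dc in -1:1) {
    cc <- c + dc
    if (cc < 1L || cc > state$cols) next
    base <- (cc - 1L) * rows
    for (dr in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr
      if (rr < 1L || rr > rows) next
      j <- base + rr
      if (state$assign[j] == 0L) out <- c(out, j)
    }
  }
  out
}

# grow one patch of class `id` up to `size` cells from `seed_idx`, restricted
# to cells where allowed[idx] is TRUE; returns number of cells placed
grow_patch <- function(state, id, size, seed_idx, allowed) {
  placed <- 0L
  frontier <- seed_idx
  flen <- 1L
  while (placed < size && flen > 0L) {
    j <- sample.int(flen, 1L)
    idx <- frontier[j]
    frontier[j] <- frontier[flen]
    flen <- flen - 1L
    if (state$assign[idx] != 0L) next         # stale entry
    state$assign[idx] <- id
    placed <- placed + 1L
    nb <- free_neighbors(state, idx)
    if (length(nb)) {
      nb <- nb[allowed[nb]]
      if (length(nb)) {
        need <- flen + length(nb)
        if (need > length(frontier)) length(frontier) <- max(need, 2L * length(frontier))
        frontier[(flen + 1L):need] <- nb
        flen <- need
      }
    }
  }
  placed
}

# place `quota` cells of class `id` as multiple patches inside `allowed`
# (logical over all cells); spills to any free cell if the region fills up
grow_class <- function(state, id, quota, allowed, cohesion) {
  target_patch <- max(5L, round(10 + cohesion * 290))
  remaining <- quota
  while (remaining > 0L) {
    cand <- which(allowed & state$assign == 0L)
    if (!length(cand)) {
      cand <- which(state$assign == 0L)      # spillover
      if (!length(cand)) stop("internal: no free cells left", call. = FALSE)
      allowed <- rep(TRUE, length(state$assign))
    }
    seed_idx <- cand[sample.int(length(cand), 1L)]
    placed <- grow_patch(state, id, min(target_patch, remaining), seed_idx, allowed)
    remaining <- remaining - placed
  }
  invisible(NULL)
}

#' Generate a seeded synthetic baseline landscape
#'
#' Allocates exact class quotas (largest-remainder apportionment of the
#' composition) and arranges them with seeded region growing: wetland and
#' waterbody along the southern (bottom) coast; one contiguous forest-reserve
#' patch in the west; rubber mostly (80 percent of its quota) in the WEST
#' zone; settlement mostly in the EAST zone with the highest density inside
#' the road CORRIDOR; cropland, palm and shrubland fill the remainder as
#' cohesive patches.
#'
#' @param spec a \code{landscape_spec}.
#' @return A list with elements \code{grid} (a \code{landscape_grid}) and
#'   \code{mask} (a \code{zone_mask}).
#' @examples
#' ls <- generate_baseline_landscape(landscape_spec(rows = 60, cols = 60, seed = 7))
#' area_shares(ls$grid)
#' @export
generate_baseline_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  rows <- spec$rows; cols <- spec$cols
  n <- rows * cols
  quotas <- quota_cells(spec$composition, n)
  nz <- quotas[spec$composition > 0]
  if (any(nz == 0L))
    stop("grid too small to honor composition: class ",
         names(nz)[which(nz == 0L)[1]], " gets no cell", call. = FALSE)

  # zone mask: WEST = left column block, EAST = rest, CORRIDOR = row band in EAST
  west_cols <- seq_len(max(1L, floor(spec$west_fraction * cols)))
  zone <- matrix("EAST", rows, cols)
  zone[, west_cols] <- "WEST"
  east_cols <- setdiff(seq_len(cols), west_cols)
  corr <- intersect(spec$corridor_rows, seq_len(rows))
  if (length(east_cols) && length(corr)) zone[corr, east_cols] <- "CORRIDOR"
  zvec <- as.vector(zone)

  cb <- spec$codebook
  id_of <- function(nm) class_id_by_name(cb, nm)
  ids <- as.integer(names(quotas))

  grid_cells <- with_seed(spec$seed, {
    state <- alloc_state(rows, cols)
    all_ok <- rep(TRUE, n)
    col_of <- (seq_len(n) - 1L) %/% rows + 1L
    row_of <- (seq_len(n) - 1L) %% rows + 1L

    take <- function(nm) {
      id <- id_of(nm)
      if (is.na(id) || !(as.character(id) %in% names(quotas))) 0L
      else quotas[[as.character(id)]]
    }

    # 1. coast: wetland + waterbody fill the bottom rows
    q_wet <- take("Wetlands"); q_wat <- take("Waterbody")
    if (q_wet + q_wat > 0L) {
      coast_order <- order(-row_of, col_of)        # bottom row first, left to right
      coast_cells <- coast_order[seq_len(q_wet + q_wat)]
      if (q_wat > 0L) {
        # waterbody as one run (a lagoon) starting at a random position
        start <- sample.int(max(1L, q_wet + q_wat - q_wat + 1L), 1L)
        wat <- coast_cells[start:(start + q_wat - 1L)]
        state$assign[wat] <- id_of("Waterbody")
      } else wat <- integer(0)
      wet <- setdiff(coast_cells, wat)
      if (q_wet > 0L) state$assign[wet] <- id_of("Wetlands")
    }

    # 2. forest: one contiguous reserve, seeded in the western interior
    q_for <- take("Forest")
    if (q_for > 0L) {
      fid <- id_of("Forest")
      pref <- which(state$assign == 0L & zvec == "WEST" &
                      row_of > rows * 0.15 & row_of < rows * 0.6)
      if (!length(pref)) pref <- which(state$assign == 0L)
      seed_idx <- pref[sample.int(length(pref), 1L)]
      placed <- grow_patch(state, fid, q_for, seed_idx, all_ok)
      if (placed < q_for)        # frontier got enclosed; finish adjacent to patch
        grow_class(state, fid, q_for - placed, all_ok, spec$patch_cohesion)
    }

    # 3. rubber: 80% of quota in WEST
    q_rub <- take("Rubber plantations")
    if (q_rub > 0L) {
      rid <- id_of("Rubber plantations")
      q_w <- round(0.8 * q_rub)
      grow_class(state, rid, q_w, zvec == "WEST", spec$patch_cohesion)
      grow_class(state, rid, q_rub - q_w, zvec != "WEST", spec$patch_cohesion)
    }

    # 4. settlement: dense in the corridor, most of the rest in EAST
    q_set <- take("Settlement")
    if (q_set > 0L) {
      sid <- id_of("Settlement")
      corr_free <- sum(state$assign == 0L & zvec == "CORRIDOR")
      q_corr <- min(round(0.45 * q_set), floor(0.85 * corr_free))
      q_east <- max(0L, round(0.85 * q_set) - q_corr)
      q_rest <- q_set - q_corr - q_east
      grow_class(state, sid, q_corr, zvec == "CORRIDOR", spec$patch_cohesion)
      grow_class(state, sid, q_east, zvec == "EAST", spec$patch_cohesion)
      grow_class(state, sid, q_rest, zvec == "WEST", spec$patch_cohesion)
    }

    # 5. everything else fills the remaining free cells as cohesive patches
    rest <- setdiff(as.character(ids),
                    as.character(stats::na.omit(c(id_of("Wetlands"), id_of("Waterbody"),
                                     id_of("Forest"), id_of("Rubber plantations"),
                                     id_of("Settlement")))))
    rest <- rest[quotas[rest] > 0L]
    # interleave patches across classes so no class is squeezed into leftovers
    rem <- quotas[rest]
    while (any(rem > 0L)) {
      for (k in names(rem)) {
        if (rem[[k]] == 0L) next
        target_patch <- max(5L, round(10 + spec$patch_cohesion * 290))
        sz <- min(target_patch, rem[[k]])
        cand <- which(state$assign == 0L)
        seed_idx <- cand[sample.int(length(cand), 1L)]
        placed <- grow_patch(state, as.integer(k), sz, seed_idx,
                             rep(TRUE, n))
        rem[[k]] <- rem[[k]] - placed
      }
    }
    matrix(state$assign, rows, cols)
  })

  list(grid = landscape_grid(grid_cells, cell_size = spec$cell_size, codebook = cb),
       mask = zone_mask(zone))
}
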