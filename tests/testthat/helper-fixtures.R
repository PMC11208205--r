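# Shared fixture builders.  All tiny grids are built in code.

toy_codebook <- function(ids = 1:3, names = c("A", "B", "C")) {
  lulc_codebook(ids, names)
}

toy_grid <- function(cells, cb = toy_codebook(), cell_size = 100) {
  landscape_grid(cells, cell_size = cell_size, codebook = cb)
}

uniform_mask <- function(nr, nc, zone = "WEST") {
  zone_mask(matrix(zone, nr, nc))
}

random_toy_grid <- function(nr, nc, cb = toy_codebook()) {
  toy_grid(matrix(sample(cb$class_id, nr * nc, replace = TRUE), nr, nc), cb)
}

small_spec <- function(seed, rows = 120, cols = 120, ...) {
  landscape_spec(rows = rows, cols = cols, seed = seed, ...)
}

# id lookup for the default codebook
default_ids <- function() {
  cb <- default_codebook()
  stats::setNames(cb$class_id, cb$name)
}
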