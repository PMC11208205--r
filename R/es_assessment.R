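# The ecosystem-service assessment matrix and landscape scoring.  Every
# indicator is standardized to a common 0-100 capacity scale; the landscape
# score of a service is the mean capacity over all (non-nodata) cells, which
# equals the area-share-weighted mean over classes.

#' Standardize a 0-5 Likert capacity rating to the 0-100 scale
#'
#' Linear map with anchored endpoints: 0 -> 0 (no capacity), 5 -> 100
#' (maximum capacity), so a rating of 3 becomes 60.
#'
#' @param score numeric vector of ratings in [0, 5].
#' @return \code{20 * score}.
#' @export
normalize_likert <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 5))
    stop("Likert scores must lie in [0, 5]", call. = FALSE)
  20 * score
}

#' Shannon-Wiener diversity index
#'
#' \eqn{H = -\sum_i p_i \log p_i} over species proportions
#' \eqn{p_i = n_i / \sum_j n_j}.  Natural log by default (the usual ecological
#' convention); the base is configurable.
#'
#' @param counts positive numeric vector of species abundances (optionally
#'   named by species).
#' @param base logarithm base (default \code{exp(1)}, i.e. nats).
#' @return The index value; 0 for a single species, at most
#'   \code{log(length(counts), base)}.
#' @examples
#' shannon_index(c(A = 5, B = 5))  # log(2)
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (length(counts) == 0L) stop("counts must not be empty", call. = FALSE)
  if (any(is.na(counts)) || any(counts <= 0))
    stop("all species counts must be positive", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Ecosystem-service assessment matrix
#'
#' A (class x service) matrix of capacities on the 0-100 scale.
#'
#' @param values numeric matrix; rownames = class ids (as character),
#'   colnames = service ids.
#' @param codebook,catalog the codebook and service catalog the matrix covers;
#'   every (class, service) pair must be present.
#' @return An object of class \code{es_matrix}.
#' @export
es_matrix <- function(values, codebook = default_codebook(),
                      catalog = default_services()) {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  want_r <- as.character(codebook$class_id)
  want_c <- catalog$service_id
  miss_r <- setdiff(want_r, rownames(values))
  miss_c <- setdiff(want_c, colnames(values))
  if (length(miss_r) || length(miss_c))
    stop("assessment matrix is missing ",
         paste(c(if (length(miss_r)) paste("classes", paste(miss_r, collapse = ",")),
                 if (length(miss_c)) paste("services", paste(miss_c, collapse = ","))),
               collapse = "; "), call. = FALSE)
  values <- values[want_r, want_c, drop = FALSE]
  if (any(is.na(values)) || any(values < 0 | values > 100))
    stop("capacities must lie in [0, 100]", call. = FALSE)
  structure(values, class = c("es_matrix", "matrix"),
            codebook = codebook, catalog = catalog)
}

#' @export
print.es_matrix <- function(x, ...) {
  cb <- attr(x, "codebook")
  m <- unclass(x)
  attr(m, "codebook") <- NULL; attr(m, "catalog") <- NULL
  rownames(m) <- cb$name[match(as.integer(rownames(m)), cb$class_id)]
  cat("es_matrix (capacity 0-100):\n")
  print(round(m, 1))
  invisible(x)
}

#' Build the assessment matrix from a perception dataset
#'
#' Percentage-type indicator scores (unit \code{"pct"}) pass through on the
#' 0-100 scale; Likert-type scores (unit \code{"likert5"}) are standardized
#' with [normalize_likert()].  If the dataset carries expert Delphi rounds,
#' the soil-quality column is the arithmetic mean of the final-round expert
#' scores per class.  If it carries species counts, the species-diversity
#' column is the per-class Shannon-Wiener index rescaled by its observed
#' maximum across classes (so the most diverse class scores 100).
#'
#' @param perception a \code{perception_dataset}.
#' @param codebook,catalog codebook and service catalog to cover.
#' @param soil_service,species_service service ids filled from
#'   \code{expert_rounds} / \code{species_counts} when present.
#' @return An \code{es_matrix} covering every (class, service) pair.
#' @export
build_es_matrix <- function(perception, codebook = default_codebook(),
                            catalog = default_services(),
                            soil_service = "soil_quality",
                            species_service = "species_diversity") {
  stopifnot(inherits(perception, "perception_dataset"))
  want_r <- as.character(codebook$class_id)
  want_c <- catalog$service_id
  m <- matrix(NA_real_, length(want_r), length(want_c),
              dimnames = list(want_r, want_c))
  es <- perception$es_scores
  for (i in seq_len(nrow(es))) {
    cid <- as.character(es$class_id[i]); sid <- es$service_id[i]
    if (!(cid %in% want_r) || !(sid %in% want_c)) next
    m[cid, sid] <- if (es$unit[i] == "likert5") normalize_likert(es$value[i])
                   else es$value[i]
  }
  if (!is.null(perception$expert_rounds) && soil_service %in% want_c) {
    agg <- tapply(perception$expert_rounds$value,
                  as.character(perception$expert_rounds$class_id), mean)
    m[names(agg), soil_service] <- as.numeric(agg)
  }
  if (!is.null(perception$species_counts) && species_service %in% want_c) {
    sc <- perception$species_counts
    h <- tapply(sc$count, as.character(sc$class_id),
                function(x) shannon_index(x))
    h100 <- if (max(h) > 0) 100 * h / max(h) else h * 0
    m[names(h100), species_service] <- as.numeric(h100)
  }
  if (any(is.na(m))) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("perception data missing pair (class %s, service %s)",
                 want_r[miss[1]], want_c[miss[2]]), call. = FALSE)
  }
  es_matrix(m, codebook, catalog)
}

#' Read / write an assessment matrix CSV
#'
#' Rows are classes (columns \code{class_id}, \code{name}, then one column
#' per service id).
#'
#' @param path file path.
#' @param codebook,catalog codebook and catalog the matrix covers.
#' @return \code{read_es_matrix}: an \code{es_matrix}.
#' @export
read_es_matrix <- function(path, codebook = default_codebook(),
                           catalog = default_services()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  svc <- setdiff(names(df), c("class_id", "name"))
  m <- as.matrix(df[, svc, drop = FALSE])
  rownames(m) <- as.character(df$class_id)
  es_matrix(m, codebook, catalog)
}

#' @rdname read_es_matrix
#' @param matrix an \code{es_matrix}.
#' @export
write_es_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "es_matrix"))
  cb <- attr(matrix, "codebook")
  df <- data.frame(class_id = as.integer(rownames(matrix)),
                   name = cb$name[match(as.integer(rownames(matrix)), cb$class_id)],
                   unclass(matrix), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Packaged default assessment matrix
#'
#' Built from the packaged synthetic perception dataset with
#' [build_es_matrix()].
#'
#' @return An \code{es_matrix}.
#' @export
default_es_matrix <- function() {
  build_es_matrix(generate_perception_dataset(mode = "paper_defaults"))
}

#' Landscape-level ecosystem-service scores
#'
#' The score of service s is the mean capacity over non-nodata cells,
#' \eqn{E_s = \sum_l A_l/100 \; v(l, s)} with \eqn{A_l} the area share of
#' class l — a pure function of landscape composition.
#'
#' @param grid a \code{landscape_grid}; every class present must be in the
#'   matrix.
#' @param matrix an \code{es_matrix}.
#' @return Named numeric vector of scores in [0, 100], one per service.
#' @export
landscape_es_scores <- function(grid, matrix) {
  stopifnot(inherits(grid, "landscape_grid"), inherits(matrix, "es_matrix"))
  present <- unique(grid$cells[!is.na(grid$cells)])
  miss <- setdiff(as.character(present), rownames(matrix))
  if (length(miss))
    stop("assessment matrix is missing classes ", paste(miss, collapse = ","),
         call. = FALSE)
  sh <- area_shares(grid)
  w <- stats::setNames(sh$share / 100, as.character(sh$class_id))
  w <- w[rownames(matrix)]
  w[is.na(w)] <- 0
  scores <- as.numeric(t(unclass(matrix)) %*% as.numeric(w))
  stats::setNames(scores, colnames(matrix))
}

#' Per-cell capacity map of one service
#'
#' Replaces each cell's class by its capacity for \code{service}; the mean of
#' the raster equals the landscape score of the service.
#'
#' @param grid a \code{landscape_grid}.
#' @param matrix an \code{es_matrix}.
#' @param service a service id present in the matrix.
#' @return Numeric matrix of capacities (NA at nodata cells).
#' @export
es_map <- function(grid, matrix, service) {
  stopifnot(inherits(grid, "landscape_grid"), inherits(matrix, "es_matrix"))
  if (!(service %in% colnames(matrix)))
    stop("unknown service: ", service, call. = FALSE)
  present <- unique(grid$cells[!is.na(grid$cells)])
  miss <- setdiff(as.character(present), rownames(matrix))
  if (length(miss))
    stop("assessment matrix is missing classes ", paste(miss, collapse = ","),
         call. = FALSE)
  v <- unclass(matrix)[, service]
  out <- matrix(v[as.character(grid$cells)], nrow(grid$cells))
  out
}
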