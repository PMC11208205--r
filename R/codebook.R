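#' Land-use/land-cover codebook
#'
#' A codebook maps small non-negative integer class ids to land-use/land-cover
#' (LULC) class names.  All grids in the package are validated against a
#' codebook.
#'
#' @param class_id integer vector of unique, non-negative class ids.
#' @param name character vector of class names.
#' @param description optional character vector of class descriptions.
#' @return An object of class \code{lulc_codebook}: a data frame with columns
#'   \code{class_id}, \code{name}, \code{description}.
#' @examples
#' lulc_codebook(1:2, c("Forest", "Cropland"))
#' @export
lulc_codebook <- function(class_id, name, description = rep("", length(class_id))) {
  class_id <- as.integer(class_id)
  if (anyNA(class_id) || any(class_id < 0))
    stop("class_id must be non-negative integers", call. = FALSE)
  if (anyDuplicated(class_id))
    stop("class_id values must be unique", call. = FALSE)
  if (length(name) != length(class_id) || length(description) != length(class_id))
    stop("class_id, name and description must have equal length", call. = FALSE)
  cb <- data.frame(class_id = class_id, name = as.character(name),
                   description = as.character(description),
                   stringsAsFactors = FALSE)
  class(cb) <- c("lulc_codebook", "data.frame")
  cb
}

#' Default eight-class codebook for the coastal rubber/settlement mosaic
#'
#' Settlement, rubber plantations, palm vegetation, cropland, forest,
#' shrubland, waterbody and wetlands — the classes of the municipal landscape
#' the package's fixtures emulate.
#'
#' @return A \code{lulc_codebook} with 8 entries (ids 1 to 8).
#' @export
default_codebook <- function() {
  read_codebook(system.file("extdata", "lulc_codebook.csv", package = "landesca",
                            mustWork = TRUE))
}

#' Read / write a codebook CSV (columns class_id, name, description)
#'
#' @param path file path of a CSV with columns \code{class_id}, \code{name},
#'   \code{description}.
#' @return \code{read_codebook}: a \code{lulc_codebook};
#'   \code{write_codebook}: \code{path}, invisibly.
#' @export
read_codebook <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class_id", "name")
  if (!all(need %in% names(df)))
    stop("codebook CSV must have columns class_id and name", call. = FALSE)
  if (is.null(df$description)) df$description <- ""
  lulc_codebook(df$class_id, df$name, df$description)
}

#' @rdname read_codebook
#' @param codebook a \code{lulc_codebook}.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "lulc_codebook"))
  utils::write.csv(as.data.frame(codebook), path, row.names = FALSE)
  invisible(path)
}

# internal: map class name -> id (NA if absent); matching is exact on the
# packaged names, so role lookups use these canonical strings.
class_id_by_name <- function(codebook, nm) {
  i <- match(nm, codebook$name)
  if (is.na(i)) NA_integer_ else codebook$class_id[i]
}

#' Ecosystem-service catalog
#'
#' The catalog lists the services scored by the assessment matrix, each with
#' a short id, a display name and the indicator used to elicit its values.
#'
#' @param service_id character vector of unique short ids.
#' @param name character vector of display names.
#' @param indicator character vector describing each service's indicator.
#' @return An object of class \code{service_catalog} (a data frame).
#' @export
service_catalog <- function(service_id, name, indicator = rep("", length(service_id))) {
  service_id <- as.character(service_id)
  if (anyDuplicated(service_id)) stop("service_id values must be unique", call. = FALSE)
  sc <- data.frame(service_id = service_id, name = as.character(name),
                   indicator = as.character(indicator), stringsAsFactors = FALSE)
  class(sc) <- c("service_catalog", "data.frame")
  sc
}

#' Default five-service catalog
#'
#' Food provision, marketable products, fuelwood provision, soil-quality
#' regulation and species diversity — the locally relevant services the
#' packaged assessment matrix scores.
#'
#' @return A \code{service_catalog} with 5 entries.
#' @export
default_services <- function() {
  df <- utils::read.csv(system.file("extdata", "service_catalog.csv",
                                    package = "landesca", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  service_catalog(df$service_id, df$name, df$indicator)
}
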