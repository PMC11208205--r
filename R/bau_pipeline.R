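# End-to-end business-as-usual reporting: area-change tables, ES balance
# tables, trade-off classification, spider-chart export, and the run_bau()
# orchestrator.

#' Area-change table of a scenario run
#'
#' Change in area share of every class at the reported iterations, in
#' percentage points relative to the baseline.  Because conversion only moves
#' cells between classes, the deltas of each iteration sum to zero.
#'
#' @param result a \code{scenario_result}.
#' @param report_iterations iterations to report (must be simulated).
#' @return An \code{area_change_table}: data frame with columns
#'   \code{class_id}, \code{name}, \code{iteration}, \code{share},
#'   \code{delta}.
#' @export
area_change_table <- function(result, report_iterations = c(2, 5, 10)) {
  stopifnot(inherits(result, "scenario_result"))
  have <- as.integer(names(result$snapshots))
  miss <- setdiff(report_iterations, have)
  if (length(miss))
    stop("iterations not simulated: ", paste(miss, collapse = ", "),
         call. = FALSE)
  base <- area_shares(result$baseline)
  out <- do.call(rbind, lapply(report_iterations, function(k) {
    sh <- area_shares(result$snapshots[[as.character(k)]])
    data.frame(class_id = sh$class_id, name = sh$name, iteration = k,
               share = sh$share, delta = sh$share - base$share,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("area_change_table", "data.frame")
  out
}

#' ES balance table of a scenario run
#'
#' Landscape ES scores at the baseline and the reported iterations, with the
#' change versus the baseline — the numbers behind the spider chart.
#'
#' @param result a \code{scenario_result}.
#' @param matrix an \code{es_matrix}.
#' @param report_iterations iterations to report.
#' @return An \code{es_balance_table}: data frame with columns
#'   \code{service_id}, \code{iteration}, \code{score}, \code{delta}
#'   (iteration 0 = baseline, delta 0).
#' @export
es_balance_table <- function(result, matrix, report_iterations = c(2, 5, 10)) {
  stopifnot(inherits(result, "scenario_result"))
  have <- as.integer(names(result$snapshots))
  miss <- setdiff(report_iterations, have)
  if (length(miss))
    stop("iterations not simulated: ", paste(miss, collapse = ", "),
         call. = FALSE)
  base <- landscape_es_scores(result$baseline, matrix)
  ks <- unique(c(0, report_iterations))
  out <- do.call(rbind, lapply(ks, function(k) {
    sc <- landscape_es_scores(result$snapshots[[as.character(k)]], matrix)
    data.frame(service_id = names(sc), iteration = k, score = as.numeric(sc),
               delta = as.numeric(sc - base), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("es_balance_table", "data.frame")
  out
}

#' Classify per-service trade-offs at one iteration
#'
#' A service INCREASEs if its change versus the baseline exceeds
#' \code{tolerance} score units, DECREASEs below \code{-tolerance}, and is
#' STABLE inside the dead band.
#'
#' @param balance an \code{es_balance_table}.
#' @param at_iteration iteration to classify (present in \code{balance}).
#' @param tolerance stability dead band in score units (default 0.5).
#' @return A \code{tradeoff_summary}: data frame with columns
#'   \code{service_id}, \code{delta}, \code{classification}.
#' @export
classify_tradeoffs <- function(balance, at_iteration, tolerance = 0.5) {
  stopifnot(inherits(balance, "es_balance_table"))
  b <- balance[balance$iteration == at_iteration, ]
  if (!nrow(b))
    stop("iteration ", at_iteration, " not present in balance table",
         call. = FALSE)
  cls <- ifelse(b$delta > tolerance, "INCREASE",
                ifelse(b$delta < -tolerance, "DECREASE", "STABLE"))
  out <- data.frame(service_id = b$service_id, delta = b$delta,
                    classification = cls, stringsAsFactors = FALSE)
  class(out) <- c("tradeoff_summary", "data.frame")
  out
}

#' Export spider-chart data
#'
#' One row per service, one column per reported iteration (baseline first),
#' values are the landscape ES scores; re-importable losslessly with
#' \code{read.csv}.
#'
#' @param balance an \code{es_balance_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
export_spider_data <- function(balance, path) {
  stopifnot(inherits(balance, "es_balance_table"))
  ks <- sort(unique(balance$iteration))
  wide <- data.frame(service_id = unique(balance$service_id),
                     stringsAsFactors = FALSE)
  for (k in ks) {
    b <- balance[balance$iteration == k, ]
    col <- if (k == 0) "baseline" else paste0("iteration_", k)
    wide[[col]] <- b$score[match(wide$service_id, b$service_id)]
  }
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Spider (radar) chart of an ES balance table
#'
#' @param x an \code{es_balance_table}.
#' @param ... further arguments (ignored).
#' @export
plot.es_balance_table <- function(x, ...) {
  svcs <- unique(x$service_id)
  ks <- sort(unique(x$iteration))
  ang <- seq(0, 2 * pi, length.out = length(svcs) + 1L)[-(length(svcs) + 1L)]
  graphics::plot(NA, xlim = c(-120, 120), ylim = c(-120, 120), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = "ES balance")
  for (r in c(25, 50, 75, 100))
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  graphics::text(112 * cos(ang), 112 * sin(ang), svcs, cex = 0.7)
  cols <- grDevices::hcl.colors(length(ks), "Dark 3")
  for (i in seq_along(ks)) {
    b <- x[x$iteration == ks[i], ]
    v <- b$score[match(svcs, b$service_id)]
    graphics::polygon(v * cos(ang), v * sin(ang), border = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", cex = 0.7, col = cols, lwd = 2,
                   legend = ifelse(ks == 0, "baseline", paste("iteration", ks)))
  invisible(x)
}

# normalize a config (list or YAML path) and check required keys
load_bau_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  need <- c("landscape", "scenario", "iterations", "seed", "output_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  config
}

#' Run the full business-as-usual pipeline
#'
#' Reads or generates the baseline landscape, runs the chosen scenario,
#' scores every reported snapshot, and writes snapshot rasters, the
#' area-change and ES-balance CSVs, the spider-chart CSV, the trade-off
#' summary and a run manifest into \code{output_dir}.  Rerunning with the
#' same config and seed reproduces every output byte-for-byte.
#'
#' @param config a list or path to a YAML file with keys:
#'   \describe{
#'     \item{landscape}{either \code{list(grid = "x.asc", mask = "z.asc")} to
#'       read rasters, or \code{list(synthetic = list(rows, cols, seed, ...))}
#'       forwarded to [landscape_spec()].}
#'     \item{scenario}{\code{"rubber_expansion"}, \code{"settlement_expansion"}
#'       or a ruleset CSV path.}
#'     \item{iterations}{integer vector of iterations to report (the run
#'       simulates up to their maximum).}
#'     \item{seed}{integer root seed for the CA.}
#'     \item{output_dir}{directory to write outputs into.}
#'     \item{matrix}{optional assessment-matrix CSV path; default: the
#'       packaged matrix.}
#'     \item{tolerance}{optional trade-off dead band (default 0.5).}
#'   }
#' @return The output directory path, invisibly; side effect: files written.
#' @export
run_bau <- function(config) {
  cfg <- load_bau_config(config)
  # landscape
  if (!is.null(cfg$landscape$synthetic)) {
    spec <- do.call(landscape_spec, cfg$landscape$synthetic)
    ls <- generate_baseline_landscape(spec)
    grid <- ls$grid; mask <- ls$mask
  } else if (!is.null(cfg$landscape$grid) && !is.null(cfg$landscape$mask)) {
    grid <- read_ascii_grid(cfg$landscape$grid)
    mask <- read_zone_mask(cfg$landscape$mask)
  } else {
    stop("config landscape must give either 'synthetic' or 'grid'+'mask'",
         call. = FALSE)
  }
  # scenario
  rs <- switch(cfg$scenario,
               rubber_expansion = rubber_ruleset(),
               settlement_expansion = settlement_ruleset(),
               {
                 if (!file.exists(cfg$scenario))
                   stop("unknown scenario '", cfg$scenario,
                        "' (not a packaged name or a ruleset CSV path)",
                        call. = FALSE)
                 read_ruleset(cfg$scenario)
               })
  mat <- if (!is.null(cfg$matrix)) read_es_matrix(cfg$matrix) else default_es_matrix()
  ks <- sort(unique(as.integer(cfg$iterations)))
  tol <- if (is.null(cfg$tolerance)) 0.5 else cfg$tolerance

  message(sprintf("run_bau: scenario=%s seed=%d iterations=%s",
                  rs$name, as.integer(cfg$seed), paste(ks, collapse = ",")))
  res <- run_scenario(grid, mask, rs, max(ks), seed = cfg$seed)
  act <- area_change_table(res, ks)
  bal <- es_balance_table(res, mat, ks)
  tro <- classify_tradeoffs(bal, max(ks), tolerance = tol)

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  write_ascii_grid(grid, out("baseline.asc"))
  write_zone_mask(mask, out("zones.asc"), cell_size = grid$cell_size)
  for (k in ks)
    write_ascii_grid(res$snapshots[[as.character(k)]],
                     out(sprintf("snapshot_iter%02d.asc", k)))
  utils::write.csv(as.data.frame(act), out("area_change.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bal), out("es_balance.csv"), row.names = FALSE)
  export_spider_data(bal, out("spider.csv"))
  utils::write.csv(as.data.frame(tro), out("tradeoffs.csv"), row.names = FALSE)

  # hash the analytic part of the config (where outputs go does not change them)
  cfg_hashable <- cfg
  cfg_hashable$output_dir <- NULL
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_hashable, cfg_file)
  manifest <- list(seed = as.integer(cfg$seed),
                   scenario = rs$name,
                   iterations = ks,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(utils::packageVersion("landesca")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  unlink(cfg_file)
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(cfg$output_dir)
}
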