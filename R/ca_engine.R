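# The stochastic cellular automaton.  One iteration applies every rule of a
# rule set synchronously: eligibility (source class, allowed zones, minimum
# Moore-neighbor count of the target class) is evaluated on the input grid
# only; each eligible cell converts independently with the rule's
# probability; a cell fired by several rules picks one uniformly at random.
# One iteration represents five years.

#' A single elicited transition rule
#'
#' @param source,target class ids (\code{source != target}).
#' @param probability_pct elicited conversion probability in percent (0-100);
#'   interpreted as the per-eligible-cell, per-iteration conversion
#'   probability.
#' @param neighborhood_min minimum number of target-class Moore neighbors an
#'   eligible cell must have (0-8); the default 1 makes expansion grow from
#'   existing frontiers.
#' @param allowed_zones character vector, subset of
#'   \code{c("WEST","EAST","CORRIDOR","NONE")}.
#' @return An object of class \code{transition_rule}.
#' @export
transition_rule <- function(source, target, probability_pct,
                            neighborhood_min = 1L,
                            allowed_zones = c("WEST", "EAST", "CORRIDOR")) {
  if (source == target) stop("source and target must differ", call. = FALSE)
  if (probability_pct < 0 || probability_pct > 100)
    stop("probability_pct must lie in [0, 100]", call. = FALSE)
  if (neighborhood_min < 0 || neighborhood_min > 8)
    stop("neighborhood_min must lie in 0..8", call. = FALSE)
  bad <- setdiff(allowed_zones, zone_levels())
  if (length(bad)) stop("unknown zones: ", paste(bad, collapse = ","), call. = FALSE)
  structure(list(source = as.integer(source), target = as.integer(target),
                 p = probability_pct / 100,
                 neighborhood_min = as.integer(neighborhood_min),
                 allowed_zones = allowed_zones),
            class = "transition_rule")
}

#' A named set of transition rules
#'
#' @param name scenario label (e.g. \code{"rubber_expansion"}).
#' @param rules list of \code{transition_rule}s; at most one per
#'   (source, target) pair.
#' @param years_per_iteration years represented by one CA iteration
#'   (default 5).
#' @return An object of class \code{ruleset}.
#' @export
ruleset <- function(name, rules, years_per_iteration = 5) {
  stopifnot(all(vapply(rules, inherits, TRUE, "transition_rule")))
  keys <- vapply(rules, function(r) paste(r$source, r$target), "")
  if (anyDuplicated(keys))
    stop("at most one rule per (source, target) pair", call. = FALSE)
  structure(list(name = name, rules = rules,
                 years_per_iteration = years_per_iteration),
            class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("ruleset '%s' (%d rules, 1 iteration = %g years)\n",
              x$name, length(x$rules), x$years_per_iteration))
  for (r in x$rules)
    cat(sprintf("  %d -> %d  p=%.2f  min neighbors=%d  zones=%s\n",
                r$source, r$target, r$p, r$neighborhood_min,
                paste(r$allowed_zones, collapse = ";")))
  invisible(x)
}

#' Read / write a rule set CSV
#'
#' Columns: \code{scenario}, \code{source}, \code{target},
#' \code{probability_pct}, \code{neighborhood_min}, \code{allowed_zones}
#' (semicolon-separated).
#'
#' @param path file path.
#' @return \code{read_ruleset}: a \code{ruleset}.
#' @export
read_ruleset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scenario", "source", "target", "probability_pct",
            "neighborhood_min", "allowed_zones")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ruleset CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rules <- lapply(seq_len(nrow(df)), function(i)
    transition_rule(df$source[i], df$target[i], df$probability_pct[i],
                    df$neighborhood_min[i],
                    strsplit(df$allowed_zones[i], ";")[[1]]))
  ruleset(df$scenario[1], rules)
}

#' @rdname read_ruleset
#' @param rs a \code{ruleset}.
#' @export
write_ruleset <- function(rs, path) {
  stopifnot(inherits(rs, "ruleset"))
  df <- do.call(rbind, lapply(rs$rules, function(r)
    data.frame(scenario = rs$name, source = r$source, target = r$target,
               probability_pct = 100 * r$p,
               neighborhood_min = r$neighborhood_min,
               allowed_zones = paste(r$allowed_zones, collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Packaged business-as-usual rule sets
#'
#' \code{rubber_ruleset()}: cropland, shrubland and palm convert to rubber
#' plantations at 85, 90 and 60 percent in the WEST zone, each requiring at
#' least one rubber Moore neighbor.  \code{settlement_ruleset()}: cropland,
#' shrubland and palm convert to settlement at 50, 90 and 50 percent in the
#' EAST zone and road CORRIDOR, each requiring at least one settlement
#' neighbor.
#'
#' @return A \code{ruleset}.
#' @export
rubber_ruleset <- function() {
  read_ruleset(system.file("extdata", "ruleset_rubber.csv",
                           package = "landesca", mustWork = TRUE))
}

#' @rdname rubber_ruleset
#' @export
settlement_ruleset <- function() {
  read_ruleset(system.file("extdata", "ruleset_settlement.csv",
                           package = "landesca", mustWork = TRUE))
}

#' Cells eligible for a rule
#'
#' Exactly the cells whose class is the rule's source, whose zone is allowed,
#' and whose Moore count of the target class is at least
#' \code{neighborhood_min}.
#'
#' @param grid a \code{landscape_grid}.
#' @param mask a \code{zone_mask} of the same shape.
#' @param rule a \code{transition_rule}.
#' @return Integer vector of linear (column-major) cell indices.
#' @export
eligible_cells <- function(grid, mask, rule) {
  check_aligned(grid, mask)
  g <- grid$cells
  ok <- !is.na(g) & g == rule$source &
    matrix(mask$cells %in% rule$allowed_zones, nrow(g))
  if (rule$neighborhood_min > 0L)
    ok <- ok & moore_counts(g, rule$target) >= rule$neighborhood_min
  which(ok)
}

#' Apply one synchronous CA step
#'
#' Eligibility of every rule is evaluated on the input grid; each eligible
#' cell converts with the rule's probability; cells fired by several rules
#' draw one uniformly at random; all other cells are unchanged.  Randomness
#' comes from R's global RNG stream (seed it, or use [run_scenario()] which
#' manages per-iteration substreams).
#'
#' @param grid a \code{landscape_grid}.
#' @param mask a \code{zone_mask}.
#' @param rs a \code{ruleset}.
#' @return The updated \code{landscape_grid}.
#' @export
apply_transition_step <- function(grid, mask, rs) {
  stopifnot(inherits(rs, "ruleset"))
  check_aligned(grid, mask)
  fired_cell <- integer(0)
  fired_target <- integer(0)
  for (rule in rs$rules) {
    elig <- eligible_cells(grid, mask, rule)
    if (!length(elig)) next
    hit <- elig[stats::runif(length(elig)) < rule$p]
    if (length(hit)) {
      fired_cell <- c(fired_cell, hit)
      fired_target <- c(fired_target, rep(rule$target, length(hit)))
    }
  }
  if (length(fired_cell)) {
    if (anyDuplicated(fired_cell)) {
      # uniform draw among fired rules: shuffle, keep first per cell
      ord <- sample.int(length(fired_cell))
      keep <- !duplicated(fired_cell[ord])
      fired_cell <- fired_cell[ord][keep]
      fired_target <- fired_target[ord][keep]
    }
    grid$cells[fired_cell] <- fired_target
  }
  grid
}

#' Run a business-as-usual scenario
#'
#' Applies [apply_transition_step()] \code{n_iterations} times and records
#' every intermediate landscape.  Iteration k draws from its own RNG
#' substream seeded with \code{(seed + 1664525 * k) mod (2^31 - 1)}, so
#' extending a run never perturbs earlier iterations.
#'
#' @param grid baseline \code{landscape_grid}.
#' @param mask a \code{zone_mask}.
#' @param rs a \code{ruleset}.
#' @param n_iterations number of CA iterations (>= 0); one iteration
#'   represents \code{rs$years_per_iteration} years.
#' @param seed integer root seed.
#' @return An object of class \code{scenario_result} with elements
#'   \code{baseline}, \code{snapshots} (list, names \code{"0"} ...
#'   \code{"n"}), \code{mask}, \code{ruleset}, \code{seed}.
#' @export
run_scenario <- function(grid, mask, rs, n_iterations, seed = 1L) {
  if (n_iterations < 0) stop("n_iterations must be >= 0", call. = FALSE)
  check_aligned(grid, mask)
  snaps <- vector("list", n_iterations + 1L)
  names(snaps) <- as.character(0:n_iterations)
  snaps[[1L]] <- grid
  cur <- grid
  for (k in seq_len(n_iterations)) {
    iter_seed <- (as.double(seed) + 1664525 * k) %% 2147483647
    cur <- with_seed(as.integer(iter_seed),
                     apply_transition_step(cur, mask, rs))
    snaps[[k + 1L]] <- cur
  }
  structure(list(baseline = grid, snapshots = snaps, mask = mask,
                 ruleset = rs, seed = as.integer(seed)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario_result: '%s', %d iterations (%g years), seed %d\n",
              x$ruleset$name, length(x$snapshots) - 1L,
              iterations_to_years(length(x$snapshots) - 1L,
                                  x$ruleset$years_per_iteration),
              x$seed))
  invisible(x)
}

#' @export
summary.scenario_result <- function(object, ...) {
  ks <- as.integer(names(object$snapshots))
  area_change_table(object, ks[ks > 0])
}

#' @export
plot.scenario_result <- function(x, classes = NULL, ...) {
  ks <- as.integer(names(x$snapshots))
  cb <- x$baseline$codebook
  sh <- sapply(x$snapshots, function(g) area_shares(g)$share)
  rownames(sh) <- cb$name
  if (is.null(classes)) classes <- cb$name
  cols <- grDevices::hcl.colors(length(classes), "Dark 3")
  graphics::matplot(ks, t(sh[classes, , drop = FALSE]), type = "b", pch = 16,
                    col = cols, lty = 1, xlab = "iteration",
                    ylab = "area share (%)",
                    main = paste("Scenario:", x$ruleset$name), ...)
  graphics::legend("topleft", legend = classes, col = cols, lty = 1,
                   cex = 0.7, bg = "white")
  invisible(x)
}

#' Convert CA iterations to simulated years
#'
#' One iteration represents five years by convention, so 10 iterations
#' simulate 50 years.
#'
#' @param k iteration count (>= 0).
#' @param years_per_iteration years per iteration (default 5).
#' @return \code{years_per_iteration * k}.
#' @export
iterations_to_years <- function(k, years_per_iteration = 5) {
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  years_per_iteration * k
}
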