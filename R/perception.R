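# Stakeholder perception data: elicited ecosystem-service scores per LULC
# class, service relevance ratings, elicited transition probabilities, and
# the raw material behind the two indirect services (expert Delphi rounds for
# soil-quality regulation, species counts for the diversity indicator).

#' Stakeholder perception dataset
#'
#' Container for elicited data before standardization: per (class, service)
#' indicator scores with their unit (\code{"pct"} for 0-100 percentage
#' indicators, \code{"likert5"} for 0-5 capacity ratings), mean service
#' relevance ratings (0-5), elicited transition probabilities (percent), and
#' optionally expert Delphi rounds and per-class species counts used to
#' derive the indirect services.
#'
#' @param es_scores data frame with columns \code{class_id}, \code{service_id},
#'   \code{value}, \code{unit}.
#' @param relevance named numeric vector, service id -> mean relevance (0-5).
#' @param transition_probs data frame with columns \code{scenario},
#'   \code{source}, \code{target}, \code{probability_pct},
#'   \code{neighborhood_min}, \code{allowed_zones}.
#' @param expert_rounds optional data frame with columns \code{expert},
#'   \code{class_id}, \code{value} (final Delphi round, 0-100) for
#'   soil-quality regulation.
#' @param species_counts optional data frame with columns \code{class_id},
#'   \code{species}, \code{count} for the diversity indicator.
#' @return An object of class \code{perception_dataset}.
#' @export
perception_dataset <- function(es_scores, relevance, transition_probs,
                               expert_rounds = NULL, species_counts = NULL) {
  stopifnot(all(c("class_id", "service_id", "value", "unit") %in% names(es_scores)))
  lik <- es_scores$unit == "likert5"
  if (any(es_scores$value[lik] < 0 | es_scores$value[lik] > 5))
    stop("likert5 scores must lie in [0, 5]", call. = FALSE)
  if (any(es_scores$value[!lik] < 0 | es_scores$value[!lik] > 100))
    stop("pct scores must lie in [0, 100]", call. = FALSE)
  if (any(relevance < 0 | relevance > 5))
    stop("relevance ratings must lie in [0, 5]", call. = FALSE)
  p <- transition_probs$probability_pct
  if (any(p < 0 | p > 100))
    stop("transition probabilities must lie in [0, 100]", call. = FALSE)
  structure(list(es_scores = es_scores, relevance = relevance,
                 transition_probs = transition_probs,
                 expert_rounds = expert_rounds,
                 species_counts = species_counts),
            class = "perception_dataset")
}

#' @export
print.perception_dataset <- function(x, ...) {
  cat(sprintf("perception_dataset: %d elicited scores, %d services, %d transition rules\n",
              nrow(x$es_scores), length(x$relevance), nrow(x$transition_probs)))
  invisible(x)
}

#' Generate or load a perception dataset
#'
#' \code{mode = "paper_defaults"} loads the packaged synthetic workshop
#' dataset: percentage-type indicator scores for food, marketable products
#' and fuelwood; expert Delphi rounds for soil-quality regulation; per-class
#' species counts for the diversity indicator; service relevance ratings; and
#' the elicited transition probabilities (cropland/shrubland/palm to rubber
#' at 85/90/60 percent, to settlement at 50/90/50 percent).
#' \code{mode = "random"} draws a seeded random dataset satisfying the type
#' invariants, for property tests.
#'
#' @param seed integer seed (used by \code{"random"} mode).
#' @param mode \code{"paper_defaults"} or \code{"random"}.
#' @param codebook,catalog codebook and service catalog the dataset covers.
#' @return A \code{perception_dataset}.
#' @export
generate_perception_dataset <- function(seed = 1L, mode = c("paper_defaults", "random"),
                                        codebook = default_codebook(),
                                        catalog = default_services()) {
  if (!is.character(mode) || !all(mode %in% c("paper_defaults", "random")))
    stop("unknown perception dataset mode", call. = FALSE)
  mode <- match.arg(mode)
  ext <- function(f) system.file("extdata", f, package = "landesca", mustWork = TRUE)
  if (mode == "paper_defaults") {
    es <- utils::read.csv(ext("perception_scores_synthetic.csv"),
                          stringsAsFactors = FALSE)
    rel <- utils::read.csv(ext("service_relevance_synthetic.csv"),
                           stringsAsFactors = FALSE)
    trans <- rbind(utils::read.csv(ext("ruleset_rubber.csv"), stringsAsFactors = FALSE),
                   utils::read.csv(ext("ruleset_settlement.csv"), stringsAsFactors = FALSE))
    rounds <- utils::read.csv(ext("delphi_soil_rounds_synthetic.csv"),
                              stringsAsFactors = FALSE)
    spcounts <- utils::read.csv(ext("species_counts_synthetic.csv"),
                                stringsAsFactors = FALSE)
    perception_dataset(es, stats::setNames(rel$relevance, rel$service_id),
                       trans, expert_rounds = rounds, species_counts = spcounts)
  } else {
    with_seed(seed, {
      grid <- expand.grid(class_id = codebook$class_id,
                          service_id = catalog$service_id,
                          stringsAsFactors = FALSE)
      es <- data.frame(grid,
                       value = sample(0:5, nrow(grid), replace = TRUE),
                       unit = "likert5", stringsAsFactors = FALSE)
      rel <- stats::setNames(stats::runif(nrow(catalog), 4, 5), catalog$service_id)
      src <- sample(codebook$class_id, 3)
      tgt <- sample(setdiff(codebook$class_id, src), 1)
      trans <- data.frame(scenario = "random",
                          source = src, target = tgt,
                          probability_pct = round(stats::runif(3, 0, 100)),
                          neighborhood_min = 1L,
                          allowed_zones = "WEST;EAST;CORRIDOR",
                          stringsAsFactors = FALSE)
      perception_dataset(es, rel, trans)
    })
  }
}
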