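test_that("Likert standardization anchors 0->0, 5->100 and is linear", {
  expect_equal(normalize_likert(0), 0)
  expect_equal(normalize_likert(5), 100)
  expect_equal(normalize_likert(3), 60)
  expect_equal(normalize_likert(c(1, 2.5)), c(20, 50))
  expect_error(normalize_likert(-1), "0, 5")
  expect_error(normalize_likert(6), "0, 5")
})

test_that("Shannon-Wiener index matches closed forms and a term-by-term oracle", {
  expect_equal(shannon_index(c(A = 10)), 0)
  expect_equal(shannon_index(c(A = 5, B = 5)), log(2))
  # hand oracle: -sum p_i ln p_i term by term
  counts <- c(A = 5, B = 3, C = 2)
  p <- counts / 10
  expect_equal(shannon_index(counts), -(p[1]*log(p[1]) + p[2]*log(p[2]) + p[3]*log(p[3])),
               ignore_attr = TRUE)
  set.seed(4)
  for (i in 1:20) {
    cnt <- stats::rpois(sample(2:12, 1), 8) + 1
    oracle <- 0
    for (x in cnt) oracle <- oracle - (x / sum(cnt)) * log(x / sum(cnt))
    expect_equal(shannon_index(cnt), oracle, tolerance = 1e-12)
    expect_lte(shannon_index(cnt), log(length(cnt)) + 1e-12)
    # independent library cross-check
    expect_equal(shannon_index(cnt), unname(vegan::diversity(cnt, "shannon")),
                 tolerance = 1e-12)
    # equal abundances maximize H for fixed richness
    expect_gte(shannon_index(rep(10, length(cnt))) + 1e-12, shannon_index(cnt))
  }
  expect_error(shannon_index(numeric(0)), "empty")
  expect_error(shannon_index(c(2, 0)), "positive")
  # configurable base
  expect_equal(shannon_index(c(5, 5), base = 2), 1)
})

test_that("packaged assessment matrix satisfies the elicited ordinal structure", {
  m <- default_es_matrix()
  cb <- default_codebook()
  v <- function(nm, svc) unclass(m)[as.character(default_ids()[[nm]]), svc]
  # cropland tops food and soil-quality regulation
  expect_equal(which.max(unclass(m)[, "food"]),
               which(rownames(m) == as.character(default_ids()[["Cropland"]])),
               ignore_attr = TRUE)
  expect_equal(which.max(unclass(m)[, "soil_quality"]),
               which(rownames(m) == as.character(default_ids()[["Cropland"]])),
               ignore_attr = TRUE)
  # settlement and rubber: no food, no species diversity
  expect_equal(v("Settlement", "food"), 0)
  expect_equal(v("Rubber plantations", "food"), 0)
  expect_equal(v("Settlement", "species_diversity"), 0)
  expect_equal(v("Rubber plantations", "species_diversity"), 0)
  # rubber tops marketable products, palm then cropland next
  mk <- unclass(m)[, "marketable"]
  expect_equal(names(sort(mk, decreasing = TRUE))[1:3],
               as.character(default_ids()[c("Rubber plantations",
                                            "Palm vegetation", "Cropland")]),
               ignore_attr = TRUE)
  # wetland tops fuelwood; forest tops species diversity with cropland second
  expect_equal(which.max(unclass(m)[, "fuelwood"]),
               which(rownames(m) == as.character(default_ids()[["Wetlands"]])),
               ignore_attr = TRUE)
  sp <- unclass(m)[, "species_diversity"]
  expect_equal(names(sort(sp, decreasing = TRUE))[1:2],
               as.character(default_ids()[c("Forest", "Cropland")]),
               ignore_attr = TRUE)
  # settlement and waterbody: no soil-quality regulation
  expect_equal(v("Settlement", "soil_quality"), 0)
  expect_equal(v("Waterbody", "soil_quality"), 0)
  expect_true(all(unclass(m) >= 0 & unclass(m) <= 100))
})

test_that("matrix building normalizes by unit and reports missing pairs", {
  cb <- toy_codebook(1:2, c("A", "B"))
  cat <- service_catalog(c("s1", "s2"), c("S1", "S2"))
  es <- data.frame(class_id = c(1, 1, 2, 2), service_id = c("s1", "s2", "s1", "s2"),
                   value = c(5, 80, 0, 40), unit = c("likert5", "pct", "likert5", "pct"))
  p <- perception_dataset(es, c(s1 = 4.5, s2 = 4.5),
                          data.frame(scenario = "x", source = 1, target = 2,
                                     probability_pct = 50, neighborhood_min = 1,
                                     allowed_zones = "WEST"))
  m <- build_es_matrix(p, cb, cat)
  expect_equal(unclass(m)["1", "s1"], 100)  # likert 5 -> 100
  expect_equal(unclass(m)["1", "s2"], 80)   # pct passes through
  expect_equal(unclass(m)["2", "s1"], 0)

  # all-zero perception gives an all-zero matrix
  es0 <- transform(es, value = 0)
  m0 <- build_es_matrix(perception_dataset(es0, c(s1 = 4, s2 = 4),
                                           p$transition_probs), cb, cat)
  expect_true(all(unclass(m0) == 0))

  es_miss <- es[-2, ]
  expect_error(build_es_matrix(perception_dataset(es_miss, c(s1 = 4, s2 = 4),
                                                  p$transition_probs), cb, cat),
               "missing pair")
})

test_that("Delphi rounds and species counts feed the indirect services", {
  p <- generate_perception_dataset(mode = "paper_defaults")
  m <- default_es_matrix()
  # soil column equals the mean of final-round expert scores
  agg <- tapply(p$expert_rounds$value, as.character(p$expert_rounds$class_id), mean)
  expect_equal(unclass(m)[names(agg), "soil_quality"], as.numeric(agg),
               ignore_attr = TRUE)
  # species column is Shannon rescaled by the cross-class maximum
  h <- tapply(p$species_counts$count, as.character(p$species_counts$class_id),
              shannon_index)
  expect_equal(unclass(m)[names(h), "species_diversity"],
               as.numeric(100 * h / max(h)), ignore_attr = TRUE)
  expect_equal(max(unclass(m)[, "species_diversity"]), 100)
})

test_that("landscape scores equal a per-cell oracle and respect bounds", {
  brute_scores <- function(grid, m) {
    v <- unclass(m)
    cells <- grid$cells[!is.na(grid$cells)]
    out <- numeric(ncol(v))
    for (s in seq_len(ncol(v))) {
      acc <- 0
      for (cell in cells) acc <- acc + v[as.character(cell), s]
      out[s] <- acc / length(cells)
    }
    stats::setNames(out, colnames(v))
  }
  cb <- toy_codebook()
  cat <- service_catalog("s", "S")
  vals <- matrix(c(100, 40, 60), 3, 1, dimnames = list(c("1", "2", "3"), "s"))
  m <- es_matrix(vals, cb, cat)
  expect_equal(landscape_es_scores(toy_grid(matrix(1L, 4, 4)), m), c(s = 100))
  expect_equal(landscape_es_scores(toy_grid(matrix(c(2L, 3L), 4, 4)), m), c(s = 50))

  set.seed(8)
  for (i in 1:100) {
    g <- random_toy_grid(sample(3:8, 1), sample(3:8, 1))
    vv <- matrix(runif(6, 0, 100), 3, 2,
                 dimnames = list(c("1", "2", "3"), c("s1", "s2")))
    mm <- es_matrix(vv, cb, service_catalog(c("s1", "s2"), c("a", "b")))
    sc <- landscape_es_scores(g, mm)
    expect_equal(sc, brute_scores(g, mm), tolerance = 1e-9)
    # bounded by the per-service min/max over classes
    expect_true(all(sc >= apply(vv, 2, min) - 1e-12))
    expect_true(all(sc <= apply(vv, 2, max) + 1e-12))
    # spatial permutation invariance
    gp <- toy_grid(matrix(sample(as.vector(g$cells)), nrow(g$cells)))
    expect_equal(landscape_es_scores(gp, mm), sc, tolerance = 1e-12)
    # linearity in the matrix
    mm2 <- es_matrix(vv * 0.5, cb, service_catalog(c("s1", "s2"), c("a", "b")))
    expect_equal(landscape_es_scores(g, mm2), sc * 0.5, tolerance = 1e-9)
  }

  bad <- es_matrix(vals[1:2, , drop = FALSE],
                   toy_codebook(1:2, c("A", "B")), cat)
  expect_error(landscape_es_scores(toy_grid(matrix(3L, 2, 2)), bad), "missing classes")
})

test_that("service maps carry per-cell capacities consistent with the scores", {
  cb <- toy_codebook(1:2, c("A", "B"))
  cat <- service_catalog("s", "S")
  m <- es_matrix(matrix(c(40, 60), 2, 1, dimnames = list(c("1", "2"), "s")), cb, cat)
  gu <- landscape_grid(matrix(1L, 3, 3), codebook = cb)
  expect_true(all(es_map(gu, m, "s") == 40))
  # checkerboard: exactly two distinct values, mean equals the landscape score
  chk <- landscape_grid(outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1L),
                        codebook = cb)
  emap <- es_map(chk, m, "s")
  expect_equal(sort(unique(as.vector(emap))), c(40, 60))
  expect_equal(mean(emap), unname(landscape_es_scores(chk, m)["s"]))
  expect_error(es_map(gu, m, "nope"), "unknown service")
})

test_that("matrix CSV round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  m <- default_es_matrix()
  write_es_matrix(m, f)
  m2 <- read_es_matrix(f)
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE, tolerance = 1e-9)
})
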