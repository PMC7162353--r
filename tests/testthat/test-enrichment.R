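test_that("normalization total-sum scales compartments to a common depth", {
  mat <- compartment_matrix(c("a", "b"),
                            LAV = c(600, 400), mouth = c(1500, 500))
  prof <- make_profile(mat)
  norm <- normalize_counts(prof, target_depth = 1000)
  expect_equal(unname(norm$counts[, "LAV"]), c(600, 400))
  expect_equal(unname(norm$counts[, "mouth"]), c(750, 250))
  ## already-equal totals with target = median are unchanged
  eq <- normalize_counts(make_profile(mat[, c(1, 1)] |>
    (\(m) {colnames(m) <- c("LAV", "mouth"); m})()))
  expect_equal(eq$counts[, "LAV"], mat[, "LAV"])
  ## random fixture: all totals equal the target within 1e-6
  big <- make_profile(compartment_matrix(
    sprintf("s%02d", 1:30),
    LAV = withr::with_seed(1, rpois(30, 80)),
    throat = withr::with_seed(2, rpois(30, 50)),
    mouth = withr::with_seed(3, rpois(30, 120)),
    nose = withr::with_seed(4, rpois(30, 20))))
  bn <- normalize_counts(big)
  expect_true(all(abs(colSums(bn$counts) - bn$target_depth) < 1e-6))
  expect_equal(bn$target_depth,
               stats::median(colSums(big$counts)))
})

test_that("compartment differencing subtracts mouth and nose from lavage", {
  mat <- compartment_matrix(c("a", "b", "c"),
                            LAV = c(400, 100, 50),
                            throat = c(250, 100, 75),
                            mouth = c(100, 100, 100),
                            nose = c(50, 100, 200))
  prof <- make_profile(mat, normalized = TRUE, target_depth = 550)
  d <- compartment_differences(prof)
  expect_equal(d$d_mouth, c(300, 0, -50))
  expect_equal(d$d_nose, c(350, 0, -150))
  ## identical compartments give all-zero differences
  same <- make_profile(mat[, c(1, 1, 1, 1)] |>
    (\(m) {colnames(m) <- c("LAV", "throat", "mouth", "nose"); m})(),
    normalized = TRUE)
  expect_true(all(compartment_differences(same)$d_mouth == 0))
  ## antisymmetry under swapping the operand compartments
  swapped <- make_profile(mat[, c(3, 2, 1, 4)] |>
    (\(m) {colnames(m) <- c("LAV", "throat", "mouth", "nose"); m})(),
    normalized = TRUE)
  expect_equal(compartment_differences(swapped)$d_mouth, -d$d_mouth)
  ## participants missing an outer compartment are excluded
  expect_error(compartment_differences(
    make_profile(mat[, c("LAV", "mouth")], normalized = TRUE)),
    "lacks compartment")
  expect_error(compartment_differences(make_profile(mat)), "normalized")
})

test_that("enrichment is the conjunction of both differences over the threshold", {
  d <- data.frame(species = c("a", "b", "c", "d"),
                  d_mouth = c(300, 100, 200, 151),
                  d_nose = c(200, 400, 150, 152),
                  stringsAsFactors = FALSE)
  res <- classify_enriched(d, threshold = 150)
  expect_identical(res$enriched, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$margin, c(50, -50, 0, 1))
  ## threshold monotonicity: raising it never enlarges the set
  withr::with_seed(10, {
    dd <- data.frame(species = sprintf("s%03d", 1:200),
                     d_mouth = rnorm(200, 0, 200),
                     d_nose = rnorm(200, 0, 200))
    prev <- classify_enriched(dd, 1)$enriched
    for (thr in c(50, 150, 300, 600)) {
      cur <- classify_enriched(dd, thr)$enriched
      expect_true(all(prev | !cur))    # cur subset of prev
      prev <- cur
    }
  })
  expect_error(classify_enriched(transform(d, d_mouth = Inf)), "finite")
})

test_that("enriched set equals a brute-force enumeration on small profiles", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      k <- sample(1:10, 1)
      mat <- compartment_matrix(sprintf("sp%02d", seq_len(k)),
                                LAV = runif(k, 0, 800),
                                mouth = runif(k, 0, 500),
                                nose = runif(k, 0, 500))
      prof <- make_profile(mat, normalized = TRUE)
      res <- classify_enriched(compartment_differences(prof), 150)
      ## direct enumeration of the definition, species by species
      oracle <- vapply(seq_len(k), function(i)
        (mat[i, "LAV"] - mat[i, "mouth"]) > 150 &&
        (mat[i, "LAV"] - mat[i, "nose"]) > 150, logical(1))
      expect_identical(res$enriched, oracle)
    }
  })
})

test_that("gradient classification orders lavage, throat and outer pool", {
  mk <- function(lav, throat, outer) {
    mat <- compartment_matrix("sp", LAV = lav, throat = throat,
                              mouth = outer, nose = outer)
    make_profile(mat, normalized = TRUE)
  }
  expect_identical(unname(gradient_classify(mk(500, 300, 90))), "inside_out")
  expect_identical(unname(gradient_classify(mk(50, 200, 350))), "outside_in")
  expect_identical(unname(gradient_classify(mk(100, 100, 100))), "flat")
  expect_identical(unname(gradient_classify(mk(100, 300, 100))), "discordant")
  ## epsilon widens the flat band
  expect_identical(unname(gradient_classify(mk(105, 100, 96), epsilon = 10)),
                   "flat")
  expect_identical(unname(gradient_classify(mk(121, 110, 99), epsilon = 10)),
                   "inside_out")
  ## missing throat: undetermined with a warning
  noth <- make_profile(compartment_matrix("sp", LAV = 10, mouth = 5, nose = 5),
                       normalized = TRUE)
  expect_warning(cls <- gradient_classify(noth), "undetermined")
  expect_true(is.na(cls[["sp"]]))
})

test_that("post-normalization results are invariant to compartment rescaling", {
  cfg <- small_scenario(depth = 2000, seed = 61)
  truth <- build_scenario(cfg)
  sc <- sample_counts(truth, cfg)
  pid <- truth$participants$participant_id[1]
  prof <- participant_profile(sc$counts, sc$metadata, pid)
  scaled <- prof
  scaled$counts[, "mouth"] <- scaled$counts[, "mouth"] * 7.3
  n1 <- normalize_counts(prof, target_depth = 2000)
  n2 <- normalize_counts(scaled, target_depth = 2000)
  expect_equal(n1$counts, n2$counts, tolerance = 1e-12)
  expect_equal(classify_enriched(compartment_differences(n1), 150),
               classify_enriched(compartment_differences(n2), 150),
               tolerance = 1e-12)
  expect_identical(gradient_classify(n1), gradient_classify(n2))
})

test_that("enriched fraction is the percent of detected species", {
  expect_equal(enriched_fraction(rep("x", 5), 100), 5)
  expect_equal(enriched_fraction(character(), 200), 0)
  expect_equal(enriched_fraction(3, 60), 5)
  expect_error(enriched_fraction(3, 0), "detected")
})

test_that("heat-map matrix holds both differences for species passing anywhere", {
  d1 <- classify_enriched(data.frame(
    species = c("a", "b", "c"), d_mouth = c(400, 10, 200),
    d_nose = c(300, 20, 500), stringsAsFactors = FALSE), 150)
  d2 <- classify_enriched(data.frame(
    species = c("a", "b", "c"), d_mouth = c(-50, 160, 100),
    d_nose = c(-60, 170, 90), stringsAsFactors = FALSE), 150)
  hm <- heatmap_matrix(list(P1 = d1, P2 = d2))
  ## species a, b, c all pass in at least one participant
  expect_identical(sort(rownames(hm)), c("a", "b", "c"))
  ## per-cell recomputation
  expect_equal(hm["a", "P1.d_mouth"], 400)
  expect_equal(hm["a", "P2.d_nose"], -60)
  expect_equal(hm["b", "P2.d_mouth"], 160)
  ## row order: descending max difference, then name
  expect_identical(rownames(hm), c("c", "a", "b"))
  ## single participant, single species
  single <- heatmap_matrix(list(P1 = classify_enriched(data.frame(
    species = "only", d_mouth = 200, d_nose = 300), 150)))
  expect_identical(dim(single), c(1L, 2L))
  ## nothing passes -> empty matrix with warning
  expect_warning(empty <- heatmap_matrix(list(P1 = classify_enriched(
    data.frame(species = "a", d_mouth = 10, d_nose = 10), 150))),
    "no species")
  expect_identical(nrow(empty), 0L)
})

test_that("planted inside-out species are recovered on a scaled-down scenario", {
  cfg <- scenario_config(n_participants = 2, depth = 20000, effect_size = 5,
                         n_inside_out = 10, n_outside_in = 20,
                         contamination_rate = 0, off_window_fraction = 0,
                         infection_participants = character(), seed = 17)
  truth <- build_scenario(cfg)
  sc <- sample_counts(truth, cfg)
  results <- list()
  for (pid in truth$participants$participant_id) {
    prof <- normalize_counts(participant_profile(sc$counts, sc$metadata, pid))
    results[[pid]] <- classify_enriched(compartment_differences(prof), 150)
  }
  called <- unique(unlist(lapply(results, function(r) r$species[r$enriched])))
  planted <- truth$species$taxon_id[truth$species$is_lung_enriched]
  tp <- length(intersect(called, planted))
  expect_gte(tp / length(called), 0.9)    # precision
  expect_gte(tp / length(planted), 0.9)   # recall
})
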