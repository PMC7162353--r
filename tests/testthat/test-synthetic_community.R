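test_that("gradient construction puts the throat at the geometric midpoint", {
  cfg <- small_scenario()
  truth <- build_scenario(cfg)
  e <- cfg$effect_size
  io <- which(truth$species$gradient_class == "inside_out")[1]
  fl <- which(truth$species$gradient_class == "flat")[1]
  m <- truth$expected[[1]]
  ## renormalization cancels in the ratio against a flat reference species
  rel <- function(comp) m[io, comp] / m[fl, comp]
  expect_equal(rel("LAV") / rel("mouth"), e, tolerance = 1e-12)
  expect_equal(rel("throat") / rel("mouth"), sqrt(e), tolerance = 1e-12)
  oi <- which(truth$species$gradient_class == "outside_in")[1]
  rel_oi <- function(comp) m[oi, comp] / m[fl, comp]
  expect_equal(rel_oi("LAV") / rel_oi("mouth"), 1 / e, tolerance = 1e-12)
  expect_equal(rel_oi("throat") / rel_oi("mouth"), 1 / sqrt(e),
               tolerance = 1e-12)
})

test_that("all-flat scenarios have identical compartment vectors", {
  cfg <- small_scenario()
  cfg$gradient_class <- rep("flat", nrow(cfg$taxonomy))
  truth <- build_scenario(cfg)
  m <- truth$expected[[1]]
  for (comp in c("throat", "mouth", "nose"))
    expect_equal(unname(m[, comp]), unname(m[, "LAV"]), tolerance = 1e-12)
})

test_that("planted lung-enriched labels match the requested count", {
  cfg <- scenario_config(n_inside_out = 20, n_outside_in = 30, seed = 7,
                         infection_participants = character())
  truth <- build_scenario(cfg)
  expect_identical(sum(truth$species$is_lung_enriched), 20L)
  expect_identical(
    truth$species$is_lung_enriched,
    truth$species$gradient_class == "inside_out"
  )
})

test_that("expected proportions are simplex-valued and monotone per class", {
  truth <- build_scenario(scenario_config(seed = 2, depth = 1000))
  for (m in truth$expected)
    expect_true(all(abs(colSums(m) - 1) < 1e-9))
  ## monotonicity on a non-infected participant, strict at the ends
  healthy <- setdiff(truth$participants$participant_id,
                     truth$config$infection_participants)[1]
  m <- truth$expected[[healthy]]
  cls <- truth$species$gradient_class
  outer <- (m[, "mouth"] + m[, "nose"]) / 2
  io <- cls == "inside_out"
  expect_true(all(m[io, "LAV"] > m[io, "throat"]))
  expect_true(all(m[io, "throat"] > outer[io]))
  oi <- cls == "outside_in"
  expect_true(all(m[oi, "LAV"] < m[oi, "throat"]))
  expect_true(all(m[oi, "throat"] < outer[oi]))
})

test_that("infection displacement reallocates the stated lavage mass", {
  cfg <- scenario_config(seed = 4, depth = 1000)
  truth <- build_scenario(cfg)
  inf_pid <- cfg$infection_participants[1]
  inf_set <- truth$species$genus %in% cfg$infection_genera
  m <- truth$expected[[inf_pid]]
  expect_equal(sum(m[inf_set, "LAV"]), cfg$infection_mass, tolerance = 1e-9)
  expect_equal(sum(m[, "LAV"]), 1, tolerance = 1e-9)
  ## non-lavage compartments are untouched
  healthy <- setdiff(truth$participants$participant_id,
                     cfg$infection_participants)[1]
  expect_equal(m[, "mouth"], truth$expected[[healthy]][, "mouth"])
})

test_that("read sampling is depth-exact and byte-deterministic", {
  cfg <- small_scenario(depth = 1000)
  cfg$contamination_rate <- 0
  truth <- build_scenario(cfg)
  rr1 <- sample_reads(truth, cfg, seed = 42)
  rr2 <- sample_reads(truth, cfg, seed = 42)
  expect_identical(rr1, rr2)
  expect_identical(
    unname(table(rr1$hits$sample_id)[rr1$metadata$sample_id] |> as.integer()),
    rep(1000L, nrow(rr1$metadata)))
  rr3 <- sample_reads(truth, cfg, seed = 43)
  expect_false(identical(rr1$hits, rr3$hits))
  expect_error(sample_reads(truth, cfg, seed = -1), "seed")
})

test_that("zero depth gives an empty sample, not an error", {
  cfg <- small_scenario(depth = 0)
  truth <- build_scenario(cfg)
  rr <- sample_reads(truth, cfg)
  expect_identical(nrow(rr$hits), 0L)
})

test_that("empirical compartment ratios track the planted truth", {
  cfg <- scenario_config(n_participants = 1, depth = 50000, effect_size = 4,
                         n_inside_out = 10, n_outside_in = 0,
                         contamination_rate = 0, off_window_fraction = 0,
                         infection_participants = character(), seed = 9)
  truth <- build_scenario(cfg)
  sc <- sample_counts(truth, cfg)
  cnt <- sc$counts$counts
  sid <- function(comp) paste0(truth$participants$participant_id[1], "_", comp)
  ## most abundant planted inside-out species: Monte-Carlo ratio within 10%
  io <- truth$species$taxon_id[truth$species$gradient_class == "inside_out"]
  s <- io[which.max(truth$species$base_abundance[
    match(io, truth$species$taxon_id)])]
  m <- truth$expected[[1]]
  emp_ratio <- (cnt[s, sid("LAV")] / sum(cnt[, sid("LAV")])) /
    mean(c(cnt[s, sid("mouth")] / sum(cnt[, sid("mouth")]),
           cnt[s, sid("nose")] / sum(cnt[, sid("nose")])))
  truth_ratio <- m[s, "LAV"] / mean(m[s, c("mouth", "nose")])
  expect_lt(abs(emp_ratio / truth_ratio - 1), 0.1)

  ## convergence: >= 99% of species within 3 SE of the expected proportion
  depth <- cfg$depth
  c0 <- cfg$concentration
  infl <- if (is.finite(c0)) (depth + c0) / (1 + c0) else 1
  ok <- 0; tot <- 0
  for (comp in COMPARTMENTS) {
    p <- m[, comp]
    se <- sqrt(p * (1 - p) * infl / depth)
    phat <- cnt[truth$species$taxon_id, sid(comp)] / sum(cnt[, sid(comp)])
    within <- abs(phat - p) <= pmax(3 * se, 1.5 / depth)
    ok <- ok + sum(within); tot <- tot + length(within)
  }
  expect_gte(ok / tot, 0.99)
})

test_that("contamination diverts the configured read fraction to reagent taxa", {
  cfg <- small_scenario(depth = 20000, seed = 31)
  cfg$contamination_rate <- 0.01
  truth <- build_scenario(cfg)
  sc <- sample_counts(truth, cfg)
  reag <- cfg$reagent_taxonomy$taxon_id
  frac <- sum(sc$counts$counts[reag, ]) / sum(sc$counts$counts)
  expect_lt(abs(frac - 0.01), 0.005)
  ## depth conserved per library
  expect_true(all(colSums(sc$counts$counts) == 20000))
})

test_that("kitome pairing matches its Poisson design", {
  cfg <- scenario_config(depth = 41135, seed = 1,
                         taxonomy = default_taxonomy(44),
                         n_inside_out = 4, n_outside_in = 8,
                         n_participants = 2,
                         infection_participants = character())
  kp0 <- kitome_pair(cfg, neg_rate = 0, seed = 1)
  expect_identical(nrow(kp0$negative), 0L)
  kp <- kitome_pair(cfg, neg_rate = 0.0003, seed = 1)
  lam <- 0.0003 * 41135
  interval <- qpois(c(0.005, 0.995), lam)
  expect_gte(nrow(kp$negative), interval[1])
  expect_lte(nrow(kp$negative), interval[2])
  expect_true(all(kp$negative$taxon_id %in% cfg$reagent_taxonomy$taxon_id))
  expect_identical(nrow(kp$positive), 41135L)
})

test_that("scenario validation rejects inconsistent configurations", {
  cfg <- small_scenario()
  tax <- cfg$taxonomy
  tax$genus[2] <- "SomewhereElse"   # same species name under two genera
  tax$species[2] <- tax$species[1]
  expect_error(scenario_config(taxonomy = tax), "inconsistent taxonomy")
  expect_error(scenario_config(effect_size = 1), "effect_size")
  expect_error(scenario_config(contamination_rate = 0.7,
                               off_window_fraction = 0.5),
               "must be < 1")
  bad <- cfg
  bad$base_abundance <- rep(1, nrow(cfg$taxonomy))
  expect_error(validate_scenario_config(bad), "sum to 1")
})

test_that("concentration calibration reproduces the target replicate CV", {
  depth <- 50000; count <- 100
  c0 <- calibrate_concentration(depth, cv = 0.12, count = count)
  p <- count / depth
  cv <- sqrt((1 - p) * (depth + c0) / (depth * p * (1 + c0)))
  expect_equal(cv, 0.12, tolerance = 1e-10)
  ## at or below the multinomial floor there is nothing to calibrate
  expect_identical(calibrate_concentration(depth, cv = 0.09, count = 100), Inf)
})
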