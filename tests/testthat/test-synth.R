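test_that("simulators are pure functions of (params, seed)", {
  fpp <- fingerprint_sim_params(profile_length = 200L, n_bands = 10L,
                                seed = 11L)
  expect_identical(simulate_fingerprints(fpp), simulate_fingerprints(fpp))
  opp <- otu_sim_params(n_otus = 30L, seed = 11L)
  expect_identical(simulate_otu_table(opp), simulate_otu_table(opp))
  gpp <- growth_sim_params(seed = 11L)
  expect_identical(simulate_growth(gpp), simulate_growth(gpp))
  expect_identical(simulate_qpcr(seed = 11L), simulate_qpcr(seed = 11L))
})

test_that("zero noise and zero shift give identical lanes, Pearson = 1", {
  fp <- simulate_fingerprints(fingerprint_sim_params(
    within_group_noise_sd = 0, between_group_band_shift = 0,
    profile_length = 200L, n_bands = 10L, seed = 3L))
  expect_equal(nrow(fp$intensity), 8L)
  for (i in 2:8) expect_equal(fp$intensity[i, ], fp$intensity[1, ],
                              ignore_attr = TRUE)
  S <- pearson_similarity(fp)$S
  expect_equal(max(abs(S - 1)), 0, tolerance = 1e-12)
})

test_that("group divergence separates within from between similarity", {
  # large shift, small noise: within-group Pearson exceeds between-group
  # Pearson in >= 95% of 100 seeded runs (checked with the package's own
  # similarity computation)
  hits <- vapply(1:100, function(s) {
    fp <- simulate_fingerprints(fingerprint_sim_params(
      between_group_band_shift = 0.8, within_group_noise_sd = 0.05,
      profile_length = 300L, n_bands = 15L, seed = s))
    S <- pearson_similarity(fp)$S
    m <- rdsoil:::pair_masks(fp$group)
    mean(S[m$within]) > mean(S[m$between])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fingerprint param invariants are enforced", {
  expect_error(fingerprint_sim_params(reps_per_group = 1L), "reps_per_group")
  expect_error(fingerprint_sim_params(profile_length = 50L, n_bands = 10L),
               "profile_length")
  expect_error(fingerprint_sim_params(within_group_noise_sd = -1), "noise")
  expect_error(fingerprint_sim_params(band_width = 0), "band_width")
})

test_that("OTU counts sum to depth within the configured range", {
  p <- otu_sim_params(n_otus = 40L, seed = 8L)
  tb <- simulate_otu_table(p)
  depths <- rowSums(tb$counts)
  expect_true(all(depths >= 4228 & depths <= 10005))
  rel <- relative_abundance(tb)
  expect_equal(rowSums(rel), rep(1, nrow(rel)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(nrow(tb$counts), 24L)  # 2 soils x 3 treatments x 4 reps
})

test_that("single-OTU table has 100% relative abundance everywhere", {
  p <- otu_sim_params(n_otus = 1L, depth_range = c(100L, 200L), seed = 2L)
  tb <- simulate_otu_table(p)
  expect_equal(as.numeric(relative_abundance(tb)), rep(1, nrow(tb$counts)))
})

test_that("empty responder_spec gives a null model centred on zero", {
  # per-OTU difference of group means (Con vs H50 within one soil),
  # averaged over 200 seeded tables, is centred on 0
  n_otus <- 20L
  diffs <- matrix(NA_real_, 200L, n_otus)
  for (s in 1:200) {
    tb <- simulate_otu_table(otu_sim_params(
      groups = data.frame(soil = "Kle", treatment = c("Con", "H50")),
      n_otus = n_otus, depth_range = c(500L, 1000L),
      overdispersion = 100, seed = s))
    rel <- relative_abundance(tb)
    con <- colMeans(rel[tb$metadata$treatment == "Con", , drop = FALSE])
    h50 <- colMeans(rel[tb$metadata$treatment == "H50", , drop = FALSE])
    diffs[s, ] <- con - h50
  }
  m <- colMeans(diffs)
  se <- apply(diffs, 2L, sd) / sqrt(nrow(diffs))
  # grand mean across OTUs is a tighter summary than per-OTU bands
  expect_lt(abs(mean(m)), 3 * mean(se))
  expect_gt(mean(abs(m) < 3 * se), 0.9)
})

test_that("responder effects are applied to the right group only", {
  spec <- data.frame(otu = 3L, soil = "Kle", treatment = "H50",
                     effect = 10)
  p <- otu_sim_params(groups = one_soil_groups(), n_otus = 10L,
                      base_composition = "uniform",
                      depth_range = c(5000L, 5000L),
                      overdispersion = 5000, responder_spec = spec,
                      seed = 4L)
  tb <- simulate_otu_table(p)
  rel <- relative_abundance(tb)
  h50 <- mean(rel[tb$metadata$treatment == "H50", 3])
  con <- mean(rel[tb$metadata$treatment == "Con", 3])
  expect_gt(h50 / con, 5)  # 10x effect, generous margin
  expect_error(otu_sim_params(n_otus = 5L, responder_spec = data.frame(
    otu = 9L, soil = "Kle", treatment = "H50", effect = 2)), "out of range")
  expect_error(otu_sim_params(n_otus = 5L, responder_spec = data.frame(
    otu = 2L, soil = "Kle", treatment = "H50", effect = 0)), "effect")
})

test_that("taxonomy covers every OTU and parses back from disk", {
  tb <- simulate_otu_table(otu_sim_params(n_otus = 25L, seed = 6L))
  expect_setequal(tb$taxonomy$otu_id, colnames(tb$counts))
  dir <- tempfile(); dir.create(dir)
  write_otu_table(tb, file.path(dir, "c.tsv"), file.path(dir, "t.tsv"),
                  file.path(dir, "m.tsv"))
  tb2 <- read_otu_table(file.path(dir, "c.tsv"), file.path(dir, "t.tsv"),
                        file.path(dir, "m.tsv"))
  expect_equal(tb2$counts, tb$counts)
  expect_equal(tb2$taxonomy, tb$taxonomy)
  expect_equal(tb2$metadata, tb$metadata)
})

test_that("mothur-style confidence suffixes are stripped on read", {
  tax <- rdsoil:::parse_lineages(
    "Otu001",
    "Bacteria(100);Firmicutes(98);Bacilli(95);Bacillales(90);Bacillaceae(80);Bacillus(77);")
  expect_equal(tax$genus, "Bacillus")
  expect_equal(tax$domain, "Bacteria")
  short <- rdsoil:::parse_lineages("Otu002", "Bacteria;Acidobacteria")
  expect_equal(short$genus, "unclassified")
})

test_that("growth simulator honours degenerate and deterministic contracts", {
  means <- default_means <- rdsoil:::default_growth_means()
  sds0 <- rdsoil:::default_growth_sds()
  sds0[, c("SL", "SFM", "SDM", "RDM")] <- 0
  g <- simulate_growth(growth_sim_params(group_means = means,
                                         group_sds = sds0, n_plants = 3L,
                                         seed = 1L))
  for (i in seq_len(nrow(means))) {
    rows <- g$soil == means$soil[i] & g$treatment == means$treatment[i]
    expect_equal(unique(g$SDM[rows]), means$SDM[i])
  }
  expect_error(growth_sim_params(group_means = transform(means, SDM = -1)),
               "positive")
})

test_that("planted biomass effects are detected by Dunnett (power check)", {
  # reference means/SDs for the Kle groups as planted truth, n = 10:
  # both treated groups flagged vs control in >= 90% of 100 seeded runs
  means <- rdsoil:::default_growth_means()
  sds <- rdsoil:::default_growth_sds()
  kle <- means$soil == "Kle"
  hits <- vapply(1:100, function(s) {
    g <- simulate_growth(growth_sim_params(group_means = means[kle, ],
                                           group_sds = sds[kle, ],
                                           n_plants = 10L, seed = s))
    dn <- dunnett_vs_control(g$SDM, g$treatment, "Con")
    all(dn$p_adj < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
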