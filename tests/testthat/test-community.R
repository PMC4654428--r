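test_that("aggregation conserves sample totals and pools lineages", {
  tb <- tiny_otu_table()
  phy <- aggregate_taxa(tb, "phylum")
  expect_equal(ncol(phy$counts), 2L)
  expect_equal(rowSums(phy$counts), rowSums(tb$counts))
  # two OTUs sharing a genus lineage sum
  tb2 <- tb
  tb2$taxonomy$genus <- c("G1", "G1", "G3", "unclassified")
  tb2$taxonomy$family <- c("F1", "F1", "F2", "unclassified")
  tb2 <- otu_table(tb2$counts, tb2$taxonomy, tb2$metadata)
  gen <- aggregate_taxa(tb2, "genus")
  g1 <- grep("G1$", colnames(gen$counts))
  expect_equal(gen$counts[, g1], tb$counts[, 1] + tb$counts[, 2])
  # domain-level aggregation on an all-Bacteria table: totals
  dom <- aggregate_taxa(tb, "domain")
  expect_equal(ncol(dom$counts), 1L)
  expect_equal(as.numeric(dom$counts), as.numeric(rowSums(tb$counts)))
  expect_error(aggregate_taxa(tb, "species"), "unknown level")
})

test_that("unclassified OTUs are pooled per parent lineage, not globally", {
  counts <- rbind(s1 = c(10, 20, 30), s2 = c(5, 10, 15))
  colnames(counts) <- paste0("Otu", 1:3)
  tax <- data.frame(otu_id = paste0("Otu", 1:3), domain = "Bacteria",
                    phylum = c("P1", "P2", "P2"),
                    class = "unclassified", order = "unclassified",
                    family = "unclassified", genus = "unclassified",
                    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("s1", "s2"), soil = "A",
                     treatment = "Con", replicate = 1:2,
                     stringsAsFactors = FALSE)
  tb <- otu_table(counts, tax, meta)
  gen <- aggregate_taxa(tb, "genus")
  # unclassified under P1 and under P2 stay separate taxa
  expect_equal(ncol(gen$counts), 2L)
  expect_equal(as.numeric(gen$counts["s1", ]), c(10, 50))
})

test_that("relative abundance and transform follow the closed forms", {
  tb <- tiny_otu_table()
  rel <- relative_abundance(tb)
  expect_equal(rowSums(rel), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rel["A_Con_1", "Otu1"], 0.5)
  tr <- transform_abundance(tb)
  expect_equal(tr["A_Con_1", "Otu1"], log10(51), tolerance = 1e-12)
  # zero count -> 0; full sample -> log10(101)
  counts <- rbind(s1 = c(100, 0), s2 = c(50, 50))
  tax <- data.frame(otu_id = c("a", "b"), domain = "Bacteria", phylum = "P",
                    class = "C", order = "O", family = "F",
                    genus = c("G1", "G2"), stringsAsFactors = FALSE)
  colnames(counts) <- c("a", "b")
  meta <- data.frame(sample_id = c("s1", "s2"), soil = "A",
                     treatment = "Con", replicate = 1:2,
                     stringsAsFactors = FALSE)
  tr2 <- transform_abundance(otu_table(counts, tax, meta))
  expect_equal(tr2["s1", "b"], 0)
  expect_equal(tr2["s1", "a"], log10(101))
  expect_equal(tr2["s2", "a"], log10(51))
})

test_that("transform is strictly increasing in n/N", {
  frac <- seq(0, 1, by = 0.05)
  vals <- log10(frac * 100 + 1)
  expect_true(all(diff(vals) > 0))
})

test_that("dominance filter applies an inclusive threshold", {
  # three taxa at 50%, 1%, 0.5% mean relative abundance
  counts <- rbind(s1 = c(985, 10, 5), s2 = c(985, 10, 5))
  colnames(counts) <- c("big", "edge", "rare")
  tax <- data.frame(otu_id = colnames(counts), domain = "Bacteria",
                    phylum = c("P1", "P2", "P3"), class = "C", order = "O",
                    family = "F", genus = c("G1", "G2", "G3"),
                    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("s1", "s2"), soil = "A",
                     treatment = "Con", replicate = 1:2,
                     stringsAsFactors = FALSE)
  rel <- relative_abundance(otu_table(counts, tax, meta))
  expect_setequal(dominant_taxa(rel, threshold = 1), c("big", "edge"))
  expect_setequal(dominant_taxa(rel, threshold = 0),
                  c("big", "edge", "rare"))
})

test_that("aggregate-then-relative equals relative-then-sum of children", {
  tb <- simulate_otu_table(otu_sim_params(n_otus = 30L, seed = 12L))
  rel_agg <- relative_abundance(aggregate_taxa(tb, "phylum"))
  rel <- relative_abundance(tb)
  pref <- apply(tb$taxonomy[, c("domain", "phylum")], 1L, paste,
                collapse = ";")
  summed <- t(rowsum(t(unclass(rel)), factor(pref, levels = unique(pref))))
  expect_equal(unclass(rel_agg), summed[, colnames(rel_agg)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rarefaction expectation matches hand binomials and edge depths", {
  # counts (2,1), d = 2: 2 - [C(1,2)/C(3,2) + C(2,2)/C(3,2)] = 5/3
  expect_equal(rarefaction_curve(c(2, 1), 2)$expected_otus, 5 / 3,
               tolerance = 1e-12)
  counts <- c(5, 3, 2, 1, 1)
  N <- sum(counts)
  expect_equal(rarefaction_curve(counts, N)$expected_otus, 5)
  expect_equal(rarefaction_curve(counts, 1)$expected_otus, 1)
  expect_error(rarefaction_curve(counts, N + 1), "depths")
})

test_that("rarefaction curves are nondecreasing, concave, and match MC", {
  set.seed(30)
  counts <- as.numeric(rmultinom(1, 800, prob = c(50, 20, 10, 5, 5, 3, 3,
                                                  2, 1, 1)))
  depths <- seq_len(sum(counts))
  curve <- rarefaction_curve(counts, depths)$expected_otus
  expect_true(all(diff(curve) > -1e-12))
  expect_true(all(diff(diff(curve)) < 1e-9))
  # Monte-Carlo subsampling oracle at 5 random depths, 1000 draws each
  pool <- rep(seq_along(counts), counts)
  for (d in sample(depths, 5L)) {
    draws <- replicate(1000, length(unique(sample(pool, d))))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - curve[d]), 3 * se + 1e-6)
  }
})

test_that("rarefaction agrees with vegan's analytic implementation", {
  set.seed(31)
  counts <- as.numeric(rmultinom(1, 500, prob = runif(20)))
  counts <- counts[counts > 0]
  depths <- c(10, 50, 100, 250, 500)
  ours <- rarefaction_curve(counts, depths)$expected_otus
  vg <- suppressWarnings(
    as.numeric(vegan::rarefy(matrix(counts, 1), sample = depths)))
  expect_equal(ours, vg, tolerance = 1e-8)
})

test_that("inverse Simpson uses the unbiased finite-sample form", {
  expect_equal(invsimpson(c(2, 2, 1)), 5)
  expect_equal(invsimpson(c(7, 0, 0)), 1)        # single taxon
  expect_identical(invsimpson(c(1, 1, 1)), Inf)  # all singletons
  expect_error(invsimpson(c(1)), "N >= 2")
  # asymptotic agreement with plug-in 1 / sum(p^2): k even taxa -> k
  k <- 7
  big <- rep(1e4, k)
  expect_equal(invsimpson(big), k, tolerance = 0.01 * k)
})

test_that("diversity_table carries metadata and flags finite indices", {
  tb <- simulate_otu_table(otu_sim_params(n_otus = 40L, seed = 9L))
  div <- diversity_table(tb)
  expect_equal(nrow(div), nrow(tb$counts))
  expect_true(all(c("soil", "treatment", "invsimpson") %in% colnames(div)))
  expect_true(all(div$invsimpson > 1))
})

test_that("ordination_input keeps dominant, genus-classified taxa only", {
  tb <- tiny_otu_table()
  ord <- ordination_input(tb, threshold = 1)
  expect_true(all(ord$taxonomy$genus != "unclassified"))
  # Otu4 (unclassified genus) must not contribute
  expect_lt(sum(ord$counts), sum(tb$counts))
})
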