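test_that("anova_oneway matches oneway.test and the t^2 identity", {
  set.seed(41)
  v <- rnorm(18, rep(c(0, 1, 2), each = 6))
  g <- rep(c("a", "b", "c"), each = 6)
  ours <- anova_oneway(v, g)
  ref <- stats::oneway.test(v ~ factor(g), var.equal = TRUE)
  expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # two groups: F = t^2 of the pooled t-test
  v2 <- rnorm(12); g2 <- rep(c("x", "y"), each = 6)
  a2 <- anova_oneway(v2, g2)
  tt <- stats::t.test(v2[g2 == "x"], v2[g2 == "y"], var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-9)
  # all observations equal: F = 0, flagged p = 1
  a0 <- anova_oneway(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
  expect_equal(a0$flag, "degenerate_no_variance")
})

test_that("anova power: planted 5-SD shifts at n=4 yield p < 0.001", {
  # successive 5-SD group shifts; analytic power (noncentral F) is > 0.999
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    v <- c(rnorm(4, 0), rnorm(4, 5), rnorm(4, 10))
    anova_oneway(v, rep(c("a", "b", "c"), each = 4))$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("tukey_letters matches stats::TukeyHSD adjusted p-values", {
  set.seed(42)
  v <- rnorm(20, rep(c(0, 0.5, 2, 1), each = 5))
  g <- rep(c("a", "b", "c", "d"), each = 5)
  ours <- tukey_letters(v, g)
  ref <- stats::TukeyHSD(stats::aov(v ~ factor(g)))$`factor(g)`
  key <- paste(ours$pairs$group2, ours$pairs$group1, sep = "-")
  expect_equal(ours$pairs$p_adj, unname(ref[key, "p adj"]),
               tolerance = 1e-9)
})

test_that("compact letters follow the sharing rule", {
  # identical groups share a letter
  all_same <- tukey_letters(rep(c(1.0, 1.1), 6),
                            rep(c("a", "b", "c"), each = 4))
  expect_equal(unname(all_same$letters), rep("a", 3))
  # means 0, 0, 100 with SD 1, n = 4: a, a, b
  set.seed(43)
  v <- c(rnorm(4, 0), rnorm(4, 0), rnorm(4, 100))
  tl <- tukey_letters(v, rep(c("g1", "g2", "g3"), each = 4))
  expect_equal(unname(tl$letters), c("a", "a", "b"))
  # letters respect pairwise significance on random instances
  for (s in 1:20) {
    set.seed(s)
    v <- rnorm(16, rep(c(0, 1, 2, 3) * runif(1, 0, 3), each = 4))
    g <- rep(letters[1:4], each = 4)
    tl <- tukey_letters(v, g)
    for (r in seq_len(nrow(tl$pairs))) {
      l1 <- strsplit(tl$letters[[tl$pairs$group1[r]]], "")[[1]]
      l2 <- strsplit(tl$letters[[tl$pairs$group2[r]]], "")[[1]]
      shared <- length(intersect(l1, l2)) > 0
      expect_equal(shared, tl$pairs$p_adj[r] >= 0.05,
                   label = sprintf("seed %d pair %d", s, r))
    }
  }
})

test_that("tukey familywise type-I error is controlled near nominal", {
  # 3 groups, n = 4, single normal: familywise rate <= 0.07 at alpha 0.05
  set.seed(44)
  rejections <- vapply(1:2000, function(i) {
    v <- rnorm(12)
    tl <- tukey_letters(v, rep(c("a", "b", "c"), each = 4))
    any(tl$pairs$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(rejections), 0.07)
})

test_that("dunnett reduces to the two-sided t-test for k = 1", {
  set.seed(45)
  v <- rnorm(20, rep(c(0, 0.8), each = 10))
  g <- rep(c("Con", "T"), each = 10)
  dn <- dunnett_vs_control(v, g, "Con")
  tt <- stats::t.test(v[g == "T"], v[g == "Con"], var.equal = TRUE)
  expect_equal(dn$p_adj, tt$p.value, tolerance = 1e-6)
  expect_error(dunnett_vs_control(v, g, "Ctrl"), "not present")
})

test_that("dunnett adjusted p agrees with a Monte-Carlo null oracle", {
  # balanced k = 2, n = 10 (df = 27): P(max |T| > q) by direct simulation
  q <- 2.5; df <- 27
  set.seed(46)
  z <- matrix(rnorm(3 * 200000), ncol = 3)
  s <- sqrt(rchisq(200000, df) / df)
  t1 <- (z[, 1] - z[, 3]) / (sqrt(2) * s)
  t2 <- (z[, 2] - z[, 3]) / (sqrt(2) * s)
  emp <- mean(pmax(abs(t1), abs(t2)) > q)
  ours <- 1 - rdsoil:::dunnett_cdf(q, c(10, 10), 10, df)
  se <- sqrt(emp * (1 - emp) / 200000)
  expect_lt(abs(ours - emp), 4 * se)
})

test_that("dunnett flags a planted 3-SD shift with high power", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    v <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 3))
    g <- rep(c("Con", "T1", "T2"), each = 10)
    dn <- dunnett_vs_control(v, g, "Con")
    dn$p_adj[dn$treatment == "T2"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # treatment identical to control: p ~ 1
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("Con", "T"), each = 4)
  expect_gt(dunnett_vs_control(v, g, "Con")$p_adj, 0.99)
})

test_that("screen_responders classifies directions consistently", {
  tb <- simulate_otu_table(otu_sim_params(
    groups = one_soil_groups(), n_otus = 30L,
    depth_range = c(5000L, 5000L), overdispersion = 5000,
    base_composition = "uniform",
    responder_spec = data.frame(otu = c(2L, 7L), soil = "Kle",
                                treatment = c("H50", "Gamma"),
                                effect = c(6, 1 / 6)),
    seed = 47L))
  res <- screen_responders(tb, level = "otu", alpha = 0.05)
  expect_true(all(res$direction[res$treatment == "Con"] == "none"))
  r2 <- res[res$taxon == "Otu00002" & res$treatment == "H50", ]
  expect_equal(r2$direction, "increased")
  r7 <- res[res$taxon == "Otu00007" & res$treatment == "Gamma", ]
  expect_equal(r7$direction, "decreased")
  # letter/direction invariant on every row: direction != none requires no
  # shared letter with the control
  for (i in seq_len(nrow(res))) {
    if (res$direction[i] == "none") next
    ctrl <- res[res$soil == res$soil[i] & res$taxon == res$taxon[i] &
                res$treatment == "Con", ]
    expect_equal(length(intersect(strsplit(res$letter[i], "")[[1]],
                                  strsplit(ctrl$letter, "")[[1]])), 0L)
  }
  expect_true(all(res$level == "otu"))
})

test_that("all-zero taxa are skipped with a note", {
  tb <- tiny_otu_table()
  tb$counts[, "Otu3"] <- 0
  tb2 <- otu_table(tb$counts, tb$taxonomy, tb$metadata)
  expect_message(res <- screen_responders(tb2, level = "otu"),
                 "skipped 1")
  expect_false("Otu3" %in% res$taxon)
  expect_equal(attr(res, "skipped"), "A:Otu3")
})

test_that("diversity_compare separates planted soil differences", {
  set.seed(48)
  div <- data.frame(
    sample_id = paste0("s", 1:24),
    soil = rep(c("Kle", "Alv"), each = 12),
    treatment = rep(rep(c("Con", "H50", "Gamma"), each = 4), 2),
    replicate = rep(1:4, 6),
    invsimpson = c(rnorm(12, 40, 3), rnorm(12, 14, 2)),
    stringsAsFactors = FALSE)
  cmp <- diversity_compare(div)
  expect_lt(cmp$across$p_value, 0.001)
  expect_equal(nrow(cmp$within), 6L)
  # identical indices: one letter everywhere
  div$invsimpson <- 20
  cmp0 <- diversity_compare(div)
  expect_true(all(cmp0$within$letter == "a"))
})

test_that("qpcr comparison runs on the log10 scale per soil", {
  qp <- simulate_qpcr(group_means = data.frame(
    soil = rep("Kle", 3), treatment = c("Con", "H50", "Gamma"),
    log10_copies = c(9.0, 9.0, 8.0)), sd_log10 = 0.05, seed = 49L)
  res <- qpcr_compare(qp)
  expect_equal(nrow(res), 3L)
  gl <- res$letter[res$treatment == "Gamma"]
  cl <- res$letter[res$treatment == "Con"]
  expect_equal(length(intersect(strsplit(gl, "")[[1]],
                                strsplit(cl, "")[[1]])), 0L)
  expect_error(qpcr_compare(transform(qp, copies_per_g = -1)), "positive")
})
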