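#' Parameters for the fingerprint lane simulator
#'
#' The simulator emulates densitometric fingerprint lanes (DGGE-style): each
#' group owns a band template (Gaussian bumps on a small constant baseline);
#' replicates perturb band amplitudes and add pixel noise; groups diverge by
#' random band deletion, insertion and position jitter. Gel physics is not
#' modelled — only the Pearson-similarity structure whole-lane comparison
#' software operates on.
#'
#' @param n_groups Number of groups.
#' @param reps_per_group Replicates (lanes) per group, >= 2.
#' @param profile_length Intensity bins per lane (>= 10 * n_bands).
#' @param n_bands Bands in the shared template.
#' @param band_width Gaussian band width in bins (> 0).
#' @param within_group_noise_sd Relative amplitude / pixel noise SD (>= 0);
#'   0 makes replicate lanes identical.
#' @param between_group_band_shift Expected fraction of template bands
#'   gained, lost or moved per group (>= 0); 0 makes all groups identical.
#' @param group_labels Optional group label vector (default `group1..`).
#' @param seed Master seed; every draw is a pure function of it.
#' @return A `fingerprint_sim_params` list.
#' @export
fingerprint_sim_params <- function(n_groups = 2L, reps_per_group = 4L,
                                   profile_length = 500L, n_bands = 20L,
                                   band_width = 4, within_group_noise_sd = 0.1,
                                   between_group_band_shift = 0.3,
                                   group_labels = NULL, seed = 1L) {
  n_groups <- check_count(n_groups, "n_groups", 1L)
  reps_per_group <- check_count(reps_per_group, "reps_per_group", 2L)
  profile_length <- check_count(profile_length, "profile_length", 10L)
  n_bands <- check_count(n_bands, "n_bands", 1L)
  if (profile_length < 10L * n_bands) {
    stop("profile_length must be >= 10 * n_bands", call. = FALSE)
  }
  band_width <- check_pos(band_width, "band_width")
  within_group_noise_sd <- check_nonneg(within_group_noise_sd,
                                        "within_group_noise_sd")
  between_group_band_shift <- check_nonneg(between_group_band_shift,
                                           "between_group_band_shift")
  if (is.null(group_labels)) group_labels <- paste0("group", seq_len(n_groups))
  if (length(group_labels) != n_groups) {
    stop("group_labels must have length n_groups", call. = FALSE)
  }
  structure(list(n_groups = n_groups, reps_per_group = reps_per_group,
                 profile_length = profile_length, n_bands = n_bands,
                 band_width = band_width,
                 within_group_noise_sd = within_group_noise_sd,
                 between_group_band_shift = between_group_band_shift,
                 group_labels = as.character(group_labels),
                 seed = seed),
            class = "fingerprint_sim_params")
}

render_lane <- function(pos, amp, L, w, baseline = 0.05) {
  bins <- seq_len(L)
  y <- rep(baseline, L)
  for (b in seq_along(pos)) {
    y <- y + amp[b] * exp(-0.5 * ((bins - pos[b]) / w)^2)
  }
  y
}

#' Simulate a fingerprint lane set
#'
#' @param params A [fingerprint_sim_params()].
#' @return A [fingerprint_set()] with `n_groups * reps_per_group` lanes.
#' @examples
#' fp <- simulate_fingerprints(fingerprint_sim_params(seed = 42))
#' @export
simulate_fingerprints <- function(params) {
  stopifnot(inherits(params, "fingerprint_sim_params"))
  p <- params
  # shared template (substream 0)
  templ <- with_substream(p$seed, 0L, {
    list(pos = stats::runif(p$n_bands, 1 + 3 * p$band_width,
                            p$profile_length - 3 * p$band_width),
         amp = stats::runif(p$n_bands, 0.5, 1.5))
  })
  lanes <- list(); ids <- character(0); grp <- character(0)
  for (g in seq_len(p$n_groups)) {
    gt <- with_substream(p$seed, g, {
      pos <- templ$pos; amp <- templ$amp
      s <- p$between_group_band_shift
      if (s > 0) {
        fate <- stats::runif(length(pos))
        del <- fate < s / 3
        mov <- fate >= s / 3 & fate < 2 * s / 3
        pos[mov] <- pos[mov] + stats::rnorm(sum(mov), 0, 5 * p$band_width)
        pos <- pos[!del]; amp <- amp[!del]
        n_new <- stats::rpois(1, s * p$n_bands / 3)
        if (n_new > 0) {
          pos <- c(pos, stats::runif(n_new, 1 + 3 * p$band_width,
                                     p$profile_length - 3 * p$band_width))
          amp <- c(amp, stats::runif(n_new, 0.5, 1.5))
        }
      }
      noise <- p$within_group_noise_sd
      reps <- lapply(seq_len(p$reps_per_group), function(r) {
        a <- amp * pmax(1 + stats::rnorm(length(amp), 0, noise), 0)
        y <- render_lane(pos, a, p$profile_length, p$band_width)
        pmax(y + stats::rnorm(p$profile_length, 0, noise * 0.05), 0)
      })
      reps
    })
    for (r in seq_along(gt)) {
      lanes[[length(lanes) + 1L]] <- gt[[r]]
      ids <- c(ids, sprintf("%s_r%d", p$group_labels[g], r))
      grp <- c(grp, p$group_labels[g])
    }
  }
  fingerprint_set(do.call(rbind, lanes), ids, grp)
}

#' Parameters for the OTU table simulator
#'
#' Emulates a processed amplicon OTU table for a two-soil, three-treatment,
#' replicated biotest design: per sample, a composition is drawn from a
#' Dirichlet around the group's expected proportions (base composition with
#' multiplicative responder effects applied and renormalised) and counts
#' are multinomial at a depth uniform in `depth_range`. Default design and
#' depth range match the study system this generator stands in for
#' (2 soils x 3 treatments x 4 replicates; 4,228-10,005 classified
#' sequences per sample).
#'
#' @param groups data.frame with columns `soil` and `treatment`, one row per
#'   group; default the full 2 x 3 design (`Kle`/`Alv` x `Con`/`H50`/
#'   `Gamma`).
#' @param n_samples_per_group Replicates per group (default 4).
#' @param n_otus Number of OTUs (default 10000).
#' @param depth_range Integer pair, counts per sample drawn uniformly in it
#'   (default `c(4228, 10005)`).
#' @param base_composition Either a positive numeric vector of length
#'   `n_otus` (relative weights) or the name of a generator:
#'   `"logseries"` (default; geometric-series weights, few abundant and a
#'   long rare tail) or `"uniform"`.
#' @param responder_spec data.frame with columns `otu` (index), `soil`,
#'   `treatment`, `effect` (multiplier > 0 on the expected relative
#'   abundance in that group); default none.
#' @param overdispersion Dirichlet concentration scale (> 0); large =
#'   near-multinomial replicates, small = strong compositional noise.
#' @param otus_per_genus Average OTUs sharing a genus (default 3).
#' @param unclassified_frac Fraction of OTUs left unclassified at genus
#'   (default 0.15).
#' @param seed Master seed.
#' @return An `otu_sim_params` list.
#' @export
otu_sim_params <- function(groups = NULL, n_samples_per_group = 4L,
                           n_otus = 10000L, depth_range = c(4228L, 10005L),
                           base_composition = "logseries",
                           responder_spec = NULL, overdispersion = 200,
                           otus_per_genus = 3L, unclassified_frac = 0.15,
                           seed = 1L) {
  if (is.null(groups)) {
    groups <- expand.grid(treatment = c("Con", "H50", "Gamma"),
                          soil = c("Kle", "Alv"),
                          stringsAsFactors = FALSE)[, c("soil", "treatment")]
  }
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  stopifnot(all(c("soil", "treatment") %in% colnames(groups)))
  n_samples_per_group <- check_count(n_samples_per_group,
                                     "n_samples_per_group", 2L)
  n_otus <- check_count(n_otus, "n_otus", 1L)
  if (length(depth_range) != 2L || depth_range[1] > depth_range[2] ||
      depth_range[1] < 1) {
    stop("depth_range must be an increasing positive pair", call. = FALSE)
  }
  if (is.numeric(base_composition)) {
    if (length(base_composition) != n_otus || any(base_composition <= 0)) {
      stop("numeric base_composition must be positive of length n_otus",
           call. = FALSE)
    }
  } else if (!base_composition %in% c("logseries", "uniform")) {
    stop("base_composition must be numeric, 'logseries' or 'uniform'",
         call. = FALSE)
  }
  if (!is.null(responder_spec)) {
    responder_spec <- as.data.frame(responder_spec, stringsAsFactors = FALSE)
    stopifnot(all(c("otu", "soil", "treatment", "effect") %in%
                  colnames(responder_spec)))
    if (any(responder_spec$otu < 1 | responder_spec$otu > n_otus)) {
      stop("responder_spec otu index out of range", call. = FALSE)
    }
    if (any(responder_spec$effect <= 0)) {
      stop("responder effects must be > 0", call. = FALSE)
    }
  }
  overdispersion <- check_pos(overdispersion, "overdispersion")
  structure(list(groups = groups, n_samples_per_group = n_samples_per_group,
                 n_otus = n_otus, depth_range = as.integer(depth_range),
                 base_composition = base_composition,
                 responder_spec = responder_spec,
                 overdispersion = overdispersion,
                 otus_per_genus = check_count(otus_per_genus,
                                              "otus_per_genus", 1L),
                 unclassified_frac = check_nonneg(unclassified_frac,
                                                  "unclassified_frac"),
                 seed = seed),
            class = "otu_sim_params")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

synthetic_taxonomy <- function(n_otus, otus_per_genus, unclassified_frac,
                               seed) {
  with_substream(seed, 999L, {
    n_gen <- max(1L, ceiling(n_otus / otus_per_genus))
    n_phy <- max(2L, min(12L, ceiling(n_gen / 30L) + 3L))
    gen_phy <- sample.int(n_phy, n_gen, replace = TRUE)
    otu_gen <- rep(seq_len(n_gen), length.out = n_otus)
    phy <- sprintf("Phylum%02d", gen_phy[otu_gen])
    gen <- sprintf("Genus%05d", otu_gen)
    uncl <- stats::runif(n_otus) < unclassified_frac
    gen[uncl] <- "unclassified"
    df <- data.frame(
      otu_id = sprintf("Otu%05d", seq_len(n_otus)),
      domain = "Bacteria", phylum = phy,
      class = sub("Phylum", "Class", phy),
      order = sub("Phylum", "Order", phy),
      family = ifelse(gen == "unclassified", "unclassified",
                      sub("Genus", "Family", gen)),
      genus = gen, stringsAsFactors = FALSE)
    df
  })
}

#' Simulate an OTU table
#'
#' @param params An [otu_sim_params()].
#' @return An [otu_table()] with taxonomy and metadata attached.
#' @examples
#' tb <- simulate_otu_table(otu_sim_params(n_otus = 50, seed = 7))
#' @export
simulate_otu_table <- function(params) {
  stopifnot(inherits(params, "otu_sim_params"))
  p <- params
  base <- if (is.numeric(p$base_composition)) {
    p$base_composition / sum(p$base_composition)
  } else if (p$base_composition == "uniform") {
    rep(1 / p$n_otus, p$n_otus)
  } else {
    # geometric-series weights: a handful of dominant OTUs, long rare tail
    w <- 0.985^(seq_len(p$n_otus) - 1)
    w / sum(w)
  }
  counts <- NULL; meta <- NULL
  for (g in seq_len(nrow(p$groups))) {
    so <- p$groups$soil[g]; tr <- p$groups$treatment[g]
    expect <- base
    if (!is.null(p$responder_spec)) {
      hit <- p$responder_spec$soil == so & p$responder_spec$treatment == tr
      for (i in which(hit)) {
        expect[p$responder_spec$otu[i]] <-
          expect[p$responder_spec$otu[i]] * p$responder_spec$effect[i]
      }
      expect <- expect / sum(expect)
    }
    block <- with_substream(p$seed, g, {
      draws <- vapply(seq_len(p$n_samples_per_group), function(r) {
        depth <- sample(seq(p$depth_range[1], p$depth_range[2]), 1L)
        comp <- rdirichlet1(expect * p$overdispersion)
        as.numeric(stats::rmultinom(1L, depth, comp))
      }, numeric(p$n_otus))
      # vapply drops to a vector when n_otus == 1
      if (is.matrix(draws)) t(draws) else matrix(draws, ncol = 1L)
    })
    rownames(block) <- sprintf("%s%s_%d", so, tr,
                               seq_len(p$n_samples_per_group))
    counts <- rbind(counts, block)
    meta <- rbind(meta, data.frame(sample_id = rownames(block),
                                   soil = so, treatment = tr,
                                   replicate = seq_len(p$n_samples_per_group),
                                   stringsAsFactors = FALSE))
  }
  colnames(counts) <- sprintf("Otu%05d", seq_len(p$n_otus))
  tax <- synthetic_taxonomy(p$n_otus, p$otus_per_genus, p$unclassified_frac,
                            p$seed)
  otu_table(counts, tax, meta)
}

#' Parameters for the plant growth simulator
#'
#' Per plant and group, each trait (SL shoot length in cm, SFM shoot fresh
#' mass in g, SDM shoot dry mass in g, RDM root dry mass in g) is drawn from
#' a normal truncated at 0 with the group's mean and SD.
#'
#' @param group_means data.frame with columns `soil`, `treatment`, `SL`,
#'   `SFM`, `SDM`, `RDM` (positive means); default the biotest's printed
#'   biomass means with shoot lengths consistent with its growth curves.
#' @param group_sds Same shape, positive SDs (0 allowed for degenerate
#'   checks).
#' @param n_plants Plants per group (default 10).
#' @param seed Master seed.
#' @return A `growth_sim_params` list.
#' @export
growth_sim_params <- function(group_means = NULL, group_sds = NULL,
                              n_plants = 10L, seed = 1L) {
  if (is.null(group_means)) {
    group_means <- default_growth_means()
  }
  group_means <- as.data.frame(group_means, stringsAsFactors = FALSE)
  if (is.null(group_sds)) {
    group_sds <- default_growth_sds()
  }
  group_sds <- as.data.frame(group_sds, stringsAsFactors = FALSE)
  need <- c("soil", "treatment", "SL", "SFM", "SDM", "RDM")
  stopifnot(all(need %in% colnames(group_means)),
            all(need %in% colnames(group_sds)))
  traits <- c("SL", "SFM", "SDM", "RDM")
  if (any(as.matrix(group_means[, traits]) <= 0)) {
    stop("group means must be positive", call. = FALSE)
  }
  if (any(as.matrix(group_sds[, traits]) < 0)) {
    stop("group sds must be non-negative", call. = FALSE)
  }
  n_plants <- check_count(n_plants, "n_plants", 2L)
  structure(list(group_means = group_means, group_sds = group_sds,
                 n_plants = n_plants, seed = seed),
            class = "growth_sim_params")
}

# Printed biomass means of the reference biotest (SFM, SDM, RDM per group);
# SL chosen consistent with its reported relative shoot-length gains.
default_growth_means <- function() {
  data.frame(
    soil = rep(c("Kle", "Alv"), each = 3L),
    treatment = rep(c("Con", "H50", "Gamma"), 2L),
    SL = c(20, 36.2, 46.2, 12, 17.5, 17.8),
    SFM = c(4.3, 9.2, 12.7, 2.5, 6.2, 5.7),
    SDM = c(3.1, 4.5, 5.7, 1.5, 2.6, 2.3),
    RDM = c(2.7, 3.0, 3.1, 3.3, 3.4, 3.2),
    stringsAsFactors = FALSE)
}

default_growth_sds <- function() {
  data.frame(
    soil = rep(c("Kle", "Alv"), each = 3L),
    treatment = rep(c("Con", "H50", "Gamma"), 2L),
    SL = c(4, 5, 6, 3, 4, 4),
    SFM = c(1.2, 0.8, 1.5, 1.1, 2.4, 2.0),
    SDM = c(0.4, 0.3, 0.4, 0.4, 0.8, 0.6),
    RDM = c(0.6, 0.5, 0.5, 0.1, 0.2, 0.3),
    stringsAsFactors = FALSE)
}

#' Simulate a plant growth table
#'
#' @param params A [growth_sim_params()].
#' @return data.frame with one row per plant: `plant_id`, `soil`,
#'   `treatment`, `replicate`, `SL`, `SFM`, `SDM`, `RDM`.
#' @examples
#' g <- simulate_growth(growth_sim_params(seed = 3))
#' @export
simulate_growth <- function(params) {
  stopifnot(inherits(params, "growth_sim_params"))
  p <- params
  traits <- c("SL", "SFM", "SDM", "RDM")
  out <- list()
  for (g in seq_len(nrow(p$group_means))) {
    m <- p$group_means[g, ]
    key <- paste(m$soil, m$treatment, sep = "_")
    srow <- p$group_sds[p$group_sds$soil == m$soil &
                        p$group_sds$treatment == m$treatment, ]
    if (nrow(srow) != 1L) {
      stop(sprintf("group_sds must have exactly one row for %s", key),
           call. = FALSE)
    }
    vals <- with_substream(p$seed, g, {
      sapply(traits, function(tr) {
        rnorm_trunc0(p$n_plants, as.numeric(m[[tr]]), as.numeric(srow[[tr]]))
      })
    })
    vals <- matrix(vals, nrow = p$n_plants,
                   dimnames = list(NULL, traits))
    out[[g]] <- data.frame(
      plant_id = sprintf("%s_p%d", key, seq_len(p$n_plants)),
      soil = m$soil, treatment = m$treatment,
      replicate = seq_len(p$n_plants), vals,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate weekly shoot-length series
#'
#' Linear growth toward each group's final shoot length with week-to-week
#' noise; groups share the starting length, so treated and control series
#' diverge progressively — the shape weekly many-to-one testing expects.
#'
#' @param params A [growth_sim_params()] (`SL` is the week-`n_weeks` mean).
#' @param n_weeks Number of weekly measurements (default 8).
#' @param sl_start Common mean shoot length at week 1 (default 5 cm).
#' @return Long data.frame: `plant_id`, `soil`, `treatment`, `week`, `SL`.
#' @export
simulate_growth_series <- function(params, n_weeks = 8L, sl_start = 5) {
  stopifnot(inherits(params, "growth_sim_params"))
  p <- params
  n_weeks <- check_count(n_weeks, "n_weeks", 2L)
  out <- list()
  for (g in seq_len(nrow(p$group_means))) {
    m <- p$group_means[g, ]
    srow <- p$group_sds[p$group_sds$soil == m$soil &
                        p$group_sds$treatment == m$treatment, ]
    sl_sd <- as.numeric(srow$SL)
    weekly_mean <- sl_start + (as.numeric(m$SL) - sl_start) *
      (seq_len(n_weeks) - 1) / (n_weeks - 1)
    block <- with_substream(p$seed, 1000L + g, {
      do.call(rbind, lapply(seq_len(p$n_plants), function(pl) {
        sl <- rnorm_trunc0(n_weeks, weekly_mean,
                           sl_sd * seq_len(n_weeks) / n_weeks)
        sl <- cummax(sl)  # shoots do not shrink
        data.frame(plant_id = sprintf("%s_%s_p%d", m$soil, m$treatment, pl),
                   soil = m$soil, treatment = m$treatment,
                   week = seq_len(n_weeks), SL = sl,
                   stringsAsFactors = FALSE)
      }))
    })
    out[[g]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a qPCR 16S copy-number table
#'
#' Lognormal copy numbers around each group's mean log10 copies per gram
#' soil (soil communities sit around 1e9 copies/g).
#'
#' @param group_means data.frame: `soil`, `treatment`, `log10_copies`;
#'   default 9.0 for the standard 2 x 3 design.
#' @param sd_log10 Common SD on the log10 scale (default 0.15).
#' @param n_replicates Replicates per group (default 4).
#' @param seed Master seed.
#' @return data.frame: `sample_id`, `soil`, `treatment`, `replicate`,
#'   `copies_per_g`.
#' @export
simulate_qpcr <- function(group_means = NULL, sd_log10 = 0.15,
                          n_replicates = 4L, seed = 1L) {
  if (is.null(group_means)) {
    group_means <- expand.grid(treatment = c("Con", "H50", "Gamma"),
                               soil = c("Kle", "Alv"),
                               stringsAsFactors = FALSE)
    group_means$log10_copies <- 9.0
    group_means <- group_means[, c("soil", "treatment", "log10_copies")]
  }
  n_replicates <- check_count(n_replicates, "n_replicates", 2L)
  sd_log10 <- check_nonneg(sd_log10, "sd_log10")
  out <- list()
  for (g in seq_len(nrow(group_means))) {
    m <- group_means[g, ]
    v <- with_substream(seed, g, {
      stats::rnorm(n_replicates, m$log10_copies, sd_log10)
    })
    out[[g]] <- data.frame(
      sample_id = sprintf("%s%s_%d", m$soil, m$treatment,
                          seq_len(n_replicates)),
      soil = m$soil, treatment = m$treatment,
      replicate = seq_len(n_replicates),
      copies_per_g = 10^v, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a growth table as CSV
#' @param growth data.frame from [simulate_growth()] (or same layout).
#' @param path File path.
#' @export
write_growth <- function(growth, path) {
  utils::write.csv(growth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a growth table CSV
#' @param path File path.
#' @return data.frame.
#' @export
read_growth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
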