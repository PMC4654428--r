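#' Read a pipeline configuration
#'
#' YAML (when the yaml package is installed) or JSON. The configuration is a
#' nested list; see [run_pipeline()] for the recognised fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package not installed; supply a JSON config", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

default_config <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    output_dir = "rdsoil_output",
    stages = list(fingerprint = TRUE, diversity = TRUE, ordination = TRUE,
                  screen = TRUE, biotest = TRUE, qpcr = FALSE),
    permutations = list(n_mc = 999L, exhaustive_cap = 20000L),
    synth = list(
      fingerprint = list(n_groups = 2L, reps_per_group = 4L,
                         profile_length = 500L, n_bands = 20L,
                         band_width = 4, within_group_noise_sd = 0.1,
                         between_group_band_shift = 0.4,
                         group_labels = c("Con", "H50")),
      otu = list(n_otus = 500L, n_samples_per_group = 4L,
                 overdispersion = 200),
      growth = list(n_plants = 10L)
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data (or on
#' files named in the config), writes every stage report as TSV/CSV under
#' `output_dir`, and finishes with a JSON run manifest recording the seed,
#' the package version, the effective config and each stage's headline
#' statistics. Idempotent for a fixed seed: two runs produce identical
#' reports.
#'
#' Config fields (all optional, defaults in place): `seed`, `alpha`,
#' `output_dir`, `stages` (logical toggles `fingerprint`, `diversity`,
#' `ordination`, `screen`, `biotest`, `qpcr`), `permutations` (`n_mc`,
#' `exhaustive_cap`), `synth` (parameter lists for the generators), or
#' `inputs` with paths (`profiles`, `otu_counts`, `taxonomy`, `metadata`,
#' `growth`) to run on user data instead.
#'
#' @param config A config list, or a path accepted by [read_config()], or
#'   `NULL` for the defaults.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_config(), if (is.null(config)) list() else config)
  if (is.null(cfg$seed)) stop("seed is mandatory", call. = FALSE)
  seed <- as.integer(cfg$seed)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "rdsoil",
                   version = as.character(utils::packageVersion("rdsoil")),
                   seed = seed, alpha = cfg$alpha, stages = list())
  alpha <- cfg$alpha
  nmc <- cfg$permutations$n_mc
  cap <- cfg$permutations$exhaustive_cap

  # --- data: synthetic unless inputs are given -------------------------
  use_inputs <- !is.null(cfg$inputs)
  fp <- tb <- growth <- NULL
  if (use_inputs) {
    if (!is.null(cfg$inputs$profiles)) fp <- read_fingerprints(cfg$inputs$profiles)
    if (!is.null(cfg$inputs$otu_counts)) {
      tb <- read_otu_table(cfg$inputs$otu_counts, cfg$inputs$taxonomy,
                           cfg$inputs$metadata)
    }
    if (!is.null(cfg$inputs$growth)) growth <- read_growth(cfg$inputs$growth)
  } else {
    fpp <- do.call(fingerprint_sim_params,
                   c(cfg$synth$fingerprint, list(seed = seed)))
    fp <- simulate_fingerprints(fpp)
    opp <- do.call(otu_sim_params, c(cfg$synth$otu, list(seed = seed)))
    tb <- simulate_otu_table(opp)
    gpp <- do.call(growth_sim_params, c(cfg$synth$growth, list(seed = seed)))
    growth <- simulate_growth(gpp)
    write_fingerprints(fp, file.path(out_dir, "lanes.csv"))
    write_otu_table(tb, file.path(out_dir, "otu_counts.tsv"),
                    file.path(out_dir, "taxonomy.tsv"),
                    file.path(out_dir, "metadata.tsv"))
    write_growth(growth, file.path(out_dir, "growth.csv"))
  }

  if (isTRUE(cfg$stages$fingerprint) && !is.null(fp)) {
    sim <- pearson_similarity(fp)
    write_similarity(sim, file.path(out_dir, "similarity.tsv"))
    writeLines(upgma(sim)$newick, file.path(out_dir, "upgma.nwk"))
    rep <- d_test_report(fp, n_mc = nmc, seed = seed, exhaustive_cap = cap)
    utils::write.table(rep, file.path(out_dir, "d_test.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$stages$fingerprint <- list(
      comparisons = rep$comparison, d_value = rep$d_value,
      p_value = rep$p_value)
  }
  if (isTRUE(cfg$stages$diversity) && !is.null(tb)) {
    div <- diversity_table(tb)
    utils::write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    rc <- rarefaction_curves(tb)
    utils::write.table(rc, file.path(out_dir, "rarefaction.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    cmp <- diversity_compare(div, alpha = alpha)
    manifest$stages$diversity <- list(
      mean_invsimpson = mean(div$invsimpson[is.finite(div$invsimpson)]),
      across_soil_p = if (!is.null(cmp$across)) cmp$across$p_value else NULL)
  }
  if (isTRUE(cfg$stages$ordination) && !is.null(tb)) {
    ord_tb <- tryCatch(ordination_input(tb), error = function(e) tb)
    dm <- bray_curtis(transform_abundance(ord_tb))
    write_distance(dm, file.path(out_dir, "bray_curtis.tsv"))
    pc <- pcoa(dm, n_axes = min(3L, length(dm$ids) - 1L))
    write_pcoa(pc, file.path(out_dir, "pcoa.tsv"))
    an_soil <- anosim(dm, stats::setNames(ord_tb$metadata$soil,
                                          ord_tb$metadata$sample_id),
                      n_perm = nmc, seed = seed, exhaustive_cap = cap)
    an_treat <- anosim(dm, stats::setNames(ord_tb$metadata$treatment,
                                           ord_tb$metadata$sample_id),
                       n_perm = nmc, seed = seed,
                       block = stats::setNames(ord_tb$metadata$soil,
                                               ord_tb$metadata$sample_id),
                       exhaustive_cap = cap)
    an <- data.frame(factor = c("soil", "treatment|soil"),
                     design = c(an_soil$design, an_treat$design),
                     R = c(an_soil$R, an_treat$R),
                     p_value = c(an_soil$p_value, an_treat$p_value))
    utils::write.table(an, file.path(out_dir, "anosim.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$stages$ordination <- list(
      anosim_soil_R = an_soil$R, anosim_soil_p = an_soil$p_value,
      anosim_treatment_R = an_treat$R, anosim_treatment_p = an_treat$p_value,
      axis1_explained = pc$explained[1])
  }
  if (isTRUE(cfg$stages$screen) && !is.null(tb)) {
    res <- screen_responders(tb, level = "genus", alpha = alpha)
    utils::write.table(res, file.path(out_dir, "responders.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_responders(res, file.path(out_dir, "responders_wide.tsv"))
    manifest$stages$screen <- list(
      n_taxa_tested = length(unique(paste(res$soil, res$taxon))),
      n_responders = sum(res$direction != "none"))
  }
  if (isTRUE(cfg$stages$biotest) && !is.null(growth)) {
    rep <- biotest_report(growth, alpha = alpha)
    utils::write.table(rep, file.path(out_dir, "biotest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$stages$biotest <- list(
      groups = nrow(rep),
      max_sdm_pct_increase = suppressWarnings(
        max(rep$sdm_pct_increase, na.rm = TRUE)))
  }
  if (isTRUE(cfg$stages$qpcr)) {
    qp <- simulate_qpcr(seed = seed)
    qrep <- qpcr_compare(qp, alpha = alpha)
    utils::write.table(qrep, file.path(out_dir, "qpcr.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$stages$qpcr <- list(groups = nrow(qrep))
  }
  manifest$config <- cfg
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
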