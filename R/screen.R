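#' One-way fixed-effects ANOVA
#'
#' Classical decomposition into between- and within-group sums of squares.
#' When every group has zero variance and all group means are equal the F
#' statistic is taken as 0 with p = 1 and the result is flagged degenerate.
#'
#' @param values Numeric vector of observations.
#' @param group Group label per observation (>= 2 groups, >= 2 values each).
#' @return List with `F`, `p`, `df1`, `df2`, `ms_within`, `flag`.
#' @export
anova_oneway <- function(values, group) {
  group <- as.character(group)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  tab <- table(group)
  if (length(tab) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs >= 2 values", call. = FALSE)
  k <- length(tab)
  n <- length(values)
  gm <- tapply(values, group, mean)
  ss_b <- sum(tab * (gm - mean(values))^2)
  ss_w <- sum((values - gm[group])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ss_w == 0 && ss_b == 0) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2, ms_within = 0,
                flag = "degenerate_no_variance"))
  }
  if (ss_w == 0) {
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2, ms_within = 0,
                flag = "zero_within_variance"))
  }
  f <- (ss_b / df1) / (ss_w / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ms_within = ss_w / df2, flag = NULL)
}

# Insert-and-absorb compact letter display. `signif_pairs` is a logical
# k x k matrix (TRUE = significantly different). Groups sharing a letter are
# not significantly different. Letters follow group input order.
compact_letters <- function(signif_pairs) {
  k <- nrow(signif_pairs)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!isTRUE(signif_pairs[i, j])) next
      hit <- vapply(sets, function(s) i %in% s && j %in% s, logical(1))
      if (!any(hit)) next
      new_sets <- list()
      for (idx in seq_along(sets)) {
        s <- sets[[idx]]
        if (hit[idx]) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- character(k)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) {
      letters_out[g] <- paste0(letters_out[g], letters[s])
    }
  }
  letters_out
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' All pairwise comparisons using the studentized range distribution with
#' the pooled within-group variance (Tukey-Kramer for unequal sizes), plus a
#' compact letter display (insert-and-absorb): groups sharing a letter do
#' not differ at `alpha`. Letters are assigned in group input order.
#'
#' @inheritParams anova_oneway
#' @param alpha Familywise significance level (default 0.05).
#' @return List with `letters` (named by group, input order), `pairs`
#'   (data.frame: group1, group2, diff, p_adj), `means`, `sds`, `anova`.
#' @export
tukey_letters <- function(values, group, alpha = 0.05) {
  group <- as.character(group)
  glev <- unique(group)
  a <- anova_oneway(values, group)
  k <- length(glev)
  ni <- as.vector(table(factor(group, levels = glev)))
  mi <- tapply(values, factor(group, levels = glev), mean)
  si <- tapply(values, factor(group, levels = glev), stats::sd)
  pairs <- utils::combn(k, 2L)
  p_adj <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(a$ms_within / 2 * (1 / ni[i] + 1 / ni[j]))
    if (se == 0) {
      return(if (mi[i] == mi[j]) 1 else 0)
    }
    q <- abs(mi[i] - mi[j]) / se
    stats::ptukey(q, nmeans = k, df = a$df2, lower.tail = FALSE)
  })
  sig <- matrix(FALSE, k, k)
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    sig[i, j] <- sig[j, i] <- p_adj[c] < alpha
  }
  lets <- compact_letters(sig)
  names(lets) <- glev
  list(letters = lets,
       pairs = data.frame(group1 = glev[pairs[1, ]],
                          group2 = glev[pairs[2, ]],
                          diff = mi[pairs[1, ]] - mi[pairs[2, ]],
                          p_adj = p_adj, stringsAsFactors = FALSE,
                          row.names = NULL),
       means = mi, sds = si, anova = a)
}

# P(max_j |T_j| <= q) for the many-to-one comparison statistics
# T_j = (Xbar_j - Xbar_0) / (S sqrt(1/n_j + 1/n_0)), computed by integrating
# out the shared control variate Z0 and the pooled scale S ~ sqrt(chi2_nu/nu).
dunnett_cdf <- function(q, n_treat, n_control, df) {
  if (q <= 0) return(0)
  a <- sqrt((1 / n_treat) / (1 / n_treat + 1 / n_control))
  b <- sqrt((1 / n_control) / (1 / n_treat + 1 / n_control))
  # finite limits: the normal / chi factors are < 1e-30 beyond them, and
  # integrate() on doubly-infinite ranges can miss mass at loose tolerances
  g <- function(u) {
    inner <- function(z) {
      prod_terms <- rep(1, length(z))
      for (j in seq_along(a)) {
        prod_terms <- prod_terms *
          (stats::pnorm((u + b[j] * z) / a[j]) -
           stats::pnorm((-u + b[j] * z) / a[j]))
      }
      stats::dnorm(z) * prod_terms
    }
    stats::integrate(inner, -12, 12, rel.tol = 1e-10)$value
  }
  f <- function(s) {
    dens <- exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
                (df - 1) * log(pmax(s, 1e-300)) - df * s^2 / 2)
    gv <- vapply(s, function(si) g(q * si), numeric(1))
    dens * gv
  }
  s_hi <- max(12, 1 + 12 / sqrt(2 * df))
  stats::integrate(f, 0, s_hi, rel.tol = 1e-9)$value
}

#' Dunnett many-to-one comparisons with a control
#'
#' Two-sided Dunnett test of each treatment mean against the control mean,
#' with the familywise adjustment computed by numeric integration of the
#' equicoordinate multivariate-t probability (exact for any balanced or
#' unbalanced one-way layout). With a single treatment it reduces to the
#' ordinary two-sided pooled t-test.
#'
#' @inheritParams anova_oneway
#' @param control Name of the control group (must be present).
#' @return data.frame: `treatment`, `estimate` (mean difference vs control),
#'   `t`, `p_adj`.
#' @export
dunnett_vs_control <- function(values, group, control) {
  group <- as.character(group)
  glev <- unique(group)
  if (!control %in% glev) {
    stop(sprintf("control group '%s' not present", control), call. = FALSE)
  }
  a <- anova_oneway(values, group)
  treats <- setdiff(glev, control)
  ni <- table(factor(group, levels = glev))
  mi <- tapply(values, factor(group, levels = glev), mean)
  n0 <- as.numeric(ni[control])
  nt <- as.numeric(ni[treats])
  est <- mi[treats] - mi[control]
  se <- sqrt(a$ms_within * (1 / nt + 1 / n0))
  tstat <- ifelse(se == 0, ifelse(est == 0, 0, Inf * sign(est)), est / se)
  p_adj <- vapply(tstat, function(tt) {
    if (!is.finite(tt)) return(if (tt == 0) 1 else 0)
    1 - dunnett_cdf(abs(tt), nt, n0, a$df2)
  }, numeric(1))
  p_adj <- pmin(pmax(p_adj, 0), 1)
  data.frame(treatment = treats, estimate = as.numeric(est),
             t = as.numeric(tstat), p_adj = p_adj,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-taxon treatment-responder screen
#'
#' The screen behind the responder tables: per soil and per taxon at
#' `level`, abundances are transformed (`log10(n/N*100 + 1)`), compared
#' across treatments by one-way ANOVA with Tukey HSD compact letters, and
#' each treatment is classified against the control: `increased` /
#' `decreased` when it shares no letter with the control, else `none`.
#' Taxa with all-zero counts within a soil are skipped. No correction is
#' applied across taxa (the familywise control is within taxon); set
#' `across_taxa_fdr = TRUE` for an optional Benjamini-Hochberg filter on the
#' per-taxon ANOVA p-values.
#'
#' @param table An [otu_table()].
#' @param level Taxonomic rank (see [tax_levels()]) or `"otu"`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param control Control treatment label (default `"Con"`).
#' @param across_taxa_fdr Apply BH across taxa to the ANOVA p-values and
#'   blank out directions of taxa that fail it (default FALSE).
#' @return data.frame, one row per (soil, taxon, treatment): `soil`,
#'   `taxon`, `phylum`, `genus`, `level`, `treatment`, `mean_rel_pct`,
#'   `sd_rel_pct`, `mean_transformed`, `sd_transformed`, `letter`,
#'   `direction`, `p_anova`. Sorted by soil, phylum, genus.
#' @export
screen_responders <- function(table, level = "genus", alpha = 0.05,
                              control = "Con", across_taxa_fdr = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  agg <- aggregate_taxa(table, level)
  soils <- unique(agg$metadata$soil)
  out <- list()
  skipped <- character(0)
  for (so in soils) {
    keep <- agg$metadata$soil == so
    cts <- agg$counts[keep, , drop = FALSE]
    treat <- agg$metadata$treatment[keep]
    if (!control %in% treat) {
      stop(sprintf("control '%s' missing in soil %s", control, so),
           call. = FALSE)
    }
    tr_mat <- log10(cts / rowSums(cts) * 100 + 1)
    rel_mat <- cts / rowSums(cts) * 100
    for (tx in colnames(cts)) {
      if (all(cts[, tx] == 0)) {
        skipped <- c(skipped, paste0(so, ":", tx))
        next
      }
      tl <- tukey_letters(tr_mat[, tx], treat, alpha = alpha)
      lets <- tl$letters
      mt <- tapply(tr_mat[, tx], factor(treat, levels = names(lets)), mean)
      st <- tapply(tr_mat[, tx], factor(treat, levels = names(lets)),
                   stats::sd)
      mr <- tapply(rel_mat[, tx], factor(treat, levels = names(lets)), mean)
      sr <- tapply(rel_mat[, tx], factor(treat, levels = names(lets)),
                   stats::sd)
      dir <- vapply(names(lets), function(tr) {
        if (tr == control) return("none")
        shared <- any(strsplit(lets[[tr]], "")[[1]] %in%
                      strsplit(lets[[control]], "")[[1]])
        if (shared) return("none")
        if (mt[[tr]] > mt[[control]]) "increased" else "decreased"
      }, character(1))
      irow <- match(tx, agg$taxonomy$otu_id)
      out[[length(out) + 1L]] <- data.frame(
        soil = so, taxon = tx,
        phylum = agg$taxonomy$phylum[irow],
        genus = agg$taxonomy$genus[irow],
        level = level, treatment = names(lets),
        mean_rel_pct = as.numeric(mr), sd_rel_pct = as.numeric(sr),
        mean_transformed = as.numeric(mt), sd_transformed = as.numeric(st),
        letter = as.character(lets), direction = dir,
        p_anova = tl$anova$p, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$soil, res$phylum, res$genus, res$taxon), ]
  rownames(res) <- NULL
  if (across_taxa_fdr) {
    key <- paste(res$soil, res$taxon)
    p1 <- res$p_anova[!duplicated(key)]
    adj <- stats::p.adjust(p1, method = "BH")
    fail <- key %in% paste(res$soil, res$taxon)[!duplicated(key)][adj >= alpha]
    res$direction[fail] <- "none"
  }
  if (length(skipped)) {
    message(sprintf("skipped %d all-zero taxon/soil combinations", length(skipped)))
    attr(res, "skipped") <- skipped
  }
  res
}

#' Compare diversity indices across treatments and soils
#'
#' Within each soil, Tukey letters across treatments on the inverse Simpson
#' index; across soils, a pooled two-sample t-test on the per-sample
#' indices.
#'
#' @param div A [diversity_table()] data.frame.
#' @param alpha Significance level (default 0.05).
#' @return List with `within` (data.frame: soil, treatment, mean, sd,
#'   letter) and `across` (data.frame: soil1, soil2, t, p_value).
#' @export
diversity_compare <- function(div, alpha = 0.05) {
  soils <- unique(div$soil)
  within <- do.call(rbind, lapply(soils, function(so) {
    d <- div[div$soil == so, ]
    tl <- tukey_letters(d$invsimpson, d$treatment, alpha = alpha)
    data.frame(soil = so, treatment = names(tl$letters),
               mean = as.numeric(tl$means), sd = as.numeric(tl$sds),
               letter = as.character(tl$letters),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  across <- NULL
  if (length(soils) >= 2L) {
    prs <- utils::combn(soils, 2L, simplify = FALSE)
    across <- do.call(rbind, lapply(prs, function(pr) {
      x <- div$invsimpson[div$soil == pr[1]]
      y <- div$invsimpson[div$soil == pr[2]]
      if (stats::sd(c(x, y)) == 0) {
        # constant data: identical soils, no evidence of a difference
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- stats::t.test(x, y, var.equal = TRUE)
      }
      data.frame(soil1 = pr[1], soil2 = pr[2],
                 t = unname(tt$statistic), p_value = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(within = within, across = across)
}

#' Compare qPCR 16S copy numbers across treatments
#'
#' Copy numbers span orders of magnitude, so the analysis runs on the log10
#' scale: per soil, one-way ANOVA with Tukey letters across treatments.
#'
#' @param qpcr data.frame with columns `sample_id`, `soil`, `treatment`,
#'   `copies_per_g` (> 0).
#' @param alpha Significance level (default 0.05).
#' @return data.frame: soil, treatment, mean_log10, sd_log10, letter,
#'   p_anova.
#' @export
qpcr_compare <- function(qpcr, alpha = 0.05) {
  if (any(qpcr$copies_per_g <= 0)) {
    stop("copy numbers must be positive", call. = FALSE)
  }
  soils <- unique(qpcr$soil)
  do.call(rbind, lapply(soils, function(so) {
    d <- qpcr[qpcr$soil == so, ]
    v <- log10(d$copies_per_g)
    tl <- tukey_letters(v, d$treatment, alpha = alpha)
    data.frame(soil = so, treatment = names(tl$letters),
               mean_log10 = as.numeric(tl$means),
               sd_log10 = as.numeric(tl$sds),
               letter = as.character(tl$letters),
               p_anova = tl$anova$p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write a responder report in the shape of a dominant-genus table
#'
#' Wide layout: one row per (phylum, genus), per-treatment columns of
#' `mean +/- sd` relative abundance (percent) with the compact letter in a
#' separate column, grouped by soil.
#'
#' @param res Output of [screen_responders()].
#' @param path File path.
#' @param digits Display rounding for the percent columns (default 1).
#' @export
write_responders <- function(res, path, digits = 1) {
  res$cell <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                      res$mean_rel_pct, res$sd_rel_pct)
  wide <- stats::reshape(
    res[, c("soil", "phylum", "genus", "taxon", "treatment", "cell",
            "letter")],
    idvar = c("soil", "phylum", "genus", "taxon"),
    timevar = "treatment", direction = "wide")
  utils::write.table(wide, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
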