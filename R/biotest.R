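#' Group summaries of a plant growth table
#'
#' Arithmetic mean and sample SD (n - 1 denominator) per soil x treatment
#' for every trait present among SL, SFM, SDM, RDM. Single-plant groups get
#' `NA` SDs.
#'
#' @param growth data.frame with `soil`, `treatment` and trait columns.
#' @return data.frame: `soil`, `treatment`, `n`, then `<trait>_mean` and
#'   `<trait>_sd` per trait.
#' @export
summarize_groups <- function(growth) {
  traits <- intersect(c("SL", "SFM", "SDM", "RDM"), colnames(growth))
  if (!length(traits)) stop("no trait columns found", call. = FALSE)
  key <- interaction(growth$soil, growth$treatment, drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(kk) {
    d <- growth[key == kk, ]
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    out <- data.frame(soil = parts[1], treatment = parts[2], n = nrow(d),
                      stringsAsFactors = FALSE)
    for (tr in traits) {
      out[[paste0(tr, "_mean")]] <- mean(d[[tr]])
      out[[paste0(tr, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[tr]]) else NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  res[order(res$soil, res$treatment), , drop = FALSE]
}

#' Percent increase and fold change of a treatment mean over the control
#'
#' `percent = 100 * (mean_treat - mean_con) / mean_con`;
#' `fold = mean_treat / mean_con`. The two are consistent:
#' `fold = 1 + percent/100` before rounding. Report rounding follows the
#' biomass-table convention (percent to integer, fold to 1 decimal).
#'
#' @param mean_treat,mean_con Group means; `mean_con > 0`.
#' @return List with `percent`, `fold` (exact) and `percent_rounded`,
#'   `fold_rounded`.
#' @examples
#' percent_increase(4.5, 3.1)  # 45% (1.5-fold)
#' @export
percent_increase <- function(mean_treat, mean_con) {
  if (!is.finite(mean_con) || mean_con <= 0) {
    stop("control mean must be positive", call. = FALSE)
  }
  pct <- 100 * (mean_treat - mean_con) / mean_con
  fold <- mean_treat / mean_con
  list(percent = pct, fold = fold,
       percent_rounded = round(pct), fold_rounded = round(fold, 1))
}

#' Root-to-shoot dry mass ratio of group means
#'
#' @param mean_rdm,mean_sdm Group mean root and shoot dry mass; `SDM > 0`.
#' @return List with `ratio` (exact) and `ratio_rounded` (1 decimal).
#' @examples
#' root_shoot_ratio(3.3, 1.5)  # 2.2
#' @export
root_shoot_ratio <- function(mean_rdm, mean_sdm) {
  if (!is.finite(mean_sdm) || mean_sdm <= 0) {
    stop("shoot dry mass mean must be positive", call. = FALSE)
  }
  r <- mean_rdm / mean_sdm
  list(ratio = r, ratio_rounded = round(r, 1))
}

#' Biomass report for a growth biotest
#'
#' Per soil: group mean +/- SD per trait, Tukey letters across treatments
#' per trait, percent/fold SDM increase vs the control, and the
#' root-to-shoot (RDM/SDM) ratio of group means — the derived columns of a
#' biomass table. Derived quantities are computed from group means, not
#' averaged per plant. A Brown-Forsythe (median-centred Levene) homogeneity
#' check per trait is run and reported as a warning column, not a gate.
#'
#' @param growth Growth table data.frame.
#' @param control Control treatment label (default `"Con"`).
#' @param alpha Significance level for the letters (default 0.05).
#' @return data.frame, one row per soil x treatment, with summary, letter,
#'   `sdm_pct_increase`, `sdm_fold`, `rdm_sdm_ratio` columns; attribute
#'   `variance_check` holds the per-trait Levene p-values.
#' @export
biotest_report <- function(growth, control = "Con", alpha = 0.05) {
  traits <- intersect(c("SL", "SFM", "SDM", "RDM"), colnames(growth))
  summ <- summarize_groups(growth)
  soils <- unique(summ$soil)
  summ$sdm_pct_increase <- NA_real_
  summ$sdm_fold <- NA_real_
  summ$rdm_sdm_ratio <- NA_real_
  lev <- list()
  for (tr in traits) summ[[paste0(tr, "_letter")]] <- NA_character_
  for (so in soils) {
    d <- growth[growth$soil == so, ]
    idx <- which(summ$soil == so)
    for (tr in traits) {
      tl <- tukey_letters(d[[tr]], d$treatment, alpha = alpha)
      summ[[paste0(tr, "_letter")]][idx] <-
        as.character(tl$letters[summ$treatment[idx]])
      lev[[paste(so, tr)]] <- levene_p(d[[tr]], d$treatment)
    }
    con_mean <- summ$SDM_mean[summ$soil == so & summ$treatment == control]
    if (length(con_mean) == 1L) {
      for (i in idx) {
        if ("SDM" %in% traits) {
          if (summ$treatment[i] != control) {
            pi <- percent_increase(summ$SDM_mean[i], con_mean)
            summ$sdm_pct_increase[i] <- pi$percent_rounded
            summ$sdm_fold[i] <- pi$fold_rounded
          }
          if ("RDM" %in% traits) {
            summ$rdm_sdm_ratio[i] <-
              root_shoot_ratio(summ$RDM_mean[i], summ$SDM_mean[i])$ratio_rounded
          }
        }
      }
    }
  }
  bad <- names(lev)[vapply(lev, function(p) is.finite(p) && p < alpha,
                           logical(1))]
  if (length(bad)) {
    warning("variance heterogeneity detected (Levene p < ", alpha, "): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(summ, "variance_check") <- unlist(lev)
  summ
}

# Brown-Forsythe variant of Levene's test: ANOVA on |x - group median|.
levene_p <- function(values, group) {
  z <- abs(values - tapply(values, group, stats::median)[as.character(group)])
  res <- tryCatch(anova_oneway(as.numeric(z), group),
                  error = function(e) NULL)
  if (is.null(res)) NA_real_ else res$p
}

#' Weekly Dunnett flags for shoot-length time courses
#'
#' Per soil and week, a two-sided Dunnett test of every treatment against
#' the control on that week's shoot lengths; reports the adjusted p-values
#' and, per treatment, the first week flagged at `alpha`.
#'
#' @param series Long data.frame: `soil`, `treatment`, `week`, `SL` (one row
#'   per plant per week).
#' @param control Control treatment label (default `"Con"`).
#' @param alpha Flagging level (default 0.05).
#' @return List with `flags` (data.frame: soil, week, treatment, estimate,
#'   p_adj, significant) and `first_significant` (data.frame: soil,
#'   treatment, week of first flag, NA if never).
#' @export
timecourse_flags <- function(series, control = "Con", alpha = 0.05) {
  stopifnot(all(c("soil", "treatment", "week", "SL") %in% colnames(series)))
  weeks <- sort(unique(series$week))
  if (length(weeks) < 2L) stop("need >= 2 weeks", call. = FALSE)
  soils <- unique(series$soil)
  rows <- list()
  for (so in soils) {
    for (w in weeks) {
      d <- series[series$soil == so & series$week == w, ]
      if (!control %in% d$treatment) {
        stop(sprintf("control '%s' missing in soil %s week %s",
                     control, so, w), call. = FALSE)
      }
      dn <- dunnett_vs_control(d$SL, d$treatment, control)
      dn$soil <- so; dn$week <- w
      rows[[length(rows) + 1L]] <- dn
    }
  }
  flags <- do.call(rbind, rows)
  flags$significant <- flags$p_adj < alpha
  flags <- flags[, c("soil", "week", "treatment", "estimate", "t", "p_adj",
                     "significant")]
  first <- do.call(rbind, lapply(split(flags,
                                       paste(flags$soil, flags$treatment)),
    function(d) {
      w <- d$week[d$significant]
      data.frame(soil = d$soil[1], treatment = d$treatment[1],
                 first_week = if (length(w)) min(w) else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  rownames(first) <- NULL
  list(flags = flags, first_significant = first)
}
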