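#' Analytic rarefaction curve
#'
#' Expected number of OTUs observed in a random subsample of `d` sequences
#' drawn without replacement from one sample:
#' `E[S_d] = S_obs - sum_i C(N - n_i, d) / C(N, d)`,
#' the hypergeometric expectation. Computed with log-binomials (`lchoose`)
#' for stability; no resampling is involved.
#'
#' @param counts Non-negative integer count vector for one sample.
#' @param depths Subsample depths, each between 1 and `N = sum(counts)`.
#' @return data.frame with columns `depth` and `expected_otus`.
#' @examples
#' rarefaction_curve(c(2, 1), depths = 2)  # 5/3
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 1) stop("empty sample", call. = FALSE)
  depths <- as.numeric(depths)
  if (any(depths < 1) || any(depths > N) || any(depths != round(depths))) {
    stop(sprintf("depths must be integers in [1, N = %d]", N), call. = FALSE)
  }
  s_obs <- length(counts)
  exp_otus <- vapply(depths, function(d) {
    miss <- exp(lchoose(N - counts, d) - lchoose(N, d))
    s_obs - sum(miss)
  }, numeric(1))
  data.frame(depth = depths, expected_otus = exp_otus)
}

#' Rarefaction curves for every sample of an OTU table
#'
#' @param table An [otu_table()].
#' @param depths Depths to evaluate; defaults to 20 points up to each
#'   sample's own total (points beyond a sample's depth are dropped for that
#'   sample).
#' @return Long data.frame: `sample_id`, `depth`, `expected_otus`.
#' @export
rarefaction_curves <- function(table, depths = NULL) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  if (is.null(depths)) {
    depths <- unique(round(seq(1, max(totals), length.out = 20L)))
  }
  out <- lapply(rownames(table$counts), function(s) {
    d <- depths[depths <= totals[s]]
    cv <- rarefaction_curve(table$counts[s, ], d)
    cbind(sample_id = s, cv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Inverse Simpson diversity index (unbiased form)
#'
#' `1/D` with the finite-sample estimator
#' `D = sum_i n_i (n_i - 1) / (N (N - 1))` (the convention of the mothur
#' amplicon pipeline). When every taxon is a singleton, `D = 0` and the
#' index is `Inf`.
#'
#' @param counts Count vector for one sample; `N >= 2` required.
#' @return The inverse Simpson index (may be `Inf`).
#' @examples
#' invsimpson(c(2, 2, 1))  # 5
#' @export
invsimpson <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  N <- sum(counts)
  if (N < 2) stop("need N >= 2 sequences", call. = FALSE)
  D <- sum(counts * (counts - 1)) / (N * (N - 1))
  if (D == 0) Inf else 1 / D
}

#' Per-sample diversity table
#'
#' @param table An [otu_table()].
#' @return data.frame with `sample_id`, `soil`, `treatment`, `replicate`,
#'   `depth`, `observed_otus`, `invsimpson`.
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  idx <- vapply(rownames(table$counts),
                function(s) invsimpson(table$counts[s, ]), numeric(1))
  data.frame(table$metadata,
             depth = rowSums(table$counts),
             observed_otus = rowSums(table$counts > 0),
             invsimpson = idx,
             stringsAsFactors = FALSE)
}
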