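#' @keywords internal
"_PACKAGE"

# Derive a reproducible substream seed from a master seed and a counter.
# Keeps every generator a pure function of (params, seed) while letting
# independent components (e.g. each sample group) own an independent stream,
# so adding a group does not shift the draws of the others.
substream_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.double(seed)) * 69069 + as.double(counter) * 104729 + 1) %%
    2147483647
  as.integer(s)
}

# Evaluate `expr` under set.seed(substream_seed(seed, counter)) and restore
# the caller's RNG state afterwards.
with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, counter))
  expr
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative number", name),
         call. = FALSE)
  }
  as.double(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  as.double(x)
}

# Exact truncated-normal sampler (lower bound 0) via inverse CDF.
# Vectorized over mean and sd; sd = 0 gives the mean exactly.
rnorm_trunc0 <- function(n, mean, sd) {
  mean <- rep_len(as.numeric(mean), n)
  sd <- rep_len(as.numeric(sd), n)
  out <- mean
  ok <- sd > 0
  if (any(ok)) {
    lo <- stats::pnorm(0, mean[ok], sd[ok])
    out[ok] <- stats::qnorm(stats::runif(sum(ok), lo, 1), mean[ok], sd[ok])
  }
  out
}

#' Taxonomic rank names used throughout the package
#'
#' The six ranks of a mothur-style consensus lineage, from domain to genus.
#' @return Character vector of length 6.
#' @export
tax_levels <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}
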