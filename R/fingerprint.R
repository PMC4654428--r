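#' Labelled fingerprint lane set
#'
#' Container for densitometric fingerprint profiles (e.g. DGGE lanes): one
#' intensity vector per lane plus a lane id and a group label. This is the
#' abstraction the similarity and permutation machinery operates on; no gel
#' image processing happens here.
#'
#' @param intensity Numeric matrix, lanes in rows, intensity bins in columns.
#' @param lane_id Character vector of unique lane identifiers.
#' @param group Character vector of group labels (e.g. `"KleCon"`), one per
#'   lane.
#' @return An object of class `fingerprint_set`.
#' @examples
#' fp <- fingerprint_set(matrix(runif(40), nrow = 4),
#'                       lane_id = paste0("L", 1:4),
#'                       group = c("A", "A", "B", "B"))
#' @export
fingerprint_set <- function(intensity, lane_id, group) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (nrow(intensity) < 2L) stop("need at least 2 lanes", call. = FALSE)
  if (ncol(intensity) < 2L) stop("profiles need length >= 2", call. = FALSE)
  if (!all(is.finite(intensity))) {
    stop("intensities must be finite", call. = FALSE)
  }
  lane_id <- as.character(lane_id)
  group <- as.character(group)
  if (length(lane_id) != nrow(intensity) || length(group) != nrow(intensity)) {
    stop("lane_id and group must have one entry per lane", call. = FALSE)
  }
  if (anyDuplicated(lane_id)) stop("lane_id must be unique", call. = FALSE)
  rownames(intensity) <- lane_id
  structure(list(intensity = intensity, lane_id = lane_id, group = group),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("<fingerprint_set> %d lanes x %d bins; groups: %s\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(unique(x$group), collapse = ", ")))
  invisible(x)
}

#' Pairwise Pearson similarity matrix of fingerprint lanes
#'
#' Computes the Pearson correlation coefficient of every pair of raw lane
#' intensity profiles, the whole-curve similarity measure used by gel
#' comparison software. No background subtraction or band binning is applied;
#' any preprocessing must happen upstream (see `preprocess`).
#'
#' @param fp A [fingerprint_set()].
#' @param preprocess Optional function applied to the lane matrix (lanes in
#'   rows) before correlation, e.g. a background-subtraction hook. Default
#'   `identity`.
#' @return A `similarity_matrix`: list with `ids` and the square symmetric
#'   correlation matrix `S` (unit diagonal).
#' @examples
#' fp <- fingerprint_set(rbind(c(1, 2, 3, 4), c(1, 2, 2, 4)),
#'                       c("a", "b"), c("g1", "g1"))
#' pearson_similarity(fp)$S
#' @export
pearson_similarity <- function(fp, preprocess = identity) {
  stopifnot(inherits(fp, "fingerprint_set"))
  m <- preprocess(fp$intensity)
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    stop(sprintf("constant lane(s) with undefined correlation: %s",
                 paste(fp$lane_id[v == 0], collapse = ", ")), call. = FALSE)
  }
  S <- stats::cor(t(m))
  diag(S) <- 1
  similarity_matrix(S, fp$lane_id)
}

#' Construct a similarity matrix object
#'
#' @param S Square symmetric numeric matrix of similarities in \[-1, 1\] with
#'   unit diagonal.
#' @param ids Sample identifiers (defaults to `rownames(S)`).
#' @return A `similarity_matrix` object.
#' @export
similarity_matrix <- function(S, ids = rownames(S)) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("S must be square", call. = FALSE)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(S)))
  ids <- as.character(ids)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric", call. = FALSE)
  S <- (S + t(S)) / 2
  if (any(S < -1 - 1e-8) || any(S > 1 + 1e-8)) {
    stop("similarities must lie in [-1, 1]", call. = FALSE)
  }
  if (max(abs(diag(S) - 1)) > 1e-8) {
    stop("diagonal must be 1", call. = FALSE)
  }
  dimnames(S) <- list(ids, ids)
  structure(list(ids = ids, S = S), class = "similarity_matrix")
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Agglomerative clustering with arithmetic-mean (average) linkage on the
#' dissimilarity `1 - S`, the clustering applied to whole-lane Pearson
#' similarities in fingerprint studies. Merge heights are nondecreasing and
#' the cophenetic distances are ultrametric.
#'
#' @param sim A `similarity_matrix`.
#' @return List with `newick` (string, branch lengths on the `1 - S` scale),
#'   `merge` (hclust merge table), `height` (merge heights) and the
#'   underlying `hclust` object.
#' @export
upgma <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  n <- length(sim$ids)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  d <- stats::as.dist(1 - sim$S)
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(newick = ape::write.tree(phy),
       merge = hc$merge,
       height = hc$height,
       hclust = hc)
}

# Mean within-group and between-group similarity over unordered off-diagonal
# pairs; shared by d_statistic and the permutation loop.
pair_masks <- function(labels) {
  n <- length(labels)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(matrix(0, n, n))
  list(within = same & ut, between = (!same) & ut)
}

#' Fingerprint d-statistic
#'
#' `d = 100 * (mean within-group similarity - mean between-group similarity)`
#' over all unordered lane pairs (diagonal excluded), in percentage points.
#' Large d indicates group structure in the community profiles.
#'
#' @param sim A `similarity_matrix`.
#' @param labels Group label per sample, aligned with `sim$ids` (or a named
#'   vector keyed by id).
#' @return The d-value (percentage points).
#' @export
d_statistic <- function(sim, labels) {
  stopifnot(inherits(sim, "similarity_matrix"))
  labels <- align_labels(labels, sim$ids)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop(sprintf("group(s) with a single member have no within pair: %s",
                 paste(names(tab)[tab < 2L], collapse = ", ")), call. = FALSE)
  }
  m <- pair_masks(labels)
  100 * (mean(sim$S[m$within]) - mean(sim$S[m$between]))
}

align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels))) {
      stop("labels are named but do not cover all ids", call. = FALSE)
    }
    labels <- labels[ids]
  }
  if (length(labels) != length(ids)) {
    stop("labels must have one entry per sample", call. = FALSE)
  }
  as.character(labels)
}

# All distinct arrangements of a label multiset (columns of the result).
# Distinctness treats equal labels as identical, so the count equals the
# multinomial coefficient, not n!.
multiset_permutations <- function(labels) {
  uniq <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = uniq)))
  n <- length(labels)
  out <- vector("list", 0L)
  rec <- function(prefix, counts) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (k in seq_along(uniq)) {
      if (counts[k] > 0L) {
        counts[k] <- counts[k] - 1L
        rec(c(prefix, uniq[k]), counts)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  rec(character(0), counts)
  matrix(unlist(out), nrow = n)
}

n_arrangements <- function(labels) {
  tab <- table(labels)
  exp(lfactorial(length(labels)) - sum(lfactorial(tab)))
}

#' Permutation test on a similarity matrix (d-test)
#'
#' Tests whether within-group similarity exceeds between-group similarity by
#' permuting group labels over samples with group sizes fixed. One-sided:
#' large d indicates group structure. When the number of distinct label
#' arrangements (a multinomial coefficient) is at most `exhaustive_cap`, all
#' arrangements are enumerated and
#' `p = #(d_perm >= d_obs) / total` (the identity arrangement is one of
#' them, so p >= 1/total). Otherwise `n_mc` Monte-Carlo permutations are
#' drawn and the identity is added to numerator and denominator.
#'
#' Note that d is invariant to swapping the group labels themselves, so for
#' two equally sized groups each sample partition is counted twice among the
#' arrangements and the smallest realisable p is 2/total (e.g. 2/70 ~ 0.03
#' for a 4-vs-4 design).
#'
#' @param sim A `similarity_matrix`.
#' @param labels Group labels as in [d_statistic()].
#' @param n_mc Number of Monte-Carlo permutations (>= 100) when exhaustive
#'   enumeration is infeasible.
#' @param seed Seed for the Monte-Carlo scheme (ignored when exhaustive).
#' @param exhaustive_cap Largest arrangement count enumerated exhaustively.
#' @return A `permutation_result`: list with `d_observed`, `p_value`,
#'   `n_permutations`, `scheme` (`"exhaustive"` or `"monte_carlo"`) and
#'   `seed`.
#' @examples
#' S <- diag(4); S[upper.tri(S)] <- c(.9, .5, .5, .5, .5, .9)
#' S <- S + t(S); diag(S) <- 1
#' sm <- similarity_matrix(S, letters[1:4])
#' permutation_test(sm, c("g1", "g1", "g2", "g2"))
#' @export
permutation_test <- function(sim, labels, n_mc = 9999L, seed = NULL,
                             exhaustive_cap = 20000L) {
  stopifnot(inherits(sim, "similarity_matrix"))
  labels <- align_labels(labels, sim$ids)
  d_obs <- d_statistic(sim, labels)
  total <- n_arrangements(labels)
  eps <- 1e-9
  if (total <= exhaustive_cap) {
    perms <- multiset_permutations(labels)
    d_perm <- apply(perms, 2L, function(l) d_statistic(sim, l))
    p <- sum(d_perm >= d_obs - eps) / ncol(perms)
    res <- list(d_observed = d_obs, p_value = p,
                n_permutations = ncol(perms), scheme = "exhaustive",
                seed = NULL)
  } else {
    n_mc <- check_count(n_mc, "n_mc", min = 100L)
    if (is.null(seed)) stop("seed required for monte_carlo scheme",
                            call. = FALSE)
    d_perm <- with_substream(seed, 0L, {
      vapply(seq_len(n_mc),
             function(i) d_statistic(sim, sample(labels)), numeric(1))
    })
    p <- (1 + sum(d_perm >= d_obs - eps)) / (n_mc + 1)
    res <- list(d_observed = d_obs, p_value = p,
                n_permutations = n_mc, scheme = "monte_carlo", seed = seed)
  }
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("d = %.2f%%, p = %.4g (%s, %d permutations)\n",
              x$d_observed, x$p_value, x$scheme, x$n_permutations))
  invisible(x)
}

#' Pairwise d-test report across group comparisons
#'
#' Runs [permutation_test()] for each requested pair of groups, producing a
#' comparison table (comparison, d-value, p-value, scheme).
#'
#' @param fp A [fingerprint_set()].
#' @param comparisons List of character pairs, e.g.
#'   `list(c("Con", "H50"))`; default all unordered group pairs.
#' @inheritParams permutation_test
#' @return data.frame with one row per comparison.
#' @export
d_test_report <- function(fp, comparisons = NULL, n_mc = 9999L, seed = NULL,
                          exhaustive_cap = 20000L) {
  stopifnot(inherits(fp, "fingerprint_set"))
  groups <- unique(fp$group)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(groups, 2L, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(pr) {
    keep <- fp$group %in% pr
    sub <- fingerprint_set(fp$intensity[keep, , drop = FALSE],
                           fp$lane_id[keep], fp$group[keep])
    res <- permutation_test(pearson_similarity(sub), sub$group,
                            n_mc = n_mc, seed = seed,
                            exhaustive_cap = exhaustive_cap)
    data.frame(comparison = paste(pr, collapse = " vs. "),
               d_value = res$d_observed, p_value = res$p_value,
               scheme = res$scheme, n_permutations = res$n_permutations,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read and write fingerprint lane profiles
#'
#' CSV layout: `lane_id,label,bin_0,...,bin_{L-1}`.
#'
#' @param fp A [fingerprint_set()].
#' @param path File path.
#' @return `read_fingerprints` returns a [fingerprint_set()];
#'   `write_fingerprints` returns `path` invisibly.
#' @export
write_fingerprints <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_set"))
  df <- data.frame(lane_id = fp$lane_id, label = fp$group,
                   fp$intensity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("lane_id", "label",
                    paste0("bin_", seq_len(ncol(fp$intensity)) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("lane_id", "label") %in% colnames(df))) {
    stop("expected columns lane_id and label", call. = FALSE)
  }
  bins <- grep("^bin_", colnames(df))
  m <- as.matrix(df[, bins, drop = FALSE])
  dimnames(m) <- NULL
  fingerprint_set(m, df$lane_id, df$label)
}

#' Write a similarity matrix as TSV
#' @param sim A `similarity_matrix`.
#' @param path File path.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  utils::write.table(data.frame(id = sim$ids, sim$S, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
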