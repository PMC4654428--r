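#' Bray-Curtis distance matrix
#'
#' `D[i, j] = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` on non-negative
#' abundance rows (counts or relative abundances give the same value after
#' row normalisation of both samples only when totals are equal; counts are
#' used as supplied).
#'
#' @param x Samples x taxa non-negative matrix (counts, relative or
#'   transformed abundances) or an [otu_table()].
#' @return A `distance_matrix`: list with `ids` and square symmetric `D`
#'   with zero diagonal, entries in \[0, 1\].
#' @examples
#' bray_curtis(rbind(a = c(1, 2), b = c(2, 1)))$D["a", "b"]  # 1/3
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "otu_table")) x <- x$counts
  x <- as.matrix(unclass(x))
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (any(rowSums(x) == 0)) {
    stop(sprintf("all-zero sample(s): %s",
                 paste(rownames(x)[rowSums(x) == 0], collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- x[i, ]
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- sum(abs(xi - x[j, ])) / sum(xi + x[j, ])
    }
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  distance_matrix(D, ids)
}

#' Construct a distance matrix object
#' @param D Square symmetric non-negative matrix with zero diagonal.
#' @param ids Sample ids (defaults to rownames).
#' @export
distance_matrix <- function(D, ids = rownames(D)) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("D must be square", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric", call. = FALSE)
  if (any(D < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(abs(diag(D))) > 1e-8) stop("diagonal must be zero", call. = FALSE)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(D)))
  ids <- as.character(ids)
  dimnames(D) <- list(ids, ids)
  structure(list(ids = ids, D = D), class = "distance_matrix")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of `-D^2 / 2`,
#' eigendecomposition, coordinates scaled by the square root of the positive
#' eigenvalues. Negative eigenvalues (non-Euclidean distances such as
#' Bray-Curtis produce them) are reported but their axes are dropped;
#' explained fractions are relative to the sum of positive eigenvalues.
#'
#' @param dm A `distance_matrix`.
#' @param n_axes Number of axes to retain (default all positive axes).
#' @return A `pcoa_result`: `coordinates` (samples x axes), `eigenvalues`
#'   (all, descending), `explained` (per retained axis).
#' @export
pcoa <- function(dm, n_axes = NULL) {
  stopifnot(inherits(dm, "distance_matrix"))
  D <- dm$D
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- ev > max(ev, 0) * 1e-10 & ev > 0
  n_pos <- sum(pos)
  if (is.null(n_axes)) n_axes <- n_pos
  if (n_axes > n_pos) {
    warning(sprintf("only %d positive axes available; truncating", n_pos))
    n_axes <- n_pos
  }
  if (n_pos == 0L) {
    coords <- matrix(0, n, 0)
  } else {
    k <- seq_len(n_axes)
    coords <- e$vectors[, k, drop = FALSE] %*%
      diag(sqrt(ev[k]), n_axes, n_axes)
  }
  rownames(coords) <- dm$ids
  if (ncol(coords) > 0) colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  explained <- if (n_pos > 0) ev[seq_len(n_axes)] / sum(ev[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = ev,
                 explained = explained),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d axes; axis1 %.1f%%, axis2 %.1f%%\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$explained[1],
              if (length(x$explained) > 1) 100 * x$explained[2] else NA))
  invisible(x)
}

# Clarke's R on a distance submatrix: rank all off-diagonal distances
# (midranks on ties); R = (mean between rank - mean within rank) / (M / 2)
# with M = n(n-1)/2 pairs, i.e. divisor n(n-1)/4.
anosim_r <- function(D, labels) {
  n <- nrow(D)
  ut <- upper.tri(D)
  r <- rank(D[ut])
  same <- outer(labels, labels, "==")[ut]
  (mean(r[!same]) - mean(r[same])) / (length(r) / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test contrasting between-group and within-group
#' dissimilarity ranks: `R = (rB - rW) / (n(n-1)/4)`, in \[-1, 1\], one-sided
#' (large R = group separation). One-way permutes labels freely; the two-way
#' crossed design computes R within each block (level of `block`), averages
#' the per-block R values, and permutes labels only within blocks, so the
#' tested factor is assessed with the blocking factor held fixed.
#'
#' @param dm A `distance_matrix`.
#' @param labels Group labels per sample (named vector or aligned with ids).
#' @param n_perm Number of Monte-Carlo permutations when exhaustive
#'   enumeration exceeds `exhaustive_cap`.
#' @param seed Seed for the Monte-Carlo scheme.
#' @param block Optional blocking factor for the two-way crossed design.
#' @param exhaustive_cap Largest arrangement count enumerated exhaustively.
#' @return An `anosim_result`: `R`, `p_value`, `n_permutations`, `scheme`,
#'   `design` (`"one_way"` or `"two_way"`).
#' @export
anosim <- function(dm, labels, n_perm = 999L, seed = NULL, block = NULL,
                   exhaustive_cap = 20000L) {
  stopifnot(inherits(dm, "distance_matrix"))
  labels <- align_labels(labels, dm$ids)
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  if (is.null(block)) {
    stat <- function(l) anosim_r(dm$D, l)
    R_obs <- stat(labels)
    perm <- permute_pvalue(labels, stat, R_obs, n_perm, seed, exhaustive_cap)
    res <- list(R = R_obs, p_value = perm$p, n_permutations = perm$n,
                scheme = perm$scheme, design = "one_way")
  } else {
    block <- align_labels(block, dm$ids)
    blocks <- unique(block)
    idx <- lapply(blocks, function(b) which(block == b))
    for (ix in idx) {
      tb <- table(labels[ix])
      if (length(tb) < 2L || any(tb < 2L)) {
        stop("each block needs >= 2 groups with >= 2 members", call. = FALSE)
      }
    }
    stat <- function(l) {
      mean(vapply(idx, function(ix) {
        anosim_r(dm$D[ix, ix, drop = FALSE], l[ix])
      }, numeric(1)))
    }
    R_obs <- stat(labels)
    total <- prod(vapply(idx, function(ix) n_arrangements(labels[ix]),
                         numeric(1)))
    eps <- 1e-9
    if (total <= exhaustive_cap) {
      per_block <- lapply(idx, function(ix) multiset_permutations(labels[ix]))
      counts <- vapply(per_block, ncol, integer(1))
      grid <- expand.grid(lapply(counts, seq_len))
      stats <- apply(grid, 1L, function(sel) {
        l <- labels
        for (b in seq_along(idx)) l[idx[[b]]] <- per_block[[b]][, sel[b]]
        stat(l)
      })
      p <- sum(stats >= R_obs - eps) / length(stats)
      res <- list(R = R_obs, p_value = p, n_permutations = length(stats),
                  scheme = "exhaustive", design = "two_way")
    } else {
      n_perm <- check_count(n_perm, "n_perm", min = 100L)
      if (is.null(seed)) stop("seed required for monte_carlo scheme",
                              call. = FALSE)
      stats <- with_substream(seed, 0L, {
        vapply(seq_len(n_perm), function(i) {
          l <- labels
          for (ix in idx) l[ix] <- sample(l[ix])
          stat(l)
        }, numeric(1))
      })
      p <- (1 + sum(stats >= R_obs - eps)) / (n_perm + 1)
      res <- list(R = R_obs, p_value = p, n_permutations = n_perm,
                  scheme = "monte_carlo", design = "two_way")
    }
  }
  class(res) <- "anosim_result"
  res
}

# Shared one-way permutation engine: exhaustive over distinct label
# arrangements when feasible, else Monte-Carlo with the identity added.
permute_pvalue <- function(labels, stat, obs, n_perm, seed, exhaustive_cap) {
  eps <- 1e-9
  total <- n_arrangements(labels)
  if (total <= exhaustive_cap) {
    perms <- multiset_permutations(labels)
    stats <- apply(perms, 2L, stat)
    list(p = sum(stats >= obs - eps) / ncol(perms), n = ncol(perms),
         scheme = "exhaustive")
  } else {
    n_perm <- check_count(n_perm, "n_perm", min = 100L)
    if (is.null(seed)) stop("seed required for monte_carlo scheme",
                            call. = FALSE)
    stats <- with_substream(seed, 0L, {
      vapply(seq_len(n_perm), function(i) stat(sample(labels)), numeric(1))
    })
    list(p = (1 + sum(stats >= obs - eps)) / (n_perm + 1), n = n_perm,
         scheme = "monte_carlo")
  }
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM (%s): R = %.3f, p = %.4g (%s, %d permutations)\n",
              x$design, x$R, x$p_value, x$scheme, x$n_permutations))
  invisible(x)
}

#' Write PCoA coordinates as TSV
#' @param res A `pcoa_result`.
#' @param path File path.
#' @export
write_pcoa <- function(res, path) {
  df <- data.frame(sample_id = rownames(res$coordinates),
                   res$coordinates, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param dm A `distance_matrix`.
#' @param path File path.
#' @export
write_distance <- function(dm, path) {
  utils::write.table(data.frame(id = dm$ids, dm$D, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
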