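#' OTU count table with taxonomy and sample metadata
#'
#' The central community container: a samples x OTUs integer count matrix, a
#' six-rank lineage per OTU (domain;phylum;class;order;family;genus, with
#' `"unclassified"` allowed at any rank), and per-sample metadata (soil,
#' treatment, replicate). Downstream analyses start from this processed
#' table; read trimming, alignment and OTU clustering are upstream concerns.
#'
#' @param counts Non-negative integer matrix, samples in rows, OTUs in
#'   columns; dimnames used as sample and OTU ids.
#' @param taxonomy data.frame with columns `otu_id` and the six ranks of
#'   [tax_levels()].
#' @param metadata data.frame with columns `sample_id`, `soil`, `treatment`,
#'   `replicate`.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("Otu", sprintf("%05d", seq_len(ncol(counts))))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (any(rowSums(counts) <= 0)) {
    stop(sprintf("empty sample(s): %s",
                 paste(rownames(counts)[rowSums(counts) <= 0],
                       collapse = ", ")), call. = FALSE)
  }
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  need <- c("otu_id", tax_levels())
  if (!all(need %in% colnames(taxonomy))) {
    stop("taxonomy must have columns otu_id, ", paste(tax_levels(),
         collapse = ", "), call. = FALSE)
  }
  if (!all(colnames(counts) %in% taxonomy$otu_id)) {
    stop("taxonomy must cover every OTU", call. = FALSE)
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), need]
  rownames(taxonomy) <- NULL
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "soil", "treatment", "replicate") %in%
           colnames(metadata))) {
    stop("metadata must have columns sample_id, soil, treatment, replicate",
         call. = FALSE)
  }
  if (!all(rownames(counts) %in% metadata$sample_id)) {
    stop("metadata must cover every sample", call. = FALSE)
  }
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  rownames(metadata) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d taxa; depth %d-%d\n",
              nrow(x$counts), ncol(x$counts),
              min(rowSums(x$counts)), max(rowSums(x$counts))))
  invisible(x)
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Counts of OTUs sharing the lineage prefix down to `level` are summed.
#' Because the prefix includes all parent ranks, OTUs unclassified at
#' `level` are pooled per parent lineage, not globally. Sample totals are
#' conserved.
#'
#' @param table An [otu_table()].
#' @param level One of [tax_levels()] or `"otu"` (identity).
#' @return An [otu_table()] whose columns are lineage prefixes; ranks below
#'   `level` are set to `"unclassified"` in the returned taxonomy.
#' @export
aggregate_taxa <- function(table, level) {
  stopifnot(inherits(table, "otu_table"))
  if (identical(level, "otu")) return(table)
  lv <- tax_levels()
  k <- match(level, lv)
  if (is.na(k)) stop(sprintf("unknown level '%s'", level), call. = FALSE)
  pref <- apply(table$taxonomy[, lv[seq_len(k)], drop = FALSE], 1L,
                paste, collapse = ";")
  groups <- factor(pref, levels = unique(pref))
  agg <- t(rowsum(t(table$counts), groups))
  colnames(agg) <- levels(groups)
  tax_rows <- table$taxonomy[!duplicated(pref), , drop = FALSE]
  tax_rows <- tax_rows[match(levels(groups),
                             apply(tax_rows[, lv[seq_len(k)], drop = FALSE],
                                   1L, paste, collapse = ";")), ]
  tax_rows$otu_id <- levels(groups)
  if (k < 6L) tax_rows[, lv[(k + 1L):6L]] <- "unclassified"
  out <- otu_table(agg, tax_rows, table$metadata)
  out
}

#' Abundance matrices: relative and log-transformed
#'
#' `relative_abundance` divides each count n by its sample total N.
#' `transform_abundance` applies the variance-stabilising transform
#' `log10(n/N * 100 + 1)` of percent relative abundance that precedes all
#' per-taxon group testing; it maps zero counts to 0 and a pure sample
#' (n = N) to log10(101).
#'
#' @param table An [otu_table()].
#' @return An `abundance_matrix`: samples x taxa matrix with attributes
#'   `kind` (`"relative"` or `"transformed"`).
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  v <- table$counts / rowSums(table$counts)
  structure(v, kind = "relative", class = c("abundance_matrix", "matrix"))
}

#' @rdname relative_abundance
#' @export
transform_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  v <- log10(table$counts / rowSums(table$counts) * 100 + 1)
  structure(v, kind = "transformed", class = c("abundance_matrix", "matrix"))
}

#' Dominant taxa by mean relative abundance
#'
#' Taxa whose mean relative abundance across samples is at least `threshold`
#' percent; taxa below the threshold are conventionally called rare. The
#' boundary is inclusive (a taxon at exactly the threshold is dominant).
#'
#' @param rel An `abundance_matrix` of kind `"relative"`.
#' @param threshold Percent threshold (default 1).
#' @param scope `"global"` (mean over all samples) or `"per_soil"` (dominant
#'   in at least one soil), in which case `soil` must give the per-sample
#'   soil labels.
#' @param soil Soil label per sample (required for `scope = "per_soil"`).
#' @return Character vector of dominant taxon names.
#' @export
dominant_taxa <- function(rel, threshold = 1, scope = c("global", "per_soil"),
                          soil = NULL) {
  if (!identical(attr(rel, "kind"), "relative")) {
    stop("dominant_taxa expects a relative abundance matrix", call. = FALSE)
  }
  scope <- match.arg(scope)
  pct <- unclass(rel) * 100
  if (scope == "global") {
    keep <- colMeans(pct) >= threshold
  } else {
    if (is.null(soil)) stop("soil labels required for per_soil scope",
                            call. = FALSE)
    by_soil <- rowsum(pct, soil) / as.vector(table(soil)[sort(unique(soil))])
    keep <- apply(by_soil, 2L, max) >= threshold
  }
  colnames(rel)[keep]
}

#' Genus-level ordination input
#'
#' Restricts an OTU table the way the ordination expects: keep only OTUs
#' from dominant phyla (mean relative abundance of the phylum >= `threshold`
#' percent) and only OTUs classified at genus level, then aggregate to
#' genus. Samples are unchanged.
#'
#' @param table An [otu_table()].
#' @param threshold Dominance threshold in percent (default 1).
#' @return A genus-aggregated [otu_table()].
#' @export
ordination_input <- function(table, threshold = 1) {
  stopifnot(inherits(table, "otu_table"))
  phy <- aggregate_taxa(table, "phylum")
  dom <- dominant_taxa(relative_abundance(phy), threshold)
  dom_phyla <- sub("^[^;]*;", "", dom)
  keep <- table$taxonomy$phylum %in% dom_phyla &
    table$taxonomy$genus != "unclassified"
  if (!any(keep)) stop("no genus-classified OTUs in dominant phyla",
                       call. = FALSE)
  sub <- otu_table(table$counts[, keep, drop = FALSE],
                   table$taxonomy[keep, , drop = FALSE], table$metadata)
  aggregate_taxa(sub, "genus")
}

#' Read and write OTU tables, taxonomy and metadata
#'
#' The on-disk layout mirrors the common amplicon-pipeline exports: an OTU
#' TSV with OTUs in rows and samples in columns, a taxonomy TSV
#' (`otu_id<TAB>lineage`) in the mothur consensus dialect — per-rank
#' bootstrap confidence suffixes such as `"(100)"` are stripped, a trailing
#' `";"` is tolerated, missing ranks are filled with `"unclassified"` — and
#' a metadata TSV (`sample_id`, `soil`, `treatment`, `replicate`).
#'
#' @param table An [otu_table()].
#' @param counts_path,taxonomy_path,metadata_path File paths.
#' @return `read_otu_table` returns an [otu_table()].
#' @export
write_otu_table <- function(table, counts_path, taxonomy_path,
                            metadata_path) {
  stopifnot(inherits(table, "otu_table"))
  cts <- data.frame(otu_id = colnames(table$counts), t(table$counts),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cts, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  lin <- apply(table$taxonomy[, tax_levels()], 1L, paste, collapse = ";")
  utils::write.table(data.frame(otu_id = table$taxonomy$otu_id,
                                taxonomy = lin, stringsAsFactors = FALSE),
                     taxonomy_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$metadata, metadata_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(counts_path, taxonomy_path, metadata_path) {
  cts <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- t(as.matrix(cts[, -1, drop = FALSE]))
  colnames(counts) <- cts[[1]]
  tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  taxonomy <- parse_lineages(tax[[1]], tax[[2]])
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  otu_table(counts, taxonomy, metadata)
}

# mothur cons.taxonomy lineage strings -> 6-column data.frame.
parse_lineages <- function(otu_id, lineage) {
  lineage <- gsub("\\([0-9.]+\\)", "", lineage)
  lineage <- sub(";$", "", lineage)
  parts <- strsplit(lineage, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- 6L
    p[is.na(p) | p == ""] <- "unclassified"
    p
  }, character(6)))
  df <- data.frame(otu_id = otu_id, mat, stringsAsFactors = FALSE)
  colnames(df) <- c("otu_id", tax_levels())
  df
}

#' Write an abundance matrix as TSV
#' @param ab An `abundance_matrix`.
#' @param path File path.
#' @export
write_abundance <- function(ab, path) {
  utils::write.table(data.frame(sample_id = rownames(ab), unclass(ab),
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
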