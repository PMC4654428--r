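# Shared in-code fixtures; everything is built programmatically.

# Similarity matrix from the upper-triangle values (row-major).
make_sim <- function(ids, upper) {
  n <- length(ids)
  S <- diag(n)
  S[upper.tri(S)] <- 0
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- upper[k]
      k <- k + 1L
    }
  }
  diag(S) <- 1
  similarity_matrix(S, ids)
}

# Tiny hand-built OTU table: 4 samples (2 treatments x 2 reps, one soil),
# 4 OTUs across 2 phyla; one OTU unclassified at genus.
tiny_otu_table <- function() {
  counts <- rbind(
    A_Con_1 = c(50, 30, 15, 5),
    A_Con_2 = c(55, 25, 15, 5),
    A_H50_1 = c(20, 60, 15, 5),
    A_H50_2 = c(25, 55, 15, 5))
  colnames(counts) <- paste0("Otu", 1:4)
  tax <- data.frame(
    otu_id = paste0("Otu", 1:4),
    domain = "Bacteria",
    phylum = c("P1", "P1", "P2", "P2"),
    class = c("C1", "C1", "C2", "C2"),
    order = c("O1", "O1", "O2", "O2"),
    family = c("F1", "F1", "F2", "unclassified"),
    genus = c("G1", "G2", "G3", "unclassified"),
    stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = rownames(counts),
    soil = "A",
    treatment = rep(c("Con", "H50"), each = 2L),
    replicate = rep(1:2, 2L),
    stringsAsFactors = FALSE)
  otu_table(counts, tax, meta)
}

# Small single-soil simulation design (3 treatments).
one_soil_groups <- function(soil = "Kle") {
  data.frame(soil = soil, treatment = c("Con", "H50", "Gamma"),
             stringsAsFactors = FALSE)
}
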