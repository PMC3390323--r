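# Independent oracles used to cross-check the implementation. These are
# deliberately written with different mechanics (explicit loops, distance
# matrices, direct summation) than the package code they verify.

# Hamming distance between a tag and every index key (full 21 positions).
oracle_hamming <- function(tag, keys) {
  tm <- strsplit(tag, "")[[1]]
  vapply(strsplit(keys, ""), function(km) sum(km != tm), numeric(1))
}

# Exhaustive-search re-implementation of the tag assignment policy:
# compartment-major (gene > mitochondrion > chloroplast > genome),
# tier-minor (exact before 1-mismatch), ambiguity = several distinct genes.
oracle_map_tag <- function(tag, index_tbl) {
  d <- oracle_hamming(tag, index_tbl$tag)
  for (cp in c("gene", "mitochondrion", "chloroplast", "genome")) {
    for (tier in c(0, 1)) {
      rows <- which(d == tier & index_tbl$compartment == cp)
      if (length(rows) == 0) next
      if (cp != "gene") {
        return(list(category = cp, gene_id = NA_character_,
                    strand = NA_character_))
      }
      ids <- unique(index_tbl$gene_id[rows])
      if (length(ids) > 1) {
        return(list(category = "gene_ambiguous", gene_id = NA_character_,
                    strand = NA_character_))
      }
      strand <- if (any(index_tbl$strand[rows] == "sense")) "sense"
      else "antisense"
      return(list(category = "gene_unambiguous", gene_id = ids,
                  strand = strand))
    }
  }
  list(category = "unknown", gene_id = NA_character_,
       strand = NA_character_)
}

# Brute-force scan for every CATG+17 tag in a sequence set (both strands),
# using regmatches rather than the package's site scanner.
oracle_index_keys <- function(sequences) {
  scan1 <- function(s) {
    starts <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    starts <- starts[starts > 0 & starts + 20 <= nchar(s)]
    if (length(starts) == 0) return(character(0))
    vapply(starts, function(p) substring(s, p, p + 20), character(1))
  }
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  unique(c(unlist(lapply(sequences, scan1)),
           unlist(lapply(lapply(sequences, rc), scan1))))
}

# Direct-summation upper-tail hypergeometric p-value via choose().
oracle_hyper_p <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Loop-based geNorm M (explicit double loop over gene pairs).
oracle_genorm_m <- function(qmat) {
  G <- nrow(qmat)
  M <- numeric(G)
  for (j in seq_len(G)) {
    acc <- c()
    for (k in seq_len(G)) {
      if (k == j) next
      acc <- c(acc, stats::sd(log2(qmat[j, ] / qmat[k, ])))
    }
    M[j] <- mean(acc)
  }
  stats::setNames(M, rownames(qmat))
}

# Expand a cleaned library back to reads (tag + adaptor padding) so
# cleaning idempotence can be exercised.
expand_library_reads <- function(library) {
  if (nrow(library$tag_counts) == 0) return(character(0))
  rep(paste0(library$tag_counts$tag, strrep("A", 14)),
      library$tag_counts$count)
}

# A small hand-built transcriptome for mapping toys.
toy_transcriptome <- function(sequences, compartments = NULL) {
  n <- length(sequences)
  tibble::tibble(
    gene_id = sprintf("T%02d", seq_len(n)),
    sequence = sequences,
    compartment = compartments %||% rep("gene", n),
    go_terms = replicate(n, character(0), simplify = FALSE),
    pathway_ids = replicate(n, character(0), simplify = FALSE)
  )
}
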