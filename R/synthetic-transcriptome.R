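#' Generate a synthetic reference transcriptome
#'
#' Produces a set of reference records emulating the input of a DGE
#' tag-profiling experiment: nuclear gene transcripts plus mitochondrial,
#' chloroplast and genomic-background decoy sequences, each annotated with a
#' synthetic GO-term and pathway vocabulary. Sequences are uniform random
#' DNA, so the fraction of gene records carrying at least one usable NlaIII
#' site (a `CATG` with >= 17 downstream bases) follows the analytic
#' occupancy probability for the chosen length range.
#'
#' @param n_genes Total number of records to generate (all compartments).
#' @param length_range Integer pair, inclusive bounds for sequence length.
#'   Must allow a CATG + 17-base tag (minimum 25).
#' @param compartment_fractions Named proportions over
#'   `c("gene", "mitochondrion", "chloroplast", "genome")`; must sum to 1.
#'   Records are allocated deterministically by largest remainder.
#' @param n_go_terms,n_pathways Size of the synthetic annotation
#'   vocabularies. GO terms are assigned only to `gene` records (mean 3 terms
#'   per gene), pathways likewise (mean 1.5).
#' @param sequences Optional character vector of length `n_genes` overriding
#'   the random sequences (compartments and annotations are still drawn).
#' @param seed Optional integer seed; a fixed seed gives bit-identical
#'   output.
#'
#' @return A tibble with columns `gene_id`, `sequence`, `compartment`,
#'   `go_terms` (list of character), `pathway_ids` (list of character), and
#'   attribute `go_vocabulary` (tibble `term_id`, `namespace`).
#' @export
#' @examples
#' tx <- generate_transcriptome(20, seed = 1)
#' dplyr::count(tx, compartment)
generate_transcriptome <- function(n_genes,
                                   length_range = c(200L, 2000L),
                                   compartment_fractions = c(
                                     gene = 0.94, mitochondrion = 0.01,
                                     chloroplast = 0.02, genome = 0.03
                                   ),
                                   n_go_terms = 40L,
                                   n_pathways = 20L,
                                   sequences = NULL,
                                   seed = NULL) {
  assert_scalar_number(n_genes, "n_genes", min = 1)
  if (length(length_range) != 2L || any(!is.finite(length_range))) {
    abort("`length_range` must be an integer pair.")
  }
  length_range <- as.integer(sort(length_range))
  if (length_range[1] < TAG_WIDTH + 4L) {
    abort(sprintf(
      "`length_range` minimum %d is too short: a CATG + 17-base tag needs at least %d bases.",
      length_range[1], TAG_WIDTH + 4L
    ))
  }
  comp_levels <- c("gene", "mitochondrion", "chloroplast", "genome")
  if (is.null(names(compartment_fractions)) ||
      !all(names(compartment_fractions) %in% comp_levels)) {
    abort("`compartment_fractions` must be named with the four compartments.")
  }
  fr <- setNames(rep(0, 4), comp_levels)
  fr[names(compartment_fractions)] <- compartment_fractions
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    abort("`compartment_fractions` must be non-negative and sum to 1.")
  }
  n_genes <- as.integer(n_genes)
  if (!is.null(sequences) && length(sequences) != n_genes) {
    abort("`sequences` must have length `n_genes`.")
  }

  with_seed_if(seed, {
    n_per <- allocate_counts(n_genes, fr)
    compartment <- rep(comp_levels, n_per)
    prefix <- c(gene = "G", mitochondrion = "MT", chloroplast = "CP",
                genome = "BG")
    gene_id <- unlist(lapply(comp_levels, function(cp) {
      k <- n_per[match(cp, comp_levels)]
      if (k == 0) character(0) else sprintf("%s%05d", prefix[[cp]], seq_len(k))
    }), use.names = FALSE)

    if (is.null(sequences)) {
      lens <- sample(seq(length_range[1], length_range[2]), n_genes,
                     replace = TRUE)
      sequences <- random_dna(lens)
    } else {
      sequences <- toupper(sequences)
      if (any(nchar(sequences) < TAG_WIDTH + 4L)) {
        abort("Supplied `sequences` shorter than a CATG + 17-base tag.")
      }
    }

    vocab <- tibble(
      term_id = sprintf("GO:%07d", seq_len(n_go_terms)),
      namespace = c("biological_process", "molecular_function",
                    "cellular_component")[(seq_len(n_go_terms) - 1L) %% 3L + 1L]
    )
    pathways <- sprintf("ko%05d", seq_len(n_pathways))

    draw_terms <- function(pool, lambda, is_gene) {
      lapply(is_gene, function(g) {
        if (!g) return(character(0))
        k <- min(rpois(1, lambda), length(pool))
        sort(sample(pool, k))
      })
    }
    is_gene <- compartment == "gene"
    tx <- tibble(
      gene_id = gene_id,
      sequence = sequences,
      compartment = compartment,
      go_terms = draw_terms(vocab$term_id, 3, is_gene),
      pathway_ids = draw_terms(pathways, 1.5, is_gene)
    )
    attr(tx, "go_vocabulary") <- vocab
    tx
  })
}

#' Long-format annotation table of a synthetic transcriptome
#'
#' Unnests the per-gene GO and pathway assignments into the
#' `gene_id, term_id, namespace` shape the enrichment module consumes
#' (pathways get namespace `"pathway"`).
#'
#' @param transcriptome Output of [generate_transcriptome()].
#' @return A tibble with columns `gene_id`, `term_id`, `namespace`.
#' @export
annotation_table <- function(transcriptome) {
  vocab <- attr(transcriptome, "go_vocabulary")
  go <- transcriptome |>
    select("gene_id", term_id = "go_terms") |>
    tidyr::unnest_longer("term_id") |>
    left_join(vocab, by = "term_id")
  kegg <- transcriptome |>
    select("gene_id", term_id = "pathway_ids") |>
    tidyr::unnest_longer("term_id") |>
    mutate(namespace = "pathway")
  bind_rows(go, kegg) |> filter(!is.na(.data$term_id))
}

#' Write / read a transcriptome as FASTA
#'
#' @param transcriptome Tibble with `gene_id` and `sequence` columns.
#' @param path File path.
#' @return `write_transcriptome_fasta()` returns `path` invisibly;
#'   `read_transcriptome_fasta()` returns a tibble with `gene_id`,
#'   `sequence` and a `compartment` column parsed from the FASTA description
#'   (written as `compartment=<value>`).
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  seqs <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(seqs) <- paste0(transcriptome$gene_id, " compartment=",
                        transcriptome$compartment)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' @rdname write_transcriptome_fasta
#' @export
read_transcriptome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  comp <- stringr::str_match(hdr, "compartment=(\\S+)")[, 2]
  tibble(
    gene_id = stringr::str_extract(hdr, "^\\S+"),
    sequence = unname(as.character(seqs)),
    compartment = dplyr::coalesce(comp, "gene")
  )
}
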