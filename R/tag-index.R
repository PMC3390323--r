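# Virtual CATG+17 tag library construction.

# All usable NlaIII tag sites in one strand of one sequence: every CATG with
# >= 17 downstream bases. Rank 1 is the 3'-most usable site, matching MmeI
# tag release from the 3'-most anchor retained on the oligo-dT bead.
scan_tag_sites <- function(sequence) {
  hits <- stringr::str_locate_all(sequence, stringr::fixed(NLAIII_ANCHOR))[[1]]
  if (nrow(hits) == 0) {
    return(tibble(tag = character(0), site_rank = integer(0)))
  }
  starts <- hits[, 1]
  usable <- starts + TAG_WIDTH - 1L <= nchar(sequence)
  starts <- starts[usable]
  if (length(starts) == 0) {
    return(tibble(tag = character(0), site_rank = integer(0)))
  }
  tibble(
    tag = stringr::str_sub(sequence, starts, starts + TAG_WIDTH - 1L),
    site_rank = rev(seq_along(starts))
  )
}

#' Canonical DGE tag of a transcript
#'
#' The 21-bp tag (CATG anchor + 17 bases) released from the 3'-most usable
#' NlaIII site of the given strand, or `NA` when the strand carries no
#' usable site.
#'
#' @param sequence Character vector of transcript sequences.
#' @param strand `"sense"` or `"antisense"` (the reverse complement is
#'   scanned for antisense).
#' @return Character vector of 21-mers (or `NA`).
#' @export
#' @examples
#' canonical_tag("AACATGACGTACGTACGTACGTACC")
canonical_tag <- function(sequence, strand = c("sense", "antisense")) {
  strand <- match.arg(strand)
  if (strand == "antisense") sequence <- reverse_complement(sequence)
  vapply(sequence, function(s) {
    sites <- scan_tag_sites(s)
    if (nrow(sites) == 0) NA_character_ else sites$tag[sites$site_rank == 1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Build the virtual CATG+17 tag index
#'
#' Enumerates, for every reference record and both strands, every CATG
#' occurrence followed by at least 17 bases, yielding the complete virtual
#' library of observable 21-bp tags. Site ranks count from the 3' end of
#' the scanned strand (rank 1 = 3'-most).
#'
#' @param transcriptome Tibble with `gene_id`, `sequence` and `compartment`
#'   columns (see [generate_transcriptome()]).
#' @return A tibble of class `tag_index` with columns `tag`, `gene_id`,
#'   `strand`, `site_rank`, `compartment`, and attribute
#'   `catg_gene_fraction`: the fraction of `gene` records with >= 1 usable
#'   sense-strand site.
#' @export
build_tag_index <- function(transcriptome) {
  stopifnot(all(c("gene_id", "sequence", "compartment") %in%
                  names(transcriptome)))
  scan_strand <- function(seqs, strand) {
    sites <- lapply(seqs, scan_tag_sites)
    n_sites <- vapply(sites, nrow, integer(1))
    out <- bind_rows(sites)
    out$gene_id <- rep(transcriptome$gene_id, n_sites)
    out$compartment <- rep(transcriptome$compartment, n_sites)
    out$strand <- strand
    out
  }
  sense <- scan_strand(transcriptome$sequence, "sense")
  anti <- scan_strand(reverse_complement(transcriptome$sequence), "antisense")
  idx <- bind_rows(sense, anti) |>
    select("tag", "gene_id", "strand", "site_rank", "compartment")

  is_gene <- transcriptome$compartment == "gene"
  frac <- if (any(is_gene)) {
    with_sites <- unique(sense$gene_id)
    mean(transcriptome$gene_id[is_gene] %in% with_sites)
  } else {
    NA_real_
  }
  attr(idx, "catg_gene_fraction") <- frac
  class(idx) <- c("tag_index", class(idx))
  idx
}

#' @exportS3Method generics::glance
glance.tag_index <- function(x, ...) {
  tibble(
    n_entries = nrow(x),
    n_distinct_tags = dplyr::n_distinct(x$tag),
    n_genes = dplyr::n_distinct(x$gene_id[x$compartment == "gene"]),
    catg_gene_fraction = attr(x, "catg_gene_fraction")
  )
}

#' Serialize / load a tag index as TSV
#'
#' @param index A `tag_index`.
#' @param path File path.
#' @return The path (write) or the reconstructed `tag_index` (read).
#' @export
write_tag_index <- function(index, path) {
  readr::write_tsv(as_tibble(index), path)
  invisible(path)
}

#' @rdname write_tag_index
#' @export
read_tag_index <- function(path) {
  idx <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           tag = "c", gene_id = "c", strand = "c",
                           site_rank = "i", compartment = "c"
                         ))
  class(idx) <- c("tag_index", class(idx))
  idx
}
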