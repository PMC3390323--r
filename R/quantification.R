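#' Normalize tag counts to transcripts per million clean tags (TPM)
#'
#' `tpm = count * 1e6 / clean_total`. The denominator is the library's
#' clean-tag total (the defining convention for DGE tag profiling), not the
#' mapped total; the mapped fraction is recoverable as `sum(tpm) / 1e6`.
#'
#' @param counts Data frame with a `count` column (and typically
#'   `gene_id`).
#' @param clean_total Library clean-tag total; must be > 0.
#' @return The input tibble with a `tpm` column appended.
#' @export
#' @examples
#' compute_tpm(tibble::tibble(gene_id = "G1", count = 50), 5000)
compute_tpm <- function(counts, clean_total) {
  stopifnot("count" %in% names(counts))
  assert_counts(counts$count, "count")
  assert_scalar_number(clean_total, "clean_total", min = 0, strict_min = TRUE)
  as_tibble(counts) |>
    mutate(tpm = .data$count * 1e6 / clean_total)
}

#' Per-gene expression profile of a mapped library
#'
#' Unambiguous per-gene tag counts (sense by default, optionally sense +
#' antisense) normalized to TPM over the library's clean total.
#'
#' @param mapping A `mapping_result` from [map_tags()].
#' @param strand `"sense"` (default, the usual expression measure) or
#'   `"both"`.
#' @return Tibble `gene_id`, `count`, `tpm` with attributes `library_id`,
#'   `clean_total` and `mapped_total`.
#' @export
expression_profile <- function(mapping, strand = c("sense", "both")) {
  stopifnot(inherits(mapping, "mapping_result"))
  strand <- match.arg(strand)
  gc <- mapping$gene_counts
  cnt <- if (strand == "sense") gc$sense_count else
    gc$sense_count + gc$antisense_count
  out <- compute_tpm(tibble(gene_id = gc$gene_id, count = cnt),
                     mapping$clean_total)
  attr(out, "library_id") <- mapping$library_id
  attr(out, "clean_total") <- mapping$clean_total
  attr(out, "mapped_total") <- sum(cnt)
  out
}

#' Tag-abundance distribution
#'
#' Bins clean tags by copy number into the three conventional abundance
#' categories `[2,5]`, `(5,100]` and `(100, Inf)` (closed-left at the
#' overlapping edges) and reports the percentage of distinct tags and of
#' total tag mass per bin.
#'
#' @param library A `tag_library`.
#' @return Tibble `bin`, `distinct_pct`, `total_pct`; each percentage
#'   column sums to 100 (all zero, with a warning, for an empty library).
#' @export
abundance_distribution <- function(library) {
  stopifnot(inherits(library, "tag_library"))
  bins <- c("2-5", "5-100", ">100")
  tc <- library$tag_counts
  if (nrow(tc) == 0) {
    warn("Empty library: abundance distribution is all zero.")
    return(tibble(bin = bins, distinct_pct = 0, total_pct = 0))
  }
  bin <- cut(tc$count, breaks = c(-Inf, 5, 100, Inf), labels = bins)
  tibble(count = tc$count, bin = bin) |>
    group_by(bin = factor(.data$bin, levels = bins), .drop = FALSE) |>
    summarise(distinct_pct = 100 * dplyr::n() / nrow(tc),
              total_pct = 100 * sum(.data$count) / sum(tc$count),
              .groups = "drop") |>
    mutate(bin = as.character(.data$bin))
}

#' Sequencing saturation analysis
#'
#' Subsamples the clean-tag stream (without replacement, nested so the
#' curve is deterministically non-decreasing for a fixed seed) at a grid of
#' depths and counts the genes detected with at least one unambiguous
#' mapped tag. The reported plateau depth is the first grid depth at which
#' the relative gain in detected genes over the previous grid point falls
#' below `plateau_threshold`.
#'
#' @param mapping A `mapping_result`.
#' @param depths Ascending integer grid of subsampling depths; depths
#'   beyond the clean total are dropped with a warning.
#' @param seed Optional integer seed for the subsampling permutation.
#' @param plateau_threshold Relative per-step gain under which the curve is
#'   considered flat (default 0.01).
#' @return Tibble `depth`, `detected_genes`, with attribute
#'   `plateau_depth` (`NA` if the curve never flattens on the grid).
#' @export
saturation_curve <- function(mapping, depths, seed = NULL,
                             plateau_threshold = 0.01) {
  stopifnot(inherits(mapping, "mapping_result"))
  if (is.unsorted(depths)) abort("`depths` must be ascending.")
  total <- sum(mapping$assignments$count)
  if (any(depths > total)) {
    warn(sprintf("Depths beyond the available %d clean tags were dropped.",
                 total))
    depths <- depths[depths <= total]
  }
  a <- mapping$assignments
  stream_gene <- rep(ifelse(a$category == "gene_unambiguous", a$gene_id,
                            NA_character_),
                     a$count)
  with_seed_if(seed, {
    stream_gene <- sample(stream_gene)
    first_seen <- tapply(seq_along(stream_gene), stream_gene, min)
    detected <- vapply(depths, function(d) sum(first_seen <= d), numeric(1))
    out <- tibble(depth = as.integer(depths),
                  detected_genes = as.integer(detected))
    gain <- diff(out$detected_genes) / pmax(head(out$detected_genes, -1), 1)
    flat <- which(gain < plateau_threshold)
    attr(out, "plateau_depth") <-
      if (length(flat) > 0) out$depth[flat[1] + 1L] else NA_integer_
    out
  })
}
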