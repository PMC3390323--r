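#' Hypergeometric term enrichment of a DE gene set
#'
#' Over-representation test of differentially expressed genes against
#' GO-term / pathway annotations relative to the annotated background:
#' for a term annotating `K` of `N` background genes, of which `k` fall in
#' the DE set of size `n`, the p-value is the upper hypergeometric tail
#' `P(X >= k)`. When the annotation carries a `namespace` column the
#' Benjamini-Hochberg correction is applied within each namespace
#' separately, otherwise across all terms.
#'
#' @param de_genes Character vector of DE gene identifiers; must be a
#'   subset of `background`.
#' @param annotation Tibble with `gene_id`, `term_id` and optionally
#'   `namespace` columns (see [annotation_table()]).
#' @param background Character vector of background gene identifiers;
#'   defaults to all genes in `annotation`.
#' @return Tibble of class `tag_enrichment`, sorted by ascending p:
#'   `term_id`, (`namespace`,) `k`, `n`, `K`, `N`, `p_value`, `fdr`.
#'   Terms with no background annotation are excluded.
#' @export
hypergeom_enrich <- function(de_genes, annotation, background = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  background <- unique(background %||% annotation$gene_id)
  de_genes <- unique(de_genes)
  missing <- setdiff(de_genes, background)
  if (length(missing) > 0) {
    abort(paste0("DE genes absent from the background: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..."))
  }
  keep <- intersect(c("term_id", "namespace", "gene_id"), names(annotation))
  ann <- as_tibble(annotation)[keep] |>
    filter(.data$gene_id %in% background) |>
    distinct()
  N <- length(background)
  n <- length(de_genes)
  grp_cols <- intersect(c("term_id", "namespace"), keep)
  rows <- ann |>
    group_by(!!!rlang::syms(grp_cols)) |>
    summarise(K = dplyr::n(),
              k = sum(.data$gene_id %in% de_genes), .groups = "drop") |>
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                       lower.tail = FALSE)
    )
  if ("namespace" %in% names(rows)) {
    rows <- rows |>
      group_by(.data$namespace) |>
      mutate(fdr = bh_fdr(.data$p_value)) |>
      ungroup()
  } else {
    rows <- mutate(rows, fdr = bh_fdr(.data$p_value))
  }
  out <- rows |>
    select(dplyr::any_of(c("term_id", "namespace")), "k", "n", "K", "N",
           "p_value", "fdr") |>
    arrange(.data$p_value, .data$term_id)
  class(out) <- c("tag_enrichment", class(out))
  out
}

#' Group enrichment rows by GO namespace
#'
#' Splits an enrichment table into the three GO ontologies (biological
#' process, molecular function, cellular component; anything else,
#' including pathways, keeps its own label) and tallies terms and DE genes
#' per namespace -- the data behind the classic GO classification
#' histogram.
#'
#' @param enrichment A `tag_enrichment` from [hypergeom_enrich()].
#' @param ontology_map Optional tibble `term_id`, `namespace` used when the
#'   enrichment rows carry no namespace; unlabeled terms fall into
#'   `"unknown"`.
#' @return Tibble `namespace`, `n_terms`, `n_de_gene_hits` (sum of `k`),
#'   `results` (list column of the per-namespace rows).
#' @export
classify_go_namespaces <- function(enrichment, ontology_map = NULL) {
  rows <- as_tibble(enrichment)
  if (!"namespace" %in% names(rows)) {
    if (!is.null(ontology_map)) {
      rows <- left_join(rows, as_tibble(ontology_map), by = "term_id")
    } else {
      rows$namespace <- NA_character_
    }
  }
  rows |>
    mutate(namespace = dplyr::coalesce(.data$namespace, "unknown")) |>
    tidyr::nest(results = -"namespace") |>
    mutate(
      n_terms = purrr::map_int(.data$results, nrow),
      n_de_gene_hits = purrr::map_int(.data$results, ~ sum(.x$k))
    ) |>
    select("namespace", "n_terms", "n_de_gene_hits", "results")
}
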