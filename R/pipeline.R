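#' Run the full tag-profiling pipeline on a simulated experiment
#'
#' Convenience wrapper chaining the whole analysis over the eight
#' simulated libraries: clean reads, map tags against the virtual index,
#' build sense expression profiles, and call differential expression for
#' every genotype contrast of the design.
#'
#' @param transcriptome Output of [generate_transcriptome()].
#' @param simulation Output of [simulate_libraries()].
#' @param ... Thresholds passed on to [call_differential()].
#' @return A list of class `dge_experiment`: `libraries` (named list of
#'   `tag_library`), `mappings` (named list of `mapping_result`),
#'   `profiles` (named list of expression tibbles), `de` (named list of
#'   `tag_de`, one per comparison), `index`, `truth`.
#' @export
run_dge_experiment <- function(transcriptome, simulation, ...) {
  stopifnot(inherits(simulation, "tag_simulation"))
  index <- build_tag_index(transcriptome)
  libraries <- purrr::imap(simulation$reads,
                           ~ clean_reads(.x, library_id = .y))
  mappings <- purrr::map(libraries, map_tags, index = index)
  profiles <- purrr::map(mappings, expression_profile)
  comps <- simulation$truth$comparisons
  de <- purrr::map(seq_len(nrow(comps)), function(i) {
    call_differential(
      profiles[[comps$library_a[i]]], profiles[[comps$library_b[i]]],
      total_a = libraries[[comps$library_a[i]]]$clean_total,
      total_b = libraries[[comps$library_b[i]]]$clean_total,
      ...
    )
  })
  names(de) <- comps$comparison
  structure(
    list(libraries = libraries, mappings = mappings, profiles = profiles,
         de = de, index = index, truth = simulation$truth),
    class = "dge_experiment"
  )
}

#' Planted-truth evaluation of a simulated experiment
#'
#' Compares the significant calls of every comparison with the planted
#' labels: recall (planted genes called significant in the planted
#' direction) and the empirical false-discovery proportion among
#' significant calls.
#'
#' @param experiment A `dge_experiment` from [run_dge_experiment()].
#' @return Tibble `comparison`, `n_planted`, `n_significant`, `recall`,
#'   `fdp`.
#' @export
evaluate_against_truth <- function(experiment) {
  truth <- experiment$truth$de_labels
  purrr::imap(experiment$de, function(de, comp) {
    lab <- truth |> filter(.data$comparison == comp)
    # planted genes that never made it into the tested universe are misses
    planted <- lab |>
      filter(.data$label != "null") |>
      left_join(as_tibble(de), by = "gene_id") |>
      mutate(significant = dplyr::coalesce(.data$significant, FALSE))
    sig <- as_tibble(de) |>
      filter(.data$significant) |>
      left_join(select(lab, "gene_id", "label"), by = "gene_id") |>
      mutate(label = dplyr::coalesce(.data$label, "null"))
    tibble(
      comparison = comp,
      n_planted = nrow(planted),
      n_significant = nrow(sig),
      recall = if (nrow(planted) == 0) NA_real_ else
        mean(planted$significant & planted$direction == planted$label),
      fdp = if (nrow(sig) == 0) 0 else mean(sig$label == "null")
    )
  }) |> bind_rows()
}
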