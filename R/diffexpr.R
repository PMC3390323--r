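#' Call differentially expressed genes between two tag libraries
#'
#' Per-gene Audic-Claverie two-sided p-values over the shared gene
#' universe (union of both profiles, absent genes counted as 0),
#' Benjamini-Hochberg FDR across all tested genes, and the conventional
#' DGE significance rule: `fdr <= max_fdr`, `p <= max_p` and
#' `|log2 ratio| >= min_log2` (boundary ties included). The TPM ratio is
#' `TPM_B / TPM_A`; a zero count is floored at `zero_floor` tags before TPM
#' conversion for the ratio only (p-values always use the true zeros), and
#' a gene absent from both libraries gets ratio 1 by convention.
#'
#' @param profile_a,profile_b Tibbles with `gene_id` and `count` columns
#'   (see [expression_profile()]).
#' @param total_a,total_b Clean-tag totals of the two libraries; default to
#'   the profile attributes, else the count sums.
#' @param max_fdr,max_p,min_log2 Significance thresholds (defaults 0.001,
#'   0.01, 1).
#' @param zero_floor Pseudo-count for zero counts in the ratio (default
#'   0.5).
#' @return A tibble of class `tag_de`: `gene_id`, `x`, `y`, `tpm_a`,
#'   `tpm_b`, `tpm_ratio`, `log2_ratio`, `p_value`, `fdr`, `direction`
#'   (up/down, `NA` at ratio exactly 1), `significant`. Attributes
#'   `total_a`, `total_b`, `thresholds`.
#' @export
call_differential <- function(profile_a, profile_b,
                              total_a = NULL, total_b = NULL,
                              max_fdr = 0.001, max_p = 0.01, min_log2 = 1,
                              zero_floor = 0.5) {
  stopifnot(all(c("gene_id", "count") %in% names(profile_a)),
            all(c("gene_id", "count") %in% names(profile_b)))
  total_a <- total_a %||% attr(profile_a, "clean_total") %||%
    sum(profile_a$count)
  total_b <- total_b %||% attr(profile_b, "clean_total") %||%
    sum(profile_b$count)
  assert_scalar_number(total_a, "total_a", min = 0, strict_min = TRUE)
  assert_scalar_number(total_b, "total_b", min = 0, strict_min = TRUE)

  joined <- dplyr::full_join(
    select(as_tibble(profile_a), "gene_id", x = "count"),
    select(as_tibble(profile_b), "gene_id", y = "count"),
    by = "gene_id"
  ) |>
    mutate(x = dplyr::coalesce(.data$x, 0L),
           y = dplyr::coalesce(.data$y, 0L))
  if (nrow(joined) == 0) {
    out <- tibble(
      gene_id = character(0), x = integer(0), y = integer(0),
      tpm_a = numeric(0), tpm_b = numeric(0), tpm_ratio = numeric(0),
      log2_ratio = numeric(0), p_value = numeric(0), fdr = numeric(0),
      direction = character(0), significant = logical(0)
    )
  } else {
    xf <- pmax(joined$x, zero_floor)
    yf <- pmax(joined$y, zero_floor)
    ratio <- (yf * 1e6 / total_b) / (xf * 1e6 / total_a)
    ratio[joined$x == 0 & joined$y == 0] <- 1
    p <- ac_pvalue_two_sided(joined$x, joined$y, total_a, total_b)
    out <- joined |>
      mutate(
        tpm_a = .data$x * 1e6 / total_a,
        tpm_b = .data$y * 1e6 / total_b,
        tpm_ratio = ratio,
        log2_ratio = log2(ratio),
        p_value = p,
        fdr = bh_fdr(p),
        direction = dplyr::case_when(
          .data$log2_ratio > 0 ~ "up",
          .data$log2_ratio < 0 ~ "down",
          TRUE ~ NA_character_
        ),
        significant = .data$fdr <= max_fdr & .data$p_value <= max_p &
          abs(.data$log2_ratio) >= min_log2
      )
  }
  attr(out, "total_a") <- total_a
  attr(out, "total_b") <- total_b
  attr(out, "thresholds") <- c(max_fdr = max_fdr, max_p = max_p,
                               min_log2 = min_log2)
  class(out) <- c("tag_de", class(out))
  out
}

#' @exportS3Method generics::glance
glance.tag_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$direction == "up", na.rm = TRUE),
    n_down = sum(x$significant & x$direction == "down", na.rm = TRUE),
    total_a = attr(x, "total_a"),
    total_b = attr(x, "total_b")
  )
}

#' Intersections of differential-expression gene sets
#'
#' Cardinalities of every non-empty intersection of the supplied gene
#' sets (each single set, every pair, up to the global intersection) --
#' the Venn-style accounting used to find genes responding across tissues
#' and stress periods.
#'
#' @param sets Named list of character vectors (DE gene identifiers).
#' @return Tibble `sets` (names joined by `&`), `degree`, `n_genes`.
#' @export
intersect_comparisons <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list.")
  }
  k <- length(sets)
  combos <- unlist(lapply(seq_len(k), function(d) {
    utils::combn(names(sets), d, simplify = FALSE)
  }), recursive = FALSE)
  purrr::map(combos, function(cb) {
    common <- purrr::reduce(sets[cb], intersect)
    tibble(
      sets = paste(cb, collapse = " & "),
      degree = length(cb),
      n_genes = length(common)
    )
  }) |> bind_rows()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `tag_de` from [call_differential()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tag_de <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$log2_ratio, y = -log10(pmax(.data$fdr, 1e-300)),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thr[["min_log2"]],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 TPM ratio", y = "-log10 FDR",
                  colour = "significant")
}
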