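# geNorm-style reference-gene stability analysis and Pfaffl
# efficiency-corrected relative quantification for qRT-PCR validation.

# Coerce a wide quantity/Ct table (first column `gene`, one column per
# sample) to a genes x samples matrix.
as_gene_matrix <- function(x, value_name = "quantity") {
  x <- as_tibble(x)
  if (!"gene" %in% names(x)) abort("Input needs a `gene` column.")
  m <- as.matrix(x[setdiff(names(x), "gene")])
  if (!is.numeric(m)) abort(sprintf("All %s columns must be numeric.",
                                    value_name))
  rownames(m) <- x$gene
  m
}

#' Efficiency-corrected relative quantities from Ct values
#'
#' Converts a Ct matrix to relative quantities against a calibrator
#' sample: `q(g, s) = E_g ^ (Ct(g, calibrator) - Ct(g, s))`, the
#' single-gene kernel of the Pfaffl method (a target/reference Pfaffl
#' ratio is the quotient of two such quantities).
#'
#' @param ct Wide tibble: `gene` column plus one numeric Ct column per
#'   sample.
#' @param efficiencies Amplification efficiency per gene (named vector) or
#'   a single value; defaults to the theoretical 2 (perfect doubling).
#' @param calibrator Sample (column) used as calibrator; default first
#'   sample column.
#' @return Tibble in the same wide shape holding relative quantities
#'   (calibrator column all 1). Missing Ct values propagate as `NA` with a
#'   warning.
#' @export
#' @examples
#' ct <- tibble::tibble(gene = "REF1", S1 = 20, S2 = 17)
#' relative_quantities(ct)  # S2: 2^3 = 8
relative_quantities <- function(ct, efficiencies = 2, calibrator = NULL) {
  m <- as_gene_matrix(ct, "Ct")
  if (anyNA(m)) warn("Missing Ct values propagate as NA quantities.")
  calibrator <- calibrator %||% colnames(m)[1]
  if (!calibrator %in% colnames(m)) {
    abort(sprintf("Calibrator sample '%s' not found.", calibrator))
  }
  if (length(efficiencies) == 1 && is.null(names(efficiencies))) {
    eff <- rep(efficiencies, nrow(m))
  } else {
    if (!all(rownames(m) %in% names(efficiencies))) {
      abort("`efficiencies` must cover every gene (named vector).")
    }
    eff <- unname(efficiencies[rownames(m)])
  }
  if (any(eff < 1 | eff > 2.2)) {
    abort("Efficiencies must lie in [1, 2.2].")
  }
  q <- eff ^ (m[, calibrator] - m)
  dplyr::bind_cols(tibble(gene = rownames(m)),
                   as_tibble(as.data.frame(q)))
}

#' geNorm expression-stability measure M
#'
#' For every pair of candidate reference genes j, k the pairwise variation
#' `V_jk` is the standard deviation (n-1 denominator) across samples of
#' the per-sample log2 ratio of their quantities; `M_j` is the mean of
#' `V_jk` over all partners. Low M = stable expression.
#'
#' @param quantities Wide tibble of relative quantities (`gene` column +
#'   samples), all > 0; needs >= 3 genes and >= 2 samples.
#' @return Tibble `gene`, `m`, sorted ascending (most stable first).
#' @export
stability_m <- function(quantities) {
  m <- as_gene_matrix(quantities)
  if (nrow(m) < 3) abort("geNorm needs at least 3 candidate genes.")
  if (ncol(m) < 2) abort("geNorm needs at least 2 samples.")
  if (anyNA(m) || any(m <= 0)) abort("Quantities must be positive and complete.")
  lm2 <- log2(m)
  G <- nrow(m)
  M <- vapply(seq_len(G), function(j) {
    v <- vapply(setdiff(seq_len(G), j),
                function(k) sd(lm2[j, ] - lm2[k, ]), numeric(1))
    mean(v)
  }, numeric(1))
  tibble(gene = rownames(m), m = M) |> arrange(.data$m, .data$gene)
}

#' geNorm stepwise exclusion ranking and pairwise-variation series
#'
#' Iteratively removes the gene with the highest M (ties broken toward
#' the lexicographically smallest identifier), recomputing M on the
#' remainder until two genes are left; the removal order is the stability
#' ranking. Normalization factors `NF_n` are per-sample geometric means of
#' the n most stable genes, and `V_{n/n+1}` is the SD across samples of
#' `log2(NF_n / NF_{n+1})`. The optimal reference count is the smallest
#' `n` with `V_{n/n+1} < v_threshold`, never below 3 (geNorm convention).
#'
#' @inheritParams stability_m
#' @param v_threshold Pairwise-variation cutoff (default 0.15) under which
#'   adding another reference gene is unnecessary.
#' @return Object of class `stability_report`: list with `m_initial`
#'   (tibble from [stability_m()]), `exclusion_order` (least stable
#'   first), `stability_order` (most stable first), `v_series` (tibble
#'   `n`, `v`), `chosen_n`, `v_threshold`.
#' @export
stepwise_ranking <- function(quantities, v_threshold = 0.15) {
  mat <- as_gene_matrix(quantities)
  if (nrow(mat) < 3) abort("geNorm needs at least 3 candidate genes.")
  if (anyNA(mat) || any(mat <= 0)) {
    abort("Quantities must be positive and complete.")
  }
  m_initial <- stability_m(quantities)

  remaining <- rownames(mat)
  excluded <- character(0)
  while (length(remaining) > 2) {
    sub <- tibble(gene = remaining) |>
      dplyr::bind_cols(as_tibble(as.data.frame(mat[remaining, ,
                                                   drop = FALSE])))
    ms <- stability_m(sub)
    worst <- ms$gene[ms$m == max(ms$m)]
    worst <- sort(worst)[1]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  stability_order <- c(sort(remaining), rev(excluded))

  lm2 <- log2(mat)
  G <- nrow(mat)
  nf_log2 <- function(genes) colMeans(lm2[genes, , drop = FALSE])
  v_series <- tibble(
    n = 2:(G - 1),
    v = vapply(2:(G - 1), function(nn) {
      sd(nf_log2(stability_order[seq_len(nn)]) -
           nf_log2(stability_order[seq_len(nn + 1)]))
    }, numeric(1))
  )
  ok <- v_series$n[v_series$v < v_threshold]
  chosen_n <- if (length(ok) == 0) G else max(3L, min(ok))

  structure(
    list(
      m_initial = m_initial,
      exclusion_order = excluded,
      stability_order = stability_order,
      v_series = v_series,
      chosen_n = as.integer(chosen_n),
      v_threshold = v_threshold
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> stability order (best first): %s\n  chosen n = %d (V threshold %.2f)\n",
    paste(x$stability_order, collapse = " > "), x$chosen_n, x$v_threshold
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stability_report <- function(x, ...) {
  x$m_initial |>
    mutate(stability_rank = match(.data$gene, x$stability_order))
}

#' @exportS3Method generics::glance
glance.stability_report <- function(x, ...) {
  tibble(
    chosen_n = x$chosen_n,
    min_v = min(x$v_series$v),
    least_stable = x$exclusion_order[1],
    most_stable = paste(head(x$stability_order, 2), collapse = ", ")
  )
}

#' Pairwise-variation bar chart of a geNorm analysis
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot of the `V_{n/n+1}` series with the decision threshold.
#' @exportS3Method ggplot2::autoplot
autoplot.stability_report <- function(object, ...) {
  df <- object$v_series |>
    mutate(label = sprintf("V%d/%d", .data$n, .data$n + 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$v)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$v_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "pairwise variation V")
}
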