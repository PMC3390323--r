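#' The eight-library two-genotype factorial design
#'
#' Library layout of the emulated experiment: two genotypes (a low-K
#' tolerant and a low-K sensitive variety), two tissues, two stress
#' periods. The four genotype contrasts (tolerant vs sensitive within each
#' tissue x period cell) are the comparisons differential expression is
#' planted into.
#'
#' @return A tibble with columns `library_id` (L1..L8), `genotype`,
#'   `tissue`, `period`.
#' @export
library_design <- function() {
  tibble(
    library_id = paste0("L", 1:8),
    genotype = rep(c("tolerant", "sensitive"), 4),
    tissue = rep(c("root", "root", "shoot", "shoot"), 2),
    period = rep(c("short", "long"), each = 4)
  )
}

comparison_table <- function(design = library_design()) {
  design |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "library_id") |>
    mutate(
      comparison = paste0(.data$tolerant, "_vs_", .data$sensitive),
      library_a = .data$tolerant, library_b = .data$sensitive
    ) |>
    select("comparison", "library_a", "library_b", "tissue", "period")
}

#' Plant per-library expected expression and differential-expression truth
#'
#' Draws a log-normal baseline expression level for every record, then for
#' each of the four genotype contrasts plants `n_de_per_comparison` genes as
#' differentially expressed: the expected expression in the second
#' (sensitive-genotype) library of the pair is multiplied (up) or divided
#' (down) by `effect_size`. Differential expression is planted only among
#' gene records carrying a usable sense-strand CATG site, because tagless
#' genes are invisible to the assay.
#'
#' @param transcriptome Output of [generate_transcriptome()].
#' @param n_de_per_comparison Genes planted per contrast (half up, half
#'   down).
#' @param effect_size Fold change for planted genes; must be >= 2 so
#'   `|log2 fold| >= 1`.
#' @param sdlog Log-normal baseline spread (log scale).
#' @param error_rate Per-base substitution probability carried into
#'   [simulate_libraries()].
#' @param adaptor_fraction Proportion of adaptor-only reads.
#' @param antisense_fraction Proportion of tag mass drawn from the
#'   antisense strand.
#' @param decoy_fractions Named proportions of tag mass drawn from the
#'   mitochondrion / chloroplast / genome decoy records.
#' @param design Library design tibble, see [library_design()].
#' @param seed Optional integer seed.
#'
#' @return A list of class `simulation_truth` with elements `expression`
#'   (tibble `gene_id`, `library_id`, `weight`), `de_labels` (tibble
#'   `gene_id`, `comparison`, `label` in up/down/null for taggable genes),
#'   `comparisons`, `design` and `params`.
#' @export
simulate_truth <- function(transcriptome,
                           n_de_per_comparison = 100L,
                           effect_size = 4,
                           sdlog = 1,
                           error_rate = 0.01,
                           adaptor_fraction = 0.05,
                           antisense_fraction = 0.2,
                           decoy_fractions = c(mitochondrion = 5e-5,
                                               chloroplast = 0.004,
                                               genome = 0.10),
                           design = library_design(),
                           seed = NULL) {
  if (effect_size < 2) {
    abort("`effect_size` must be >= 2 so planted genes have |log2 fold| >= 1.")
  }
  assert_probability(error_rate, "error_rate")
  assert_probability(adaptor_fraction, "adaptor_fraction")
  assert_probability(antisense_fraction, "antisense_fraction")

  with_seed_if(seed, {
    base <- rlnorm(nrow(transcriptome), meanlog = 0, sdlog = sdlog)
    names(base) <- transcriptome$gene_id

    taggable <- transcriptome$gene_id[
      transcriptome$compartment == "gene" &
        !is.na(canonical_tag(transcriptome$sequence))
    ]
    comps <- comparison_table(design)

    expr <- tidyr::expand_grid(
      gene_id = transcriptome$gene_id,
      library_id = design$library_id
    ) |>
      mutate(weight = base[.data$gene_id])

    de <- purrr::map(seq_len(nrow(comps)), function(i) {
      k <- min(n_de_per_comparison, length(taggable))
      picked <- sample(taggable, k)
      tibble(
        gene_id = taggable,
        comparison = comps$comparison[i],
        label = dplyr::case_when(
          taggable %in% picked[seq_len(k %/% 2)] ~ "up",
          taggable %in% picked ~ "down",
          TRUE ~ "null"
        )
      )
    }) |> bind_rows()

    for (i in seq_len(nrow(comps))) {
      lab <- de[de$comparison == comps$comparison[i], ]
      lib_b <- comps$library_b[i]
      up <- lab$gene_id[lab$label == "up"]
      dn <- lab$gene_id[lab$label == "down"]
      sel_up <- expr$library_id == lib_b & expr$gene_id %in% up
      sel_dn <- expr$library_id == lib_b & expr$gene_id %in% dn
      expr$weight[sel_up] <- expr$weight[sel_up] * effect_size
      expr$weight[sel_dn] <- expr$weight[sel_dn] / effect_size
    }

    structure(
      list(
        expression = expr,
        de_labels = de,
        comparisons = comps,
        design = design,
        params = list(
          effect_size = effect_size, sdlog = sdlog, error_rate = error_rate,
          adaptor_fraction = adaptor_fraction,
          antisense_fraction = antisense_fraction,
          decoy_fractions = decoy_fractions, seed = seed
        )
      ),
      class = "simulation_truth"
    )
  })
}

#' Multinomial tag-count sampling
#'
#' Samples `depth` tags from a vector of expected expression weights --
#' the count-level core of the library simulator, also handy on its own
#' for null-calibration experiments on the exact test.
#'
#' @param weights Non-negative expected expression, one entry per gene.
#' @param depth Total tag count to draw.
#' @param seed Optional integer seed.
#' @return Integer vector of counts summing exactly to `depth`, named after
#'   `weights`.
#' @export
simulate_counts <- function(weights, depth, seed = NULL) {
  assert_counts(weights, "weights")
  if (sum(weights) <= 0) abort("`weights` must have positive sum.")
  assert_scalar_number(depth, "depth", min = 1)
  with_seed_if(seed, {
    drop(rmultinom(1, size = as.integer(depth), prob = weights)) |>
      setNames(names(weights))
  })
}

# Substitute sequencing errors into 21-bp tag strings; each base mutates
# independently with probability `error_rate`.
inject_errors <- function(tags, error_rate) {
  if (error_rate <= 0 || length(tags) == 0) return(tags)
  n_err <- rbinom(length(tags), TAG_WIDTH, error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(TAG_WIDTH, n_err[i])
    s <- tags[i]
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(DNA_BASES, old), 1)
    }
    tags[i] <- s
  }
  tags
}

#' Simulate the eight raw 35-bp read sets
#'
#' For each library, tag counts are drawn once from a single multinomial
#' over the library's tag pool: canonical sense tags of taggable genes
#' (mass `1 - adaptor - decoys`, split `(1 - antisense_fraction)` sense /
#' `antisense_fraction` antisense), canonical antisense tags (3'-most
#' CATG+17 site of the reverse-complement strand), organellar/genomic decoy
#' tags, and adaptor-only reads. Per-base substitution errors are then
#' injected into the tag portion and each tag is padded with the fixed
#' 14-bp adaptor suffix to a 35-bp read.
#'
#' @param transcriptome Output of [generate_transcriptome()].
#' @param truth Output of [simulate_truth()].
#' @param depth Reads per library (each library gets exactly `depth`).
#' @param seed Optional integer seed.
#' @return A list of class `tag_simulation`: `reads` (named list, one
#'   character vector of 35-mers per library), `sampled_counts` (tibble
#'   `library_id`, `tag`, `gene_id`, `strand`, `compartment`, `count` of
#'   error-free planted tags), `adaptor_reads` (tibble `library_id`, `n`),
#'   and `truth`.
#' @export
simulate_libraries <- function(transcriptome, truth, depth = 2e5,
                               seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  assert_scalar_number(depth, "depth", min = 1)
  depth <- as.integer(depth)
  p <- truth$params

  sense_tag <- canonical_tag(transcriptome$sequence, "sense")
  anti_tag <- canonical_tag(transcriptome$sequence, "antisense")
  pool0 <- tibble(
    gene_id = transcriptome$gene_id,
    compartment = transcriptome$compartment,
    sense_tag = sense_tag,
    anti_tag = anti_tag
  )

  decoy_mass <- sum(p$decoy_fractions)
  gene_mass <- 1 - p$adaptor_fraction - decoy_mass
  if (gene_mass <= 0) abort("adaptor + decoy fractions must leave room for gene tags.")

  with_seed_if(seed, {
    out_reads <- list()
    counts_all <- list()
    adaptor_n <- integer(0)
    for (lib in truth$design$library_id) {
      w <- truth$expression |> filter(.data$library_id == lib)
      w <- setNames(w$weight, w$gene_id)[pool0$gene_id]

      genes <- pool0$compartment == "gene" & !is.na(pool0$sense_tag)
      sense_w <- w * genes
      anti_ok <- genes & !is.na(pool0$anti_tag)
      anti_w <- w * anti_ok

      rows <- list()
      if (sum(sense_w) > 0) {
        rows$sense <- tibble(
          tag = pool0$sense_tag[sense_w > 0],
          gene_id = pool0$gene_id[sense_w > 0],
          strand = "sense", compartment = "gene",
          prob = gene_mass * (1 - p$antisense_fraction) *
            sense_w[sense_w > 0] / sum(sense_w)
        )
      }
      if (p$antisense_fraction > 0 && sum(anti_w) > 0) {
        rows$anti <- tibble(
          tag = pool0$anti_tag[anti_w > 0],
          gene_id = pool0$gene_id[anti_w > 0],
          strand = "antisense", compartment = "gene",
          prob = gene_mass * p$antisense_fraction *
            anti_w[anti_w > 0] / sum(anti_w)
        )
      } else if (sum(sense_w) > 0) {
        # no antisense mass requested (or no antisense sites): give the
        # full gene mass to the sense tags
        rows$sense$prob <- gene_mass * sense_w[sense_w > 0] / sum(sense_w)
      }
      for (cp in names(p$decoy_fractions)) {
        sel <- pool0$compartment == cp & !is.na(pool0$sense_tag)
        if (p$decoy_fractions[[cp]] > 0 && any(sel)) {
          rows[[cp]] <- tibble(
            tag = pool0$sense_tag[sel],
            gene_id = pool0$gene_id[sel],
            strand = "sense", compartment = cp,
            prob = p$decoy_fractions[[cp]] * w[sel] / sum(w[sel])
          )
        }
      }
      pool <- bind_rows(rows)
      probs <- c(pool$prob, adaptor = p$adaptor_fraction)
      cnt <- drop(rmultinom(1, depth, probs))
      n_adaptor <- cnt[length(cnt)]
      cnt <- cnt[-length(cnt)]

      tags <- rep(pool$tag, cnt)
      tags <- inject_errors(tags, p$error_rate)
      reads <- if (length(tags)) paste0(tags, ADAPTOR_14) else character(0)
      if (n_adaptor > 0) {
        empty <- strrep(ADAPTOR_14, ceiling(READ_WIDTH / nchar(ADAPTOR_14)))
        reads <- c(reads, rep(substr(empty, 1, READ_WIDTH), n_adaptor))
      }
      out_reads[[lib]] <- sample(reads)
      counts_all[[lib]] <- pool |>
        mutate(count = as.integer(cnt), library_id = lib) |>
        filter(.data$count > 0) |>
        select("library_id", "tag", "gene_id", "strand", "compartment",
               "count")
      adaptor_n[lib] <- n_adaptor
    }
    structure(
      list(
        reads = out_reads,
        sampled_counts = bind_rows(counts_all),
        adaptor_reads = tibble(library_id = names(adaptor_n),
                               n = as.integer(adaptor_n)),
        truth = truth
      ),
      class = "tag_simulation"
    )
  })
}

#' Simulate a qPCR Ct matrix with planted reference-gene stability
#'
#' Emulates candidate housekeeping genes measured across samples. Each
#' sample has a shared input-amount offset (cancelling in pairwise gene
#' ratios), each gene a baseline Ct, and per-gene Gaussian noise whose
#' standard deviation (`stability_profile`, in cycles) encodes planted
#' stability: low-noise genes are the stable references a geNorm analysis
#' should keep.
#'
#' @param n_ref_genes Number of candidate reference genes (>= 3, geNorm
#'   needs at least three).
#' @param n_samples Number of samples (columns).
#' @param stability_profile Numeric vector of per-gene Ct noise SDs in
#'   cycles; default plants genes 4 and 5 of five as unstable.
#' @param efficiencies Per-gene amplification efficiencies in `[1.6, 2.1]`.
#' @param seed Optional integer seed.
#' @return A list of class `ct_simulation`: `ct` (tibble, `gene` column +
#'   one column per sample), `efficiencies` (named), `truth` (tibble
#'   `gene`, `noise_sd`, `stability_rank`; rank 1 = most stable).
#' @export
simulate_ct_matrix <- function(n_ref_genes = 5L,
                               n_samples = 8L,
                               stability_profile = c(rep(0.15, n_ref_genes - 2L),
                                                     rep(1, 2L)),
                               efficiencies = rep(2, n_ref_genes),
                               seed = NULL) {
  assert_scalar_number(n_ref_genes, "n_ref_genes", min = 3)
  assert_scalar_number(n_samples, "n_samples", min = 2)
  n_ref_genes <- as.integer(n_ref_genes)
  n_samples <- as.integer(n_samples)
  if (length(stability_profile) != n_ref_genes || any(stability_profile < 0)) {
    abort("`stability_profile` must give one non-negative SD per gene.")
  }
  if (length(efficiencies) != n_ref_genes ||
      any(efficiencies < 1.6 | efficiencies > 2.1)) {
    abort("`efficiencies` must lie in [1.6, 2.1], one per gene.")
  }
  with_seed_if(seed, {
    genes <- sprintf("REF%d", seq_len(n_ref_genes))
    samples <- sprintf("S%d", seq_len(n_samples))
    mu_s <- rnorm(n_samples, 0, 1.5)          # shared cDNA input offset
    base_g <- runif(n_ref_genes, 18, 28)
    eps <- matrix(rnorm(n_ref_genes * n_samples, 0, rep(stability_profile,
                                                        n_samples)),
                  nrow = n_ref_genes)
    ct <- outer(base_g, rep(1, n_samples)) +
      outer(rep(1, n_ref_genes), mu_s) + eps
    ct_tbl <- as_tibble(setNames(as.data.frame(ct), samples))
    ct_tbl <- dplyr::bind_cols(tibble(gene = genes), ct_tbl)
    structure(
      list(
        ct = ct_tbl,
        efficiencies = setNames(efficiencies, genes),
        truth = tibble(
          gene = genes, noise_sd = stability_profile,
          stability_rank = rank(stability_profile, ties.method = "first")
        )
      ),
      class = "ct_simulation"
    )
  })
}
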