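# Virtual-library construction and mismatch-tiered tag assignment.

lib_from <- function(tags, counts = rep(2L, length(tags))) {
  tag_library_from_counts(tibble::tibble(tag = tags, count = counts))
}

test_that("index entries match constructed sequences and skip CATG-free ones", {
  tx <- toy_transcriptome(c(
    "AACATGACGTACGTACGTACGTACC",       # one usable sense site
    strrep("A", 40)                    # no CATG at all
  ))
  idx <- build_tag_index(tx)
  sense <- idx[idx$strand == "sense" & idx$gene_id == "T01", ]
  expect_equal(sense$tag, "CATGACGTACGTACGTACGTA")
  expect_equal(sense$site_rank, 1L)
  expect_false("T02" %in% idx$gene_id)
  expect_equal(attr(idx, "catg_gene_fraction"), 0.5)
})

test_that("site ranks count from the 3' end", {
  two_sites <- paste0("CATG", strrep("A", 17), "CATG", strrep("C", 17))
  idx <- build_tag_index(toy_transcriptome(two_sites))
  sense <- idx[idx$strand == "sense", ]
  expect_equal(sense$site_rank[sense$tag == paste0("CATG", strrep("C", 17))],
               1L)
  expect_equal(sense$site_rank[sense$tag == paste0("CATG", strrep("A", 17))],
               2L)
})

test_that("index keys equal a brute-force scan of both strands", {
  tx <- generate_transcriptome(100, length_range = c(60, 400), seed = 13)
  idx <- build_tag_index(tx)
  expect_setequal(unique(idx$tag), oracle_index_keys(tx$sequence))
})

test_that("exact single-gene hits are unambiguous; shared tags are not", {
  shared <- paste0("CATG", strrep("G", 17))
  tx <- toy_transcriptome(c(
    paste0("TT", shared, "TT"),
    paste0("AAAA", shared),
    paste0("CC", "CATG", strrep("A", 17))
  ))
  idx <- build_tag_index(tx)
  lib <- lib_from(c(shared, paste0("CATG", strrep("A", 17))))
  mr <- map_tags(lib, idx)
  amb <- mr$assignments[mr$assignments$tag == shared, ]
  expect_equal(amb$category, "gene_ambiguous")
  una <- mr$assignments[mr$assignments$tag == paste0("CATG", strrep("A", 17)), ]
  expect_equal(una$category, "gene_unambiguous")
  expect_equal(una$gene_id, "T03")
  expect_equal(una$strand, "sense")
  expect_false("T01" %in% mr$gene_counts$gene_id)
})

test_that("one-mismatch hits resolve to the unique closest gene", {
  base <- paste0("CATG", strrep("A", 17))
  tx <- toy_transcriptome(paste0("GG", base, "GG"))
  idx <- build_tag_index(tx)
  mut <- paste0("CATG", "T", strrep("A", 16))  # distance 1 from base
  mr <- map_tags(lib_from(mut), idx)
  expect_equal(mr$assignments$category, "gene_unambiguous")
  expect_equal(mr$assignments$match_type, "mismatch")
  expect_equal(mr$assignments$gene_id, "T01")
  # distance-2 tags stay unknown
  mut2 <- paste0("CATG", "TT", strrep("A", 15))
  mr2 <- map_tags(lib_from(mut2), idx)
  expect_equal(mr2$assignments$category, "unknown")
})

test_that("tags lacking the CATG anchor are removed before mapping", {
  lib <- lib_from(paste0("CTTG", strrep("A", 17)))
  expect_equal(lib$distinct_count, 0L)
  expect_equal(lib$ledger[["no_anchor"]], 2L)
})

test_that("random toys agree with the exhaustive Hamming oracle", {
  for (seed in 1:15) {
    tx <- generate_transcriptome(
      8, length_range = c(50, 120),
      compartment_fractions = c(gene = 0.75, mitochondrion = 0.08,
                                chloroplast = 0.08, genome = 0.09),
      seed = 100 + seed
    )
    idx <- build_tag_index(tx)
    withr::with_seed(200 + seed, {
      picks <- sample(unique(idx$tag), min(8, dplyr::n_distinct(idx$tag)))
      mutated <- vapply(picks, function(t) {
        pos <- sample(5:21, 1)
        substr(t, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(t, pos, pos)), 1)
        t
      }, character(1), USE.NAMES = FALSE)
      randoms <- replicate(4, paste0("CATG", paste(
        sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = ""
      )))
    })
    tags <- unique(c(picks, mutated, randoms))
    mr <- map_tags(lib_from(tags), idx)
    idx_tbl <- tibble::as_tibble(idx)
    for (i in seq_along(tags)) {
      o <- oracle_map_tag(tags[i], idx_tbl)
      row <- mr$assignments[mr$assignments$tag == tags[i], ]
      expect_equal(row$category, o$category, label = tags[i])
      expect_equal(row$gene_id, o$gene_id, label = tags[i])
      expect_equal(row$strand, o$strand, label = tags[i])
    }
    # category totals must partition the clean totals exactly
    cs <- mr$category_summary
    expect_equal(sum(cs$total), sum(mr$assignments$count))
    expect_equal(sum(cs$distinct), nrow(mr$assignments))
  }
})

test_that("antisense fractions behave at the extremes and under simulation", {
  # asymmetric flanks so the sense tag (CATG + A17) and the antisense tag
  # (CATG + C17, from the reverse complement) are distinct
  base <- paste0(strrep("G", 20), "CATG", strrep("A", 17), strrep("T", 20))
  tx <- toy_transcriptome(base)
  idx <- build_tag_index(tx)
  sense_only <- map_tags(lib_from(paste0("CATG", strrep("A", 17))), idx)
  expect_equal(antisense_report(sense_only)$antisense_fraction, 0)

  anti_tag <- idx$tag[idx$strand == "antisense" & idx$site_rank == 1][1]
  all_anti <- map_tags(lib_from(anti_tag), idx)
  expect_equal(antisense_report(all_anti)$antisense_fraction, 1)

  none <- map_tags(clean_reads(character(0)), idx)
  expect_true(is.na(antisense_report(none)$antisense_fraction))

  # simulated 20% antisense mass at depth 1e5 lands within 3 SD
  tx2 <- generate_transcriptome(200, length_range = c(600, 1200),
                                seed = 41)
  truth <- simulate_truth(tx2, n_de_per_comparison = 0, sdlog = 0.5,
                          error_rate = 0, adaptor_fraction = 0,
                          antisense_fraction = 0.2,
                          decoy_fractions = c(mitochondrion = 0,
                                              chloroplast = 0, genome = 0),
                          seed = 42)
  sim <- simulate_libraries(tx2, truth, depth = 1e5, seed = 43)
  mr <- map_tags(clean_reads(sim$reads$L1, "L1"), build_tag_index(tx2))
  frac <- antisense_report(mr)$antisense_fraction
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))
})

test_that("error-free decoy-free mapping reproduces planted counts exactly", {
  tx <- generate_transcriptome(300, length_range = c(300, 900), seed = 51)
  truth <- simulate_truth(tx, n_de_per_comparison = 20, error_rate = 0,
                          adaptor_fraction = 0,
                          decoy_fractions = c(mitochondrion = 0,
                                              chloroplast = 0, genome = 0),
                          seed = 52)
  sim <- simulate_libraries(tx, truth, depth = 5e4, seed = 53)
  idx <- build_tag_index(tx)
  lib <- clean_reads(sim$reads$L2, "L2")
  mr <- map_tags(lib, idx)
  expect_equal(
    mr$category_summary$total[mr$category_summary$category == "unknown"], 0
  )
  planted <- sim$sampled_counts |>
    dplyr::filter(library_id == "L2", count >= 2) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(
      sense = sum(count[strand == "sense"]),
      anti = sum(count[strand == "antisense"]),
      .groups = "drop"
    ) |>
    dplyr::filter(sense + anti > 0) |>
    dplyr::arrange(gene_id)
  got <- mr$gene_counts |> dplyr::arrange(gene_id)
  expect_equal(got$gene_id, planted$gene_id)
  expect_equal(got$sense_count, planted$sense)
  expect_equal(got$antisense_count, planted$anti)
})

test_that("index TSV round trip preserves entries", {
  tx <- generate_transcriptome(20, seed = 61)
  idx <- build_tag_index(tx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tag_index(idx, path)
  back <- read_tag_index(path)
  for (col in c("tag", "gene_id", "strand", "site_rank", "compartment")) {
    expect_identical(back[[col]], idx[[col]])
  }
})
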