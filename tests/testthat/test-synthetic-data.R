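# Synthetic transcriptome, library and Ct-matrix generators.

test_that("a forced sequence yields the expected canonical tag", {
  tx <- generate_transcriptome(1, sequences = "AACATGACGTACGTACGTACGTACC",
                               seed = 7)
  expect_equal(canonical_tag(tx$sequence), "CATGACGTACGTACGTACGTA")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_transcriptome(50, seed = 42)
  b <- generate_transcriptome(50, seed = 42)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$go_terms, b$go_terms)
  fa <- withr::local_tempfile(fileext = ".fa")
  fb <- withr::local_tempfile(fileext = ".fa")
  write_transcriptome_fasta(a, fa)
  write_transcriptome_fasta(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  rt <- read_transcriptome_fasta(fa)
  expect_identical(rt$sequence, a$sequence)
  expect_identical(rt$compartment, a$compartment)
})

test_that("too-short length ranges are rejected with a clear message", {
  expect_error(generate_transcriptome(5, length_range = c(10, 20)),
               "too short")
  expect_error(generate_transcriptome(5, compartment_fractions = c(gene = 2)),
               "sum to 1")
})

test_that("CATG-bearing gene fraction matches the analytic occupancy", {
  tx <- generate_transcriptome(
    1000, length_range = c(200, 2000),
    compartment_fractions = c(gene = 1, mitochondrion = 0,
                              chloroplast = 0, genome = 0),
    seed = 11
  )
  idx <- build_tag_index(tx)
  observed <- attr(idx, "catg_gene_fraction")

  # independent scan of every generated sequence
  scanned <- mean(vapply(tx$sequence, function(s) {
    starts <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    any(starts > 0 & starts + 20 <= nchar(s))
  }, logical(1)))
  expect_identical(observed, scanned)

  # analytic: CATG cannot overlap itself, so P(no hit in m bases) follows
  # the renewal recursion a(m) = a(m-1) - p a(m-4), p = 4^-4. A usable
  # site needs 17 downstream bases, i.e. no hit in the first L-17 bases.
  p <- 4^-4
  mmax <- max(nchar(tx$sequence))
  a <- rep(1, mmax)
  for (m in 4:mmax) {
    prev <- if (m == 4) 1 else a[m - 4]
    a[m] <- a[m - 1] - p * prev
  }
  p_gene <- 1 - a[nchar(tx$sequence) - 17]
  se <- sqrt(mean(p_gene * (1 - p_gene)) / length(p_gene))
  expect_lt(abs(observed - mean(p_gene)), 3 * se)
})

test_that("error-free single-gene libraries carry only the canonical tag", {
  seqs <- paste0(strrep("T", 30), "CATGACGTACGTACGTACGTA", strrep("G", 30))
  tx <- generate_transcriptome(
    1, sequences = seqs,
    compartment_fractions = c(gene = 1, mitochondrion = 0,
                              chloroplast = 0, genome = 0), seed = 1
  )
  truth <- simulate_truth(tx, n_de_per_comparison = 0, error_rate = 0,
                          adaptor_fraction = 0, antisense_fraction = 0,
                          decoy_fractions = c(mitochondrion = 0,
                                              chloroplast = 0, genome = 0),
                          seed = 2)
  sim <- simulate_libraries(tx, truth, depth = 500, seed = 3)
  expect_true(all(lengths(sim$reads) == 500))
  expect_true(all(nchar(sim$reads$L1) == 35))
  expect_true(all(substr(sim$reads$L1, 1, 21) == canonical_tag(seqs)))
})

test_that("multinomial sampling respects planted fold changes and depth", {
  counts <- simulate_counts(c(g1 = 1, g2 = 2), depth = 1e5, seed = 9)
  expect_identical(sum(counts), 100000L)
  ci <- stats::binom.test(counts[["g2"]], 1e5)$conf.int
  expect_gt(2 / 3, ci[1])
  expect_lt(2 / 3, ci[2])
})

test_that("adaptor-only reads appear at the requested rate", {
  tx <- generate_transcriptome(30, seed = 4)
  truth <- simulate_truth(tx, n_de_per_comparison = 0, error_rate = 0,
                          adaptor_fraction = 0.1, seed = 5)
  sim <- simulate_libraries(tx, truth, depth = 1e4, seed = 6)
  n_empty <- sim$adaptor_reads$n[sim$adaptor_reads$library_id == "L1"]
  expect_lt(abs(n_empty - 1000), 3 * sqrt(1e4 * 0.1 * 0.9))
})

test_that("error-free reads all exist in the virtual tag index", {
  tx <- generate_transcriptome(40, seed = 21)
  truth <- simulate_truth(tx, n_de_per_comparison = 0, error_rate = 0,
                          adaptor_fraction = 0,
                          decoy_fractions = c(mitochondrion = 0,
                                              chloroplast = 0, genome = 0),
                          seed = 22)
  sim <- simulate_libraries(tx, truth, depth = 2000, seed = 23)
  idx <- build_tag_index(tx)
  expect_true(all(substr(sim$reads$L3, 1, 21) %in% idx$tag))
})

test_that("Ct simulation is reproducible and noise-free when asked", {
  a <- simulate_ct_matrix(5, 6, seed = 31)
  b <- simulate_ct_matrix(5, 6, seed = 31)
  expect_identical(a$ct, b$ct)

  quiet <- simulate_ct_matrix(4, 6, stability_profile = rep(0, 4), seed = 32)
  q <- relative_quantities(quiet$ct)
  m <- stability_m(q)
  expect_equal(m$m, rep(0, 4), tolerance = 1e-12)

  expect_error(simulate_ct_matrix(2, 4), ">= 3")
  expect_error(simulate_ct_matrix(5, 4, efficiencies = rep(3, 5)),
               "\\[1.6, 2.1\\]")
})
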