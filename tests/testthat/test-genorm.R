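# geNorm stability analysis and Pfaffl relative quantification.

wide_q <- function(mat) {
  dplyr::bind_cols(tibble::tibble(gene = rownames(mat)),
                   tibble::as_tibble(as.data.frame(mat)))
}

test_that("relative quantities follow the efficiency-corrected formula", {
  ct <- tibble::tibble(gene = c("tgt", "ref"), S1 = c(25, 22),
                       S2 = c(22, 21))
  q <- relative_quantities(ct, efficiencies = 2, calibrator = "S1")
  expect_equal(q$S1, c(1, 1))           # delta Ct = 0
  expect_equal(q$S2[q$gene == "tgt"], 8)  # 2^3
  # Pfaffl ratio: E_t^dCt_t / E_r^dCt_r = 8 / 2 = 4
  expect_equal(q$S2[q$gene == "tgt"] / q$S2[q$gene == "ref"], 4)

  expect_warning(relative_quantities(
    tibble::tibble(gene = "g", S1 = 20, S2 = NA_real_)
  ), "Missing")
  expect_error(relative_quantities(ct, calibrator = "S9"), "not found")
})

test_that("proportional genes have zero pairwise variation", {
  m <- rbind(g1 = c(1, 2, 4, 8), g2 = c(3, 6, 12, 24),
             g3 = c(1, 3, 2, 5))
  ms <- stability_m(wide_q(m))
  # V(g1, g2) = 0, so M_g1 = M_g2 = V(g1, g3)/2 ... both below M_g3
  expect_equal(ms$m[ms$gene == "g1"], ms$m[ms$gene == "g2"],
               tolerance = 1e-12)
  v13 <- stats::sd(log2(m["g1", ] / m["g3", ]))
  expect_equal(ms$m[ms$gene == "g1"], v13 / 2, tolerance = 1e-12)
})

test_that("M matches the explicit double-loop oracle", {
  withr::with_seed(23, {
    m <- matrix(2 ^ rnorm(4 * 6, sd = 1), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("S", 1:6)))
  })
  ms <- stability_m(wide_q(m))
  oracle <- oracle_genorm_m(m)
  expect_equal(ms$m, unname(oracle[ms$gene]), tolerance = 1e-10)
})

test_that("M is invariant to per-gene scaling and sample order", {
  withr::with_seed(24, {
    m <- matrix(2 ^ rnorm(5 * 8), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("S", 1:8)))
  })
  base <- stability_m(wide_q(m))
  scaled <- m
  scaled["g2", ] <- scaled["g2", ] * 77
  expect_equal(stability_m(wide_q(scaled))$m, base$m, tolerance = 1e-12)
  perm <- m[, sample(8)]
  expect_equal(stability_m(wide_q(perm))$m, base$m, tolerance = 1e-12)
})

test_that("stepwise exclusion and the V series match a 4-gene hand oracle", {
  withr::with_seed(25, {
    m <- matrix(2 ^ rnorm(4 * 6, sd = c(0.1, 0.1, 0.4, 1.5)), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("S", 1:6)))
  })
  rep4 <- stepwise_ranking(wide_q(m))
  # hand-rolled: first exclusion is the max-M gene of the full set
  ms <- oracle_genorm_m(m)
  expect_equal(rep4$exclusion_order[1], names(which.max(ms)))
  # V3/4 oracle: geometric means over the 3 and 4 most stable genes
  ord <- rep4$stability_order
  nf3 <- exp(colMeans(log(m[ord[1:3], ])))
  nf4 <- exp(colMeans(log(m[ord[1:4], ])))
  expect_equal(rep4$v_series$v[rep4$v_series$n == 3],
               stats::sd(log2(nf3 / nf4)), tolerance = 1e-10)
})

test_that("proportional candidates give all-zero M and the minimum n", {
  m <- rbind(g1 = c(1, 2, 4, 8), g2 = 3 * c(1, 2, 4, 8),
             g3 = 0.5 * c(1, 2, 4, 8), g4 = 10 * c(1, 2, 4, 8))
  rep0 <- stepwise_ranking(wide_q(m))
  expect_equal(rep0$m_initial$m, rep(0, 4))
  expect_equal(rep0$v_series$v, rep(0, 2))
  expect_equal(rep0$chosen_n, 3L)
})

test_that("ties at the maximum M exclude the lexicographically first gene", {
  # two samples; log2 quantities g1 = (0, 0), g2 = (0, d), g3 = (0, d/2)
  # give M_g1 = M_g2 > M_g3
  d <- 2
  m <- rbind(g1 = c(1, 1), g2 = c(1, 2 ^ d), g3 = c(1, 2 ^ (d / 2)))
  rep_t <- stepwise_ranking(wide_q(m))
  expect_equal(rep_t$exclusion_order, "g1")
})

test_that("planted unstable references are excluded first", {
  sim <- simulate_ct_matrix(5, 8, stability_profile = c(0.15, 0.15, 0.15,
                                                        1, 1), seed = 77)
  q <- relative_quantities(sim$ct, efficiencies = sim$efficiencies)
  rep5 <- stepwise_ranking(q)
  expect_setequal(rep5$exclusion_order[1:2], c("REF4", "REF5"))
  expect_error(stability_m(q[1:2, ]), "at least 3")
})
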