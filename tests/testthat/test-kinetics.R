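test_that("exonic coverage follows the linear ramp before the wave reaches the TES", {
  m <- toy_gene()
  r <- toy_rates()
  # sigma (t - x/v): 2 * (5 - 1) = 8
  expect_equal(expected_coverage(m, r, 5, bins = 1000), 8, tolerance = 1e-8)
  expect_equal(expected_coverage(m, r, 3, bins = 0), 6, tolerance = 1e-8)
  # not yet transcribed
  expect_equal(expected_coverage(m, r, 3, bins = 4000), 0)
})

test_that("with no splicing and negligible cleavage intronic = exonic coverage", {
  m <- toy_gene()
  r <- rate_set(2, 1000, s = 0, c = 1e-9)
  cov <- expected_coverage(m, r, 4, bins = c(1500, 2500))  # exon vs intron
  expect_equal(cov[2], 2 * (4 - 2.5), tolerance = 1e-6)
  expect_equal(cov[1], 2 * (4 - 1.5), tolerance = 1e-6)
})

test_that("expected coverage is homogeneous in sigma", {
  m <- toy_gene()
  r1 <- toy_rates()
  r2 <- rate_set(2 * r1$sigma, r1$v, r1$s, r1$c)
  b <- seq(0, 4999, 100)
  expect_equal(expected_coverage(m, r2, 7, bins = b),
               2 * expected_coverage(m, r1, 7, bins = b), tolerance = 1e-10)
})

test_that("forward model matches the molecule simulator at every bin", {
  withr::with_seed(19, {
    for (i in 1:5) {
      L_exon1 <- sample(500:2500, 1)
      L_int <- sample(500:2500, 1)
      L_exon2 <- sample(500:2500, 1)
      m <- gene_model("g", c(0, L_exon1 + L_int),
                      c(L_exon1, L_exon1 + L_int + L_exon2))
      r <- rate_set(runif(1, 0.5, 3), runif(1, 800, 2500),
                    s = exp(runif(1, log(0.05), log(2))),
                    c = exp(runif(1, log(0.1), log(2))))
      t <- runif(1, 3, 10)
      n <- 1e5
      sim <- simulate_molecules(m, r, t, n = n,
                                seed = sample.int(1e6, 1), method = "lhs")
      bins <- seq(0, m$length - 1, length.out = 15)
      mc <- molecule_coverage(sim, bins = bins)
      p_exp <- expected_coverage(m, r, t, bins = bins) / (r$sigma * t)
      se <- sqrt((p_exp * (1 - p_exp) + 1 / n) / n)
      expect_lt(max(abs(mc$p_hat - p_exp) / pmax(se, 1e-9)), 3)
    }
  })
})

test_that("molecule simulator obeys its own exponential clocks", {
  m <- toy_gene()
  r <- toy_rates(s = 0.4)
  sim <- simulate_molecules(m, r, 8, n = 5e4, seed = 3)
  td <- tidy(sim)
  # molecules whose introns are transcribed: empirical splice fraction at age a
  age <- 8 - td$tau
  done <- age > m$introns[[1]]$end / r$v
  surv_age <- age[done] - m$introns[[1]]$end[1] / r$v
  frac_unspliced <- 1 - mean(td$intron_1[done] == "spliced")
  expect_equal(frac_unspliced, mean(exp(-0.4 * surv_age)), tolerance = 0.02)
  # huge splicing rate: every transcribed intron is spliced
  simfast <- simulate_molecules(m, toy_rates(s = 1e6), 8, n = 2000, seed = 4)
  tdf <- tidy(simfast)
  # every molecule whose 3'SS is transcribed has spliced instantly
  done2 <- tdf$front > m$introns[[1]]$end
  expect_true(all(tdf$intron_1[done2] == "spliced"))
})

test_that("molecule count is Poisson with mean sigma * t", {
  m <- toy_gene()
  r <- toy_rates()
  ns <- withr::with_seed(11, vapply(1:200, function(i) {
    simulate_molecules(m, r, 10, seed = NULL)$n
  }, numeric(1)))
  expect_lt(abs(mean(ns) - 20), 3 * sqrt(20 / 200) + 0.5)
})

test_that("time to transcribe is length over elongation rate", {
  expect_equal(time_to_transcribe(3000, 1500), 2)
  expect_equal(time_to_transcribe(1000, 2000), 0.5)
})

test_that("detained introns transcribe faster than background (planted shorter)", {
  study <- small_study()
  ft <- intron_features(study$models)
  truth <- dplyr::filter(study$truth$introns, condition == "control")
  joined <- dplyr::inner_join(ft, truth, by = c("gene_id", "intron_index")) %>%
    dplyr::left_join(study$truth$genes, by = "gene_id") %>%
    dplyr::mutate(ttt = time_to_transcribe(length, v))
  expect_lt(median(joined$ttt[joined$detained]),
            median(joined$ttt[!joined$detained]))
})

test_that("cleavage-before-splicing closed form has its limits and ordering", {
  expect_equal(cleavage_before_splicing_prob(0, 1, 5), 1)
  expect_equal(cleavage_before_splicing_prob(1, 1, 0), 0.5)
  # monotonicity: decreasing in s and d, increasing in c
  expect_true(all(diff(cleavage_before_splicing_prob(c(.1, .5, 2), 1, 1)) < 0))
  expect_true(all(diff(cleavage_before_splicing_prob(.5, c(.1, .5, 2), 1)) > 0))
  expect_true(all(diff(cleavage_before_splicing_prob(.5, 1, c(0, 1, 3))) < 0))
})

test_that("cleavage-before-splitting closed form matches brute-force draws", {
  grid <- expand.grid(s = c(0.02, 0.2, 2), c = c(0.05, 0.5, 5),
                      d = c(0.01, 0.3, 3))
  seeds <- withr::with_seed(5, sample.int(1e6, nrow(grid)))
  for (i in seq_len(nrow(grid))) {
    p <- cleavage_before_splicing_prob(grid$s[i], grid$c[i], grid$d[i])
    mc <- mc_cleavage_before_splicing(grid$s[i], grid$c[i], grid$d[i],
                                      n = 2e5, seed = seeds[i], method = "lhs")
    expect_lt(abs(p - mc$p_hat), 3 * pmax(mc$se, 1e-9) + 1e-6)
  }
})

test_that("predicted cassette PSI has exact limits and matches the race", {
  expect_equal(predicted_cassette_psi(1, 1, 0, 2), 1)
  expect_equal(predicted_cassette_psi(0, 1, 1, 5), 0.5)
  expect_equal(predicted_cassette_psi(1, 1, 1, log(2)), 5 / 6)
  expect_error(predicted_cassette_psi(0, 0, 0, 1), "positive")
  # monotone in each rate
  expect_true(all(diff(predicted_cassette_psi(c(.1, 1, 5), 1, 1, 1)) > 0))
  expect_true(all(diff(predicted_cassette_psi(1, c(.1, 1, 5), 1, 1)) > 0))
  expect_true(all(diff(predicted_cassette_psi(1, 1, c(.1, 1, 5), 1)) < 0))
  mc <- mc_cassette_psi(1, 1, 1, log(2), n = 2e5, seed = 8, method = "lhs")
  expect_lt(abs(mc$psi_hat - 5 / 6), 3 * mc$se + 1e-6)
})
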