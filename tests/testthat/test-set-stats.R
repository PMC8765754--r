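test_that("overlap odds ratio matches hand arithmetic and Fisher oracle", {
  u <- sprintf("g%04d", 1:1000)
  a <- u[1:100]                     # 30 shared, 70 A-only
  b <- c(u[1:30], u[101:120])       # 20 B-only
  res <- overlap_or(a, b, u)
  expect_equal(res$n11, 30)
  expect_equal(res$or, (30 * 880) / (70 * 20), tolerance = 1e-12)
  expect_equal(res$log2_or, log2(18.857143), tolerance = 1e-6)
  # symmetric in (A, B)
  expect_equal(overlap_or(b, a, u)$or, res$or)
  expect_error(overlap_or(a, b, u[1:50]), "universe")
})

test_that("Fisher p equals exhaustive hypergeometric tail summation (N <= 50)", {
  # independent oracle: enumerate all tables with the observed margins and
  # sum the probabilities no larger than the observed table's
  fisher_oracle <- function(n11, n12, n21, n22) {
    m <- n11 + n12
    k <- n11 + n21
    N <- n11 + n12 + n21 + n22
    support <- max(0, k + m - N):min(k, m)
    probs <- dhyper(support, m, N - m, k)
    p_obs <- dhyper(n11, m, N - m, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  cases <- list(c(5, 10, 3, 20), c(0, 12, 8, 25), c(9, 1, 2, 30),
                c(4, 4, 4, 4), c(1, 0, 0, 40))
  for (cs in cases) {
    u <- sprintf("x%02d", seq_len(sum(cs)))
    a <- u[seq_len(cs[1] + cs[2])]
    b <- c(u[seq_len(cs[1])], u[cs[1] + cs[2] + seq_len(cs[3])])
    expect_equal(overlap_or(a, b, u)$p,
                 fisher_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
})

test_that("independent random sets give near-zero log2 odds ratio on average", {
  u <- sprintf("g%04d", 1:800)
  lors <- withr::with_seed(5, vapply(1:200, function(i) {
    overlap_or(sample(u, 120), sample(u, 150), u)$log2_or
  }, numeric(1)))
  expect_lt(abs(mean(lors)), 0.2)
})

test_that("pair lists get one BH family per call", {
  u <- sprintf("g%03d", 1:300)
  sets <- withr::with_seed(9, list(s1 = sample(u, 50), s2 = sample(u, 60)))
  res <- overlap_or(sets, list(t1 = u[1:40], t2 = u[250:300]), u)
  expect_equal(nrow(res), 4)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
})

test_that("delta-PSI concordance detects identity, inversion, and shared signal", {
  df <- tibble::tibble(event_id = sprintf("e%02d", 1:30),
                       delta_psi = seq(-0.5, 0.5, length.out = 30))
  self <- delta_psi_concordance(df, df)
  expect_equal(self$rho, 1)
  expect_equal(self$sign_agreement, 1)
  anti <- delta_psi_concordance(df, dplyr::mutate(df, delta_psi = -delta_psi))
  expect_equal(anti$rho, -1)
  expect_lt(anti$sign_agreement, 0.1)
  # common latent signal plus noise
  withr::with_seed(3, {
    lat <- rnorm(200, 0, 0.2)
    a <- tibble::tibble(event_id = sprintf("e%03d", 1:200),
                        delta_psi = lat + rnorm(200, 0, 0.08))
    b <- tibble::tibble(event_id = sprintf("e%03d", 1:200),
                        delta_psi = lat + rnorm(200, 0, 0.08))
    expect_gt(delta_psi_concordance(a, b)$rho, 0.6)
  })
  expect_error(delta_psi_concordance(df[1:5, ], df[1:5, ]), "10 common")
})

test_that("subsampled rank-sum test is calibrated and powered", {
  withr::with_seed(41, {
    glob <- rnorm(2000)
    null_sub <- sample(glob, 100)
    res <- subsampled_wilcoxon(null_sub, glob, n_rep = 1000, seed = 5)
    expect_gt(res$median_p, 0.2)
    expect_lt(res$median_p, 0.8)
    shifted <- rnorm(100, mean = 2)
    res_s <- subsampled_wilcoxon(shifted, glob, n_rep = 200, seed = 5)
    expect_lt(res_s$median_p, 1e-4)
  })
  glob2 <- withr::with_seed(8, rnorm(100))
  one <- subsampled_wilcoxon(1:10, glob2, n_rep = 1, seed = 7)
  two <- subsampled_wilcoxon(1:10, glob2, n_rep = 1, seed = 7)
  expect_identical(one$p_values, two$p_values)
  expect_error(subsampled_wilcoxon(1:2, rnorm(50)), "at least 3")
})

test_that("null p-values of the subsampled test are uniform across draws", {
  # marginal calibration: fresh (subset, draw) pair each repetition
  ps <- withr::with_seed(53, vapply(1:400, function(i) {
    glob <- rnorm(500)
    subsampled_wilcoxon(rnorm(60), glob, n_rep = 1)$median_p
  }, numeric(1)))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Welch enrichment test reproduces the closed form", {
  m <- rbind(p1 = c(1, 2, 3, 4, 5, 6), p2 = c(2, 2, 2, 2, 2, 2))
  res <- diff_enrichment(m, group_a = 1:3, group_b = 4:6, normalize = FALSE)
  expect_equal(res$statistic[1], -3.674235, tolerance = 1e-6)
  expect_equal(res$df[1], 4, tolerance = 1e-9)
  expect_equal(res$p[1], 0.02131164, tolerance = 1e-6)
  expect_equal(res$log2fc[1], -3)
  expect_equal(res$p[2], 1)            # identical groups
  expect_equal(res$log2fc[2], 0)
})

test_that("enrichment p-values are uniform under the null", {
  withr::with_seed(61, {
    m <- matrix(rnorm(500 * 6), 500, 6)
    res <- diff_enrichment(m, 1:3, 4:6, normalize = FALSE)
    expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  })
})

test_that("normalization centres each sample on the log2 scale", {
  m <- matrix(2^c(1, 2, 3, 4, 7, 9), 3, 2)
  norm <- normalize_abundance(m)
  expect_equal(colMeans(norm), c(0, 0))
})

test_that("background subtraction keeps true binders and drops sticky proteins", {
  withr::with_seed(71, {
    true_b <- matrix(rnorm(60, 6), 20, 3,
                     dimnames = list(sprintf("bind%02d", 1:20)))
    sticky <- matrix(rnorm(60, 4), 20, 3,
                     dimnames = list(sprintf("bg%02d", 1:20)))
    enriched <- rbind(true_b, sticky)
    control <- rbind(
      matrix(rnorm(60, 4), 20, 3, dimnames = list(rownames(true_b))),
      matrix(rnorm(60, 4), 20, 3, dimnames = list(rownames(sticky)))
    )
    out <- background_subtract_polya(enriched, control)
    expect_gt(mean(rownames(true_b) %in% rownames(out)), 0.9)
    expect_lt(mean(rownames(sticky) %in% rownames(out)),
              mean(rownames(true_b) %in% rownames(out)))
  })
  # control == enriched drops everything; zero control changes nothing
  e <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c")))
  expect_equal(nrow(background_subtract_polya(e, e)), 0)
  z <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c")))
  out_z <- background_subtract_polya(e, z)
  expect_true(all(out_z == e) && nrow(out_z) == 3)
})
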