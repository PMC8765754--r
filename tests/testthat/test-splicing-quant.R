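test_that("PSI is length-normalized and bounded", {
  expect_equal(compute_psi(100, 50, 2, 1), 0.5)
  expect_equal(compute_psi(10, 0), 1)
  expect_equal(compute_psi(0, 10), 0)
  expect_true(is.na(compute_psi(0, 0)))
  # invariant to common count scaling
  expect_equal(compute_psi(30, 20), compute_psi(300, 200))
})

test_that("PSI estimates are nearly unbiased at high depth", {
  cfg <- sim_config(n_genes = 40, seed = 7, depth = 1e4, replicates = 1)
  mt <- sample_models_and_rates(cfg)
  counts <- simulate_polya_counts(mt$truth, cfg)
  est <- compute_psi(counts$I, counts$S, counts$l_I, counts$l_S)
  expect_lt(abs(mean(est - counts$psi)), 0.01)
})

test_that("differential inclusion is null-calibrated and recovers planted shifts", {
  # identical counts in both conditions: delta = 0, p = 1
  cts <- tibble::tibble(
    event_id = rep(c("e1", "e2"), each = 2),
    condition = rep(c("control", "trt"), 2),
    replicate = 1L, I = 40L, S = 60L, l_I = 2, l_S = 1
  )
  rec <- delta_psi_test(cts, control = "control", treatment = "trt")
  expect_equal(rec$delta_psi, c(0, 0))
  expect_equal(rec$p, c(1, 1))

  # planted +0.3 shift at depth 1000, 3 replicates: nearly always significant
  withr::with_seed(23, {
    n_ev <- 60
    psi0 <- runif(n_ev, 0.2, 0.5)
    mk <- function(cond, psi) {
      tidyr::expand_grid(event_id = sprintf("ev%02d", seq_len(n_ev)),
                         replicate = 1:3) %>%
        dplyr::mutate(condition = cond,
                      I = rpois(dplyr::n(), 1000 * psi[match(event_id, sprintf("ev%02d", seq_len(n_ev)))] * 2),
                      S = rpois(dplyr::n(), 1000 * (1 - psi[match(event_id, sprintf("ev%02d", seq_len(n_ev)))])),
                      l_I = 2, l_S = 1)
    }
    cts2 <- dplyr::bind_rows(mk("control", psi0), mk("treated", psi0 + 0.3))
    rec2 <- delta_psi_test(cts2, control = "control", treatment = "treated")
    expect_gt(mean(rec2$q < 0.05), 0.9)
    expect_gt(min(rec2$delta_psi), 0)
  })
})

test_that("false-positive rate is controlled on null events", {
  withr::with_seed(31, {
    n_ev <- 1000
    psi0 <- runif(n_ev, 0.1, 0.9)
    mk <- function(cond) {
      tidyr::expand_grid(event_id = sprintf("ev%04d", seq_len(n_ev)),
                         replicate = 1:2) %>%
        dplyr::mutate(condition = cond,
                      I = rpois(dplyr::n(), 500 * psi0[match(event_id, sprintf("ev%04d", seq_len(n_ev)))] * 2),
                      S = rpois(dplyr::n(), 500 * (1 - psi0[match(event_id, sprintf("ev%04d", seq_len(n_ev)))])),
                      l_I = 2, l_S = 1)
    }
    rec <- delta_psi_test(dplyr::bind_rows(mk("control"), mk("treated")),
                          control = "control", treatment = "treated")
    # all events are null, so anything called at q < 0.05 is a false discovery
    expect_lte(mean(rec$q < 0.05, na.rm = TRUE), 0.05)
    # the length-normalized z-test is conservative, never anti-conservative
    expect_lte(mean(rec$p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / n_ev))
  })
})

test_that("RI calling separates the planted condition directions", {
  study <- small_study()
  rec2 <- delta_psi_test(study$polya_counts, control = "control",
                         treatment = "type2i")
  rec1 <- delta_psi_test(study$polya_counts, control = "control",
                         treatment = "type1i")
  ri2 <- call_ri(rec2)
  ri1 <- call_ri(rec1)
  expect_gt(nrow(ri2), 0)
  expect_gt(nrow(ri1), 0)
  # slow-splicing / slow-decay arm retains more; fast-decay arm retains less
  expect_gt(mean(ri2$direction == "more_retained"), 0.8)
  expect_gt(mean(ri1$direction == "less_retained"), 0.8)
  # called events are overwhelmingly the planted detained introns
  truth <- dplyr::filter(study$truth$introns, condition == "control") %>%
    dplyr::mutate(event_id = paste0(gene_id, ":", intron_index))
  expect_gt(mean(ri2$event_id %in% truth$event_id[truth$detained]), 0.8)
  # degenerate thresholds
  expect_equal(nrow(call_ri(rec2, fdr_threshold = 0)), 0)
  expect_equal(nrow(call_ri(rec2[0, ])), 0)
})

test_that("z-scoring standardizes rows and flags flat ones", {
  df <- tibble::tibble(event_id = c("a", "b", "c"),
                       c1 = c(0.8, 1, 1), c2 = c(-0.6, 1, 2), c3 = c(NA, 1, 3))
  z2 <- zscore_common_ri(df[1:2, 1:3])
  expect_equal(unlist(z2[1, c("c1", "c2")], use.names = FALSE),
               c(0.7071068, -0.7071068), tolerance = 1e-6)
  expect_true(z2$flat[2])
  expect_equal(unlist(z2[2, c("c1", "c2")], use.names = FALSE), c(0, 0))
  z3 <- zscore_common_ri(df[3, ])
  expect_equal(unlist(z3[1, c("c1", "c2", "c3")], use.names = FALSE),
               c(-1, 0, 1))
  expect_error(zscore_common_ri(df[, 1:2]), "two condition")
})

test_that("feature-distribution comparison matches the exact rank-sum tail", {
  res <- compare_feature_distributions(c(1, 2, 3), c(4, 5, 6))
  # exact two-sided rank-sum: most extreme of the 20 arrangements, p = 2/20
  expect_equal(res$p[res$test == "wilcoxon"], 0.1)
  expect_warning(compare_feature_distributions(rep(1, 3), rep(1, 4)), "tied")
  big <- withr::with_seed(2, compare_feature_distributions(rnorm(500, 1), rnorm(500)))
  expect_lt(big$p[big$test == "wilcoxon"], 1e-6)
})
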