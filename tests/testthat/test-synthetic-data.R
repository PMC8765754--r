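test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 8, seed = 3)
  a <- sample_models_and_rates(cfg)
  b <- sample_models_and_rates(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$models$length, b$models$length)
  ta <- simulate_timecourse(a$models, a$truth, cfg, genes = a$models$gene_id[1])
  tb <- simulate_timecourse(b$models, b$truth, cfg, genes = b$models$gene_id[1])
  expect_identical(ta$coverage, tb$coverage)
})

test_that("the planted detained fraction is binomial around its target", {
  cfg <- sim_config(n_genes = 170, seed = 29, ri_fraction = 0.2)
  mt <- sample_models_and_rates(cfg)
  truth <- dplyr::filter(mt$truth$introns, condition == "control")
  n <- nrow(truth)
  expect_gte(n, 400)
  n_ri <- sum(truth$detained)
  # within 4 sd of Binomial(n, 0.2)
  expect_lt(abs(n_ri - 0.2 * n), 4 * sqrt(n * 0.2 * 0.8))
})

test_that("noiseless time courses equal the forward model exactly and scale with depth", {
  cfg <- sim_config(n_genes = 2, seed = 5, noise = "none", depth = 1)
  mt <- sample_models_and_rates(cfg)
  gid <- mt$models$gene_id[1]
  tc <- simulate_timecourse(mt$models, mt$truth, cfg, genes = gid)
  m <- mt$models[1, ]
  r <- truth_rate_set(mt$truth, gid)
  t1 <- dplyr::filter(tc, time == 10)
  expect_equal(t1$coverage, expected_coverage(m, r, 10, bins = t1$position))
  # doubling the spawn rate doubles every value
  tr2 <- mt$truth
  tr2$genes$sigma <- 2 * tr2$genes$sigma
  tc2 <- simulate_timecourse(mt$models, tr2, cfg, genes = gid)
  expect_equal(tc2$coverage, 2 * tc$coverage, tolerance = 1e-10)
})

test_that("Poisson noise has the right dispersion", {
  cfg <- sim_config(n_genes = 1, seed = 5, noise = "poisson", depth = 50,
                    tc_genes = 1)
  mt <- sample_models_and_rates(cfg)
  cfg_none <- cfg
  cfg_none$noise <- "none"
  mu <- simulate_timecourse(mt$models, mt$truth, cfg_none)$coverage
  # many replicate draws of the same bins
  devs <- withr::with_seed(2, {
    draws <- vapply(1:200, function(i) {
      cfg_i <- cfg
      cfg_i$seed <- 10000 + i
      simulate_timecourse(mt$models, mt$truth, cfg_i)$coverage
    }, numeric(length(mu)))
    keep <- mu > 5
    (apply(draws[keep, ], 1, var) - mu[keep]) / mu[keep]
  })
  # chi-square dispersion: variance tracks the mean
  expect_lt(abs(mean(devs)), 0.1)
})

test_that("polyA counts respect the planted PSI and recover delta-PSI signs", {
  cfg <- sim_config(n_genes = 40, seed = 19, depth = 1000, replicates = 3)
  mt <- sample_models_and_rates(cfg)
  counts <- simulate_polya_counts(mt$truth, cfg)
  # Psi = 1 events have zero skip counts by construction
  ones <- dplyr::filter(counts, psi == 1)
  if (nrow(ones) > 0) expect_true(all(ones$S == 0))
  rec <- delta_psi_test(counts, control = "control", treatment = "type2i")
  truth_d <- dplyr::filter(mt$truth$introns, condition == "type2i") %>%
    dplyr::mutate(event_id = paste0(gene_id, ":", intron_index),
                  d_true = psi - mt$truth$introns$psi[
                    mt$truth$introns$condition == "control"])
  joined <- dplyr::inner_join(rec, truth_d, by = "event_id") %>%
    dplyr::filter(abs(d_true) > 0.05)
  expect_gt(mean(sign(joined$delta_psi) == sign(joined$d_true)), 0.95)
})

test_that("transcription-block counts encode the planted half-lives", {
  cfg <- sim_config(n_genes = 30, seed = 37, depth = 1e4)
  mt <- sample_models_and_rates(cfg)
  # forced half-life of exactly 60 min gives one lost half-life
  tr <- mt$truth
  tr$introns$k <- log(2) / 60
  ac <- simulate_actd_counts(tr, cfg)
  dec <- actd_decay_stat(ac$intron_minus, ac$intron_plus,
                         ac$exon_minus, ac$exon_plus)
  expect_lt(abs(mean(dec$delta) + 1), 0.05)
  # zero decay: log2 ratio centred on zero
  tr$introns$k <- 0
  ac0 <- simulate_actd_counts(tr, cfg)
  dec0 <- actd_decay_stat(ac0$intron_minus, ac0$intron_plus,
                          ac0$exon_minus, ac0$exon_plus)
  expect_lt(abs(mean(dec0$delta)), 0.05)
})

test_that("fixture bundles round-trip and manifests track the config", {
  study <- simulate_study(sim_config(n_genes = 4, seed = 43, tc_genes = 1))
  dir1 <- file.path(tempdir(), "bundle1")
  files <- write_fixture_bundle(study, dir1)
  expect_true(all(file.exists(files)))
  back <- read_fixture_bundle(dir1)
  expect_equal(sort(back$models$gene_id), sort(study$models$gene_id))
  expect_equal(back$models$length[match(study$models$gene_id, back$models$gene_id)],
               study$models$length)
  expect_equal(back$sequences[study$models$gene_id],
               study$sequences[study$models$gene_id])
  expect_equal(nrow(back$polya_counts), nrow(study$polya_counts))
  expect_equal(sum(back$polya_counts$I), sum(study$polya_counts$I))
  # coverage round-trips through the genomic map
  tc1 <- dplyr::arrange(study$timecourse, gene_id, time, position)
  tc2 <- dplyr::arrange(back$timecourse, gene_id, time, position)
  expect_equal(tc2$coverage, tc1$coverage)
  expect_equal(tc2$position, tc1$position)
  # manifest hash changes iff the config changes
  study2 <- simulate_study(sim_config(n_genes = 4, seed = 43, tc_genes = 1,
                                      depth = 2000))
  dir2 <- file.path(tempdir(), "bundle2")
  write_fixture_bundle(study2, dir2)
  m1 <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  expect_false(identical(m1$config_hash, m2$config_hash))
  expect_identical(m1$config_hash,
                   splicewave:::hash_config(study$config))
})
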