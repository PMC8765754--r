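#' Configuration for the synthetic study
#'
#' Defines the statistical structure the analysis assumes: gene
#' architectures, log-normal rate priors, condition effects, sequencing
#' depth and noise. The defaults emulate a synchronized-release
#' nascent-RNA study in human cells: time points every 5 min to 35 min,
#' Poisson count noise, and a three-arm design — `control`, a
#' `type2i` arm (symmetric-methylation inhibitor-like: slower splicing and
#' slower post-transcriptional decay of detained introns) and a `type1i`
#' arm (asymmetric-methylation inhibitor-like: faster detained-intron
#' decay). Condition effects apply to detained introns only; all other
#' introns are unaffected nulls.
#'
#' @param n_genes Number of genes.
#' @param mean_introns Mean introns per gene (min 1).
#' @param exon_meanlog,exon_sdlog Log-normal exon length prior (nt).
#' @param intron_meanlog,intron_sdlog Log-normal intron length prior (nt).
#' @param ri_intron_meanlog,ri_intron_sdlog Length prior for detained
#'   introns (drawn shorter).
#' @param ri_fraction Probability that an intron is planted as detained.
#' @param sigma_meanlog,sigma_sdlog Spawn-rate prior (events/min).
#' @param v_meanlog,v_sdlog Elongation-rate prior (nt/min).
#' @param s_meanlog,s_sdlog Splicing-rate prior for ordinary introns
#'   (1/min).
#' @param ri_s_meanlog,ri_s_sdlog Splicing-rate prior for detained introns
#'   (slow).
#' @param c_meanlog,c_sdlog Cleavage-rate prior (1/min).
#' @param k_meanlog,k_sdlog Post-transcriptional intron decay-rate prior
#'   (1/min); default median ln(2)/60, a 60-min half-life.
#' @param residence_time Nuclear residence window (min) converting decay
#'   into steady-state poly(A) retention.
#' @param conditions Named list of condition effects, each a list with
#'   `s_mult` and `k_mult` applied multiplicatively to detained introns.
#' @param times DRB-release collection times (min).
#' @param depth Sequencing depth scale (expected counts / coverage units).
#' @param exon_factor Flanking-exon depth relative to `depth` in the
#'   transcription-block experiment.
#' @param k_exon Exon decay rate during the transcription block (default
#'   0: stable exons).
#' @param actd_time Transcription-block duration (min).
#' @param replicates Replicates per condition.
#' @param noise `"poisson"` or `"none"`.
#' @param bin_size Coverage bin size (nt).
#' @param tc_genes Number of genes given a coverage time course by
#'   [simulate_study()].
#' @param tc_conditions Conditions simulated as time courses.
#' @param seed RNG seed; a fixed seed makes every output byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50,
                       mean_introns = 3,
                       exon_meanlog = log(150), exon_sdlog = 0.4,
                       intron_meanlog = log(1500), intron_sdlog = 0.6,
                       ri_intron_meanlog = log(400), ri_intron_sdlog = 0.5,
                       ri_fraction = 0.2,
                       sigma_meanlog = log(0.5), sigma_sdlog = 0.5,
                       v_meanlog = log(1500), v_sdlog = 0.3,
                       s_meanlog = log(0.7), s_sdlog = 0.5,
                       ri_s_meanlog = log(0.08), ri_s_sdlog = 0.5,
                       c_meanlog = log(0.5), c_sdlog = 0.4,
                       k_meanlog = log(log(2) / 60), k_sdlog = 0.4,
                       residence_time = 60,
                       conditions = list(
                         control = list(s_mult = 1, k_mult = 1),
                         type2i = list(s_mult = 0.4, k_mult = 0.4),
                         type1i = list(s_mult = 1, k_mult = 2.5)
                       ),
                       times = seq(5, 35, by = 5),
                       depth = 1000,
                       exon_factor = 10,
                       k_exon = 0,
                       actd_time = 60,
                       replicates = 2,
                       noise = c("poisson", "none"),
                       bin_size = 50,
                       tc_genes = 5,
                       tc_conditions = "control",
                       seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_genes >= 1, depth > 0, replicates >= 1,
            ri_fraction >= 0, ri_fraction <= 1,
            all(times > 0), actd_time > 0, residence_time >= 0)
  mults <- unlist(map(conditions, ~ c(.x$s_mult, .x$k_mult)))
  if (any(mults <= 0)) abort("condition multipliers must be positive")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Sample gene structures and kinetic ground truth
#'
#' Draws gene architectures and the per-gene, per-condition rate sets.
#' A fraction `ri_fraction` of introns is planted as detained: they are
#' drawn shorter, placed TES-proximal (last in the gene), and given slow
#' splicing rates. Condition effects multiply the splicing and decay rates
#' of detained introns. The planted true poly(A) retention of intron `i`
#' combines the chance it escapes co-transcriptional splicing with its
#' post-transcriptional survival over the nuclear residence window:
#' `psi = P(cleaved before spliced) * exp(-k * residence_time)`.
#'
#' @param config A [sim_config()].
#' @return List: `models` (a `gene_models` tibble), `truth` (list of
#'   tibbles `genes` = per-gene `sigma`, `v`, `c`; `introns` = per intron
#'   per condition `s`, `k`, `psi`, `detained`).
#' @export
sample_models_and_rates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    model_list <- vector("list", config$n_genes)
    gene_rows <- vector("list", config$n_genes)
    intron_rows <- vector("list", config$n_genes)
    offset <- 0
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("gene_%03d", g)
      n_int <- 1L + rpois(1, max(config$mean_introns - 1, 0))
      detained <- runif(n_int) < config$ri_fraction
      detained <- detained[order(detained)]     # detained last: TES-proximal
      ilen <- ifelse(
        detained,
        pmax(70, round(rlnorm(n_int, config$ri_intron_meanlog, config$ri_intron_sdlog))),
        pmax(70, round(rlnorm(n_int, config$intron_meanlog, config$intron_sdlog)))
      )
      elen <- pmax(50, round(rlnorm(n_int + 1L, config$exon_meanlog, config$exon_sdlog)))
      pieces <- as.vector(rbind(elen, c(ilen, NA)))
      pieces <- pieces[!is.na(pieces)]
      bounds <- c(0, cumsum(pieces))
      exon_idx <- seq(1, length(pieces), by = 2)
      strand <- if (g %% 2 == 0) "-" else "+"
      m <- gene_model(gid,
                      exon_starts = bounds[exon_idx],
                      exon_ends = bounds[exon_idx + 1],
                      strand = strand, chrom = "chr1",
                      genomic_start = offset)
      offset <- offset + m$length + 10000
      model_list[[g]] <- m

      sigma <- rlnorm(1, config$sigma_meanlog, config$sigma_sdlog)
      v <- rlnorm(1, config$v_meanlog, config$v_sdlog)
      cc <- rlnorm(1, config$c_meanlog, config$c_sdlog)
      s0 <- ifelse(detained,
                   rlnorm(n_int, config$ri_s_meanlog, config$ri_s_sdlog),
                   rlnorm(n_int, config$s_meanlog, config$s_sdlog))
      k0 <- rlnorm(n_int, config$k_meanlog, config$k_sdlog)
      gene_rows[[g]] <- tibble(gene_id = gid, sigma = sigma, v = v, c = cc)
      it <- m$introns[[1]]
      d_min <- it$dist_to_tes / v
      intron_rows[[g]] <- bind_rows(map(names(config$conditions), function(cond) {
        eff <- config$conditions[[cond]]
        s <- ifelse(detained, s0 * eff$s_mult, s0)
        k <- ifelse(detained, k0 * eff$k_mult, k0)
        tibble(
          gene_id = gid, intron_index = it$index, condition = cond,
          s = s, k = k,
          psi = cleavage_before_splicing_prob(s, cc, d_min) *
            exp(-k * config$residence_time),
          detained = detained
        )
      }))
    }
    models <- gene_models(model_list)
    list(models = models,
         truth = list(genes = bind_rows(gene_rows),
                      introns = bind_rows(intron_rows)))
  })
}

#' Rate set of one gene under one condition
#'
#' @param truth The `truth` list from [sample_models_and_rates()].
#' @param gene_id Gene.
#' @param condition Condition name.
#' @return A [rate_set()].
#' @export
truth_rate_set <- function(truth, gene_id, condition = "control") {
  g <- truth$genes[truth$genes$gene_id == gene_id, ]
  it <- truth$introns %>%
    filter(.data$gene_id == !!gene_id, .data$condition == !!condition) %>%
    arrange(.data$intron_index)
  rate_set(g$sigma, g$v, it$s, g$c)
}

#' Simulate planted pre-mRNA sequences
#'
#' Uniform-random background with donor and acceptor windows at every
#' intron boundary sampled from fixed position weight matrices
#' (approximate human consensus; see [splice_site_profiles()] for the
#' window convention).
#'
#' @param models A `gene_models` tibble.
#' @param seed RNG seed.
#' @return Named character vector of sequences (one per gene).
#' @export
sample_sequences <- function(models, seed = 1L) {
  withr::with_seed(seed, {
    d_pwm <- donor_pwm()
    a_pwm <- acceptor_pwm()
    offs5 <- attr_offsets(d_pwm)
    offs3 <- attr_offsets(a_pwm)
    seqs <- map_chr(seq_len(nrow(models)), function(i) {
      m <- models[i, ]
      base <- sample(c("A", "C", "G", "T"), m$length, replace = TRUE)
      it <- m$introns[[1]]
      for (j in seq_len(nrow(it))) {
        plant <- function(anchor, offs, pwm) {
          idx <- anchor + offs + as.integer(offs < 0)
          ok <- idx >= 1 & idx <= m$length
          draws <- vapply(seq_along(offs), function(p) {
            sample(rownames(pwm), 1, prob = pwm[, p])
          }, character(1))
          base[idx[ok]] <<- draws[ok]
        }
        plant(it$start[j], offs5, d_pwm)
        plant(it$end[j], offs3, a_pwm)
      }
      paste(base, collapse = "")
    })
    setNames(seqs, models$gene_id)
  })
}

attr_offsets <- function(pwm) as.integer(colnames(pwm))

#' Simulate a synchronized-release coverage time course
#'
#' Coverage is the forward-model expectation scaled by `depth`, with
#' per-bin Poisson noise when configured.
#'
#' @param models A `gene_models` tibble.
#' @param truth Ground truth from [sample_models_and_rates()].
#' @param config A [sim_config()].
#' @param condition Condition to simulate.
#' @param times Collection times (default from config).
#' @param genes Optional subset of gene ids.
#' @param depth Coverage scale; recycled across genes (overrides
#'   `config$depth`, e.g. to normalize mean bin coverage per gene).
#' @return A `coverage_tc` tibble with a `condition` column.
#' @export
simulate_timecourse <- function(models, truth, config,
                                condition = "control",
                                times = config$times, genes = NULL,
                                depth = config$depth) {
  if (!is.null(genes)) models <- models[models$gene_id %in% genes, ]
  depth <- rep_len(depth, nrow(models))
  seeds <- derive_seeds(config$seed + 1L, nrow(models))
  out <- map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    r <- truth_rate_set(truth, m$gene_id, condition)
    bins <- seq(0, m$length - 1, by = config$bin_size)
    mat <- depth[i] * coverage_kernel(m, r, times, bins = bins)
    if (config$noise == "poisson") {
      mat <- withr::with_seed(seeds[i],
        matrix(rpois(length(mat), mat), nrow(mat), ncol(mat)))
    }
    coverage_timecourse(m$gene_id, bins, times, mat, config$bin_size)
  })
  res <- bind_rows(out) %>% mutate(condition = condition)
  attr(res, "bin_size") <- config$bin_size
  class(res) <- c("coverage_tc", setdiff(class(res), "coverage_tc"))
  res
}

#' Simulate poly(A) junction-count tables
#'
#' Per condition and replicate, inclusion counts are
#' `Poisson(depth * psi * l_I)` and skip counts
#' `Poisson(depth * (1 - psi) * l_S)` with `l_I = 2`, `l_S = 1`.
#'
#' @inheritParams simulate_timecourse
#' @param depth Overrides `config$depth`.
#' @param replicates Overrides `config$replicates`.
#' @return Event-count tibble: `event_id`, `gene_id`, `intron_index`,
#'   `event_type`, `condition`, `replicate`, `I`, `S`, `l_I`, `l_S`.
#' @export
simulate_polya_counts <- function(truth, config, depth = config$depth,
                                  replicates = config$replicates) {
  l_I <- 2
  l_S <- 1
  base <- truth$introns %>%
    mutate(event_id = paste0(.data$gene_id, ":", .data$intron_index))
  grid <- tidyr::expand_grid(replicate = seq_len(replicates), base)
  withr::with_seed(config$seed + 2L, {
    mu_i <- depth * grid$psi * l_I
    mu_s <- depth * (1 - grid$psi) * l_S
    if (config$noise == "poisson") {
      grid$I <- rpois(nrow(grid), mu_i)
      grid$S <- rpois(nrow(grid), mu_s)
    } else {
      grid$I <- mu_i
      grid$S <- mu_s
    }
  })
  grid %>%
    mutate(event_type = "RI", l_I = l_I, l_S = l_S) %>%
    select("event_id", "gene_id", "intron_index", "event_type", "condition",
           "replicate", "I", "S", "l_I", "l_S", "psi", "detained")
}

#' Simulate a transcription-block (ActD) decay experiment
#'
#' Intron counts before the block are `Poisson(depth * psi)`; after
#' `t_actd` minutes of blocked transcription they decay to
#' `Poisson(depth * psi * exp(-k * t_actd))`. Flanking-exon counts are
#' stable by default (`k_exon = 0`).
#'
#' @inheritParams simulate_timecourse
#' @param t_actd Block duration, min (default from config).
#' @param depth Overrides `config$depth`.
#' @return Tibble: `intron_id`, `condition`, `intron_minus`, `intron_plus`,
#'   `exon_minus`, `exon_plus`, plus truth columns `k`, `psi`, `detained`.
#' @export
simulate_actd_counts <- function(truth, config, t_actd = config$actd_time,
                                 depth = config$depth) {
  stopifnot(all(truth$introns$k >= 0))
  df <- truth$introns %>%
    mutate(intron_id = paste0(.data$gene_id, ":", .data$intron_index))
  withr::with_seed(config$seed + 3L, {
    mu_im <- depth * df$psi
    mu_ip <- depth * df$psi * exp(-df$k * t_actd)
    mu_e <- depth * config$exon_factor
    mu_ep <- mu_e * exp(-config$k_exon * t_actd)
    draw <- function(mu) {
      if (config$noise == "poisson") rpois(length(mu), mu) else mu
    }
    df$intron_minus <- draw(mu_im)
    df$intron_plus <- draw(mu_ip)
    df$exon_minus <- draw(rep(mu_e, nrow(df)))
    df$exon_plus <- draw(rep(mu_ep, nrow(df)))
  })
  df %>%
    select("intron_id", "gene_id", "intron_index", "condition",
           "intron_minus", "intron_plus", "exon_minus", "exon_plus",
           "k", "psi", "detained")
}

#' Run the whole synthetic study
#'
#' @param config A [sim_config()].
#' @return List: `config`, `models`, `truth`, `sequences`,
#'   `timecourse` (first `tc_genes` genes, `tc_conditions`),
#'   `polya_counts`, `actd_counts`.
#' @export
simulate_study <- function(config = sim_config()) {
  mt <- sample_models_and_rates(config)
  seqs <- sample_sequences(mt$models, seed = derive_seeds(config$seed, 5)[4])
  tc_genes <- head(mt$models$gene_id, config$tc_genes)
  tc <- bind_rows(map(config$tc_conditions, function(cond) {
    simulate_timecourse(mt$models, mt$truth, config, condition = cond,
                        genes = tc_genes)
  }))
  attr(tc, "bin_size") <- config$bin_size
  class(tc) <- c("coverage_tc", setdiff(class(tc), "coverage_tc"))
  list(
    config = config,
    models = mt$models,
    truth = mt$truth,
    sequences = seqs,
    timecourse = tc,
    polya_counts = simulate_polya_counts(mt$truth, config),
    actd_counts = simulate_actd_counts(mt$truth, config)
  )
}
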