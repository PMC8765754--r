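#' Actinomycin-D intron decay statistic
#'
#' After a transcription block, post-transcriptionally removed introns lose
#' signal relative to their flanking exons. The statistic is
#' `delta = log2( ((intron+ + eps) / (exon+ + eps)) /
#'                ((intron- + eps) / (exon- + eps)) )`
#' where `-`/`+` denote before/after the block and `eps` is a pseudocount.
#' For first-order decay at rate `k` over `t` minutes with stable exons,
#' `delta` estimates `-k t / ln 2` (minus the number of half-lives elapsed).
#'
#' @param intron_minus,intron_plus Intron counts without / with the block.
#' @param exon_minus,exon_plus Flanking-exon counts (sum over both flanking
#'   exons, or one if only one is usable).
#' @param pseudocount Added to every count (default 0.5).
#' @return Tibble: `delta` and `flagged` (all four counts zero). Vectorized.
#' @export
actd_decay_stat <- function(intron_minus, intron_plus, exon_minus, exon_plus,
                            pseudocount = 0.5) {
  stopifnot(all(c(intron_minus, intron_plus, exon_minus, exon_plus) >= 0))
  eps <- pseudocount
  delta <- log2(((intron_plus + eps) / (exon_plus + eps)) /
                ((intron_minus + eps) / (exon_minus + eps)))
  tibble(delta = delta,
         flagged = intron_minus + intron_plus + exon_minus + exon_plus == 0)
}

#' Compare intron decay statistics across conditions
#'
#' Per-condition medians of `delta` on the common intron set, and pairwise
#' two-sided Wilcoxon rank-sum p-values between conditions.
#'
#' @param decay Tibble with columns `intron_id`, `condition`, `delta`.
#' @return List with `medians` (tibble `condition`, `median_delta`, `n`)
#'   and `pairs` (tibble `condition_a`, `condition_b`, `p`); `p` is `NA`
#'   when either group has fewer than 3 introns.
#' @export
compare_decay <- function(decay) {
  stopifnot(all(c("condition", "delta") %in% names(decay)))
  if ("intron_id" %in% names(decay)) {
    common <- decay %>%
      group_by(.data$intron_id) %>%
      filter(dplyr::n_distinct(.data$condition) ==
               dplyr::n_distinct(decay$condition)) %>%
      ungroup()
    if (nrow(common) > 0) decay <- common
  }
  meds <- decay %>%
    group_by(.data$condition) %>%
    summarise(median_delta = median(.data$delta), n = n(), .groups = "drop")
  conds <- meds$condition
  pairs <- tidyr::expand_grid(a = seq_along(conds), b = seq_along(conds)) %>%
    filter(.data$a < .data$b)
  ps <- map_dbl(seq_len(nrow(pairs)), function(i) {
    xa <- decay$delta[decay$condition == conds[pairs$a[i]]]
    xb <- decay$delta[decay$condition == conds[pairs$b[i]]]
    if (length(xa) < 3 || length(xb) < 3) return(NA_real_)
    if (length(unique(c(xa, xb))) == 1) return(1)
    suppressWarnings(wilcox.test(xa, xb)$p.value)
  })
  list(
    medians = meds,
    pairs = tibble(condition_a = conds[pairs$a], condition_b = conds[pairs$b],
                   p = ps)
  )
}

#' Subcellular-fraction enrichment of introns
#'
#' Tests whether an intron class (e.g. retained introns) is preferentially
#' nuclear. Abundances are log2-transformed with a 0.5 pseudocount; the
#' per-intron enrichment ratio is mean nuclear (nucleoplasm + chromatin)
#' over mean cytoplasmic abundance, and the class-level test is a two-way
#' ANOVA (fraction x class) with Tukey-adjusted pairwise comparisons.
#'
#' @param counts Tibble with columns `intron_id`, `class`, `fraction`
#'   (values among `"cytoplasm"`, `"nucleoplasm"`, `"chromatin"`),
#'   `replicate`, `count`.
#' @return List: `ratios` (per-intron nuclear/cytoplasmic ratio), `anova`
#'   (tidy ANOVA table), `tukey` (Tukey pairwise contrasts for the
#'   interaction).
#' @export
fraction_enrichment <- function(counts) {
  stopifnot(all(c("intron_id", "class", "fraction", "replicate", "count")
                %in% names(counts)))
  if (dplyr::n_distinct(counts$fraction) < 2) abort("need at least 2 fractions")
  if (dplyr::n_distinct(counts$replicate) < 2) {
    abort("ANOVA undefined with a single replicate")
  }
  dat <- counts %>%
    mutate(log_ab = log2(.data$count + 0.5),
           fraction = factor(.data$fraction),
           class = factor(.data$class))
  nuclear <- c("nucleoplasm", "chromatin")
  ratios <- dat %>%
    group_by(.data$intron_id, .data$class) %>%
    summarise(
      nuclear_mean = mean(.data$count[.data$fraction %in% nuclear]),
      cyto_mean = mean(.data$count[.data$fraction == "cytoplasm"]),
      .groups = "drop"
    ) %>%
    mutate(ratio = (.data$nuclear_mean + 0.5) / (.data$cyto_mean + 0.5))
  fit <- aov(log_ab ~ fraction * class, data = dat)
  an <- as_tibble(summary(fit)[[1]], rownames = "term") %>%
    rename(df = "Df", sumsq = "Sum Sq", meansq = "Mean Sq",
           statistic = "F value", p = "Pr(>F)") %>%
    mutate(term = trimws(.data$term))
  tk <- TukeyHSD(fit)
  tukey <- bind_rows(map(names(tk), function(nm) {
    as_tibble(tk[[nm]], rownames = "contrast") %>%
      mutate(term = nm) %>%
      rename(estimate = "diff", conf_low = "lwr", conf_high = "upr",
             p_adj = "p adj")
  }))
  list(ratios = ratios, anova = an, tukey = tukey)
}
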