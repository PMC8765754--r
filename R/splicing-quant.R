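#' Percent spliced in from junction counts
#'
#' Length-normalized inclusion level:
#' `Psi = (I / l_I) / (I / l_I + S / l_S)`. For a retained intron the
#' inclusion form spans two exon-intron junctions and the skip form one
#' exon-exon junction, hence the default effective lengths `l_I = 2`,
#' `l_S = 1`.
#'
#' @param I,S Inclusion and skip read counts (vectorized).
#' @param l_I,l_S Effective lengths (> 0).
#' @return Psi in `[0, 1]`; `NA` where `I + S == 0`.
#' @export
compute_psi <- function(I, S, l_I = 2, l_S = 1) {
  stopifnot(all(l_I > 0), all(l_S > 0), all(I >= 0), all(S >= 0))
  ni <- I / l_I
  ns <- S / l_S
  out <- ni / (ni + ns)
  out[I + S == 0] <- NA_real_
  out
}

#' Differential inclusion across conditions
#'
#' Pools counts across replicates within each condition (count summation,
#' not Psi averaging), computes Psi per condition and
#' `delta_psi = Psi(treatment) - Psi(control)`, and tests each event with a
#' two-proportion z-test on the length-normalized pooled counts. BH
#' correction across all testable events gives the FDR `q`. Events with
#' pooled `I + S` below `min_count` in either condition are flagged and
#' excluded from the FDR family. This is a transparent substitute for
#' event-level differential-splicing likelihood models, calibrated on
#' count data but not equivalent to them.
#'
#' @param counts Tibble with columns `event_id`, `condition`, `replicate`,
#'   `I`, `S` and optionally `l_I`, `l_S` (defaults 2 and 1).
#' @param control,treatment Condition labels to compare.
#' @param min_count Minimum pooled `I + S` per condition (default 10).
#' @return Tibble, one row per event: `event_id`, `psi_control`,
#'   `psi_treatment`, `delta_psi`, `p`, `q`, `flagged`.
#' @export
delta_psi_test <- function(counts, control = "control", treatment,
                           min_count = 10) {
  stopifnot(all(c("event_id", "condition", "I", "S") %in% names(counts)))
  if (!"l_I" %in% names(counts)) counts$l_I <- 2
  if (!"l_S" %in% names(counts)) counts$l_S <- 1
  pooled <- counts %>%
    filter(.data$condition %in% c(control, treatment)) %>%
    group_by(.data$event_id, .data$condition) %>%
    summarise(I = sum(.data$I), S = sum(.data$S),
              l_I = .data$l_I[1], l_S = .data$l_S[1], .groups = "drop")
  wide <- pooled %>%
    mutate(grp = ifelse(.data$condition == control, "ctrl", "trt")) %>%
    select(-"condition") %>%
    tidyr::pivot_wider(names_from = "grp",
                       values_from = c("I", "S"),
                       values_fill = 0)
  if (!all(c("I_ctrl", "I_trt") %in% names(wide))) {
    abort("both conditions must be present in `counts`")
  }
  wide <- wide %>%
    mutate(
      flagged = (.data$I_ctrl + .data$S_ctrl < min_count) |
        (.data$I_trt + .data$S_trt < min_count),
      psi_control = compute_psi(.data$I_ctrl, .data$S_ctrl, .data$l_I, .data$l_S),
      psi_treatment = compute_psi(.data$I_trt, .data$S_trt, .data$l_I, .data$l_S),
      delta_psi = .data$psi_treatment - .data$psi_control,
      p = two_prop_p(.data$I_ctrl / .data$l_I, .data$S_ctrl / .data$l_S,
                     .data$I_trt / .data$l_I, .data$S_trt / .data$l_S)
    )
  wide$q <- NA_real_
  testable <- !wide$flagged & !is.na(wide$p)
  wide$q[testable] <- p.adjust(wide$p[testable], method = "BH")
  wide %>%
    select("event_id", "psi_control", "psi_treatment", "delta_psi",
           "p", "q", "flagged") %>%
    arrange(.data$event_id)
}

# two-proportion z-test on (possibly non-integer) effective counts
two_prop_p <- function(i1, s1, i2, s2) {
  n1 <- i1 + s1
  n2 <- i2 + s2
  p1 <- i1 / n1
  p2 <- i2 / n2
  pp <- (i1 + i2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  p <- 2 * pnorm(-abs(z))
  p[se == 0 | !is.finite(z)] <- 1
  p[n1 == 0 | n2 == 0] <- NA_real_
  p
}

#' Call retained introns at an FDR threshold
#'
#' @param records Output of [delta_psi_test()].
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return The significant subset with a `direction` column:
#'   `"more_retained"` for positive `delta_psi`, `"less_retained"` for
#'   negative.
#' @export
call_ri <- function(records, fdr_threshold = 0.05) {
  records %>%
    filter(!is.na(.data$q), .data$q < fdr_threshold, .data$delta_psi != 0) %>%
    mutate(direction = ifelse(.data$delta_psi > 0,
                              "more_retained", "less_retained"))
}

#' Row-standardize delta-Psi across conditions for common events
#'
#' Each event's delta-Psi values across conditions are centred and scaled
#' to sample SD 1 (denominator n - 1). Rows with zero SD are emitted as
#' zeros and flagged.
#'
#' @param delta_psi Wide tibble or data frame: an `event_id` column plus
#'   one numeric column per condition (at least two).
#' @return Tibble of the same shape with standardized values and a logical
#'   `flat` column marking zero-SD rows.
#' @export
zscore_common_ri <- function(delta_psi) {
  delta_psi <- as_tibble(delta_psi)
  num_cols <- names(delta_psi)[vapply(delta_psi, is.numeric, logical(1))]
  if (length(num_cols) < 2) abort("need at least two condition columns")
  m <- as.matrix(delta_psi[num_cols])
  mu <- rowMeans(m)
  sdev <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  out <- delta_psi
  out[num_cols] <- as_tibble(z)
  out$flat <- sdev == 0
  out
}

#' Compare a feature distribution against a background
#'
#' Two-sided Wilcoxon rank-sum for location (the test used for median
#' shifts in intron length and TES distance), optionally with a
#' Kolmogorov-Smirnov test for overall shape.
#'
#' @param x Feature values of the subset (e.g. retained introns).
#' @param y Background values.
#' @param tests Any of `"wilcoxon"`, `"ks"`.
#' @return Tibble: `test`, `statistic`, `p`.
#' @export
compare_feature_distributions <- function(x, y, tests = c("wilcoxon", "ks")) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  rows <- list()
  if (length(unique(c(x, y))) == 1) {
    warn("all values tied; p = 1")
    return(tibble(test = tests, statistic = NA_real_, p = 1))
  }
  if ("wilcoxon" %in% tests) {
    wt <- suppressWarnings(wilcox.test(x, y))
    rows <- c(rows, list(tibble(test = "wilcoxon",
                                statistic = unname(wt$statistic),
                                p = wt$p.value)))
  }
  if ("ks" %in% tests) {
    kt <- suppressWarnings(ks.test(x, y))
    rows <- c(rows, list(tibble(test = "ks",
                                statistic = unname(kt$statistic),
                                p = kt$p.value)))
  }
  bind_rows(rows)
}
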