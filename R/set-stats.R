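#' Gene-set overlap odds ratio with Fisher's exact test
#'
#' Builds the 2x2 table `[[|A and B|, |A only|], [|B only|, |neither|]]`
#' over a stated universe and reports the sample odds ratio
#' `(n11 * n22) / (n12 * n21)` (with a Haldane-Anscombe +0.5 on every cell
#' when any cell is zero) together with the two-sided Fisher exact
#' (hypergeometric) p-value. When `a` and `b` are named lists of sets, all
#' pairs are computed and BH-adjusted together (the adjustment family is
#' the call's pair list).
#'
#' @param a,b Character vectors (sets), or named lists of sets.
#' @param universe Character vector containing every element of `a` and
#'   `b`; an explicit required argument because the odds ratio depends on
#'   it.
#' @return Tibble, one row per pair: set sizes, table cells, `or`,
#'   `log2_or`, `p`, `p_adj`.
#' @export
overlap_or <- function(a, b, universe) {
  if (is.list(a) || is.list(b)) {
    if (!is.list(a)) a <- list(setA = a)
    if (!is.list(b)) b <- list(setB = b)
    if (is.null(names(a))) names(a) <- paste0("A", seq_along(a))
    if (is.null(names(b))) names(b) <- paste0("B", seq_along(b))
    grid <- tidyr::expand_grid(name_a = names(a), name_b = names(b))
    out <- bind_rows(map2(grid$name_a, grid$name_b, function(na, nb) {
      overlap_or_one(a[[na]], b[[nb]], universe) %>%
        mutate(name_a = na, name_b = nb, .before = 1)
    }))
    out$p_adj <- p.adjust(out$p, method = "BH")
    return(out)
  }
  out <- overlap_or_one(a, b, universe)
  out$p_adj <- out$p
  out
}

overlap_or_one <- function(a, b, universe) {
  a <- unique(a)
  b <- unique(b)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    abort("universe must contain both sets")
  }
  n <- length(unique(universe))
  n11 <- length(intersect(a, b))
  n12 <- length(setdiff(a, b))
  n21 <- length(setdiff(b, a))
  n22 <- n - n11 - n12 - n21
  if (n22 < 0) abort("universe smaller than the union of the sets")
  tab <- matrix(c(n11, n21, n12, n22), 2)
  cells <- c(n11, n12, n21, n22)
  adj <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (adj[1] * adj[4]) / (adj[2] * adj[3])
  p <- fisher.test(tab)$p.value
  tibble(n_a = length(a), n_b = length(b), n_universe = n,
         n11 = n11, n12 = n12, n21 = n21, n22 = n22,
         or = or, log2_or = log2(or), p = p)
}

#' Concordance of delta-Psi between two datasets
#'
#' Spearman rank correlation and the fraction of sign-concordant pairs on
#' events present in both tables.
#'
#' @param table_a,table_b Tibbles with columns `event_id` and `delta_psi`
#'   (e.g. [delta_psi_test()] outputs).
#' @return Tibble: `rho`, `p`, `sign_agreement`, `n`.
#' @export
delta_psi_concordance <- function(table_a, table_b) {
  joined <- inner_join(
    select(table_a, "event_id", dpsi_a = "delta_psi"),
    select(table_b, "event_id", dpsi_b = "delta_psi"),
    by = "event_id"
  ) %>% filter(complete.cases(.data$dpsi_a, .data$dpsi_b))
  if (nrow(joined) < 10) abort("need at least 10 common events")
  if (sd(joined$dpsi_a) == 0 || sd(joined$dpsi_b) == 0) {
    abort("ties-only input: rank correlation undefined")
  }
  ct <- suppressWarnings(cor.test(joined$dpsi_a, joined$dpsi_b,
                                  method = "spearman"))
  agree <- mean(sign(joined$dpsi_a) == sign(joined$dpsi_b))
  tibble(rho = unname(ct$estimate), p = ct$p.value,
         sign_agreement = agree, n = nrow(joined))
}

#' Size-matched subsampled Wilcoxon test
#'
#' Compares a subset (e.g. retained introns) against a much larger global
#' population without letting the sample-size imbalance drive the p-value:
#' on each repetition, `|subset|` values are drawn without replacement from
#' the global population and compared to the subset by a two-sided Wilcoxon
#' rank-sum test; the median p over `n_rep` repetitions (conventionally
#' 1000) is reported.
#'
#' @param subset Numeric values of the subset (length >= 3).
#' @param global Numeric values of the global population
#'   (`length(global) >= length(subset)`).
#' @param n_rep Number of repetitions (default 1000).
#' @param seed Optional seed (recommended for reproducibility).
#' @return List: `median_p`, `p_values` (length `n_rep`), `n_rep`.
#' @export
subsampled_wilcoxon <- function(subset, global, n_rep = 1000, seed = NULL) {
  if (length(subset) < 3) abort("subset must have at least 3 values")
  if (length(subset) > length(global)) abort("subset larger than global")
  stopifnot(n_rep >= 1)
  ps <- with_seed_if(seed, {
    vapply(seq_len(n_rep), function(i) {
      draw <- sample(global, length(subset), replace = FALSE)
      suppressWarnings(wilcox.test(subset, draw)$p.value)
    }, numeric(1))
  })
  list(median_p = median(ps), p_values = ps, n_rep = n_rep)
}

#' Per-sample normalization of an abundance matrix
#'
#' log2-transforms raw intensities and centres each sample (column) by the
#' average of its data distribution, i.e. subtracts the column mean
#' (`center = "median"` subtracts the column median instead).
#'
#' @param mat Numeric matrix, proteins x samples, raw intensities (> 0) or
#'   already-log2 values with `log2_transform = FALSE`.
#' @param log2_transform Apply `log2` first (default `TRUE`).
#' @param center `"mean"` (default) or `"median"`.
#' @return Normalized matrix.
#' @export
normalize_abundance <- function(mat, log2_transform = TRUE,
                                center = c("mean", "median")) {
  center <- match.arg(center)
  m <- as.matrix(mat)
  if (log2_transform) m <- log2(m)
  fun <- if (center == "mean") base::colMeans else function(x) apply(x, 2, median)
  sweep(m, 2, fun(m), "-")
}

#' Differential protein enrichment (two-tailed heteroscedastic t-test)
#'
#' Per-protein Welch (unequal-variance) two-tailed t-test between two
#' sample groups of a normalized log2 abundance matrix, with
#' `log2fc = mean(group_a) - mean(group_b)`.
#'
#' @param mat Proteins x samples matrix (rownames = protein ids).
#' @param group_a,group_b Column names or indices of the two groups
#'   (>= 2 samples each).
#' @param normalize Apply [normalize_abundance()] first (default `TRUE`;
#'   set `FALSE` if `mat` is already normalized log2 data).
#' @param ... Passed to [normalize_abundance()].
#' @return Tibble: `protein`, `log2fc`, `statistic`, `df`, `p`, `flagged`
#'   (non-finite input values in either group).
#' @export
diff_enrichment <- function(mat, group_a, group_b, normalize = TRUE, ...) {
  m <- as.matrix(mat)
  if (normalize) m <- normalize_abundance(m, ...)
  ma <- m[, group_a, drop = FALSE]
  mb <- m[, group_b, drop = FALSE]
  if (ncol(ma) < 2 || ncol(mb) < 2) abort("need >= 2 replicates per group")
  res <- map(seq_len(nrow(m)), function(i) {
    xa <- ma[i, ]
    xb <- mb[i, ]
    bad <- any(!is.finite(xa)) || any(!is.finite(xb))
    if (bad) {
      return(tibble(log2fc = NA_real_, statistic = NA_real_, df = NA_real_,
                    p = NA_real_, flagged = TRUE))
    }
    if (var(xa) == 0 && var(xb) == 0) {
      return(tibble(log2fc = mean(xa) - mean(xb), statistic = 0, df = NA_real_,
                    p = 1, flagged = FALSE))
    }
    tt <- t.test(xa, xb)
    tibble(log2fc = mean(xa) - mean(xb), statistic = unname(tt$statistic),
           df = unname(tt$parameter), p = tt$p.value, flagged = FALSE)
  })
  bind_rows(res) %>%
    mutate(protein = rownames(m) %||% as.character(seq_len(nrow(m))),
           .before = 1)
}

#' Background-subtract a poly(A) pulldown against a competitor control
#'
#' Subtracts, on the log2 scale, each protein's mean control abundance from
#' its enriched abundances; proteins whose corrected abundance is <= 0 in
#' every replicate are dropped as background binders. Proteins absent from
#' the control are kept, subtracting the control matrix's limit of
#' detection (its minimum), and flagged.
#'
#' @param enriched Proteins x replicates matrix, log2 scale.
#' @param control Matching control matrix (rows matched by rowname).
#' @return Corrected matrix with attributes `flagged` (unmatched proteins)
#'   and `dropped` (background proteins removed).
#' @export
background_subtract_polya <- function(enriched, control) {
  e <- as.matrix(enriched)
  ctrl <- as.matrix(control)
  lod <- min(ctrl)
  matched <- rownames(e) %in% rownames(ctrl)
  idx <- match(rownames(e), rownames(ctrl))
  if (ncol(ctrl) == ncol(e)) {
    # replicate-matched design: subtract the paired control replicate
    sub <- ctrl[ifelse(matched, idx, 1L), , drop = FALSE]
    sub[!matched, ] <- lod
  } else {
    ctrl_mean <- rowMeans(ctrl)
    sub <- matrix(ifelse(matched, ctrl_mean[idx], lod), nrow(e), ncol(e))
  }
  corrected <- e - sub
  drop <- apply(corrected <= 0, 1, all)
  out <- corrected[!drop, , drop = FALSE]
  attr(out, "flagged") <- rownames(e)[!matched & !drop]
  attr(out, "dropped") <- rownames(e)[drop]
  out
}
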