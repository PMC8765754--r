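#' Per-gene kinetic rate set
#'
#' The four rates of the synchronized nascent-transcription model:
#' polymerase spawn (initiation plus pause-release) `sigma` in events/min,
#' elongation `v` in nt/min, per-intron co-transcriptional splicing rates
#' `s` in 1/min (one per intron, in intron order), and transcript cleavage
#' `c` in 1/min.
#'
#' @param sigma Spawn rate (> 0), events/min.
#' @param v Elongation rate (> 0), nt/min.
#' @param s Numeric vector of per-intron splicing rates (>= 0), 1/min.
#' @param c Cleavage rate (> 0), 1/min.
#' @return A `rate_set` list.
#' @export
rate_set <- function(sigma, v, s, c) {
  stopifnot(sigma > 0, v > 0, c > 0, all(s >= 0))
  structure(list(sigma = sigma, v = v, s = as.numeric(s), c = c),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("rate_set: sigma %.3g /min, v %.4g nt/min, c %.3g /min, s [%s] /min\n",
              x$sigma, x$v, x$c, paste(signif(x$s, 3), collapse = ", ")))
  invisible(x)
}

#' Long-format coverage time course
#'
#' @param gene_id Gene identifier.
#' @param positions Bin start positions (nt, transcript-relative).
#' @param times Time points (minutes post release).
#' @param matrix Coverage matrix, `length(positions)` x `length(times)`.
#' @param bin_size Bin width in nt.
#' @return A tibble of class `coverage_tc` with columns `gene_id`,
#'   `position`, `time`, `coverage`.
#' @export
coverage_timecourse <- function(gene_id, positions, times, matrix, bin_size = 50) {
  stopifnot(nrow(matrix) == length(positions), ncol(matrix) == length(times),
            all(matrix >= 0))
  out <- tidyr::expand_grid(time = times, position = positions) %>%
    arrange(.data$time, .data$position) %>%
    mutate(gene_id = gene_id, coverage = as.vector(matrix)) %>%
    select("gene_id", "position", "time", "coverage")
  attr(out, "bin_size") <- bin_size
  class(out) <- c("coverage_tc", class(out))
  out
}

tc_matrix <- function(tc) {
  times <- sort(unique(tc$time))
  pos <- sort(unique(tc$position))
  m <- matrix(NA_real_, length(pos), length(times),
              dimnames = list(pos, times))
  m[cbind(match(tc$position, pos), match(tc$time, times))] <- tc$coverage
  list(positions = pos, times = times, matrix = m)
}

# classify bin positions against the gene's introns:
# 0 = exonic, i > 0 = inside intron i
classify_positions <- function(model, x) {
  it <- model$introns[[1]]
  cls <- integer(length(x))
  if (nrow(it) > 0) {
    for (j in seq_len(nrow(it))) {
      cls[x >= it$start[j] & x < it$end[j]] <- j
    }
  }
  cls
}

#' Expected chromatin-associated nascent-RNA coverage
#'
#' Forward model of a DRB-release experiment. Polymerases spawn as a
#' Poisson process at rate `sigma` from `t = 0` and elongate at `v`; a
#' position `x` is covered by a molecule spawned at `tau` once
#' `v (t - tau) > x`. Intronic signal at a position inside intron `i`
#' survives with probability `exp(-s_i max(0, age - e3_i / v))`, the
#' splicing clock starting when the intron's 3' splice site (at `e3_i`) is
#' transcribed. Cleaved molecules leave the chromatin fraction: every
#' position carries the cleavage survival `exp(-c max(0, age - L / v))`.
#' The spawn-time integral is evaluated by trapezoidal quadrature on an age
#' grid with step at most `quad_step` (kink points included).
#'
#' @param model One-row `gene_models` tibble.
#' @param rates A [rate_set()] with one `s` per intron of `model`.
#' @param t Time post release, minutes (> 0).
#' @param bins Bin start positions; default `seq(0, L - 1, bin_size)`.
#' @param bin_size Default bin width when `bins` is `NULL`.
#' @param quad_step Quadrature step in minutes (default 0.05).
#' @return Numeric vector of expected coverage, one value per bin.
#' @export
expected_coverage <- function(model, rates, t, bins = NULL, bin_size = 50,
                              quad_step = 0.05) {
  drop(coverage_kernel(model, rates, t, bins, bin_size, quad_step))
}

# expected coverage for several time points at once. The survival factor
# depends only on molecule age u = t - tau, so a single cumulative
# integral F(u) = int_0^u f(u') du' serves every time point:
# coverage(x, t) = sigma * (F(t) - F(x / v)).
coverage_kernel <- function(model, rates, times, bins = NULL, bin_size = 50,
                            quad_step = 0.05) {
  if (any(times <= 0)) abort("t must be positive")
  if (rates$v <= 0) abort("elongation rate must be positive")
  L <- model$length
  it <- model$introns[[1]]
  if (length(rates$s) != nrow(it)) {
    abort("rate_set must carry one splicing rate per intron")
  }
  if (is.null(bins)) bins <- seq(0, L - 1, by = bin_size)
  v <- rates$v
  cls <- classify_positions(model, bins)
  t_max <- max(times)

  kinks <- c(it$end / v, L / v, times)
  grid <- sort(unique(c(
    seq(0, t_max, length.out = max(2L, ceiling(t_max / quad_step) + 1L)),
    kinks[kinks > 0 & kinks < t_max]
  )))
  surv_cleave <- exp(-rates$c * pmax(0, grid - L / v))
  n_cls <- nrow(it) + 1L
  Fm <- matrix(0, length(grid), n_cls)
  for (k in seq_len(n_cls)) {
    f <- surv_cleave
    if (k > 1) {
      f <- f * exp(-rates$s[k - 1] * pmax(0, grid - it$end[k - 1] / v))
    }
    Fm[, k] <- cumtrapz_vec(grid, f)
  }
  ages <- bins / v                      # minimal age to reach bin x
  out <- matrix(0, length(bins), length(times))
  Ft <- Fm[match(times, grid), , drop = FALSE]  # times are on the grid
  for (k in seq_len(n_cls)) {
    sel <- which(cls == (k - 1L))
    if (length(sel) == 0) next
    Fa <- approx(grid, Fm[, k], xout = pmin(ages[sel], t_max), rule = 2)$y
    for (j in seq_along(times)) {
      val <- rates$sigma * (Ft[j, k] - Fa)
      val[ages[sel] >= times[j]] <- 0
      out[sel, j] <- pmax(0, val)
    }
  }
  out
}

cumtrapz_vec <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

#' Stochastic molecule simulator (oracle for the forward model)
#'
#' Simulates individual nascent transcripts: spawn times uniform on
#' `[0, t)` (the conditional law of a Poisson process), exponential
#' splicing waiting times started when each intron's 3' splice site is
#' transcribed, and an exponential cleavage waiting time started when the
#' polymerase reaches the TES. `method = "lhs"` uses Latin-hypercube
#' (stratified) sampling of the underlying uniforms — the estimator stays
#' unbiased and, the coverage indicator being monotone in every coordinate,
#' its variance can only decrease; use it for tight oracle comparisons.
#'
#' @inheritParams expected_coverage
#' @param n Number of molecules; default a Poisson draw with mean
#'   `sigma * t`.
#' @param seed Optional RNG seed.
#' @param method `"iid"` (default) or `"lhs"`.
#' @return A `molecule_sim` object (list with `tau`, `front`, `cleaved`,
#'   logical splice matrix `spliced`, and the inputs).
#' @export
simulate_molecules <- function(model, rates, t, n = NULL, seed = NULL,
                               method = c("iid", "lhs")) {
  method <- match.arg(method)
  it <- model$introns[[1]]
  k <- nrow(it)
  L <- model$length
  v <- rates$v
  with_seed_if(seed, {
    if (is.null(n)) n <- rpois(1, rates$sigma * t)
    n <- max(as.integer(n), 1L)
    draw_unif <- function() {
      if (method == "iid") runif(n) else (sample.int(n) - runif(n)) / n
    }
    tau <- t * draw_unif()
    age <- t - tau
    front <- pmin(v * age, L)
    cleave_wait <- qexp(draw_unif(), rate = rates$c)
    cleaved <- age > L / v & cleave_wait < (age - L / v)
    spliced <- matrix(FALSE, n, k)
    if (k > 0) {
      for (j in seq_len(k)) {
        sw <- if (rates$s[j] <= 0) rep(Inf, n) else qexp(draw_unif(), rate = rates$s[j])
        spliced[, j] <- age > it$end[j] / v & sw < (age - it$end[j] / v)
      }
    }
    structure(list(tau = tau, front = front, cleaved = cleaved,
                   spliced = spliced, model = model, rates = rates,
                   t = t, n = n, method = method),
              class = "molecule_sim")
  })
}

#' @export
print.molecule_sim <- function(x, ...) {
  cat(sprintf("molecule_sim: %d molecules at t = %g min (%s sampling); %.1f%% cleaved\n",
              x$n, x$t, x$method, 100 * mean(x$cleaved)))
  invisible(x)
}

#' Per-molecule state table
#'
#' @param x A `molecule_sim`.
#' @param ... Unused.
#' @return Tibble with one row per molecule: spawn time, front position,
#'   cleavage flag, and per-intron status
#'   (`untranscribed` / `present` / `spliced`).
#' @export
tidy.molecule_sim <- function(x, ...) {
  it <- x$model$introns[[1]]
  out <- tibble(molecule = seq_len(x$n), tau = x$tau, front = x$front,
                cleaved = x$cleaved)
  for (j in seq_len(nrow(it))) {
    status <- ifelse(x$front <= it$start[j], "untranscribed",
                     ifelse(x$spliced[, j], "spliced", "present"))
    out[[paste0("intron_", j)]] <- status
  }
  out
}

#' Empirical coverage from simulated molecules
#'
#' Counts, per bin, molecules that have transcribed past the bin, are not
#' cleaved, and (for intronic bins) still carry the intron.
#'
#' @param sim A [simulate_molecules()] result.
#' @param bins Bin start positions (default as in [expected_coverage()]).
#' @param bin_size Default bin width.
#' @return Tibble `position`, `count`, `p_hat` (count / n).
#' @export
molecule_coverage <- function(sim, bins = NULL, bin_size = 50) {
  model <- sim$model
  if (is.null(bins)) bins <- seq(0, model$length - 1, by = bin_size)
  cls <- classify_positions(model, bins)
  alive <- !sim$cleaved
  counts <- vapply(seq_along(bins), function(i) {
    keep <- alive & sim$front > bins[i]
    if (cls[i] > 0) keep <- keep & !sim$spliced[, cls[i]]
    sum(keep)
  }, numeric(1))
  tibble(position = bins, count = counts, p_hat = counts / sim$n)
}

#' Time to transcribe an intron
#'
#' @param length Intron length(s), nt.
#' @param v Elongation rate, nt/min.
#' @return Minutes.
#' @export
time_to_transcribe <- function(length, v) {
  stopifnot(all(v > 0))
  length / v
}

#' Probability that a transcript is cleaved before an intron is spliced
#'
#' Competing-risks closed form. After the intron's 3' splice site is made,
#' splicing is exponential at rate `s`; cleavage becomes possible only a
#' delay `d = (L - e3) / v` later and is then exponential at rate `c`. The
#' intron escapes co-transcriptional splicing when `d + Exp(c) < Exp(s)`:
#' `P = exp(-s d) * c / (c + s)`. With `s = 0` the intron never splices and
#' `P = 1`.
#'
#' @param s Splicing rate (>= 0), 1/min.
#' @param c Cleavage rate (> 0), 1/min.
#' @param d Delay between 3'SS synthesis and TES arrival, minutes (>= 0).
#' @return Probability in (0, 1]. Vectorized over the inputs.
#' @export
cleavage_before_splicing_prob <- function(s, c, d) {
  stopifnot(all(s >= 0), all(c > 0), all(d >= 0))
  exp(-s * d) * c / (c + s)
}

#' Monte-Carlo estimate of the cleavage-before-splicing probability
#'
#' Brute-force check of [cleavage_before_splicing_prob()]: draws the two
#' exponential waiting times and counts `d + Exp(c) < Exp(s)`.
#'
#' @inheritParams cleavage_before_splicing_prob
#' @param n Number of draws.
#' @param seed Optional seed.
#' @param method `"iid"` or `"lhs"` (stratified uniforms; variance-reduced).
#' @return List with `p_hat` and its standard error `se`.
#' @export
mc_cleavage_before_splicing <- function(s, c, d, n = 1e6, seed = NULL,
                                        method = c("iid", "lhs")) {
  method <- match.arg(method)
  with_seed_if(seed, {
    draw_unif <- function() {
      if (method == "iid") runif(n) else (sample.int(n) - runif(n)) / n
    }
    splice_wait <- if (s <= 0) rep(Inf, n) else qexp(draw_unif(), rate = s)
    cleave_wait <- qexp(draw_unif(), rate = c)
    hit <- d + cleave_wait < splice_wait
    # Laplace-smoothed SE so the uncertainty never collapses to zero at the
    # resolution limit of n draws
    pt <- (sum(hit) + 1) / (n + 2)
    list(p_hat = mean(hit), se = sqrt(pt * (1 - pt) / n))
  })
}

#' Predicted poly(A)-RNA cassette-exon percent spliced in
#'
#' Commitment-race model for a cassette exon flanked by an upstream intron
#' (splicing rate `s_u`), a downstream intron (`s_d`) and a skip event
#' (`s_skip`). The upstream intron's clock starts a head start
#' `delta_t = (e3_down - e3_up) / v` before the downstream and skip clocks.
#' Inclusion is committed if either flanking intron splices before the skip
#' event; by memorylessness
#' `Psi = 1 - exp(-s_u delta_t) * s_skip / (s_u + s_d + s_skip)`.
#' Cleavage does not censor the race (splicing can finish
#' post-transcriptionally).
#'
#' @param s_u,s_d,s_skip Non-negative rates, 1/min (not all zero).
#' @param delta_t Head start in minutes (>= 0).
#' @return Psi in `[0, 1]`. Vectorized.
#' @export
predicted_cassette_psi <- function(s_u, s_d, s_skip, delta_t) {
  tot <- s_u + s_d + s_skip
  if (any(tot <= 0)) abort("at least one of s_u, s_d, s_skip must be positive")
  stopifnot(all(s_u >= 0), all(s_d >= 0), all(s_skip >= 0), all(delta_t >= 0))
  1 - exp(-s_u * delta_t) * s_skip / tot
}

#' Monte-Carlo estimate of the cassette-exon race
#'
#' Simulates the explicit three-way race behind
#' [predicted_cassette_psi()]: `T_u ~ Exp(s_u)` from time 0,
#' `T_d ~ delta_t + Exp(s_d)`, `T_skip ~ delta_t + Exp(s_skip)`; inclusion
#' iff `min(T_u, T_d) < T_skip`.
#'
#' @inheritParams predicted_cassette_psi
#' @param n Number of molecules.
#' @param seed Optional seed.
#' @param method `"iid"` or `"lhs"`.
#' @return List with `psi_hat` and `se`.
#' @export
mc_cassette_psi <- function(s_u, s_d, s_skip, delta_t, n = 1e6, seed = NULL,
                            method = c("iid", "lhs")) {
  method <- match.arg(method)
  if (s_u + s_d + s_skip <= 0) abort("at least one rate must be positive")
  with_seed_if(seed, {
    draw_unif <- function() {
      if (method == "iid") runif(n) else (sample.int(n) - runif(n)) / n
    }
    qexp0 <- function(u, rate) if (rate <= 0) rep(Inf, length(u)) else qexp(u, rate)
    t_u <- qexp0(draw_unif(), s_u)
    t_d <- delta_t + qexp0(draw_unif(), s_d)
    t_skip <- delta_t + qexp0(draw_unif(), s_skip)
    inc <- pmin(t_u, t_d) < t_skip
    pt <- (sum(inc) + 1) / (n + 2)
    list(psi_hat = mean(inc), se = sqrt(pt * (1 - pt) / n))
  })
}
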