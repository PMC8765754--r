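#' Initialize the elongation rate from the coverage wavefront
#'
#' After DRB release the polymerase wave advances at `v` nt/min, so the
#' position of the coverage front is linear in time. For each time point
#' the front is the first bin whose coverage drops below
#' `threshold_frac` times the maximum upstream coverage; `v` is the
#' least-squares slope of front position against time.
#'
#' @param tc A single-gene [coverage_timecourse()].
#' @param threshold_frac Fraction of the per-time maximum coverage that
#'   defines the front (default 0.1).
#' @param fallback_v Value returned (with a warning) when fewer than two
#'   time points have a detectable front, e.g. the prior median elongation
#'   rate. Default 1500 nt/min.
#' @return Estimated `v` in nt/min.
#' @export
estimate_elongation_wavefront <- function(tc, threshold_frac = 0.1,
                                          fallback_v = 1500) {
  m <- tc_matrix(tc)
  fronts <- vapply(seq_along(m$times), function(j) {
    y <- m$matrix[, j]
    if (all(y <= 0)) return(NA_real_)
    thr <- threshold_frac * max(y)
    below <- which(y < thr)
    # the front must lie beyond the maximum (ignore a sub-threshold start bin)
    below <- below[below > which.max(y)]
    if (length(below) == 0) return(NA_real_)  # wave past the gene end
    crossing <- m$positions[below[1]]
    # refine on the leading edge: before saturation the profile ramps
    # linearly to zero at the true front, so extrapolate the ramp
    ramp <- which(y >= 0.05 * max(y) & y <= 0.8 * max(y) &
                    seq_along(y) >= which.max(y) &
                    m$positions <= crossing)
    if (length(ramp) >= 3) {
      fit <- lm(cov ~ pos, data = data.frame(cov = y[ramp],
                                             pos = m$positions[ramp]))
      if (is.finite(coef(fit)[2]) && coef(fit)[2] < 0) {
        x0 <- -coef(fit)[1] / coef(fit)[2]
        if (x0 > 0 && x0 <= max(m$positions) + diff(m$positions[1:2])) {
          return(unname(x0))
        }
      }
    }
    crossing
  }, numeric(1))
  ok <- !is.na(fronts)
  if (sum(ok) < 2) {
    warn("fewer than two usable wavefronts; returning fallback elongation rate")
    return(fallback_v)
  }
  fit <- lm(front ~ time, data = tibble(front = fronts[ok], time = m$times[ok]))
  unname(coef(fit)[2])
}

default_fit_options <- function() {
  list(
    n_restarts = 5L,
    seed = NULL,
    loss = "ls",          # or "poisson" (deviance; for Poisson count noise)
    quad_step = 0.05,
    maxit = 400L,
    jitter_sdlog = 0.5,
    bounds = list(sigma = c(1e-3, 1e3), v = c(1e2, 1e5),
                  s = c(1e-4, 1e2), c = c(1e-3, 1e2)),
    threshold_frac = 0.1,
    fallback_v = 1500
  )
}

#' Fit the four kinetic rates to a coverage time course
#'
#' Minimizes the sum of squared residuals between observed coverage and
#' [expected_coverage()] over log-parameters
#' (log sigma, log v, log s_1..k, log c) with box constraints, using
#' L-BFGS-B from multiple jittered starts. The elongation rate is
#' initialized from the wavefront, the spawn rate from the early exonic
#' ramp. Bins with zero coverage at every time point (never transcribed
#' within the experiment) are excluded.
#'
#' @param tc A single-gene [coverage_timecourse()] with at least 3 time
#'   points.
#' @param model The matching one-row `gene_models` tibble.
#' @param options Named list overriding the defaults: `n_restarts` (5),
#'   `seed`, `quad_step` (0.05 min), `maxit`, `jitter_sdlog`, `bounds`.
#' @return A `skater_fit` object: `rates` ([rate_set()]), `loss`,
#'   `convergence` flag, `n_restarts`, plus the data used.
#' @export
fit_rates <- function(tc, model, options = list()) {
  opt <- modifyList(default_fit_options(), options)
  m <- tc_matrix(tc)
  if (length(m$times) < 3) abort("need at least 3 time points")
  if (all(m$matrix == 0)) abort("gene not expressed: all-zero coverage")
  keep <- rowSums(m$matrix) > 0
  pos <- m$positions[keep]
  obs <- m$matrix[keep, , drop = FALSE]
  it <- model$introns[[1]]
  k <- nrow(it)

  bounds <- opt$bounds
  lower <- log(c(bounds$sigma[1], bounds$v[1], rep(bounds$s[1], k), bounds$c[1]))
  upper <- log(c(bounds$sigma[2], bounds$v[2], rep(bounds$s[2], k), bounds$c[2]))

  v0 <- estimate_elongation_wavefront(tc, opt$threshold_frac, opt$fallback_v)
  v0 <- min(max(v0, bounds$v[1] * 1.5), bounds$v[2] / 1.5)
  # spawn rate from the linear ramp near the TSS at the last time point
  t_max <- max(m$times)
  near <- which(pos <= 0.2 * model$length & pos / v0 < 0.8 * t_max)
  sigma0 <- if (length(near) > 0) {
    median(obs[near, length(m$times)] / pmax(t_max - pos[near] / v0, 0.5))
  } else {
    1
  }
  sigma0 <- min(max(sigma0, bounds$sigma[1] * 2), bounds$sigma[2] / 2)
  # per-intron start: the intron/exon coverage ratio at the last time point
  # approximates the mean splicing survival exp(-s * residual age)
  cls <- classify_positions(model, pos)
  s0 <- rep(0.3, k)
  if (k > 0) {
    last_cov <- obs[, length(m$times)]
    exon_mean <- mean(last_cov[cls == 0 & pos / v0 < 0.8 * t_max])
    for (j in seq_len(k)) {
      sel <- cls == j & pos / v0 < 0.8 * t_max
      if (!is.finite(exon_mean) || exon_mean <= 0 || sum(sel) == 0) next
      ratio <- min(max(mean(last_cov[sel]) / exon_mean, 0.02), 0.98)
      # molecules spawned uniformly since release: mean splicing-clock time
      res_age <- max((t_max - it$end[j] / v0) / 2, 0.2)
      s0[j] <- min(max(-log(ratio) / res_age, 0.01), 5)
    }
  }
  theta0 <- log(c(sigma0, v0, s0, 0.3))
  theta0 <- pmin(pmax(theta0, lower), upper)

  poisson_dev <- function(obs, pred) {
    pred <- pmax(pred, 1e-8)
    ll <- obs * log(obs / pred)
    ll[obs == 0] <- 0
    2 * sum(pred - obs + ll)
  }
  loss_fn <- function(theta) {
    r <- rate_set(exp(theta[1]), exp(theta[2]),
                  if (k > 0) exp(theta[2 + seq_len(k)]) else numeric(),
                  exp(theta[length(theta)]))
    pred <- coverage_kernel(model, r, m$times, bins = pos,
                            quad_step = opt$quad_step)
    if (opt$loss == "poisson") poisson_dev(obs, pred) else sum((obs - pred)^2)
  }

  seeds <- if (is.null(opt$seed)) rep(NA, opt$n_restarts) else
    derive_seeds(opt$seed, opt$n_restarts)
  run_start <- function(i) {
    th <- theta0
    if (i > 1) {
      jitter <- if (is.na(seeds[i])) rnorm(length(th), 0, opt$jitter_sdlog)
      else withr::with_seed(seeds[i], rnorm(length(th), 0, opt$jitter_sdlog))
      th <- pmin(pmax(theta0 + jitter, lower), upper)
    }
    res <- tryCatch(
      optim(th, loss_fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = opt$maxit, factr = 1e4)),
      error = function(e) list(par = th, value = loss_fn(th), convergence = 99L)
    )
    res
  }
  fits <- map(seq_len(opt$n_restarts), run_start)
  losses <- map_dbl(fits, "value")
  norms <- map_dbl(fits, ~ sqrt(sum(.x$par^2)))
  best <- order(losses, norms)[1]       # ties broken by smallest norm
  res <- fits[[best]]
  theta <- res$par
  rates <- rate_set(exp(theta[1]), exp(theta[2]),
                    if (k > 0) exp(theta[2 + seq_len(k)]) else numeric(),
                    exp(theta[length(theta)]))
  # converged if the best start exited cleanly, or any cleanly-exited start
  # reached (essentially) the same loss
  conv_codes <- map_int(fits, ~ as.integer(.x$convergence %||% 0L))
  loss_tol <- res$value * 1e-3 + 1e-10 * sum(obs^2)   # numerically equal fits
  converged <- conv_codes[best] == 0L ||
    any(conv_codes == 0L & losses <= res$value + loss_tol)
  if (!converged) {
    warn(sprintf("gene %s: no start converged; returning best loss anyway",
                 model$gene_id))
  }
  structure(list(
    gene_id = model$gene_id,
    rates = rates,
    loss = res$value,
    convergence = converged,
    n_restarts = opt$n_restarts,
    n_bins = length(pos),
    times = m$times,
    model = model,
    positions = pos,
    observed = obs
  ), class = "skater_fit")
}

#' @export
print.skater_fit <- function(x, ...) {
  cat(sprintf("skater_fit for %s: loss %.4g (%s, %d starts)\n",
              x$gene_id, x$loss,
              if (x$convergence) "converged" else "NOT converged",
              x$n_restarts))
  print(x$rates)
  invisible(x)
}

#' Tidy a fitted rate set
#' @param x A `skater_fit`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `term`, `estimate`.
#' @export
tidy.skater_fit <- function(x, ...) {
  s <- x$rates$s
  tibble(
    gene_id = x$gene_id,
    term = c("sigma", "v",
             if (length(s) > 0) paste0("s_", seq_along(s)) else character(), "c"),
    estimate = c(x$rates$sigma, x$rates$v, s, x$rates$c)
  )
}

#' One-row fit summary
#' @param x A `skater_fit`.
#' @param ... Unused.
#' @export
glance.skater_fit <- function(x, ...) {
  tibble(gene_id = x$gene_id, loss = x$loss, convergence = x$convergence,
         n_restarts = x$n_restarts, n_bins = x$n_bins,
         n_times = length(x$times))
}

#' Rank correlation between fitted spawn rates and expression
#'
#' @param fits Tibble with columns `gene_id` and `sigma` (e.g. from binding
#'   `tidy()` results), or a list of `skater_fit` objects.
#' @param expression Tibble with columns `gene_id` and `tpm`.
#' @return Tibble with Spearman `rho`, `p`, and `n`.
#' @export
spawn_expression_correlation <- function(fits, expression) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- bind_rows(map(fits, tidy)) %>%
      filter(.data$term == "sigma") %>%
      select("gene_id", sigma = "estimate")
  }
  joined <- inner_join(fits, expression, by = "gene_id")
  if (nrow(joined) < 10) abort("need at least 10 shared genes")
  if (sd(joined$sigma) == 0 || sd(joined$tpm) == 0) {
    abort("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(cor.test(joined$sigma, joined$tpm, method = "spearman"))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = nrow(joined))
}
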