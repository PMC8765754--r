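# shared small fixtures, built in code

# two-exon gene: exon [0,2000), intron [2000,3000), exon [3000,5000)
toy_gene <- function() {
  gene_model("toy", exon_starts = c(0, 3000), exon_ends = c(2000, 5000))
}

toy_rates <- function(s = 0.3) rate_set(sigma = 2, v = 1000, s = s, c = 0.5)

# small study shared across tests (cached per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(n_genes = 30, seed = 101,
                                          tc_genes = 2))
    }
    cache
  }
})

expect_rel_error <- function(est, truth, tol) {
  expect_lt(max(abs(est - truth) / abs(truth)), tol)
}
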