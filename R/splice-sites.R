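#' Position probability matrices at splice sites
#'
#' Tabulates the nucleotide distribution in fixed windows around each
#' intron's 5' splice site (donor) and 3' splice site (acceptor), across all
#' introns of the supplied gene models. Offsets are counted without a zero:
#' `-1` is the last exonic base before the site, `+1` the first base after
#' it, so the canonical donor GT sits at offsets `+1, +2` and the acceptor
#' AG at `-2, -1`.
#'
#' Ambiguous bases (`N`) and window positions that fall outside the gene
#' sequence are excluded from that column's denominator.
#'
#' @param models A `gene_models` tibble.
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`)
#'   of pre-mRNA sequences, one per gene, each of length `L` in the
#'   transcript-relative frame.
#' @param window5,window3 Integer `c(from, to)` offset ranges for the donor
#'   and acceptor windows. Defaults `-3..+6` and `-20..+3`.
#' @return A list with elements `five_prime` and `three_prime`, each a
#'   `splice_site_profile`: a 4 x width probability matrix (rows A, C, G, T)
#'   with offset column names and attributes `site` and `offsets`.
#' @export
splice_site_profiles <- function(models, sequences,
                                 window5 = c(-3L, 6L), window3 = c(-20L, 3L)) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  stopifnot(!is.null(names(sequences)))
  list(
    five_prime = site_profile(models, sequences, window5, "5prime"),
    three_prime = site_profile(models, sequences, window3, "3prime")
  )
}

offset_seq <- function(window) {
  setdiff(seq(window[1], window[2]), 0L)
}

site_profile <- function(models, sequences, window, site) {
  offs <- offset_seq(window)
  counts <- matrix(0, nrow = 4, ncol = length(offs),
                   dimnames = list(c("A", "C", "G", "T"), as.character(offs)))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    seq_i <- sequences[[m$gene_id]]
    if (is.null(seq_i) || is.na(seq_i)) next
    it <- m$introns[[1]]
    for (j in seq_len(nrow(it))) {
      anchor <- if (site == "5prime") it$start[j] else it$end[j]
      # 1-based character index for offset o (no offset 0)
      idx <- anchor + offs + as.integer(offs < 0)
      ok <- idx >= 1 & idx <= nchar(seq_i)
      bases <- rep(NA_character_, length(offs))
      bases[ok] <- strsplit(substring(seq_i, 1, nchar(seq_i)), "")[[1]][idx[ok]]
      for (p in seq_along(offs)) {
        b <- toupper(bases[p])
        if (!is.na(b) && b %in% rownames(counts)) {
          counts[b, p] <- counts[b, p] + 1
        }
      }
    }
  }
  totals <- colSums(counts)
  probs <- sweep(counts, 2, pmax(totals, 1), "/")
  structure(probs, site = site, offsets = offs, n_sites = totals,
            class = c("splice_site_profile", "matrix"))
}

#' @export
print.splice_site_profile <- function(x, ...) {
  cat(sprintf("splice-site profile (%s), %d positions\n",
              attr(x, "site"), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

# position weight matrices used by the synthetic-sequence generator:
# approximate human donor (consensus cAG|GTAAGt) and acceptor
# (polypyrimidine tract + yAG|g) compositions.
donor_pwm <- function() {
  m <- rbind(
    A = c(.33, .60, .10, .00, .00, .55, .70, .10, .15),
    C = c(.35, .12, .05, .00, .00, .03, .08, .05, .18),
    G = c(.20, .13, .80, 1.0, .00, .40, .12, .80, .20),
    T = c(.12, .15, .05, .00, 1.0, .02, .10, .05, .47)
  )
  colnames(m) <- as.character(offset_seq(c(-3L, 6L)))
  m
}

acceptor_pwm <- function() {
  ppt <- c(A = .10, C = .30, G = .10, T = .50)
  m <- matrix(rep(ppt, 16), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  tail_m <- rbind(
    A = c(.25, .05, 1.0, .00, .25, .25, .25),
    C = c(.30, .65, .00, .00, .15, .25, .25),
    G = c(.15, .05, .00, 1.0, .50, .25, .25),
    T = c(.30, .25, .00, .00, .10, .25, .25)
  )
  m <- cbind(m, tail_m)
  colnames(m) <- as.character(offset_seq(c(-20L, 3L)))
  m
}

sample_from_pwm <- function(pwm, n) {
  apply(pwm, 2, function(p) sample(rownames(pwm), n, replace = TRUE, prob = p))
}
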