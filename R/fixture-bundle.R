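#' Write a synthetic study to plain-text files
#'
#' Emits everything a downstream run needs: the annotation (GTF), one
#' bedGraph per condition and time point, the junction-count and
#' transcription-block count tables (TSV), the ground truth (TSV), the
#' planted sequences (FASTA) and a manifest carrying the seed and a hash
#' of the configuration.
#'
#' @param study A [simulate_study()] result.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create %s", outdir))
  files <- c()
  p <- function(x) file.path(outdir, x)

  write_gtf(study$models, p("genes.gtf"))
  files["gtf"] <- p("genes.gtf")

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$sequences), p("sequences.fa"))
  files["fasta"] <- p("sequences.fa")

  tc <- study$timecourse
  if (nrow(tc) > 0) {
    combos <- dplyr::distinct(tc, .data$condition, .data$time)
    for (i in seq_len(nrow(combos))) {
      nm <- sprintf("coverage_%s_t%02d.bedGraph",
                    combos$condition[i], as.integer(combos$time[i]))
      write_coverage_bedgraph(
        filter(tc, .data$condition == combos$condition[i],
               .data$time == combos$time[i]),
        study$models, p(nm), bin_size = study$config$bin_size)
      files[nm] <- p(nm)
    }
  }

  readr::write_tsv(study$polya_counts, p("polya_counts.tsv"))
  readr::write_tsv(study$actd_counts, p("actd_counts.tsv"))
  readr::write_tsv(study$truth$genes, p("truth_genes.tsv"))
  readr::write_tsv(study$truth$introns, p("truth_introns.tsv"))
  files[c("polya", "actd", "truth_genes", "truth_introns")] <-
    p(c("polya_counts.tsv", "actd_counts.tsv", "truth_genes.tsv",
        "truth_introns.tsv"))

  manifest <- list(seed = study$config$seed,
                   config_hash = hash_config(study$config),
                   files = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  files["manifest"] <- p("manifest.json")
  invisible(files)
}

hash_config <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write one time point of coverage as bedGraph
#'
#' @param tc A `coverage_tc` slice at a single time (and condition).
#' @param models The matching `gene_models` tibble (for the genomic map).
#' @param path Output path.
#' @param bin_size Bin width in nt.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(tc, models, path, bin_size = 50) {
  rows <- map(unique(tc$gene_id), function(gid) {
    m <- models[models$gene_id == gid, ]
    sub <- filter(tc, .data$gene_id == gid)
    g1 <- txn_to_genomic(m, sub$position)
    g2 <- txn_to_genomic(m, pmin(sub$position + bin_size, m$length))
    tibble(chrom = m$chrom, start = pmin(g1, g2), end = pmax(g1, g2),
           score = sub$coverage)
  })
  df <- bind_rows(rows) %>% arrange(.data$chrom, .data$start)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph back into a transcript-relative coverage slice
#'
#' @param path bedGraph file.
#' @param models `gene_models` tibble providing the genomic map.
#' @param time Time point to stamp on the slice (min).
#' @param condition Optional condition label.
#' @return A `coverage_tc` tibble.
#' @export
read_coverage_bedgraph <- function(path, models, time, condition = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               coverage = gr$score)
  out <- map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    sub <- filter(df, .data$chrom == m$chrom,
                  .data$start >= m$genomic_start,
                  .data$end <= m$genomic_start + m$length)
    if (nrow(sub) == 0) return(NULL)
    pos <- if (m$strand == "+") genomic_to_txn(m, sub$start)
           else genomic_to_txn(m, sub$end)
    tibble(gene_id = m$gene_id, position = pos, time = time,
           coverage = sub$coverage) %>% arrange(.data$position)
  })
  res <- bind_rows(purrr::compact(out))
  if (!is.null(condition)) res$condition <- condition
  class(res) <- c("coverage_tc", class(res))
  res
}

#' Read a fixture bundle back into memory
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with `models`, `sequences`, `truth`, `polya_counts`,
#'   `actd_counts`, `timecourse`, `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  models <- read_annotation(file.path(dir, "genes.gtf"))
  seqs <- as.character(Biostrings::readDNAStringSet(file.path(dir, "sequences.fa")))
  bg <- list.files(dir, pattern = "^coverage_.*\\.bedGraph$", full.names = TRUE)
  tc <- bind_rows(map(bg, function(f) {
    nm <- sub("\\.bedGraph$", "", basename(f))
    parts <- strsplit(nm, "_")[[1]]
    read_coverage_bedgraph(f, models,
                           time = as.numeric(sub("^t", "", parts[3])),
                           condition = parts[2])
  }))
  list(
    models = models,
    sequences = seqs,
    truth = list(
      genes = readr::read_tsv(file.path(dir, "truth_genes.tsv"),
                              show_col_types = FALSE),
      introns = readr::read_tsv(file.path(dir, "truth_introns.tsv"),
                                show_col_types = FALSE)
    ),
    polya_counts = readr::read_tsv(file.path(dir, "polya_counts.tsv"),
                                   show_col_types = FALSE),
    actd_counts = readr::read_tsv(file.path(dir, "actd_counts.tsv"),
                                  show_col_types = FALSE),
    timecourse = tc,
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"))
  )
}
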