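#' Build a single gene model from transcript-relative exon intervals
#'
#' A gene model is the coordinate frame for all kinetic computations:
#' positions are measured in nucleotides along the direction of
#' transcription, 0-based and half-open, with the transcription start site
#' (TSS) at 0 and the transcription end site (TES) at `L`. Exons and the
#' introns between them tile `[0, L)`.
#'
#' @param gene_id Gene identifier.
#' @param exon_starts,exon_ends Transcript-relative exon intervals
#'   (`[start, end)`), already strand-normalized and sorted.
#' @param strand `"+"` or `"-"`; kept for the genomic coordinate map.
#' @param chrom Chromosome name for the genomic map.
#' @param genomic_start Genomic coordinate (0-based) of the leftmost base of
#'   the gene span.
#' @param intron_class Optional character vector of intron classes
#'   (`"constitutive"`, `"cassette-flank"`, `"alt5"`, `"alt3"`), recycled.
#' @return A one-row tibble of class `gene_models` with list-columns
#'   `exons` and `introns`.
#' @export
#' @examples
#' gene_model("g1", exon_starts = c(0, 200), exon_ends = c(100, 300))
gene_model <- function(gene_id, exon_starts, exon_ends, strand = "+",
                       chrom = "chr1", genomic_start = 0L,
                       intron_class = "constitutive") {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1)
  o <- order(exon_starts)
  exon_starts <- as.numeric(exon_starts[o])
  exon_ends <- as.numeric(exon_ends[o])
  if (any(exon_ends <= exon_starts)) {
    abort("exon intervals must have positive width")
  }
  if (exon_starts[1] != 0) {
    abort("first exon must start at the TSS (position 0)")
  }
  if (any(exon_starts[-1] <= exon_ends[-length(exon_ends)] - 1e-9 &
          exon_starts[-1] < exon_ends[-length(exon_ends)])) {
    abort("exons overlap after sorting")
  }
  L <- exon_ends[length(exon_ends)]
  n_int <- length(exon_starts) - 1L
  introns <- if (n_int > 0) {
    istart <- exon_ends[-length(exon_ends)]
    iend <- exon_starts[-1]
    if (any(iend <= istart)) abort("adjacent exons must be separated by an intron")
    tibble(
      index = seq_len(n_int),
      start = istart,
      end = iend,
      length = iend - istart,
      dist_to_tes = L - iend,
      class = rep_len(intron_class, n_int)
    )
  } else {
    tibble(index = integer(), start = numeric(), end = numeric(),
           length = numeric(), dist_to_tes = numeric(), class = character())
  }
  out <- tibble(
    gene_id = gene_id,
    chrom = chrom,
    strand = strand,
    genomic_start = as.numeric(genomic_start),
    length = L,
    n_introns = n_int,
    exons = list(tibble(start = exon_starts, end = exon_ends)),
    introns = list(introns)
  )
  class(out) <- c("gene_models", class(out))
  validate_gene_models(out)
}

#' Bind gene models into one table
#' @param ... `gene_models` tibbles (or a list of them).
#' @return A `gene_models` tibble, one row per gene.
#' @export
gene_models <- function(...) {
  x <- list(...)
  if (length(x) == 1 && is.list(x[[1]]) && !is_tibble(x[[1]])) x <- x[[1]]
  out <- bind_rows(x)
  class(out) <- c("gene_models", setdiff(class(out), "gene_models"))
  validate_gene_models(out)
}

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    it <- models$introns[[i]]
    L <- models$length[i]
    covered <- sum(ex$end - ex$start) + sum(it$end - it$start)
    if (abs(covered - L) > 1e-9) {
      abort(sprintf("gene %s: exons and introns do not tile [0, L)",
                    models$gene_id[i]))
    }
    if (nrow(it) > 0) {
      if (is.unsorted(it$start)) abort("introns must be sorted by start")
      if (any(it$length <= 0)) abort("intron length must be positive")
      if (any(it$dist_to_tes < 0) || any(it$end >= L + 1e-9)) {
        abort("every intron 3' end must lie strictly inside the gene")
      }
    }
  }
  models
}

#' Map transcript-relative positions to genomic coordinates (and back)
#'
#' Because exons and introns tile the gene span, the map is affine:
#' on `+` genes `genomic = genomic_start + x`, on `-` genes
#' `genomic = genomic_start + L - x`.
#'
#' @param model One row of a `gene_models` tibble.
#' @param x Transcript-relative positions (0-based).
#' @return Genomic positions (0-based).
#' @export
txn_to_genomic <- function(model, x) {
  if (model$strand == "+") model$genomic_start + x
  else model$genomic_start + model$length - x
}

#' @rdname txn_to_genomic
#' @param g Genomic positions (0-based).
#' @export
genomic_to_txn <- function(model, g) {
  if (model$strand == "+") g - model$genomic_start
  else model$genomic_start + model$length - g
}

#' Read gene annotations into transcript-relative gene models
#'
#' Reads GTF (gene/transcript/exon features) or BED12. One representative
#' transcript is kept per gene: the one with the largest exonic span
#' (ties broken by transcript id, deterministically). All coordinates are
#' converted to the transcript-relative, strand-normalized frame
#' (TSS = 0); the genomic map is retained on each row.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return A `gene_models` tibble.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(12)?$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (format == "gtf") read_annotation_gtf(path) else read_annotation_bed12(path)
}

read_annotation_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) abort(sprintf("parse error in %s: %s", path, conditionMessage(e)))
  )
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) abort(sprintf("no exon features in %s", path))
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1,  # to 0-based
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id)
  )
  models <- df %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(exonic = sum(.data$end - .data$start), .groups = "drop_last") %>%
    arrange(dplyr::desc(.data$exonic), .data$transcript_id) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    inner_join(df, by = c("gene_id", "transcript_id")) %>%
    group_by(.data$gene_id) %>%
    dplyr::group_split() %>%
    map(blocks_to_model) %>%
    purrr::compact()
  gene_models(models)
}

read_annotation_bed12 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) abort(sprintf("parse error in %s: %s", path, conditionMessage(e)))
  )
  rows <- map(seq_along(gr), function(i) {
    blocks <- if (!is.null(gr$blocks)) gr$blocks[[i]] else IRanges::IRanges(1, GenomicRanges::width(gr[i]))
    gstart <- GenomicRanges::start(gr[i]) - 1
    tibble(
      chrom = as.character(GenomicRanges::seqnames(gr[i])),
      start = gstart + IRanges::start(blocks) - 1,
      end = gstart + IRanges::end(blocks),
      strand = as.character(GenomicRanges::strand(gr[i])),
      gene_id = gr$name[i] %||% sprintf("gene_%d", i),
      transcript_id = gr$name[i] %||% sprintf("tx_%d", i)
    )
  })
  # longest per name
  tab <- bind_rows(rows) %>%
    group_by(.data$gene_id) %>%
    dplyr::group_split()
  models <- map(tab, function(df) {
    widths <- df %>% group_by(.data$transcript_id) %>%
      summarise(w = sum(.data$end - .data$start)) %>%
      arrange(dplyr::desc(.data$w), .data$transcript_id)
    blocks_to_model(df[df$transcript_id == widths$transcript_id[1], ])
  })
  gene_models(purrr::compact(models))
}

# genomic exon blocks (0-based, one transcript) -> gene model, or NULL
blocks_to_model <- function(df) {
  if (nrow(df) == 0) return(NULL)
  strand <- df$strand[1]
  if (!strand %in% c("+", "-")) strand <- "+"
  gstart <- min(df$start)
  gend <- max(df$end)
  if (gend <= gstart) {
    warn(sprintf("transcript %s has no exonic span; skipped", df$transcript_id[1]))
    return(NULL)
  }
  if (strand == "+") {
    s <- sort(df$start) - gstart
    e <- sort(df$end) - gstart
  } else {
    s <- sort(gend - df$end)
    e <- sort(gend - df$start)
  }
  gene_model(df$gene_id[1], s, e, strand = strand, chrom = df$chrom[1],
             genomic_start = gstart)
}

#' Write gene models as GTF
#'
#' Emits gene, transcript and exon features in genomic coordinates so that
#' [read_annotation()] round-trips the models.
#'
#' @param models A `gene_models` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  grs <- map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    gs <- txn_to_genomic(m, c(ex$start, ex$end))
    gstart <- pmin(gs[seq_len(nrow(ex))], gs[nrow(ex) + seq_len(nrow(ex))])
    gend <- pmax(gs[seq_len(nrow(ex))], gs[nrow(ex) + seq_len(nrow(ex))])
    span <- c(m$genomic_start, m$genomic_start + m$length)
    GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(
        start = c(span[1], span[1], gstart) + 1,
        end = c(span[2], span[2], gend)
      ),
      strand = m$strand,
      type = c("gene", "transcript", rep("exon", nrow(ex))),
      gene_id = m$gene_id,
      transcript_id = paste0(m$gene_id, ".t1")
    )
  })
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Per-intron feature table
#'
#' Intron length and distance to the TES, each also expressed as
#' log10(kilobases), the scale on which retained-intron feature shifts are
#' usually displayed.
#'
#' @param models A `gene_models` tibble.
#' @return A tibble with one row per intron: `gene_id`, `intron_index`,
#'   `length`, `dist_to_tes`, `log10_kb_length`, `log10_kb_dist`, `class`.
#' @export
intron_features <- function(models) {
  models %>%
    select("gene_id", "introns") %>%
    tidyr::unnest("introns") %>%
    rename(intron_index = "index") %>%
    mutate(
      log10_kb_length = log10(.data$length / 1000),
      log10_kb_dist = ifelse(.data$dist_to_tes > 0,
                             log10(.data$dist_to_tes / 1000), NA_real_)
    ) %>%
    select("gene_id", "intron_index", "length", "dist_to_tes",
           "log10_kb_length", "log10_kb_dist", "class")
}
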