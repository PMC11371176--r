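#' Write gene models to GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 is 1-based inclusive,
#' so `start` gains 1 on the way out and loses it on the way in.
#'
#' @param genes a [gene_model()] table.
#' @param path output file.
#' @param chrom_len optional chromosome length recorded as a sequence
#'   region length.
#' @export
write_genes_gff3 <- function(genes, path, chrom_len = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$source <- "paskit"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$Name <- genes$gene_id
  S4Vectors::mcols(gr)$is_tf <- ifelse(genes$is_tf, "true", "false")
  if (!is.null(chrom_len))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(chrom_len, unique(genes$chrom))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene` features carrying `ID` (and optionally
#'   `is_tf`) attributes.
#' @return a [gene_model()] table in 0-based half-open coordinates.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  is_tf <- if ("is_tf" %in% names(S4Vectors::mcols(gr)))
    tolower(as.character(gr$is_tf)) == "true" else rep(FALSE, length(gr))
  gene_model(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_tf = is_tf
  )
}

#' Write intervals as BED6
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, a name column and a score column.
#' @param path output file.
#' @param name,score column names to use for the BED name/score fields.
#' @export
write_bed6 <- function(df, path, name = "gene_id", score = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$name <- as.character(df[[name]])
  S4Vectors::mcols(gr)$score <- if (is.null(score)) 0 else df[[score]]
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file into a 0-based interval table
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed; zero runs are omitted. Coordinates
#' are 0-based half-open, matching the in-memory representation.
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    score = r$values[keep]
  )
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(length(track$values), track$chrom)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph file.
#' @param chrom_len chromosome length (bases not covered by any record are
#'   zero).
#' @param strand strand label to attach.
#' @param condition condition label to attach.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_len, strand = "+", condition = "22C") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- numeric(chrom_len)
  if (length(gr)) {
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) values[s[i]:e[i]] <- gr$score[i]
  }
  chrom <- if (length(gr)) as.character(GenomeInfoDb::seqnames(gr)[1]) else "chrS"
  coverage_track(chrom, strand, values, condition)
}

#' Write a count matrix as TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns; sample ids
#' encode the condition as `<condition>_rep<k>`.
#'
#' @param m a [count_matrix()].
#' @param path output file.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene_id = m$gene_ids, m$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV written by [write_counts()].
#' @param condition optional per-sample condition labels; by default parsed
#'   from sample ids of the form `<condition>_rep<k>`.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, condition = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  samp <- colnames(counts)
  if (is.null(condition)) condition <- sub("_rep[0-9]+$", "", samp)
  count_matrix(counts, gene_ids = df$gene_id, sample_ids = samp,
               condition = condition)
}

#' Write decay series as a long TSV
#'
#' @param series list of [decay_series()] objects.
#' @param path output file with columns `gene_id`, `temperature`,
#'   `time_min`, `replicate`, `cq`.
#' @export
write_decay_tsv <- function(series, path) {
  rows <- lapply(series, function(s) {
    data.frame(gene_id = s$gene_id, temperature = s$temperature,
               time_min = rep(s$times, each = nrow(s$cq)),
               replicate = rep(seq_len(nrow(s$cq)), times = length(s$times)),
               cq = as.vector(s$cq), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read decay series from a long TSV
#'
#' @param path TSV as written by [write_decay_tsv()].
#' @param efficiency amplification factor attached to every series.
#' @return list of [decay_series()], one per gene x temperature.
#' @export
read_decay_tsv <- function(path, efficiency = 2) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(df$gene_id, df$temperature))) {
    sub <- df[paste(df$gene_id, df$temperature) == key, ]
    times <- sort(unique(sub$time_min))
    reps <- sort(unique(sub$replicate))
    cq <- matrix(NA_real_, length(reps), length(times))
    for (r in seq_along(reps)) for (ti in seq_along(times))
      cq[r, ti] <- sub$cq[sub$replicate == reps[r] & sub$time_min == times[ti]]
    out[[key]] <- decay_series(sub$gene_id[1], sub$temperature[1], times, cq,
                               efficiency)
  }
  out
}

#' Write a differential-expression table as TSV
#'
#' @param de table from [test_differential()].
#' @param path output file.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table from TSV
#' @param path TSV written by [write_de_tsv()].
#' @return data.frame.
#' @export
read_de_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read an electrolyte-leakage table
#'
#' Accepts either precomputed `el_percent` or raw
#' `cond_before`/`cond_after` conductivities (converted on read).
#'
#' @param path TSV with columns `genotype`, `temperature`, `replicate` and
#'   either `el_percent` or `cond_before` + `cond_after`.
#' @return data.frame with an `el_percent` column.
#' @export
read_leakage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!("el_percent" %in% names(df)))
    df$el_percent <- as.numeric(
      electrolyte_leakage(df$cond_before, df$cond_after))
  df
}
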