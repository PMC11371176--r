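#' Build +1-nucleosome (or TSS) anchors for metagene windows
#'
#' Anchors each gene at TSS + `offset` in the gene's own direction — the
#' canonical +1-nucleosome position when `offset` is ~150 bp, or the TSS
#' itself at `offset = 0`.
#'
#' @param genes a [gene_model()] table.
#' @param offset bases downstream of the TSS (strand-aware).
#' @param window half-width of the profile window in bases (total span
#'   `2 * window`, 500 bp by default).
#' @param bin bin width in bases; `2 * window` must be divisible by `bin`.
#' @return data.frame of class `anchor_set`: `gene_id`, `chrom`, `anchor`,
#'   `strand`, with `window` and `bin` attributes.
#' @export
make_plus1_anchors <- function(genes, offset = 150L, window = 250L,
                               bin = 10L) {
  if ((2L * window) %% bin != 0)
    stop("make_plus1_anchors: 2*window must be divisible by bin")
  a <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    anchor = ifelse(genes$strand == "+", genes$tss + as.integer(offset),
                    genes$tss - as.integer(offset)),
    strand = genes$strand, stringsAsFactors = FALSE
  )
  attr(a, "window") <- as.integer(window)
  attr(a, "bin") <- as.integer(bin)
  class(a) <- c("anchor_set", "data.frame")
  a
}

# Bin a per-base vector (already 5'->3') by the mean over fixed-width bins.
bin_means <- function(v, bin) {
  colMeans(matrix(v, nrow = bin))
}

#' Anchored metagene matrix
#'
#' For each gene, takes the bases at 5'->3' offsets `-window .. window - 1`
#' from the anchor on the gene's own strand (genome interval
#' `[anchor - window, anchor + window)` for plus-strand genes and its mirror
#' `[anchor - window + 1, anchor + window + 1)`, read backwards, for
#' minus-strand ones — so profiles are exactly reflection-invariant), and
#' averages into `2 * window / bin` bins reading 5' to 3'. Genes whose
#' window falls outside the chromosome are excluded (and listed in the
#' `excluded` attribute) rather than zero-padded.
#'
#' @param track_plus,track_minus [coverage_track()] objects.
#' @param anchors an [make_plus1_anchors()] anchor set.
#' @return object of class `profile_matrix`: list with `matrix`
#'   (genes x bins), `bin`, `window`, `condition`, `excluded`.
#' @export
anchored_matrix <- function(track_plus, track_minus, anchors) {
  window <- attr(anchors, "window")
  bin <- attr(anchors, "bin")
  len <- length(track_plus$values)
  stopifnot(length(track_minus$values) == len)
  nb <- (2L * window) %/% bin
  rows <- list(); kept <- character(); excluded <- character()
  for (i in seq_len(nrow(anchors))) {
    plus <- anchors$strand[i] == "+"
    s0 <- anchors$anchor[i] - window + (!plus)
    e0 <- anchors$anchor[i] + window + (!plus)
    if (s0 < 0 || e0 > len) { excluded <- c(excluded, anchors$gene_id[i]); next }
    v <- if (plus) track_plus$values[(s0 + 1L):e0]
         else rev(track_minus$values[(s0 + 1L):e0])
    rows[[length(rows) + 1L]] <- bin_means(v, bin)
    kept <- c(kept, anchors$gene_id[i])
  }
  mat <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(), 0, nb)
  rownames(mat) <- kept
  structure(list(matrix = mat, bin = bin, window = window,
                 condition = track_plus$condition, excluded = excluded,
                 mode = "anchored"),
            class = "profile_matrix")
}

#' Scaled gene-body metagene matrix
#'
#' Each gene body is read 5' to 3' (minus-strand bodies reversed) and
#' resampled to `nbins` bins by averaging over a partition into
#' near-equal-width base runs; when the length is not divisible the
#' remainder bases are spread one per bin from the 5' end. Genes shorter
#' than `nbins` bases are excluded. The partition conserves total signal:
#' sum(bin mean x bin width) equals the per-base sum.
#'
#' @param track_plus,track_minus [coverage_track()] objects.
#' @param genes a [gene_model()] table.
#' @param nbins number of bins per gene body.
#' @return object of class `profile_matrix` with a `widths` element
#'   (per-row bin widths in bases).
#' @export
scaled_body_matrix <- function(track_plus, track_minus, genes, nbins = 40L) {
  len <- length(track_plus$values)
  stopifnot(length(track_minus$values) == len)
  rows <- list(); widths <- list(); kept <- character(); excluded <- character()
  for (i in seq_len(nrow(genes))) {
    L <- genes$end[i] - genes$start[i]
    if (L < nbins || genes$start[i] < 0 || genes$end[i] > len) {
      excluded <- c(excluded, genes$gene_id[i]); next
    }
    v <- if (genes$strand[i] == "+")
      track_plus$values[(genes$start[i] + 1L):genes$end[i]]
    else rev(track_minus$values[(genes$start[i] + 1L):genes$end[i]])
    w <- rep(L %/% nbins, nbins) + (seq_len(nbins) <= L %% nbins)
    idx <- factor(rep(seq_len(nbins), times = w), levels = seq_len(nbins))
    rows[[length(rows) + 1L]] <- as.numeric(tapply(v, idx, mean))
    widths[[length(widths) + 1L]] <- w
    kept <- c(kept, genes$gene_id[i])
  }
  mat <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(), 0, nbins)
  rownames(mat) <- kept
  wmat <- if (length(widths)) do.call(rbind, widths) else matrix(integer(), 0, nbins)
  structure(list(matrix = mat, nbins = as.integer(nbins), widths = wmat,
                 condition = track_plus$condition, excluded = excluded,
                 mode = "scaled_body"),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> [%s] %d genes x %d bins (%d excluded), condition %s\n",
              x$mode, nrow(x$matrix), ncol(x$matrix), length(x$excluded),
              x$condition))
  invisible(x)
}

#' Per-bin mean profile with 95% confidence band
#'
#' @param m a [anchored_matrix()] / [scaled_body_matrix()] profile matrix.
#' @return data.frame with `bin`, `mean`, `ci_lo`, `ci_hi`, `n`; a
#'   `degenerate` attribute flags n < 2 (zero-width interval).
#' @export
profile_summary <- function(m) {
  mat <- m$matrix
  n <- nrow(mat)
  if (n == 0) stop("profile_summary: empty profile matrix")
  mu <- colMeans(mat)
  sdv <- if (n > 1) apply(mat, 2, stats::sd) else rep(0, ncol(mat))
  half <- 1.96 * sdv / sqrt(n)
  out <- data.frame(bin = seq_len(ncol(mat)), mean = mu,
                    ci_lo = mu - half, ci_hi = mu + half, n = n)
  attr(out, "degenerate") <- n < 2
  out
}

#' Plot a metagene profile with its confidence band
#'
#' @param x a `profile_matrix`.
#' @param ... passed to [graphics::plot()].
#' @method plot profile_matrix
#' @export
plot.profile_matrix <- function(x, ...) {
  s <- profile_summary(x)
  graphics::plot(s$bin, s$mean, type = "l", xlab = "bin",
                 ylab = "mean signal", ...)
  graphics::polygon(c(s$bin, rev(s$bin)), c(s$ci_lo, rev(s$ci_hi)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(s$bin, s$mean)
  invisible(s)
}
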