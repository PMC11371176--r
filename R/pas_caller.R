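#' Detect transcription units from strand-specific coverage
#'
#' Segments each strand into maximal runs of bases with signal at or above
#' `min_signal`, bridging internal gaps of up to `max_gap` bases, and keeps
#' units spanning at least `min_len` bases. The unit's own TSS is its
#' 5'-most base: the left span edge on the plus strand, the right one on the
#' minus strand.
#'
#' @param cov_plus,cov_minus [coverage_track()] objects over the same
#'   chromosome, equal lengths.
#' @param min_signal minimum per-base signal (reads/base) to seed a unit.
#' @param min_len minimum unit span (bases).
#' @param max_gap largest internal below-threshold gap (bases) bridged.
#' @return data.frame of units: `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), `tss` (5' end), `mean_signal` (mean coverage over the span).
#' @export
detect_units <- function(cov_plus, cov_minus, min_signal = 1,
                         min_len = 100L, max_gap = 50L) {
  stopifnot(inherits(cov_plus, "coverage_track"),
            inherits(cov_minus, "coverage_track"))
  if (length(cov_plus$values) != length(cov_minus$values))
    stop("detect_units: plus and minus tracks have different lengths")
  if (cov_plus$chrom != cov_minus$chrom)
    stop("detect_units: tracks cover different chromosomes")
  one_strand <- function(tr) {
    v <- tr$values
    r <- rle(v >= min_signal)
    if (!any(r$values)) return(NULL)
    # bridge internal short gaps between above-threshold runs
    n <- length(r$values)
    internal <- !r$values & seq_len(n) > 1 & seq_len(n) < n
    r$values[internal & r$lengths <= max_gap] <- TRUE
    r <- rle(inverse.rle(r))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    s0 <- starts[keep] - 1L   # 0-based half-open
    e0 <- ends[keep]
    data.frame(
      chrom = tr$chrom, strand = tr$strand, start = s0, end = e0,
      tss = if (tr$strand == "+") s0 else e0 - 1L,
      mean_signal = vapply(which(keep), function(i)
        mean(v[starts[i]:ends[i]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_strand(cov_plus), one_strand(cov_minus))
  if (is.null(out))
    out <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), tss = integer(),
                      mean_signal = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Antisense-acceptance windows of a gene, 0-based half-open. The 3'-half
# takes the ceiling of L/2, the downstream window the ceiling of 0.2*L.
pas_windows <- function(start, end, strand) {
  L <- end - start
  if (strand == "+") {
    list(half = c(start + ceiling(L / 2), end),
         down = c(end, end + ceiling(0.2 * L)))
  } else {
    list(half = c(start, end - ceiling(L / 2)),
         down = c(start - ceiling(0.2 * L), start))
  }
}

#' Classify one antisense TSS against a host gene
#'
#' Applies the PAS-gene rule: the host is a PAS gene if antisense
#' transcription initiates in the 3'-half of the gene or within 20% of the
#' gene length downstream of its 3' end. For a plus-strand gene `[s, e)` of
#' length L the windows are `[s + ceil(L/2), e)` and `[e, e + ceil(0.2 L))`;
#' minus-strand genes mirror exactly.
#'
#' @param gene single gene: one row of a [gene_model()] table (or a list
#'   with `start`, `end`, `strand`).
#' @param as_tss candidate antisense TSS (0-based position).
#' @param antisense_strand strand of the antisense unit; must be opposite
#'   to the gene's strand.
#' @return list with `is_pas` (logical) and `window_hit` (one of
#'   `"3prime_half"`, `"downstream_20pct"`, `"none"`).
#' @export
classify_pas <- function(gene, as_tss, antisense_strand) {
  if (antisense_strand == gene$strand)
    stop("classify_pas: unit on the same strand as the gene is not antisense")
  w <- pas_windows(gene$start, gene$end, gene$strand)
  hit <- if (as_tss >= w$half[1] && as_tss < w$half[2]) "3prime_half"
         else if (as_tss >= w$down[1] && as_tss < w$down[2]) "downstream_20pct"
         else "none"
  list(is_pas = hit != "none", window_hit = hit)
}

#' Call PAS genes from detected transcription units
#'
#' Pairs every gene with opposite-strand units whose 5' end (TSS) falls in
#' its antisense-acceptance windows. When several units match, the one with
#' the highest mean signal wins; ties go to the leftmost TSS.
#'
#' @param genes a [gene_model()] table.
#' @param units unit table from [detect_units()].
#' @return data.frame with one row per gene: `gene_id`, `is_pas`,
#'   `window_hit`, `as_tss`, `unit_start`, `unit_end`, `unit_mean_signal`.
#' @export
call_pas_genes <- function(genes, units) {
  n <- nrow(genes)
  out <- data.frame(
    gene_id = genes$gene_id, is_pas = rep(FALSE, n),
    window_hit = rep("none", n), as_tss = rep(NA_integer_, n),
    unit_start = rep(NA_integer_, n), unit_end = rep(NA_integer_, n),
    unit_mean_signal = rep(NA_real_, n), stringsAsFactors = FALSE
  )
  if (nrow(units) == 0) return(out)
  for (i in seq_len(n)) {
    anti <- if (genes$strand[i] == "+") "-" else "+"
    cand <- units[units$strand == anti & units$chrom == genes$chrom[i], ,
                  drop = FALSE]
    if (nrow(cand) == 0) next
    w <- pas_windows(genes$start[i], genes$end[i], genes$strand[i])
    in_half <- cand$tss >= w$half[1] & cand$tss < w$half[2]
    in_down <- cand$tss >= w$down[1] & cand$tss < w$down[2]
    hits <- cand[in_half | in_down, , drop = FALSE]
    if (nrow(hits) == 0) next
    best <- which(hits$mean_signal == max(hits$mean_signal))
    if (length(best) > 1) best <- best[which.min(hits$tss[best])]
    h <- hits[best, ]
    out$is_pas[i] <- TRUE
    out$window_hit[i] <- if (h$tss >= w$half[1] && h$tss < w$half[2])
      "3prime_half" else "downstream_20pct"
    out$as_tss[i] <- h$tss
    out$unit_start[i] <- h$start
    out$unit_end[i] <- h$end
    out$unit_mean_signal[i] <- h$mean_signal
  }
  out
}
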