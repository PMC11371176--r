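# Independent brute-force references used across tests.

# Position-by-position segmentation scanner: clusters above-threshold bases
# whose pairwise gaps are <= max_gap, keeps clusters spanning >= min_len.
brute_segment <- function(values, min_signal, min_len, max_gap) {
  above <- which(values >= min_signal)
  if (length(above) == 0)
    return(data.frame(start = integer(), end = integer()))
  breaks <- which(diff(above) - 1L > max_gap)
  starts <- above[c(1L, breaks + 1L)]
  ends <- above[c(breaks, length(above))]
  keep <- (ends - starts + 1L) >= min_len
  data.frame(start = starts[keep] - 1L, end = ends[keep])  # 0-based half-open
}

# Step-up BH by direct evaluation of min_{j >= i} p_(j) * m / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Toy single-strand coverage pair on a short chromosome.
toy_tracks <- function(plus_values, minus_values, chrom = "chrT",
                       condition = "22C") {
  list(plus = coverage_track(chrom, "+", plus_values, condition),
       minus = coverage_track(chrom, "-", minus_values, condition))
}

# Reflect a genome of length len: values reversed, strands swapped,
# interval [s, e) -> [len - e, len - s), position p -> len - 1 - p.
reflect_genes <- function(genes, len) {
  out <- genes
  out$start <- len - genes$end
  out$end <- len - genes$start
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out$pas <- ifelse(out$strand == "+", out$end - 1L, out$start)
  out
}
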