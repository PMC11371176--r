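#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of its count to the gene's geometric mean across samples.
#' Reference genes are those with a nonzero count in every sample.
#'
#' @param m a [count_matrix()].
#' @return numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(m) {
  counts <- m$counts
  if (ncol(counts) == 1) return(stats::setNames(1, m$sample_ids))
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("estimate_size_factors: no gene has nonzero counts in all samples")
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  stats::setNames(sf, m$sample_ids)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; the input order is
#' preserved.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Negative-binomial Wald differential expression test
#'
#' A self-contained NB test in the DESeq2 mould: counts are normalised by
#' median-of-ratios size factors, the log2 fold change is computed from
#' group means with a 0.5 pseudocount, gene dispersions are estimated by
#' method of moments (a single pooled value by default, or per-gene
#' estimates shrunk halfway to the pooled value), and the Wald statistic
#' log2FC / SE uses a delta-method standard error. Two-sided p-values come
#' from the normal reference and are BH-adjusted across genes. Genes are called UP when `fdr < alpha` and
#' `log2fc >= lfc_threshold`, DOWN when `fdr < alpha` and
#' `log2fc <= -lfc_threshold`, and nonDE otherwise.
#'
#' @param m a [count_matrix()].
#' @param cond_a,cond_b condition labels; the fold change is b over a.
#' @param dispersion_mode `"pooled"` (one dispersion for all genes) or
#'   `"per_gene"` (moment estimates shrunk toward the pooled value).
#' @param alpha FDR threshold for calls.
#' @param lfc_threshold minimum |log2 fold change| for calls.
#' @param pseudocount added to normalised group means before taking logs.
#' @return data.frame with columns `gene_id`, `base_mean`, `log2fc`, `p`,
#'   `fdr`, `call`.
#' @export
test_differential <- function(m, cond_a, cond_b,
                              dispersion_mode = c("pooled", "per_gene"),
                              alpha = 0.05, lfc_threshold = 0.5,
                              pseudocount = 0.5) {
  dispersion_mode <- match.arg(dispersion_mode)
  ia <- which(m$condition == cond_a)
  ib <- which(m$condition == cond_b)
  if (length(ia) == 0) stop("test_differential: no samples with condition ", cond_a)
  if (length(ib) == 0) stop("test_differential: no samples with condition ", cond_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("test_differential: need >= 2 replicates per condition")
  sf <- m$size_factors
  if (is.null(sf)) sf <- estimate_size_factors(m)
  norm <- sweep(m$counts, 2, sf, "/")
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  lfc <- log2((mb + pseudocount) / (ma + pseudocount))

  # method-of-moments dispersion on normalised counts:
  # Var(K/s) = mu/s + phi mu^2, so phi = (v - mu * mean(1/s)) / mu^2
  va <- apply(norm[, ia, drop = FALSE], 1, stats::var)
  vb <- apply(norm[, ib, drop = FALSE], 1, stats::var)
  inv_s <- c(mean(1 / sf[ia]), mean(1 / sf[ib]))
  phi_g <- rep(NA_real_, nrow(norm))
  ok <- ma > 0 & mb > 0
  phi_raw <- (((va - ma * inv_s[1]) / ma^2) + ((vb - mb * inv_s[2]) / mb^2)) / 2
  phi_g[ok] <- pmax(phi_raw[ok], 0)
  expressed <- ok & (ma + mb) / 2 >= 1
  phi_pool <- if (any(expressed)) max(mean(phi_g[expressed]), 0) else 0
  phi <- switch(dispersion_mode,
    pooled = rep(phi_pool, length(phi_g)),
    per_gene = ifelse(is.na(phi_g), phi_pool, (phi_g + phi_pool) / 2))

  # delta-method SE of log2fc: Var(mean_g) = (mu sum(1/s) + phi mu^2 n) / n^2
  va_hat <- (ma * sum(1 / sf[ia]) / na + phi * ma^2 * na) / na^2
  vb_hat <- (mb * sum(1 / sf[ib]) / nb + phi * mb^2 * nb) / nb^2
  se2 <- (va_hat / (ma + pseudocount)^2 + vb_hat / (mb + pseudocount)^2) / log(2)^2
  se <- sqrt(se2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[ma + mb == 0] <- 1
  fdr <- bh_adjust(p)
  call <- rep("nonDE", length(p))
  call[fdr < alpha & lfc >= lfc_threshold] <- "UP"
  call[fdr < alpha & lfc <= -lfc_threshold] <- "DOWN"
  data.frame(gene_id = m$gene_ids, base_mean = (ma + mb) / 2,
             log2fc = lfc, p = p, fdr = fdr, call = call,
             stringsAsFactors = FALSE)
}

#' Overlap between two differential-expression result sets
#'
#' Counts genes called in the same direction by both analyses (e.g. nascent
#' and steady-state) and correlates their fold changes over the
#' same-direction overlap.
#'
#' @param a,b DE tables from [test_differential()].
#' @param method correlation method; Pearson by default (fold changes are
#'   compared on the linear log2 scale).
#' @return list with `n_up_a`, `n_down_a`, `n_up_b`, `n_down_b`,
#'   `n_up_both`, `n_down_both` and `fc_correlation` (NULL when fewer than
#'   3 genes overlap).
#' @export
overlap_de <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  up_a <- a$gene_id[a$call == "UP"]; dn_a <- a$gene_id[a$call == "DOWN"]
  up_b <- b$gene_id[b$call == "UP"]; dn_b <- b$gene_id[b$call == "DOWN"]
  both <- c(intersect(up_a, up_b), intersect(dn_a, dn_b))
  r <- NULL
  if (length(both) >= 3) {
    fa <- a$log2fc[match(both, a$gene_id)]
    fb <- b$log2fc[match(both, b$gene_id)]
    r <- stats::cor(fa, fb, method = method)
  }
  list(n_up_a = length(up_a), n_down_a = length(dn_a),
       n_up_b = length(up_b), n_down_b = length(dn_b),
       n_up_both = length(intersect(up_a, up_b)),
       n_down_both = length(intersect(dn_a, dn_b)),
       fc_correlation = r)
}

#' Genes with a transient (CBF2-like) induction pattern
#'
#' Selects genes called UP in the 0 -> 3 h contrast and DOWN in the
#' 3 -> 12 h contrast, the hallmark of transiently peaking cold-response
#' regulators.
#'
#' @param de_0_3 DE table for the 0 -> 3 h contrast.
#' @param de_3_12 DE table for the 3 -> 12 h contrast.
#' @return character vector of gene ids, sorted.
#' @export
match_induction_pattern <- function(de_0_3, de_3_12) {
  sort(intersect(de_0_3$gene_id[de_0_3$call == "UP"],
                 de_3_12$gene_id[de_3_12$call == "DOWN"]))
}

#' Cold-responsive genes across assays and timepoints
#'
#' A gene is cold-responsive if it is differentially expressed (call not
#' nonDE) in any of the supplied DE tables — typically two assays (nascent,
#' steady-state) at two cold timepoints.
#'
#' @param de_tables list of DE tables sharing the same gene universe.
#' @return named logical vector over the union of gene ids.
#' @export
classify_cold_responsive <- function(de_tables) {
  stopifnot(length(de_tables) >= 1)
  ids <- sort(unique(unlist(lapply(de_tables, `[[`, "gene_id"))))
  resp <- stats::setNames(rep(FALSE, length(ids)), ids)
  for (d in de_tables) {
    hit <- d$gene_id[d$call != "nonDE"]
    resp[hit] <- TRUE
  }
  resp
}

#' Mann-Whitney U comparison of a metric between two gene classes
#'
#' Two-sided rank-sum test on a per-gene metric (gene length, steady-state
#' level, decay rate, ...) between two gene sets. When both groups have at
#' most `exact_max` observations the null distribution of U is enumerated
#' exactly over all label assignments (ties handled by mid-ranks);
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param values named numeric vector of the per-gene metric.
#' @param class_a,class_b gene ids (or indices) of the two classes.
#' @param exact_max largest group size for exact enumeration.
#' @return list with `U` (statistic for class_a), `p` (two-sided), `method`.
#' @export
compare_gene_classes <- function(values, class_a, class_b, exact_max = 8L) {
  x <- if (is.character(class_a)) values[class_a] else values[class_a]
  y <- if (is.character(class_b)) values[class_b] else values[class_b]
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("compare_gene_classes: NA values in classes")
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("compare_gene_classes: empty class")
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    centre <- n1 * n2 / 2
    p <- mean(abs(u_all - centre) >= abs(U - centre) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal approximation"))
    z <- (U - n1 * n2 / 2)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}
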