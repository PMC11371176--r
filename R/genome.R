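#' Construct a table of gene models
#'
#' Gene models are plain data frames with one row per gene and 0-based
#' half-open coordinates, the convention used by BED and bedGraph. The TSS is
#' the 5'-most transcribed base (`start` on the plus strand, `end - 1` on the
#' minus strand) and the PAS (poly(A) site) the 3'-most one.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome name (recycled).
#' @param start,end integer base positions, 0-based half-open; `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param is_tf logical; does the gene encode a transcription factor?
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `is_tf`, `tss`, `pas` and derived length attribute-free column
#'   order used throughout the package.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand, is_tf = FALSE) {
  n <- length(gene_id)
  stopifnot(!anyDuplicated(gene_id), length(start) == n, length(end) == n)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("gene_model: need start < end for every gene")
  if (!all(strand %in% c("+", "-"))) stop("gene_model: strand must be '+' or '-'")
  strand <- rep_len(strand, n)
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom   = rep_len(as.character(chrom), n),
    start   = start,
    end     = end,
    strand  = strand,
    is_tf   = rep_len(as.logical(is_tf), n),
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$pas <- ifelse(df$strand == "+", df$end - 1L, df$start)
  df
}

#' Transcription-decay kinetic parameters for one gene
#'
#' Synthesis rates `alpha` (arbitrary units/min) and first-order decay rates
#' `k` (1/min) at 22 degC and at 4 degC. The induction fold is
#' `alpha_4 / alpha_22`.
#'
#' @param alpha_22,alpha_4 synthesis rates at 22 and 4 degC; must be > 0.
#' @param k_22,k_4 decay rates at 22 and 4 degC; must be > 0.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(alpha_22, alpha_4, k_22, k_4) {
  vals <- c(alpha_22 = alpha_22, alpha_4 = alpha_4, k_22 = k_22, k_4 = k_4)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("kinetic_params: all rates must be finite and > 0")
  structure(as.list(vals), class = "kinetic_params")
}

#' Steady-state mRNA abundance after a step change at cold onset
#'
#' Solves dM/dt = alpha - k * M in closed form for a step change of both
#' rates at t = 0, starting from the 22 degC steady state
#' M0 = alpha_22 / k_22:
#' \deqn{M(t) = \frac{\alpha_4}{k_4}(1 - e^{-k_4 t}) + M_0 e^{-k_4 t}}
#'
#' @param kin a [kinetic_params()] object.
#' @param t minutes since cold onset; vectorised, must be >= 0.
#' @return Numeric vector of abundances, same length as `t`.
#' @export
solve_mrna_level <- function(kin, t) {
  if (!inherits(kin, "kinetic_params")) kin <- do.call(kinetic_params, as.list(kin))
  if (any(t < 0)) stop("solve_mrna_level: t must be >= 0")
  m0 <- kin$alpha_22 / kin$k_22
  decay <- exp(-kin$k_4 * t)
  (kin$alpha_4 / kin$k_4) * (1 - decay) + m0 * decay
}

#' Nascent and steady-state fold change implied by the kinetic model
#'
#' The nascent (transcriptional) fold change is the synthesis-rate ratio
#' f = alpha_4/alpha_22; the steady-state fold change is M(t)/M0 from
#' [solve_mrna_level()]. When decay accelerates in the cold (k_4 > k_22) the
#' steady-state response is muted below the nascent one: asymptotically
#' steady_fc = f * k_22 / k_4 <= f.
#'
#' @inheritParams solve_mrna_level
#' @return A list with elements `nascent_fc` and `steady_fc` (vector over `t`).
#' @export
predict_steady_state_fc <- function(kin, t) {
  if (!inherits(kin, "kinetic_params")) kin <- do.call(kinetic_params, as.list(kin))
  m0 <- kin$alpha_22 / kin$k_22
  list(
    nascent_fc = kin$alpha_4 / kin$alpha_22,
    steady_fc  = solve_mrna_level(kin, t) / m0
  )
}

# Mean abundance per gene at time t (minutes of cold), honouring the
# transient class whose synthesis reverts to alpha_22 at t_off while decay
# stays at its cold value. Vectorised over the rows of `truth`.
mean_abundance <- function(truth, t) {
  m0 <- truth$alpha_22 / truth$k_22
  if (t == 0) return(m0)
  dec <- exp(-truth$k_4 * t)
  m <- (truth$alpha_4 / truth$k_4) * (1 - dec) + m0 * dec
  tr <- which(truth$profile == "transient" & t > truth$t_off)
  if (length(tr)) {
    toff <- truth$t_off[tr]
    dec1 <- exp(-truth$k_4[tr] * toff)
    m_off <- (truth$alpha_4[tr] / truth$k_4[tr]) * (1 - dec1) + m0[tr] * dec1
    dec2 <- exp(-truth$k_4[tr] * (t - toff))
    m[tr] <- (truth$alpha_22[tr] / truth$k_4[tr]) * (1 - dec2) + m_off * dec2
  }
  m
}

#' Simulate a toy genome with antisense (PAS) transcription ground truth
#'
#' Lays out non-overlapping genes along one chromosome, flags a fixed
#' fraction as hosting antisense transcription (PAS genes) and a fixed
#' fraction as transcription factors, and assigns each gene a kinetic class
#' driving its cold response: sustained induction, sustained repression,
#' transient ("CBF2-like") induction that peaks by 3 h and falls again by
#' 12 h, or no response.
#'
#' For a PAS gene the antisense TSS is drawn uniformly from the union of the
#' 3'-half of the gene and the window covering 20% of the gene length
#' downstream of its 3' end (the same geometry [classify_pas()] tests), and
#' the antisense unit extends on the opposite strand from that TSS to 1 kb
#' upstream of the host TSS.
#'
#' @param n_genes number of genes.
#' @param frac_pas fraction of genes hosting antisense transcription; exactly
#'   `round(n_genes * frac_pas)` genes are flagged.
#' @param frac_tf fraction of genes encoding transcription factors.
#' @param chrom_len chromosome length in bases, or `NULL` to size the
#'   chromosome to fit the layout. If given and too small to place all genes
#'   an error is raised.
#' @param gene_len length-2 range (bases) gene lengths are drawn from.
#' @param intergenic length-2 range of intergenic gap sizes. The default
#'   keeps antisense units (which reach 1 kb past the host TSS) well clear of
#'   neighbouring genes on the same strand.
#' @param n_transient number of transient-induction genes (drawn from the TF
#'   set, mirroring the CBF2-like class).
#' @param frac_up,frac_down fractions of genes with sustained up/down
#'   regulation in cold.
#' @param as_upstream how far (bases) the antisense unit runs past the host
#'   TSS.
#' @param t_half_median,t_half_sdlog lognormal parameters for 22 degC mRNA
#'   half-lives in minutes.
#' @param seed integer seed; the same seed reproduces the genome bit for bit.
#' @param chrom chromosome name.
#' @return A list with elements `genes` (a [gene_model()] data frame),
#'   `truth` (per-gene truth table: PAS status, antisense span, kinetic
#'   parameters, profile class and expected DE direction at 3 h and 12 h)
#'   and `chrom_len`.
#' @export
simulate_genome <- function(n_genes, frac_pas = 0.25, frac_tf = 0.15,
                            chrom_len = NULL,
                            gene_len = c(1000L, 3000L),
                            intergenic = c(1800L, 3000L),
                            n_transient = min(25L, floor(n_genes * frac_tf)),
                            frac_up = 0.15, frac_down = 0.15,
                            as_upstream = 1000L,
                            t_half_median = 60, t_half_sdlog = 0.4,
                            seed = NULL, chrom = "chrS") {
  stopifnot(frac_pas >= 0, frac_pas <= 1, frac_tf >= 0, frac_tf <= 1)
  if (!is.null(seed)) set.seed(seed)
  empty_truth <- function() data.frame(
    gene_id = character(), is_pas = logical(), as_strand = character(),
    as_tss = integer(), as_start = integer(), as_end = integer(),
    profile = character(), alpha_22 = numeric(), alpha_4 = numeric(),
    k_22 = numeric(), k_4 = numeric(), t_off = numeric(),
    de_3h = character(), de_12h = character(), stringsAsFactors = FALSE)
  if (n_genes == 0) {
    genes <- gene_model(character(), chrom, integer(), integer(), character())[0, ]
    return(list(genes = genes, truth = empty_truth(),
                chrom_len = if (is.null(chrom_len)) 0L else chrom_len))
  }

  lens <- sample(gene_len[1]:gene_len[2], n_genes, replace = TRUE)
  gaps <- sample(intergenic[1]:intergenic[2], n_genes, replace = TRUE)
  margin <- as_upstream + 1000L
  starts <- margin + cumsum(c(0L, (lens + gaps)[-n_genes]))
  ends <- starts + lens
  needed <- ends[n_genes] + margin
  if (is.null(chrom_len)) {
    chrom_len <- needed
  } else if (chrom_len < needed) {
    stop(sprintf("simulate_genome: chrom_len=%d too small to place %d genes (need %d)",
                 chrom_len, n_genes, needed))
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  is_tf <- rep(FALSE, n_genes)
  n_tf <- round(n_genes * frac_tf)
  if (n_tf > 0) is_tf[sample.int(n_genes, n_tf)] <- TRUE
  ids <- sprintf("G%04d", seq_len(n_genes))
  genes <- gene_model(ids, chrom, starts, ends, strand, is_tf)

  # PAS assignment and antisense geometry
  n_pas <- round(n_genes * frac_pas)
  is_pas <- rep(FALSE, n_genes)
  if (n_pas > 0) is_pas[sample.int(n_genes, n_pas)] <- TRUE
  as_tss <- rep(NA_integer_, n_genes)
  as_start <- rep(NA_integer_, n_genes)
  as_end <- rep(NA_integer_, n_genes)
  as_strand <- ifelse(strand == "+", "-", "+")
  as_strand[!is_pas] <- NA_character_
  for (i in which(is_pas)) {
    L <- lens[i]
    if (strand[i] == "+") {
      lo <- starts[i] + ceiling(L / 2)          # 3'-half left edge
      hi <- ends[i] + ceiling(0.2 * L) - 1L     # last base of downstream window
      tssi <- sample(lo:hi, 1L)
      as_tss[i] <- tssi
      as_start[i] <- max(0L, genes$tss[i] - as_upstream)
      as_end[i] <- tssi + 1L                    # minus-strand unit: 5' end is right edge
    } else {
      lo <- starts[i] - ceiling(0.2 * L)
      hi <- ends[i] - ceiling(L / 2) - 1L
      tssi <- sample(lo:hi, 1L)
      as_tss[i] <- tssi
      as_start[i] <- tssi
      as_end[i] <- min(chrom_len, genes$tss[i] + as_upstream + 1L)
    }
  }

  # Kinetic classes: transient genes come from the TF pool
  profile <- rep("none", n_genes)
  n_transient <- min(n_transient, sum(is_tf))
  if (n_transient > 0) profile[sample(which(is_tf), n_transient)] <- "transient"
  pool <- which(profile == "none")
  n_up <- min(round(n_genes * frac_up), length(pool))
  if (n_up > 0) {
    up <- sample(pool, n_up); profile[up] <- "up"; pool <- setdiff(pool, up)
  }
  n_down <- min(round(n_genes * frac_down), length(pool))
  if (n_down > 0) profile[sample(pool, n_down)] <- "down"

  alpha_22 <- exp(rnorm(n_genes, 0, 0.5))
  k_22 <- log(2) / (t_half_median * exp(rnorm(n_genes, 0, t_half_sdlog)))
  alpha_4 <- alpha_22
  k_4 <- k_22
  t_off <- rep(NA_real_, n_genes)
  up_i <- profile == "up"
  alpha_4[up_i] <- alpha_22[up_i] * runif(sum(up_i), 4, 8)
  k_4[up_i] <- k_22[up_i] * runif(sum(up_i), 1, 1.6)
  dn_i <- profile == "down"
  alpha_4[dn_i] <- alpha_22[dn_i] / runif(sum(dn_i), 4, 8)
  tr_i <- profile == "transient"
  alpha_4[tr_i] <- alpha_22[tr_i] * runif(sum(tr_i), 6, 10)
  k_4[tr_i] <- k_22[tr_i] * runif(sum(tr_i), 1.2, 2)
  t_off[tr_i] <- 180

  truth <- data.frame(
    gene_id = ids, is_pas = is_pas, as_strand = as_strand, as_tss = as_tss,
    as_start = as_start, as_end = as_end, profile = profile,
    alpha_22 = alpha_22, alpha_4 = alpha_4, k_22 = k_22, k_4 = k_4,
    t_off = t_off, stringsAsFactors = FALSE
  )
  m0 <- mean_abundance(truth, 0)
  lfc3 <- log2(mean_abundance(truth, 180) / m0)
  lfc12 <- log2(mean_abundance(truth, 720) / m0)
  dir_of <- function(lfc) ifelse(lfc >= 0.5, "UP", ifelse(lfc <= -0.5, "DOWN", "nonDE"))
  truth$de_3h <- dir_of(lfc3)
  truth$de_12h <- dir_of(lfc12)
  list(genes = genes, truth = truth, chrom_len = as.integer(chrom_len))
}
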