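#' Per-base strand-specific coverage track
#'
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param values non-negative numeric vector, one value per base.
#' @param condition condition label, e.g. `"22C"`, `"4C_3h"`, `"4C_12h"`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, strand, values, condition = "22C") {
  stopifnot(strand %in% c("+", "-"))
  if (any(values < 0)) stop("coverage_track: values must be >= 0")
  structure(list(chrom = as.character(chrom), strand = strand,
                 values = as.numeric(values), condition = condition),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s(%s) %s: %d bases, mean %.3f reads/base\n",
              x$chrom, x$strand, x$condition, length(x$values),
              mean(x$values)))
  invisible(x)
}

#' @export
length.coverage_track <- function(x) length(x$values)

#' Gene-by-sample count matrix with condition labels
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids row/column identifiers.
#' @param condition per-sample condition labels.
#' @param size_factors optional per-sample normalisation factors (filled by
#'   [estimate_size_factors()]).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts), condition,
                         size_factors = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers")
  stopifnot(length(gene_ids) == nrow(counts),
            length(sample_ids) == ncol(counts),
            length(condition) == ncol(counts))
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 condition = as.character(condition),
                 size_factors = size_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Current synthesis rate per gene for a condition label; transient genes
# have reverted to their warm rate by 12 h.
synthesis_rate <- function(truth, condition) {
  switch(condition,
    "22C" = truth$alpha_22,
    "4C_3h" = truth$alpha_4,
    "4C_12h" = ifelse(truth$profile == "transient", truth$alpha_22, truth$alpha_4),
    stop("unknown condition: ", condition)
  )
}

#' Expected (noise-free) nascent coverage
#'
#' The expectation path of [simulate_nascent_coverage()]: per-base signal
#' over each gene body proportional to its current synthesis rate, scaled so
#' the mean over gene-body bases equals `depth`; a `stall_width`-bp window
#' centred at the +1-nucleosome anchor (TSS + `plus1_offset`, strand-aware)
#' is multiplied by `stall_amp`; PAS genes add antisense signal at
#' `as_ratio` times their warm body level over the antisense span on the
#' opposite strand.
#'
#' @inheritParams simulate_nascent_coverage
#' @return list with elements `plus` and `minus`, numeric expectation vectors.
#' @export
nascent_expectation <- function(genes, truth, chrom_len, condition = "22C",
                                depth = 2, stall_amp = 3, plus1_offset = 150L,
                                stall_width = 150L, as_ratio = 0.5) {
  stopifnot(depth > 0)
  plus <- numeric(chrom_len)
  minus <- numeric(chrom_len)
  if (nrow(genes) == 0) return(list(plus = plus, minus = minus))
  rate <- synthesis_rate(truth, condition)
  scale <- depth / mean(rate)
  half <- stall_width %/% 2L
  for (i in seq_len(nrow(genes))) {
    body <- (genes$start[i] + 1L):genes$end[i]  # 1-based indices
    lev <- rate[i] * scale
    prof <- rep(lev, length(body))
    anchor <- if (genes$strand[i] == "+") genes$tss[i] + plus1_offset
              else genes$tss[i] - plus1_offset
    w0 <- max(genes$start[i], anchor - half)
    w1 <- min(genes$end[i], anchor - half + stall_width)
    if (w1 > w0) {
      rel <- (w0 + 1L):w1 - genes$start[i]
      prof[rel] <- prof[rel] * stall_amp
    }
    if (genes$strand[i] == "+") plus[body] <- plus[body] + prof
    else minus[body] <- minus[body] + prof
    if (isTRUE(truth$is_pas[i])) {
      span <- (truth$as_start[i] + 1L):truth$as_end[i]
      as_lev <- as_ratio * truth$alpha_22[i] * scale
      if (truth$as_strand[i] == "+") plus[span] <- plus[span] + as_lev
      else minus[span] <- minus[span] + as_lev
    }
  }
  list(plus = plus, minus = minus)
}

#' Simulate strand-specific nascent-transcription coverage
#'
#' Draws per-base Poisson counts around the expectation computed by
#' [nascent_expectation()], emulating a plaNET-seq-style readout: gene-body
#' signal tracking the current synthesis rate, an RNAPII stall peak at the
#' +1 nucleosome, and antisense-unit signal on the opposite strand of PAS
#' genes.
#'
#' @param genes gene table from [simulate_genome()].
#' @param truth matching truth table.
#' @param chrom_len chromosome length in bases.
#' @param condition one of `"22C"`, `"4C_3h"`, `"4C_12h"`.
#' @param depth mean reads/base over gene bodies.
#' @param stall_amp signal multiplier over the +1-nucleosome window.
#' @param plus1_offset distance (bases) from TSS to the +1-nucleosome anchor.
#' @param stall_width width (bases) of the stall window, centred at the anchor.
#' @param as_ratio antisense:sense amplitude ratio for PAS genes (antisense
#'   amplitude follows the host's warm synthesis rate at all conditions).
#' @param seed integer seed for reproducibility.
#' @return list of two [coverage_track()] objects, `plus` and `minus`.
#' @export
simulate_nascent_coverage <- function(genes, truth, chrom_len,
                                      condition = "22C", depth = 2,
                                      stall_amp = 3, plus1_offset = 150L,
                                      stall_width = 150L, as_ratio = 0.5,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- nascent_expectation(genes, truth, chrom_len, condition, depth,
                            stall_amp, plus1_offset, stall_width, as_ratio)
  chrom <- if (nrow(genes)) genes$chrom[1] else "chrS"
  list(
    plus = coverage_track(chrom, "+", rpois(chrom_len, mu$plus), condition),
    minus = coverage_track(chrom, "-", rpois(chrom_len, mu$minus), condition)
  )
}

#' Sampling schedule for the cold time course
#'
#' @param timepoints minutes since cold onset; strictly increasing. The
#'   defaults are 0 (22 degC), 180 and 720 min at 4 degC.
#' @param conditions labels matching `timepoints`.
#' @param n_reps biological replicates per condition (>= 2).
#' @return list of class `condition_schedule`.
#' @export
condition_schedule <- function(timepoints = c(0, 180, 720),
                               conditions = c("22C", "4C_3h", "4C_12h"),
                               n_reps = 3L) {
  stopifnot(length(timepoints) == length(conditions),
            all(diff(timepoints) > 0), n_reps >= 2)
  structure(list(timepoints = timepoints, conditions = conditions,
                 n_reps = as.integer(n_reps)),
            class = "condition_schedule")
}

#' Expected counts under the kinetic model
#'
#' The expectation path of [simulate_counts()]: for sample j at time t,
#' the expected count of gene g is `lib_size[j] * q_g(t) / sum_g q_g(t)`,
#' where q is the steady-state abundance M from the closed-form
#' transcription-decay model for an RNA-seq-style (`"steady"`) assay, or
#' the current synthesis rate alpha for a nascent (plaNET-seq-style,
#' `"nascent"`) assay.
#'
#' @inheritParams simulate_counts
#' @return numeric matrix of expected counts (genes x samples).
#' @export
expected_counts <- function(truth, schedule = condition_schedule(),
                            lib_sizes = NULL,
                            assay = c("steady", "nascent")) {
  assay <- match.arg(assay)
  n_samp <- length(schedule$timepoints) * schedule$n_reps
  if (is.null(lib_sizes)) lib_sizes <- rep(1e6, n_samp)
  stopifnot(length(lib_sizes) == n_samp)
  cond_of_t <- function(t) if (t == 0) "22C" else if (t <= 360) "4C_3h" else "4C_12h"
  mu <- matrix(0, nrow(truth), n_samp)
  j <- 0L
  for (ti in seq_along(schedule$timepoints)) {
    t <- schedule$timepoints[ti]
    m <- if (assay == "steady") mean_abundance(truth, t)
         else synthesis_rate(truth, cond_of_t(t))
    frac <- m / sum(m)
    for (r in seq_len(schedule$n_reps)) {
      j <- j + 1L
      mu[, j] <- lib_sizes[j] * frac
    }
  }
  mu
}

#' Simulate an RNA-seq-style count matrix
#'
#' Draws negative-binomial counts around the kinetic expectation
#' ([expected_counts()]) for each condition/replicate of the schedule.
#'
#' @param truth truth table from [simulate_genome()].
#' @param schedule a [condition_schedule()].
#' @param lib_sizes per-sample library sizes (total expected counts);
#'   default 1e6 each.
#' @param dispersion NB overdispersion phi in Var = mu + phi * mu^2; the
#'   Poisson limit is phi -> 0.
#' @param assay `"steady"` (RNA-seq-like, means follow M(t)) or
#'   `"nascent"` (plaNET-seq-like, means follow the synthesis rate).
#' @param seed integer seed.
#' @return a [count_matrix()] with sample ids `<condition>_rep<k>`.
#' @export
simulate_counts <- function(truth, schedule = condition_schedule(),
                            lib_sizes = NULL, dispersion = 0.05,
                            assay = c("steady", "nascent"), seed = NULL) {
  stopifnot(dispersion >= 0)
  assay <- match.arg(assay)
  if (!is.null(seed)) set.seed(seed)
  mu <- expected_counts(truth, schedule, lib_sizes, assay)
  cond <- rep(schedule$conditions, each = schedule$n_reps)
  samp <- paste0(cond, "_rep", rep(seq_len(schedule$n_reps),
                                   times = length(schedule$conditions)))
  n <- length(mu)
  counts <- if (dispersion == 0) rpois(n, mu)
            else rnbinom(n, size = 1 / dispersion, mu = mu)
  counts <- matrix(counts, nrow(mu), ncol(mu))
  count_matrix(counts, gene_ids = truth$gene_id, sample_ids = samp,
               condition = cond)
}

#' qPCR decay time course after transcription inhibition
#'
#' @param gene_id gene identifier.
#' @param temperature 22 or 4 (degC).
#' @param times minutes after inhibitor addition, strictly increasing from 0.
#' @param cq matrix of quantification cycles, replicates x timepoints.
#' @param efficiency amplification factor per cycle E in (1, 2].
#' @return list of class `decay_series`.
#' @export
decay_series <- function(gene_id, temperature, times, cq, efficiency = 2) {
  cq <- as.matrix(cq)
  stopifnot(times[1] == 0, all(diff(times) > 0), ncol(cq) == length(times),
            all(is.finite(cq)), efficiency > 1, efficiency <= 2)
  colnames(cq) <- paste0("t", times)
  structure(list(gene_id = gene_id, temperature = temperature,
                 times = as.numeric(times), cq = cq,
                 efficiency = efficiency),
            class = "decay_series")
}

#' @export
print.decay_series <- function(x, ...) {
  cat(sprintf("<decay_series> %s at %g degC: %d reps x %d timepoints (E=%g)\n",
              x$gene_id, x$temperature, nrow(x$cq), length(x$times),
              x$efficiency))
  invisible(x)
}

#' Simulate a qPCR decay series after transcription inhibition
#'
#' After inhibition M(t) = M0 exp(-k t) with k the decay rate at the assay
#' temperature, so the quantification cycle rises as
#' Cq(t) = cq0 + log2(M0/M(t)) = cq0 + k t / ln 2, plus Gaussian
#' measurement noise. Samples are taken at 0, 15, 30, 60 and 120 min.
#'
#' @param kin a [kinetic_params()] object.
#' @param temperature 22 or 4; selects `k_22` or `k_4`.
#' @param cq0 baseline quantification cycle.
#' @param noise_sd Gaussian noise on Cq, in cycles.
#' @param n_reps biological replicates.
#' @param times sampling times (minutes).
#' @param gene_id label carried through to the series.
#' @param seed integer seed.
#' @return a [decay_series()].
#' @export
simulate_decay_series <- function(kin, temperature = 22, cq0 = 20,
                                  noise_sd = 0.1, n_reps = 3L,
                                  times = c(0, 15, 30, 60, 120),
                                  gene_id = "gene", seed = NULL) {
  if (!inherits(kin, "kinetic_params")) kin <- do.call(kinetic_params, as.list(kin))
  stopifnot(temperature %in% c(22, 4))
  if (!is.null(seed)) set.seed(seed)
  k <- if (temperature == 22) kin$k_22 else kin$k_4
  ideal <- cq0 + k * times / log(2)
  cq <- matrix(rep(ideal, each = n_reps), n_reps, length(times)) +
    matrix(rnorm(n_reps * length(times), 0, noise_sd), n_reps)
  decay_series(gene_id, temperature, times, cq)
}

#' Four-parameter logistic electrolyte-leakage model
#'
#' @param temp temperature (degC), vectorised.
#' @param bottom,top lower/upper leakage asymptotes (%).
#' @param lt50 inflection temperature (degC).
#' @param hill slope factor (1/degC), > 0 so leakage rises as temperature
#'   falls.
#' @return expected % electrolyte leakage.
#' @export
logistic_el <- function(temp, bottom, top, lt50, hill) {
  bottom + (top - bottom) / (1 + exp(hill * (temp - lt50)))
}

#' Simulate an electrolyte-leakage freezing assay
#'
#' Expected leakage follows the four-parameter logistic [logistic_el()];
#' replicate measurements get Gaussian noise and are clamped to [0, 100].
#'
#' @param lt50_true true inflection temperature (degC).
#' @param hill slope factor (1/degC).
#' @param bottom,top asymptotes (%).
#' @param temps assay temperatures (degC); default -1 to -10 in 1 degC steps.
#' @param n_reps replicates per temperature.
#' @param noise_sd Gaussian noise sd (% leakage).
#' @param genotype label attached to the table.
#' @param seed integer seed.
#' @return data.frame with columns `genotype`, `temperature`, `replicate`,
#'   `el_percent`.
#' @export
simulate_leakage <- function(lt50_true = -5, hill = 1, bottom = 5, top = 95,
                             temps = seq(-1, -10), n_reps = 3L,
                             noise_sd = 5, genotype = "WT", seed = NULL) {
  stopifnot(hill > 0, bottom < top)
  if (!is.null(seed)) set.seed(seed)
  mu <- logistic_el(rep(temps, each = n_reps), bottom, top, lt50_true, hill)
  el <- mu + rnorm(length(mu), 0, noise_sd)
  el <- pmin(100, pmax(0, el))
  data.frame(
    genotype = genotype,
    temperature = rep(temps, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(temps)),
    el_percent = el,
    stringsAsFactors = FALSE
  )
}
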