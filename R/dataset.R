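#' Default simulation configuration
#'
#' The study conditions the synthetic pipeline is exercised under: a
#' 200-gene chromosome with 25% PAS genes and 15% transcription factors,
#' three conditions (22 degC, 3 h and 12 h at 4 degC) with three NB
#' replicates each, qPCR decay series for a handful of transient genes at
#' both temperatures, and electrolyte-leakage curves for a freezing-
#' tolerant and a freezing-sensitive genotype (LT50 -6.1 vs -3.7 degC, the
#' magnitudes reported for acclimated wild type and a sensitive mutant).
#'
#' @param seed integer seed used for every stochastic step.
#' @return nested list of parameters; see the methods vignette for the
#'   rationale behind each default.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(n_genes = 200L, frac_pas = 0.25, frac_tf = 0.15,
                  n_transient = 25L, frac_up = 0.15, frac_down = 0.15),
    coverage = list(depth = 2, stall_amp = 3, plus1_offset = 150L,
                    stall_width = 150L, as_ratio = 0.5),
    counts = list(n_reps = 3L, lib_size = 1e6, dispersion = 0.05),
    decay = list(n_genes = 3L, cq0 = 20, noise_sd = 0.1, n_reps = 3L),
    leakage = list(
      genotypes = list(
        list(name = "WT", lt50 = -6.1, hill = 1, bottom = 5, top = 95),
        list(name = "mutant", lt50 = -3.7, hill = 1, bottom = 5, top = 95)
      ),
      n_reps = 3L, noise_sd = 5
    )
  )
}

# recursively overlay user config onto defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
                      !is.null(names(user[[nm]])))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Load a simulation configuration from YAML
#'
#' Missing entries fall back to [default_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Generate the full synthetic dataset and write every assay file
#'
#' Runs the generator end to end under one configuration: the toy genome
#' (GFF3 + BED + truth TSV), strand-specific nascent coverage per
#' condition (bedGraph x 2), the count matrix (TSV), decay series for the
#' first few transient genes at 22 and 4 degC (TSV), and leakage curves
#' per genotype (TSV), plus the resolved configuration as YAML.
#'
#' @param config configuration list ([default_config()]) or path to a YAML
#'   file.
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the in-memory objects (`genes`, `truth`,
#'   `chrom_len`, `coverage`, `counts`, `decay`, `leakage`) and `files`.
#' @export
simulate_dataset <- function(config = default_config(), outdir) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  files <- character()

  g <- cfg$genome
  sim <- simulate_genome(n_genes = g$n_genes, frac_pas = g$frac_pas,
                         frac_tf = g$frac_tf, n_transient = g$n_transient,
                         frac_up = g$frac_up, frac_down = g$frac_down,
                         seed = cfg$seed)
  write_genes_gff3(sim$genes, fp("genes.gff3"), sim$chrom_len)
  write_bed6(sim$genes, fp("genes.bed"), name = "gene_id")
  utils::write.table(sim$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, "genes.gff3", "genes.bed", "truth.tsv")

  cv <- cfg$coverage
  conditions <- c("22C", "4C_3h", "4C_12h")
  coverage <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    tracks <- simulate_nascent_coverage(
      sim$genes, sim$truth, sim$chrom_len, condition = cond,
      depth = cv$depth, stall_amp = cv$stall_amp,
      plus1_offset = cv$plus1_offset, stall_width = cv$stall_width,
      as_ratio = cv$as_ratio, seed = cfg$seed + ci)
    coverage[[cond]] <- tracks
    write_bedgraph(tracks$plus, fp(sprintf("coverage_%s_plus.bedGraph", cond)))
    write_bedgraph(tracks$minus, fp(sprintf("coverage_%s_minus.bedGraph", cond)))
    files <- c(files, sprintf("coverage_%s_%s.bedGraph", cond, c("plus", "minus")))
  }

  ct <- cfg$counts
  sched <- condition_schedule(n_reps = ct$n_reps)
  libs <- rep(ct$lib_size, ct$n_reps * length(sched$timepoints))
  counts <- simulate_counts(sim$truth, sched, lib_sizes = libs,
                            dispersion = ct$dispersion, assay = "steady",
                            seed = cfg$seed + 10L)
  write_counts(counts, fp("counts.tsv"))
  counts_nascent <- simulate_counts(sim$truth, sched, lib_sizes = libs,
                                    dispersion = ct$dispersion,
                                    assay = "nascent", seed = cfg$seed + 11L)
  write_counts(counts_nascent, fp("counts_nascent.tsv"))
  files <- c(files, "counts.tsv", "counts_nascent.tsv")

  dk <- cfg$decay
  tr_genes <- utils::head(sim$truth[sim$truth$profile == "transient", ],
                          dk$n_genes)
  series <- list()
  for (i in seq_len(nrow(tr_genes))) {
    kin <- kinetic_params(tr_genes$alpha_22[i], tr_genes$alpha_4[i],
                          tr_genes$k_22[i], tr_genes$k_4[i])
    for (temp in c(22, 4)) {
      series[[length(series) + 1L]] <- simulate_decay_series(
        kin, temperature = temp, cq0 = dk$cq0, noise_sd = dk$noise_sd,
        n_reps = dk$n_reps, gene_id = tr_genes$gene_id[i],
        seed = cfg$seed + 100L + 2L * i + (temp == 4))
    }
  }
  if (length(series)) write_decay_tsv(series, fp("decay.tsv"))
  files <- c(files, "decay.tsv")

  lk <- cfg$leakage
  leak <- do.call(rbind, lapply(seq_along(lk$genotypes), function(i) {
    gt <- lk$genotypes[[i]]
    simulate_leakage(lt50_true = gt$lt50, hill = gt$hill, bottom = gt$bottom,
                     top = gt$top, n_reps = lk$n_reps, noise_sd = lk$noise_sd,
                     genotype = gt$name, seed = cfg$seed + 200L + i)
  }))
  utils::write.table(leak, fp("leakage.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, "leakage.tsv")

  yaml::write_yaml(cfg, fp("config.yaml"))
  files <- c(files, "config.yaml")

  invisible(list(genes = sim$genes, truth = sim$truth,
                 chrom_len = sim$chrom_len, coverage = coverage,
                 counts = counts, counts_nascent = counts_nascent,
                 decay = series, leakage = leak, files = fp(files)))
}

#' Read a truth table written by [simulate_dataset()]
#' @param path truth TSV.
#' @return data.frame.
#' @export
read_truth_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
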