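#' Configuration for the synthetic phase-change study generator
#'
#' Defines the statistical structure of the generated studies: a fraction of
#' planted phase-biased "core" genes whose between-phase shift is
#' \code{phase_effect} log2 units, per-confounder-level shifts of
#' \code{confounder_effect} log2 units that dominate the phase signal (the
#' regime in which ordinary PCA fails and the confounder-adjusted fit is
#' needed), a planted TF-to-target network, and negative-binomial counts.
#'
#' @param n_genes number of genes (> 0); TF genes are included in this total.
#' @param core_fraction fraction of genes planted as phase-biased, in (0,1).
#' @param phase_effect log2-scale between-phase shift of planted core genes.
#' @param confounder_effect log2-scale s.d. of the per-gene shift between
#'   confounder levels (stages / tissues / time points).
#' @param noise_sd log2-scale residual standard deviation.
#' @param dispersion negative-binomial dispersion of the simulated counts
#'   (0 gives Poisson counts).
#' @param n_tfs number of planted transcription factors (> 0).
#' @param targets_per_tf planted targets per TF.
#' @param tf_effect log2-scale amplitude of TF activity (propagated to
#'   targets with weight 0.8 and a random sign); 0 disables the network
#'   signal.
#' @param seed integer RNG seed; fully determines the generated study.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_genes = 2000, core_fraction = 0.10,
                              phase_effect = 1, confounder_effect = 5,
                              noise_sd = 0.5, dispersion = 0.01,
                              n_tfs = 50, targets_per_tf = 20,
                              tf_effect = 0.5, seed = 1) {
  if (n_genes <= 0 || n_tfs <= 0)
    stop("config error: n_genes and n_tfs must be positive")
  if (core_fraction <= 0 || core_fraction >= 1)
    stop("config error: core_fraction must be in (0,1)")
  if (phase_effect < 0 || confounder_effect < 0 || noise_sd < 0 ||
      dispersion < 0 || tf_effect < 0)
    stop("config error: effect sizes must be >= 0")
  if (n_tfs >= n_genes) stop("config error: n_tfs must be < n_genes")
  structure(list(n_genes = n_genes, core_fraction = core_fraction,
                 phase_effect = phase_effect,
                 confounder_effect = confounder_effect, noise_sd = noise_sd,
                 dispersion = dispersion, n_tfs = n_tfs,
                 targets_per_tf = targets_per_tf, tf_effect = tf_effect,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# attenuation schedule of the phase signal along the transition time course;
# the final time point is fully converged (the two phases cluster together)
timecourse_schedule <- function(times) {
  s <- 1 - (seq_along(times) - 1) / (length(times) - 1)
  s[length(s)] <- 0
  stats::setNames(s, times)
}

#' Generate a synthetic three-design phase-change study
#'
#' Emulates the study designs the analysis assumes: a development design
#' (6 stages x 2 phases), a tissue design (8 tissues/organs x 2 phases) and a
#' phase-transition time course (2 tissues x 2 treatment directions x 6 time
#' points, one sample each, with the phase signal attenuated to zero at the
#' final time point). Expression is built as a log2-scale latent signal
#' (gene baseline + confounder-level shift + planted phase effect + TF-driven
#' target signal + Gaussian noise), exponentiated and converted to
#' negative-binomial counts. Time-course treatments are labelled by their
#' phase of origin (CS -> S, IG -> G).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{synthetic_study}: list with \code{datasets} (named list of
#'   count \code{expression_dataset}s), \code{latent} (the noise-free-scale
#'   latent log2 matrices actually used, including noise), \code{truth_core}
#'   (data.frame gene_id, direction +1 gregarious-biased / -1
#'   solitary-biased), \code{truth_edges} (data.frame tf, target, sign),
#'   \code{tf_ids}, \code{sequences} (named character vector),
#'   \code{methylation} (long data.frame gene_id, site_pos, beta),
#'   \code{behavior} (per-animal records), \code{gene_lengths}, \code{config}.
#' @export
simulate_studies <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  tf_ids <- sprintf("tf%04d", seq_len(config$n_tfs))
  gene_ids <- c(tf_ids, sprintf("g%05d", seq_len(ng - config$n_tfs)))

  n_core <- round(config$core_fraction * ng)
  core_idx <- sample.int(ng, n_core)
  core_dir <- sample(c(1, -1), n_core, replace = TRUE)
  truth_core <- data.frame(gene_id = gene_ids[core_idx],
                           direction = core_dir, stringsAsFactors = FALSE)

  targets <- lapply(seq_len(config$n_tfs), function(i)
    sample(setdiff(seq_len(ng), i), config$targets_per_tf))
  edge_signs <- lapply(seq_len(config$n_tfs), function(i)
    sample(c(1, -1), config$targets_per_tf, replace = TRUE))
  truth_edges <- data.frame(
    tf = rep(tf_ids, each = config$targets_per_tf),
    target = gene_ids[unlist(targets)],
    sign = unlist(edge_signs),
    stringsAsFactors = FALSE)

  base <- stats::rnorm(ng, mean = 12, sd = 2)
  gene_lengths <- stats::setNames(
    round(exp(stats::runif(ng, log(500), log(10000)))), gene_ids)

  phase_vec <- numeric(ng)
  phase_vec[core_idx] <- core_dir * config$phase_effect / 2

  metas <- list(
    development = expand_meta("development",
                              levels = c("egg", "instar12", "instar3",
                                         "instar4", "instar5", "adult")),
    tissue = expand_meta("tissue",
                         levels = c("brain", "ganglia", "antenna_n4",
                                    "antenna_adult", "wing", "pronotum",
                                    "fat_body", "hemolymph")),
    timecourse = timecourse_meta())

  sim <- lapply(metas, function(meta)
    simulate_one_dataset(meta, config, base, phase_vec, targets,
                         edge_signs, gene_ids, gene_lengths))
  datasets <- lapply(sim, `[[`, "dataset")
  latent <- lapply(sim, `[[`, "latent")

  depletion <- rep(0.6, ng)
  depletion[core_idx] <- 0.9
  sequences <- simulate_sequences(ng, length = 1500, gc_content = 0.42,
                                  cpg_depletion = depletion,
                                  seed = config$seed + 1L)
  names(sequences) <- gene_ids

  methylation <- simulate_methylation(gene_ids, core_idx,
                                      seed = config$seed + 2L)
  behavior <- simulate_behavior(30, seed = config$seed + 3L)

  structure(list(datasets = datasets, latent = latent,
                 truth_core = truth_core, truth_edges = truth_edges,
                 tf_ids = tf_ids, sequences = sequences,
                 methylation = methylation, behavior = behavior,
                 gene_lengths = gene_lengths, config = config),
            class = "synthetic_study")
}

expand_meta <- function(kind, levels) {
  meta <- expand.grid(confounder_level = levels, phase = c("G", "S"),
                      stringsAsFactors = FALSE)
  meta$dataset <- kind
  meta$sample_id <- paste(substr(kind, 1, 3), meta$confounder_level,
                          meta$phase, sep = "_")
  meta
}

timecourse_meta <- function() {
  meta <- expand.grid(time = c(0, 4, 8, 16, 32, 64),
                      treatment = c("CS", "IG"),
                      tissue = c("brain", "ganglia"),
                      stringsAsFactors = FALSE)
  meta$phase <- ifelse(meta$treatment == "CS", "S", "G")
  meta$confounder_level <- paste(meta$tissue, meta$time, sep = "_")
  # the dominant nuisance axis of the time course is the tissue; the level
  # column above still identifies matched G/S pairs for no-replicate testing
  meta$delta_level <- meta$tissue
  meta$dataset <- "timecourse"
  meta$sample_id <- paste("tc", meta$tissue, meta$treatment, meta$time,
                          sep = "_")
  meta
}

simulate_one_dataset <- function(meta, config, base, phase_vec, targets,
                                 edge_signs, gene_ids, gene_lengths) {
  ng <- length(base)
  n <- nrow(meta)
  dlev <- if (!is.null(meta$delta_level)) meta$delta_level
          else meta$confounder_level
  lev <- unique(dlev)
  # per-gene per-level shifts are bounded (uniform in +/- confounder_effect):
  # unbounded Gaussian tails, once exponentiated, would let single gene/level
  # cells dominate whole library sizes, which real stage/tissue effects do not
  delta <- matrix(stats::runif(ng * length(lev),
                               -config$confounder_effect,
                               config$confounder_effect),
                  ng, length(lev), dimnames = list(NULL, lev))
  psign <- ifelse(meta$phase == "G", 1, -1)
  sched <- rep(1, n)
  if (!is.null(meta$time)) {
    s <- timecourse_schedule(sort(unique(meta$time)))
    sched <- s[as.character(meta$time)]
  }
  latent <- matrix(base, ng, n) + delta[, dlev] +
    outer(phase_vec, psign * sched)
  if (config$tf_effect > 0) {
    # per-sample TF activity, expressed in the TF's own profile and
    # propagated to its planted targets with the edge sign at weight 0.8
    act <- matrix(stats::rnorm(config$n_tfs * n), config$n_tfs, n)
    for (i in seq_len(config$n_tfs)) {
      latent[i, ] <- latent[i, ] + config$tf_effect * act[i, ]
      latent[targets[[i]], ] <- latent[targets[[i]], ] +
        0.8 * config$tf_effect * outer(edge_signs[[i]], act[i, ])
    }
  }
  latent <- latent + matrix(stats::rnorm(ng * n, sd = config$noise_sd),
                            ng, n)
  mu <- 2^latent
  counts <- if (config$dispersion > 0)
    matrix(stats::rnbinom(ng * n, mu = mu, size = 1 / config$dispersion),
           ng, n)
  else matrix(stats::rpois(ng * n, lambda = mu), ng, n)
  rownames(counts) <- rownames(latent) <- gene_ids
  colnames(counts) <- colnames(latent) <- meta$sample_id
  ds <- expression_dataset(counts, meta, kind = "counts",
                           gene_ids = gene_ids, gene_lengths = gene_lengths)
  list(dataset = ds, latent = latent)
}

simulate_methylation <- function(gene_ids, core_idx, seed,
                                 mean_core = 0.3, mean_other = 0.6) {
  set.seed(seed)
  ng <- length(gene_ids)
  n_sites <- 5 + stats::rpois(ng, 25)
  mu <- rep(mean_other, ng)
  mu[core_idx] <- mean_core
  do.call(rbind, lapply(seq_len(ng), function(i) {
    data.frame(gene_id = gene_ids[i], site_pos = sort(sample.int(1500,
               n_sites[i])),
               beta = stats::rbeta(n_sites[i], mu[i] * 10,
                                   (1 - mu[i]) * 10),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate gene sequences with a controlled CpG depletion
#'
#' Nucleotides are drawn from a first-order chain that is i.i.d. except after
#' a C, where the probability of G is set so that the expected CpG
#' observed/expected ratio equals \code{cpg_depletion} exactly (the mass
#' removed from or added to G after a C is balanced against A/T so base
#' composition stays consistent).
#'
#' @param n_genes number of sequences.
#' @param length sequence length in nt (>= 2).
#' @param gc_content total G+C fraction, in (0,1).
#' @param cpg_depletion target CpG o/e (> 0); scalar or per-gene vector.
#' @param seed RNG seed.
#' @return character vector of sequences.
#' @export
simulate_sequences <- function(n_genes, length, gc_content = 0.42,
                               cpg_depletion = 1, seed = 1) {
  if (length < 2) stop("CpG o/e undefined for length < 2")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  if (any(cpg_depletion <= 0)) stop("cpg_depletion must be > 0")
  set.seed(seed)
  d <- rep_len(cpg_depletion, n_genes)
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  pc <- p[2]; pg <- p[3]
  # stationary G frequency g solving g = (1-pc)*pg + pc*d*g keeps
  # %CG/(%C*%G) = d in expectation
  g_freq <- (1 - pc) * pg / (1 - pc * d)
  qg <- d * g_freq
  if (any(1 - pc - qg < 0)) stop("cpg_depletion too large for this gc_content")
  seqs <- matrix("", n_genes, length)
  cur <- sample(bases, n_genes, replace = TRUE, prob = p)
  seqs[, 1] <- cur
  at <- p[c(1, 4)] / sum(p[c(1, 4)])
  for (j in 2:length) {
    nxt <- sample(bases, n_genes, replace = TRUE, prob = p)
    after_c <- cur == "C"
    if (any(after_c)) {
      k <- sum(after_c)
      qG <- qg[after_c]
      rest <- 1 - pc - qG
      u <- stats::runif(k)
      nxt_c <- ifelse(u < qG, "G",
               ifelse(u < qG + pc, "C",
               ifelse(u < qG + pc + rest * at[1], "A", "T")))
      nxt[after_c] <- nxt_c
    }
    seqs[, j] <- nxt
    cur <- nxt
  }
  apply(seqs, 1, paste, collapse = "")
}

#' Simulate arena-behavior records for the two phases
#'
#' Gregarious animals are drawn with high attraction index, total distance
#' moved and movement duration; solitary animals with low values, so the
#' P_greg medians of the two groups separate.
#'
#' @param n_per_phase animals per phase (0 gives an empty table).
#' @param seed RNG seed.
#' @return data.frame with \code{animal_id}, \code{phase},
#'   \code{dur_stimulus}, \code{dur_opposite}, \code{total_distance_moved},
#'   \code{total_duration_movement}.
#' @export
simulate_behavior <- function(n_per_phase, seed = 1) {
  if (n_per_phase < 0) stop("n_per_phase must be >= 0")
  set.seed(seed)
  cols <- c("animal_id", "phase", "dur_stimulus", "dur_opposite",
            "total_distance_moved", "total_duration_movement")
  if (n_per_phase == 0) {
    out <- data.frame(animal_id = character(0), phase = character(0),
                      dur_stimulus = numeric(0), dur_opposite = numeric(0),
                      total_distance_moved = numeric(0),
                      total_duration_movement = numeric(0))
    return(out)
  }
  draw <- function(phase, ds, do_, tdm, tdmv) {
    stim <- pmax(0, stats::rnorm(n_per_phase, ds[1], ds[2]))
    opp <- pmax(0, stats::rnorm(n_per_phase, do_[1], do_[2]))
    over <- stim + opp > 300
    sc <- ifelse(over, 300 / (stim + opp), 1)
    data.frame(
      animal_id = paste0(phase, seq_len(n_per_phase)), phase = phase,
      dur_stimulus = stim * sc, dur_opposite = opp * sc,
      total_distance_moved = pmax(0, stats::rnorm(n_per_phase, tdm[1],
                                                  tdm[2])),
      total_duration_movement = pmax(0, stats::rnorm(n_per_phase, tdmv[1],
                                                     tdmv[2])),
      stringsAsFactors = FALSE)
  }
  rbind(draw("G", c(170, 40), c(60, 25), c(150, 40), c(100, 30)),
        draw("S", c(60, 25), c(170, 40), c(30, 15), c(25, 12)))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes (%d TFs), %d planted core genes\n",
              x$config$n_genes, x$config$n_tfs, nrow(x$truth_core)))
  for (nm in names(x$datasets))
    cat(sprintf("  %s: %d samples\n", nm, ncol(x$datasets[[nm]]$values)))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Expression and metadata TSVs per dataset, FASTA sequences, methylation and
#' truth tables, and behavior records.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$datasets))
    write_expression_tsv(study$datasets[[nm]],
                         file.path(dir, paste0(nm, "_counts.tsv")),
                         file.path(dir, paste0(nm, "_meta.tsv")))
  seqs <- Biostrings::DNAStringSet(study$sequences)
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
  utils::write.table(study$methylation, file.path(dir, "methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth_core, file.path(dir, "truth_core.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth_edges, file.path(dir, "truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(study$tf_ids, file.path(dir, "tfs.txt"))
  invisible(dir)
}
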