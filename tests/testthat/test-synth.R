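test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(n_tfs = -1), "positive")
  expect_error(simulation_config(core_fraction = 1.2), "core_fraction")
  expect_error(simulation_config(phase_effect = -1), "effect sizes")
  expect_error(simulation_config(n_genes = 50, n_tfs = 50), "n_tfs")
})

test_that("the same seed reproduces the study exactly", {
  cfg <- simulation_config(n_genes = 200, n_tfs = 10, targets_per_tf = 5,
                           seed = 11)
  a <- simulate_studies(cfg)
  b <- simulate_studies(cfg)
  expect_identical(a$datasets$development$values,
                   b$datasets$development$values)
  expect_identical(a$truth_core, b$truth_core)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$behavior, b$behavior)
})

test_that("planted truth sizes and labels are bookkept", {
  cfg <- simulation_config(n_genes = 300, core_fraction = 0.1, n_tfs = 12,
                           targets_per_tf = 7, seed = 2)
  st <- simulate_studies(cfg)
  expect_equal(nrow(st$truth_core), round(0.1 * 300))
  expect_true(all(st$truth_edges$tf %in% st$tf_ids))
  expect_true(all(st$truth_core$direction %in% c(1, -1)))
  expect_equal(nrow(st$truth_edges), 12 * 7)
  for (ds in st$datasets) {
    expect_true(all(ds$values >= 0))
    expect_true(all(ds$values == round(ds$values)))
    expect_true(all(ds$samples$phase %in% c("G", "S")))
  }
  expect_equal(ncol(st$datasets$development$values), 12)
  expect_equal(ncol(st$datasets$tissue$values), 16)
  expect_equal(ncol(st$datasets$timecourse$values), 24)
})

test_that("zero-noise latent signal carries the exact planted phase shift", {
  cfg <- simulation_config(n_genes = 150, core_fraction = 0.2,
                           phase_effect = 1.5, confounder_effect = 0,
                           noise_sd = 0, tf_effect = 0, n_tfs = 5,
                           targets_per_tf = 3, seed = 5)
  st <- simulate_studies(cfg)
  lat <- st$latent$development
  ph <- st$datasets$development$samples$phase
  diff <- rowMeans(lat[, ph == "G", drop = FALSE]) -
    rowMeans(lat[, ph == "S", drop = FALSE])
  core <- st$truth_core
  expect_equal(unname(diff[core$gene_id]), 1.5 * core$direction)
  non_core <- setdiff(rownames(lat), core$gene_id)
  expect_equal(unname(diff[non_core]), rep(0, length(non_core)))
})

test_that("the final time point of the time course is converged", {
  cfg <- simulation_config(n_genes = 150, core_fraction = 0.2,
                           phase_effect = 2, confounder_effect = 0,
                           noise_sd = 0, tf_effect = 0, n_tfs = 5,
                           targets_per_tf = 3, seed = 6)
  st <- simulate_studies(cfg)
  lat <- st$latent$timecourse
  meta <- st$datasets$timecourse$samples
  core <- st$truth_core$gene_id
  last <- meta$time == 64
  cs64 <- lat[core, last & meta$treatment == "CS", drop = FALSE]
  ig64 <- lat[core, last & meta$treatment == "IG", drop = FALSE]
  expect_equal(rowMeans(cs64), rowMeans(ig64))
  first <- meta$time == 0
  cs0 <- rowMeans(lat[core, first & meta$treatment == "CS", drop = FALSE])
  ig0 <- rowMeans(lat[core, first & meta$treatment == "IG", drop = FALSE])
  expect_true(all(abs(ig0 - cs0) > 1))
})

test_that("simulated sequences hit the requested CpG o/e", {
  s1 <- simulate_sequences(200, 10000, gc_content = 0.42,
                           cpg_depletion = 1, seed = 3)
  expect_equal(mean(cpg_oe(s1)), 1.0, tolerance = 0.05)
  s05 <- simulate_sequences(200, 10000, gc_content = 0.42,
                            cpg_depletion = 0.5, seed = 3)
  expect_equal(mean(cpg_oe(s05)), 0.5, tolerance = 0.05)
  expect_error(simulate_sequences(5, 1), "length")
  expect_identical(simulate_sequences(5, 100, seed = 9),
                   simulate_sequences(5, 100, seed = 9))
})

test_that("behavior records separate the phases and honor edge cases", {
  expect_equal(nrow(simulate_behavior(0)), 0)
  b <- simulate_behavior(30, seed = 4)
  expect_identical(b, simulate_behavior(30, seed = 4))
  expect_equal(nrow(b), 60)
  expect_true(all(b$dur_stimulus >= 0 & b$dur_opposite >= 0))
  expect_true(all(b$dur_stimulus + b$dur_opposite <= 300 + 1e-9))
  scored <- pgreg_records(b)
  expect_gt(median(scored$p_greg[scored$phase == "G"]),
            median(scored$p_greg[scored$phase == "S"]))
})

test_that("ordinary PCA groups samples by confounder level, not phase", {
  st <- simulate_studies(simulation_config(seed = 1))
  ds <- rpkm(st$datasets$development)
  x <- log_quantile_center(ds)
  pc <- stats::prcomp(x, center = FALSE)
  ph <- ds$samples$phase
  acc <- max(mean((pc$x[, 1] > 0) == (ph == "G")),
             mean((pc$x[, 1] > 0) == (ph == "S")))
  expect_lt(acc, 0.70)
  # PC1 separates at least one pair of confounder levels cleanly
  lev_means <- tapply(pc$x[, 1], ds$samples$confounder_level, mean)
  expect_gt(max(lev_means) - min(lev_means), stats::sd(pc$x[, 1]))
})

test_that("a study writes to plain-text files that round-trip", {
  dir <- withr::local_tempdir()
  st <- simulate_studies(simulation_config(n_genes = 120, n_tfs = 6,
                                           targets_per_tf = 4, seed = 8))
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "development_counts.tsv")))
  back <- read_expression_tsv(file.path(dir, "development_counts.tsv"),
                              file.path(dir, "development_meta.tsv"))
  expect_equal(back$values, st$datasets$development$values,
               ignore_attr = TRUE)
  expect_equal(back$samples$phase, st$datasets$development$samples$phase)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fasta"))
  expect_equal(as.character(fa), st$sequences)
})
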