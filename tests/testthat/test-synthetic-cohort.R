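test_that("process spectra are proper distributions with the right structure", {
  bg <- process_spectrum("background")
  pl <- process_spectrum("pole_like")
  msi <- process_spectrum("msi_like")
  for (v in list(bg, pl, msi)) {
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
  }
  # the POLE-like process is propensity-heavy and C>G-poor
  expect_gt(sum(pl[c("TCT>TAT", "TCG>TTG")]), 0.3)
  type <- paste0(
    substr(names(pl), 2, 2), ">", substr(names(pl), 6, 6)
  )
  expect_lt(sum(pl[type == "C>G"]), 0.03)
  # the MSI-like process is not propensity-heavy
  expect_lt(sum(msi[c("TCT>TAT", "TCG>TTG")]), 0.05)
})

test_that("gene pool generation is reproducible and honours constraints", {
  cfg <- small_config(n_genes = 12, n_background_genes = 10)
  a <- make_gene_pool(cfg, seed = 3)
  b <- make_gene_pool(cfg, seed = 3)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$gene_model, b$gene_model)

  expect_equal(
    a$gene_model$protein_length_aa,
    pmax(1L, as.integer(floor(a$gene_model$coding_length_nt / 3)))
  )

  # zero-density band: no TCG canonical window anywhere
  cfg0 <- small_config(
    n_genes = 4, n_background_genes = 2,
    tcg_density_band = c(0, 0)
  )
  p0 <- make_gene_pool(cfg0, seed = 4)
  for (s in p0$sequences) {
    comp <- exon_motif_composition(s)
    expect_equal(comp$n[comp$triplet == "TCG"], 0L)
  }
})

test_that("generated gene lengths track the log-normal target", {
  cfg <- small_config(n_genes = 5, n_background_genes = 400)
  pool <- make_gene_pool(cfg, seed = 5)
  lens <- pool$gene_model$coding_length_nt[
    pool$gene_model$class == "background"
  ]
  target <- exp(cfg$gene_length_meanlog + cfg$gene_length_sdlog^2 / 2)
  expect_lt(abs(mean(lens) - target) / target, 0.1)
})

test_that("catalog simulation is deterministic and truth covers every record", {
  cfg <- small_config(
    n_pole_samples = 2, n_common_samples = 4, n_nonhyper_samples = 1,
    n_genes = 20, n_background_genes = 60, n_shoulder_genes = 6,
    pole_snv_range = c(600, 900), common_snv_range = c(300, 500)
  )
  pool <- make_gene_pool(cfg, seed = 6)
  a <- simulate_catalog(cfg, pool, seed = 6)
  b <- simulate_catalog(cfg, pool, seed = 6)
  expect_identical(as.data.frame(a$catalog), as.data.frame(b$catalog))

  expect_equal(nrow(a$truth$mutations), nrow(a$catalog))
  expect_setequal(unique(a$catalog$sample_id), a$truth$samples$sample_id)
  expect_true(all(a$catalog$gene %in% a$truth$genes$gene))

  # per-sample nonsynonymous counts hit their targets (catalog side)
  ann_counts <- table(
    a$catalog$sample_id[a$catalog$consequence == "nonsynonymous"]
  )
  expect_true(all(ann_counts >= cfg$nonhyper_snv_range[1]))
})

test_that("pre-onset VAFs exceed post-onset VAFs in every POLE sample", {
  sim <- shared_cohort()
  tm <- sim$truth$mutations
  tm$vaf <- sim$catalog$vaf[tm$row_id]
  pole <- tm[!is.na(tm$pre_onset), ]
  per_sample <- split(pole, pole$sample_id)
  for (d in per_sample) {
    expect_gt(mean(d$vaf[d$pre_onset]), mean(d$vaf[!d$pre_onset]))
  }
})

test_that("a fully pre-onset cohort carries no POLE-like process mutations", {
  cfg <- small_config(
    n_pole_samples = 2, n_common_samples = 3, n_nonhyper_samples = 1,
    n_genes = 15, n_background_genes = 40, n_shoulder_genes = 4,
    pre_onset_fraction = 1
  )
  pool <- make_gene_pool(cfg, seed = 7)
  sim <- simulate_catalog(cfg, pool, seed = 7)
  expect_false(any(sim$truth$mutations$process == "pole_like"))
  ann <- suppressMessages(classify_samples(sim$catalog))
  pole_ids <- sim$truth$samples$sample_id[
    sim$truth$samples$group == "pole_category"
  ]
  expect_false(any(
    ann$group[ann$sample_id %in% pole_ids] == "pole_category"
  ))
})

test_that("under extreme enrichment POLE-process mutations are triad-only", {
  cfg <- small_config(
    n_pole_samples = 2, n_common_samples = 3, n_nonhyper_samples = 0,
    n_genes = 15, n_background_genes = 40, n_shoulder_genes = 4,
    pole_like_enrichment = 1e7
  )
  pool <- make_gene_pool(cfg, seed = 8)
  sim <- simulate_catalog(cfg, pool, seed = 8)
  pole_mut <- sim$truth$mutations[sim$truth$mutations$process == "pole_like", ]
  expect_gt(nrow(pole_mut), 100)
  expect_true(all(
    pole_mut$class %in% c("TCT>TAT", "TCG>TTG", "TTT>TGT")
  ))
})

test_that("default group spectra satisfy the propensity-fraction contrast", {
  sim <- shared_cohort()
  truth <- sim$truth$samples
  cat_g <- dplyr::left_join(
    sim$catalog, truth[, c("sample_id", "group")], by = "sample_id"
  )
  sp <- suppressMessages(count_spectrum(cat_g, by = "group"))
  pole_sp <- sp[sp$group == "pole_category", ]
  common_sp <- sp[sp$group == "common_hypermutator", ]
  expect_gt(propensity_count(pole_sp) / sum(pole_sp$n), 0.3)
  expect_lt(propensity_count(common_sp) / sum(common_sp$n), 0.05)
})

test_that("expression simulation is reproducible and shifts HR genes only in POLE", {
  cfg <- small_config()
  samples <- tibble::tibble(
    sample_id = c(sprintf("P%d", 1:6), sprintf("C%d", 1:10)),
    group = rep(c("pole_category", "common_hypermutator"), c(6, 10))
  )
  a <- simulate_expression(cfg, samples, seed = 9)
  b <- simulate_expression(cfg, samples, seed = 9)
  expect_identical(a$expr, b$expr)

  # delta = 0 removes the group difference
  cfg0 <- small_config(expression_effect_delta = 0)
  z <- simulate_expression(cfg0, samples, seed = 10)
  sc <- signature_score(z$expr, default_gene_sets()$HR, "HR")
  m <- dplyr::inner_join(sc, samples, by = "sample_id")
  tt <- welch_t(
    m$score[m$group == "pole_category"],
    m$score[m$group != "pole_category"]
  )
  expect_gt(tt$p_value, 0.05)
})

test_that("simulate_inputs writes a bundle the readers can consume", {
  dir <- withr::local_tempdir()
  cfg <- small_config(
    n_pole_samples = 2, n_common_samples = 4, n_nonhyper_samples = 1,
    n_genes = 15, n_background_genes = 30, n_shoulder_genes = 4,
    pole_snv_range = c(600, 900), common_snv_range = c(300, 500)
  )
  paths <- suppressWarnings(simulate_inputs(cfg, dir, seed = 11))
  expect_true(all(file.exists(paths)))
  cat1 <- read_mutation_table(paths["catalog"], "maf_like")
  expect_gt(nrow(cat1), 1000)
  gm <- read_gene_model(paths["gene_model"])
  expect_equal(nrow(gm), 45)
  sig <- read_signature_matrix(paths["signatures"])
  expect_equal(dim(sig), c(96L, 3L))
  sets <- read_gene_sets(paths["gene_sets"])
  expect_length(sets$HR, 5)
  expr <- suppressWarnings(read_expression_matrix(paths["expression"]))
  expect_equal(expr$gene[1:5], default_gene_sets()$HR)
})
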