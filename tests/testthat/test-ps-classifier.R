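# catalog with a configurable per-gene presence pattern across two groups
presence_catalog <- function(pole_pattern, common_pattern, gene = "GX") {
  rows <- list()
  k <- 0
  for (i in seq_along(pole_pattern)) {
    if (pole_pattern[i]) {
      k <- k + 1
      rows[[k]] <- records_from_classes("TCT>TAT",
        sample_id = sprintf("P%02d", i), gene = gene
      )
    }
  }
  for (i in seq_along(common_pattern)) {
    if (common_pattern[i]) {
      k <- k + 1
      rows[[k]] <- records_from_classes("ACA>AGA",
        sample_id = sprintf("C%02d", i), gene = gene
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$pos <- seq_len(nrow(out))
  out
}

two_group_annotations <- function(n_pole = 10, n_common = 80) {
  tibble::tibble(
    sample_id = c(sprintf("P%02d", 1:n_pole), sprintf("C%02d", 1:n_common)),
    group = rep(c("pole_category", "common_hypermutator"), c(n_pole, n_common))
  )
}

test_that("gene selection tests the sample 2x2 with BH and pole enrichment", {
  ann <- two_group_annotations()
  cat1 <- presence_catalog(
    pole_pattern = c(rep(TRUE, 8), FALSE, FALSE),
    common_pattern = c(rep(TRUE, 2), rep(FALSE, 78))
  )
  sel <- select_pole_specific_genes(cat1, ann)
  expect_lt(sel$fisher_p, 1e-4)
  expect_true(sel$retained)
  expect_equal(sel$bh_q, sel$fisher_p)  # m = 1 identity

  # identical proportions: p = 1, not retained
  cat2 <- presence_catalog(
    pole_pattern = c(rep(TRUE, 5), rep(FALSE, 5)),
    common_pattern = c(rep(TRUE, 40), rep(FALSE, 40))
  )
  sel2 <- select_pole_specific_genes(cat2, ann)
  expect_equal(sel2$fisher_p, 1)
  expect_false(sel2$retained)

  # depletion is never "specific": enrichment toward pole required
  cat3 <- presence_catalog(
    pole_pattern = c(TRUE, rep(FALSE, 9)),
    common_pattern = rep(TRUE, 80)
  )
  sel3 <- select_pole_specific_genes(cat3, ann)
  expect_false(sel3$retained)
})

test_that("low-mutation-number filter uses the POLE-group count only", {
  ann <- two_group_annotations(n_pole = 3, n_common = 3)
  mk <- function(n_pole_records, n_common_records, gene) {
    rec <- dplyr::bind_rows(
      records_from_classes(rep("TCT>TAT", n_pole_records),
        sample_id = "P01", gene = gene
      ),
      records_from_classes(rep("TCT>TAT", n_common_records),
        sample_id = "C01", gene = gene
      )
    )
    rec$pos <- seq_len(nrow(rec))
    rec
  }
  cat1 <- dplyr::bind_rows(
    mk(9, 50, "nine"), mk(10, 0, "ten")
  )
  sel <- tibble::tibble(gene = c("nine", "ten"), retained = TRUE)
  kept <- filter_low_mutation_genes(sel, cat1, ann, min_snv = 10)
  expect_equal(kept, "ten")
})

test_that("FMP and PS follow their defining formulas", {
  expect_equal(compute_fmp(4, 10), 40)
  expect_equal(compute_fmp(0, 25), 0)
  expect_equal(compute_fmp(7, 7), 100)
  expect_error(compute_fmp(8, 7), "invariant")
  expect_warning(na_fmp <- compute_fmp(0, 0), "zero total")
  expect_true(is.na(na_fmp))

  expect_equal(compute_ps(40, 5), 35)
  expect_equal(compute_ps(20, 20), 0)
  expect_equal(compute_ps(0, 100), -100)
  expect_error(compute_ps(150, 0), "\\[0, 100\\]")
})

test_that("the PS table agrees exactly with a brute-force per-record recount", {
  set.seed(31)
  ann <- two_group_annotations(n_pole = 4, n_common = 6)
  for (rep in 1:25) {
    probs <- setNames(runif(96), context_classes())
    cat1 <- dplyr::bind_rows(lapply(ann$sample_id, function(s) {
      r <- sample_with_spectrum(s, sample(30:80, 1), probs)
      r$gene <- sample(c("A", "B", "C"), nrow(r), replace = TRUE)
      r
    }))
    tab <- suppressWarnings(compute_ps_table(cat1, ann))

    # oracle: literal per-record loop, independent canonicalization
    pole_ids <- ann$sample_id[ann$group == "pole_category"]
    for (g in tab$gene) {
      recs <- cat1[cat1$gene == g, ]
      cls <- oracle_canonical(recs$context3, recs$ref, recs$alt)
      prop <- cls %in% c("TCT>TAT", "TCG>TTG")
      in_pole <- recs$sample_id %in% pole_ids
      row <- tab[tab$gene == g, ]
      expect_identical(row$propensity_pole, sum(prop & in_pole))
      expect_identical(row$total_pole, sum(in_pole))
      expect_identical(row$propensity_common, sum(prop & !in_pole))
      expect_identical(row$total_common, sum(!in_pole))
      expect_identical(
        row$ps,
        100 * sum(prop & in_pole) / sum(in_pole) -
          100 * sum(prop & !in_pole) / sum(!in_pole)
      )
    }
  }
})

test_that("period assignment brackets PS against the CI", {
  tab <- tibble::tibble(gene = c("a", "b", "c"), ps = c(0.1, 25, 30))
  out <- assign_periods(tab, c(20, 30))
  expect_equal(
    as.character(out$period),
    c("pole_independent", "indefinite", "pole_dependent")
  )
  # monotone in PS
  set.seed(32)
  tab2 <- tibble::tibble(gene = sprintf("g%02d", 1:40), ps = runif(40, -10, 60))
  out2 <- assign_periods(tab2, c(15, 35))
  o <- order(out2$ps)
  expect_true(all(diff(as.integer(out2$period[o])) >= 0))
  # missing PS reported unassigned
  expect_warning(
    out3 <- assign_periods(
      tibble::tibble(gene = "x", ps = NA_real_), c(0, 1)
    ),
    "unassigned"
  )
  expect_true(is.na(out3$period))
})

test_that("segmented Q-Q fit recovers a noiseless break at the origin", {
  x <- qnorm((1:200 - 0.5) / 200)
  y <- ifelse(x < 0, x, 3 * x)
  fit <- fit_qq_breakpoint(y)
  expect_lt(abs(fit$psi_x), 0.05)
  expect_lt(abs(fit$ip_ps), 0.05)
  expect_equal(unname(fit$slopes), c(1, 3), tolerance = 0.01)
  expect_lt(fit$davies_p, 1e-10)
})

test_that("degenerate PS inputs are rejected", {
  expect_error(fit_qq_breakpoint(rnorm(10)), "insufficient genes")
  expect_error(fit_qq_breakpoint(rep(1, 50)), "degenerate")
})

test_that("a straight line yields a non-significant Davies test mostly", {
  set.seed(33)
  x <- qnorm((1:200 - 0.5) / 200)
  rej <- replicate(60, {
    fit_segmented(x, 2 * x + rnorm(200, 0, 0.1))$davies_p < 0.05
  })
  expect_lte(mean(rej), 0.10)
})

test_that("bootstrap CI is deterministic under a seed and brackets the IP", {
  set.seed(34)
  ps <- c(rnorm(30, 0, 2), rnorm(170, 30, 4))
  a <- bootstrap_ip_ci(ps, n_boot = 100, seed = 5)
  b <- bootstrap_ip_ci(ps, n_boot = 100, seed = 5)
  expect_identical(a$ci, b$ci)
  expect_lte(a$ci[1], a$ip_ps)
  expect_gte(a$ci[2], a$ip_ps)
})

test_that("tidy, glance and autoplot expose the fit", {
  set.seed(35)
  ps <- c(rnorm(30, 0, 2), rnorm(170, 30, 4))
  fit <- bootstrap_ip_ci(ps, n_boot = 50, seed = 1)
  td <- tidy(fit)
  expect_setequal(
    td$term,
    c("psi_x", "ip_ps", "slope_left", "slope_right", "ci_lower", "ci_upper")
  )
  gl <- glance(fit)
  expect_equal(gl$n, 200)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("FMPs of MSI-like subsets are uncorrelated with POLE FMPs", {
  sim <- shared_cohort()
  ann <- suppressMessages(classify_samples(sim$catalog))
  truth <- sim$truth$samples
  # restrict the common group to its MSI-like samples only
  msi_ids <- truth$sample_id[truth$msi]
  ann_msi <- ann
  ann_msi$group[ann$group == "common_hypermutator" &
    !ann$sample_id %in% msi_ids] <- "other"
  tab <- suppressWarnings(compute_ps_table(sim$catalog, ann_msi))
  ok <- !is.na(tab$fmp_pole) & !is.na(tab$fmp_common) & tab$total_common >= 5
  expect_gt(sum(ok), 30)
  r <- suppressWarnings(cor(tab$fmp_pole[ok], tab$fmp_common[ok]))
  expect_lt(abs(r), 0.25)
})
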