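test_that("the 96 classes are well-formed and pyrimidine-centred", {
  cls <- context_classes()
  expect_length(cls, 96)
  expect_false(anyDuplicated(cls) > 0)
  expect_true(all(substr(cls, 2, 2) %in% c("C", "T")))
  expect_true(all(substr(cls, 1, 1) == substr(cls, 5, 5)))
  expect_true(all(substr(cls, 3, 3) == substr(cls, 7, 7)))
})

test_that("canonical_context reverse-complements purine-centred records", {
  expect_equal(canonical_context("AGA", "G", "T"), "TCT>TAT")
  expect_equal(canonical_context("TCG", "C", "T"), "TCG>TTG")
  expect_equal(canonical_context("TTT", "T", "G"), "TTT>TGT")
  expect_error(canonical_context("TNT", "N", "A"), "ambiguous")
  expect_error(canonical_context("TCT", "T", "A"), "does not match")
  expect_error(canonical_context("TCT", "C", "C"), "must differ")
})

test_that("canonicalization is strand-invariant and idempotent (property)", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ctx <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    ref <- substr(ctx, 2, 2)
    alt <- sample(setdiff(bases, ref), 1)
    got <- canonical_context(ctx, ref, alt)
    expect_equal(got, oracle_canonical(ctx, ref, alt))
    # flipping the strand representation gives the same class
    flip_ctx <- paste(rev(strsplit(chartr("ACGT", "TGCA", ctx), "")[[1]]),
      collapse = ""
    )
    expect_equal(
      canonical_context(flip_ctx, chartr("ACGT", "TGCA", ref),
        chartr("ACGT", "TGCA", alt)
      ),
      got
    )
    # an already-canonical class maps to itself
    lhs <- substr(got, 1, 3)
    expect_equal(canonical_context(lhs, substr(got, 2, 2), substr(got, 6, 6)), got)
  }
})

test_that("count_spectrum tallies, is strand-invariant, and handles empties", {
  rec <- records_from_classes(rep("TCT>TAT", 3))
  sp <- count_spectrum(rec)
  expect_equal(sum(sp$n), 3)
  expect_equal(sp$n[sp$class == "TCT>TAT"], 3L)

  flipped <- records_from_classes(rep("TCT>TAT", 3), flip = TRUE)
  expect_equal(count_spectrum(flipped)$n, sp$n)

  empty <- records_from_classes(character(0))
  sp0 <- count_spectrum(empty)
  expect_equal(sum(sp0$n), 0)
  expect_equal(nrow(sp0), 96)
})

test_that("spectrum totals are conserved under sample partitions", {
  set.seed(7)
  probs <- setNames(runif(96), context_classes())
  cat1 <- dplyr::bind_rows(
    sample_with_spectrum("A", 120, probs),
    sample_with_spectrum("B", 80, probs),
    sample_with_spectrum("C", 55, probs)
  )
  total <- count_spectrum(cat1)
  by_sample <- count_spectrum(cat1, by = "sample_id")
  summed <- by_sample |>
    dplyr::group_by(class) |>
    dplyr::summarise(n = sum(n)) |>
    dplyr::arrange(match(class, context_classes()))
  expect_equal(summed$n, total$n)
})

test_that("propensity_count sums TCT>TAT and TCG>TTG, never TTT>TGT", {
  sp <- setNames(integer(96), context_classes())
  sp[c("TCT>TAT", "TCG>TTG", "TTT>TGT")] <- c(3L, 1L, 5L)
  expect_equal(propensity_count(sp), 4)
  expect_equal(propensity_count(setNames(integer(96), context_classes())), 0)
  expect_equal(propensity_count(c("TCG>TTG" = 7L)), 7)
})

test_that("exon_motif_composition canonicalizes sliding windows", {
  comp <- exon_motif_composition("TCTCG")
  got <- setNames(comp$n, comp$triplet)
  expect_equal(unname(got[c("TCT", "CTC", "TCG")]), c(1L, 1L, 1L))
  expect_equal(sum(comp$n), 3)

  comp2 <- exon_motif_composition("AGA")
  expect_equal(comp2$n[comp2$triplet == "TCT"], 1L)

  expect_error(exon_motif_composition("TT"), "too short")
  expect_error(exon_motif_composition("ACGNA"), "position 4")
})

test_that("motif composition matches a brute-force window oracle", {
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  comp <- exon_motif_composition(s)
  # oracle: enumerate windows one by one
  oracle <- table(vapply(1:(nchar(s) - 2), function(i) {
    w <- substr(s, i, i + 2)
    if (substr(w, 2, 2) %in% c("A", "G")) {
      w <- paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]),
        collapse = ""
      )
    }
    w
  }, ""))
  for (t in names(oracle)) {
    expect_equal(comp$n[comp$triplet == t], as.integer(oracle[[t]]))
  }
})

test_that("uniform substitutions recover the motif-implied propensity fraction", {
  # every site mutated to each alternate once: the propensity fraction of the
  # resulting spectrum equals the analytic fraction implied by composition
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  bases <- c("A", "C", "G", "T")
  rows <- list()
  k <- 0
  for (i in 2:(nchar(s) - 1)) {
    ref <- substr(s, i, i)
    for (alt in setdiff(bases, ref)) {
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        sample_id = "S", gene = "G", chrom = "c", pos = k,
        ref = ref, alt = alt, context3 = substr(s, i - 1, i + 1),
        consequence = "nonsynonymous"
      )
    }
  }
  cat1 <- dplyr::bind_rows(rows)
  sp <- count_spectrum(cat1)
  comp <- exon_motif_composition(s)
  n_win <- sum(comp$n)
  # each window contributes 3 mutations; propensity classes arise once per
  # TCT window (C>A) and once per TCG window (C>T)
  expected <- (comp$n[comp$triplet == "TCT"] + comp$n[comp$triplet == "TCG"]) /
    (3 * n_win)
  expect_equal(propensity_count(sp) / sum(sp$n), expected)
})

test_that("motif_mutated_fraction counts distinct sites", {
  # sequence with known TCG positions; mutate some centres
  s <- "AATCGAATCGAATCGAA"  # TCG windows centred at 4, 9, 14
  rec <- tibble::tibble(
    sample_id = c("S1", "S1", "S2"), gene = "G",
    chrom = "c", pos = c(4L, 9L, 4L),
    ref = "C", alt = "T", context3 = "TCG",
    consequence = "nonsynonymous"
  )
  out <- motif_mutated_fraction(rec, "G", s)
  # canonical windows include the CGA windows read on the minus strand, so
  # the sequence has 6 TCG sites; sites 4 and 9 carry the substitution and
  # the recurrent record at site 4 counts once
  expect_equal(out$n_sites[out$motif == "TCG"], 6L)
  expect_equal(out$fraction[out$motif == "TCG"], 2 / 6)
  expect_true(is.na(out$fraction[out$motif == "TCT"]) ||
    out$n_sites[out$motif == "TCT"] > 0)

  none <- motif_mutated_fraction(rec[0, ], "G", "AAAAAA")
  expect_true(all(is.na(none$fraction)))
})

test_that("propensity VAF summary separates the two class means", {
  rec <- dplyr::bind_rows(
    records_from_classes(c("TCT>TAT", "TCG>TTG"), vaf = c(0.1, 0.3)),
    records_from_classes("ACA>AGA", vaf = 0.5)
  )
  rec$pos <- 1:3
  out <- propensity_vaf_summary(rec)
  expect_equal(out$vaf_propensity, 0.2)
  expect_equal(out$vaf_other, 0.5)

  only_prop <- records_from_classes("TCT>TAT", vaf = 0.2)
  out2 <- propensity_vaf_summary(only_prop)
  expect_true(is.na(out2$vaf_other))
})

test_that("late-mutated genes show depressed propensity-class VAF", {
  sim <- shared_cohort()
  tg <- sim$truth$genes
  late_genes <- tg$gene[tg$class == "late"][1:10]
  out <- propensity_vaf_summary(sim$catalog, genes = late_genes)
  ok <- !is.na(out$vaf_propensity) & !is.na(out$vaf_other)
  expect_true(mean(out$vaf_propensity[ok] < out$vaf_other[ok]) > 0.8)
})
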