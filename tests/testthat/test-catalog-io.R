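test_that("MAF-like round trip preserves every field", {
  rec <- records_from_classes(
    c("TCT>TAT", "ACA>AGA", "TCG>TTG"),
    gene = c("G1", "G2", "G1")
  )
  rec$depth <- c(50L, NA, 80L)
  rec$quality <- c(90, 70.5, NA)
  cat1 <- polefoot:::as_mutation_catalog(rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(cat1, path)
  back <- read_mutation_table(path, "maf_like")
  expect_equal(
    as.data.frame(back),
    as.data.frame(cat1),
    ignore_attr = TRUE
  )
})

test_that("non-SNV rows are skipped with a count; errors name missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tgene\tchrom\tpos\tref\talt\tconsequence",
    "S1\tG1\tc1\t10\tC\tA\tnonsynonymous",
    "S1\tG1\tc1\t20\tCT\tC\tnonsynonymous",   # indel
    "S1\tG2\tc1\t30\tT\tG\tnonsynonymous"
  ), path)
  expect_message(cat1 <- read_mutation_table(path, "maf_like"), "1 non-SNV")
  expect_equal(nrow(cat1), 2)
  expect_equal(attr(cat1, "skipped_non_snv"), 1)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tref\talt", "G1\tC\tA"), bad)
  expect_error(read_mutation_table(bad, "maf_like"), "sample_id")
})

test_that("minimal VCF input maps records and splits multi-allelic sites", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\t.\tC\tA\t90\tPASS\tSAMPLE=S1;GENE=G1;VAF=0.4;DP=55",
    "chr1\t202\t.\tT\tG,C\t80\tPASS\tSAMPLE=S1;GENE=G2;VAF=0.2;DP=40"
  ), path)
  cat1 <- read_mutation_table(path, "vcf_minimal")
  expect_equal(nrow(cat1), 3)
  expect_equal(cat1$pos[1], 101L)
  expect_equal(sort(cat1$alt[cat1$pos == 202]), c("C", "G"))
  expect_equal(cat1$sample_id, rep("S1", 3))
})

test_that("attach_context fills triplets and polices mismatches", {
  skip_if_not_installed("Biostrings")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ATCTGA"), fa)  # pos 3 = C with context TCT
  rec <- tibble::tibble(
    sample_id = c("S1", "S1", "S1"), gene = "G1", chrom = "c1",
    pos = c(3L, 4L, 1L),
    ref = c("C", "C", "A"),  # pos 4 is really T -> mismatch
    alt = c("A", "A", "G"),
    consequence = "nonsynonymous"
  )
  suppressMessages(out <- attach_context(rec, fa))
  expect_equal(out$context3[out$pos == 3], "TCT")
  expect_false(4 %in% out$pos)                     # mismatch excluded
  expect_equal(attr(out, "excluded_ref_mismatch"), 1)
  expect_equal(out$context_status[out$pos == 1], "incomplete")
  expect_true(is.na(out$context3[out$pos == 1]))
})

test_that("variant filters drop records per criterion and are idempotent", {
  base <- records_from_classes(rep("TCT>TAT", 6), gene = sprintf("G%d", 1:6))
  base$pos <- 1:6
  base$quality <- c(59, 90, 90, 90, 90, 90)
  base$depth <- c(50L, 19L, 50L, 50L, 50L, 50L)
  base$var_plus <- c(5L, 5L, 7L, 5L, 5L, 5L)
  base$var_minus <- c(5L, 5L, 0L, 5L, 5L, 5L)
  base$clipped_len <- c(150, 150, 150, 99, 150, 150)
  base$pos_fraction <- c(0.5, 0.5, 0.5, 0.5, 0.04, 0.5)

  out <- suppressMessages(apply_variant_filters(base, filter_config()))
  expect_equal(nrow(out), 1)
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts[c(
    "quality", "depth", "single_strand", "clipped_len", "pos_fraction"
  )]), c(1L, 1L, 1L, 1L, 1L))
  expect_true(sum(counts) >= nrow(base) - nrow(out))

  again <- suppressMessages(apply_variant_filters(out, filter_config()))
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
})

test_that("missing QC fields never trigger removal, only a warning", {
  rec <- records_from_classes(rep("TCG>TTG", 2), gene = c("G1", "G2"))
  rec$pos <- 1:2
  rec$quality <- NA_real_
  expect_warning(
    out <- apply_variant_filters(rec, filter_config()),
    "skipped"
  )
  expect_equal(nrow(out), 2)
})

test_that("blacklisted sites are discarded", {
  rec <- records_from_classes(rep("TCT>TAT", 2), gene = c("G1", "G2"))
  rec$pos <- c(10L, 20L)
  cfg <- filter_config(blacklist = tibble::tibble(
    chrom = "chr_G1", pos = 10L, alt = rec$alt[1]
  ))
  out <- suppressMessages(apply_variant_filters(rec, cfg))
  expect_equal(out$pos, 20L)
})

test_that("gene sets read from two-column and GMT layouts, deduplicated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "set\tgene",
    "HR\tBRCA1", "HR\tRAD51", "HR\tBRCA2", "HR\tRAD54L", "HR\tRAD52",
    "NHEJ\tLIG4", "NHEJ\tPRKDC", "NHEJ\tXRCC4", "NHEJ\tXRCC6",
    "NHEJ\tXRCC6"
  ), path)
  sets <- read_gene_sets(path)
  expect_length(sets$HR, 5)
  expect_length(sets$NHEJ, 4)

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "HR\tBRCA1\tRAD51\tBRCA2\tRAD54L\tRAD52",
    "EMPTY"
  ), gmt)
  expect_warning(sets2 <- read_gene_sets(gmt), "EMPTY")
  expect_length(sets2$HR, 5)
  expect_length(sets2$EMPTY, 0)
})

test_that("gene model and expression readers validate their inputs", {
  gm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tcoding_length_nt\tprotein_length_aa",
    "G1\t303\t100",
    "G2\t500\t100"  # inconsistent
  ), gm)
  expect_warning(out <- read_gene_model(gm), "inconsistent")
  expect_equal(nrow(out), 2)

  ex <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "A\t1\t2", "A\t3\t4"), ex)
  expect_error(read_expression_matrix(ex), "duplicate")
})
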