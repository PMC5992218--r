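# Shared fixture builders. All data are generated in code; nothing binary.

# a record tibble from canonical class labels, optionally strand-flipped
records_from_classes <- function(classes, sample_id = "S1", gene = "G1",
                                 flip = FALSE, vaf = 0.4,
                                 consequence = "nonsynonymous") {
  ctx <- substr(classes, 1, 3)
  alt <- substr(classes, 6, 6)
  if (flip) {
    ctx <- vapply(ctx, function(x) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
    }, "")
    alt <- chartr("ACGT", "TGCA", alt)
  }
  tibble::tibble(
    sample_id = sample_id, gene = gene,
    chrom = paste0("chr_", gene),
    pos = seq_along(classes) * 10L +
      sample.int(5L, length(classes), replace = TRUE),
    ref = substr(ctx, 2, 2), alt = alt, context3 = ctx,
    vaf = vaf, consequence = consequence
  )
}

# catalog in which a sample's spectrum follows the given class proportions
sample_with_spectrum <- function(sample_id, n, probs) {
  classes <- sample(names(probs), n, replace = TRUE, prob = probs)
  rec <- records_from_classes(classes, sample_id = sample_id,
    gene = sample(sprintf("G%02d", 1:20), n, replace = TRUE)
  )
  rec$pos <- seq_len(n)  # unique positions per sample
  rec
}

# independent re-implementation of pyrimidine canonicalization (oracle)
oracle_canonical <- function(ctx, ref, alt) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  out <- character(length(ctx))
  for (i in seq_along(ctx)) {
    if (substr(ctx[i], 2, 2) %in% c("A", "G")) {
      c2 <- rc(ctx[i])
      a2 <- chartr("ACGT", "TGCA", alt[i])
    } else {
      c2 <- ctx[i]
      a2 <- alt[i]
    }
    out[i] <- paste0(c2, ">", substr(c2, 1, 1), a2, substr(c2, 3, 3))
  }
  out
}

# signature matrix built from the generator's process spectra
test_signature_matrix <- function() {
  m <- cbind(
    background = polefoot::process_spectrum("background"),
    pole_like = polefoot::process_spectrum("pole_like"),
    msi_like = polefoot::process_spectrum("msi_like")
  )
  rownames(m) <- polefoot::context_classes()
  m
}

# scaled-down cohort configuration for fast unit tests; overrides win
small_config <- function(...) {
  defaults <- list(
    n_pole_samples = 8, n_common_samples = 30, n_nonhyper_samples = 4,
    n_genes = 60, n_background_genes = 1200, n_shoulder_genes = 30,
    pole_snv_range = c(1212, 4000), common_snv_range = c(600, 900),
    nonhyper_snv_range = c(50, 300),
    placement_weights = list(
      pre = c(early = 20, analog = 40, late = 1, shoulder = 1, background = 1),
      post = c(early = 0.2, analog = 0.2, late = 24, shoulder = 25,
               background = 0.25)
    )
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(polefoot::simulation_config, args)
}

# one small cohort shared across test files (built once per test run)
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        polefoot::simulate_cohort(small_config(), seed = 101)
      )
    }
    cache
  }
})
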