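#' Hypermutator subtype criteria
#'
#' Gates used to stratify samples. A sample whose nonsynonymous SNV count
#' strictly exceeds `hypermutator_min_snv` is a hypermutator; a
#' hypermutator is placed in the POLE category when its spectrum is
#' C>A-rich (`>= min_CtoA_fraction`), C>G-poor (`<= max_CtoG_fraction`) and
#' enriched for the propensity classes TCT>TAT + TCG>TTG
#' (`>= min_propensity_fraction`). The pattern thresholds are explicit,
#' overridable defaults (the subtype definition in the source literature
#' cites pattern criteria without printing numbers) and are recorded in
#' pipeline manifests.
#'
#' @param hypermutator_min_snv Strict lower bound on nonsynonymous SNV
#'   count for hypermutators (default 500, i.e. "exceeding 500 counts").
#' @param min_CtoA_fraction Minimum C>A fraction among all SNVs
#'   (default 0.20).
#' @param max_CtoG_fraction Maximum C>G fraction (default 0.03).
#' @param min_propensity_fraction Minimum fraction of TCT>TAT + TCG>TTG
#'   among all SNVs (default 0.10).
#' @return A `subtype_criteria` list.
#' @export
subtype_criteria <- function(hypermutator_min_snv = 500,
                             min_CtoA_fraction = 0.20,
                             max_CtoG_fraction = 0.03,
                             min_propensity_fraction = 0.10) {
  stopifnot(
    hypermutator_min_snv >= 0,
    min_CtoA_fraction >= 0, min_CtoA_fraction <= 1,
    max_CtoG_fraction >= 0, max_CtoG_fraction <= 1,
    min_propensity_fraction >= 0, min_propensity_fraction <= 1
  )
  structure(
    list(
      hypermutator_min_snv = hypermutator_min_snv,
      min_CtoA_fraction = min_CtoA_fraction,
      max_CtoG_fraction = max_CtoG_fraction,
      min_propensity_fraction = min_propensity_fraction
    ),
    class = "subtype_criteria"
  )
}

#' Count nonsynonymous SNVs for one sample
#'
#' @param catalog A (filtered) mutation catalog.
#' @param sample_id Sample identifier; an unknown sample yields 0 with a
#'   warning.
#' @return Integer count.
#' @export
count_nonsyn_snv <- function(catalog, sample_id) {
  catalog <- as_tibble(catalog)
  if (nrow(catalog) == 0 || !sample_id %in% catalog$sample_id) {
    if (nrow(catalog) > 0) {
      warn(sprintf("unknown sample '%s'; returning 0", sample_id))
    }
    return(0L)
  }
  sum(
    catalog$sample_id == sample_id &
      !is.na(catalog$consequence) &
      catalog$consequence == "nonsynonymous"
  )
}

#' Classify samples into hypermutator subtypes
#'
#' Assigns every sample in the catalog to `non_hypermutator`,
#' `common_hypermutator` or `pole_category` according to its nonsynonymous
#' SNV count and substitution-pattern gates (see [subtype_criteria()]).
#' Pattern fractions are computed from the sample's canonical 96-class
#' spectrum of nonsynonymous SNVs.
#'
#' @param catalog A mutation catalog with contexts attached.
#' @param criteria A [subtype_criteria()] object.
#' @return Tibble with one row per sample: `sample_id`,
#'   `nonsyn_snv_count`, `c_to_a_fraction`, `c_to_g_fraction`,
#'   `propensity_fraction`, `group`.
#' @export
classify_samples <- function(catalog, criteria = subtype_criteria()) {
  catalog <- as_tibble(catalog)
  samples <- unique(catalog$sample_id)

  counts <- catalog %>%
    filter(!is.na(.data$consequence), .data$consequence == "nonsynonymous") %>%
    dplyr::count(.data$sample_id, name = "nonsyn_snv_count")
  counts <- tibble(sample_id = samples) %>%
    left_join(counts, by = "sample_id") %>%
    mutate(nonsyn_snv_count = dplyr::coalesce(.data$nonsyn_snv_count, 0L))

  spec <- suppressMessages(count_spectrum(catalog, by = "sample_id"))
  spec$type <- paste0(
    substr(spec$class, 2, 2), ">", substr(spec$class, 6, 6)
  )
  fractions <- spec %>%
    group_by(.data$sample_id) %>%
    summarise(
      total = sum(.data$n),
      c_to_a_fraction = ifelse(
        .data$total > 0, sum(.data$n[.data$type == "C>A"]) / .data$total, 0
      ),
      c_to_g_fraction = ifelse(
        .data$total > 0, sum(.data$n[.data$type == "C>G"]) / .data$total, 0
      ),
      propensity_fraction = ifelse(
        .data$total > 0,
        sum(.data$n[.data$class %in% propensity_classes()]) / .data$total, 0
      ),
      .groups = "drop"
    ) %>%
    select(-"total")

  out <- counts %>%
    left_join(fractions, by = "sample_id") %>%
    mutate(
      dplyr::across(
        c("c_to_a_fraction", "c_to_g_fraction", "propensity_fraction"),
        ~ dplyr::coalesce(.x, 0)
      ),
      hyper = .data$nonsyn_snv_count > criteria$hypermutator_min_snv,
      pole_pattern = .data$c_to_a_fraction >= criteria$min_CtoA_fraction &
        .data$c_to_g_fraction <= criteria$max_CtoG_fraction &
        .data$propensity_fraction >= criteria$min_propensity_fraction,
      group = case_when(
        !.data$hyper ~ "non_hypermutator",
        .data$pole_pattern ~ "pole_category",
        TRUE ~ "common_hypermutator"
      )
    ) %>%
    select(-"hyper", -"pole_pattern")
  out
}

#' Read a mutational-signature matrix
#'
#' Tab-delimited: first column the 96 context labels (`"ACA>AAA"` style,
#' pyrimidine-centred), remaining columns one probability vector per
#' signature (each summing to 1).
#'
#' @param path Path to the signature TSV.
#' @return Numeric matrix, 96 rows (labelled) by K signatures.
#' @export
read_signature_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- tab[[1]]
  m <- as.matrix(tab[-1])
  rownames(m) <- labels
  missing_cls <- setdiff(context_classes(), labels)
  if (length(missing_cls) > 0) {
    abort(sprintf(
      "signature matrix missing %d context class(es)", length(missing_cls)
    ))
  }
  m[context_classes(), , drop = FALSE]
}

#' Fit signature exposures by non-negative least squares
#'
#' Refits a sample's normalized 96-class spectrum against a user-supplied
#' signature probability matrix by non-negative least squares and
#' normalizes the non-negative weights to sum 1. This is a minimal
#' exposure refit for flagging (e.g. MSI-high when an MSI-like signature
#' exposure exceeds 0.5), not a re-implementation of iterative
#' signature-selection algorithms.
#'
#' @param spectrum A single-scope spectrum tibble from [count_spectrum()]
#'   or a named count vector over the 96 classes; total must be positive.
#' @param signatures 96 x K matrix of per-signature context probabilities;
#'   each column must sum to 1. Row names must be the class labels.
#' @return Tibble with columns `signature`, `exposure`; the Euclidean norm
#'   of the fit residual is attached as attribute `"residual"`.
#' @export
fit_signature_exposures <- function(spectrum, signatures) {
  if (is.data.frame(spectrum)) {
    counts <- setNames(spectrum$n, spectrum$class)
  } else {
    counts <- spectrum
  }
  cls <- context_classes()
  v <- setNames(numeric(96), cls)
  v[intersect(names(counts), cls)] <- counts[intersect(names(counts), cls)]
  if (sum(v) <= 0) abort("empty spectrum")

  if (is.null(rownames(signatures))) {
    abort("signature matrix must have context-class row names")
  }
  signatures <- signatures[cls, , drop = FALSE]
  colsums <- colSums(signatures)
  if (any(abs(colsums - 1) > 1e-6)) {
    abort("each signature column must sum to 1")
  }

  d <- v / sum(v)
  fit <- pracma::lsqnonneg(signatures, d)
  w <- fit$x
  if (sum(w) <= 0) {
    abort("non-negative fit degenerate: all exposures zero")
  }
  out <- tibble(
    signature = colnames(signatures) %||%
      paste0("S", seq_len(ncol(signatures))),
    exposure = w / sum(w)
  )
  attr(out, "residual") <- sqrt(fit$resid.norm)
  out
}

#' Flag MSI-high from a fitted exposure
#'
#' @param exposure Tibble from [fit_signature_exposures()].
#' @param signature_name Name of the MSI-like signature column.
#' @param cutoff Strict threshold on the exposure (default 0.5).
#' @return Logical: `TRUE` when `exposure > cutoff` (strict).
#' @export
flag_msi_high <- function(exposure, signature_name, cutoff = 0.5) {
  hit <- exposure$exposure[exposure$signature == signature_name]
  if (length(hit) != 1) {
    abort(sprintf("unknown signature '%s'", signature_name))
  }
  hit > cutoff
}

#' Gate a sample table on the POLE-mutant hypermutator definition
#'
#' Applies, to a sample annotation table, the combined gate used to define
#' POLE-mutated tumours: nonsynonymous SNV count strictly above `min_snv`,
#' microsatellite-stable status, and the presence of a POLE protein
#' change.
#'
#' @param samples Tibble with columns `n_nonsyn_snv`, `msi_status`
#'   (`"MSS"`/`"MSI"`), `pole_substitution` (protein-change string or
#'   missing).
#' @param min_snv Strict SNV threshold (default 500).
#' @return The gated tibble.
#' @export
filter_pole_mutant_hypermutators <- function(samples, min_snv = 500) {
  samples <- as_tibble(samples)
  required <- c("n_nonsyn_snv", "msi_status", "pole_substitution")
  missing_req <- setdiff(required, names(samples))
  if (length(missing_req) > 0) {
    abort(sprintf(
      "sample table missing column(s): %s",
      paste(missing_req, collapse = ", ")
    ))
  }
  samples %>%
    filter(
      .data$n_nonsyn_snv > min_snv,
      .data$msi_status == "MSS",
      !is.na(.data$pole_substitution),
      nzchar(.data$pole_substitution),
      .data$pole_substitution != "-"
    )
}
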