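#' Select genes with POLE-category-specific mutations
#'
#' For each gene builds the 2x2 table of samples carrying at least one
#' nonsynonymous SNV of that gene versus not, split by group
#' (`pole_category` vs `common_hypermutator`), tests it with a two-sided
#' Fisher exact test, and adjusts across genes with the Benjamini-Hochberg
#' procedure. A gene is retained when `q < q_threshold` *and* the
#' enrichment points toward the POLE category (specific genes are
#' enrichments, not depletions). Genes mutated in neither group are
#' excluded from testing.
#'
#' @param catalog A filtered mutation catalog with consequences.
#' @param annotations Sample classification tibble from
#'   [classify_samples()] (or any tibble with `sample_id`, `group`).
#' @param q_threshold BH q-value threshold (default 0.05).
#' @param count Count `"samples"` carrying a mutation (default) or
#'   mutation `"events"` in the 2x2 table.
#' @return Tibble with one row per tested gene: group counts and totals,
#'   `fisher_p`, `bh_q`, `enriched_pole`, `retained`.
#' @export
select_pole_specific_genes <- function(catalog, annotations,
                                       q_threshold = 0.05,
                                       count = c("samples", "events")) {
  count <- match.arg(count)
  catalog <- as_tibble(catalog)
  annotations <- as_tibble(annotations)

  pole_ids <- annotations$sample_id[annotations$group == "pole_category"]
  common_ids <- annotations$sample_id[annotations$group == "common_hypermutator"]
  if (length(pole_ids) == 0 || length(common_ids) == 0) {
    abort("need samples in both pole_category and common_hypermutator groups")
  }

  nonsyn <- catalog %>%
    filter(
      !is.na(.data$consequence), .data$consequence == "nonsynonymous",
      .data$sample_id %in% c(pole_ids, common_ids)
    )

  per_gene <- nonsyn %>%
    mutate(in_pole = .data$sample_id %in% pole_ids) %>%
    group_by(.data$gene) %>%
    summarise(
      pole_mutated_samples = dplyr::n_distinct(.data$sample_id[.data$in_pole]),
      common_mutated_samples = dplyr::n_distinct(.data$sample_id[!.data$in_pole]),
      pole_events = sum(.data$in_pole),
      common_events = sum(!.data$in_pole),
      .groups = "drop"
    ) %>%
    filter(.data$pole_mutated_samples + .data$common_mutated_samples > 0)

  n_pole <- length(pole_ids)
  n_common <- length(common_ids)
  if (count == "samples") {
    a <- per_gene$pole_mutated_samples
    c_ <- per_gene$common_mutated_samples
    tot1 <- n_pole
    tot2 <- n_common
  } else {
    a <- per_gene$pole_events
    c_ <- per_gene$common_events
    tot1 <- sum(per_gene$pole_events)
    tot2 <- sum(per_gene$common_events)
  }

  p <- vapply(seq_len(nrow(per_gene)), function(i) {
    fisher.test(matrix(
      c(a[i], tot1 - a[i], c_[i], tot2 - c_[i]),
      nrow = 2, byrow = TRUE
    ))$p.value
  }, numeric(1))

  per_gene %>%
    mutate(
      pole_total = n_pole,
      common_total = n_common,
      fisher_p = p,
      bh_q = bh_adjust(p),
      enriched_pole = a / tot1 > c_ / tot2,
      retained = .data$bh_q < q_threshold & .data$enriched_pole
    ) %>%
    arrange(.data$gene)
}

#' Remove low-mutation-number genes
#'
#' Keeps retained genes with at least `min_snv` nonsynonymous SNVs summed
#' across POLE-category samples (genes with fewer are too thinly sampled
#' for a stable pattern frequency). The bound is on the POLE-group count
#' only; mutations in common hypermutators do not rescue a gene.
#'
#' @param selection Output of [select_pole_specific_genes()].
#' @param catalog The mutation catalog.
#' @param annotations Sample classification tibble.
#' @param min_snv Minimum POLE-group nonsynonymous SNV count (default 10;
#'   genes with `SNV < 10` are removed).
#' @return Character vector of gene symbols passing both filters.
#' @export
filter_low_mutation_genes <- function(selection, catalog, annotations,
                                      min_snv = 10) {
  catalog <- as_tibble(catalog)
  pole_ids <- annotations$sample_id[annotations$group == "pole_category"]
  counts <- catalog %>%
    filter(
      !is.na(.data$consequence), .data$consequence == "nonsynonymous",
      .data$sample_id %in% pole_ids
    ) %>%
    dplyr::count(.data$gene, name = "pole_snv")
  kept <- selection %>%
    filter(.data$retained) %>%
    left_join(counts, by = "gene") %>%
    filter(dplyr::coalesce(.data$pole_snv, 0L) >= min_snv)
  sort(kept$gene)
}

#' Frequency of a mutation pattern (FMP)
#'
#' `FMP(%) = propensity mutation / total mutation x 100`, where propensity
#' mutations are the TCT>TAT and TCG>TTG substitutions (TTT>TGT excluded).
#'
#' @param propensity Propensity mutation count(s).
#' @param total Total mutation count(s); `total = 0` yields `NA` with a
#'   warning (the gene is dropped from PS).
#' @return Percentage(s) in `[0, 100]`.
#' @export
compute_fmp <- function(propensity, total) {
  if (any(propensity < 0 | total < 0)) {
    abort("counts must be non-negative")
  }
  if (any(propensity > total)) {
    abort("invariant violation: propensity count exceeds total count")
  }
  out <- ifelse(total == 0, NA_real_, 100 * propensity / total)
  if (any(total == 0)) {
    warn(sprintf("%d scope(s) with zero total mutations: FMP missing",
      sum(total == 0)
    ))
  }
  out
}

#' Propensity score (PS)
#'
#' `PS = FMP_POLEcategory - FMP_CommonHypermutator`. Low PS marks genes
#' mutated independently of the POLE mutant; high PS marks genes whose
#' propensity mutations accumulated dependently on defective POLE.
#'
#' @param fmp_pole,fmp_common FMP percentages in `[0, 100]`.
#' @return PS value(s) in `[-100, 100]`.
#' @export
compute_ps <- function(fmp_pole, fmp_common) {
  ok <- is.na(fmp_pole) | is.na(fmp_common) |
    (fmp_pole >= 0 & fmp_pole <= 100 & fmp_common >= 0 & fmp_common <= 100)
  if (!all(ok)) abort("FMP values must lie in [0, 100]")
  fmp_pole - fmp_common
}

#' Per-gene FMP and PS table
#'
#' Counts propensity and total nonsynonymous SNVs per gene within the
#' POLE-category and common-hypermutator groups and applies
#' [compute_fmp()] / [compute_ps()]. By default the FMP denominator is the
#' gene's own mutation count within the group (`fmp_denominator = "gene"`);
#' `"group"` divides instead by the group-wide mutation total.
#'
#' @param catalog A mutation catalog with contexts attached.
#' @param annotations Sample classification tibble.
#' @param genes Optional gene subset (e.g. from
#'   [filter_low_mutation_genes()]); default all genes mutated in either
#'   group.
#' @param fmp_denominator `"gene"` (default) or `"group"`.
#' @return Tibble with one row per gene: propensity/total counts per
#'   group, `fmp_pole`, `fmp_common`, `ps`. Genes with an undefined FMP in
#'   either group carry `ps = NA`.
#' @export
compute_ps_table <- function(catalog, annotations, genes = NULL,
                             fmp_denominator = c("gene", "group")) {
  fmp_denominator <- match.arg(fmp_denominator)
  catalog <- as_tibble(catalog)
  pole_ids <- annotations$sample_id[annotations$group == "pole_category"]
  common_ids <- annotations$sample_id[annotations$group == "common_hypermutator"]

  recs <- catalog %>%
    filter(
      !is.na(.data$consequence), .data$consequence == "nonsynonymous",
      !is.na(.data$context3),
      .data$sample_id %in% c(pole_ids, common_ids)
    )
  if (!is.null(genes)) {
    recs <- recs %>% filter(.data$gene %in% genes)
  }
  if (nrow(recs) == 0) {
    abort("no usable records for PS computation")
  }
  recs$class <- canonical_context(recs$context3, recs$ref, recs$alt)
  recs$is_prop <- recs$class %in% propensity_classes()
  recs$in_pole <- recs$sample_id %in% pole_ids

  tab <- recs %>%
    group_by(.data$gene) %>%
    summarise(
      propensity_pole = sum(.data$is_prop & .data$in_pole),
      total_pole = sum(.data$in_pole),
      propensity_common = sum(.data$is_prop & !.data$in_pole),
      total_common = sum(!.data$in_pole),
      .groups = "drop"
    )

  if (fmp_denominator == "gene") {
    denom_pole <- tab$total_pole
    denom_common <- tab$total_common
  } else {
    denom_pole <- rep(sum(tab$total_pole), nrow(tab))
    denom_common <- rep(sum(tab$total_common), nrow(tab))
  }
  fmp_pole <- suppressWarnings(compute_fmp(tab$propensity_pole, denom_pole))
  fmp_common <- suppressWarnings(
    compute_fmp(tab$propensity_common, denom_common)
  )
  n_dropped <- sum(is.na(fmp_pole) | is.na(fmp_common))
  if (n_dropped > 0) {
    warn(sprintf(
      "%d gene(s) with zero mutations in a group: PS missing", n_dropped
    ))
  }
  tab %>%
    mutate(
      fmp_pole = fmp_pole,
      fmp_common = fmp_common,
      ps = compute_ps(fmp_pole, fmp_common)
    ) %>%
    arrange(.data$gene)
}

#' Assign genes to the three temporal periods
#'
#' Places each gene relative to the bootstrap confidence interval of the
#' Q-Q inflection point: `ps < ci_lower` is POLE-independent (mutated
#' before/independent of proofreading loss), `ci_lower <= ps < ci_upper`
#' is indefinite (the CI acts as a buffering border), and `ps >= ci_upper`
#' is POLE-dependent. Genes with missing PS are reported unassigned.
#'
#' @param ps_table Tibble with `gene` and `ps` (e.g. from
#'   [compute_ps_table()]).
#' @param ip An `ip_fit` object with a confidence interval (see
#'   [bootstrap_ip_ci()]), or a numeric length-2 vector `c(lower, upper)`.
#' @return Tibble with `gene`, `ps`, `period` (factor ordered
#'   `pole_independent < indefinite < pole_dependent`; `NA` period for
#'   missing PS).
#' @export
assign_periods <- function(ps_table, ip) {
  ci <- if (is.numeric(ip) && length(ip) == 2) {
    ip
  } else if (inherits(ip, "ip_fit") && !is.null(ip$ci)) {
    ip$ci
  } else {
    abort("ip must be an ip_fit with a CI or a numeric c(lower, upper)")
  }
  if (is.na(ci[1]) || is.na(ci[2]) || ci[1] > ci[2]) {
    abort("invalid confidence interval")
  }
  n_missing <- sum(is.na(ps_table$ps))
  if (n_missing > 0) {
    warn(sprintf("%d gene(s) with missing PS left unassigned", n_missing))
  }
  ps_table %>%
    select("gene", "ps") %>%
    mutate(
      period = factor(
        case_when(
          is.na(.data$ps) ~ NA_character_,
          .data$ps < ci[1] ~ "pole_independent",
          .data$ps >= ci[2] ~ "pole_dependent",
          TRUE ~ "indefinite"
        ),
        levels = c("pole_independent", "indefinite", "pole_dependent"),
        ordered = TRUE
      )
    )
}
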