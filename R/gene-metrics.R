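#' Nonsynonymous mutation rate per protein length
#'
#' For each gene with a model, counts the nonsynonymous SNVs carried by
#' samples of the requested group and divides by the protein length in
#' amino acids (set `per = "nt"` to use the coding length in nucleotides
#' instead). Genes without a model are skipped with a warning.
#'
#' @param catalog A mutation catalog.
#' @param gene_model Tibble with `gene`, `coding_length_nt`,
#'   `protein_length_aa` (see [read_gene_model()]).
#' @param annotations Sample classification tibble.
#' @param group Group whose samples are counted (default
#'   `"pole_category"`).
#' @param per Denominator: `"aa"` (protein length, default) or `"nt"`.
#' @return Tibble with `gene`, `nonsyn_count`, the denominator length and
#'   `rate_per_aa` (or `rate_per_nt`).
#' @export
mutation_rate_per_length <- function(catalog, gene_model, annotations,
                                     group = "pole_category",
                                     per = c("aa", "nt")) {
  per <- match.arg(per)
  catalog <- as_tibble(catalog)
  ids <- annotations$sample_id[annotations$group == group]
  counts <- catalog %>%
    filter(
      !is.na(.data$consequence), .data$consequence == "nonsynonymous",
      .data$sample_id %in% ids
    ) %>%
    dplyr::count(.data$gene, name = "nonsyn_count")

  no_model <- setdiff(counts$gene, gene_model$gene)
  if (length(no_model) > 0) {
    warn(sprintf("%d mutated gene(s) without a gene model skipped",
      length(no_model)
    ))
  }

  out <- gene_model %>%
    select("gene", "coding_length_nt", "protein_length_aa") %>%
    left_join(counts, by = "gene") %>%
    mutate(nonsyn_count = dplyr::coalesce(.data$nonsyn_count, 0L))
  if (per == "aa") {
    bad <- is.na(out$protein_length_aa) | out$protein_length_aa <= 0
    if (any(bad)) abort("protein_length_aa must be positive")
    out$rate_per_aa <- out$nonsyn_count / out$protein_length_aa
  } else {
    bad <- is.na(out$coding_length_nt) | out$coding_length_nt <= 0
    if (any(bad)) abort("coding_length_nt must be positive")
    out$rate_per_nt <- out$nonsyn_count / out$coding_length_nt
  }
  out
}

#' Annotate genes with cancer-gene roles
#'
#' Joins a curated role table (tumour suppressor genes and oncogenes, e.g.
#' from Vogelstein's list) and an optional broader cancer-related gene set
#' onto a gene table. Precedence: an explicit `TSG`/`oncogene` role wins;
#' genes only in the cancer-related set become `other_cancer_related`;
#' everything else is `none`. Annotation is pure decoration: no counts or
#' period assignments are altered.
#'
#' @param genes A tibble with a `gene` column (e.g. burden or period
#'   tables).
#' @param role_table Tibble with columns `gene`, `role`
#'   (`"TSG"`/`"oncogene"`); conflicting rows for one gene are an error.
#' @param cancer_related Optional character vector of cancer-related gene
#'   symbols.
#' @return `genes` with a `role` column
#'   (`TSG`, `oncogene`, `other_cancer_related`, `none`).
#' @export
annotate_roles <- function(genes, role_table, cancer_related = NULL) {
  role_table <- as_tibble(role_table) %>% distinct()
  conflicts <- role_table %>%
    dplyr::count(.data$gene) %>%
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(sprintf(
      "conflicting role rows for gene(s): %s",
      paste(conflicts$gene, collapse = ", ")
    ))
  }
  out <- as_tibble(genes) %>%
    left_join(role_table, by = "gene") %>%
    mutate(
      role = case_when(
        !is.na(.data$role) ~ .data$role,
        .data$gene %in% (cancer_related %||% character(0)) ~
          "other_cancer_related",
        TRUE ~ "none"
      )
    )
  out
}
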