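#' Fold-change z-scores per gene and tumour
#'
#' Computes `log2fc = tumour - matched normal` for every gene and paired
#' tumour (expression is assumed already on a log scale, so the fold
#' change is a column difference) and standardizes it per gene across the
#' paired tumours using the population standard deviation. Tumours without
#' a matched normal carry missing values; genes whose fold changes have
#' zero spread carry missing z-scores.
#'
#' @param expr Expression tibble: `gene` column plus one column per
#'   sample (log scale, normalized).
#' @param pairing Tibble with `tumour_id`, `normal_id` (`NA` when no
#'   matched normal exists).
#' @return Long tibble: `gene`, `sample_id` (tumour), `log2fc`, `z`.
#' @export
fold_change_z <- function(expr, pairing) {
  expr <- as_tibble(expr)
  pairing <- as_tibble(pairing)
  missing_t <- setdiff(
    pairing$tumour_id[!is.na(pairing$tumour_id)], names(expr)
  )
  if (length(missing_t) > 0) {
    abort(sprintf(
      "tumour sample(s) absent from expression matrix: %s",
      paste(missing_t, collapse = ", ")
    ))
  }

  fc <- purrr::map_dfc(seq_len(nrow(pairing)), function(i) {
    t_id <- pairing$tumour_id[i]
    n_id <- pairing$normal_id[i]
    v <- if (is.na(n_id) || !n_id %in% names(expr)) {
      rep(NA_real_, nrow(expr))
    } else {
      expr[[t_id]] - expr[[n_id]]
    }
    tibble(!!t_id := v)
  })
  fcm <- as.matrix(fc)

  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) {
      return(NA_real_)
    }
    sqrt(mean((v - mean(v))^2))
  }
  mu <- apply(fcm, 1, function(v) mean(v, na.rm = TRUE))
  s <- apply(fcm, 1, pop_sd)
  z <- sweep(fcm, 1, mu, `-`)
  z <- sweep(z, 1, ifelse(is.na(s) | s == 0, NA_real_, s), `/`)

  tibble(
    gene = rep(expr$gene, times = ncol(fcm)),
    sample_id = rep(colnames(fcm), each = nrow(fcm)),
    log2fc = as.vector(fcm),
    z = as.vector(z)
  )
}

#' Expression signature scores
#'
#' Scores each sample on a gene set as the unweighted mean of the member
#' genes' normalized log expression values ("average of gene expression").
#' A score is reported missing when fewer than half of the member genes
#' are present in the matrix.
#'
#' @param expr Expression tibble (`gene` column plus sample columns).
#' @param gene_set Character vector of member gene symbols (duplicates
#'   ignored).
#' @param set_name Label for the output (default the expression used).
#' @return Tibble: `sample_id`, `set_name`, `score`, `n_genes_used`,
#'   `n_genes_set`.
#' @export
signature_score <- function(expr, gene_set, set_name = "signature") {
  gene_set <- unique(gene_set)
  expr <- as_tibble(expr)
  members <- expr %>% filter(.data$gene %in% gene_set)
  n_used <- nrow(members)
  samples <- setdiff(names(expr), "gene")
  if (n_used == 0) {
    warn(sprintf("no member genes of '%s' present; scores missing", set_name))
    return(tibble(
      sample_id = samples, set_name = set_name, score = NA_real_,
      n_genes_used = 0L, n_genes_set = length(gene_set)
    ))
  }
  low_cover <- n_used < length(gene_set) / 2
  if (low_cover) {
    warn(sprintf(
      "fewer than 50%% of '%s' member genes present (%d of %d); scores missing",
      set_name, n_used, length(gene_set)
    ))
  }
  scores <- vapply(
    samples,
    function(s) mean(members[[s]], na.rm = TRUE),
    numeric(1)
  )
  tibble(
    sample_id = samples, set_name = set_name,
    score = if (low_cover) NA_real_ else unname(scores),
    n_genes_used = n_used, n_genes_set = length(gene_set)
  )
}

#' Compare signature scores between groups
#'
#' Welch's t-test per signature between two sample groups, with optional
#' Bonferroni adjustment across signatures. Signatures with fewer than two
#' scored samples in a group are skipped and reported.
#'
#' @param scores Tibble from [signature_score()] (rows for one or more
#'   `set_name`s).
#' @param annotations Tibble with `sample_id`, `group`.
#' @param groups Length-2 character vector naming the groups to compare
#'   (default POLE category vs common hypermutator).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return Tibble with one row per signature: group means, the Welch test
#'   result and `p_adjusted`.
#' @export
compare_signature_groups <- function(scores, annotations,
                                     groups = c(
                                       "pole_category",
                                       "common_hypermutator"
                                     ),
                                     correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(groups) == 2)
  joined <- as_tibble(scores) %>%
    inner_join(
      as_tibble(annotations) %>% select("sample_id", "group"),
      by = "sample_id"
    ) %>%
    filter(.data$group %in% groups, !is.na(.data$score))

  out <- joined %>%
    group_by(.data$set_name) %>%
    summarise(
      n1 = sum(.data$group == groups[1]),
      n2 = sum(.data$group == groups[2]),
      mean1 = mean(.data$score[.data$group == groups[1]]),
      mean2 = mean(.data$score[.data$group == groups[2]]),
      p_value = if (n1 >= 2 && n2 >= 2) {
        welch_t(
          .data$score[.data$group == groups[1]],
          .data$score[.data$group == groups[2]]
        )$p_value
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  skipped <- out$set_name[is.na(out$p_value)]
  if (length(skipped) > 0) {
    warn(sprintf(
      "signature(s) skipped (a group has < 2 scored samples): %s",
      paste(skipped, collapse = ", ")
    ))
  }
  m <- sum(!is.na(out$p_value))
  out$p_adjusted <- if (correction == "bonferroni" && m > 0) {
    ifelse(is.na(out$p_value), NA_real_, bonferroni(out$p_value, m = m))
  } else {
    out$p_value
  }
  out
}

#' Correlate a signature score with a gene's expression
#'
#' Pearson correlation (two-sided test) between per-sample signature
#' scores and one gene's expression values across the shared samples.
#'
#' @param scores Tibble from [signature_score()] for a single signature.
#' @param expr Expression tibble.
#' @param gene Gene symbol to correlate.
#' @return One-row tibble: `gene`, `set_name`, `r`, `p_value`, `n`
#'   (missing `r` for degenerate/zero-variance input).
#' @export
correlate_signature_gene <- function(scores, expr, gene) {
  expr <- as_tibble(expr)
  row <- expr %>% filter(.data$gene == !!gene)
  if (nrow(row) != 1) {
    abort(sprintf("gene '%s' not found uniquely in expression matrix", gene))
  }
  set_name <- unique(scores$set_name)
  if (length(set_name) != 1) {
    abort("scores must contain exactly one signature")
  }
  shared <- intersect(scores$sample_id, setdiff(names(expr), "gene"))
  s <- scores$score[match(shared, scores$sample_id)]
  g <- as.numeric(row[1, shared])
  keep <- !is.na(s) & !is.na(g)
  s <- s[keep]
  g <- g[keep]
  if (length(s) < 3) {
    abort("need at least 3 paired observations")
  }
  if (sd(s) == 0 || sd(g) == 0) {
    return(tibble(
      gene = gene, set_name = set_name, r = NA_real_,
      p_value = NA_real_, n = length(s)
    ))
  }
  ct <- cor.test(s, g, method = "pearson")
  tibble(
    gene = gene, set_name = set_name, r = unname(ct$estimate),
    p_value = ct$p.value, n = length(s)
  )
}
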