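#' Pipeline configuration
#'
#' Collects the file paths and analysis options of a full run. Only the
#' catalog and an output directory are mandatory; stages whose inputs are
#' absent (expression, gene model, signature matrix, roles) are skipped.
#'
#' @param catalog Path to the mutation catalog (tab-delimited dialect).
#' @param out_dir Output directory.
#' @param gene_model,expression,pairing,gene_sets,signature_matrix,roles
#'   Optional input paths.
#' @param criteria A [subtype_criteria()].
#' @param filters A [filter_config()].
#' @param q_threshold BH q threshold for gene selection (default 0.05).
#' @param min_snv POLE-group SNV floor for retained genes (default 10).
#' @param fmp_denominator `"gene"` or `"group"` (see [compute_ps_table()]).
#' @param n_boot,level Bootstrap resamples and CI level for the IP.
#' @param msi_signature Signature column used for MSI flagging.
#' @param seed Integer seed (bootstrap resampling).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(catalog, out_dir,
                            gene_model = NULL, expression = NULL,
                            pairing = NULL, gene_sets = NULL,
                            signature_matrix = NULL, roles = NULL,
                            criteria = subtype_criteria(),
                            filters = filter_config(),
                            q_threshold = 0.05, min_snv = 10,
                            fmp_denominator = "gene",
                            n_boot = 2000, level = 0.99999,
                            msi_signature = "msi_like", seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; nested
#' `criteria:` and `filters:` blocks override the defaults of
#' [subtype_criteria()] / [filter_config()].
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  crit <- do.call(subtype_criteria, y$criteria %||% list())
  filt <- do.call(filter_config, y$filters %||% list())
  y$criteria <- NULL
  y$filters <- NULL
  do.call(pipeline_config, c(y, list(criteria = crit, filters = filt)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full mutation-footprint analysis
#'
#' Executes filtering, cohort classification, optional MSI flagging,
#' spectrum tallies, POLE-specific gene selection, FMP/PS computation,
#' inflection-point estimation with bootstrap CI, three-period
#' assignment, per-length burden metrics, and expression-signature
#' comparisons, writing a TSV/JSON bundle plus a manifest of every
#' decided convention to `out_dir`.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with every intermediate result
#'   (`annotations`, `selection`, `ps_table`, `ip`, `periods`, ...).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$catalog) || !file.exists(config$catalog)) {
    abort("validation error: catalog path missing or nonexistent")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  res <- list(config = config)

  say("reading catalog")
  catalog <- stage("read_catalog", suppressMessages(
    read_mutation_table(config$catalog, "maf_like")
  ))
  say("applying variant filters (%d records)", nrow(catalog))
  catalog <- stage("filters", suppressMessages(suppressWarnings(
    apply_variant_filters(catalog, config$filters)
  )))
  res$catalog <- catalog

  say("classifying samples")
  annotations <- stage("classification", suppressMessages(
    classify_samples(catalog, config$criteria)
  ))

  if (!is.null(config$signature_matrix)) {
    say("fitting signature exposures")
    sig <- stage("signatures_read", read_signature_matrix(config$signature_matrix))
    hyper_ids <- annotations$sample_id[
      annotations$group != "non_hypermutator"
    ]
    spectra <- suppressMessages(count_spectrum(catalog, by = "sample_id"))
    annotations$msi_high <- NA
    for (sid in hyper_ids) {
      sp <- spectra[spectra$sample_id == sid, c("class", "n")]
      exp_fit <- stage("exposures", fit_signature_exposures(sp, sig))
      annotations$msi_high[annotations$sample_id == sid] <-
        flag_msi_high(exp_fit, config$msi_signature)
    }
  }
  res$annotations <- annotations

  say("tallying group spectra")
  cat_grp <- catalog %>%
    left_join(annotations %>% select("sample_id", "group"), by = "sample_id")
  res$group_spectra <- stage("spectra", suppressMessages(
    count_spectrum(cat_grp, by = "group")
  ))

  say("selecting POLE-category-specific genes")
  selection <- stage("gene_selection", select_pole_specific_genes(
    catalog, annotations,
    q_threshold = config$q_threshold
  ))
  genes <- stage("low_mutation_filter", filter_low_mutation_genes(
    selection, catalog, annotations,
    min_snv = config$min_snv
  ))
  res$selection <- selection
  res$retained_genes <- genes
  say("%d gene(s) retained", length(genes))

  say("computing FMP/PS")
  ps_tab <- stage("ps", suppressWarnings(compute_ps_table(
    catalog, annotations,
    genes = genes,
    fmp_denominator = config$fmp_denominator
  )))
  res$ps_table <- ps_tab

  say("estimating inflection point (%d bootstrap resamples)", config$n_boot)
  ip <- stage("inflection_point", bootstrap_ip_ci(
    ps_tab$ps, ps_tab$gene,
    n_boot = config$n_boot, level = config$level, seed = config$seed
  ))
  res$ip <- ip

  periods <- stage("periods", suppressWarnings(assign_periods(ps_tab, ip)))
  res$periods <- periods

  if (!is.null(config$gene_model)) {
    say("computing burden metrics")
    gm <- stage("gene_model", read_gene_model(config$gene_model))
    burdens <- stage("burdens", suppressWarnings(mutation_rate_per_length(
      catalog, gm, annotations,
      group = "pole_category"
    )))
    burdens <- burdens %>% left_join(periods, by = "gene")
    if (!is.null(config$roles)) {
      roles <- readr::read_tsv(config$roles, show_col_types = FALSE)
      burdens <- stage("roles", annotate_roles(burdens, roles))
    }
    res$burdens <- burdens
  }

  if (!is.null(config$expression) && !is.null(config$gene_sets)) {
    say("scoring expression signatures")
    expr <- stage("expression", suppressWarnings(
      read_expression_matrix(config$expression)
    ))
    sets <- stage("gene_sets", read_gene_sets(config$gene_sets))
    scores <- stage("signature_scores", bind_rows(lapply(
      names(sets),
      function(nm) suppressWarnings(signature_score(expr, sets[[nm]], nm))
    )))
    res$signature_scores <- scores
    res$signature_comparisons <- stage("signature_comparisons",
      suppressWarnings(compare_signature_groups(scores, annotations))
    )
    if (!is.null(config$pairing)) {
      pairing <- stage("pairing", read_sample_pairing(config$pairing))
      res$fold_change_z <- stage("fold_change", fold_change_z(expr, pairing))
    }
  }

  say("writing output bundle")
  write_bundle(res, config$out_dir)
  invisible(res)
}

write_bundle <- function(res, out_dir) {
  readr::write_tsv(res$annotations, file.path(out_dir, "samples.tsv"))
  readr::write_tsv(res$selection, file.path(out_dir, "gene_selection.tsv"))
  readr::write_tsv(res$ps_table, file.path(out_dir, "ps_table.tsv"))
  readr::write_tsv(res$periods, file.path(out_dir, "periods.tsv"))
  write_spectrum_tsv(
    res$group_spectra, file.path(out_dir, "group_spectra.tsv"),
    by = "group"
  )
  if (!is.null(res$burdens)) {
    readr::write_tsv(res$burdens, file.path(out_dir, "burdens.tsv"))
  }
  if (!is.null(res$signature_scores)) {
    readr::write_tsv(
      res$signature_scores, file.path(out_dir, "signature_scores.tsv")
    )
    readr::write_tsv(
      res$signature_comparisons,
      file.path(out_dir, "signature_comparisons.tsv")
    )
  }
  ip <- res$ip
  jsonlite::write_json(
    list(
      psi_x = ip$psi_x, ip_ps = ip$ip_ps, slopes = as.list(ip$slopes),
      davies_p = ip$davies_p, ci = ip$ci, n_boot = ip$n_boot,
      level = ip$level, seed = ip$seed,
      n_failed_refits = ip$n_failed_refits
    ),
    file.path(out_dir, "ip_estimate.json"),
    auto_unbox = TRUE, digits = NA
  )
  cfg <- res$config
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("polefoot")),
      seed = cfg$seed,
      criteria = unclass(cfg$criteria),
      q_threshold = cfg$q_threshold,
      min_snv = cfg$min_snv,
      fmp_denominator = cfg$fmp_denominator,
      n_boot = cfg$n_boot, level = cfg$level,
      conventions = list(
        plotting_positions = "(i - 0.5)/n",
        breakpoint_grid = "observed quantiles, 5th-95th percentile",
        bootstrap = "percentile",
        fisher_table = "mutated samples, two-sided, pole-enrichment required",
        period_boundaries = "ps < lower -> independent; ps >= upper -> dependent"
      )
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
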