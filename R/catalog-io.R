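#' @section Mutation catalogs:
#' A mutation catalog is a tibble with one row per somatic SNV and the
#' columns of the tab-delimited catalog dialect:
#' `sample_id, gene, chrom, pos, ref, alt, context3, vaf, depth, quality,
#' var_plus, var_minus, clipped_len, pos_fraction, consequence`.
#' `pos` is 1-based; `context3` is the reference triplet on the plus strand
#' centred on the mutated base; `consequence` is one of
#' `nonsynonymous, synonymous, splice, other`. Missing values are written
#' as `"."` on disk.
#' @name catalog-io
NULL

catalog_columns <- function() {
  c(
    "sample_id", "gene", "chrom", "pos", "ref", "alt", "context3",
    "vaf", "depth", "quality", "var_plus", "var_minus",
    "clipped_len", "pos_fraction", "consequence"
  )
}

consequence_levels <- function() {
  c("nonsynonymous", "synonymous", "splice", "other")
}

# Coerce a data frame to the catalog column set, filling absent optional
# columns with NA and checking core invariants.
as_mutation_catalog <- function(x, provenance = NULL) {
  x <- as_tibble(x)
  required <- c("sample_id", "gene", "ref", "alt")
  missing_req <- setdiff(required, names(x))
  if (length(missing_req) > 0) {
    abort(sprintf(
      "catalog format error: missing required column(s): %s",
      paste(missing_req, collapse = ", ")
    ))
  }
  for (col in setdiff(catalog_columns(), names(x))) {
    x[[col]] <- if (col %in% c("pos", "depth", "var_plus", "var_minus")) {
      NA_integer_
    } else if (col %in% c("vaf", "quality", "clipped_len", "pos_fraction")) {
      NA_real_
    } else {
      NA_character_
    }
  }
  x <- x[, catalog_columns()]
  x$pos <- as.integer(x$pos)
  x$depth <- as.integer(x$depth)
  x$var_plus <- as.integer(x$var_plus)
  x$var_minus <- as.integer(x$var_minus)
  for (col in c("vaf", "quality", "clipped_len", "pos_fraction")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  if (any(x$ref == x$alt, na.rm = TRUE)) {
    abort("invalid catalog: ref equals alt in at least one record")
  }
  bad_vaf <- !is.na(x$vaf) & (x$vaf < 0 | x$vaf > 1)
  if (any(bad_vaf)) {
    abort("invalid catalog: vaf outside [0, 1]")
  }
  has_ctx <- !is.na(x$context3) & !is.na(x$ref)
  if (any(has_ctx & substr(x$context3, 2, 2) != x$ref)) {
    abort("invalid catalog: ref does not match centre of context3")
  }
  has_coord <- !is.na(x$chrom) & !is.na(x$pos)
  if (any(has_coord)) {
    key <- paste(x$sample_id, x$chrom, x$pos, x$alt)[has_coord]
    if (anyDuplicated(key)) {
      abort("invalid catalog: duplicate (sample_id, chrom, pos, alt) records")
    }
  }
  if (!is.null(provenance)) attr(x, "provenance") <- provenance
  x
}

#' Read a somatic mutation catalog
#'
#' Reads a mutation catalog from either the package's tab-delimited dialect
#' (`maf_like`) or a minimal VCF (`vcf_minimal`, SNV records only, one sample
#' per record identified through the `SAMPLE` INFO key). Rows that are not
#' single-nucleotide variants (indels, MNVs) are skipped with a message;
#' multi-allelic VCF ALT fields are split into one record per alternate.
#'
#' @param path Path to the catalog file.
#' @param dialect `"maf_like"` (tab-delimited, `"."` for missing) or
#'   `"vcf_minimal"`.
#' @return A mutation catalog tibble (see [catalog-io]); the number of
#'   skipped non-SNV rows is attached as attribute `"skipped_non_snv"`.
#' @export
read_mutation_table <- function(path, dialect = c("maf_like", "vcf_minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  if (dialect == "maf_like") {
    raw <- readr::read_tsv(
      path,
      na = c(".", "NA", ""),
      show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    required <- c("sample_id", "gene", "ref", "alt")
    missing_req <- setdiff(required, names(raw))
    if (length(missing_req) > 0) {
      abort(sprintf(
        "catalog format error: missing required column(s): %s",
        paste(missing_req, collapse = ", ")
      ))
    }
  } else {
    raw <- read_vcf_minimal(path)
  }

  is_snv <- !is.na(raw$ref) & !is.na(raw$alt) &
    nchar(raw$ref) == 1 & nchar(raw$alt) == 1 &
    raw$ref %in% c("A", "C", "G", "T") & raw$alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    inform(sprintf("skipped %d non-SNV record(s)", n_skipped))
  }
  out <- as_mutation_catalog(raw[is_snv, , drop = FALSE], provenance = path)
  attr(out, "skipped_non_snv") <- n_skipped
  out
}

# Minimal VCF reader: SNV-oriented, sample/gene/vaf/depth carried in INFO
# (SAMPLE=, GENE=, VAF=, DP=, CONSEQ=). Uses vcfR when available.
read_vcf_minimal <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF input requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[nchar(m) > 0 & hit[seq_along(info)] ] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    tibble(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      quality = suppressWarnings(as.numeric(fix$QUAL[i])),
      info = fix$INFO[i]
    )
  })
  rows$sample_id <- info_get(rows$info, "SAMPLE")
  rows$gene <- info_get(rows$info, "GENE")
  rows$vaf <- suppressWarnings(as.numeric(info_get(rows$info, "VAF")))
  rows$depth <- suppressWarnings(as.integer(info_get(rows$info, "DP")))
  cons <- info_get(rows$info, "CONSEQ")
  rows$consequence <- ifelse(is.na(cons), "nonsynonymous", cons)
  rows$info <- NULL
  rows
}

#' Write a mutation catalog in the tab-delimited dialect
#'
#' @param catalog A mutation catalog tibble.
#' @param path Output path. Missing values are written as `"."`.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(catalog, path) {
  catalog <- as_mutation_catalog(catalog)
  out <- as.data.frame(lapply(catalog, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "."
    col
  }), stringsAsFactors = FALSE)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Fill trinucleotide contexts from a reference sequence
#'
#' Looks up the reference triplet around each record's coordinate. Records
#' whose reference base disagrees with the reference sequence are excluded
#' (count reported); records at a contig boundary, where no full triplet
#' exists, are retained with `context3 = NA` and flagged.
#'
#' @param catalog A mutation catalog with `chrom`/`pos` filled.
#' @param reference A named `Biostrings::DNAStringSet` or path to a FASTA
#'   file whose sequence names match `chrom`.
#' @return The catalog with `context3` filled and a `context_status` column
#'   (`"ok"` or `"incomplete"`); the reference-mismatch exclusion count is
#'   attached as attribute `"excluded_ref_mismatch"`.
#' @export
attach_context <- function(catalog, reference) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("attach_context requires the 'Biostrings' package")
  }
  catalog <- as_mutation_catalog(catalog)
  if (any(is.na(catalog$chrom) | is.na(catalog$pos))) {
    abort("attach_context requires chrom and pos on every record")
  }
  if (is.character(reference) && length(reference) == 1) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  missing_chrom <- setdiff(unique(catalog$chrom), names(reference))
  if (length(missing_chrom) > 0) {
    abort(sprintf(
      "reference does not cover contig(s): %s",
      paste(missing_chrom, collapse = ", ")
    ))
  }

  widths <- setNames(Biostrings::width(reference), names(reference))
  w <- unname(widths[catalog$chrom])
  incomplete <- catalog$pos <= 1 | catalog$pos >= w
  outside <- catalog$pos < 1 | catalog$pos > w
  incomplete <- incomplete | outside

  ctx <- rep(NA_character_, nrow(catalog))
  idx <- which(!incomplete)
  if (length(idx) > 0) {
    for (chr in unique(catalog$chrom[idx])) {
      i <- idx[catalog$chrom[idx] == chr]
      s <- as.character(reference[[chr]])
      ctx[i] <- substring(s, catalog$pos[i] - 1L, catalog$pos[i] + 1L)
    }
  }

  mismatch <- !incomplete & substr(ctx, 2, 2) != catalog$ref
  if (any(mismatch)) {
    inform(sprintf(
      "excluded %d record(s) whose ref base mismatches the reference",
      sum(mismatch)
    ))
  }
  if (any(incomplete)) {
    inform(sprintf(
      "flagged %d record(s) with incomplete context at contig boundary",
      sum(incomplete)
    ))
  }
  catalog$context3 <- ifelse(incomplete | mismatch, NA_character_, ctx)
  catalog$context_status <- ifelse(incomplete, "incomplete", "ok")
  out <- catalog[!mismatch, , drop = FALSE]
  attr(out, "excluded_ref_mismatch") <- sum(mismatch)
  out
}

#' Variant-level false-positive filter configuration
#'
#' Thresholds for the six read-level false-positive criteria applied to
#' called somatic mutations: (1) quality score below `min_quality`,
#' (2) depth of coverage below `min_depth`, (3) variant reads observed on
#' one strand only, (4) average clipped read length below `min_clipped_len`,
#' (5) variant positioned within the first/last `min_pos_fraction` of the
#' read, (6) membership of a user-supplied blacklist of known false-positive
#' sites.
#'
#' @param min_quality Minimum quality score (default 60).
#' @param min_depth Minimum depth of coverage (default 20).
#' @param require_both_strands Drop variants seen on a single strand
#'   (default `TRUE`).
#' @param min_clipped_len Minimum average clipped read length (default 100).
#' @param min_pos_fraction Minimum variant position as a fraction of read
#'   length (default 0.05).
#' @param blacklist Tibble with columns `chrom`, `pos`, `alt` of sites to
#'   discard (default empty).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_quality = 60, min_depth = 20,
                          require_both_strands = TRUE,
                          min_clipped_len = 100, min_pos_fraction = 0.05,
                          blacklist = NULL) {
  stopifnot(
    min_quality >= 0, min_depth >= 0,
    min_clipped_len >= 0, min_pos_fraction >= 0
  )
  if (is.null(blacklist)) {
    blacklist <- tibble(
      chrom = character(0), pos = integer(0), alt = character(0)
    )
  }
  structure(
    list(
      min_quality = min_quality, min_depth = min_depth,
      require_both_strands = require_both_strands,
      min_clipped_len = min_clipped_len,
      min_pos_fraction = min_pos_fraction,
      blacklist = as_tibble(blacklist)
    ),
    class = "filter_config"
  )
}

#' Apply variant-level false-positive filters
#'
#' Removes every record failing at least one of the six criteria in
#' [filter_config()]. A record with a missing QC field is *not* removed by
#' the corresponding criterion (filters test only observable fields); a
#' summary reports how many criterion evaluations were skipped for that
#' reason.
#'
#' @param catalog A mutation catalog tibble.
#' @param cfg A [filter_config()].
#' @return The filtered catalog. Per-criterion removal counts are attached
#'   as attribute `"filter_counts"` and skipped evaluations as
#'   `"filter_skipped"`.
#' @export
apply_variant_filters <- function(catalog, cfg = filter_config()) {
  catalog <- as_mutation_catalog(catalog)
  n <- nrow(catalog)

  fails <- list(
    quality = !is.na(catalog$quality) & catalog$quality < cfg$min_quality,
    depth = !is.na(catalog$depth) & catalog$depth < cfg$min_depth,
    single_strand = if (cfg$require_both_strands) {
      !is.na(catalog$var_plus) & !is.na(catalog$var_minus) &
        (catalog$var_plus + catalog$var_minus) > 0 &
        (catalog$var_plus == 0 | catalog$var_minus == 0)
    } else {
      rep(FALSE, n)
    },
    clipped_len = !is.na(catalog$clipped_len) &
      catalog$clipped_len < cfg$min_clipped_len,
    pos_fraction = !is.na(catalog$pos_fraction) &
      catalog$pos_fraction < cfg$min_pos_fraction,
    blacklist = if (nrow(cfg$blacklist) > 0) {
      paste(catalog$chrom, catalog$pos, catalog$alt) %in%
        paste(cfg$blacklist$chrom, cfg$blacklist$pos, cfg$blacklist$alt)
    } else {
      rep(FALSE, n)
    }
  )

  skipped <- c(
    quality = sum(is.na(catalog$quality)),
    depth = sum(is.na(catalog$depth)),
    single_strand = if (cfg$require_both_strands) {
      sum(is.na(catalog$var_plus) | is.na(catalog$var_minus))
    } else 0L,
    clipped_len = sum(is.na(catalog$clipped_len)),
    pos_fraction = sum(is.na(catalog$pos_fraction)),
    blacklist = 0L
  )

  counts <- vapply(fails, sum, integer(1))
  drop <- Reduce(`|`, fails)
  if (any(drop)) {
    inform(sprintf(
      "removed %d of %d record(s) [%s]",
      sum(drop), n,
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")
    ))
  }
  if (sum(skipped) > 0) {
    warn(sprintf(
      "%d criterion evaluation(s) skipped because the QC field was missing",
      sum(skipped)
    ))
  }
  out <- catalog[!drop, , drop = FALSE]
  attr(out, "filter_counts") <- counts
  attr(out, "filter_skipped") <- skipped
  out
}

#' Read named gene sets
#'
#' Accepts either a two-column tab-delimited table (`set`, `gene`) or a
#' GMT-style layout (one set per line: name followed by its members,
#' tab-separated). Duplicate symbols within a set are dropped.
#'
#' @param path Path to the gene-set file.
#' @return A named list of unique gene-symbol vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  two_col <- all(nf == 2)
  if (two_col && length(fields) > 0 &&
      identical(tolower(fields[[1]]), c("set", "gene"))) {
    fields <- fields[-1]
  }
  if (two_col) {
    set_names <- vapply(fields, `[`, "", 1)
    genes <- vapply(fields, `[`, "", 2)
    sets <- split(genes, set_names)
  } else {
    sets <- setNames(
      lapply(fields, function(f) f[-1]),
      vapply(fields, `[`, "", 1)
    )
  }
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    warn(sprintf("empty gene set(s): %s", paste(empty, collapse = ", ")))
  }
  sets
}

#' Read a gene model table
#'
#' Tab-delimited with columns `gene`, `coding_length_nt`,
#' `protein_length_aa`. Where both lengths are present, a coding length far
#' from `3 * protein_length + 3` (stop codon handling) triggers a warning.
#'
#' @param path Path to the gene-model file.
#' @return Tibble with one row per gene.
#' @export
read_gene_model <- function(path) {
  gm <- readr::read_tsv(path, show_col_types = FALSE, na = c(".", "NA", ""))
  required <- c("gene", "coding_length_nt", "protein_length_aa")
  missing_req <- setdiff(required, names(gm))
  if (length(missing_req) > 0) {
    abort(sprintf(
      "gene model format error: missing column(s): %s",
      paste(missing_req, collapse = ", ")
    ))
  }
  both <- !is.na(gm$coding_length_nt) & !is.na(gm$protein_length_aa)
  off <- both & abs(gm$coding_length_nt - (3 * gm$protein_length_aa + 3)) > 3
  if (any(off)) {
    warn(sprintf(
      "%d gene(s) with coding length inconsistent with protein length",
      sum(off)
    ))
  }
  as_tibble(gm)
}

#' Read a normalized expression matrix
#'
#' First column `gene`, remaining columns one per sample; values are
#' assumed already log-transformed and normalized (e.g. to the 75th
#' percentile). The function does not re-normalize; it warns when sample
#' medians diverge wildly, which usually indicates un-normalized input.
#'
#' @param path Path to the expression TSV.
#' @return Tibble with a `gene` column and one numeric column per sample.
#' @export
read_expression_matrix <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, na = c(".", "NA", ""))
  if (names(expr)[1] != "gene") {
    abort("expression format error: first column must be 'gene'")
  }
  if (anyDuplicated(expr$gene)) {
    abort("expression format error: duplicate gene symbols")
  }
  med <- vapply(expr[-1], function(x) stats::median(x, na.rm = TRUE), 0)
  if (length(med) > 1 && (max(med) - min(med)) > 4) {
    warn("sample medians diverge by more than 4 log units; input may not be normalized")
  }
  expr
}

#' Read a tumour-normal pairing table
#'
#' Tab-delimited with columns `tumour_id` and `normal_id`; `normal_id` may
#' be `NA` when no matched normal is available.
#'
#' @param path Path to the pairing TSV.
#' @return Tibble with `tumour_id`, `normal_id`.
#' @export
read_sample_pairing <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE, na = c(".", "NA", ""))
  required <- c("tumour_id", "normal_id")
  missing_req <- setdiff(required, names(p))
  if (length(missing_req) > 0) {
    abort(sprintf(
      "pairing format error: missing column(s): %s",
      paste(missing_req, collapse = ", ")
    ))
  }
  as_tibble(p)
}
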