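#' Tally the 96-class trinucleotide spectrum of a catalog
#'
#' Canonicalizes every record into its pyrimidine-centred substitution class
#' (see [canonical_context()]) and counts classes, optionally within groups
#' defined by catalog columns (e.g. `"sample_id"`, `"gene"`, or a joined
#' `group` column). All 96 classes are reported for every scope, with zero
#' counts where absent.
#'
#' @param catalog A mutation catalog with `context3` filled.
#' @param by Character vector of catalog column names defining the scope
#'   (default none: one spectrum for the whole catalog).
#' @param include_synonymous Include records whose consequence is not
#'   `nonsynonymous` (default `FALSE`, matching the convention that pattern
#'   statistics are computed on nonsynonymous SNVs).
#' @return Tibble with the `by` columns plus `class` and `n`.
#' @export
count_spectrum <- function(catalog, by = character(0),
                           include_synonymous = FALSE) {
  catalog <- as_tibble(catalog)
  if (!include_synonymous && "consequence" %in% names(catalog)) {
    catalog <- catalog[
      is.na(catalog$consequence) | catalog$consequence == "nonsynonymous", ,
      drop = FALSE
    ]
  }
  usable <- !is.na(catalog$context3)
  if (any(!usable)) {
    inform(sprintf(
      "%d record(s) without context3 omitted from spectrum", sum(!usable)
    ))
  }
  catalog <- catalog[usable, , drop = FALSE]

  classes <- context_classes()
  if (nrow(catalog) == 0 && length(by) == 0) {
    return(tibble(class = classes, n = 0L))
  }
  catalog$class <- canonical_context(catalog$context3, catalog$ref, catalog$alt)
  catalog$class <- factor(catalog$class, levels = classes)

  tallied <- catalog %>%
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "class"))),
      .drop = FALSE, name = "n"
    ) %>%
    mutate(class = as.character(.data$class)) %>%
    arrange(dplyr::across(dplyr::all_of(by)))
  as_tibble(tallied)
}

#' Number of propensity mutations in a spectrum
#'
#' Sums the `TCT>TAT` and `TCG>TTG` counts; `TTT>TGT` is explicitly not
#' included (T>G substitutions can reflect dNTP-pool imbalance rather than
#' proofreading loss).
#'
#' @param spectrum A spectrum tibble from [count_spectrum()] (single scope)
#'   or a named count vector over class labels.
#' @return Integer count.
#' @export
propensity_count <- function(spectrum) {
  if (is.data.frame(spectrum)) {
    counts <- setNames(spectrum$n, spectrum$class)
  } else {
    counts <- spectrum
  }
  sum(counts[names(counts) %in% propensity_classes()], na.rm = TRUE)
}

#' Motif composition of an exonic sequence
#'
#' Counts all overlapping trinucleotide windows (step 1) after
#' pyrimidine-centre canonicalization: windows with a purine centre are
#' reverse-complemented before counting, so the result is over the 32
#' canonical triplets. With `both_strands = TRUE`, windows of the reverse
#' complement are counted as well.
#'
#' @param sequence A nucleotide string (ACGT alphabet, length >= 3).
#' @param both_strands Count windows of both strands (default `FALSE`).
#' @return Tibble with columns `triplet` (the 32 canonical triplets) and `n`.
#' @export
exon_motif_composition <- function(sequence, both_strands = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3) {
    abort("sequence too short: need at least 3 bases")
  }
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    abort(sprintf("non-ACGT character at position %d", bad))
  }
  windows_of <- function(s) {
    n <- nchar(s)
    substring(s, 1:(n - 2), 3:n)
  }
  win <- windows_of(sequence)
  if (both_strands) {
    win <- c(win, windows_of(paste(rev(strsplit(chartr(
      "ACGT", "TGCA", sequence
    ), "")[[1]]), collapse = "")))
  }
  centre <- substr(win, 2, 2)
  canon <- ifelse(centre %in% c("A", "G"), revcomp3(win), win)
  tab <- table(factor(canon, levels = canonical_triplets()))
  tibble(triplet = names(tab), n = as.integer(tab))
}

#' Fraction of motif sites carrying the biased transversion
#'
#' For each motif (default `TCT` and `TCG`), finds every canonical
#' occurrence of the motif in a gene's exonic sequence and reports the
#' fraction of distinct occurrences at which the catalog carries the
#' corresponding propensity substitution (`TCT>TAT` for TCT, `TCG>TTG` for
#' TCG). Sites, not mutation records, are counted, so recurrent mutations
#' at one site count once. Record positions are taken as 1-based indices
#' into `sequence`.
#'
#' @param catalog A mutation catalog (records of `gene` with `pos` filled).
#' @param gene Gene symbol to evaluate.
#' @param sequence The gene's exonic sequence.
#' @param motifs Canonical motifs to score (default `c("TCT", "TCG")`).
#' @return Tibble with `gene`, `motif`, `n_sites`, `n_mutated`, `fraction`
#'   (`NA` when the motif does not occur).
#' @export
motif_mutated_fraction <- function(catalog, gene, sequence,
                                   motifs = c("TCT", "TCG")) {
  sequence <- toupper(sequence)
  catalog <- as_tibble(catalog)
  rec <- catalog[catalog$gene == gene & !is.na(catalog$pos), , drop = FALSE]

  n <- nchar(sequence)
  win <- substring(sequence, 1:(n - 2), 3:n)
  centre_pos <- 2:(n - 1)
  centre <- substr(win, 2, 2)
  canon <- ifelse(centre %in% c("A", "G"), revcomp3(win), win)

  biased_class <- c(TCT = "TCT>TAT", TCG = "TCG>TTG")
  rec_class <- if (nrow(rec) > 0 && any(!is.na(rec$context3))) {
    ok <- !is.na(rec$context3)
    cls <- rep(NA_character_, nrow(rec))
    cls[ok] <- canonical_context(rec$context3[ok], rec$ref[ok], rec$alt[ok])
    cls
  } else {
    character(0)
  }

  purrr::map_dfr(motifs, function(m) {
    sites <- centre_pos[canon == m]
    if (length(sites) == 0) {
      return(tibble(
        gene = gene, motif = m, n_sites = 0L, n_mutated = 0L,
        fraction = NA_real_
      ))
    }
    target <- biased_class[[m]] %||% NA_character_
    hit_pos <- unique(rec$pos[!is.na(rec_class) & rec_class == target])
    n_mut <- sum(sites %in% hit_pos)
    tibble(
      gene = gene, motif = m, n_sites = length(sites),
      n_mutated = n_mut, fraction = n_mut / length(sites)
    )
  })
}

#' Mean VAF of propensity-class versus other records
#'
#' Splits a gene's records into the propensity classes (`TCT>TAT`,
#' `TCG>TTG`) and all other classes and reports the mean variant allele
#' frequency of each side. Records without a VAF are excluded from both
#' means. A lower propensity-class mean is the expected footprint of
#' mutations acquired late (subclonally), after proofreading loss.
#'
#' @param catalog A mutation catalog with `context3` and `vaf` filled.
#' @param genes Optional gene symbols to restrict to (default all genes).
#' @return Tibble with one row per gene: `vaf_propensity`, `vaf_other`,
#'   `n_propensity`, `n_other` (means are `NA` when a side is empty).
#' @export
propensity_vaf_summary <- function(catalog, genes = NULL) {
  catalog <- as_tibble(catalog)
  if (!is.null(genes)) {
    catalog <- catalog[catalog$gene %in% genes, , drop = FALSE]
  }
  catalog <- catalog[!is.na(catalog$context3) & !is.na(catalog$vaf), ,
    drop = FALSE
  ]
  if (nrow(catalog) == 0) {
    return(tibble(
      gene = character(0), vaf_propensity = double(0), vaf_other = double(0),
      n_propensity = integer(0), n_other = integer(0)
    ))
  }
  catalog$class <- canonical_context(
    catalog$context3, catalog$ref, catalog$alt
  )
  catalog$is_prop <- catalog$class %in% propensity_classes()
  catalog %>%
    group_by(.data$gene) %>%
    summarise(
      vaf_propensity = if (any(.data$is_prop)) {
        mean(.data$vaf[.data$is_prop])
      } else {
        NA_real_
      },
      vaf_other = if (any(!.data$is_prop)) {
        mean(.data$vaf[!.data$is_prop])
      } else {
        NA_real_
      },
      n_propensity = sum(.data$is_prop),
      n_other = sum(!.data$is_prop),
      .groups = "drop"
    )
}

#' Write a spectrum table to TSV
#'
#' Writes 96 rows per scope with `class`, `n` and the within-scope
#' fraction.
#'
#' @param spectrum A tibble from [count_spectrum()].
#' @param path Output path.
#' @param by Scope columns present in `spectrum`.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path, by = character(0)) {
  out <- spectrum %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0) %>%
    ungroup()
  readr::write_tsv(out, path)
  invisible(path)
}
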