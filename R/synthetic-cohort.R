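#' @section Synthetic cohorts:
#' The generator emulates the statistical structure the analysis assumes:
#' a small POLE-category group whose mutations arrive in two tranches
#' (a clonal pre-onset tranche drawn from a background substitution
#' process, then a dominant post-onset tranche drawn from a POLE-like
#' process concentrated on TCT>TAT / TCG>TTG / TTT>TGT), a larger
#' common-hypermutator group mixing background and MSI-like processes,
#' non-hypermutator samples, and paired expression with group-shifted
#' homologous-recombination genes. "Early" genes (including POLE/PTEN
#' analogs) attract the pre-onset tranche; "late" genes attract the
#' post-onset tranche; a wide universe of background genes absorbs the
#' remainder so that POLE-category-specific gene selection has genuine
#' negatives. Every mutation carries ground-truth process and timing
#' labels for recovery testing.
#' @name synthetic-cohort
NULL

#' Mutational process spectra for the generator
#'
#' Returns the 96-class probability vector of one of the generator's
#' substitution processes. `background` is transition-dominant with a low
#' C>G share (type weights C>A 0.12, C>G 0.05, C>T 0.40, T>A 0.10,
#' T>C 0.25, T>G 0.08, uniform across the 16 flanking contexts of each
#' type). `pole_like` adds `enrichment / 96` of extra probability mass on
#' the proofreading-deficiency triad, split 0.60 / 0.25 / 0.15 across
#' TCT>TAT / TCG>TTG / TTT>TGT (TCT>TAT-dominant), then renormalizes.
#' `msi_like` concentrates half its mass on C>T at NpCpG contexts
#' (ACG/CCG/GCG-heavy, only 0.03 on TCG>TTG so MSI does not mimic the
#' propensity pattern) over a background floor.
#'
#' @param name One of `"background"`, `"pole_like"`, `"msi_like"`.
#' @param enrichment Triad weight multiplier for `pole_like`
#'   (default 300).
#' @return Named numeric vector over [context_classes()], summing to 1.
#' @export
process_spectrum <- function(name = c("background", "pole_like", "msi_like"),
                             enrichment = 300) {
  name <- match.arg(name)
  cls <- context_classes()
  type <- paste0(substr(cls, 2, 2), ">", substr(cls, 6, 6))
  type_w <- c(
    "C>A" = 0.12, "C>G" = 0.05, "C>T" = 0.40,
    "T>A" = 0.10, "T>C" = 0.25, "T>G" = 0.08
  )
  bg <- setNames(as.numeric(type_w[type] / 16), cls)

  if (name == "background") {
    return(bg)
  }
  if (name == "pole_like") {
    triad <- c("TCT>TAT" = 0.60, "TCG>TTG" = 0.25, "TTT>TGT" = 0.15)
    add <- setNames(numeric(96), cls)
    add[names(triad)] <- enrichment * triad / 96
    v <- bg + add
    return(v / sum(v))
  }
  # msi_like
  v <- 0.5 * bg
  v[c("ACG>ATG", "CCG>CTG", "GCG>GTG")] <-
    v[c("ACG>ATG", "CCG>CTG", "GCG>GTG")] + 0.47 / 3
  v["TCG>TTG"] <- v["TCG>TTG"] + 0.03
  v / sum(v)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults mirror the study
#' conditions the analysis targets: ~10 POLE-category and ~80 common
#' hypermutator samples, 414 focal genes, per-sample nonsynonymous SNV
#' counts spanning 1212-16632 (POLE) and 500-3000 (common).
#'
#' @param n_pole_samples,n_common_samples,n_nonhyper_samples Group sizes
#'   (defaults 10 / 80 / 10).
#' @param n_genes Number of focal, sequence-backed genes (default 414).
#' @param early_gene_fraction Fraction of focal genes whose mutations
#'   predominantly predate POLE onset (default 0.05; includes the
#'   POLE/PTEN analogs — the low-PS subpopulation is a minority of the
#'   retained genes).
#' @param n_background_genes Size of the wider gene universe absorbing
#'   untargeted mutations (default 3000); these genes have lengths but no
#'   bundled sequences.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal coding-length
#'   distribution (defaults `log(1500)`, 0.25; lengths are floored at
#'   300 nt).
#' @param pole_snv_range,common_snv_range,nonhyper_snv_range Per-sample
#'   nonsynonymous SNV count ranges (uniform draws).
#' @param pre_onset_fraction Fraction of a POLE sample's mutations drawn
#'   before proofreading loss (default 0.10).
#' @param late_susceptibility_floor,late_susceptibility_shape Per-gene
#'   POLE-footprint susceptibility of late genes: the fraction of a late
#'   gene's post-onset mutations drawn from the POLE-like (rather than
#'   background) process is `1 - (1 - floor) * rbeta(shape)` (default
#'   floor 0.9, shape `c(2, 2)`): late genes are uniformly strongly
#'   susceptible, while gene-to-gene variation in susceptibility — the
#'   signal the propensity score is designed to resolve — is carried by
#'   the shoulder genes below.
#' @param early_susceptibility,background_susceptibility Susceptibility of
#'   early genes (default 0.15: unsusceptible drivers) and the cap for
#'   ordinary background genes, whose susceptibility is drawn as
#'   `background_susceptibility * rbeta(2.5, 1)` (default cap 0.3).
#' @param n_shoulder_genes,shoulder_susceptibility_top,shoulder_susceptibility_range
#'   A subset of the background universe ("shoulder" genes, default 260)
#'   lies in the mutational path of the defective polymerase with
#'   intermediate susceptibility
#'   `top - range * rbeta(1, 3.5)` (defaults 0.93 and 0.40): dense just
#'   below the late-gene floor and thinning downward. These genes produce
#'   the indefinite shoulder of the PS distribution that the buffering
#'   period of the classifier exists for; without them the PS Q-Q plot
#'   degenerates into two disconnected clusters, which no single-break
#'   segmented model describes.
#' @param pole_like_enrichment Triad enrichment of the POLE-like process
#'   (default 300; see [process_spectrum()]).
#' @param placement_weights Per-tranche gene-class placement multipliers
#'   (relative, applied on top of coding length).
#' @param msi_fraction Fraction of common samples driven by the MSI-like
#'   process (default 0.40).
#' @param msi_weight Mixing weight of the MSI-like process within an MSI
#'   sample (default 0.70, so a fitted MSI exposure exceeds the 0.5 flag
#'   cutoff).
#' @param syn_ratio Synonymous records generated per nonsynonymous record
#'   (default 0.25).
#' @param purity Tumour purity scaling all VAFs (default 0.8).
#' @param vaf_pre_shape,vaf_post_shape Beta shapes of pre-/post-onset VAF
#'   (defaults `c(8, 8)` and `c(2, 8)`: clonal pre-onset mutations sit at
#'   higher allele fractions than subclonal post-onset ones).
#' @param tct_density_band,tcg_density_band Allowed canonical-window
#'   density bands for the TCT / TCG motifs in generated sequences.
#' @param expression_effect_delta Expression shift of HR-signature genes
#'   in POLE-category tumours, log2 units (default 1.0).
#' @param noise_sd Expression noise standard deviation (default 0.5, so
#'   the default shift equals two noise SDs).
#' @param n_extra_genes Background genes in the expression matrix
#'   (default 50).
#' @param unpaired_fraction Fraction of tumours without a matched normal
#'   (default 0.05).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pole_samples = 10,
                              n_common_samples = 80,
                              n_nonhyper_samples = 10,
                              n_genes = 414,
                              early_gene_fraction = 0.05,
                              n_background_genes = 3000,
                              gene_length_meanlog = log(1500),
                              gene_length_sdlog = 0.25,
                              pole_snv_range = c(1212, 16632),
                              common_snv_range = c(500, 3000),
                              nonhyper_snv_range = c(50, 400),
                              pre_onset_fraction = 0.10,
                              pole_like_enrichment = 300,
                              placement_weights = list(
                                pre = c(
                                  early = 20, analog = 40,
                                  late = 1, shoulder = 1, background = 1
                                ),
                                post = c(
                                  early = 0.2, analog = 0.2,
                                  late = 24, shoulder = 25,
                                  background = 0.5
                                )
                              ),
                              late_susceptibility_floor = 0.9,
                              late_susceptibility_shape = c(2, 2),
                              early_susceptibility = 0.15,
                              background_susceptibility = 0.3,
                              n_shoulder_genes = 260,
                              shoulder_susceptibility_top = 0.93,
                              shoulder_susceptibility_range = 0.40,
                              msi_fraction = 0.40,
                              msi_weight = 0.70,
                              syn_ratio = 0.25,
                              purity = 0.8,
                              vaf_pre_shape = c(8, 8),
                              vaf_post_shape = c(2, 8),
                              tct_density_band = c(0.005, 0.10),
                              tcg_density_band = c(0.002, 0.10),
                              expression_effect_delta = 1.0,
                              noise_sd = 0.5,
                              n_extra_genes = 50,
                              unpaired_fraction = 0.05) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes >= 1,
    cfg$early_gene_fraction >= 0, cfg$early_gene_fraction <= 1,
    cfg$pre_onset_fraction >= 0, cfg$pre_onset_fraction <= 1,
    cfg$msi_fraction >= 0, cfg$msi_fraction <= 1,
    cfg$msi_weight >= 0, cfg$msi_weight <= 1,
    all(cfg$pole_snv_range > 0), all(cfg$common_snv_range > 0)
  )
  structure(cfg, class = "simulation_config")
}

# canonical-window density of a motif in a sequence
motif_density <- function(sequence, motif) {
  comp <- exon_motif_composition(sequence)
  comp$n[comp$triplet == motif] / sum(comp$n)
}

# generate one sequence honouring the motif-density bands; centre-base
# repair is used to knock down over-dense motifs (e.g. a band of [0, 0]).
generate_sequence <- function(len, cfg) {
  bands <- list(TCT = cfg$tct_density_band, TCG = cfg$tcg_density_band)
  for (attempt in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
      collapse = ""
    )
    for (rep_round in 1:20) {
      dens <- vapply(names(bands), function(m) motif_density(s, m), 0)
      over <- dens > vapply(bands, `[`, 0, 2)
      if (!any(over)) break
      # mutate the centre of offending canonical windows
      chars <- strsplit(s, "")[[1]]
      n <- length(chars)
      win <- substring(s, 1:(n - 2), 3:n)
      centre <- substr(win, 2, 2)
      canon <- ifelse(centre %in% c("A", "G"), revcomp3(win), win)
      for (m in names(bands)[over]) {
        idx <- which(canon == m) + 1
        swap <- sample(c("A", "G"), length(idx), replace = TRUE)
        chars[idx] <- ifelse(chars[idx] %in% c("A", "G"),
          chartr("AG", "TC", chars[idx]), swap
        )
      }
      s <- paste(chars, collapse = "")
    }
    dens <- vapply(names(bands), function(m) motif_density(s, m), 0)
    in_band <- all(
      dens >= vapply(bands, `[`, 0, 1) & dens <= vapply(bands, `[`, 0, 2)
    )
    zero_band <- vapply(bands, function(b) b[2] == 0, TRUE)
    comp <- exon_motif_composition(s)
    complete <- all(comp$n[!comp$triplet %in% names(bands)[zero_band]] > 0 |
      nchar(s) < 300)
    if (in_band && (complete || any(zero_band))) {
      return(s)
    }
  }
  abort("infeasible motif-density constraint: could not generate sequence")
}

#' Generate the synthetic gene pool
#'
#' Builds the focal, sequence-backed genes (with per-gene canonical-motif
#' site indices used for mutation placement) and the wider background gene
#' universe (lengths only). The first two early genes are the POLE and
#' PTEN analogs (`POLE_analog`, long; `PTEN_analog`, short), emulating
#' early-mutated driver genes.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list: `gene_model` (gene, coding_length_nt,
#'   protein_length_aa, class, is_analog), `sequences` (named character
#'   vector, focal genes), `site_index` (per focal gene, canonical triplet
#'   -> centre positions).
#' @export
make_gene_pool <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_genes
  n_early <- max(2, round(config$early_gene_fraction * n))
  classes <- c(rep("early", n_early), rep("late", n - n_early))
  genes <- sprintf("SG%04d", seq_len(n))
  genes[1:2] <- c("POLE_analog", "PTEN_analog")
  is_analog <- genes %in% c("POLE_analog", "PTEN_analog")

  len <- pmax(
    300,
    round(stats::rlnorm(n, config$gene_length_meanlog, config$gene_length_sdlog))
  )
  len[genes == "POLE_analog"] <- 2000   # early driver analog
  len[genes == "PTEN_analog"] <- 1212   # short TSG-sized coding region

  sequences <- setNames(
    vapply(len, function(l) generate_sequence(l, config), ""),
    genes
  )
  site_index <- lapply(sequences, function(s) {
    nchar_s <- nchar(s)
    win <- substring(s, 1:(nchar_s - 2), 3:nchar_s)
    centre <- substr(win, 2, 2)
    canon <- ifelse(centre %in% c("A", "G"), revcomp3(win), win)
    split(2:(nchar_s - 1), canon)
  })

  nb <- config$n_background_genes
  n_sh <- min(config$n_shoulder_genes, nb)
  bg_len <- pmax(300, round(
    stats::rlnorm(nb, config$gene_length_meanlog, config$gene_length_sdlog)
  ))
  gene_model <- tibble(
    gene = c(genes, sprintf("BG%04d", seq_len(nb))),
    coding_length_nt = c(len, bg_len),
    class = c(classes, rep("background", nb)),
    subclass = c(
      ifelse(is_analog, "analog", classes),
      rep(c("shoulder", "background"), c(n_sh, nb - n_sh))
    ),
    is_analog = c(is_analog, rep(FALSE, nb))
  ) %>%
    mutate(protein_length_aa = pmax(1L, as.integer(floor(.data$coding_length_nt / 3))))

  list(
    gene_model = gene_model, sequences = sequences, site_index = site_index
  )
}

# draw mutation rows for one sample tranche (vectorised); when a per-gene
# susceptibility vector is given (post-onset tranche), each mutation's
# process is pole_like with the gene's susceptibility, else background
draw_tranche <- function(n_mut, sample_id, spectra, spectrum_probs,
                         gene_tbl, gene_weights, pre_onset,
                         susceptibility = NULL) {
  if (n_mut <= 0) {
    return(NULL)
  }
  g <- sample(gene_tbl$gene, n_mut, replace = TRUE, prob = gene_weights)
  if (is.null(susceptibility)) {
    proc <- sample(names(spectrum_probs), n_mut,
      replace = TRUE, prob = spectrum_probs
    )
  } else {
    proc <- ifelse(
      runif(n_mut) < susceptibility[g], "pole_like", "background"
    )
  }
  cls_v <- character(n_mut)
  for (p in unique(proc)) {
    i <- proc == p
    cls_v[i] <- sample(names(spectra[[p]]), sum(i),
      replace = TRUE, prob = spectra[[p]]
    )
  }
  tibble(
    sample_id = sample_id, gene = g, class = cls_v, process = proc,
    pre_onset = pre_onset
  )
}

# place rows on concrete sites: focal genes on true motif sites, background
# genes on random positions with a random strand representation
place_rows <- function(rows, pool) {
  triplet <- substr(rows$class, 1, 3)
  alt_canon <- substr(rows$class, 6, 6)
  focal <- rows$gene %in% names(pool$sequences)
  pos <- integer(nrow(rows))
  ctx <- character(nrow(rows))
  ref <- character(nrow(rows))
  alt <- character(nrow(rows))

  if (any(focal)) {
    key <- paste(rows$gene[focal], triplet[focal])
    idx_by_key <- split(which(focal), key)
    for (k in names(idx_by_key)) {
      parts <- strsplit(k, " ", fixed = TRUE)[[1]]
      sites <- pool$site_index[[parts[1]]][[parts[2]]]
      ii <- idx_by_key[[k]]
      if (is.null(sites) || length(sites) == 0) {
        pos[ii] <- NA_integer_
        next
      }
      pos[ii] <- sites[sample.int(length(sites), length(ii), replace = TRUE)]
    }
    ok <- focal & !is.na(pos)
    if (any(ok)) {
      seqs <- pool$sequences[rows$gene[ok]]
      win <- substr(
        substring(seqs, pos[ok] - 1, pos[ok] + 1), 1, 3
      )
      centre <- substr(win, 2, 2)
      as_is <- centre %in% c("C", "T")
      ctx[ok] <- win
      ref[ok] <- centre
      alt[ok] <- ifelse(as_is, alt_canon[ok], comp1(alt_canon[ok]))
    }
  }

  bg <- !focal
  if (any(bg)) {
    len <- pool$bg_lengths[rows$gene[bg]]
    pos[bg] <- 2L + as.integer(floor(runif(sum(bg)) * pmax(1, len - 2)))
    flip <- runif(sum(bg)) < 0.5
    trip_bg <- triplet[bg]
    ctx[bg] <- ifelse(flip, revcomp3(trip_bg), trip_bg)
    ref[bg] <- substr(ctx[bg], 2, 2)
    alt[bg] <- ifelse(flip, comp1(alt_canon[bg]), alt_canon[bg])
  }

  rows$pos <- pos
  rows$context3 <- ctx
  rows$ref <- ref
  rows$alt <- alt
  rows[!is.na(rows$pos), , drop = FALSE]
}

#' Simulate a mutation catalog with ground truth
#'
#' Generates per-sample mutation records for the POLE-category, common
#' hypermutator and non-hypermutator groups. POLE samples draw a clonal
#' pre-onset tranche (background process, placement biased toward early
#' genes) followed by a post-onset tranche (POLE-like process, placement
#' biased toward late genes); common samples mix background and MSI-like
#' processes. Mutations on focal genes are placed on actual canonical
#' motif sites of the synthetic sequences; pre-onset VAFs are drawn higher
#' than post-onset VAFs (clonal ordering). Per-sample nonsynonymous counts
#' hit their drawn targets exactly (positions are re-drawn on collision).
#'
#' @param config A [simulation_config()].
#' @param pool Output of [make_gene_pool()].
#' @param seed Integer seed.
#' @return A list: `catalog` (mutation catalog tibble), `truth` with
#'   `mutations` (per-record process and pre/post-onset flag), `genes`
#'   (per-gene class), `samples` (per-sample group and MSI status).
#' @export
simulate_catalog <- function(config = simulation_config(), pool, seed = 1) {
  set.seed(seed + 1L)
  cfg <- config
  gm <- pool$gene_model
  pool$bg_lengths <- setNames(
    gm$coding_length_nt[gm$class == "background"],
    gm$gene[gm$class == "background"]
  )

  spectra <- list(
    background = process_spectrum("background"),
    pole_like = process_spectrum("pole_like",
      enrichment = cfg$pole_like_enrichment
    ),
    msi_like = process_spectrum("msi_like")
  )

  w_class <- function(tranche) {
    w <- cfg$placement_weights[[tranche]]
    gm$coding_length_nt * as.numeric(w[gm$subclass])
  }
  w_pre <- w_class("pre")
  w_post <- w_class("post")
  w_flat <- gm$coding_length_nt

  susc <- numeric(nrow(gm))
  is_late <- gm$subclass == "late"
  susc[is_late] <- 1 - (1 - cfg$late_susceptibility_floor) *
    rbeta(
      sum(is_late),
      cfg$late_susceptibility_shape[1], cfg$late_susceptibility_shape[2]
    )
  susc[gm$subclass %in% c("early", "analog")] <- cfg$early_susceptibility
  is_sh <- gm$subclass == "shoulder"
  susc[is_sh] <- cfg$shoulder_susceptibility_top -
    cfg$shoulder_susceptibility_range * rbeta(sum(is_sh), 1, 3.5)
  is_bg <- gm$subclass == "background"
  susc[is_bg] <- cfg$background_susceptibility *
    rbeta(sum(is_bg), 2.5, 1)
  susc <- setNames(susc, gm$gene)

  samples <- tibble(
    sample_id = c(
      sprintf("POLE%02d", seq_len(cfg$n_pole_samples)),
      sprintf("COMM%02d", seq_len(cfg$n_common_samples)),
      sprintf("NORM%02d", seq_len(cfg$n_nonhyper_samples))
    ),
    group = c(
      rep("pole_category", cfg$n_pole_samples),
      rep("common_hypermutator", cfg$n_common_samples),
      rep("non_hypermutator", cfg$n_nonhyper_samples)
    )
  )
  samples$msi <- samples$group == "common_hypermutator" &
    runif(nrow(samples)) < cfg$msi_fraction

  draw_count <- function(range, n) {
    as.integer(round(runif(n, range[1], range[2])))
  }
  samples$target_nonsyn <- NA_integer_
  samples$target_nonsyn[samples$group == "pole_category"] <-
    draw_count(cfg$pole_snv_range, cfg$n_pole_samples)
  samples$target_nonsyn[samples$group == "common_hypermutator"] <-
    draw_count(cfg$common_snv_range, cfg$n_common_samples)
  samples$target_nonsyn[samples$group == "non_hypermutator"] <-
    draw_count(cfg$nonhyper_snv_range, cfg$n_nonhyper_samples)

  all_rows <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    grp <- samples$group[si]
    n_nonsyn <- samples$target_nonsyn[si]
    n_total <- n_nonsyn + round(cfg$syn_ratio * n_nonsyn)
    overdraw <- ceiling(n_total * 1.08) + 20

    if (grp == "pole_category") {
      n_pre <- round(overdraw * cfg$pre_onset_fraction)
      rows <- bind_rows(
        draw_tranche(
          n_pre, sid, spectra, c(background = 1),
          gm, w_pre,
          pre_onset = TRUE
        ),
        draw_tranche(
          overdraw - n_pre, sid, spectra, NULL,
          gm, w_post,
          pre_onset = FALSE, susceptibility = susc
        )
      )
    } else {
      probs <- if (samples$msi[si]) {
        c(msi_like = cfg$msi_weight, background = 1 - cfg$msi_weight)
      } else {
        c(background = 1)
      }
      rows <- draw_tranche(
        overdraw, sid, spectra, probs, gm, w_flat,
        pre_onset = NA
      )
    }
    rows <- place_rows(rows, pool)
    rows$chrom <- paste0("chr_", rows$gene)
    rows <- rows[!duplicated(paste(rows$chrom, rows$pos, rows$alt)), ,
      drop = FALSE
    ]
    if (nrow(rows) < n_total) {
      warn(sprintf(
        "sample %s: only %d unique sites for %d requested mutations",
        sid, nrow(rows), n_total
      ))
      n_total <- nrow(rows)
      n_nonsyn <- min(n_nonsyn, n_total)
    }
    rows <- rows[sample.int(nrow(rows), n_total), , drop = FALSE]
    cons <- rep("nonsynonymous", n_total)
    if (n_total > n_nonsyn) {
      cons[sample.int(n_total, n_total - n_nonsyn)] <- "synonymous"
    }
    rows$consequence <- cons
    all_rows[[si]] <- rows
  }
  rows <- bind_rows(all_rows)

  n <- nrow(rows)
  pre <- !is.na(rows$pre_onset) & rows$pre_onset
  post <- !is.na(rows$pre_onset) & !rows$pre_onset
  vaf <- numeric(n)
  vaf[pre] <- rbeta(sum(pre), cfg$vaf_pre_shape[1], cfg$vaf_pre_shape[2])
  vaf[post] <- rbeta(sum(post), cfg$vaf_post_shape[1], cfg$vaf_post_shape[2])
  other <- is.na(rows$pre_onset)
  vaf[other] <- rbeta(sum(other), cfg$vaf_pre_shape[1], cfg$vaf_pre_shape[2])
  rows$vaf <- pmin(1, pmax(0, vaf * cfg$purity))

  rows$depth <- 20L + rpois(n, 80)
  var_reads <- pmax(1L, as.integer(round(rows$depth * rows$vaf)))
  rows$var_plus <- rbinom(n, var_reads, 0.5)
  rows$var_minus <- var_reads - rows$var_plus
  flip <- rows$var_plus == 0 | rows$var_minus == 0
  rows$var_plus[flip] <- pmax(1L, rows$var_plus[flip])
  rows$var_minus[flip] <- pmax(1L, rows$var_minus[flip])
  rows$quality <- round(runif(n, 65, 120), 1)
  rows$clipped_len <- round(runif(n, 120, 200), 1)
  rows$pos_fraction <- round(runif(n, 0.1, 0.9), 3)

  rows$row_id <- seq_len(n)
  catalog <- as_mutation_catalog(
    rows[, catalog_columns()],
    provenance = "polefoot synthetic cohort"
  )
  truth_mut <- rows %>%
    select("row_id", "sample_id", "gene", "class", "process", "pre_onset")

  # clonal ordering must hold per POLE sample
  chk <- truth_mut %>%
    filter(!is.na(.data$pre_onset)) %>%
    mutate(vaf = rows$vaf[.data$row_id]) %>%
    group_by(.data$sample_id, .data$pre_onset) %>%
    summarise(m = mean(.data$vaf), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "pre_onset", values_from = "m")
  if (all(c("TRUE", "FALSE") %in% names(chk)) &&
    any(chk$`FALSE` >= chk$`TRUE`)) {
    abort("generator invariant violated: post-onset VAF not below pre-onset")
  }

  list(
    catalog = catalog,
    truth = list(
      mutations = truth_mut,
      genes = gm %>%
        select("gene", "class", "subclass", "is_analog") %>%
        mutate(susceptibility = unname(susc[.data$gene])),
      samples = samples %>% select("sample_id", "group", "msi")
    )
  )
}

#' The expression gene sets used by the generator and examples
#'
#' Homologous-recombination (HR) and non-homologous end-joining (NHEJ)
#' signature genes, plus a nine-gene HR-restoration panel (TTK and DEPDC1
#' are the members singled out in group comparisons; the remaining panel
#' members are synthetic placeholders).
#'
#' @return Named list of gene-symbol vectors (`HR`, `NHEJ`,
#'   `restoration`).
#' @export
default_gene_sets <- function() {
  list(
    HR = c("BRCA1", "RAD51", "BRCA2", "RAD54L", "RAD52"),
    NHEJ = c("LIG4", "PRKDC", "XRCC4", "XRCC6"),
    restoration = c(
      "TTK", "DEPDC1", "RESG03", "RESG04", "RESG05",
      "RESG06", "RESG07", "RESG08", "RESG09"
    )
  )
}

#' Simulate a paired expression matrix
#'
#' Baseline log2 expression per gene (N(8, 1) across genes) shared by each
#' tumour and its matched normal, plus Gaussian noise (`noise_sd`).
#' HR-signature genes are shifted by `expression_effect_delta` in
#' POLE-category tumours; HR-restoration panel genes by 0.8 of it. The TTK
#' row is regenerated as the per-sample HR-gene mean plus noise, so TTK
#' tracks the HR signature. A configurable fraction of tumours lacks a
#' matched normal (pairing `NA`).
#'
#' @param config A [simulation_config()].
#' @param samples Tibble with `sample_id`, `group` (e.g. the generator's
#'   sample truth).
#' @param seed Integer seed.
#' @return A list: `expr` (gene x sample tibble), `pairing`
#'   (`tumour_id`, `normal_id`), `truth` (per-gene group shift).
#' @export
simulate_expression <- function(config = simulation_config(), samples,
                                seed = 1) {
  set.seed(seed + 2L)
  cfg <- config
  sets <- default_gene_sets()
  genes <- c(
    unlist(sets, use.names = FALSE),
    sprintf("BGX%03d", seq_len(cfg$n_extra_genes))
  )
  genes <- unique(genes)
  ng <- length(genes)

  tumours <- samples$sample_id
  is_pole <- samples$group == "pole_category"
  normals <- paste0("NRM_", tumours)
  unpaired <- runif(length(tumours)) < cfg$unpaired_fraction

  shift <- setNames(numeric(ng), genes)
  shift[sets$HR] <- cfg$expression_effect_delta
  shift[setdiff(sets$restoration, "TTK")] <- 0.8 * cfg$expression_effect_delta

  base <- rnorm(ng, 8, 1)
  tum <- matrix(
    base + rnorm(ng * length(tumours), 0, cfg$noise_sd),
    nrow = ng
  )
  tum <- tum + outer(shift, as.numeric(is_pole))
  nrm <- matrix(
    base + rnorm(ng * length(tumours), 0, cfg$noise_sd),
    nrow = ng
  )
  rownames(tum) <- rownames(nrm) <- genes

  hr_mean <- colMeans(tum[sets$HR, , drop = FALSE])
  tum["TTK", ] <- hr_mean + rnorm(length(tumours), 0, 0.5 * sd(hr_mean))

  expr <- bind_cols(
    tibble(gene = genes),
    as_tibble(tum, .name_repair = ~tumours),
    as_tibble(nrm[, !unpaired, drop = FALSE],
      .name_repair = ~ normals[!unpaired]
    )
  )
  pairing <- tibble(
    tumour_id = tumours,
    normal_id = ifelse(unpaired, NA_character_, normals)
  )
  list(
    expr = expr,
    pairing = pairing,
    truth = tibble(gene = genes, group_shift = unname(shift))
  )
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: gene pool, mutation catalog with truth, and paired
#' expression, all reproducible from one seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list: `pool`, `catalog`, `truth`, `expr`, `pairing`,
#'   `expression_truth`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  pool <- make_gene_pool(config, seed = seed)
  sim <- simulate_catalog(config, pool, seed = seed)
  ex <- simulate_expression(config, sim$truth$samples, seed = seed)
  list(
    pool = pool,
    catalog = sim$catalog,
    truth = sim$truth,
    expr = ex$expr,
    pairing = ex$pairing,
    expression_truth = ex$truth
  )
}

#' Write synthetic inputs to disk
#'
#' Emits the file bundle the readers consume: catalog (tab-delimited
#' dialect), gene model, expression matrix, pairing, gene sets, a
#' three-column signature matrix (the generator's processes), a role
#' table for the analogs, and the ground truth tables.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_inputs <- function(config = simulation_config(), dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config, seed = seed)

  paths <- c(
    catalog = file.path(dir, "catalog.tsv"),
    gene_model = file.path(dir, "gene_model.tsv"),
    expression = file.path(dir, "expression.tsv"),
    pairing = file.path(dir, "pairing.tsv"),
    gene_sets = file.path(dir, "gene_sets.tsv"),
    signatures = file.path(dir, "signature_matrix.tsv"),
    roles = file.path(dir, "roles.tsv"),
    truth_mutations = file.path(dir, "truth_mutations.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv")
  )

  write_mutation_table(sim$catalog, paths["catalog"])
  readr::write_tsv(
    sim$pool$gene_model %>%
      select("gene", "coding_length_nt", "protein_length_aa"),
    paths["gene_model"]
  )
  readr::write_tsv(sim$expr, paths["expression"])
  readr::write_tsv(sim$pairing, paths["pairing"])

  sets <- default_gene_sets()
  readr::write_tsv(
    tibble(
      set = rep(names(sets), lengths(sets)),
      gene = unlist(sets, use.names = FALSE)
    ),
    paths["gene_sets"]
  )
  sig <- tibble(
    class = context_classes(),
    background = unname(process_spectrum("background")),
    pole_like = unname(
      process_spectrum("pole_like", enrichment = config$pole_like_enrichment)
    ),
    msi_like = unname(process_spectrum("msi_like"))
  )
  readr::write_tsv(sig, paths["signatures"])
  readr::write_tsv(
    tibble(
      gene = c("PTEN_analog", "POLE_analog"),
      role = c("TSG", "oncogene")
    ),
    paths["roles"]
  )
  readr::write_tsv(sim$truth$mutations, paths["truth_mutations"])
  readr::write_tsv(sim$truth$genes, paths["truth_genes"])
  readr::write_tsv(sim$truth$samples, paths["truth_samples"])
  invisible(paths)
}
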