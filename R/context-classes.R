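#' The 96 canonical trinucleotide substitution classes
#'
#' Substitution classes are labelled `"XYZ>XWZ"` where `XYZ` is the reference
#' triplet with a pyrimidine (`C` or `T`) centre and `XWZ` the same triplet
#' with the centre replaced by the alternate base. Purine-centred
#' substitutions are reported on the opposite strand, so exactly 96 classes
#' exist. Ordering follows the conventional six substitution types
#' (C>A, C>G, C>T, T>A, T>C, T>G) with the 16 flanking contexts alphabetical
#' within each type, the layout used by mutational-signature matrices.
#'
#' @return Character vector of the 96 class labels.
#' @export
#' @examples
#' head(context_classes())
context_classes <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (ref in c("C", "T")) {
    for (alt in setdiff(bases, ref)) {
      for (left in bases) {
        for (right in bases) {
          out <- c(out, paste0(
            left, ref, right, ">", left, alt, right
          ))
        }
      }
    }
  }
  out
}

#' The 32 pyrimidine-centred reference triplets
#'
#' @return Character vector of the 32 canonical triplets (centre `C` or `T`).
#' @export
canonical_triplets <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (centre in c("C", "T")) {
    for (left in bases) for (right in bases) {
      out <- c(out, paste0(left, centre, right))
    }
  }
  out
}

# vectorised reverse complement of length-3 strings
revcomp3 <- function(x) {
  y <- chartr("ACGT", "TGCA", x)
  paste0(substr(y, 3, 3), substr(y, 2, 2), substr(y, 1, 1))
}

comp1 <- function(x) chartr("ACGT", "TGCA", x)

#' Canonicalize a substitution into its trinucleotide class
#'
#' Maps a reference triplet plus single-base substitution onto one of the 96
#' pyrimidine-centred classes. Purine-centred substitutions (central base
#' `A` or `G`) are reverse-complemented first, so both strand representations
#' of a mutation yield the same class.
#'
#' @param context3 Character vector of reference triplets (read on the
#'   plus strand) centred on the mutated base.
#' @param ref,alt Character vectors of single reference/alternate bases;
#'   `ref` must equal the central base of `context3`.
#' @return Character vector of class labels such as `"TCT>TAT"`.
#' @export
#' @examples
#' canonical_context("AGA", "G", "T")  # reverse-complemented to "TCT>TAT"
#' canonical_context("TCG", "C", "T")
canonical_context <- function(context3, ref, alt) {
  context3 <- toupper(context3)
  ref <- toupper(ref)
  alt <- toupper(alt)
  n <- max(length(context3), length(ref), length(alt))
  context3 <- rep_len(context3, n)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)

  ok_bases <- c("A", "C", "G", "T")
  bad <- !grepl("^[ACGT]{3}$", context3) | !(ref %in% ok_bases) |
    !(alt %in% ok_bases)
  if (any(bad)) {
    abort(sprintf(
      "ambiguous context: non-ACGT base in %d record(s) (first at index %d)",
      sum(bad), which(bad)[1]
    ))
  }
  if (any(substr(context3, 2, 2) != ref)) {
    i <- which(substr(context3, 2, 2) != ref)[1]
    abort(sprintf(
      "ref base '%s' does not match centre of context '%s' (index %d)",
      ref[i], context3[i], i
    ))
  }
  if (any(ref == alt)) {
    abort("ref and alt must differ")
  }

  flip <- ref %in% c("A", "G")
  ctx <- ifelse(flip, revcomp3(context3), context3)
  sub <- ifelse(flip, comp1(alt), alt)
  paste0(ctx, ">", substr(ctx, 1, 1), sub, substr(ctx, 3, 3))
}

#' Propensity mutation classes
#'
#' The two substitution classes treated as POLE-proofreading-deficiency
#' propensity mutations: `TCT>TAT` and `TCG>TTG`. `TTT>TGT`, although also
#' enriched in POLE-mutant tumours, is excluded from propensity scoring
#' because T>G substitutions can arise from dNTP-pool imbalance.
#'
#' @return Character vector of length 2.
#' @export
propensity_classes <- function() {
  c("TCT>TAT", "TCG>TTG")
}
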