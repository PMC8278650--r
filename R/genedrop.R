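#' Monte-Carlo gene dropping with Kalinowski decomposition
#'
#' Drops uniquely labelled founder alleles through the pedigree at a single
#' unlinked locus per replicate.  An individual is autozygous when its two
#' allele labels match.  Allele copies carry a sticky "exposed" flag set
#' whenever the copy resides in an autozygous individual; autozygosity
#' through an already-exposed allele counts as ancestral inbreeding
#' (F_anc_Kal, alleles IBD before), otherwise as new inbreeding (F_new_Kal,
#' IBD for the first time).  A Ballou-style ancestral inbreeding column
#' (probability that either inherited allele was exposed in an ancestor) is
#' reported as well.
#'
#' @param ped A `ped_tbl`.
#' @param n_reps Number of replicates (default 1e5).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Tibble (animal, f_hat, f_new_kal, f_anc_kal, f_anc_ballou,
#'   n_reps, mc_se) where `mc_se = sqrt(f_hat (1 - f_hat) / n_reps)`.
#' @export
gene_drop <- function(ped, n_reps = 1e5, seed = 1) {
  stopifnot(inherits(ped, "ped_tbl"), n_reps >= 1)
  ix <- ped_indices(ped)
  set.seed(as.integer(seed))
  res <- gene_drop_cpp(ix$sire, ix$dam, as.integer(n_reps))
  tibble(animal = ped$animal,
         f_hat = res$f_hat,
         f_new_kal = res$f_new_kal,
         f_anc_kal = res$f_anc_kal,
         f_anc_ballou = res$f_anc_ballou,
         n_reps = as.integer(n_reps),
         mc_se = sqrt(res$f_hat * (1 - res$f_hat) / n_reps))
}

#' Exact gene-dropping probabilities by exhaustive enumeration
#'
#' Enumerates every equally likely transmission pattern (two choices per
#' known-parent meiosis) with the same exposure bookkeeping as [gene_drop()],
#' yielding exact probabilities.  Limited to pedigrees with at most
#' `max_meioses` parent links (default 22, i.e. ~4M patterns).
#'
#' @param ped A `ped_tbl`.
#' @param max_meioses Enumeration size guard.
#' @return Tibble like [gene_drop()] with `mc_se = 0`.
#' @export
exact_drop_small <- function(ped, max_meioses = 22) {
  stopifnot(inherits(ped, "ped_tbl"))
  ix <- ped_indices(ped)
  res <- exact_drop_cpp(ix$sire, ix$dam, as.integer(max_meioses))
  tibble(animal = ped$animal,
         f_hat = res$f_hat,
         f_new_kal = res$f_new_kal,
         f_anc_kal = res$f_anc_kal,
         f_anc_ballou = res$f_anc_ballou,
         n_reps = NA_integer_,
         mc_se = 0)
}
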