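#' Pedigree inbreeding coefficients
#'
#' F for every animal by the Meuwissen-Luo recursive algorithm (the kinship
#' of the two parents; 0 when either parent is unknown).  Animals with an
#' unknown parent are flagged: their F understates true autozygosity and a
#' downstream switch can exclude them from depression analyses.
#'
#' @param ped A `ped_tbl`.
#' @return Tibble (animal, f_ped, incomplete) in pedigree order.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "ped_tbl"))
  ix <- ped_indices(ped)
  tibble(animal = ped$animal,
         f_ped = as.numeric(ml_inbreeding_cpp(ix$sire, ix$dam)),
         incomplete = ix$sire == 0L | ix$dam == 0L)
}

#' Truncated (changing base generation) inbreeding
#'
#' Inbreeding of each focal animal on the pedigree truncated `t` generations
#' above it: every ancestor exactly `t` generations up has both parents set
#' unknown, so only common ancestry within `t` generations contributes.
#' Parents count as generation 1, i.e. `t = 1` leaves only the parents as
#' founders.  When `t >= max_gen(focal)` the result equals the full F.
#'
#' For generation-layered pedigrees (see [is_layered()]) all animals of a
#' cohort share the same truncated pedigree (a global generation cutoff), and
#' F is computed once per cohort with the Meuwissen-Luo sweep; otherwise the
#' literal per-focal truncation is used.
#'
#' @param ped A `ped_tbl`.
#' @param t Number of ancestral generations retained (scalar integer >= 1).
#' @param animals Animal ids to compute (default: all).
#' @return Tibble (animal, f_ped_t).
#' @export
truncated_inbreeding <- function(ped, t, animals = NULL) {
  stopifnot(inherits(ped, "ped_tbl"), length(t) == 1L, t >= 1)
  t <- as.integer(t)
  ids <- animals %||% ped$animal
  miss <- setdiff(ids, ped$animal)
  if (length(miss)) {
    abort(paste0("unknown animal id(s): ", paste(head(miss, 5), collapse = ", ")))
  }
  ix <- ped_indices(ped)
  pos <- match(ids, ped$animal)
  mg <- as.integer(max_gen_cpp(ix$sire, ix$dam))

  out <- numeric(length(ids))
  full_needed <- t >= mg[pos]
  if (any(full_needed)) {
    f_full <- as.numeric(ml_inbreeding_cpp(ix$sire, ix$dam))
    out[full_needed] <- f_full[pos[full_needed]]
  }
  todo <- which(!full_needed)
  if (length(todo)) {
    if (is_layered(ped)) {
      gen <- ped_generation(ped)
      for (g in unique(gen[pos[todo]])) {
        sel <- todo[gen[pos[todo]] == g]
        s2 <- ix$sire
        d2 <- ix$dam
        cut <- gen == g - t
        s2[cut] <- 0L
        d2[cut] <- 0L
        f_t <- as.numeric(ml_inbreeding_cpp(s2, d2))
        out[sel] <- f_t[pos[sel]]
      }
    } else {
      for (k in todo) {
        out[k] <- truncated_f_cpp(ix$sire, ix$dam, pos[k], t)
      }
    }
  }
  tibble(animal = ids, f_ped_t = out)
}

#' Partition pedigree inbreeding into new and old components
#'
#' Changing-base-generation partition: `f_new = F_ped_t` (common ancestry
#' within `t` generations) and `f_old = F_ped - F_ped_t`.  Truncation cannot
#' add ancestral paths, so `f_old >= 0` and `f_new` is non-decreasing in `t`.
#'
#' @param ped A `ped_tbl`.
#' @param t Ancestral-generation threshold (scalar) or vector of thresholds;
#'   with a vector the result is stacked long over thresholds.
#' @param animals Optional subset of animal ids.
#' @return Tibble (animal, f_total, f_new, f_old, method, threshold).
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 40, n_generations = 5,
#'                                     seed = 1))
#' head(partition_pedigree_inbreeding(ped, t = 3))
#' @export
partition_pedigree_inbreeding <- function(ped, t, animals = NULL) {
  stopifnot(all(t >= 1))
  ids <- animals %||% ped$animal
  f_tot <- inbreeding_coefficients(ped)
  f_tot <- f_tot$f_ped[match(ids, f_tot$animal)]
  purrr::map_dfr(as.integer(t), function(tt) {
    f_new <- truncated_inbreeding(ped, tt, ids)$f_ped_t
    tibble(animal = ids,
           f_total = f_tot,
           f_new = f_new,
           f_old = f_tot - f_new,
           method = "pedigree_t",
           threshold = as.numeric(tt))
  })
}
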