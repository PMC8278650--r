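#' Simulate growth-trait phenotypes with age-dependent inbreeding depression
#'
#' Generates `y = mu + sex + year + beta_new * z(f_new) + beta_old * z(f_old)
#' + age_slope * (age - 365) + u + m + pe + e` for every animal at or past
#' `phenotype_min_generation` with both parents known.  Direct (`u`) and
#' maternal (`m`) breeding values follow the pedigree covariance by the
#' Mendelian-sampling recursion; the depression covariates are the supplied
#' truth partition, standardized over the phenotyped animals, so `beta_new`
#' and `beta_old` are in trait units per SD of the true covariates (the
#' default unit-variance trait makes them phenotypic-SD effects).
#'
#' @param ped A `ped_tbl` (with a `generation` column, as produced by
#'   [simulate_pedigree()]).
#' @param truth Partition tibble (animal, f_new, f_old) used as the
#'   generative covariates, e.g. [partition_pedigree_inbreeding()] at
#'   `t_star` or [true_partition()] from simulated genomes.
#' @param cfg A [sim_config()]; variances and effects from `cfg$trait`.
#' @return Phenotype tibble (animal, dam, sex, birth_year, generation, age,
#'   value, f_new_true, f_old_true).
#' @export
simulate_phenotypes <- function(ped, truth, cfg) {
  stopifnot(inherits(ped, "ped_tbl"), inherits(cfg, "sim_config"))
  tr <- cfg$trait
  set.seed(as.integer(cfg$seed) + 2L)
  ix <- ped_indices(ped)
  n <- nrow(ped)
  gen <- if ("generation" %in% names(ped)) ped$generation else
    ped_generation(ped)

  s2u <- tr$h2
  s2m <- tr$m2
  s2p <- tr$pe2
  s2e <- 1 - s2u - s2m - s2p
  if (s2e <= 0) abort("h2 + m2 + pe2 must be < 1")
  f <- ml_inbreeding_cpp(ix$sire, ix$dam)

  bv <- function(s2) {
    if (s2 <= 0) return(numeric(n))
    u <- numeric(n)
    for (i in seq_len(n)) {
      s <- ix$sire[i]; d <- ix$dam[i]
      if (s == 0L && d == 0L) {
        u[i] <- rnorm(1L, 0, sqrt(s2))
      } else {
        pu <- 0
        fs <- if (s > 0L) f[s] else -1
        fd <- if (d > 0L) f[d] else -1
        if (s > 0L) pu <- pu + 0.5 * u[s]
        if (d > 0L) pu <- pu + 0.5 * u[d]
        msv <- (0.5 - 0.25 * (fs + fd)) * s2
        u[i] <- pu + rnorm(1L, 0, sqrt(msv))
      }
    }
    u
  }
  u <- bv(s2u)
  m <- bv(s2m)

  sel <- which(gen >= tr$phenotype_min_generation & ix$sire > 0L & ix$dam > 0L)
  if (!length(sel)) abort("no animals eligible for phenotyping")
  ids <- ped$animal[sel]
  j <- match(ids, truth$animal)
  if (anyNA(j)) abort("truth partition does not cover all phenotyped animals")
  zsafe <- function(x) if (sd(x) < 1e-300) rep(0, length(x)) else standardize(x)
  z_new <- zsafe(truth$f_new[j])
  z_old <- zsafe(truth$f_old[j])

  years <- sort(unique(ped$birth_year[sel]))
  year_eff <- setNames(rnorm(length(years), 0, tr$year_sd), years)
  pe_dam <- setNames(rnorm(n, 0, sqrt(max(s2p, 0))), ped$animal)
  age <- round(rnorm(length(sel), 365, 15))

  y <- tr$mean +
    ifelse(ped$sex[sel] == "M", tr$sex_effect, 0) +
    year_eff[as.character(ped$birth_year[sel])] +
    tr$age_slope * (age - 365) +
    tr$beta_new * z_new + tr$beta_old * z_old +
    u[sel] +
    (if (s2m > 0) m[ix$dam[sel]] else 0) +
    (if (s2p > 0) pe_dam[ped$dam[sel]] else 0) +
    rnorm(length(sel), 0, sqrt(s2e))

  tibble(animal = ids,
         dam = ped$dam[sel],
         sex = ped$sex[sel],
         birth_year = ped$birth_year[sel],
         generation = gen[sel],
         age = age,
         value = unname(y),
         f_new_true = truth$f_new[j],
         f_old_true = truth$f_old[j])
}

#' Simulate a complete herd: pedigree, truth partition and phenotypes
#'
#' Convenience wrapper for the depression test bed: simulates the pedigree,
#' takes the changing-base-generation partition at the true boundary
#' `cfg$trait$t_star` as the generative truth, and simulates phenotypes.
#' (For genomic ground truth use [simulate_genomes()] + [true_partition()]
#' instead.)
#'
#' @param cfg A [sim_config()].
#' @return List (pedigree, truth, phenotypes, config).
#' @export
simulate_herd <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  truth <- partition_pedigree_inbreeding(ped, cfg$trait$t_star)
  phen <- simulate_phenotypes(ped, truth, cfg)
  list(pedigree = ped, truth = truth, phenotypes = phen, config = cfg)
}
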