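#' Configuration for the synthetic closed-herd test bed
#'
#' The simulator emulates a small closed beef herd with deep, complete
#' pedigree records: discrete generations, equal-sized cohorts, managed
#' matings that avoid close kin, a 29-autosome SNP panel at ~80 kb spacing
#' with recombination at 1 cM/Mb, and growth-trait phenotypes in which
#' recent autozygosity is more harmful than old autozygosity.
#'
#' Key default choices (see the methods vignette for the rationale): matings
#' reject pairs sharing a common ancestor within `avoid_kin_depth = 4`
#' generations above the prospective offspring, so autozygosity variation
#' starts at coalescence depth 5 and the true trait boundary `t_star = 6`
#' splits identifiable recent variation (depths 5-6) from older background
#' (7+).  The trait is on a unit phenotypic-SD scale with direct heritability
#' 0.35 and depression effects -0.8 / -0.2 per SD of the true new / old
#' covariates.
#'
#' @param n_founders Founder cohort size (half male, half female).
#' @param n_generations Number of discrete generations bred after the
#'   founders.
#' @param offspring_per_mating Offspring per mating; matings per generation
#'   keep the cohort size at `n_founders`.
#' @param consanguinity_rate Probability a mating deliberately pairs close
#'   relatives drawn from `consanguinity_mix`.
#' @param consanguinity_mix Named weights over `full_sib`, `half_sib`,
#'   `first_cousin` for deliberate consanguineous matings.
#' @param avoid_kin_depth Random matings reject pairs sharing a common
#'   ancestor within this many generations above the offspring (0 disables).
#' @param n_chromosomes,chrom_length_mb,marker_spacing_kb SNP panel layout.
#' @param cm_per_mb Recombination rate (centiMorgan per Mb).
#' @param maf_beta_shape1,maf_beta_shape2,maf_min Founder allele frequencies
#'   are Beta(shape1, shape2) truncated below at `maf_min`, so chance
#'   homozygosity exists and short ROH are imperfect IBD proxies.
#' @param trait List of trait-model settings: `name`, `mean`, `sex_effect`,
#'   `year_sd`, `age_slope`, `h2` (direct), `m2` (maternal genetic), `pe2`
#'   (maternal permanent environment), `t_star` (true age boundary,
#'   generations), `beta_new`, `beta_old` (per SD of the true covariates),
#'   `phenotype_min_generation`.
#' @param seed Integer seed; every simulator operation is deterministic
#'   given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 280,
                       n_generations = 12,
                       offspring_per_mating = 2,
                       consanguinity_rate = 0,
                       consanguinity_mix = c(full_sib = 0.2, half_sib = 0.4,
                                             first_cousin = 0.4),
                       avoid_kin_depth = 4,
                       n_chromosomes = 29,
                       chrom_length_mb = 100,
                       marker_spacing_kb = 80,
                       cm_per_mb = 1,
                       maf_beta_shape1 = 0.5,
                       maf_beta_shape2 = 0.5,
                       maf_min = 0.05,
                       trait = list(),
                       seed = 1) {
  trait_def <- list(name = "yw", mean = 10, sex_effect = 0.4, year_sd = 0.3,
                    age_slope = 0.02, h2 = 0.35, m2 = 0, pe2 = 0,
                    t_star = 6, beta_new = -0.8, beta_old = -0.2,
                    phenotype_min_generation = 6)
  trait <- utils::modifyList(trait_def, trait)
  stopifnot(consanguinity_rate >= 0, consanguinity_rate <= 1,
            n_founders >= 4, n_generations >= 1, offspring_per_mating >= 1,
            marker_spacing_kb > 0, trait$t_star < n_generations + 1)
  structure(list(n_founders = n_founders, n_generations = n_generations,
                 offspring_per_mating = offspring_per_mating,
                 consanguinity_rate = consanguinity_rate,
                 consanguinity_mix = consanguinity_mix,
                 avoid_kin_depth = avoid_kin_depth,
                 n_chromosomes = n_chromosomes,
                 chrom_length_mb = chrom_length_mb,
                 marker_spacing_kb = marker_spacing_kb,
                 cm_per_mb = cm_per_mb,
                 maf_beta_shape1 = maf_beta_shape1,
                 maf_beta_shape2 = maf_beta_shape2,
                 maf_min = maf_min,
                 trait = trait, seed = seed),
            class = "sim_config")
}

#' Simulate a closed-herd pedigree
#'
#' Discrete generations: the founder cohort is generation 0; each later
#' generation is bred from matings within the previous one.  With
#' probability `consanguinity_rate` a mating pairs close relatives (type
#' drawn from `consanguinity_mix`); otherwise mates are drawn at random,
#' rejecting pairs that share a common ancestor within `avoid_kin_depth`
#' generations above the prospective offspring.
#'
#' @param cfg A [sim_config()].
#' @return A `ped_tbl` with a `generation` column (`birth_year` = 2000 +
#'   generation).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed))
  nf <- cfg$n_founders
  # matings per generation keep the cohort size at ~ n_founders
  n_mat <- max(1L, floor(nf / cfg$offspring_per_mating))
  sample1 <- function(x) x[sample.int(length(x), 1L)]

  id <- function(g, i) sprintf("G%02d_%04d", g, i)
  rows <- list()
  rows[[1L]] <- tibble(animal = id(0L, seq_len(nf)),
                       sire = NA_character_, dam = NA_character_,
                       sex = rep(c("M", "F"), length.out = nf),
                       birth_year = 2000L, generation = 0L)
  # parent index bookkeeping for kin checks (positions in growing table)
  all_sire <- rep(0L, nf)
  all_dam <- rep(0L, nf)
  offset <- 0L

  anc_set <- function(i, depth) {
    # ancestors of animal position i within `depth` generations (inclusive)
    cur <- i
    out <- integer(0)
    for (d in seq_len(depth)) {
      nxt <- unique(c(all_sire[cur], all_dam[cur]))
      nxt <- nxt[nxt > 0L]
      if (!length(nxt)) break
      out <- c(out, nxt)
      cur <- nxt
    }
    unique(out)
  }

  pick_consang <- function(males, females, type) {
    # returns c(sire_pos, dam_pos) of the requested relationship, or NULL
    for (try in seq_len(50L)) {
      m <- sample1(males)
      rel <- switch(type,
        full_sib = {
          f <- females[all_sire[females] == all_sire[m] &
                         all_dam[females] == all_dam[m] &
                         all_sire[m] > 0L & all_dam[m] > 0L]
          f
        },
        half_sib = {
          f <- females[(all_sire[females] == all_sire[m] &
                          all_sire[m] > 0L) !=
                         (all_dam[females] == all_dam[m] & all_dam[m] > 0L)]
          f
        },
        first_cousin = {
          gm <- anc_set(m, 2L)
          gm <- setdiff(gm, anc_set(m, 1L))
          f <- females[vapply(females, function(ff) {
            gf <- setdiff(anc_set(ff, 2L), anc_set(ff, 1L))
            length(intersect(gf, gm)) > 0L &&
              !length(intersect(anc_set(ff, 1L), anc_set(m, 1L)))
          }, TRUE)]
          f
        })
      if (length(rel)) return(c(m, sample1(rel)))
    }
    NULL
  }

  for (g in seq_len(cfg$n_generations)) {
    prev <- which(rows[[g]]$sex == "M") + offset
    prev_f <- which(rows[[g]]$sex == "F") + offset
    if (!length(prev) || !length(prev_f)) {
      abort("population extinct: a cohort lacks one sex; increase n_founders")
    }
    sires <- integer(n_mat)
    dams <- integer(n_mat)
    for (k in seq_len(n_mat)) {
      pair <- NULL
      if (runif(1) < cfg$consanguinity_rate) {
        type <- sample(names(cfg$consanguinity_mix), 1L,
                       prob = cfg$consanguinity_mix)
        pair <- pick_consang(prev, prev_f, type)
      }
      if (is.null(pair)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          m <- sample1(prev)
          f <- sample1(prev_f)
          if (cfg$avoid_kin_depth > 0L) {
            # common ancestor within avoid_kin_depth above the OFFSPRING:
            # parents' ancestor sets within avoid_kin_depth - 1, plus the
            # parents themselves
            d <- cfg$avoid_kin_depth - 1L
            am <- c(m, if (d > 0L) anc_set(m, d))
            af <- c(f, if (d > 0L) anc_set(f, d))
            if (length(intersect(am, af))) next
          }
          ok <- TRUE
          break
        }
        if (!ok) {
          abort("population extinct: no mating satisfies the kin-avoidance rule; increase n_founders")
        }
        pair <- c(m, f)
      }
      sires[k] <- pair[1L]
      dams[k] <- pair[2L]
    }
    n_off <- n_mat * cfg$offspring_per_mating
    offset <- offset + nrow(rows[[g]])
    rows[[g + 1L]] <- tibble(
      animal = id(g, seq_len(n_off)),
      sire = rows_animal(rows, rep(sires, each = cfg$offspring_per_mating)),
      dam = rows_animal(rows, rep(dams, each = cfg$offspring_per_mating)),
      sex = sample(rep(c("M", "F"), length.out = n_off)),
      birth_year = 2000L + g, generation = g)
    all_sire <- c(all_sire, rep(sires, each = cfg$offspring_per_mating))
    all_dam <- c(all_dam, rep(dams, each = cfg$offspring_per_mating))
  }
  df <- dplyr::bind_rows(rows)
  ped <- pedigree(df[, c("animal", "sire", "dam", "sex", "birth_year")])
  ped$generation <- df$generation[match(ped$animal, df$animal)]
  new_ped_tbl(ped)
}

# id lookup across the growing list of cohort tibbles
rows_animal <- function(rows, pos) {
  all <- unlist(lapply(rows, function(r) r$animal), use.names = FALSE)
  all[pos]
}
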