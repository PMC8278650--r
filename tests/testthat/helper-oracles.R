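# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force / enumerative and shares no
# code path with the package internals it checks.

toy_ped <- function() {
  pedigree(data.frame(animal = c("g1", "g2", "s", "d", "x"),
                      sire = c(0, 0, "g1", "g1", "s"),
                      dam = c(0, 0, "g2", "g2", "d")))
}

# random valid pedigree: n animals, each non-founder draws parents among
# earlier animals (possibly unknown)
random_pedigree <- function(n, p_founder = 0.2, seed = 1) {
  set.seed(seed)
  sire <- dam <- character(n)
  for (i in seq_len(n)) {
    if (i <= 2 || runif(1) < p_founder) {
      sire[i] <- "0"
      dam[i] <- "0"
    } else {
      sire[i] <- paste0("a", sample.int(i - 1L, 1L))
      dam[i] <- paste0("a", sample.int(i - 1L, 1L))
      if (sire[i] == dam[i]) dam[i] <- "0"  # no selfing
    }
  }
  pedigree(data.frame(animal = paste0("a", seq_len(n)), sire = sire,
                      dam = dam))
}

# exhaustive ancestor-path enumeration: ECG = sum over all distinct paths
# to known ancestors of (1/2)^path_length
ecg_oracle <- function(ped, animal) {
  si <- attr(ped, "sire_idx")
  di <- attr(ped, "dam_idx")
  total <- 0
  rec <- function(i, depth) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        total <<- total + 0.5^(depth + 1L)
        rec(p, depth + 1L)
      }
    }
  }
  rec(match(animal, ped$animal), 0L)
  total
}

# exhaustive maximal-run ROH oracle for one chromosome vector
# calls: 0 hom, 1 het, 2 missing; returns start/end indices + counts
roh_oracle <- function(calls, pos, params) {
  n <- length(calls)
  ch <- cumsum(calls == 1)
  cm <- cumsum(calls == 2)
  nh <- function(i, j) ch[j] - if (i > 1) ch[i - 1] else 0
  nm <- function(i, j) cm[j] - if (i > 1) cm[i - 1] else 0
  gap_ok <- c(diff(pos) <= params$max_gap_bp, TRUE)
  feas <- function(i, j) {
    nh(i, j) <= params$max_het_per_segment &&
      nm(i, j) <= params$max_missing_per_segment &&
      (j == i || all(gap_ok[i:(j - 1)]))
  }
  cand <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!feas(i, j)) break  # feasibility monotone in j for fixed i
      cand <- rbind(cand, c(i, j))
    }
  }
  if (is.null(cand)) return(NULL)
  # maximal: no feasible strict superset (extension by one suffices given
  # monotonicity, but test the general containment definition)
  maximal <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    !((i > 1 && feas(i - 1, j)) || (j < n && feas(i, j + 1)))
  }, TRUE)
  cand <- cand[maximal, , drop = FALSE]
  keep <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    len <- pos[j] - pos[i]
    nsnp <- j - i + 1
    nsnp >= params$min_snps && len >= params$min_length_bp &&
      len / nsnp <= params$min_density_bp_per_snp
  }, TRUE)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  # greedy non-overlap: longest first, leftmost on ties
  len <- pos[cand[, 2]] - pos[cand[, 1]]
  ord <- order(-len, cand[, 1])
  chosen <- NULL
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (is.null(chosen) ||
        !any(i <= chosen[, 2] & j >= chosen[, 1])) {
      chosen <- rbind(chosen, c(i, j))
    }
  }
  chosen[order(chosen[, 1]), , drop = FALSE]
}

# wrap a single-chromosome call vector in a geno_set
geno1 <- function(calls, pos, id = "s1") {
  g <- matrix(NA_integer_, 1L, length(calls))
  g[1, calls == 0] <- 0L   # hom
  g[1, calls == 1] <- 1L   # het
  # calls == 2 stays NA (missing)
  genotypes(g, tibble::tibble(marker = paste0("m", seq_along(pos)),
                              chromosome = 1L, position_bp = pos),
            samples = id)
}

# small herd config for fast model tests
small_herd_cfg <- function(seed, ...) {
  sim_config(n_founders = 60, n_generations = 8,
             trait = list(phenotype_min_generation = 5, ...), seed = seed)
}
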