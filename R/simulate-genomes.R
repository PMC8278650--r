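#' Simulate genomes by linked gene dropping with recombination
#'
#' Founders carry uniquely labelled haplotypes; each meiosis places
#' crossovers by a Poisson process at `cm_per_mb` (Haldane, no interference)
#' and transmits a mosaic of the parent's two haplotypes.  An interval where
#' an individual's two haplotypes descend from the same founder haplotype is
#' a true autozygous segment; it is annotated with the number of generations
#' back to the coalescing common-ancestor haplotype by tracing both allele
#' lineages up through the recorded meioses in lockstep (the annotation
#' assumes a generation-layered pedigree, which [simulate_pedigree()]
#' guarantees).  SNP genotypes are derived by assigning founder-haplotype
#' alleles (frequencies from the truncated Beta model) at markers spaced
#' `marker_spacing_kb` apart.
#'
#' @param ped A `ped_tbl`, typically from [simulate_pedigree()].
#' @param cfg A [sim_config()].
#' @param markers If `FALSE`, skip genotype synthesis and return tracks only
#'   (faster when only the IBD ground truth is needed).
#' @param track_animals Animal ids to extract IBD tracks for (default: all
#'   non-founders).
#' @return List with `tracks` (tibble animal, chromosome, start_bp, end_bp,
#'   length_bp, coalescence_generation), `genotypes` (a `geno_set`, or
#'   `NULL`), and `genome_length_bp`.
#' @export
simulate_genomes <- function(ped, cfg, markers = TRUE, track_animals = NULL) {
  stopifnot(inherits(ped, "ped_tbl"), inherits(cfg, "sim_config"))
  if (!is_layered(ped)) {
    warn("pedigree is not generation-layered; coalescence ages may be unreliable")
  }
  set.seed(as.integer(cfg$seed) + 1L)
  ix <- ped_indices(ped)
  n <- nrow(ped)
  L <- cfg$chrom_length_mb * 1e6
  nchr <- cfg$n_chromosomes
  morgans <- cfg$chrom_length_mb * cfg$cm_per_mb / 100
  track_ids <- track_animals %||% ped$animal[ix$sire > 0L | ix$dam > 0L]
  track_pos <- match(track_ids, ped$animal)

  # per chromosome: meiosis mosaics and founder-descent tracks
  all_tracks <- vector("list", nchr)
  geno_chr <- vector("list", nchr)
  map_chr <- vector("list", nchr)
  n_founder_haps <- 0L

  for (ch in seq_len(nchr)) {
    mei <- vector("list", n)    # per ind: list(h1 = (bp, par), h2 = ...)
    trk <- vector("list", n)    # per ind: list(h1 = (bp, lab), h2 = ...)
    next_lab <- 0L  # founder-haplotype labels are per-chromosome
    new_founder_hap <- function() {
      next_lab <<- next_lab + 1L
      list(bp = L, lab = next_lab)
    }
    meiosis <- function() {
      k <- rpois(1L, morgans)
      xo <- if (k) sort(runif(k, 0, L)) else numeric(0)
      start <- sample.int(2L, 1L)
      list(bp = c(xo, L),
           par = rep(c(start, 3L - start), length.out = k + 1L))
    }
    compose <- function(m, t1, t2) {
      out_bp <- numeric(0)
      out_lab <- integer(0)
      prev <- 0
      for (s in seq_along(m$bp)) {
        end <- m$bp[s]
        if (end <= prev) next
        tr <- if (m$par[s] == 1L) t1 else t2
        i1 <- findInterval(prev, tr$bp) + 1L    # first end > prev
        i2 <- which.max(tr$bp >= end)           # first end >= end
        ends <- tr$bp[i1:i2]
        ends[length(ends)] <- end
        out_bp <- c(out_bp, ends)
        out_lab <- c(out_lab, tr$lab[i1:i2])
        prev <- end
      }
      # merge adjacent equal labels
      if (length(out_lab) > 1L) {
        keep <- c(out_lab[-length(out_lab)] != out_lab[-1L], TRUE)
        out_bp <- out_bp[keep]
        out_lab <- out_lab[keep]
      }
      list(bp = out_bp, lab = out_lab)
    }
    for (i in seq_len(n)) {
      hm <- list(NULL, NULL)
      ht <- list(NULL, NULL)
      pars <- c(ix$sire[i], ix$dam[i])
      for (k in 1:2) {
        p <- pars[k]
        if (p == 0L) {
          ht[[k]] <- new_founder_hap()
        } else {
          m <- meiosis()
          hm[[k]] <- m
          ht[[k]] <- compose(m, trk[[p]][[1L]], trk[[p]][[2L]])
        }
      }
      mei[[i]] <- hm
      trk[[i]] <- ht
    }
    if (ch == 1L) n_founder_haps <- next_lab

    # ascend one generation: pieces of (lo, hi] mapped through a meiosis
    ascend <- function(ind, hap, lo, hi) {
      p <- if (hap == 1L) ix$sire[ind] else ix$dam[ind]
      m <- mei[[ind]][[hap]]
      if (p == 0L || is.null(m)) return(NULL)  # founder haplotype
      i1 <- findInterval(lo, m$bp) + 1L
      i2 <- which.max(m$bp >= hi)
      ends <- m$bp[i1:i2]
      ends[length(ends)] <- hi
      los <- c(lo, ends[-length(ends)])
      list(lo = los, hi = ends, ind = rep(p, length(ends)),
           hap = m$par[i1:i2])
    }
    # `sig` accumulates the two lineage chains (the loop below the common
    # ancestor); pieces of one tract split by breakpoints ABOVE the meeting
    # node share the signature and are re-merged afterwards, while a real
    # crossover in the loop changes the signature and ends the tract.
    trace <- function(i1, h1, i2, h2, lo, hi, depth, sig) {
      if (i1 == i2 && h1 == h2) {
        return(list(list(lo = lo, hi = hi, g = depth, sig = sig)))
      }
      a1 <- ascend(i1, h1, lo, hi)
      a2 <- ascend(i2, h2, lo, hi)
      if (is.null(a1) || is.null(a2)) return(list())  # hit founders unequal
      out <- list()
      for (u in seq_along(a1$lo)) {
        for (v in seq_along(a2$lo)) {
          l <- max(a1$lo[u], a2$lo[v])
          h <- min(a1$hi[u], a2$hi[v])
          if (l < h) {
            out <- c(out, trace(a1$ind[u], a1$hap[u], a2$ind[v], a2$hap[v],
                                l, h, depth + 1L,
                                paste(sig, a1$ind[u], a1$hap[u],
                                      a2$ind[v], a2$hap[v])))
          }
        }
      }
      out
    }

    # IBD intervals per tracked animal: equal founder labels, then age
    res <- vector("list", length(track_pos))
    for (j in seq_along(track_pos)) {
      i <- track_pos[j]
      t1 <- trk[[i]][[1L]]
      t2 <- trk[[i]][[2L]]
      bps <- sort(unique(c(t1$bp, t2$bp)))
      los <- c(0, bps[-length(bps)])
      l1 <- t1$lab[findInterval(los, t1$bp) + 1L]
      l2 <- t2$lab[findInterval(los, t2$bp) + 1L]
      eq <- l1 == l2
      if (!any(eq)) next
      segs <- list()
      for (s in which(eq)) {
        segs <- c(segs, trace(i, 1L, i, 2L, los[s], bps[s], 0L, ""))
      }
      if (!length(segs)) next
      d <- tibble(animal = ped$animal[i],
                  lo = vapply(segs, `[[`, 0, "lo"),
                  hi = vapply(segs, `[[`, 0, "hi"),
                  g = vapply(segs, function(x) as.numeric(x$g), 0),
                  sig = vapply(segs, `[[`, "", "sig"))
      res[[j]] <- d
    }
    tr_ch <- dplyr::bind_rows(res)
    if (nrow(tr_ch)) {
      # merge contiguous pieces of the same tract (equal coalescence path);
      # remaining boundaries are genuine crossovers in the autozygosity loop
      tr_ch <- tr_ch |>
        dplyr::arrange(.data$animal, .data$lo) |>
        dplyr::group_by(.data$animal) |>
        dplyr::mutate(brk = cumsum(
          c(TRUE, .data$lo[-1L] > .data$hi[-dplyr::n()] + 1e-6 |
              .data$sig[-1L] != .data$sig[-dplyr::n()]))) |>
        dplyr::group_by(.data$animal, .data$brk) |>
        dplyr::summarise(lo = min(.data$lo), hi = max(.data$hi),
                         g = .data$g[1L], .groups = "drop") |>
        dplyr::arrange(.data$animal, .data$lo) |>
        dplyr::transmute(animal = .data$animal, chromosome = ch,
                         start_bp = .data$lo, end_bp = .data$hi,
                         length_bp = .data$hi - .data$lo,
                         coalescence_generation = .data$g)
    }
    all_tracks[[ch]] <- tr_ch

    if (markers) {
      mpos <- seq(cfg$marker_spacing_kb * 1e3 / 2, L,
                  by = cfg$marker_spacing_kb * 1e3)
      m <- length(mpos)
      # truncated-Beta allele frequencies (minor allele >= maf_min)
      q <- rbeta(m, cfg$maf_beta_shape1, cfg$maf_beta_shape2)
      bad <- pmin(q, 1 - q) < cfg$maf_min
      while (any(bad)) {
        q[bad] <- rbeta(sum(bad), cfg$maf_beta_shape1, cfg$maf_beta_shape2)
        bad <- pmin(q, 1 - q) < cfg$maf_min
      }
      H <- matrix(rbinom(next_lab * m, 1L, rep(q, each = next_lab)),
                  nrow = next_lab)
      calls <- matrix(0L, nrow = length(track_pos), ncol = m)
      for (j in seq_along(track_pos)) {
        i <- track_pos[j]
        f1 <- trk[[i]][[1L]]$lab[findInterval(mpos, trk[[i]][[1L]]$bp,
                                              left.open = TRUE) + 1L]
        f2 <- trk[[i]][[2L]]$lab[findInterval(mpos, trk[[i]][[2L]]$bp,
                                              left.open = TRUE) + 1L]
        calls[j, ] <- H[cbind(f1, seq_len(m))] + H[cbind(f2, seq_len(m))]
      }
      geno_chr[[ch]] <- calls
      map_chr[[ch]] <- tibble(marker = sprintf("snp%d_%d", ch, seq_len(m)),
                              chromosome = ch, position_bp = mpos)
    }
  }

  tracks <- dplyr::bind_rows(all_tracks)
  if (!nrow(tracks)) {
    tracks <- tibble(animal = character(), chromosome = integer(),
                     start_bp = numeric(), end_bp = numeric(),
                     length_bp = numeric(), coalescence_generation = numeric())
  }
  geno <- NULL
  if (markers) {
    geno <- genotypes(do.call(cbind, geno_chr), dplyr::bind_rows(map_chr),
                      samples = track_ids)
  }
  list(tracks = tracks, genotypes = geno,
       genome_length_bp = nchr * L)
}

#' Ground-truth partition of autozygosity by coalescence age
#'
#' New inbreeding is the genome fraction in true IBD segments coalescing at
#' most `t_star` generations back; old inbreeding the remainder of the true
#' autozygous fraction.
#'
#' @param tracks Track tibble from [simulate_genomes()].
#' @param t_star Age boundary in generations (>= 0).
#' @param l_auto_bp Genome length denominator (e.g. `genome_length_bp`).
#' @param animals Animal ids to report (default: those present in `tracks`).
#' @return Tibble (animal, f_total, f_new, f_old, method, threshold).
#' @export
true_partition <- function(tracks, t_star, l_auto_bp, animals = NULL) {
  stopifnot(t_star >= 0, l_auto_bp > 0)
  animals <- animals %||% unique(tracks$animal)
  sums <- tracks |>
    dplyr::group_by(animal = .data$animal) |>
    dplyr::summarise(
      new = sum(.data$length_bp[.data$coalescence_generation <= t_star]),
      tot = sum(.data$length_bp), .groups = "drop")
  j <- match(animals, sums$animal)
  f_new <- dplyr::coalesce(sums$new[j], 0) / l_auto_bp
  f_tot <- dplyr::coalesce(sums$tot[j], 0) / l_auto_bp
  tibble(animal = animals, f_total = f_tot, f_new = f_new,
         f_old = f_tot - f_new, method = "true_ibd",
         threshold = as.numeric(t_star))
}
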