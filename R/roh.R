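#' ROH detection parameters
#'
#' Defaults follow common medium-density panel practice: minimum segment
#' length 1 Mb with at least 15 SNPs, at most two heterozygous and five
#' missing calls per segment, no gap above 500 kb between adjacent SNPs
#' inside a segment, and a density of at least one SNP per 500 kb.
#'
#' @param min_length_bp Minimum segment length (end - start), bp.
#' @param min_snps Minimum number of SNPs in a segment.
#' @param max_het_per_segment Maximum heterozygous calls tolerated.
#' @param max_missing_per_segment Maximum missing calls tolerated.
#' @param max_gap_bp Maximum gap between adjacent SNPs inside a segment.
#' @param min_density_bp_per_snp Maximum bp per SNP (length / n_snps).
#' @return A `roh_params` list.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 15,
                       max_het_per_segment = 2, max_missing_per_segment = 5,
                       max_gap_bp = 5e5, min_density_bp_per_snp = 5e5) {
  p <- list(min_length_bp = min_length_bp, min_snps = min_snps,
            max_het_per_segment = max_het_per_segment,
            max_missing_per_segment = max_missing_per_segment,
            max_gap_bp = max_gap_bp,
            min_density_bp_per_snp = min_density_bp_per_snp)
  if (any(unlist(p) < 0) || min_length_bp < 1) {
    abort("roh_params must be positive")
  }
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Deterministic maximal-run scan: per animal and chromosome, all maximal
#' marker runs that respect the heterozygote, missing-call and gap budgets
#' are found, filtered by minimum SNP count, minimum length and SNP density,
#' and reduced to a non-overlapping set (longest kept first).  Segment bounds
#' are the first and last marker positions of the run.  This is the same set
#' of constraints as the PLINK sliding-window screen but reproducible and
#' oracle-testable; the windowed heuristic's window size/hit-rate knobs are
#' deliberately not emulated.
#'
#' @param data A `geno_set`.
#' @param params A [roh_params()] list.
#' @return A `roh_set`: tibble (animal, chromosome, start_bp, end_bp,
#'   length_bp, n_snps, n_het, n_missing) with attributes `l_auto_bp` (sum of
#'   per-chromosome SNP spans), `samples` and `params`.
#' @export
detect_roh <- function(data, params = roh_params()) {
  stopifnot(inherits(data, "geno_set"), inherits(params, "roh_params"))
  spans <- panel_span(data)
  chroms <- spans$chromosome
  out <- vector("list", length(chroms) * length(data$samples))
  k <- 0L
  for (ch in chroms) {
    sel <- data$map$chromosome == ch
    pos <- data$map$position_bp[sel]
    sub <- data$calls[, sel, drop = FALSE]
    for (i in seq_along(data$samples)) {
      g <- sub[i, ]
      cc <- ifelse(is.na(g), 2L, ifelse(g == 1L, 1L, 0L))
      runs <- roh_scan_cpp(cc, pos,
                           params$min_length_bp, params$min_snps,
                           params$max_het_per_segment,
                           params$max_missing_per_segment,
                           params$max_gap_bp, params$min_density_bp_per_snp)
      if (nrow(runs)) {
        k <- k + 1L
        out[[k]] <- tibble(
          animal = data$samples[i], chromosome = ch,
          start_bp = pos[runs[, 1L]], end_bp = pos[runs[, 2L]],
          n_snps = runs[, 3L], n_het = runs[, 4L], n_missing = runs[, 5L])
      }
    }
  }
  segs <- if (k) dplyr::bind_rows(out[seq_len(k)]) else
    tibble(animal = character(), chromosome = integer(),
           start_bp = numeric(), end_bp = numeric(),
           n_snps = integer(), n_het = integer(), n_missing = integer())
  segs <- segs |>
    dplyr::mutate(length_bp = .data$end_bp - .data$start_bp,
                  .after = "end_bp") |>
    dplyr::arrange(.data$animal, .data$chromosome, .data$start_bp)
  roh_set(segs, l_auto_bp = sum(spans$span_bp), samples = data$samples,
          params = params)
}

#' Construct an ROH segment set
#'
#' @param segments Tibble of segments (animal, chromosome, start_bp, end_bp,
#'   length_bp, ...).
#' @param l_auto_bp SNP-covered autosomal length (denominator of F_ROH).
#' @param samples All analysed sample ids (so animals without segments keep
#'   F_ROH = 0 rather than dropping out).
#' @param params Optional `roh_params` provenance.
#' @return A `roh_set` tibble.
#' @export
roh_set <- function(segments, l_auto_bp, samples = unique(segments$animal),
                    params = NULL) {
  segments <- as_tibble(segments)
  if (!"length_bp" %in% names(segments)) {
    segments$length_bp <- segments$end_bp - segments$start_bp
  }
  if (l_auto_bp <= 0) abort("l_auto_bp must be positive")
  if (nrow(segments) && any(segments$length_bp > l_auto_bp)) {
    abort("segment longer than l_auto_bp")
  }
  structure(segments, l_auto_bp = as.numeric(l_auto_bp),
            samples = as.character(samples), params = params,
            class = c("roh_set", class(tibble())))
}

#' ROH-based inbreeding coefficient
#'
#' F_ROH = sum of segment lengths / L_AUTO per animal; animals without
#' segments get 0.
#'
#' @param rohs A `roh_set`.
#' @return Tibble (animal, f_roh).
#' @export
roh_inbreeding <- function(rohs) {
  stopifnot(inherits(rohs, "roh_set"))
  l_auto <- attr(rohs, "l_auto_bp")
  samples <- attr(rohs, "samples")
  sums <- tibble(animal = rohs$animal, length_bp = rohs$length_bp) |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(total = sum(.data$length_bp), .groups = "drop")
  tibble(animal = samples,
         f_roh = dplyr::coalesce(sums$total[match(samples, sums$animal)], 0) /
           l_auto)
}

#' Partition ROH inbreeding into short (old) and long (new) components
#'
#' Segments at least `m_mb` megabases long are "long" (recent inbreeding;
#' the tie at exactly m is classified long), shorter ones "short" (old).
#'
#' @param rohs A `roh_set`.
#' @param m_mb Length threshold(s) in Mb; with a vector the result is stacked
#'   long over thresholds.
#' @return Tibble (animal, f_total, f_new, f_old, method, threshold).
#' @export
partition_roh_inbreeding <- function(rohs, m_mb) {
  stopifnot(inherits(rohs, "roh_set"), all(m_mb > 0))
  l_auto <- attr(rohs, "l_auto_bp")
  samples <- attr(rohs, "samples")
  f_tot <- roh_inbreeding(rohs)
  purrr::map_dfr(m_mb, function(m) {
    long <- rohs$length_bp >= m * 1e6
    sums <- tibble(animal = rohs$animal,
                   lng = ifelse(long, rohs$length_bp, 0),
                   sht = ifelse(long, 0, rohs$length_bp)) |>
      dplyr::group_by(.data$animal) |>
      dplyr::summarise(lng = sum(.data$lng), sht = sum(.data$sht),
                       .groups = "drop")
    j <- match(samples, sums$animal)
    tibble(animal = samples,
           f_total = f_tot$f_roh,
           f_new = dplyr::coalesce(sums$lng[j], 0) / l_auto,
           f_old = dplyr::coalesce(sums$sht[j], 0) / l_auto,
           method = "roh_m",
           threshold = m)
  })
}

#' Convert ROH length to age of inbreeding, and back
#'
#' The expected length of an IBD segment coalescing g generations back is
#' exponential with mean 1/(2g) Morgan; at a uniform map of 1 cM/Mb
#' (`mb_per_morgan = 100`) a length l Mb therefore corresponds to
#' g = mb_per_morgan / (2 l) generations, and conversely.
#'
#' @param l_mb Segment length(s) in Mb (> 0).
#' @param g Age(s) in generations to the common ancestor (> 0).
#' @param mb_per_morgan Megabases per Morgan (default 100, i.e. 1 cM/Mb).
#' @return Numeric vector.
#' @examples
#' length_to_generations(17)  # ~2.94 generations
#' generations_to_length(15)  # ~3.3 Mb
#' @export
length_to_generations <- function(l_mb, mb_per_morgan = 100) {
  if (any(l_mb <= 0)) abort("l_mb must be positive")
  mb_per_morgan / (2 * l_mb)
}

#' @rdname length_to_generations
#' @export
generations_to_length <- function(g, mb_per_morgan = 100) {
  if (any(g <= 0)) abort("g must be positive")
  mb_per_morgan / (2 * g)
}

#' Write an ROH table in .hom-style TSV
#'
#' @param rohs A `roh_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_roh <- function(rohs, path) {
  readr::write_tsv(
    tibble(IID = rohs$animal, CHR = rohs$chromosome,
           POS1 = rohs$start_bp, POS2 = rohs$end_bp,
           KB = rohs$length_bp / 1e3, NSNP = rohs$n_snps,
           NHET = rohs$n_het, NMISS = rohs$n_missing),
    path)
  invisible(path)
}
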