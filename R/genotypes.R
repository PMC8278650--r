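#' Genotype dataset container
#'
#' Diploid SNP calls for an ordered set of samples over an ordered marker
#' map.  Calls are coded 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing; ROH analysis only distinguishes
#' homozygous / heterozygous / missing.
#'
#' @param calls Integer matrix samples x markers with values 0/1/2/NA.
#' @param map Data frame (marker, chromosome, position_bp); positions must be
#'   strictly increasing within chromosome.
#' @param samples Character vector of unique sample ids (defaults to the
#'   rownames of `calls`).
#' @return A `geno_set` object.
#' @export
genotypes <- function(calls, map, samples = rownames(calls)) {
  map <- as_tibble(map)
  need <- c("marker", "chromosome", "position_bp")
  if (!all(need %in% names(map))) {
    abort(paste0("map needs columns ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(map$marker)) abort("duplicate marker ids in map")
  if (is.null(samples)) abort("sample ids required")
  if (anyDuplicated(samples)) abort("duplicate sample ids")
  if (nrow(map) != ncol(calls) || length(samples) != nrow(calls)) {
    abort("call-matrix dimensions do not match map/sample lengths")
  }
  ord <- order(map$chromosome, map$position_bp)
  map <- map[ord, ]
  calls <- calls[, ord, drop = FALSE]
  bad <- map |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(ok = all(diff(.data$position_bp) > 0)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    abort(paste0("positions not strictly increasing on chromosome ",
                 bad$chromosome[1L]))
  }
  mode(calls) <- "integer"
  dimnames(calls) <- list(samples, map$marker)
  structure(list(samples = as.character(samples), map = map, calls = calls),
            class = "geno_set")
}

#' @method print geno_set
#' @export
print.geno_set <- function(x, ...) {
  cat("<geno_set> ", length(x$samples), " samples x ", nrow(x$map),
      " markers on ", length(unique(x$map$chromosome)), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' Span of the marker panel per chromosome
#'
#' The SNP-covered autosomal length: per chromosome, last minus first marker
#' position.  The sum is the L_AUTO denominator of ROH-based inbreeding.
#'
#' @param x A `geno_set`.
#' @return Tibble (chromosome, first_bp, last_bp, span_bp).
#' @export
panel_span <- function(x) {
  stopifnot(inherits(x, "geno_set"))
  x$map |>
    dplyr::group_by(chromosome = .data$chromosome) |>
    dplyr::summarise(first_bp = min(.data$position_bp),
                     last_bp = max(.data$position_bp),
                     span_bp = max(.data$position_bp) - min(.data$position_bp),
                     .groups = "drop")
}

#' Read PLINK text genotypes
#'
#' Reads a `.ped`/`.map` pair (PLINK 1.x text format).  Alleles are recoded
#' to 0/1/2 against the first allele observed at each marker; `0 0` is
#' missing.  Markers are sorted by (chromosome, position).
#'
#' @param ped_path,map_path File paths.
#' @return A `geno_set`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  map_raw <- readr::read_table(map_path, col_names = FALSE,
                               col_types = readr::cols(.default = "c"),
                               show_col_types = FALSE)
  if (ncol(map_raw) < 4L) abort(".map must have 4 columns (chr id cm bp)")
  pos <- suppressWarnings(as.numeric(map_raw[[4L]]))
  chr <- suppressWarnings(as.integer(map_raw[[1L]]))
  if (anyNA(pos) || anyNA(chr)) abort("non-numeric chromosome/position in .map")
  map <- tibble(marker = map_raw[[2L]], chromosome = chr, position_bp = pos)
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt != 6L + 2L * m)) {
    abort(paste0(".ped rows have ", nt[which(nt != 6L + 2L * m)[1L]],
                 " fields; expected ", 6L + 2L * m,
                 " for ", m, " markers"))
  }
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  samples <- tok[, 2L]
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]
    x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    alleles <- unique(c(x1[!miss], x2[!miss]))
    if (length(alleles) > 2L) {
      abort(paste0("marker ", map$marker[j], " has >2 alleles"))
    }
    ref <- alleles[1L]
    g <- (x1 != ref) + (x2 != ref)
    g[miss] <- NA_integer_
    calls[, j] <- as.integer(g)
  }
  genotypes(calls, map, samples = samples)
}

#' Write PLINK text genotypes
#'
#' Inverse of [read_plink_text()]: calls 0/1/2 become `A A`, `A B`, `B B`
#' and missing becomes `0 0`.
#'
#' @param x A `geno_set`.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(x, ped_path, map_path) {
  stopifnot(inherits(x, "geno_set"))
  readr::write_tsv(
    tibble(chr = x$map$chromosome, id = x$map$marker, cm = 0,
           bp = format(x$map$position_bp, scientific = FALSE, trim = TRUE)),
    map_path, col_names = FALSE)
  g <- x$calls
  enc <- function(row) {
    out <- character(2L * length(row))
    i1 <- seq_along(row) * 2L - 1L
    out[i1] <- c("A", "A", "B")[row + 1L]
    out[i1 + 1L] <- c("A", "B", "B")[row + 1L]
    out[is.na(rep(row, each = 2L))] <- "0"
    out
  }
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_along(x$samples)) {
    writeLines(paste(c(x$samples[i], x$samples[i], "0", "0", "0", "-9",
                       enc(g[i, ])), collapse = " "), con)
  }
  invisible(c(ped_path, map_path))
}
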