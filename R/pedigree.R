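#' Construct a validated pedigree
#'
#' A pedigree is a tibble with one row per animal carrying `animal`, `sire`,
#' `dam` identifiers (with `NA` for an unknown parent) and optional `sex`
#' (`"M"`, `"F"`, or `NA`) and `birth_year` columns.  Rows are reordered so
#' that parents always precede their offspring, cycles are rejected, and
#' integer parent indices are cached for the fast kernels.
#'
#' @param df Data frame with at least `animal`, `sire`, `dam` columns.
#'   Identifiers are coerced to character.
#' @param unknown Character vector of codes (besides `NA`) marking an unknown
#'   parent.  Default `c("0", "NA", ".")`.
#' @param strict If `TRUE`, a parent id that never appears as an animal is an
#'   error; otherwise such parents are added as founders with a warning.
#' @return A `ped_tbl`: a tibble (animal, sire, dam, sex, birth_year) in
#'   topological order.
#' @examples
#' ped <- pedigree(data.frame(animal = c("A", "B", "C"),
#'                            sire   = c(0, 0, "A"),
#'                            dam    = c(0, 0, "B")))
#' pedigree_stats(ped)
#' @export
pedigree <- function(df, unknown = c("0", "NA", "."), strict = FALSE) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    abort(paste0("pedigree needs columns ", paste(need, collapse = ", ")))
  }
  df <- as_tibble(df)
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% unknown | is.na(x) | x == ""] <- NA_character_
    x
  }
  df$animal <- as.character(df$animal)
  df$sire <- clean(df$sire)
  df$dam <- clean(df$dam)
  if (anyNA(df$animal) || any(df$animal %in% unknown)) {
    abort("animal ids may not be missing or use an unknown-parent code")
  }
  if (anyDuplicated(df$animal)) {
    abort(paste0("duplicated animal id(s): ",
                 paste(unique(df$animal[duplicated(df$animal)]), collapse = ", ")))
  }
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  if (!"birth_year" %in% names(df)) df$birth_year <- NA_integer_
  df$sex <- toupper(as.character(df$sex))
  df$sex[!df$sex %in% c("M", "F")] <- NA_character_
  df$birth_year <- suppressWarnings(as.integer(df$birth_year))

  dangling <- setdiff(c(df$sire, df$dam), c(df$animal, NA))
  if (length(dangling)) {
    if (strict) {
      abort(paste0("parent id(s) never defined as animals: ",
                   paste(dangling, collapse = ", ")))
    }
    warn(paste0(length(dangling), " parent id(s) not defined as animals; ",
                "added as founders: ",
                paste(head(dangling, 5), collapse = ", "),
                if (length(dangling) > 5) ", ..." else ""))
    df <- dplyr::bind_rows(
      tibble(animal = dangling, sire = NA_character_, dam = NA_character_,
             sex = NA_character_, birth_year = NA_integer_),
      df
    )
  }
  df <- df[, c("animal", "sire", "dam", "sex", "birth_year")]

  # Kahn topological sort; leftover rows imply a cycle.
  idx <- setNames(seq_len(nrow(df)), df$animal)
  si <- ifelse(is.na(df$sire), 0L, idx[df$sire])
  di <- ifelse(is.na(df$dam), 0L, idx[df$dam])
  n <- nrow(df)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order) < n) {
    on_cycle <- df$animal[setdiff(seq_len(n), order)]
    abort(paste0("pedigree contains a cycle involving animal '",
                 on_cycle[1L], "'"))
  }
  df <- df[order, ]
  new_ped_tbl(df)
}

new_ped_tbl <- function(df) {
  idx <- setNames(seq_len(nrow(df)), df$animal)
  attr(df, "sire_idx") <- unname(ifelse(is.na(df$sire), 0L, idx[df$sire]))
  attr(df, "dam_idx") <- unname(ifelse(is.na(df$dam), 0L, idx[df$dam]))
  class(df) <- c("ped_tbl", class(tibble()))
  df
}

#' Read a pedigree file
#'
#' Reads a delimited text pedigree (comma or whitespace separated; header
#' optional) with columns animal, sire, dam and optionally sex, birth_year,
#' and validates it with [pedigree()].
#'
#' @param path File path.
#' @param unknown,strict Passed to [pedigree()].
#' @return A `ped_tbl`.
#' @export
read_pedigree <- function(path, unknown = c("0", "NA", "."), strict = FALSE) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl(",", first)) "," else NULL
  has_header <- grepl("animal", first, ignore.case = TRUE)
  if (is.null(delim)) {
    df <- readr::read_table(path, col_names = has_header,
                            col_types = readr::cols(.default = "c"),
                            show_col_types = FALSE)
  } else {
    df <- readr::read_csv(path, col_names = has_header,
                          col_types = readr::cols(.default = "c"),
                          show_col_types = FALSE)
  }
  if (!has_header) {
    names(df) <- c("animal", "sire", "dam", "sex", "birth_year")[seq_len(ncol(df))]
  }
  names(df) <- tolower(names(df))
  pedigree(df, unknown = unknown, strict = strict)
}

ped_indices <- function(ped) {
  list(sire = attr(ped, "sire_idx"), dam = attr(ped, "dam_idx"))
}

#' Pedigree depth and completeness statistics
#'
#' MaxGen is the length of the longest ancestor chain from an animal to a
#' founder; ECG (equivalent complete generations) is the sum of (1/2)^n over
#' all known-ancestor paths, computed by the recursion
#' `ecg(i) = 0.5 * (1 + ecg(sire)) + 0.5 * (1 + ecg(dam))` over known parents.
#'
#' @param ped A `ped_tbl`.
#' @return Tibble (animal, max_gen, ecg).
#' @export
pedigree_stats <- function(ped) {
  stopifnot(inherits(ped, "ped_tbl"))
  ix <- ped_indices(ped)
  tibble(animal = ped$animal,
         max_gen = as.integer(max_gen_cpp(ix$sire, ix$dam)),
         ecg = as.numeric(ecg_cpp(ix$sire, ix$dam)))
}

#' Check whether a pedigree is generation-layered
#'
#' A pedigree is layered when a generation number g exists with
#' g(child) = g(parent) + 1 for every recorded parent link (all founders in
#' generation 0).  In a layered pedigree every path from an animal to one of
#' its ancestors has the same length, which licenses the fast cohort-shared
#' truncation used by [truncated_inbreeding()].
#'
#' @param ped A `ped_tbl`.
#' @return `TRUE`/`FALSE`.
#' @export
is_layered <- function(ped) {
  ix <- ped_indices(ped)
  n <- nrow(ped)
  g <- integer(n)
  ok <- TRUE
  for (i in seq_len(n)) {
    ps <- c(ix$sire[i], ix$dam[i])
    ps <- ps[ps > 0L]
    if (!length(ps)) {
      g[i] <- 0L
    } else {
      gp <- g[ps]
      if (length(unique(gp)) > 1L) {
        ok <- FALSE
        break
      }
      g[i] <- gp[1L] + 1L
    }
  }
  if (!ok) return(FALSE)
  # all founders must sit in generation 0 relative to every descendant path:
  # verify each link spans exactly one generation
  for (i in seq_len(n)) {
    for (p in c(ix$sire[i], ix$dam[i])) {
      if (p > 0L && g[i] != g[p] + 1L) return(FALSE)
    }
  }
  TRUE
}

ped_generation <- function(ped) {
  ix <- ped_indices(ped)
  n <- nrow(ped)
  g <- integer(n)
  for (i in seq_len(n)) {
    ps <- c(ix$sire[i], ix$dam[i])
    ps <- ps[ps > 0L]
    g[i] <- if (length(ps)) max(g[ps]) + 1L else 0L
  }
  g
}
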