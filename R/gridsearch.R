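#' Grid search for the trait-specific new/old inbreeding threshold
#'
#' Scans candidate thresholds from the most recent boundary to the oldest
#' (ancestral generations `t` ascending for pedigree partitions; segment
#' length `m` descending for ROH partitions).  At each threshold the new and
#' old inbreeding components are standardized and fitted jointly in the
#' depression model; the selected threshold is the first at which the
#' detrimental effect of new inbreeding is at least as large as that of old
#' inbreeding (for a higher-is-better trait: `beta_new <= beta_old`; a tie
#' selects).  Thresholds where either component is constant are skipped with
#' a warning and recorded in the trace.  All crossings are reported; the
#' first in scan order is the selection.
#'
#' @param partitions Long tibble of per-animal partitions stacked over
#'   thresholds: columns animal, f_total, f_new, f_old, method, threshold
#'   (the output of [partition_pedigree_inbreeding()] or
#'   [partition_roh_inbreeding()] called with a threshold grid).
#' @param data Phenotype tibble; joined to the partitions by `animal`.
#' @param spec A [model_spec()]; its `inbreeding` entry is ignored (the
#'   partition columns are used).
#' @param ped Pedigree, required when `engine = "mixed"`.
#' @param engine `"mixed"` (default; the full depression model) or
#'   `"fixed"` (OLS).
#' @param orientation Currently `"higher_is_better"` (all growth traits);
#'   more detrimental means more negative.
#' @return An `autozyg_grid` object: list with `table` (per-threshold betas
#'   and SEs, skip and rule flags), `selected_threshold` (`NA` if the rule
#'   never fires), `crossings`, `source`, `engine`, `trait`.
#' @export
threshold_search <- function(partitions, data, spec, ped = NULL,
                             engine = c("mixed", "fixed"),
                             orientation = "higher_is_better") {
  engine <- match.arg(engine)
  orientation <- match.arg(orientation, "higher_is_better")
  stopifnot(inherits(spec, "model_spec"))
  need <- c("animal", "f_total", "f_new", "f_old", "threshold", "method")
  if (!all(need %in% names(partitions))) {
    abort(paste0("partitions needs columns ", paste(need, collapse = ", ")))
  }
  source <- unique(partitions$method)
  if (length(source) != 1L) abort("mixed partition methods in one search")
  grid <- sort(unique(partitions$threshold),
               decreasing = source %in% c("roh_m", "mixture"))
  if (!length(grid)) abort("empty threshold grid")
  if (engine == "mixed" && is.null(ped)) abort("mixed engine needs `ped`")

  spec2 <- spec
  spec2$inbreeding <- c(new = "..f_new", old = "..f_old")
  rows <- purrr::map(grid, function(th) {
    part <- partitions[partitions$threshold == th, ]
    cov <- tibble(animal = part$animal, ..f_new = part$f_new,
                  ..f_old = part$f_old)
    dat <- dplyr::inner_join(data, cov, by = "animal")
    frac_zero_new <- mean(dat$..f_new == 0)
    if (sd(dat$..f_new) < 1e-12 || sd(dat$..f_old) < 1e-12) {
      which_const <- if (sd(dat$..f_new) < 1e-12) "new" else "old"
      warn(paste0("threshold ", th, ": ", which_const,
                  " component is constant; skipped"))
      return(tibble(threshold = th, beta_new = NA_real_, se_new = NA_real_,
                    beta_old = NA_real_, se_old = NA_real_,
                    skipped = TRUE, frac_zero_new = frac_zero_new,
                    low_information = NA))
    }
    fit <- if (engine == "mixed") fit_mixed(dat, spec2, ped)
           else fit_fixed(dat, spec2)
    cf <- fit$coefficients
    bn <- cf[cf$term == "z_new", ]
    bo <- cf[cf$term == "z_old", ]
    tibble(threshold = th,
           beta_new = bn$estimate, se_new = bn$std.error,
           beta_old = bo$estimate, se_old = bo$std.error,
           skipped = FALSE, frac_zero_new = frac_zero_new,
           low_information = frac_zero_new >= 0.5)
  })
  tab <- dplyr::bind_rows(rows)
  tab$new_at_least_old <- !tab$skipped & tab$beta_new <= tab$beta_old
  crossings <- tab$threshold[which(tab$new_at_least_old)]
  selected <- if (length(crossings)) crossings[1L] else NA_real_
  if (is.na(selected)) {
    inform("threshold rule never fired: new inbreeding never at least as detrimental as old")
  }
  structure(list(table = tab, selected_threshold = selected,
                 crossings = crossings, source = source, engine = engine,
                 trait = spec$trait, orientation = orientation),
            class = "autozyg_grid")
}

#' @method print autozyg_grid
#' @export
print.autozyg_grid <- function(x, ...) {
  cat("<autozyg_grid> trait:", x$trait, " source:", x$source,
      " engine:", x$engine, "\n")
  if (is.na(x$selected_threshold)) {
    cat("  no threshold selected (rule never fired)\n")
  } else {
    unit <- if (x$source == "pedigree_t") "generations" else "Mb"
    cat("  selected threshold:", x$selected_threshold, unit, "\n")
  }
  print(x$table, n = 6)
  invisible(x)
}

#' @export
tidy.autozyg_grid <- function(x, ...) x$table

#' @export
glance.autozyg_grid <- function(x, ...) {
  tibble(selected_threshold = x$selected_threshold,
         n_thresholds = nrow(x$table),
         n_skipped = sum(x$table$skipped),
         n_crossings = length(x$crossings),
         source = x$source, engine = x$engine, trait = x$trait)
}

#' Contribution of new inbreeding to total inbreeding across thresholds
#'
#' Population means of the new component and its share of total inbreeding,
#' per threshold (zero-safe: animals without long segments contribute 0).
#'
#' @param partitions Long partition tibble (as in [threshold_search()]).
#' @return Tibble (threshold, mean_f_new, mean_f_total, ratio).
#' @export
contribution_curve <- function(partitions) {
  partitions |>
    dplyr::group_by(threshold = .data$threshold) |>
    dplyr::summarise(mean_f_new = mean(.data$f_new),
                     mean_f_total = mean(.data$f_total),
                     ratio = mean(.data$f_new) / mean(.data$f_total),
                     .groups = "drop")
}

#' Correlation between two partitions' new-inbreeding coefficients
#'
#' Pearson correlation of `f_new` across the animals common to both
#' partitions (e.g. the pedigree-based vs ROH-based new inbreeding).
#'
#' @param a,b Partition tibbles at single thresholds.
#' @return Correlation (scalar).
#' @export
partition_correlation <- function(a, b) {
  j <- dplyr::inner_join(a[, c("animal", "f_new")], b[, c("animal", "f_new")],
                         by = "animal")
  if (nrow(j) < 3L) abort("fewer than 3 shared animals")
  if (sd(j$f_new.x) < 1e-300 || sd(j$f_new.y) < 1e-300) {
    abort("zero variance in f_new on one side")
  }
  cor(j$f_new.x, j$f_new.y)
}

#' Compare inbreeding-classification methods by model fit
#'
#' Fits the fixed-effects-only depression model once per method (identical
#' fixed terms; only the two standardized inbreeding covariates differ) and
#' reports adjusted R^2, RMSE, AIC and BIC, the AIC difference to the best
#' method, and whether that difference is significant by the > 2 convention.
#'
#' @param methods Named list of partition tibbles (one threshold each).
#' @param data Phenotype tibble.
#' @param spec A [model_spec()].
#' @return Tibble (method, adj_r2, rmse, aic, bic, aic_delta,
#'   significant_delta).
#' @export
compare_methods <- function(methods, data, spec) {
  if (is.null(names(methods)) || any(names(methods) == "")) {
    abort("methods must be a named list")
  }
  spec2 <- spec
  spec2$inbreeding <- c(new = "..f_new", old = "..f_old")
  rows <- purrr::imap(methods, function(part, label) {
    cov <- tibble(animal = part$animal, ..f_new = part$f_new,
                  ..f_old = part$f_old)
    dat <- dplyr::inner_join(data, cov, by = "animal")
    fit <- fit_fixed(dat, spec2)
    dplyr::bind_cols(tibble(method = label), fit$criteria)
  })
  out <- dplyr::bind_rows(rows)
  out$aic_delta <- out$aic - min(out$aic)
  out$significant_delta <- out$aic_delta > 2
  out
}
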