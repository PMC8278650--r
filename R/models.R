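#' Standardize a covariate to zero mean and unit variance
#'
#' Z-scores with the sample (n - 1) standard deviation.  Inbreeding
#' covariates are standardized separately in every depression analysis so
#' that regression coefficients are comparable across thresholds.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(values) {
  s <- sd(values)
  if (!is.finite(s) || s < 1e-300) {
    abort("covariate is constant; cannot standardize")
  }
  (values - mean(values)) / s
}

#' Specify an inbreeding-depression model
#'
#' Describes one trait model: the response column, fixed effects, the two
#' inbreeding covariates (standardized at fit time), optional pedigree
#' random effects and their variance components.  The classical growth-trait
#' layout is sex + birth year (factor) fixed, an age covariate for weaning /
#' yearling-type traits, a direct genetic effect for all traits and maternal
#' genetic + maternal permanent-environment effects for the early-growth
#' traits.
#'
#' @param trait Response column name.
#' @param fixed Character vector of fixed factor/covariate columns
#'   (birth_year is treated as an unordered factor).
#' @param age_covariate Optional numeric covariate column (e.g. age in days).
#' @param inbreeding Length-2 named character vector: columns holding the
#'   new and old inbreeding covariates, e.g. `c(new = "f_new", old =
#'   "f_old")`.
#' @param random Subset of `c("direct", "maternal_genetic", "maternal_pe")`;
#'   empty for a fixed-effects-only model.
#' @param varcomp Named list of variance components: `direct`,
#'   `maternal_genetic`, `dir_mat_cov`, `maternal_pe`, `residual` (only the
#'   ones used need be set; `dir_mat_cov` defaults to 0).
#' @return A `model_spec` list.
#' @export
model_spec <- function(trait, fixed = c("sex", "birth_year"),
                       age_covariate = NULL,
                       inbreeding = c(new = "f_new", old = "f_old"),
                       random = character(),
                       varcomp = list()) {
  if (length(random)) {
    random <- match.arg(random,
                        c("direct", "maternal_genetic", "maternal_pe"),
                        several.ok = TRUE)
  }
  if (length(inbreeding) != 2L || !all(c("new", "old") %in% names(inbreeding))) {
    abort("inbreeding must be c(new = ..., old = ...)")
  }
  vc <- list(direct = varcomp$direct %||% NA_real_,
             maternal_genetic = varcomp$maternal_genetic %||% NA_real_,
             dir_mat_cov = varcomp$dir_mat_cov %||% 0,
             maternal_pe = varcomp$maternal_pe %||% NA_real_,
             residual = varcomp$residual %||% NA_real_)
  structure(list(trait = trait, fixed = fixed, age_covariate = age_covariate,
                 inbreeding = inbreeding, random = random, varcomp = vc),
            class = "model_spec")
}

# Build the fixed-effects design matrix and response; standardizes the two
# inbreeding covariates and errors on rank deficiency, naming the columns.
build_design <- function(data, spec) {
  for (col in c(spec$trait, spec$fixed, spec$age_covariate,
                unname(spec$inbreeding))) {
    if (!col %in% names(data)) abort(paste0("column not in data: ", col))
  }
  data <- as_tibble(data)
  keep <- complete.cases(data[, c(spec$trait, spec$fixed, spec$age_covariate,
                                  unname(spec$inbreeding))])
  data <- data[keep, ]
  df <- data
  for (f in spec$fixed) {
    if (f == "birth_year" || !is.numeric(df[[f]])) df[[f]] <- factor(df[[f]])
  }
  z_new <- standardize(df[[spec$inbreeding[["new"]]]])
  z_old <- standardize(df[[spec$inbreeding[["old"]]]])
  rhs <- c(spec$fixed, spec$age_covariate)
  fml <- stats::reformulate(c(rhs, "z_new", "z_old"))
  mf <- df[, rhs, drop = FALSE]
  mf$z_new <- z_new
  mf$z_old <- z_old
  X <- model.matrix(fml, data = mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(drop_cols, collapse = ", ")))
  }
  list(X = X, y = df[[spec$trait]], data = data,
       sd_new = sd(df[[spec$inbreeding[["new"]]]]),
       sd_old = sd(df[[spec$inbreeding[["old"]]]]))
}

#' Fit the fixed-effects-only depression model
#'
#' Ordinary least squares of the trait on the fixed effects plus the two
#' standardized inbreeding covariates (fitted jointly).  Reports
#' coefficients, standard errors, t-statistics and the model-comparison
#' criteria: adjusted R^2, RMSE = sqrt(RSS / n), and Gaussian-likelihood AIC
#' and BIC counting the residual variance as a parameter (the stats
#' convention).
#'
#' @param data Phenotype tibble (one row per animal).
#' @param spec A [model_spec()].
#' @return A `depression_fit` object; see [tidy()] / [glance()].
#' @export
fit_fixed <- function(data, spec) {
  d <- build_design(data, spec)
  fit <- lm(d$y ~ d$X - 1)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  names(est) <- names(se) <- colnames(d$X)
  n <- length(d$y)
  k <- ncol(d$X)
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / sum((d$y - mean(d$y))^2)
  structure(list(
    coefficients = tibble(term = colnames(d$X), estimate = unname(est),
                          std.error = unname(se),
                          statistic = unname(est) / unname(se)),
    n_obs = n, rss = rss, loglik = as.numeric(logLik(fit)),
    criteria = tibble(adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k),
                      rmse = sqrt(rss / n),
                      aic = AIC(fit), bic = BIC(fit)),
    engine = "fixed", spec = spec,
    sd_new = d$sd_new, sd_old = d$sd_old),
    class = "depression_fit")
}

#' Significance of depression coefficients
#'
#' A coefficient is significant when |beta / SE| > 2 (strict inequality; no
#' multiple-testing adjustment).
#'
#' @param fit A `depression_fit`.
#' @param terms Terms to test (default: the two inbreeding covariates).
#' @return Tibble (term, estimate, statistic, significant).
#' @export
significance <- function(fit, terms = c("z_new", "z_old")) {
  stopifnot(inherits(fit, "depression_fit"))
  fit$coefficients |>
    dplyr::filter(.data$term %in% terms) |>
    dplyr::mutate(significant = abs(.data$statistic) > 2) |>
    dplyr::select("term", "estimate", "statistic", "significant")
}

#' @export
tidy.depression_fit <- function(x, ...) {
  x$coefficients |>
    dplyr::mutate(significant = abs(.data$statistic) > 2)
}

#' @export
glance.depression_fit <- function(x, ...) {
  out <- tibble(n_obs = x$n_obs, engine = x$engine)
  if (!is.null(x$criteria)) out <- dplyr::bind_cols(out, x$criteria)
  if (!is.null(x$loglik)) out$logLik <- x$loglik
  out
}

#' @method print depression_fit
#' @export
print.depression_fit <- function(x, ...) {
  cat("<depression_fit> trait:", x$spec$trait, " engine:", x$engine,
      " n =", x$n_obs, "\n")
  ib <- x$coefficients[x$coefficients$term %in% c("z_new", "z_old"), ]
  for (i in seq_len(nrow(ib))) {
    cat(sprintf("  %s: %+0.4f (SE %0.4f, t = %+0.2f)\n", ib$term[i],
                ib$estimate[i], ib$std.error[i], ib$statistic[i]))
  }
  invisible(x)
}
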