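#' Two-component Gaussian mixture on ROH segment lengths
#'
#' EM fit of a two-component, unequal-variance Gaussian mixture on
#' log10(length in Mb); raw ROH lengths are heavily right-skewed, so the fit
#' is done on the log scale.  Initialisation is a seeded k-means (10 starts),
#' making the fit deterministic given `seed`.  The short/long classification
#' boundary is the length at which the posterior membership of the long
#' component crosses 0.5, solved on the original Mb scale.
#'
#' @param lengths_mb Segment lengths in Mb (at least 10 values).
#' @param seed Integer seed for the initialisation.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @return A `length_mixture` object with elements `weights`, `means`,
#'   `variances` (log10 scale, short component first), `boundary_mb`,
#'   `loglik`, `loglik_trace`, `n_iter`, `n`.
#' @export
fit_length_mixture <- function(lengths_mb, seed = 1, max_iter = 500,
                               tol = 1e-10) {
  lengths_mb <- lengths_mb[!is.na(lengths_mb)]
  if (length(lengths_mb) < 10) abort("need at least 10 segment lengths")
  if (any(lengths_mb <= 0)) abort("lengths must be positive")
  x <- log10(lengths_mb)
  n <- length(x)

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  km <- kmeans(x, centers = 2L, nstart = 10L)
  ord <- order(km$centers)
  z <- matrix(0, n, 2L)
  z[cbind(seq_len(n), match(km$cluster, ord))] <- 1

  mu <- as.numeric(km$centers[ord])
  s2 <- rep(max(var(x) / 4, 1e-6), 2L)
  w <- colMeans(z)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d1 <- w[1L] * dnorm(x, mu[1L], sqrt(s2[1L]))
    d2 <- w[2L] * dnorm(x, mu[2L], sqrt(s2[2L]))
    tot <- d1 + d2
    if (any(tot == 0)) abort("mixture degenerate: zero density point")
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    z1 <- d1 / tot
    z2 <- 1 - z1
    w <- c(mean(z1), mean(z2))
    mu <- c(sum(z1 * x) / sum(z1), sum(z2 * x) / sum(z2))
    s2 <- c(sum(z1 * (x - mu[1L])^2) / sum(z1),
            sum(z2 * (x - mu[2L])^2) / sum(z2))
    if (any(s2 < 1e-10)) {
      abort("EM variance collapse; too few distinct lengths to fit a mixture")
    }
    if (iter >= max_iter || (ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (mu[1L] > mu[2L]) {  # keep short component first
    mu <- rev(mu); s2 <- rev(s2); w <- rev(w)
  }

  # posterior-0.5 crossing between the two means
  post_long <- function(xx) {
    a <- w[1L] * dnorm(xx, mu[1L], sqrt(s2[1L]))
    b <- w[2L] * dnorm(xx, mu[2L], sqrt(s2[2L]))
    b / (a + b) - 0.5
  }
  lo <- mu[1L]
  hi <- mu[2L]
  if (post_long(lo) >= 0 || post_long(hi) <= 0) {
    boundary <- (lo + hi) / 2  # components fused; midpoint fallback
  } else {
    boundary <- uniroot(post_long, c(lo, hi), tol = 1e-10)$root
  }
  structure(list(weights = w, means = mu, variances = s2,
                 boundary_mb = 10^boundary, loglik = ll_trace[iter],
                 loglik_trace = ll_trace, n_iter = iter, n = n),
            class = "length_mixture")
}

#' @method print length_mixture
#' @export
print.length_mixture <- function(x, ...) {
  cat("<length_mixture> 2-component Gaussian fit on log10(Mb), n =", x$n, "\n")
  cat(sprintf("  short: mean %.2f Mb (w = %.2f); long: mean %.2f Mb (w = %.2f)\n",
              10^x$means[1L], x$weights[1L], 10^x$means[2L], x$weights[2L]))
  cat(sprintf("  boundary: %.2f Mb; loglik %.2f after %d EM iterations\n",
              x$boundary_mb, x$loglik, x$n_iter))
  invisible(x)
}

#' @export
tidy.length_mixture <- function(x, ...) {
  tibble(component = c("short", "long"),
         weight = x$weights,
         mean_log10 = x$means,
         sd_log10 = sqrt(x$variances),
         mean_mb = 10^x$means)
}

#' @export
glance.length_mixture <- function(x, ...) {
  tibble(boundary_mb = x$boundary_mb, logLik = x$loglik, n_iter = x$n_iter,
         n = x$n)
}

#' Partition ROH inbreeding at the mixture boundary
#'
#' Delegates to [partition_roh_inbreeding()] at `fit$boundary_mb`, tagging
#' the result with method `"mixture"`.
#'
#' @param rohs A `roh_set`.
#' @param fit A `length_mixture` (default: fitted to the segment lengths of
#'   `rohs` with `seed`).
#' @param seed Seed used when `fit` is not supplied.
#' @return Tibble (animal, f_total, f_new, f_old, method, threshold).
#' @export
partition_by_mixture <- function(rohs, fit = NULL, seed = 1) {
  stopifnot(inherits(rohs, "roh_set"))
  fit <- fit %||% fit_length_mixture(rohs$length_bp / 1e6, seed = seed)
  out <- partition_roh_inbreeding(rohs, fit$boundary_mb)
  out$method <- "mixture"
  out
}
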