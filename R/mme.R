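#' Inverse numerator-relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `alpha = 1 / d_i` to the diagonal, `-alpha/2` to animal x parent and
#' `alpha/4` to parent x parent cells, where `d_i` is the Mendelian-sampling
#' variance `0.5 - 0.25 (F_s + F_d)` (both parents known), `0.75 - 0.25 F_p`
#' (one known) or 1 (none), using Meuwissen-Luo inbreeding coefficients.
#'
#' @param ped A `ped_tbl`.
#' @param ids Optional subset/order of animal ids (must be topologically
#'   ordered if a subset is requested; default: all, pedigree order).  All
#'   ancestors of the requested ids must be included, so the usual call is
#'   over the whole pedigree.
#' @return Sparse symmetric `Matrix::dsCMatrix` with dimnames = ids.
#' @export
build_a_inverse <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "ped_tbl"))
  ids <- ids %||% ped$animal
  if (!all(ids %in% ped$animal)) {
    abort(paste0("id(s) not in pedigree: ",
                 paste(head(setdiff(ids, ped$animal), 5), collapse = ", ")))
  }
  keep <- ped$animal %in% ids
  ix <- ped_indices(ped)
  parents <- unique(c(ix$sire[keep], ix$dam[keep]))
  parents <- parents[parents > 0L]
  if (!all(ped$animal[parents] %in% ids)) {
    abort("ids must be closed under ancestry (include all parents)")
  }
  f <- ml_inbreeding_cpp(ix$sire, ix$dam)
  n <- length(ids)
  pos <- match(ped$animal, ids)  # position of each pedigree row in ids

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rows <- which(keep)
  si <- ix$sire[rows]; di <- ix$dam[rows]
  fs <- rep(-1, length(si)); fs[si > 0L] <- f[si[si > 0L]]
  fd <- rep(-1, length(di)); fd[di > 0L] <- f[di[di > 0L]]
  d <- 0.5 - 0.25 * (fs + fd)
  alpha <- 1 / d
  me <- pos[rows]
  ps <- rep(NA_integer_, length(si)); ps[si > 0L] <- pos[si[si > 0L]]
  pd <- rep(NA_integer_, length(di)); pd[di > 0L] <- pos[di[di > 0L]]

  add <- function(i, j, v) {
    ok <- !is.na(i) & !is.na(j)
    ii <<- c(ii, i[ok]); jj <<- c(jj, j[ok]); xx <<- c(xx, v[ok])
  }
  add(me, me, alpha)
  add(me, ps, -alpha / 2); add(ps, me, -alpha / 2)
  add(me, pd, -alpha / 2); add(pd, me, -alpha / 2)
  add(ps, ps, alpha / 4); add(pd, pd, alpha / 4)
  add(ps, pd, alpha / 4); add(pd, ps, alpha / 4)
  A_inv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                                dimnames = list(ids, ids))
  Matrix::forceSymmetric((A_inv + Matrix::t(A_inv)) / 2)
}

#' Dense numerator-relationship matrix (tabular method)
#'
#' The recursive tabular method; intended as a readable reference and test
#' oracle rather than for large pedigrees.
#'
#' @param ped A `ped_tbl`.
#' @return Dense numeric matrix with dimnames = animal ids.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "ped_tbl"))
  ix <- ped_indices(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- ix$sire[i]; d <- ix$dam[i]
    asd <- if (s > 0L && d > 0L) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  A
}

#' Fit the pedigree mixed depression model
#'
#' Solves Henderson's mixed-model equations for the depression model
#' `y = Xb + Zu + Wm + Sp + e` with direct genetic (`u`) and, optionally,
#' maternal genetic (`m`) and maternal permanent-environment (`p`) random
#' effects.  Genetic effects are A-inverse weighted (with a 2x2 G when both
#' direct and maternal are present; their covariance defaults to 0), the
#' permanent-environment block is identity weighted.  Variance components
#' are configuration inputs (`spec$varcomp`), not estimated.  Fixed-effect
#' standard errors come from the fixed block of the inverse coefficient
#' matrix times the residual variance.
#'
#' @param data Phenotype tibble with `animal` (and `dam` for maternal
#'   terms) columns.
#' @param spec A [model_spec()] with non-empty `random`.
#' @param ped A `ped_tbl` covering all record animals (and dams).
#' @return A `depression_fit` (no fixed-only criteria block).
#' @export
fit_mixed <- function(data, spec, ped) {
  stopifnot(inherits(spec, "model_spec"), inherits(ped, "ped_tbl"))
  if (!length(spec$random)) {
    abort("spec$random is empty; use fit_fixed()")
  }
  if (!"animal" %in% names(data)) abort("data needs an `animal` column")
  d <- build_design(data, spec)
  data <- d$data
  X <- Matrix::Matrix(d$X, sparse = TRUE)
  y <- d$y
  n <- length(y)
  vc <- spec$varcomp
  if (!is.finite(vc$residual) || vc$residual <= 0) {
    abort("varcomp$residual must be a positive number")
  }
  if (!all(data$animal %in% ped$animal)) {
    abort("record animal(s) missing from pedigree")
  }

  has_dir <- "direct" %in% spec$random
  has_mat <- "maternal_genetic" %in% spec$random
  has_pe <- "maternal_pe" %in% spec$random
  if ((has_mat || has_pe)) {
    if (!"dam" %in% names(data) || anyNA(data$dam)) {
      abort("maternal terms require a complete `dam` column")
    }
  }
  ids <- ped$animal
  q <- length(ids)
  Ainv <- build_a_inverse(ped)

  blocks <- list()   # design matrices, in order
  pens <- list()     # penalty matrices (already x sigma2_e)
  s2e <- vc$residual
  Zfun <- function(col) {
    Matrix::sparseMatrix(i = seq_len(n), j = match(col, ids),
                         x = 1, dims = c(n, q))
  }
  if (has_dir && has_mat) {
    if (!is.finite(vc$direct) || !is.finite(vc$maternal_genetic)) {
      abort("direct and maternal_genetic variances required")
    }
    G0 <- matrix(c(vc$direct, vc$dir_mat_cov, vc$dir_mat_cov,
                   vc$maternal_genetic), 2L)
    Gi <- solve(G0) * s2e
    blocks$u <- Zfun(data$animal)
    blocks$m <- Zfun(data$dam)
    pens$um <- Matrix::kronecker(Gi, Ainv)
  } else if (has_dir) {
    if (!is.finite(vc$direct)) abort("direct variance required")
    blocks$u <- Zfun(data$animal)
    pens$u <- Ainv * (s2e / vc$direct)
  } else if (has_mat) {
    if (!is.finite(vc$maternal_genetic)) abort("maternal variance required")
    blocks$m <- Zfun(data$dam)
    pens$m <- Ainv * (s2e / vc$maternal_genetic)
  }
  if (has_pe) {
    if (!is.finite(vc$maternal_pe)) abort("maternal_pe variance required")
    dams <- sort(unique(data$dam))
    S <- Matrix::sparseMatrix(i = seq_len(n), j = match(data$dam, dams),
                              x = 1, dims = c(n, length(dams)))
    blocks$p <- S
    pens$p <- Matrix::Diagonal(length(dams)) * (s2e / vc$maternal_pe)
  }

  W <- do.call(cbind, c(list(X), unname(blocks)))
  M <- Matrix::crossprod(W)
  # add penalties on the random blocks; the joint (u, m) penalty spans the
  # first 2q random columns when both genetic effects are present
  at <- ncol(X)
  if ("um" %in% names(pens)) {
    r <- at + seq_len(2L * q)
    M[r, r] <- M[r, r] + pens$um
    at <- at + 2L * q
    rest <- setdiff(names(blocks), c("u", "m"))
  } else {
    rest <- names(blocks)
  }
  for (nm in rest) {
    p <- ncol(blocks[[nm]])
    r <- at + seq_len(p)
    M[r, r] <- M[r, r] + pens[[nm]]
    at <- at + p
  }
  rhs <- Matrix::crossprod(W, y)
  k <- ncol(X)
  E <- Matrix::sparseMatrix(i = seq_len(k), j = seq_len(k), x = 1,
                            dims = c(ncol(M), k))
  sol <- tryCatch(Matrix::solve(M, cbind(rhs, E)),
                  error = function(e) abort(paste0(
                    "mixed-model equations singular: ", conditionMessage(e))))
  theta <- sol[, 1L]
  Cbb <- as.matrix(sol[seq_len(k), 1L + seq_len(k)])
  est <- theta[seq_len(k)]
  se <- sqrt(pmax(diag(Cbb), 0) * s2e)
  structure(list(
    coefficients = tibble(term = colnames(d$X), estimate = as.numeric(est),
                          std.error = as.numeric(se),
                          statistic = as.numeric(est) / as.numeric(se)),
    n_obs = n, rss = NULL, loglik = NULL, criteria = NULL,
    engine = "mixed", spec = spec,
    sd_new = d$sd_new, sd_old = d$sd_old,
    solutions = theta),
    class = "depression_fit")
}
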