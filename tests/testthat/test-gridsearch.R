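# shared small herd for the search tests
gs_herd <- function(seed) {
  simulate_herd(sim_config(n_founders = 150, n_generations = 10,
                           trait = list(t_star = 6,
                                        phenotype_min_generation = 6),
                           seed = seed))
}
gs_spec <- function(random = "direct") {
  model_spec("value", age_covariate = "age", random = random,
             varcomp = list(direct = 0.35, residual = 0.65))
}

test_that("threshold search selects near the generative boundary", {
  herd <- gs_herd(101)
  parts <- partition_pedigree_inbreeding(herd$pedigree, 3:10,
                                         animals = herd$phenotypes$animal)
  gs <- suppressWarnings(
    threshold_search(parts, herd$phenotypes, gs_spec(), ped = herd$pedigree))
  expect_s3_class(gs, "autozyg_grid")
  expect_true(abs(gs$selected_threshold - 6) <= 1)
  # trace reconstructs the selection deterministically
  tab <- gs$table
  firing <- tab$threshold[!tab$skipped & tab$beta_new <= tab$beta_old]
  expect_equal(gs$selected_threshold, firing[1])
  expect_equal(gs$crossings, firing)
  # skipped thresholds (constant covariates under kin avoidance) are flagged
  expect_true(all(tab$skipped[tab$threshold <= 4]))
})

test_that("search scans ROH partitions from long to short thresholds", {
  set.seed(5)
  n <- 400
  segs <- tibble::tibble(
    animal = rep(paste0("a", 1:n), each = 2),
    chromosome = 1L,
    start_bp = rep(c(0, 60e6), n),
    end_bp = rep(c(0, 60e6), n) +
      1e6 * c(rexp(2 * n, 1 / 4) + 1)[1:(2 * n)],
    n_snps = 30L, n_het = 0L, n_missing = 0L)
  rs <- roh_set(segs, l_auto_bp = 120e6, samples = paste0("a", 1:n))
  parts <- partition_roh_inbreeding(rs, c(3, 5, 7, 9))
  d <- tibble::tibble(animal = paste0("a", 1:n),
                      sex = rep(c("M", "F"), n / 2),
                      birth_year = 2000L)
  p5 <- parts[parts$threshold == 5, ]
  set.seed(6)
  d$value <- 10 - 1.2 * standardize(p5$f_new[match(d$animal, p5$animal)]) +
    rnorm(n, 0, 0.5)
  spec <- model_spec("value", fixed = "sex")
  gs <- suppressWarnings(threshold_search(parts, d, spec, engine = "fixed"))
  # scan order is descending in m
  expect_equal(gs$table$threshold, c(9, 7, 5, 3))
  expect_false(is.na(gs$selected_threshold))
})

test_that("the rule can never fire, and ties select", {
  d <- tibble::tibble(animal = paste0("a", 1:50),
                      sex = rep(c("M", "F"), 25), birth_year = 2000L,
                      f_new = runif(50), f_old = runif(50))
  # beta_new > beta_old at every threshold: y loads only on f_old
  set.seed(2)
  d$value <- 5 - 2 * standardize(d$f_old) + rnorm(50, 0, 0.2)
  parts <- purrr::map_dfr(1:3, function(t) {
    tibble::tibble(animal = d$animal, f_total = d$f_new + d$f_old,
                   f_new = d$f_new, f_old = d$f_old,
                   method = "pedigree_t", threshold = t)
  })
  spec <- model_spec("value", fixed = "sex")
  expect_message(
    gs <- threshold_search(parts, d, spec, engine = "fixed"),
    "never")
  expect_true(is.na(gs$selected_threshold))
  expect_equal(length(gs$crossings), 0L)
})

test_that("contribution curve is zero-safe and monotone for pedigree grids", {
  herd <- gs_herd(77)
  parts <- partition_pedigree_inbreeding(herd$pedigree, 3:10,
                                         animals = herd$phenotypes$animal)
  cc <- contribution_curve(parts)
  expect_equal(nrow(cc), 8L)
  expect_true(all(diff(cc$ratio) >= -1e-12))
  # at t >= max_gen the ratio is 1
  mg <- max(pedigree_stats(herd$pedigree)$max_gen)
  ccm <- contribution_curve(
    partition_pedigree_inbreeding(herd$pedigree, mg,
                                  animals = herd$phenotypes$animal))
  expect_equal(ccm$ratio, 1, tolerance = 1e-12)
})

test_that("partition correlations behave at the identity and null poles", {
  herd <- gs_herd(31)
  p6 <- herd$truth
  expect_equal(partition_correlation(p6, p6), 1)
  set.seed(8)
  n <- 1000
  a <- tibble::tibble(animal = paste0("x", 1:n), f_new = runif(n))
  b <- tibble::tibble(animal = paste0("x", 1:n), f_new = runif(n))
  expect_lt(abs(partition_correlation(a, b)), 3 / sqrt(n))
  expect_error(partition_correlation(a[1:2, ], b[1:2, ]), "3 shared")
})

test_that("compare_methods ranks identical partitions identically", {
  herd <- gs_herd(55)
  p6 <- herd$truth
  p5 <- partition_pedigree_inbreeding(herd$pedigree, 5,
                                      animals = herd$phenotypes$animal)
  spec <- model_spec("value", age_covariate = "age")
  cmp <- compare_methods(list(a = p6, b = p6, lit5 = p5),
                         herd$phenotypes, spec)
  expect_equal(cmp$adj_r2[cmp$method == "a"], cmp$adj_r2[cmp$method == "b"])
  expect_equal(cmp$aic[cmp$method == "a"], cmp$aic[cmp$method == "b"])
  expect_equal(min(cmp$aic_delta), 0)
  # generative-threshold covariates should beat the 5-generation literature
  # convention on data generated at t* = 6
  expect_lt(cmp$aic[cmp$method == "a"], cmp$aic[cmp$method == "lit5"])
})

test_that("proposed threshold outperforms the literature default across seeds", {
  wins <- 0L
  n_rep <- 6L
  for (s in seq_len(n_rep)) {
    herd <- gs_herd(200 + s)
    parts <- partition_pedigree_inbreeding(herd$pedigree, 3:10,
                                           animals = herd$phenotypes$animal)
    gs <- suppressWarnings(
      threshold_search(parts, herd$phenotypes, gs_spec(),
                       ped = herd$pedigree))
    sel <- gs$selected_threshold
    if (is.na(sel)) next
    spec <- model_spec("value", age_covariate = "age")
    cmp <- compare_methods(
      list(proposed = parts[parts$threshold == sel, ],
           literature_5 = parts[parts$threshold == 5, ]),
      herd$phenotypes, spec)
    if (cmp$aic[cmp$method == "proposed"] <=
        cmp$aic[cmp$method == "literature_5"]) wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})
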