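test_that("simulated pedigrees are valid, layered and deterministic", {
  cfg <- sim_config(n_founders = 30, n_generations = 5,
                    avoid_kin_depth = 2, trait = list(t_star = 3), seed = 4)
  ped <- simulate_pedigree(cfg)
  expect_s3_class(ped, "ped_tbl")
  expect_true(is_layered(ped))
  expect_equal(sum(ped$generation == 0), 30)
  # same seed -> identical pedigree
  ped2 <- simulate_pedigree(cfg)
  expect_identical(as.data.frame(ped), as.data.frame(ped2))
  # different seed -> different matings
  cfg3 <- sim_config(n_founders = 30, n_generations = 5,
                     avoid_kin_depth = 2, trait = list(t_star = 3), seed = 5)
  expect_false(identical(as.data.frame(simulate_pedigree(cfg3)),
                         as.data.frame(ped)))
})

test_that("kin avoidance suppresses shallow inbreeding loops", {
  cfg <- sim_config(n_founders = 150, n_generations = 7, avoid_kin_depth = 4,
                    trait = list(t_star = 5), seed = 2)
  ped <- simulate_pedigree(cfg)
  # no common ancestry within 4 generations -> truncated F at t = 4 is zero
  t4 <- truncated_inbreeding(ped, 4)
  expect_equal(max(t4$f_ped_t), 0)
  # but deeper background inbreeding exists in the closed herd
  f <- inbreeding_coefficients(ped)
  expect_gt(max(f$f_ped), 0)
})

test_that("obligate sib mating drives inbreeding up every generation", {
  cfg <- sim_config(n_founders = 24, n_generations = 6,
                    consanguinity_rate = 1,
                    consanguinity_mix = c(full_sib = 1, half_sib = 0,
                                          first_cousin = 0),
                    avoid_kin_depth = 0, trait = list(t_star = 2), seed = 6)
  ped <- simulate_pedigree(cfg)
  f <- inbreeding_coefficients(ped)
  mean_f <- tapply(f$f_ped, ped$generation, mean)
  expect_true(all(diff(mean_f[as.character(2:6)]) > 0))
})

test_that("founders have empty IBD tracks and fractions track pedigree F", {
  cfg <- sim_config(n_founders = 30, n_generations = 6,
                    consanguinity_rate = 0.4, avoid_kin_depth = 0,
                    n_chromosomes = 6, trait = list(t_star = 3), seed = 12)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_genomes(ped, cfg, markers = FALSE,
                          track_animals = ped$animal)
  founders <- ped$animal[ped$generation == 0]
  expect_false(any(sim$tracks$animal %in% founders))
  # regression of true autozygous fraction on pedigree F: slope ~ 1
  f <- inbreeding_coefficients(ped)
  tp <- true_partition(sim$tracks, 99, sim$genome_length_bp,
                       animals = ped$animal)
  keep <- f$f_ped > 0
  b <- coef(summary(lm(tp$f_total[keep] ~ f$f_ped[keep])))
  expect_lt(abs(b[2, 1] - 1), 3 * b[2, 2])
})

test_that("true_partition is additive and respects boundary conventions", {
  tracks <- tibble::tibble(animal = c("a", "a", "b"),
                           chromosome = 1L,
                           start_bp = c(0, 50e6, 10e6),
                           end_bp = c(10e6, 70e6, 15e6),
                           length_bp = c(10e6, 20e6, 5e6),
                           coalescence_generation = c(2, 8, 5))
  tp <- true_partition(tracks, 5, 100e6)
  expect_equal(tp$f_new + tp$f_old, tp$f_total, tolerance = 1e-12)
  expect_equal(tp$f_new[tp$animal == "a"], 0.1)   # g = 2 only
  expect_equal(tp$f_new[tp$animal == "b"], 0.05)  # g = 5 counts as new
  # t_star = 0 -> nothing new; t_star >= max age -> nothing old
  expect_equal(true_partition(tracks, 0, 100e6)$f_new, c(0, 0))
  expect_equal(true_partition(tracks, 10, 100e6)$f_old, c(0, 0))
})

test_that("noiseless phenotypes return the generative coefficients exactly", {
  # strip every stochastic channel: the phenotype is then the deterministic
  # linear predictor and OLS must return the generative betas to 1e-8
  cfg <- sim_config(n_founders = 40, n_generations = 8,
                    consanguinity_rate = 0.3, avoid_kin_depth = 0,
                    trait = list(t_star = 4, h2 = 1e-12, year_sd = 0,
                                 phenotype_min_generation = 5), seed = 9)
  ped <- simulate_pedigree(cfg)
  truth <- partition_pedigree_inbreeding(ped, 4)
  phen <- simulate_phenotypes(ped, truth, cfg)
  phen$value <- cfg$trait$mean +
    ifelse(phen$sex == "M", cfg$trait$sex_effect, 0) +
    cfg$trait$age_slope * (phen$age - 365) +
    cfg$trait$beta_new * standardize(phen$f_new_true) +
    cfg$trait$beta_old * standardize(phen$f_old_true)
  phen$f_new <- phen$f_new_true
  phen$f_old <- phen$f_old_true
  fit <- fit_fixed(phen, model_spec("value", age_covariate = "age"))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "z_new"], -0.8, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "z_old"], -0.2, tolerance = 1e-8)
  expect_equal(fit$criteria$rmse, 0, tolerance = 1e-8)

  # and the stochastic generator with defaults recovers them within noise
  herd <- simulate_herd(sim_config(n_founders = 120, n_generations = 10,
                                   trait = list(t_star = 6,
                                                phenotype_min_generation = 6),
                                   seed = 13))
  dat <- herd$phenotypes
  dat$f_new <- dat$f_new_true
  dat$f_old <- dat$f_old_true
  spec <- model_spec("value", age_covariate = "age", random = "direct",
                     varcomp = list(direct = 0.35, residual = 0.65))
  fm <- fit_mixed(dat, spec, herd$pedigree)
  cf <- fm$coefficients
  expect_lt(abs(cf$estimate[cf$term == "z_new"] + 0.8),
            3 * cf$std.error[cf$term == "z_new"])
  expect_lt(abs(cf$estimate[cf$term == "z_old"] + 0.2),
            3 * cf$std.error[cf$term == "z_old"])
})

test_that("simulated genomes are deterministic given the seed", {
  cfg <- sim_config(n_founders = 12, n_generations = 3, n_chromosomes = 2,
                    avoid_kin_depth = 0,
                    chrom_length_mb = 50, trait = list(t_star = 2), seed = 31)
  ped <- simulate_pedigree(cfg)
  a <- simulate_genomes(ped, cfg)
  b <- simulate_genomes(ped, cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
})

test_that("detected ROH recover most of the true IBD base pairs", {
  cfg <- sim_config(n_founders = 30, n_generations = 8,
                    consanguinity_rate = 0.4, avoid_kin_depth = 0,
                    n_chromosomes = 3, trait = list(t_star = 3), seed = 9)
  ped <- simulate_pedigree(cfg)
  ids <- ped$animal[ped$generation >= 7]
  sim <- simulate_genomes(ped, cfg, markers = TRUE, track_animals = ids)
  rohs <- detect_roh(sim$genotypes)
  tt <- sim$tracks[sim$tracks$length_bp >= 2e6, ]
  ov_total <- 0
  for (i in seq_len(nrow(tt))) {
    r <- rohs[rohs$animal == tt$animal[i] &
                rohs$chromosome == tt$chromosome[i], ]
    if (!nrow(r)) next
    ov <- pmax(0, pmin(r$end_bp, tt$end_bp[i]) -
                 pmax(r$start_bp, tt$start_bp[i]))
    ov_total <- ov_total + sum(ov)
  }
  expect_gt(ov_total / sum(tt$length_bp), 0.9)
})
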