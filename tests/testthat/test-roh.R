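test_that("detector finds a clean homozygous run and applies filters", {
  # 30 consecutive homozygous SNPs spanning 2.4 Mb (80 kb gaps)
  pos <- seq(1e6, by = 8e4, length.out = 30)
  g <- geno1(rep(0L, 30), pos)
  segs <- detect_roh(g, roh_params())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 30L)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[30])

  # too few SNPs
  pos14 <- seq(1e6, by = 1.2e6 / 13, length.out = 14)
  expect_equal(nrow(detect_roh(geno1(rep(0L, 14), pos14), roh_params())), 0L)
  # long enough in SNPs but too short in bp
  pos30 <- seq(1e6, by = 0.9e6 / 29, length.out = 30)
  expect_equal(nrow(detect_roh(geno1(rep(0L, 30), pos30), roh_params())), 0L)
  # a gap > 500 kb splits the run; both halves fail min_snps
  pos_gap <- c(seq(1e6, by = 8e4, length.out = 10),
               seq(3e6, by = 8e4, length.out = 10))
  expect_equal(nrow(detect_roh(geno1(rep(0L, 20), pos_gap), roh_params())), 0L)
})

test_that("het and missing budgets bound every emitted segment", {
  set.seed(77)
  params <- roh_params(min_length_bp = 4e5, min_snps = 5)
  for (r in 1:50) {
    calls <- sample(0:2, 60, replace = TRUE, prob = c(0.85, 0.1, 0.05))
    pos <- cumsum(runif(60, 2e4, 1.5e5)) + 1e5
    segs <- detect_roh(geno1(calls, pos), params)
    if (!nrow(segs)) next
    expect_true(all(segs$n_het <= params$max_het_per_segment))
    expect_true(all(segs$n_missing <= params$max_missing_per_segment))
    expect_true(all(segs$n_snps >= params$min_snps))
    expect_true(all(segs$length_bp >= params$min_length_bp))
    expect_true(all(segs$length_bp / segs$n_snps <=
                      params$min_density_bp_per_snp))
    # non-overlap within the chromosome
    if (nrow(segs) > 1) {
      expect_true(all(segs$start_bp[-1] > segs$end_bp[-nrow(segs)]))
    }
  }
})

test_that("detector equals the exhaustive maximal-run oracle", {
  set.seed(2024)
  params <- roh_params(min_length_bp = 5e5, min_snps = 6,
                       max_het_per_segment = 1, max_missing_per_segment = 2,
                       max_gap_bp = 3e5, min_density_bp_per_snp = 2e5)
  n_mismatch <- 0
  for (r in 1:400) {
    m <- sample(20:60, 1)
    calls <- sample(0:2, m, replace = TRUE, prob = c(0.8, 0.12, 0.08))
    pos <- cumsum(runif(m, 1e4, 3.5e5)) + 1e5
    segs <- detect_roh(geno1(calls, pos), params)
    orc <- roh_oracle(calls, pos, params)
    if (is.null(orc)) {
      n_mismatch <- n_mismatch + (nrow(segs) != 0)
    } else {
      same <- nrow(segs) == nrow(orc) &&
        all(segs$start_bp == pos[orc[, 1]]) &&
        all(segs$end_bp == pos[orc[, 2]])
      n_mismatch <- n_mismatch + !same
    }
  }
  expect_equal(n_mismatch, 0)
})

test_that("F_ROH is the covered fraction and additive over any bipartition", {
  segs <- tibble::tibble(
    animal = c("a", "a", "a", "b"),
    chromosome = c(1L, 1L, 2L, 1L),
    start_bp = c(1e6, 5e6, 2e6, 3e6),
    end_bp = c(2e6, 9e6, 4e6, 4.5e6),
    n_snps = 20L, n_het = 0L, n_missing = 0L)
  rs <- roh_set(segs, l_auto_bp = 24e6, samples = c("a", "b", "c"))
  f <- roh_inbreeding(rs)
  expect_equal(f$f_roh[f$animal == "a"], 7e6 / 24e6)
  expect_equal(f$f_roh[f$animal == "c"], 0)
  for (m in c(1, 2, 3, 5)) {
    p <- partition_roh_inbreeding(rs, m)
    expect_equal(p$f_new + p$f_old, f$f_roh, tolerance = 1e-12)
  }
  # boundary tie: a segment of exactly m Mb is long (new)
  p4 <- partition_roh_inbreeding(rs, 4)
  expect_equal(p4$f_new[p4$animal == "a"], 4e6 / 24e6)
  # monotone: f_new non-increasing in m
  grid <- partition_roh_inbreeding(rs, c(1, 2, 3, 4, 5))
  wide <- tidyr::pivot_wider(grid[, c("animal", "threshold", "f_new")],
                             names_from = "threshold", values_from = "f_new")
  expect_true(all(apply(as.matrix(wide[, -1]), 1,
                        function(r) all(diff(r) <= 1e-12))))
  # all segments below m: everything old
  p99 <- partition_roh_inbreeding(rs, 99)
  expect_equal(p99$f_new, rep(0, 3))
  expect_equal(p99$f_old, f$f_roh)
})

test_that("length-age conversion matches the 1/(2g) Morgan relation", {
  expect_equal(length_to_generations(17), 100 / 34, tolerance = 1e-12)
  expect_equal(generations_to_length(15), 100 / 30, tolerance = 1e-12)
  expect_equal(length_to_generations(50), 1)
  # inverse pair
  l <- c(0.5, 2, 8, 17, 50)
  expect_equal(generations_to_length(length_to_generations(l)), l)
  expect_error(length_to_generations(0), "positive")
  # non-default map density
  expect_equal(length_to_generations(10, mb_per_morgan = 80), 4)
})

test_that("plink text round-trip preserves calls and map", {
  cfg <- sim_config(n_founders = 12, n_generations = 2, n_chromosomes = 2,
                    chrom_length_mb = 10, marker_spacing_kb = 500,
                    trait = list(t_star = 1), seed = 8)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_genomes(ped, cfg)
  g <- sim$genotypes
  pedf <- tempfile(fileext = ".ped"); mapf <- tempfile(fileext = ".map")
  write_plink_text(g, pedf, mapf)
  g2 <- read_plink_text(pedf, mapf)
  expect_equal(g2$samples, g$samples)
  expect_equal(g2$map$position_bp, g$map$position_bp)
  # recoding against the first observed allele can flip hom classes but
  # never changes het/missing status or run structure
  expect_equal(g2$calls == 1L, g$calls == 1L)
  expect_equal(is.na(g2$calls), is.na(g$calls))
  expect_true(all((g2$calls %in% c(0L, 2L)) == (g$calls %in% c(0L, 2L)),
                  na.rm = TRUE))
})

test_that("plink reader flags malformed inputs", {
  mapf <- tempfile(); writeLines(c("1 m1 0 100", "1 m2 0 200"), mapf)
  pedf <- tempfile(); writeLines("f1 s1 0 0 1 -9 A A", pedf)
  expect_error(read_plink_text(pedf, mapf), "expected")
  writeLines(c("f1 s1 0 0 1 -9 A A C C",
               "f2 s2 0 0 1 -9 G T C C"), pedf)
  expect_error(read_plink_text(pedf, mapf), ">2 alleles")
  # missing allele pair becomes NA
  writeLines(c("f1 s1 0 0 1 -9 A A 0 0", "f2 s2 0 0 1 -9 A G G G"), pedf)
  g <- read_plink_text(pedf, mapf)
  expect_true(is.na(g$calls["s1", "m2"]))
  expect_equal(g$calls["s2", "m1"], 1L)
})
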