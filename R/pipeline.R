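#' Run the inbreeding-classification pipeline
#'
#' Executes the stages in dependency order from a single configuration:
#' simulate (or load) a herd, compute pedigree inbreeding and its
#' changing-base partitions over the `t` grid, optionally detect ROH and
#' partition over the `m` grid, run the grid search per source, and compare
#' methods.  Every output file carries a metadata header (tool version,
#' seed, config hash); reruns with the same config and seed are
#' byte-identical.
#'
#' The configuration is a nested list (or YAML file) with sections:
#' \describe{
#'   \item{seed}{integer; funnels all randomness.}
#'   \item{simulate}{arguments for [sim_config()] (used when no `paths`
#'     section provides data).}
#'   \item{paths}{`pedigree`, `phenotypes`, optionally `ped`/`map` input
#'     files.}
#'   \item{grid}{`t` (integer vector, default 3:16) and `m_mb` (default
#'     c(3, 5, 7, 9, 11, 13, 15, 17)).}
#'   \item{roh}{[roh_params()] overrides; `enabled` to force ROH stage.}
#'   \item{model}{`trait` column, `fixed`, `age_covariate`, `random`,
#'     `varcomp`, `engine`.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config List or path to a YAML file.
#' @return Invisibly, a list of stage results (pedigree, partitions,
#'   searches, comparison, output paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  hcfg <- config
  hcfg$out_dir <- NULL  # identical analyses hash identically
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(paste(deparse(hcfg),
                                                  collapse = ""))))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  meta <- c(sprintf("# autozyg %s", as.character(utils::packageVersion("autozyg"))),
            sprintf("# seed: %d", seed),
            sprintf("# config_hash: %s", cfg_hash))
  write_meta_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(meta, path)
    suppressWarnings(readr::write_tsv(df, path, append = TRUE,
                                      col_names = TRUE))
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  results <- list()

  # ---- data stage -------------------------------------------------------
  have_paths <- !is.null(config$paths$pedigree)
  if (have_paths) {
    ped <- stage("load-pedigree", read_pedigree(config$paths$pedigree))
    phen <- stage("load-phenotypes", {
      p <- config$paths$phenotypes
      if (is.null(p) || !file.exists(p %||% "")) {
        abort(paste0("phenotype file not found: ", p))
      }
      readr::read_csv(p, show_col_types = FALSE)
    })
    geno <- NULL
    if (!is.null(config$paths$ped) && !is.null(config$paths$map)) {
      geno <- stage("load-genotypes",
                    read_plink_text(config$paths$ped, config$paths$map))
    }
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- seed
    scfg <- stage("simulate", do.call(sim_config, sim_args))
    herd <- stage("simulate", simulate_herd(scfg))
    ped <- herd$pedigree
    phen <- herd$phenotypes
    geno <- NULL
    results$sim_config <- scfg
    write_meta_tsv(ped, "pedigree.tsv")
    write_meta_tsv(phen, "phenotypes.tsv")
  }

  # ---- pedigree inbreeding stage ---------------------------------------
  t_grid <- as.integer(config$grid$t %||% 3:16)
  inb <- stage("ped-inbreed", {
    dplyr::left_join(inbreeding_coefficients(ped), pedigree_stats(ped),
                     by = "animal")
  })
  parts_ped <- stage("partition",
                     partition_pedigree_inbreeding(ped, t_grid,
                                                   animals = phen$animal))
  results$inbreeding <- inb
  results$partitions_pedigree <- parts_ped
  write_meta_tsv(inb, "inbreeding.tsv")
  write_meta_tsv(parts_ped, "partitions_pedigree.tsv")

  # ---- ROH stage (only with genotype input) ----------------------------
  parts_roh <- NULL
  if (!is.null(geno)) {
    m_grid <- as.numeric(config$grid$m_mb %||% c(3, 5, 7, 9, 11, 13, 15, 17))
    rp_args <- config$roh %||% list()
    rp_args$enabled <- NULL
    rohs <- stage("roh-detect", detect_roh(geno, do.call(roh_params, rp_args)))
    parts_roh <- stage("partition", partition_roh_inbreeding(rohs, m_grid))
    results$roh <- rohs
    results$partitions_roh <- parts_roh
    write_meta_tsv(as_tibble(rohs), "roh_segments.tsv")
    write_meta_tsv(parts_roh, "partitions_roh.tsv")
  }

  # ---- model / grid search stage ---------------------------------------
  mcfg <- config$model %||% list()
  spec <- model_spec(
    trait = mcfg$trait %||% "value",
    fixed = mcfg$fixed %||% c("sex", "birth_year"),
    age_covariate = mcfg$age_covariate %||% "age",
    random = mcfg$random %||% "direct",
    varcomp = mcfg$varcomp %||%
      list(direct = 0.35, residual = 0.65))
  engine <- mcfg$engine %||% "mixed"
  searches <- list()
  searches$pedigree <- stage("gridsearch",
    threshold_search(parts_ped, phen, spec, ped = ped, engine = engine))
  if (!is.null(parts_roh)) {
    searches$roh <- stage("gridsearch",
      threshold_search(parts_roh, phen, spec, ped = ped, engine = engine))
  }
  results$searches <- searches
  for (nm in names(searches)) {
    write_meta_tsv(searches[[nm]]$table, paste0("gridsearch_", nm, ".tsv"))
  }

  # ---- method comparison stage -----------------------------------------
  sel <- searches$pedigree$selected_threshold
  methods <- list()
  if (!is.na(sel)) {
    methods[[paste0("P_", sel, "P")]] <-
      parts_ped[parts_ped$threshold == sel, ]
  }
  methods[["P_5L"]] <- partition_pedigree_inbreeding(ped, 5L,
                                                     animals = phen$animal)
  kal <- stage("gene-drop", gene_drop(ped, n_reps = config$gene_drop_reps %||%
                                        2e4, seed = seed))
  methods[["Kalinowski"]] <- tibble(animal = kal$animal,
                                    f_total = kal$f_hat,
                                    f_new = kal$f_new_kal,
                                    f_old = kal$f_anc_kal,
                                    method = "kalinowski",
                                    threshold = NA_real_)
  cmp <- stage("compare", compare_methods(methods, phen, spec))
  results$comparison <- cmp
  write_meta_tsv(cmp, "method_comparison.tsv")
  results$out_dir <- out_dir
  invisible(results)
}
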