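#' Run the full analysis pipeline
#'
#' Chains the stages end to end: simulate (or load) a VCF, read and
#' hard-filter variants, build and site-filter the dosage matrix, summarize
#' variants, compute the NJ tree and PCA, select the core collection,
#' evaluate diversity, and build the fingerprint panel. Every artifact is
#' written under `output_dir` together with a manifest (parameters, derived
#' per-stage seeds, output checksums).
#'
#' @param config Either a path to a YAML file or a nested list. Recognized
#'   top-level keys: `output_dir` (required), `seed`, `input_vcf`,
#'   `simulate` (a list of [pop_config()] arguments; used when `input_vcf`
#'   is absent), `filter` (`maf_min`, `max_missing`), `tree`
#'   (`bootstrap`), `pca` (`k`), `core` (`target_size` or
#'   `target_coverage`/`gain_floor`), `diversity` (`proportions`),
#'   `fingerprint` (`method` = "ga", "greedy" or "exact", plus [ga_params()]
#'   fields). Unknown keys are rejected.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("output_dir", "seed", "input_vcf", "simulate", "filter",
             "tree", "pca", "core", "diversity", "fingerprint")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  if (is.null(config$output_dir)) stop("config field 'output_dir' is missing")
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage_seeds <- list()
  manifest <- list(parameters = config, stages = list(), seeds = list())
  artifacts <- character(0)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # stage 1: obtain a VCF
  vcf_path <- config$input_vcf
  if (is.null(vcf_path)) {
    vcf_path <- file.path(out, "simulated.vcf")
    run_stage("simulate", {
      args <- config$simulate
      args$seed <- stage_seed(seed, 1L)
      stage_seeds$simulate <- args$seed
      cfg <- do.call(pop_config, args)
      gm0 <- simulate_population(cfg)
      info <- simulate_info(gm0, seed = stage_seed(seed, 11L))
      write_vcf(gm0, vcf_path, info = info, timestamp = FALSE)
    })
    artifacts <- c(artifacts, vcf_path)
  } else if (!file.exists(vcf_path)) {
    stop("config field 'input_vcf' names a missing file: ", vcf_path)
  }

  # stage 2: read + hard filters + summary
  vcf <- run_stage("stats", read_vcf(vcf_path))
  run_stage("stats", {
    cls <- classify_variant(vcf$variants$ref, vcf$variants$alt)
    pass <- rep(TRUE, nrow(vcf$variants))
    pass[cls == "SNP"] <-
      apply_hard_filters(vcf$variants[cls == "SNP", , drop = FALSE],
                         "SNP")$pass
    ind <- cls %in% c("insertion", "deletion")
    pass[ind] <- apply_hard_filters(vcf$variants[ind, , drop = FALSE],
                                    "InDel")$pass
    pass[cls == "mixed"] <- FALSE
    vcf$variants <- vcf$variants[pass, , drop = FALSE]
    vcf$gt <- vcf$gt[pass, , drop = FALSE]
    smry <- summarize_variants(vcf$variants)
    write_variant_summary(smry, tsv = file.path(out, "variant_summary.tsv"),
                          json = file.path(out, "variant_summary.json"))
  })
  artifacts <- c(artifacts, file.path(out, "variant_summary.tsv"),
                 file.path(out, "variant_summary.json"))

  # stage 3: dosage matrix + site filter
  gm <- run_stage("filter", {
    g <- from_vcf(vcf)
    fargs <- config$filter
    g <- site_filter(g,
                     maf_min = fargs$maf_min %||% 0.05,
                     max_missing = fargs$max_missing %||% 0.20)
    write.table(filter_audit(g), file.path(out, "filter_audit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_dosage_tsv(g, file.path(out, "dosages.tsv"))
    g
  })
  artifacts <- c(artifacts, file.path(out, "filter_audit.tsv"),
                 file.path(out, "dosages.tsv"))

  # stage 4: tree
  run_stage("tree", {
    n_boot <- config$tree$bootstrap %||% 0
    stage_seeds$tree <- stage_seed(seed, 4L)
    tr <- if (n_boot > 0)
      bootstrap_support(gm, n_reps = n_boot, seed = stage_seeds$tree)
    else nj_tree(squared_distance(gm))
    ape::write.tree(tr, file.path(out, "nj_tree.nwk"))
  })
  artifacts <- c(artifacts, file.path(out, "nj_tree.nwk"))

  # stage 5: pca
  pca <- run_stage("pca", {
    k <- config$pca$k %||% 10
    p <- pca_grm(grm(gm), k = min(k, nrow(gm$dosages)))
    write.table(p$coordinates, file.path(out, "pca_coordinates.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(data.frame(component = seq_along(p$variance_explained),
                           variance_explained = p$variance_explained),
                file.path(out, "pca_variance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    p
  })
  artifacts <- c(artifacts, file.path(out, "pca_coordinates.tsv"),
                 file.path(out, "pca_variance.tsv"))

  # stage 6: core collection
  core <- run_stage("core", {
    cargs <- config$core
    cr <- if (!is.null(cargs$target_size))
      greedy_core(gm, target_size = cargs$target_size)
    else greedy_core(gm,
                     target_coverage = cargs$target_coverage %||% 99,
                     gain_floor = cargs$gain_floor %||% 0.01)
    write_core_result(cr, ids_path = file.path(out, "core_ids.txt"),
                      trajectory_path = file.path(out,
                                                  "core_trajectory.tsv"))
    cr
  })
  artifacts <- c(artifacts, file.path(out, "core_ids.txt"),
                 file.path(out, "core_trajectory.tsv"))

  # stage 7: diversity evaluation
  run_stage("diversity", {
    stage_seeds$diversity <- stage_seed(seed, 6L)
    tab <- sampling_evaluation(
      gm, core$ids,
      proportions = config$diversity$proportions %||% c(10, 25, 50, 75, 100),
      seed = stage_seeds$diversity)
    write.table(tab, file.path(out, "diversity_sampling.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  artifacts <- c(artifacts, file.path(out, "diversity_sampling.tsv"))

  # stage 8: fingerprint
  run_stage("fingerprint", {
    method <- config$fingerprint$method %||% "ga"
    cand <- candidate_filter(gm)
    stage_seeds$fingerprint <- stage_seed(seed, 7L)
    panel <- switch(method,
      ga = {
        ga_args <- config$fingerprint
        ga_args$method <- NULL
        ga_args$n_candidates <- length(cand)
        ga_args$seed <- stage_seeds$fingerprint
        ga_select(gm, cand, do.call(ga_params, ga_args))
      },
      greedy = greedy_select(gm, cand),
      exact = exhaustive_min(gm, cand),
      stop("unknown fingerprint method '", method, "'"))
    sites <- gm$loci[panel$loci, c("chrom", "pos", "ref", "alt")]
    write.table(sites, file.path(out, "fingerprint_sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    fingerprint_table(gm, panel, tsv = file.path(out, "fingerprint.tsv"))
    writeLines(paste(names(panel$codes), panel$codes, sep = "\t"),
               file.path(out, "fingerprint_codes.tsv"))
  })
  artifacts <- c(artifacts, file.path(out, "fingerprint_sites.tsv"),
                 file.path(out, "fingerprint.tsv"),
                 file.path(out, "fingerprint_codes.tsv"))

  manifest$seeds <- c(list(global = seed), stage_seeds)
  manifest$stages <- c("simulate", "stats", "filter", "tree", "pca", "core",
                       "diversity", "fingerprint")
  manifest$checksums <- as.list(tools::md5sum(artifacts))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
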