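#' Assemble a pipeline configuration
#'
#' All stage thresholds in one validated list; defaults are the analysis
#' defaults used throughout the package (adjusted p < 0.05, two-fold
#' change, epsilon 0.5, module min size 5, density 0.5, top 50 drugs).
#'
#' @param matrices,labels Character vectors of expression/label TSV paths,
#'   one per study.
#' @param out_dir Output directory (created if absent).
#' @param alpha Adjusted-p cutoff for differential expression, default 0.05.
#' @param fc_threshold Linear fold-change cutoff, default 2.
#' @param epsilon Differential-correlation threshold, default 0.5.
#' @param pcritic_abs Use |SCC| in the critical-cutoff formula, default
#'   `FALSE` (signed).
#' @param min_module_size,density_threshold Module filter, defaults 5 and
#'   0.5.
#' @param top_k Drugs returned by the reversal ranking, default 50.
#' @param survival_table,survival_matrix,survival_labels Optional paths to
#'   the validation-cohort survival TSV and expression matrix/labels.
#' @param stratify_by_stage Run stage-stratified prognostics, default
#'   `FALSE`.
#' @param drug_library,corpus,drugs Optional paths: drug-signature TSV,
#'   JSON-lines abstract corpus, plain-text drug-name list.
#' @param gmt Optional GMT path for over-representation of the common DEGs.
#' @param seed Integer seed recorded in the manifest, default 1.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrices, labels, out_dir,
                            alpha = 0.05, fc_threshold = 2, epsilon = 0.5,
                            pcritic_abs = FALSE, min_module_size = 5,
                            density_threshold = 0.5, top_k = 50,
                            survival_table = NULL, survival_matrix = NULL,
                            survival_labels = NULL,
                            stratify_by_stage = FALSE,
                            drug_library = NULL, corpus = NULL, drugs = NULL,
                            gmt = NULL, seed = 1) {
  stopifnot(length(matrices) == length(labels), length(matrices) >= 2,
            alpha > 0, alpha < 1, fc_threshold >= 1, epsilon >= 0,
            min_module_size >= 3, density_threshold > 0,
            density_threshold <= 1, top_k >= 1)
  paths <- c(matrices, labels, survival_table, survival_matrix,
             survival_labels, drug_library, corpus, gmt)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("referenced file(s) do not exist: ", paste(missing, collapse = ", "))
  }
  rm(paths, missing)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the differential co-expression pipeline end to end
#'
#' Stages: per-study differential expression, common-DEG intersection,
#' optional over-representation, condition-wise pooled Spearman
#' correlation, critical-cutoff and epsilon pair selection, network and
#' module construction, then (as configured) prognostic evaluation,
#' drug-reversal ranking and literature-novelty scoring. All stage outputs
#' are written under `config$out_dir` together with a manifest recording
#' inputs, thresholds, the seed and every output file, enabling exact
#' re-runs.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results (`degs`, `common_degs`, `pairs`, `network`, `modules`, and
#'   when configured `ora`, `prognostic`, `repurposing`, `novelty`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  out <- function(...) file.path(config$out_dir, paste0(...))
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  studies <- stage("read", mapply(function(m, l) {
    collapse_duplicate_genes(read_expression_matrix(m, l))
  }, config$matrices, config$labels, SIMPLIFY = FALSE))

  degs <- stage("deg", lapply(studies, differential_expression,
                              alpha = config$alpha,
                              fc_threshold = config$fc_threshold))
  for (i in seq_along(degs)) {
    f <- out("deg_", studies[[i]]$study_id, ".tsv")
    write_deg_table(degs[[i]], f)
    outputs <- c(outputs, f)
  }

  common <- stage("intersect", intersect_common_degs(degs))
  writeLines(common, out("common_degs.txt"))
  outputs <- c(outputs, out("common_degs.txt"))

  results <- list(degs = degs, common_degs = common)

  if (!is.null(config$gmt)) {
    results$ora <- stage("ora", {
      collection <- read_gmt(config$gmt)
      universe <- Reduce(intersect, lapply(studies, `[[`, "genes"))
      ora_fisher(intersect(common, universe), universe, collection,
                 alpha = config$alpha)
    })
    utils::write.table(results$ora, out("ora.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, out("ora.tsv"))
  }

  if (length(common) < 2) stop("pipeline stage 'coexpress' failed: fewer than 2 common DEGs")
  corr <- stage("coexpress", {
    pool_d <- pool_condition_samples(studies, common, "disease")
    pool_h <- pool_condition_samples(studies, common, "control")
    list(d = pairwise_scc(pool_d, condition = "disease"),
         h = pairwise_scc(pool_h, condition = "control"))
  })
  pc_d <- compute_pcritic(corr$d, use_abs = config$pcritic_abs)
  pc_h <- compute_pcritic(corr$h, use_abs = config$pcritic_abs)
  pairs <- stage("pairs", select_differential_pairs(
    corr$d, corr$h, pc_d, epsilon_threshold = config$epsilon,
    pcritic_h = pc_h))
  utils::write.table(pairs, out("differential_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  net <- stage("network", build_network(pairs))
  write_network_graphml(net, out("network.graphml"))
  write_network_sif(net, out("network.sif"))
  modules <- stage("modules", detect_modules(
    net, min_size = config$min_module_size,
    density_threshold = config$density_threshold))
  write_module_summary(modules, out("modules.tsv"))
  if (length(modules) > 0) {
    write_gmt(stats::setNames(lapply(modules, `[[`, "nodes"),
                              vapply(modules, `[[`, character(1), "module_id")),
              out("modules.gmt"))
    outputs <- c(outputs, out("modules.gmt"))
  }
  outputs <- c(outputs, out("differential_pairs.tsv"), out("network.graphml"),
               out("network.sif"), out("modules.tsv"))
  results <- c(results, list(correlations = corr,
                             pcritic = list(disease = pc_d, control = pc_h),
                             pairs = pairs, network = net, modules = modules))

  # meta DEG summary over the common genes drives the module signature
  meta_deg <- stage("meta_deg", {
    fc <- sapply(degs, function(t) t$log2fc[match(common, t$gene)])
    fc <- rowMeans(matrix(fc, nrow = length(common)))
    data.frame(gene = common, log2fc = fc,
               direction = ifelse(fc > 0, "up", "down"),
               stringsAsFactors = FALSE)
  })

  top_module <- if (length(modules) > 0) modules[[1]] else NULL

  if (!is.null(top_module) && !is.null(config$survival_table)) {
    results$prognostic <- stage("survival", {
      surv <- read_survival_table(config$survival_table)
      vstudy <- if (!is.null(config$survival_matrix)) {
        read_expression_matrix(config$survival_matrix,
                               config$survival_labels,
                               require_min_samples = FALSE)
      } else studies[[1]]
      evaluate_prognostic_module(surv, top_module, vstudy,
                                 stratify_by_stage = config$stratify_by_stage,
                                 alpha = config$alpha)
    })
    write_km_curves(results$prognostic$km, out("km_curves.tsv"))
    jsonlite::write_json(
      list(p_value = results$prognostic$logrank$p_value,
           statistic = results$prognostic$logrank$statistic,
           prognostic = results$prognostic$prognostic),
      out("prognostic.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, out("km_curves.tsv"), out("prognostic.json"))
  }

  if (!is.null(top_module) && !is.null(config$drug_library)) {
    results$repurposing <- stage("repurpose", {
      sig <- build_module_signature(top_module, meta_deg)
      reversal_score(sig, read_drug_library(config$drug_library),
                     top_k = config$top_k)
    })
    utils::write.table(results$repurposing, out("repurposing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, out("repurposing.tsv"))
  }

  if (!is.null(config$corpus) && !is.null(config$drugs)) {
    results$novelty <- stage("textmine", {
      drug_names <- readLines(config$drugs, warn = FALSE)
      tfidf_novelty(drug_names[nzchar(drug_names)],
                    read_corpus_jsonl(config$corpus))
    })
    utils::write.table(results$novelty, out("novelty.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, out("novelty.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dicoexnet")),
    inputs = list(matrices = config$matrices, labels = config$labels,
                  survival_table = config$survival_table,
                  drug_library = config$drug_library,
                  corpus = config$corpus, gmt = config$gmt),
    thresholds = list(alpha = config$alpha,
                      fc_threshold = config$fc_threshold,
                      epsilon = config$epsilon,
                      pcritic_abs = config$pcritic_abs,
                      min_module_size = config$min_module_size,
                      density_threshold = config$density_threshold,
                      top_k = config$top_k),
    seed = config$seed,
    n_common_degs = length(common),
    n_modules = length(modules),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
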