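#' Simulation configuration
#'
#' Parameters of the synthetic multi-cohort generator. Defaults echo the
#' scale of a five-cohort, ~300-pooled-sample two-phenotype design with a
#' planted 20-gene differential co-expression module inside a pool of 50
#' planted differentially expressed genes.
#'
#' @param n_studies Number of cohorts, default 5.
#' @param samples_per_phenotype Samples per phenotype per cohort, default
#'   30 (150 pooled per condition over 5 cohorts).
#' @param n_genes Genes per cohort, default 500.
#' @param n_planted_degs Genes given a disease shift, default 50.
#' @param deg_log2fc Disease shift on the log2 scale, default 1.5
#'   (about a 2.8-fold change; sign per gene is its planted direction).
#' @param module_size Genes of the planted co-expression module (a subset
#'   of the planted DEGs), default 20.
#' @param module_loading_disease Latent-factor loading of module genes in
#'   the disease condition, in (0,1), default 0.8 (pairwise correlation
#'   magnitude about loading^2 = 0.64).
#' @param module_loading_control Loading in the control condition,
#'   default 0.
#' @param noise_sd Residual standard deviation, default 0.5.
#' @param survival_baseline_hazard Exponential baseline hazard, default
#'   0.01 per time unit (months).
#' @param survival_beta Log-hazard per unit module score, default 1.
#' @param censoring_rate Target fraction censored, in \[0,1), default 0.3.
#' @param seed Integer seed driving every random draw, default 1.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_studies = 5,
                              samples_per_phenotype = 30,
                              n_genes = 500,
                              n_planted_degs = 50,
                              deg_log2fc = 1.5,
                              module_size = 20,
                              module_loading_disease = 0.8,
                              module_loading_control = 0,
                              noise_sd = 0.5,
                              survival_baseline_hazard = 0.01,
                              survival_beta = 1,
                              censoring_rate = 0.3,
                              seed = 1) {
  cfg <- list(n_studies = n_studies,
              samples_per_phenotype = samples_per_phenotype,
              n_genes = n_genes, n_planted_degs = n_planted_degs,
              deg_log2fc = deg_log2fc, module_size = module_size,
              module_loading_disease = module_loading_disease,
              module_loading_control = module_loading_control,
              noise_sd = noise_sd,
              survival_baseline_hazard = survival_baseline_hazard,
              survival_beta = survival_beta,
              censoring_rate = censoring_rate, seed = seed)
  stopifnot(n_studies >= 1, samples_per_phenotype >= 3, n_genes >= 1,
            n_planted_degs >= 0, n_planted_degs <= n_genes,
            module_size <= n_planted_degs,
            module_loading_disease > 0, module_loading_disease < 1,
            module_loading_control >= 0, module_loading_control < 1,
            noise_sd > 0, survival_baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1)
  structure(cfg, class = "simulation_config")
}

#' Simulate multi-cohort expression data with planted structure
#'
#' Each cohort is a genes x samples log2-scale matrix: background genes
#' draw from Normal(mu_g, noise_sd) identically in both phenotypes;
#' planted DEGs are shifted by `deg_log2fc` in disease (sign = planted
#' direction); module genes additionally load on a per-sample latent
#' factor with loading `module_loading_disease` in disease and
#' `module_loading_control` in control, so module pairs are strongly
#' positively correlated in disease and essentially uncorrelated in
#' control. Study-specific noise genes are
#' also shifted so each cohort's DEG list contains non-shared genes.
#'
#' @param config A [simulation_config()].
#' @return List with `studies` (list of [expression_study()]) and `truth`
#'   (list: `planted_degs`, `module_genes`, `directions` named
#'   up/down vector, `study_specific_degs`).
#' @export
simulate_multistudy_expression <- function(config) {
  set.seed(config$seed)
  n_g <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n_g))
  planted <- genes[seq_len(config$n_planted_degs)]
  module <- planted[seq_len(config$module_size)]
  directions <- stats::setNames(
    sample(c("up", "down"), config$n_planted_degs, replace = TRUE), planted)
  mu <- stats::rnorm(n_g, mean = 8, sd = 1.5)
  names(mu) <- genes
  shift <- stats::setNames(numeric(n_g), genes)
  shift[planted] <- ifelse(directions == "up", 1, -1) * config$deg_log2fc
  lam_sign <- stats::setNames(numeric(n_g), genes)
  lam_sign[module] <- 1
  n_noise <- max(1L, round(0.02 * n_g))
  free <- setdiff(genes, planted)
  studies <- vector("list", config$n_studies)
  study_specific <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    n <- config$samples_per_phenotype
    labels <- rep(c("disease", "control"), each = n)
    ids <- sprintf("S%d_%s%02d", s,
                   ifelse(labels == "disease", "D", "C"),
                   c(seq_len(n), seq_len(n)))
    extra <- sample(free, n_noise)
    study_specific[[s]] <- extra
    extra_dir <- sample(c(1, -1), n_noise, replace = TRUE)
    lam <- config$module_loading_disease
    lam0 <- config$module_loading_control
    f <- stats::rnorm(2 * n)
    vals <- matrix(0, n_g, 2 * n, dimnames = list(genes, ids))
    for (j in seq_len(2 * n)) {
      is_d <- labels[j] == "disease"
      loading <- if (is_d) lam else lam0
      factor_part <- lam_sign * loading * f[j]
      resid_scale <- ifelse(lam_sign != 0, sqrt(1 - loading^2), 1)
      e <- stats::rnorm(n_g)
      vals[, j] <- mu + shift * is_d +
        config$noise_sd * (factor_part + resid_scale * e)
    }
    if (n_noise > 0) {
      dcols <- which(labels == "disease")
      vals[extra, dcols] <- vals[extra, dcols] +
        extra_dir * config$deg_log2fc
    }
    studies[[s]] <- expression_study(sprintf("SIM%d", s), vals, labels)
  }
  list(studies = studies,
       truth = list(planted_degs = planted, module_genes = module,
                    directions = directions,
                    study_specific_degs = study_specific))
}

#' Simulate survival data whose hazard depends on a score
#'
#' Event times are Exponential with rate
#' `baseline * exp(beta * score)`; censoring times are independent
#' Uniform(0, tau), with tau solved numerically so that the expected
#' censored fraction under the mixture of the samples' hazards equals
#' `censoring_rate`. Stage I-IV is assigned by score quartile, mimicking
#' stage-linked prognosis.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param config A [simulation_config()] (`survival_baseline_hazard`,
#'   `survival_beta`, `censoring_rate`, `seed` are used).
#' @param seed Optional seed overriding `config$seed`.
#' @return Survival `data.frame`: `sample_id`, `time`, `event`, `stage`,
#'   `score`.
#' @export
simulate_survival <- function(scores, config, seed = config$seed) {
  stopifnot(all(is.finite(scores)))
  if (config$survival_baseline_hazard <= 0) stop("baseline hazard must be > 0")
  set.seed(seed)
  n <- length(scores)
  rate <- config$survival_baseline_hazard *
    exp(config$survival_beta * scores)
  t_event <- stats::rexp(n, rate = rate)
  if (config$censoring_rate > 0) {
    # censored fraction under C ~ U(0, tau), T_i ~ Exp(rate_i):
    # P(censored) = mean_i (1 - exp(-rate_i * tau)) / (rate_i * tau)
    target <- config$censoring_rate
    f <- function(tau) {
      mean((1 - exp(-rate * tau)) / (rate * tau)) - target
    }
    rbar <- mean(rate)
    tau <- stats::uniroot(f, lower = 1e-9 / rbar, upper = 1e9 / rbar,
                          tol = 1e-10)$root
    t_cens <- stats::runif(n, 0, tau)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75))
  stage <- cut(scores, breaks = c(-Inf, q, Inf),
               labels = c("I", "II", "III", "IV"))
  ids <- if (!is.null(names(scores))) names(scores)
         else sprintf("P%04d", seq_len(n))
  data.frame(sample_id = ids, time = time, event = event,
             stage = as.character(stage), score = unname(scores),
             stringsAsFactors = FALSE)
}

#' Simulate an abstract corpus and a drug-signature library
#'
#' The corpus contains `n_docs` short abstracts; drugs designated "known"
#' are mentioned with set per-document frequencies in cancer-context
#' abstracts, drugs designated "novel" never occur. The library holds one
#' exact reverser of the supplied signature (weights = minus the
#' signature weights) plus random-weight decoys over the signature genes.
#'
#' @param drugs Character vector of drug names; the first
#'   `n_known` are mentioned in the corpus, the rest never are.
#' @param config A [simulation_config()] (seed).
#' @param signature A `gene_signature`; the first drug acts as its exact
#'   reverser in the library.
#' @param n_docs Corpus size, default 10.
#' @param n_known How many drugs are mentioned, default
#'   `ceiling(length(drugs)/2)`.
#' @param mentions_per_known Occurrences of each known drug in its single
#'   mentioning abstract, default 3.
#' @return List with `corpus` (named character vector), `library`
#'   (`drug_signature_library`), `known_drugs`, `novel_drugs`.
#' @export
simulate_corpus_and_library <- function(drugs, config, signature,
                                        n_docs = 10,
                                        n_known = ceiling(length(drugs) / 2),
                                        mentions_per_known = 3) {
  stopifnot(length(drugs) >= 1, n_known <= length(drugs))
  set.seed(config$seed + 1L)
  known <- drugs[seq_len(n_known)]
  novel <- setdiff(drugs, known)
  base_texts <- c(
    "Thyroid cancer incidence has increased steadily over the last decade.",
    "We profile gene expression in papillary thyroid carcinoma cohorts.",
    "Patients with thyroid carcinoma show distinct co-expression patterns.",
    "Cancer progression is driven by rewiring of regulatory networks.",
    "This study examines survival outcomes in a large cancer registry.",
    "Module-based biomarkers improve prognosis prediction in cancer.",
    "Differential correlation reveals phenotype-specific gene pairs.",
    "Network medicine links molecular interactions to disease phenotypes.",
    "Drug repurposing screens prioritise compounds reversing signatures.",
    "Text mining of abstracts quantifies the novelty of drug candidates.")
  corpus <- rep_len(base_texts, n_docs)
  for (i in seq_along(known)) {
    doc <- 1 + (i - 1) %% n_docs
    mention <- paste(rep(known[i], mentions_per_known), collapse = " and ")
    corpus[doc] <- paste(corpus[doc], "Treatment with", mention,
                         "reduced tumour growth in thyroid cancer models.")
  }
  names(corpus) <- sprintf("DOC%03d", seq_len(n_docs))
  sig_genes <- c(signature$up, signature$down)
  w <- signature$weights[sig_genes]
  lib <- list()
  lib[[drugs[1]]] <- -w
  for (d in drugs[-1]) {
    k <- sample(seq(3, max(3, length(sig_genes))), 1)
    gsel <- sample(sig_genes, min(k, length(sig_genes)))
    lib[[d]] <- stats::setNames(stats::rnorm(length(gsel)), gsel)
  }
  list(corpus = corpus, library = validate_drug_library(lib),
       known_drugs = known, novel_drugs = novel)
}
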