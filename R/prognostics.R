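#' Per-sample module expression score
#'
#' Summarizes a gene module in one number per sample: the mean of the
#' (z-scored) expression of the module genes present in the matrix.
#' Module genes missing from the matrix are dropped with a warning.
#'
#' @param study An [expression_study()].
#' @param module_genes Character vector of module gene symbols (or a
#'   `coexpression_module`, whose `nodes` are used).
#' @param zscore Z-score the matrix rows before averaging; default `TRUE`.
#' @return Named numeric vector of scores, one per sample.
#' @export
module_score <- function(study, module_genes, zscore = TRUE) {
  if (inherits(module_genes, "coexpression_module")) {
    module_genes <- module_genes$nodes
  }
  present <- intersect(module_genes, study$genes)
  if (length(present) == 0) stop("no module gene present in the matrix")
  missing <- setdiff(module_genes, study$genes)
  if (length(missing) > 0) {
    warning(length(missing), " module gene(s) absent from matrix: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  if (zscore) {
    study <- zscore_normalize(
      expression_study(study$study_id,
                       study$values[present, , drop = FALSE],
                       study$labels, require_min_samples = FALSE))
    present <- study$genes
    if (length(present) == 0) stop("no module gene with nonzero variance")
  }
  colMeans(study$values[present, , drop = FALSE])
}

#' Median split of samples into high/low risk groups
#'
#' `high` = score strictly above the median, `low` = score at or below it
#' (ties go low). With distinct scores the group sizes differ by at most
#' one.
#'
#' @param scores Numeric vector of per-sample scores (names kept).
#' @return Character vector (`"high"`/`"low"`) parallel to `scores`.
#' @export
assign_risk_groups <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples")
  if (length(unique(scores)) == 1) {
    stop("all scores identical; no stratification possible")
  }
  med <- stats::median(scores)
  stats::setNames(ifelse(scores > med, "high", "low"), names(scores))
}

#' Read a survival table from TSV
#'
#' Columns: `sample_id`, `time` (non-negative), `event` (1 = event,
#' 0 = censored), optional `stage` (I-IV or `unknown`).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with validated columns.
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_survival_table(tab)
}

validate_survival_table <- function(tab) {
  needed <- c("sample_id", "time", "event")
  if (!all(needed %in% names(tab))) {
    stop("survival table needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(tab$time < 0)) stop("negative survival time")
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0 or 1")
  tab
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival curve S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), with events preceding censorings at tied times.
#'
#' @param table Survival `data.frame` with `time` and `event` columns.
#' @return A `km_curve`: list with `event_times` (sorted distinct times at
#'   which an event occurred), `survival` (estimate just after each event
#'   time), `at_risk` (risk-set size just before each event time).
#' @export
km_estimate <- function(table) {
  validate_survival_table(
    if (is.null(table$sample_id)) cbind(sample_id = "", table) else table)
  if (sum(table$event) < 1) {
    # all censored: flat curve at 1
    return(structure(list(event_times = numeric(0), survival = numeric(0),
                          at_risk = integer(0)),
                     class = "km_curve"))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  keep <- fit$n.event > 0
  structure(
    list(event_times = fit$time[keep], survival = fit$surv[keep],
         at_risk = fit$n.risk[keep]),
    class = "km_curve"
  )
}

#' Evaluate a km_curve at arbitrary times
#'
#' @param curve A `km_curve`.
#' @param times Times at which to read off S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- sum(curve$event_times <= t)
    if (i == 0) 1 else curve$survival[i]
  }, numeric(1))
}

#' Log-rank test between survival groups
#'
#' Chi-square statistic on k-1 degrees of freedom from observed-minus-
#' expected event counts over the pooled event times (two-group variance
#' by the hypergeometric formula). An optional `strata` vector pools the
#' observed-minus-expected contributions within strata.
#'
#' @param table Survival `data.frame` with `time` and `event`.
#' @param groups Group label per row (>= 2 non-empty groups).
#' @param strata Optional stratification label per row.
#' @return List with `statistic`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(table, groups, strata = NULL) {
  validate_survival_table(
    if (is.null(table$sample_id)) cbind(sample_id = "", table) else table)
  groups <- as.factor(groups)
  if (length(groups) != nrow(table)) stop("one group label per row required")
  if (any(table(groups) == 0) || nlevels(groups) < 2) {
    stop("need >= 2 non-empty groups")
  }
  if (sum(table$event) < 1) stop("need at least one event")
  d <- data.frame(time = table$time, event = table$event, g = groups)
  if (is.null(strata)) {
    fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  } else {
    d$s <- as.factor(strata)
    fit <- survival::survdiff(
      survival::Surv(time, event) ~ g + survival::strata(s), data = d)
  }
  df <- nlevels(groups) - 1
  list(statistic = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(groups))
}

#' Prognostic evaluation of a co-expression module
#'
#' Scores each sample by module expression, splits at the median into
#' high/low risk groups, estimates per-group Kaplan-Meier curves and runs
#' the log-rank test. With `stratify_by_stage = TRUE` two further analyses
#' are run on the samples with known stage: a log-rank across stage groups
#' and a stage-stratified log-rank of the score split.
#'
#' @param table Survival `data.frame` (`sample_id`, `time`, `event`,
#'   optional `stage`; `unknown` stages are excluded from stage analyses
#'   only).
#' @param module A `coexpression_module` or vector of gene symbols.
#' @param study [expression_study()] holding the samples' expression.
#' @param stratify_by_stage Run the stage analyses; default `FALSE`.
#' @param alpha Significance level for the prognostic call, default 0.05.
#' @return List with `scores`, `groups`, `km` (per-group `km_curve`s),
#'   `logrank` (the score-split test), `prognostic` (logical, p < alpha),
#'   `alpha`, and when stage-stratified also `logrank_stage` and
#'   `logrank_score_stratified` plus `n_excluded_unknown_stage`.
#' @export
evaluate_prognostic_module <- function(table, module, study,
                                       stratify_by_stage = FALSE,
                                       alpha = 0.05) {
  shared <- intersect(table$sample_id, study$samples)
  if (length(shared) == 0) stop("no shared samples between table and study")
  table <- table[match(shared, table$sample_id), , drop = FALSE]
  sub <- expression_study(study$study_id,
                          study$values[, shared, drop = FALSE],
                          study$labels[match(shared, study$samples)],
                          require_min_samples = FALSE)
  scores <- module_score(sub, module)
  groups <- assign_risk_groups(scores)
  km <- lapply(split(seq_along(groups), groups), function(idx) {
    km_estimate(table[idx, , drop = FALSE])
  })
  lr <- logrank_test(table, groups)
  out <- list(scores = scores, groups = groups, km = km, logrank = lr,
              prognostic = lr$p_value < alpha, alpha = alpha)
  if (stratify_by_stage) {
    if (is.null(table$stage)) stop("stage column required for stratification")
    known <- !is.na(table$stage) & table$stage != "unknown"
    out$n_excluded_unknown_stage <- sum(!known)
    tk <- table[known, , drop = FALSE]
    gk <- groups[known]
    if (length(unique(tk$stage)) >= 2) {
      out$logrank_stage <- logrank_test(tk, tk$stage)
    }
    # the stratified test is informative only where some stratum mixes
    # both risk groups; a score-determined stage can make it degenerate
    mixed <- tapply(gk, tk$stage, function(x) length(unique(x)) >= 2)
    keep <- tk$stage %in% names(mixed)[mixed]
    if (any(keep) && length(unique(gk[keep])) >= 2 &&
        sum(tk$event[keep]) >= 1) {
      out$logrank_score_stratified <- logrank_test(
        tk[keep, , drop = FALSE], gk[keep], strata = tk$stage[keep])
    } else {
      out$logrank_score_stratified <- NULL
    }
  }
  out
}

#' Write Kaplan-Meier curves as TSV
#'
#' @param km Named list of `km_curve` objects (e.g. per risk group).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_km_curves <- function(km, path) {
  rows <- lapply(names(km), function(g) {
    c <- km[[g]]
    if (length(c$event_times) == 0) return(NULL)
    data.frame(group = g, time = c$event_times, survival = c$survival,
               at_risk = c$at_risk, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(group = character(0), time = numeric(0),
                     survival = numeric(0), at_risk = integer(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
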