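#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input
#' and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene differential expression between disease and control
#'
#' Runs a two-sample t-test for every gene (Welch by default, pooled
#' variance optionally), adjusts p-values by Benjamini-Hochberg across all
#' genes, and retains genes with adjusted p below `alpha` and absolute
#' log2 fold change of at least `log2(fc_threshold)`. Input values are
#' assumed to be on the log2 scale, so the fold change is the difference
#' of phenotype means. Genes whose fold change is exactly zero have no
#' up/down direction and are excluded.
#'
#' @param study An [expression_study()].
#' @param alpha Adjusted-p cutoff, default 0.05.
#' @param fc_threshold Linear fold-change cutoff, default 2 (i.e.
#'   |log2FC| >= 1).
#' @param var_equal Use pooled-variance t instead of Welch; default `FALSE`.
#' @return A `data.frame` (one row per retained gene) with columns `gene`,
#'   `log2fc`, `p_value`, `adj_p`, `direction` (`"up"`/`"down"`), sorted by
#'   `adj_p` then `p_value`.
#' @export
differential_expression <- function(study, alpha = 0.05, fc_threshold = 2,
                                    var_equal = FALSE) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold >= 1)
  d <- study$values[, study$labels == "disease", drop = FALSE]
  h <- study$values[, study$labels == "control", drop = FALSE]
  if (ncol(d) < 2 || ncol(h) < 2) {
    stop("each phenotype needs >=2 samples for a variance estimate")
  }
  nd <- ncol(d); nh <- ncol(h)
  md <- rowMeans(d); mh <- rowMeans(h)
  vd <- rowSums((d - md)^2) / (nd - 1)
  vh <- rowSums((h - mh)^2) / (nh - 1)
  log2fc <- md - mh
  if (var_equal) {
    sp2 <- ((nd - 1) * vd + (nh - 1) * vh) / (nd + nh - 2)
    se <- sqrt(sp2 * (1 / nd + 1 / nh))
    df <- rep(nd + nh - 2, length(se))
  } else {
    se <- sqrt(vd / nd + vh / nh)
    df <- (vd / nd + vh / nh)^2 /
      ((vd / nd)^2 / (nd - 1) + (vh / nh)^2 / (nh - 1))
  }
  tstat <- log2fc / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # genes identical across all samples: no evidence either way
  p[se == 0 & log2fc == 0] <- 1
  p[se == 0 & log2fc != 0] <- 0
  adj <- bh_adjust(p)
  keep <- adj < alpha & abs(log2fc) >= log2(fc_threshold) & log2fc != 0
  res <- data.frame(gene = study$genes[keep],
                    log2fc = log2fc[keep],
                    p_value = p[keep],
                    adj_p = adj[keep],
                    direction = ifelse(log2fc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  res[order(res$adj_p, res$p_value, res$gene), , drop = FALSE]
}

#' Genes shared by every differential-expression table
#'
#' Intersects the gene symbols of two or more DEG tables. Direction
#' consistency across studies is reported via the `consistent` attribute
#' (genes whose up/down call agrees in all tables) but not enforced.
#'
#' @param deg_tables List of data frames as returned by
#'   [differential_expression()] (only `gene` and `direction` are used).
#' @return Character vector of common gene symbols (sorted); attribute
#'   `consistent` is a logical vector flagging direction-consistent genes.
#' @export
intersect_common_degs <- function(deg_tables) {
  if (length(deg_tables) == 0) stop("need at least one DEG table")
  if (length(deg_tables) < 2) {
    warning("only one table supplied; intersection is that table")
  }
  common <- Reduce(intersect, lapply(deg_tables, function(t) t$gene))
  common <- sort(common)
  dirs <- vapply(common, function(g) {
    calls <- unique(vapply(deg_tables, function(t) {
      t$direction[match(g, t$gene)]
    }, character(1)))
    length(calls) == 1
  }, logical(1))
  structure(common, consistent = dirs)
}

#' Over-representation analysis against a gene-set collection
#'
#' One-sided hypergeometric (Fisher's exact) test of the overlap between a
#' query gene list and each set of the collection, with each set first
#' intersected with the universe; Benjamini-Hochberg adjustment across
#' sets.
#'
#' @param query Character vector of query genes (must be within `universe`).
#' @param universe Character vector of background genes.
#' @param collection A `gene_set_collection` from [read_gmt()], or a named
#'   list of gene vectors.
#' @param alpha Significance cutoff recorded in the `significant` column;
#'   default 0.05.
#' @return `data.frame` with columns `set_name`, `overlap`, `set_size`,
#'   `universe_size`, `query_size`, `p_value`, `adj_p`, `significant`,
#'   sorted by `adj_p`.
#' @export
ora_fisher <- function(query, universe, collection, alpha = 0.05) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  query <- unique(query); universe <- unique(universe)
  if (length(setdiff(query, universe)) > 0) {
    stop("query genes missing from universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  }
  n_u <- length(universe); n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(set, query))
    # P(X >= k) for X ~ Hypergeometric(universe, |set| successes, draws |query|)
    p <- stats::phyper(k - 1, length(set), n_u - length(set), n_q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(set),
               universe_size = n_u, query_size = n_q, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- bh_adjust(res$p_value)
  res$significant <- res$adj_p < alpha
  res[order(res$adj_p, res$p_value, res$set_name), , drop = FALSE]
}

#' Write a DEG table as TSV
#'
#' @param deg_table Data frame from [differential_expression()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(deg_table, path) {
  utils::write.table(deg_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
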