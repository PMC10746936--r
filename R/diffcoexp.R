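#' Pairwise Spearman correlation of a pooled condition
#'
#' Computes the Spearman rank correlation (average ranks for ties) for
#' every unordered gene pair over the pooled samples of one condition.
#'
#' @param pooled Numeric matrix (genes x samples) for one condition, e.g.
#'   from [pool_condition_samples()].
#' @param genes Gene symbols to correlate; default all rows. Every gene
#'   must be present in the matrix.
#' @param condition `"disease"` or `"control"`.
#' @return A `condition_correlation`: list with `genes`, `scc` (symmetric
#'   correlation matrix, unit diagonal), `condition`, `n_samples`.
#' @export
pairwise_scc <- function(pooled, genes = rownames(pooled),
                         condition = c("disease", "control")) {
  condition <- match.arg(condition)
  missing <- setdiff(genes, rownames(pooled))
  if (length(missing) > 0) {
    stop("gene(s) absent from pooled matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (ncol(pooled) < 3) stop("need >=3 pooled samples for correlation")
  scc <- stats::cor(t(pooled[genes, , drop = FALSE]), method = "spearman")
  diag(scc) <- 1
  structure(
    list(genes = genes, scc = scc, condition = condition,
         n_samples = ncol(pooled)),
    class = "condition_correlation"
  )
}

#' Critical correlation cutoff for one condition
#'
#' The significance cutoff for pairwise correlations is derived from the
#' distribution of the correlation coefficients themselves:
#' `pcritic = mean(SCC) + 1.96 * sd(SCC)`, taken over all off-diagonal
#' values (each unordered pair once). By default the signed coefficients
#' feed the formula; `use_abs = TRUE` switches to their absolute values.
#'
#' @param corr A `condition_correlation` from [pairwise_scc()].
#' @param use_abs Feed |SCC| instead of signed SCC into mean/sd.
#' @return A `pcritic`: list with `condition`, `mean_scc`, `std_scc`,
#'   `value`.
#' @export
compute_pcritic <- function(corr, use_abs = FALSE) {
  vals <- corr$scc[upper.tri(corr$scc)]
  if (length(vals) < 2) stop("need at least 2 gene pairs")
  if (use_abs) vals <- abs(vals)
  m <- mean(vals)
  s <- stats::sd(vals)
  structure(
    list(condition = corr$condition, mean_scc = m, std_scc = s,
         value = m + 1.96 * s),
    class = "pcritic"
  )
}

#' Select differentially co-expressed gene pairs
#'
#' A pair is retained when it is significantly correlated in the disease
#' condition, `|SCCd| > pcritic_d`, and its correlation changes between
#' conditions by more than the epsilon threshold, `|SCCd - SCCh| >
#' epsilon_threshold` (default 0.5). Significance flags for both
#' conditions are populated from the respective cutoffs.
#'
#' @param corr_d,corr_h `condition_correlation` objects for disease and
#'   control, over the same gene universe.
#' @param pcritic_d A `pcritic` for the disease condition (or a number).
#' @param epsilon_threshold Minimum |SCCd - SCCh|, default 0.5.
#' @param pcritic_h Cutoff used for the control-significance flag; default
#'   [compute_pcritic()] on `corr_h`.
#' @return `data.frame` of retained pairs: `gene_a`, `gene_b`
#'   (lexicographically ordered within pair), `scc_d`, `scc_h`, `epsilon`,
#'   `significant_d`, `significant_h`.
#' @export
select_differential_pairs <- function(corr_d, corr_h, pcritic_d = NULL,
                                      epsilon_threshold = 0.5,
                                      pcritic_h = NULL) {
  if (!identical(corr_d$genes, corr_h$genes)) {
    stop("disease and control correlations must share the same gene universe")
  }
  if (is.null(pcritic_d)) pcritic_d <- compute_pcritic(corr_d)
  if (is.null(pcritic_h)) pcritic_h <- compute_pcritic(corr_h)
  pd <- if (is.list(pcritic_d)) pcritic_d$value else pcritic_d
  ph <- if (is.list(pcritic_h)) pcritic_h$value else pcritic_h
  genes <- corr_d$genes
  ut <- which(upper.tri(corr_d$scc), arr.ind = TRUE)
  scc_d <- corr_d$scc[ut]
  scc_h <- corr_h$scc[ut]
  a <- genes[ut[, 1]]; b <- genes[ut[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  eps <- abs(scc_d - scc_h)
  keep <- abs(scc_d) > pd & eps > epsilon_threshold
  res <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    scc_d = scc_d[keep], scc_h = scc_h[keep],
                    epsilon = eps[keep],
                    significant_d = abs(scc_d[keep]) > pd,
                    significant_h = abs(scc_h[keep]) > ph,
                    stringsAsFactors = FALSE)
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

#' Spearman correlation p-value by the t approximation
#'
#' Optional pre-filter on pairwise correlations: two-sided p from
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom. Exposed for
#' completeness; the critical-cutoff rule supersedes it downstream and it
#' is off by default in [run_pipeline()].
#'
#' @param r Spearman correlation value(s).
#' @param n Number of samples.
#' @return Two-sided p-value(s).
#' @export
scc_pvalue <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
}

#' Build the differential co-expression network
#'
#' Simple undirected graph whose nodes are the endpoints of the retained
#' pairs; duplicate pairs (in either order) collapse onto one edge. Edge
#' attributes carry `scc_d`, `scc_h` and `epsilon`.
#'
#' @param pairs `data.frame` from [select_differential_pairs()].
#' @return An [igraph::graph] object.
#' @export
build_network <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  el <- data.frame(from = a[keep], to = b[keep],
                   scc_d = pairs$scc_d[keep], scc_h = pairs$scc_h[keep],
                   epsilon = pairs$epsilon[keep], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Density of a simple undirected graph
#'
#' `2 * edges / (nodes * (nodes - 1))`: the fraction of possible
#' unordered pairs that are connected.
#'
#' @param nodes Node count, >= 2.
#' @param edges Edge count, between 0 and `nodes*(nodes-1)/2`.
#' @return Density in \[0, 1\].
#' @export
network_density <- function(nodes, edges) {
  if (nodes < 2) stop("need at least 2 nodes")
  max_edges <- nodes * (nodes - 1) / 2
  if (edges < 0 || edges > max_edges) {
    stop("edge count ", edges, " outside [0, ", max_edges, "]")
  }
  2 * edges / (nodes * (nodes - 1))
}

#' Detect dense co-expression modules
#'
#' Candidate modules are found per connected component: a component that
#' already meets the density bar is itself a module (a dense quasi-clique
#' must not be fragmented), while sparser components are partitioned by
#' deterministic greedy modularity maximization and each resulting
#' community becomes a candidate. Candidates with at least `min_size`
#' nodes and density at least `density_threshold` are returned (the
#' "highly clustered" criterion). Nodes are processed in sorted order so
#' the result is deterministic.
#'
#' @param network An [igraph::graph], e.g. from [build_network()].
#' @param min_size Minimum module size, default 5 (must be >= 3).
#' @param density_threshold Minimum module density in (0, 1\], default 0.5.
#' @return List of `coexpression_module` objects (possibly empty), each a
#'   list with `module_id`, `nodes`, `edges` (two-column matrix),
#'   `density`; ordered by decreasing size then id.
#' @export
detect_modules <- function(network, min_size = 5, density_threshold = 0.5) {
  stopifnot(min_size >= 3, density_threshold > 0, density_threshold <= 1)
  if (igraph::vcount(network) == 0) return(list())
  network <- igraph::permute(
    network, order(order(igraph::V(network)$name)))
  as_module <- function(nodes) {
    if (length(nodes) < 2) return(NULL)
    sub <- igraph::induced_subgraph(network, nodes)
    dens <- network_density(length(nodes), igraph::ecount(sub))
    el <- igraph::as_edgelist(sub)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    structure(
      list(module_id = NA_character_, nodes = sort(nodes), edges = el,
           density = dens),
      class = "coexpression_module"
    )
  }
  comp <- igraph::components(network)
  mods <- list()
  for (cid in sort(unique(comp$membership))) {
    cnodes <- sort(names(comp$membership)[comp$membership == cid])
    if (length(cnodes) < min_size) next
    whole <- as_module(cnodes)
    if (whole$density >= density_threshold) {
      mods[[length(mods) + 1]] <- whole
      next
    }
    sub <- igraph::induced_subgraph(network, cnodes)
    membership <- igraph::membership(igraph::cluster_fast_greedy(sub))
    for (mid in sort(unique(membership))) {
      nodes <- sort(names(membership)[membership == mid])
      if (length(nodes) < min_size) next
      cand <- as_module(nodes)
      if (cand$density >= density_threshold) {
        mods[[length(mods) + 1]] <- cand
      }
    }
  }
  if (length(mods) > 1) {
    ord <- order(-vapply(mods, function(m) length(m$nodes), numeric(1)),
                 vapply(mods, function(m) m$nodes[1], character(1)))
    mods <- mods[ord]
  }
  for (i in seq_along(mods)) mods[[i]]$module_id <- paste0("M", i)
  mods
}

#' @export
print.coexpression_module <- function(x, ...) {
  cat("<coexpression_module> ", x$module_id, ": ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges, density ",
      sprintf("%.3f", x$density), "\n", sep = "")
  invisible(x)
}

#' Correlation sign-pattern summary for a module
#'
#' For each condition, counts the module gene pairs whose correlation
#' exceeds that condition's critical cutoff positively (`SCC > pcritic`)
#' or negatively (`SCC < -pcritic`). Percentages are reported against two
#' candidate denominators, clearly labelled: the per-condition significant
#' pair count and the total pair count of the module.
#'
#' @param module A `coexpression_module`.
#' @param corr_d,corr_h `condition_correlation` objects covering the
#'   module genes.
#' @param pcritic_d,pcritic_h `pcritic` objects (or numbers) per condition.
#' @return List with `n_pairs` and, per condition, `positive`, `negative`,
#'   `pct_of_significant`, `pct_of_total` (each a named positive/negative
#'   pair of percentages).
#' @export
correlation_pattern_summary <- function(module, corr_d, corr_h,
                                        pcritic_d, pcritic_h) {
  count_one <- function(corr, pc) {
    pc <- if (is.list(pc)) pc$value else pc
    missing <- setdiff(module$nodes, corr$genes)
    if (length(missing) > 0) {
      stop("module gene(s) missing from correlation: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    sub <- corr$scc[module$nodes, module$nodes, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    c(positive = sum(vals > pc), negative = sum(vals < -pc))
  }
  n_pairs <- length(module$nodes) * (length(module$nodes) - 1) / 2
  per_condition <- function(counts) {
    n_sig <- sum(counts)
    list(positive = unname(counts["positive"]),
         negative = unname(counts["negative"]),
         pct_of_significant = if (n_sig > 0) 100 * counts / n_sig
                              else counts * 0,
         pct_of_total = 100 * counts / n_pairs)
  }
  list(n_pairs = n_pairs,
       disease = per_condition(count_one(corr_d, pcritic_d)),
       control = per_condition(count_one(corr_h, pcritic_h)))
}

#' Export a network as GraphML
#'
#' Edge attributes (`scc_d`, `scc_h`, `epsilon`) are preserved.
#'
#' @param network An [igraph::graph].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Export a network in SIF format
#'
#' One `nodeA<TAB>relation<TAB>nodeB` line per edge; isolated nodes are
#' written as bare node lines.
#'
#' @param network An [igraph::graph].
#' @param path Output path.
#' @param relation Interaction type string, default `"coexp"`.
#' @return Invisibly, `path`.
#' @export
write_network_sif <- function(network, path, relation = "coexp") {
  el <- igraph::as_edgelist(network)
  lines <- if (nrow(el) > 0) paste(el[, 1], relation, el[, 2], sep = "\t")
           else character(0)
  isolated <- igraph::V(network)$name[igraph::degree(network) == 0]
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Write a one-line-per-module TSV summary
#'
#' @param modules List from [detect_modules()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_module_summary <- function(modules, path) {
  df <- data.frame(
    module_id = vapply(modules, `[[`, character(1), "module_id"),
    n_nodes = vapply(modules, function(m) length(m$nodes), integer(1)),
    n_edges = vapply(modules, function(m) nrow(m$edges), integer(1)),
    density = vapply(modules, `[[`, numeric(1), "density"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
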