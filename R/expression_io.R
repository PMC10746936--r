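#' Construct an expression study
#'
#' Bundles a genes x samples expression matrix (log2 scale assumed) with
#' per-sample phenotype labels into a validated `expression_study` object,
#' the basic unit of one cohort in a two-phenotype comparison.
#'
#' @param study_id Character scalar identifying the cohort.
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene symbols, column names are sample ids.
#' @param labels Character vector of phenotypes, one per sample, each either
#'   `"disease"` or `"control"`. Named vectors are matched to the matrix
#'   columns by name.
#' @param require_min_samples If `TRUE` (default), enforce the cohort
#'   selection rule that each phenotype contains at least three samples.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `study_id`, `genes`, `samples`, `values`, `labels`.
#' @export
expression_study <- function(study_id, values, labels,
                             require_min_samples = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene symbols as row names and sample ids as column names")
  }
  rownames(values) <- trimws(rownames(values))
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing) > 0) {
      stop("samples present in matrix but absent from labels: ",
           paste(missing, collapse = ", "))
    }
    labels <- unname(labels[colnames(values)])
  }
  if (length(labels) != ncol(values)) {
    stop("dimension mismatch: ", length(labels), " labels for ",
         ncol(values), " samples")
  }
  bad <- setdiff(unique(labels), c("disease", "control"))
  if (length(bad) > 0) {
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         " (expected 'disease' or 'control')")
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (require_min_samples) {
    counts <- table(factor(labels, levels = c("disease", "control")))
    if (any(counts < 3)) {
      stop("each phenotype must contain at least three samples; got ",
           counts[["disease"]], " disease and ", counts[["control"]],
           " control")
    }
  }
  structure(
    list(study_id = as.character(study_id),
         genes = rownames(values),
         samples = colnames(values),
         values = values,
         labels = labels),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study> ", x$study_id, ": ", length(x$genes), " genes x ",
      length(x$samples), " samples (",
      sum(x$labels == "disease"), " disease / ",
      sum(x$labels == "control"), " control)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and its phenotype labels
#'
#' The matrix is tab-separated with a `gene` first column and sample ids in
#' the header; the labels file is a two-column TSV (`sample_id`,
#' `phenotype`), phenotype being `disease` or `control`. Every matrix sample
#' must appear in the labels file and each phenotype must have at least
#' three samples.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the labels TSV.
#' @param study_id Study identifier; defaults to the matrix file name.
#' @param require_min_samples Enforce the >=3-samples-per-phenotype cohort
#'   rule (default `TRUE`); a single-phenotype validation cohort is read
#'   with `FALSE`.
#' @return An [expression_study()].
#' @export
read_expression_matrix <- function(path, labels_path,
                                   study_id = basename(path),
                                   require_min_samples = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression matrix needs a gene column and >=1 sample")
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("labels file needs columns sample_id, phenotype")
  labels <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  expression_study(study_id, values, labels,
                   require_min_samples = require_min_samples)
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_expression_matrix()]: the matrix goes to `path` with a
#' `gene` first column, the labels to `labels_path`. Values are written at
#' full precision so a write-then-read round trip is exact.
#'
#' @param study An [expression_study()].
#' @param path,labels_path Output file paths.
#' @return Invisibly, `study`.
#' @export
write_expression_matrix <- function(study, path, labels_path) {
  # %.17g keeps doubles exact across the round trip
  chr <- matrix(sprintf("%.17g", study$values), nrow = nrow(study$values),
                dimnames = dimnames(study$values))
  df <- data.frame(gene = study$genes, chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = study$samples, phenotype = study$labels)
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}

#' Average together rows that share a gene symbol
#'
#' When a symbol occurs more than once in the same dataset (e.g. several
#' probes mapping to one gene), the duplicate rows are replaced by their
#' element-wise arithmetic mean. Gene order follows first occurrence.
#'
#' @param study An [expression_study()].
#' @return An [expression_study()] with unique gene symbols.
#' @export
collapse_duplicate_genes <- function(study) {
  if (!anyDuplicated(study$genes)) return(study)
  keys <- factor(study$genes, levels = unique(study$genes))
  collapsed <- apply(study$values, 2, function(col) {
    tapply(col, keys, mean)
  })
  collapsed <- matrix(collapsed, nrow = nlevels(keys),
                      dimnames = list(levels(keys), study$samples))
  expression_study(study$study_id, collapsed, study$labels,
                   require_min_samples = FALSE)
}

#' Z-score normalize each gene across a study's samples
#'
#' Centers and scales every gene row to mean 0 and sample (n-1) standard
#' deviation 1 across all samples of the study, the within-study
#' batch-effect removal applied before pooling cohorts for correlation.
#' Constant rows cannot be scaled and are dropped with a warning.
#'
#' @param study An [expression_study()].
#' @return An [expression_study()] of z-scores.
#' @export
zscore_normalize <- function(study) {
  sds <- apply(study$values, 1, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant gene row(s): ",
            paste(utils::head(study$genes[constant], 5), collapse = ", "),
            if (sum(constant) > 5) ", ..." else "")
  }
  values <- study$values[!constant, , drop = FALSE]
  z <- (values - rowMeans(values)) / sds[!constant]
  expression_study(study$study_id, z, study$labels,
                   require_min_samples = FALSE)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. Empty sets
#' are rejected.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of gene
#'   symbol vectors) and `source` (the path).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GMT line: ", substr(line, 1, 40))
    genes <- trimws(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("empty gene set in GMT: ", parts[1])
    sets[[parts[1]]] <- genes
  }
  structure(list(sets = sets, source = path), class = "gene_set_collection")
}

#' Write named gene sets to a GMT file
#'
#' @param sets Named list of gene symbol vectors.
#' @param path Output path.
#' @param description Description field, recycled over sets.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pool the z-scored samples of one condition across studies
#'
#' Restricts each study to a common gene list, z-scores it within study,
#' and concatenates the columns belonging to `condition` across studies,
#' yielding the per-condition matrix on which pooled pairwise correlations
#' are computed.
#'
#' @param studies List of [expression_study()] objects.
#' @param genes Gene symbols to keep (must be present in every study).
#' @param condition `"disease"` or `"control"`.
#' @return Numeric matrix, `genes` x pooled samples.
#' @export
pool_condition_samples <- function(studies, genes, condition) {
  condition <- match.arg(condition, c("disease", "control"))
  blocks <- lapply(studies, function(st) {
    missing <- setdiff(genes, st$genes)
    if (length(missing) > 0) {
      stop("genes absent from study ", st$study_id, ": ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    sub <- expression_study(st$study_id,
                            st$values[genes, , drop = FALSE],
                            st$labels, require_min_samples = FALSE)
    z <- zscore_normalize(sub)
    dropped <- setdiff(genes, z$genes)
    if (length(dropped) > 0) {
      stop("constant gene row(s) in study ", st$study_id,
           " prevent z-scoring: ", paste(utils::head(dropped, 5), collapse = ", "))
    }
    z$values[genes, z$labels == condition, drop = FALSE]
  })
  pooled <- do.call(cbind, blocks)
  colnames(pooled) <- make.unique(colnames(pooled))
  pooled
}
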