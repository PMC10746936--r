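#' Build an up/down signature from a module and its DEG calls
#'
#' Partitions the module genes into up- and down-regulated sets using the
#' differential-expression directions, carrying log2 fold changes as
#' weights. Module genes without a DEG record are dropped with a warning.
#'
#' @param module A `coexpression_module` or character vector of genes.
#' @param degs DEG `data.frame` from [differential_expression()] (columns
#'   `gene`, `log2fc`, `direction`).
#' @return A `gene_signature`: list with `up`, `down` (gene vectors) and
#'   `weights` (named log2fc vector over all signature genes).
#' @export
build_module_signature <- function(module, degs) {
  genes <- if (inherits(module, "coexpression_module")) module$nodes
           else module
  idx <- match(genes, degs$gene)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " module gene(s) without a DEG record dropped: ",
            paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
    genes <- genes[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  if (length(genes) == 0) stop("empty signature: no module gene has a DEG record")
  dir <- degs$direction[idx]
  structure(
    list(up = genes[dir == "up"], down = genes[dir == "down"],
         weights = stats::setNames(degs$log2fc[idx], genes)),
    class = "gene_signature"
  )
}

#' Read a drug-signature library from TSV
#'
#' Long format, columns `drug`, `gene`, `weight` (positive = induced,
#' negative = repressed by the drug).
#'
#' @param path Path to the TSV file.
#' @return A `drug_signature_library`: named list of per-drug named
#'   weight vectors.
#' @export
read_drug_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "gene", "weight") %in% names(tab))) {
    stop("drug library needs columns: drug, gene, weight")
  }
  drugs <- lapply(split(tab, tab$drug), function(d) {
    stats::setNames(as.numeric(d$weight), d$gene)
  })
  validate_drug_library(drugs)
}

validate_drug_library <- function(drugs) {
  if (length(drugs) == 0) stop("empty drug library")
  for (nm in names(drugs)) {
    w <- drugs[[nm]]
    if (length(w) == 0 || any(!is.finite(w))) {
      stop("drug ", nm, " has no genes or non-finite weights")
    }
  }
  structure(drugs, class = "drug_signature_library")
}

#' Rank drugs by how strongly they reverse a signature
#'
#' For each drug sharing at least one gene with the signature, the score
#' is minus the cosine similarity between the signature weight vector and
#' the drug weight vector on their gene intersection (signature genes
#' without weights count +1 for up, -1 for down). A perfect reverser
#' scores +1; drugs are ranked by descending score and the top `top_k`
#' returned.
#'
#' @param signature A `gene_signature` from [build_module_signature()].
#' @param library A `drug_signature_library`.
#' @param top_k Number of drugs to return, default 50.
#' @return `data.frame` with `rank`, `drug`, `score`, `n_overlap`.
#' @export
reversal_score <- function(signature, library, top_k = 50) {
  stopifnot(top_k >= 1)
  sig_genes <- c(signature$up, signature$down)
  w <- signature$weights
  if (is.null(w)) w <- stats::setNames(numeric(0), character(0))
  sig_w <- stats::setNames(
    ifelse(sig_genes %in% names(w), w[sig_genes],
           ifelse(sig_genes %in% signature$up, 1, -1)),
    sig_genes)
  rows <- lapply(names(library), function(drug) {
    dw <- library[[drug]]
    ov <- intersect(names(dw), sig_genes)
    if (length(ov) == 0) return(NULL)
    x <- sig_w[ov]; y <- dw[ov]
    denom <- sqrt(sum(x^2)) * sqrt(sum(y^2))
    score <- if (denom == 0) 0 else -sum(x * y) / denom
    data.frame(drug = drug, score = score, n_overlap = length(ov),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no drug overlaps the signature")
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$drug), , drop = FALSE]
  res <- utils::head(res, top_k)
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Read a JSON-lines abstract corpus
#'
#' One record per line, each `{"id": ..., "text": ...}`.
#'
#' @param path Path to the .jsonl file.
#' @return Character vector of abstract texts, named by id.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  stats::setNames(vapply(recs, function(r) as.character(r$text), character(1)),
                  vapply(recs, function(r) as.character(r$id), character(1)))
}

#' The four literature query templates
#'
#' Contexts under which a drug name is searched: the name alone, and the
#' name combined with "thyroid cancer", "thyroid carcinoma" and "cancer".
#' An empty context means the whole corpus is searched.
#'
#' @return Named character vector of context phrases.
#' @export
default_query_templates <- function() {
  c("drug candidate" = "",
    "drug candidate + thyroid cancer" = "thyroid cancer",
    "drug candidate + thyroid carcinoma" = "thyroid carcinoma",
    "drug candidate + cancer" = "cancer")
}

count_phrase <- function(texts, phrase) {
  # case-insensitive whole-phrase occurrences per document
  pat <- paste0("(?<![A-Za-z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                         tolower(phrase)),
                "(?![A-Za-z0-9])")
  vapply(tolower(texts), function(t) {
    m <- gregexpr(pat, t, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' TF-IDF literature-novelty score for drug names
#'
#' For each drug and query template: the sub-corpus is the set of
#' documents matching the template context (the whole corpus for the bare
#' template); `tf` is the total number of case-insensitive whole-phrase
#' occurrences of the drug name in the sub-corpus; `idf = ln(N / df)`
#' with `N` the sub-corpus size and `df` the number of sub-corpus
#' documents mentioning the name; `tfidf = tf * idf`, defined as 0 when
#' `df = 0`. A drug is novel when its tfidf is 0 under every template.
#'
#' @param drugs Character vector of drug names.
#' @param corpus Character vector of abstract texts (one per document).
#' @param query_templates Named character vector of context phrases;
#'   default [default_query_templates()].
#' @return `data.frame` with one row per drug x template: `drug`, `query`,
#'   `tf`, `df`, `n_docs`, `idf`, `tfidf`, `novel` (constant within drug).
#' @export
tfidf_novelty <- function(drugs, corpus,
                          query_templates = default_query_templates()) {
  if (length(corpus) == 0) stop("empty corpus")
  if (length(drugs) == 0 || any(!nzchar(drugs))) {
    stop("drug names must be non-empty")
  }
  rows <- list()
  for (qi in seq_along(query_templates)) {
    context <- query_templates[[qi]]
    sub <- if (nzchar(context)) corpus[count_phrase(corpus, context) > 0]
           else corpus
    n_docs <- length(sub)
    for (drug in drugs) {
      counts <- if (n_docs > 0) count_phrase(sub, drug) else integer(0)
      tf <- sum(counts)
      df <- sum(counts > 0)
      idf <- if (df > 0) log(n_docs / df) else 0
      tfidf <- if (df == 0) 0 else tf * idf
      rows[[length(rows) + 1]] <- data.frame(
        drug = drug, query = names(query_templates)[qi],
        tf = tf, df = df, n_docs = n_docs, idf = idf, tfidf = tfidf,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  novel_by_drug <- tapply(res$tfidf, res$drug, function(v) all(v == 0))
  res$novel <- unname(novel_by_drug[res$drug])
  res[order(match(res$drug, drugs), match(res$query, names(query_templates))), ,
      drop = FALSE]
}
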