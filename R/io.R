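# Readers/writers for every external format the pipeline touches:
# GMT gene sets, expression TSV/CSV (+ sample annotations), 3-column PPI edge
# lists, drug tables, and response tables. All readers validate strictly and
# preserve input order.

#' Construct an expression matrix object
#'
#' The central expression container: a genes x samples numeric matrix on log2
#' scale plus per-sample batch and cancer-type labels.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene symbols) and colnames (sample ids).
#' @param batch character vector of per-sample batch labels (recycled if
#'   length 1).
#' @param cancer_type character vector of per-sample cancer-type labels
#'   (recycled if length 1).
#' @return an object of class `expr_matrix` with elements `values`, `batch`,
#'   `cancer_type`.
#' @export
expression_matrix <- function(values, batch = "batch1", cancer_type = "unknown") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop2("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop2("duplicate sample ids")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop2("expression values must be finite numeric")
  n <- ncol(values)
  if (length(batch) == 1) batch <- rep(batch, n)
  if (length(cancer_type) == 1) cancer_type <- rep(cancer_type, n)
  if (length(batch) != n || length(cancer_type) != n)
    stop2("batch/cancer_type length must equal sample count")
  structure(list(values = values, batch = as.character(batch),
                 cancer_type = as.character(cancer_type)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, %d batch(es)\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a GMT gene-set file
#'
#' One pathway per line: name, description (discarded), then member gene
#' symbols, tab-separated. Duplicate genes within a line are deduplicated.
#'
#' @param path file path.
#' @return a named list of character vectors with attribute `provenance`
#'   (class `gene_sets`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop2("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    nm <- fields[[1]]
    if (nm %in% names(sets)) stop2("duplicate pathway name: ", nm)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop2("empty gene set on line ", i)
    sets[[nm]] <- genes
  }
  gene_sets(sets, provenance = "FILE")
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (pathway -> member genes).
#' @param provenance free-text tag (e.g. "PID", "REACTOME", "COMBINED").
#' @return `gene_sets` object.
#' @export
gene_sets <- function(sets, provenance = "CUSTOM") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop2("pathway names must be unique and non-empty")
  if (any(lengths(sets) == 0)) stop2("every gene set must be non-empty")
  structure(lapply(sets, as.character), provenance = provenance, class = "gene_sets")
}

#' Write a gene-set collection to GMT
#'
#' @param sets `gene_sets` object or named list.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV/CSV
#'
#' Genes in rows by default (`orient = "genes"`), with a header row of sample
#' ids and the first column holding gene symbols. Optional sample annotations
#' (batch, cancer_type) come from a sidecar TSV keyed by sample_id.
#'
#' @param path expression file (TSV, or CSV when the extension is .csv).
#' @param log_transform if TRUE, values are replaced by log2(x + 1).
#' @param annot optional path to a sample-annotation TSV with columns
#'   sample_id, batch, cancer_type.
#' @param orient `"genes"` (genes in rows, default) or `"samples"`.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, log_transform = FALSE, annot = NULL,
                            orient = c("genes", "samples")) {
  orient <- match.arg(orient)
  if (!file.exists(path)) stop2("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop2("duplicate gene row: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m)))
  if (any(is.na(storage) & !is.na(m)))
    stop2("non-numeric cell in expression file")
  if (any(is.na(storage))) stop2("missing value in expression file")
  rownames(storage) <- ids
  if (orient == "samples") storage <- t(storage)
  if (log_transform) {
    if (any(storage < 0)) stop2("negative raw values cannot be log2(x+1) transformed")
    storage <- log2(storage + 1)
  }
  batch <- "batch1"; cancer <- "unknown"
  if (!is.null(annot)) {
    a <- utils::read.table(annot, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("sample_id", "batch", "cancer_type")
    if (!all(need %in% names(a))) stop2("annotation file needs columns: ", paste(need, collapse = ", "))
    idx <- match(colnames(storage), a$sample_id)
    if (any(is.na(idx))) stop2("annotation missing for samples: ",
                               paste(colnames(storage)[is.na(idx)], collapse = ", "))
    batch <- a$batch[idx]; cancer <- a$cancer_type[idx]
  }
  expression_matrix(storage, batch = batch, cancer_type = cancer)
}

#' Write an expression matrix (and its annotations) to TSV
#'
#' @param x `expr_matrix`.
#' @param path output TSV path; annotations go to `<path>.annot.tsv` unless
#'   `annot` is given.
#' @param annot optional explicit annotation path.
#' @export
write_expression <- function(x, path, annot = paste0(path, ".annot.tsv")) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- data.frame(sample_id = colnames(x$values), batch = x$batch,
                  cancer_type = x$cancer_type, stringsAsFactors = FALSE)
  utils::write.table(a, annot, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted PPI edge list
#'
#' Three tab-separated columns (geneA, geneB, weight >= 0), with a header
#' detected automatically. Repeated edges keep the maximum weight; self-loops
#' are dropped.
#'
#' @param path edge-list TSV.
#' @return an undirected simple [igraph::graph] with edge attribute `weight`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = c("a", "b", "w"))
  if (is.character(df$w)) {  # header row present
    suppressWarnings(first <- as.numeric(df$w[1]))
    if (is.na(first)) df <- df[-1, , drop = FALSE]
    df$w <- as.numeric(df$w)
  }
  if (any(is.na(df$w))) stop2("non-numeric edge weight")
  if (any(df$w < 0)) stop2("negative edge weight")
  keep <- df$a != df$b
  nodes <- unique(c(df$a, df$b))
  df <- df[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(df) > 0) {
    g <- igraph::add_edges(g, rbind(match(df$a, nodes), match(df$b, nodes)),
                           weight = df$w)
    # collapse parallel edges, keeping the maximum weight
    g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  }
  g
}

#' Write a graph as a 3-column edge list
#' @param g igraph with `weight` edge attribute.
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  e <- igraph::as_data_frame(g, what = "edges")
  if (is.null(e$weight)) e$weight <- 1
  utils::write.table(e[, c("from", "to", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a drug table
#'
#' TSV with columns `drug_id`, `smiles`, `targets` (semicolon-separated gene
#' symbols, possibly empty).
#'
#' @param path drug-table TSV.
#' @return data.frame with columns drug_id, smiles and list-column targets.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (!all(c("drug_id", "smiles") %in% names(df)))
    stop2("drug table needs columns drug_id and smiles")
  if (!"targets" %in% names(df)) df$targets <- ""
  if (anyDuplicated(df$drug_id)) stop2("repeated drug_id in drug table")
  df$targets <- lapply(df$targets, function(t) {
    if (is.na(t) || !nzchar(t)) character(0)
    else unique(strsplit(t, ";", fixed = TRUE)[[1]])
  })
  df
}

#' Write a drug table
#' @param drugs data.frame as returned by [read_drug_table()].
#' @param path output path.
#' @export
write_drug_table <- function(drugs, path) {
  out <- data.frame(drug_id = drugs$drug_id, smiles = drugs$smiles,
                    targets = vapply(drugs$targets, paste, character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a response table
#'
#' TSV with columns sample_id, drug_id, response. Outcome kind is declared,
#' not guessed: dichotomous responses must be 0/1, continuous must lie in
#' `range`.
#'
#' @param path response TSV.
#' @param kind `"dichotomous"` or `"continuous"`.
#' @param range permitted range for continuous outcomes.
#' @return `response_table` data.frame with attribute `kind`.
#' @export
read_response <- function(path, kind = c("dichotomous", "continuous"),
                          range = c(0, 1)) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  response_table(df$sample_id, df$drug_id, df$response, kind = kind, range = range)
}

#' Construct a response table
#' @param sample_id,drug_id,response parallel vectors.
#' @param kind outcome kind.
#' @param range continuous range.
#' @export
response_table <- function(sample_id, drug_id, response,
                           kind = c("dichotomous", "continuous"), range = c(0, 1)) {
  kind <- match.arg(kind)
  df <- data.frame(sample_id = as.character(sample_id),
                   drug_id = as.character(drug_id),
                   response = as.numeric(response), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("sample_id", "drug_id")]))
    stop2("duplicate (sample_id, drug_id) pair in response table")
  if (kind == "dichotomous" && !all(df$response %in% c(0, 1)))
    stop2("dichotomous responses must be 0/1")
  if (kind == "continuous" && (any(df$response < range[1]) || any(df$response > range[2])))
    stop2("continuous responses outside declared range")
  attr(df, "kind") <- kind
  class(df) <- c("response_table", "data.frame")
  df
}

#' Write a response table
#' @param tab `response_table`.
#' @param path output path.
#' @export
write_response <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a file against one of the pipeline formats
#'
#' @param path file path.
#' @param format one of "gmt", "expr", "edges", "drugs", "annot".
#' @return TRUE invisibly on success; errors otherwise.
#' @export
validate_file <- function(path, format = c("gmt", "expr", "edges", "drugs", "annot")) {
  format <- match.arg(format)
  switch(format,
    gmt = read_gmt(path),
    expr = read_expression(path),
    edges = read_edge_list(path),
    drugs = read_drug_table(path),
    annot = {
      a <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
      if (!all(c("sample_id", "batch", "cancer_type") %in% names(a)))
        stop2("annotation file needs sample_id, batch, cancer_type columns")
      a
    })
  invisible(TRUE)
}
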