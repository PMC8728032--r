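# Readers and writers for the on-disk formats the pipeline touches. The
# disk orientation of expression data is always genes x samples; the tests
# transpose to samples x genes internally (see expression_subset()).

#' Read an expression matrix
#'
#' Dense TSV/CSV: first column gene ids, header row sample ids, numeric
#' cells. Sparse `mtx_dir`: a directory holding `matrix.mtx` (MatrixMarket
#' triplet, genes x samples), `genes.tsv` (one gene id per line) and
#' `samples.tsv` (one sample id per line). Sparse input is kept sparse and
#' densified only when a gene subset is extracted.
#'
#' @param path File (dense) or directory (`mtx_dir`) path.
#' @param format `"tsv"`, `"csv"` or `"mtx_dir"`.
#' @return An [expression_dataset()] (without labels or gene sets).
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx_dir")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    return(read_expression_mtx(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = ""
  )
  if (ncol(df) < 2) {
    abort(sprintf("'%s': expected a gene-id column plus at least one sample column (got %d).", path, ncol(df)))
  }
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    abort(sprintf("'%s': duplicate gene id '%s'.", path, dup))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
    abort(sprintf("'%s': non-numeric cells in column %d.", path, bad))
  }
  expression_dataset(mat, gene_ids, colnames(df)[-1])
}

read_expression_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "samples.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("Missing mtx_dir file(s): ", paste(missing, collapse = ", ")))
  }
  m <- Matrix::readMM(paths[1])
  gene_ids <- readLines(paths[2])
  sample_ids <- readLines(paths[3])
  if (nrow(m) != length(gene_ids) || ncol(m) != length(sample_ids)) {
    abort(sprintf(
      "Matrix is %d x %d but sidecars list %d genes and %d samples.",
      nrow(m), ncol(m), length(gene_ids), length(sample_ids)
    ))
  }
  expression_dataset(as.matrix(m), gene_ids, sample_ids)
}

#' Write an expression dataset
#'
#' @param expr An [expression_dataset()].
#' @param path Output file (dense) or directory (`mtx_dir`).
#' @param format `"tsv"`, `"csv"` or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "csv", "mtx_dir")) {
  format <- match.arg(format)
  stopifnot(inherits(expr, "expression_dataset"))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(
      Matrix::Matrix(expr$matrix, sparse = TRUE),
      file.path(path, "matrix.mtx")
    )
    writeLines(expr$gene_ids, file.path(path, "genes.tsv"))
    writeLines(expr$sample_ids, file.path(path, "samples.tsv"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene_id = expr$gene_ids, expr$matrix, check.names = FALSE)
  utils::write.table(df, path,
    sep = sep, quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Read / write sample labels
#'
#' Two-column TSV without header: sample id, 0/1 label.
#'
#' @param path File path.
#' @return `read_labels`: a named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path,
    header = FALSE, sep = "\t",
    stringsAsFactors = FALSE
  )
  if (ncol(df) != 2) {
    abort(sprintf("'%s': expected 2 tab-separated columns, got %d.", path, ncol(df)))
  }
  labels <- as.integer(df[[2]])
  if (!all(labels %in% c(0L, 1L))) abort(sprintf("'%s': labels must be 0/1.", path))
  names(labels) <- as.character(df[[1]])
  labels
}

#' @rdname read_labels
#' @param labels Named 0/1 vector (names are sample ids).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(names(labels), as.integer(labels)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member gene ids. File
#' order is preserved; duplicate genes within a line are removed with a
#' notice; trailing empty fields are tolerated; an empty file yields an
#' empty collection.
#'
#' @param path GMT file path.
#' @return A named list of character vectors, with the per-set descriptions
#'   in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("'%s' line %d: expected at least 3 tab-separated fields.", path, i))
    }
    name <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      inform(sprintf(
        "read_gmt: %d duplicate gene(s) removed from set '%s'.",
        sum(duplicated(genes)), name
      ))
      genes <- unique(genes)
    }
    if (length(genes) == 0) {
      abort(sprintf("'%s' line %d: set '%s' has no genes.", path, i, name))
    }
    if (name %in% names(sets)) {
      abort(sprintf("'%s' line %d: duplicate set name '%s'.", path, i, name))
    }
    sets[[name]] <- genes
    descs[name] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(gene_sets, "descriptions")
  }
  lines <- vapply(seq_along(gene_sets), function(i) {
    desc <- if (!is.null(descriptions) && length(descriptions) >= i) {
      descriptions[[i]]
    } else {
      "na"
    }
    paste(c(names(gene_sets)[i], desc, gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one reference distribution: each
#' column's sorted values are replaced by the across-column mean of sorted
#' values, with ties receiving the mean of the reference values they span.
#' The computation is delegated to [limma::normalizeQuantiles()].
#'
#' @param expr An [expression_dataset()] or a numeric genes x samples
#'   matrix.
#' @return Same type as the input, normalized.
#' @export
quantile_normalize <- function(expr) {
  mat <- if (inherits(expr, "expression_dataset")) expr$matrix else as.matrix(expr)
  if (ncol(mat) < 2) abort("Quantile normalization needs at least 2 samples.")
  if (!all(is.finite(mat))) abort("Expression values must be finite.")
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(norm) <- dimnames(mat)
  if (inherits(expr, "expression_dataset")) {
    expr$matrix <- norm
    expr
  } else {
    norm
  }
}

#' Select the most variable genes
#'
#' Ranks genes by their across-sample variance (descending, ties broken by
#' input order) and keeps the top `k` -- the sparse-data preprocessing step
#' that keeps downstream covariance inversions well-posed.
#'
#' @param expr An [expression_dataset()].
#' @param k Number of genes to keep (default 100).
#' @return An [expression_dataset()] restricted to the `k` selected genes.
#' @export
top_variable_genes <- function(expr, k = 100) {
  stopifnot(inherits(expr, "expression_dataset"))
  n_genes <- length(expr$gene_ids)
  if (k > n_genes) {
    abort(sprintf("k = %d exceeds the number of genes (%d).", k, n_genes))
  }
  v <- apply(expr$matrix, 1, var)
  keep <- order(-v)[seq_len(k)] # stable order(): ties keep input order
  expression_dataset(
    expr$matrix[keep, , drop = FALSE],
    expr$gene_ids[keep], expr$sample_ids, expr$labels, expr$gene_sets
  )
}
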