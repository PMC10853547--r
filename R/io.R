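#' Construct a validated expression matrix
#'
#' The package's central container: a numeric genes x observations matrix
#' with unique row (gene) and column (observation) identifiers and a layer
#' tag recording what the values are.
#'
#' @param values numeric matrix with rownames (genes) and colnames
#'   (observations).
#' @param layer one of `"counts"`, `"lognorm"`, `"bulk"`.
#' @return the matrix, validated, with a `layer` attribute.
#' @export
expression_matrix <- function(values, layer = c("counts", "lognorm", "bulk")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires row (gene) and column (observation) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate observation identifiers in expression matrix")
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (layer == "counts" &&
      (any(values < 0) || any(values != floor(values))))
    stop("counts layer must contain non-negative integers")
  attr(values, "layer") <- layer
  values
}

#' Layer tag of an expression matrix
#' @param x matrix produced by [expression_matrix()] or a reader.
#' @return character layer tag, or `NA` if untagged.
#' @export
expr_layer <- function(x) {
  l <- attr(x, "layer")
  if (is.null(l)) NA_character_ else l
}

## Collapse duplicate gene symbols: keep, per symbol, the row with the
## highest total signal. Deterministic; warns when anything is dropped.
collapse_duplicate_genes <- function(values) {
  dup <- duplicated(rownames(values)) | duplicated(rownames(values), fromLast = TRUE)
  if (!any(dup)) return(values)
  tot <- rowSums(values)
  keep <- order(-tot)                       # highest-signal first
  keep <- keep[!duplicated(rownames(values)[keep])]
  keep <- sort(keep)
  warning(sprintf("collapsed %d duplicate gene symbols (kept highest total signal)",
                  nrow(values) - length(keep)))
  values[keep, , drop = FALSE]
}

#' Read an expression matrix
#'
#' Reads a 10x-style MatrixMarket triplet directory (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`) or a dense delimited file with genes as
#' rows. Dense files whose first header field is `sample_id` are taken as
#' samples x genes and transposed on read.
#'
#' @param path directory (for `mtx_dir`) or file path.
#' @param format `"mtx_dir"`, `"csv"` or `"tsv"`.
#' @param layer layer tag to attach, see [expression_matrix()].
#' @return a validated expression matrix.
#' @export
read_expression <- function(path, format = c("mtx_dir", "csv", "tsv"),
                            layer = c("counts", "lognorm", "bulk")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (format == "mtx_dir") {
    files <- file.path(path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
    if (!all(file.exists(files)))
      stop("MTX directory must contain matrix.mtx, features.tsv and barcodes.tsv")
    m <- as.matrix(Matrix::readMM(files[1]))
    feats <- utils::read.table(files[2], sep = "\t", header = FALSE,
                               colClasses = "character")
    bars <- readLines(files[3])
    if (nrow(feats) != nrow(m))
      stop(sprintf("features.tsv has %d rows but matrix has %d rows",
                   nrow(feats), nrow(m)))
    if (length(bars) != ncol(m))
      stop(sprintf("barcodes.tsv has %d lines but matrix has %d columns",
                   length(bars), ncol(m)))
    rownames(m) <- feats[[1]]
    colnames(m) <- bars
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    first_field <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]][1]
    if (identical(first_field, "sample_id")) m <- t(m)
  }
  m <- collapse_duplicate_genes(m)
  expression_matrix(m, layer = layer)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: writes either an MTX triplet directory or
#' a dense delimited file (genes as rows).
#'
#' @param x expression matrix.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(rownames(x), rownames(x)),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(colnames(x), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then one or more genes, tab-separated.
#' Duplicate genes within a set are removed preserving first occurrence.
#'
#' @param path GMT file path.
#' @return a gene-set collection: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1]))
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_))
    stop("duplicate gene-set names in GMT file")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- which(lengths(sets) == 0)
  if (length(empty))
    stop(sprintf("gene set '%s' has an empty gene list", names_[empty[1]]))
  names(sets) <- names_
  desc <- vapply(fields, `[[`, character(1), 2)
  names(desc) <- names_
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#' @param sets named list of character gene vectors (unique within a set).
#' @param descriptions optional named character vector of descriptions.
#' @return list with elements `sets` and `descriptions`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection a gene-set collection.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' Expects tab- or comma-separated columns `sample_id`, `time`, `event`
#' (0 = censored, 1 = event).
#'
#' @param path file path.
#' @return data.frame with validated `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, header = TRUE,
                          sep = if (grepl("\\.csv$", path)) "," else "\t")
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table requires columns sample_id, time, event")
  validate_survival(df[need])
}

validate_survival <- function(df) {
  bad <- which(!is.finite(df$time) | df$time < 0)
  if (length(bad)) stop(sprintf("negative or missing time in row %d", bad[1]))
  bad <- which(!df$event %in% c(0, 1))
  if (length(bad)) stop(sprintf("event not in {0,1} in row %d", bad[1]))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_ids in survival table")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a gene coordinate table
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `gene`; coordinates
#' 0-based half-open, one row per gene.
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `chromosome`, `start`, `end`.
#' @export
read_gene_coords <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(df)))
    stop("gene coordinate table requires columns chrom, start, end, gene")
  out <- data.frame(gene = as.character(df$gene),
                    chromosome = as.character(df$chrom),
                    start = df$start, end = df$end)
  validate_gene_coords(out)
}

validate_gene_coords <- function(df) {
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("start >= end in gene coordinate row %d", bad[1]))
  if (anyDuplicated(df$gene)) stop("duplicate genes in coordinate table")
  df
}

#' Read a ligand-receptor pair table
#'
#' CSV/TSV with columns `pair_id`, `ligand`, `receptor`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE,
                          sep = if (grepl("\\.csv$", path)) "," else "\t")
  need <- c("pair_id", "ligand", "receptor")
  if (!all(need %in% names(df)))
    stop("ligand-receptor table requires columns pair_id, ligand, receptor")
  bad <- which(!nzchar(df$ligand) | !nzchar(df$receptor))
  if (length(bad)) stop(sprintf("empty ligand or receptor in row %d", bad[1]))
  if (anyDuplicated(df$pair_id)) stop("duplicate pair_ids")
  df[need]
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
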