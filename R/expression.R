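#' Construct an expression matrix object
#'
#' An `expr_matrix` holds a dense numeric matrix of expression values with
#' samples as rows and genes as columns, together with a flag recording
#' whether the values are on the log2 scale (normalized counts floored at 1,
#' then log2-transformed).
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param sample_ids character vector of unique sample identifiers (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param is_log2 logical; `TRUE` once values are log2(max(count, 1)).
#' @param gene_meta optional data.frame of per-gene metadata (e.g. Entrez
#'   ids recovered from composite identifiers), one row per gene.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `is_log2` and optionally `gene_meta`. Row and column names of `values`
#'   carry the ids.
#' @export
expr_matrix <- function(values, sample_ids = rownames(values),
                        gene_ids = colnames(values), is_log2 = FALSE,
                        gene_meta = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("sample_ids and gene_ids are required")
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(sample_ids) || ncol(values) != length(gene_ids)) {
    stop("dimensions of values do not match id lengths (need samples x genes)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing")
  }
  if (isTRUE(is_log2) && any(values < 0)) {
    stop("log2-scale expression values must be >= 0")
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, is_log2 = isTRUE(is_log2),
                 gene_meta = gene_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d samples x %d genes (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log2) "log2" else "raw count"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
gene_ids_of <- function(x) colnames(x$values)

#' Read a tab-separated expression table
#'
#' Reads the GDAC RSEM export dialect: a tab-separated numeric table with a
#' single header row and a single identifier column. Both orientations are
#' supported; internally the matrix is always stored samples x genes.
#'
#' @param path path to the TSV file.
#' @param orientation `"genes_as_rows"` (GDAC layout: header = sample ids,
#'   first column = gene ids) or `"samples_as_rows"`.
#' @param id_style `"plain"` or `"pipe_composite"`. With the composite style
#'   an identifier such as `"TP53|7157"` resolves to gene id `"TP53"` with
#'   the numeric part kept as metadata; identifiers whose resolved symbol
#'   collides with another row (e.g. `"?|100130426"`) keep the full
#'   composite string as id.
#'
#' @return An [expr_matrix] with `is_log2 = FALSE`.
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes_as_rows",
                                                  "samples_as_rows"),
                                  id_style = c("plain", "pipe_composite")) {
  orientation <- match.arg(orientation)
  id_style <- match.arg(id_style)
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(tab) < 2L) stop("expected an identifier column plus data columns")
  row_ids <- tab[[1L]]
  col_ids <- colnames(tab)[-1L]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  if (any(cells == "" | is.na(cells))) {
    bad <- which(cells == "" | is.na(cells), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row '%s', column '%s'",
                 row_ids[bad[1L]], col_ids[bad[2L]]))
  }
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 cells[bad[1L], bad[2L]], row_ids[bad[1L]], col_ids[bad[2L]]))
  }

  if (orientation == "genes_as_rows") {
    values <- t(num)
    gids <- row_ids
    sids <- col_ids
  } else {
    values <- num
    gids <- col_ids
    sids <- row_ids
  }

  gene_meta <- NULL
  if (id_style == "pipe_composite") {
    res <- resolve_composite_ids(gids)
    gids <- res$ids
    gene_meta <- res$meta
  }
  if (anyDuplicated(gids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gids[duplicated(gids)]), collapse = ", "))
  }
  if (anyDuplicated(sids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))
  }
  expr_matrix(values, sids, gids, is_log2 = FALSE, gene_meta = gene_meta)
}

# "SYMBOL|ENTREZ" -> symbol, entrez kept as metadata; rows whose resolved
# symbol collides (or is "?") fall back to the full composite string.
resolve_composite_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  symbol <- vapply(parts, `[[`, "", 1L)
  entrez <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_, "")
  resolved <- symbol
  unknown <- symbol == "?" | symbol == ""
  dup <- symbol %in% symbol[duplicated(symbol)]
  keep_full <- unknown | dup
  resolved[keep_full] <- ids[keep_full]
  list(ids = resolved,
       meta = data.frame(gene_id = resolved, symbol = symbol,
                         entrez = entrez, composite = ids,
                         stringsAsFactors = FALSE))
}

#' Floor counts at 1 and log2-transform
#'
#' Normalized counts below 1 are regarded as noise and replaced with 1,
#' then the whole table is log2-transformed. Applying the transformation to
#' an already transformed matrix is an error.
#'
#' @param raw an [expr_matrix] with `is_log2 = FALSE` and non-negative
#'   values.
#' @return An [expr_matrix] with `is_log2 = TRUE`; value 0 exactly where the
#'   input was <= 1.
#' @export
preprocess_expression <- function(raw) {
  stopifnot(inherits(raw, "expr_matrix"))
  if (raw$is_log2) stop("matrix is already log2-transformed")
  if (any(raw$values < 0)) stop("negative expression values cannot be counts")
  out <- raw
  out$values <- log2(pmax(raw$values, 1))
  out$is_log2 <- TRUE
  out
}

#' Read a sample annotation table
#'
#' Tab-separated with columns `sample_id`, `group_label` and optionally
#' `sample_type_code`. A sample is flagged normal exactly when its type code
#' is present and starts with the character "1" (TCGA code-table rule).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample_id`, `group_label`,
#'   `sample_type_code` (NA when absent) and `is_normal`.
#' @export
read_sample_annotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "group_label") %in% colnames(tab))) {
    stop("annotation file needs columns sample_id and group_label")
  }
  if (!"sample_type_code" %in% colnames(tab)) tab$sample_type_code <- NA_character_
  tab$sample_type_code[tab$sample_type_code == ""] <- NA_character_
  sample_annotations(tab$sample_id, tab$group_label, tab$sample_type_code)
}

#' Build a sample annotation data.frame
#'
#' @param sample_id,group_label,sample_type_code character vectors (the type
#'   code may be NA).
#' @return data.frame with the derived `is_normal` flag.
#' @export
sample_annotations <- function(sample_id, group_label,
                               sample_type_code = NA_character_) {
  ann <- data.frame(sample_id = as.character(sample_id),
                    group_label = as.character(group_label),
                    sample_type_code = as.character(sample_type_code),
                    stringsAsFactors = FALSE)
  ann$is_normal <- !is.na(ann$sample_type_code) &
    substr(ann$sample_type_code, 1L, 1L) == "1"
  ann
}

#' Subset samples of an expression matrix by an annotation predicate
#'
#' @param expr an [expr_matrix].
#' @param annotations data.frame as returned by [sample_annotations()].
#' @param keep predicate: a function taking the annotation data.frame and
#'   returning a logical vector (e.g. `function(a) !a$is_normal`).
#' @return The row-subset [expr_matrix]; gene set and column order unchanged.
#'   Annotations for unknown samples are skipped with a warning; samples
#'   with no annotation row are retained. An empty result is an error.
#' @export
filter_samples <- function(expr, annotations, keep) {
  stopifnot(inherits(expr, "expr_matrix"), is.function(keep))
  sids <- sample_ids(expr)
  unknown <- setdiff(annotations$sample_id, sids)
  if (length(unknown)) {
    warning("annotations for unknown samples skipped: ",
            paste(unknown, collapse = ", "))
    annotations <- annotations[annotations$sample_id %in% sids, , drop = FALSE]
  }
  kp <- keep(annotations)
  if (!is.logical(kp) || length(kp) != nrow(annotations)) {
    stop("keep must return one logical per annotation row")
  }
  drop_ids <- annotations$sample_id[!kp]
  retained <- setdiff(sids, drop_ids)
  if (!length(retained)) stop("no samples retained by the predicate")
  out <- expr
  out$values <- expr$values[retained, , drop = FALSE]
  out
}

#' Write an expression matrix as a GDAC-style TSV
#'
#' Genes as rows, header row of sample ids, first column of gene ids.
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces the matrix to floating-point accuracy.
#'
#' @param expr an [expr_matrix].
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  write_matrix_tsv(t(expr$values), gene_ids_of(expr), path,
                   id_header = "gene_id")
}

#' Write a numeric matrix as TSV with an identifier column
#'
#' @param m numeric matrix; column names become the header.
#' @param row_ids identifiers for the first column.
#' @param path output path.
#' @param id_header name of the identifier column.
#' @export
write_matrix_tsv <- function(m, row_ids, path, id_header = "id") {
  m <- as.matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("cannot write an empty matrix")
  if (length(row_ids) != nrow(m)) stop("row_ids length does not match matrix")
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(m)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(id_header, cn), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(row_ids, body, sep = "\t"), con)
  invisible(path)
}
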