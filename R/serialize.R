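#' Write a fitted embedding to a directory
#'
#' Writes `gene_vectors.tsv` (id column plus m coordinate columns),
#' `sample_vectors.tsv`, `biases.tsv` (entity, id, bias) and `model.json`
#' (dimension, training configuration, loss history). Values carry 17
#' significant digits, so two identical models serialize byte-identically
#' and a round trip reproduces the parameters exactly.
#'
#' @param model a `gene_embedding`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_embedding <- function(model, dir) {
  stopifnot(inherits(model, "gene_embedding"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(model$G, model$gene_ids,
                   file.path(dir, "gene_vectors.tsv"), id_header = "gene_id")
  write_matrix_tsv(model$S, model$sample_ids,
                   file.path(dir, "sample_vectors.tsv"),
                   id_header = "sample_id")
  con <- file(file.path(dir, "biases.tsv"), open = "wb")
  writeLines(c("entity\tid\tbias",
               paste("gene", model$gene_ids,
                     sprintf("%.17g", model$b_gene), sep = "\t"),
               paste("sample", model$sample_ids,
                     sprintf("%.17g", model$b_sample), sep = "\t")), con)
  close(con)
  meta <- list(package = "genevec", class = "gene_embedding",
               dim = model$dim, n_genes = length(model$gene_ids),
               n_samples = length(model$sample_ids),
               config = model$config,
               history = model$history)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fitted embedding from a directory
#'
#' @param dir directory written by [write_embedding()].
#' @return a `gene_embedding` (without the training data).
#' @export
read_embedding <- function(dir) {
  need <- file.path(dir, c("gene_vectors.tsv", "sample_vectors.tsv",
                           "biases.tsv", "model.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("model files not found: ",
                            paste(missing, collapse = ", "))
  gv <- utils::read.delim(need[1L], check.names = FALSE)
  sv <- utils::read.delim(need[2L], check.names = FALSE)
  bias <- utils::read.delim(need[3L], check.names = FALSE)
  meta <- jsonlite::read_json(need[4L], simplifyVector = TRUE)
  G <- as.matrix(gv[, -1L, drop = FALSE])
  rownames(G) <- gv[[1L]]
  S <- as.matrix(sv[, -1L, drop = FALSE])
  rownames(S) <- sv[[1L]]
  bg <- bias$bias[bias$entity == "gene"]
  names(bg) <- bias$id[bias$entity == "gene"]
  bs <- bias$bias[bias$entity == "sample"]
  names(bs) <- bias$id[bias$entity == "sample"]
  history <- as.data.frame(meta$history)
  if (!nrow(history)) {
    history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                          val_mse = numeric(0))
  }
  structure(list(gene_ids = rownames(G), sample_ids = rownames(S),
                 G = G, S = S, b_gene = bg[rownames(G)],
                 b_sample = bs[rownames(S)], dim = as.integer(meta$dim),
                 config = as.list(meta$config), history = history,
                 data = NULL, call = quote(read_embedding(dir))),
            class = "gene_embedding")
}

#' Export entity vectors for the TensorBoard embedding projector
#'
#' Writes `<space>_vectors.tsv` (tab-separated coordinates, no header) and
#' `<space>_metadata.tsv` (ids; with a header row only when labels are
#' supplied, following the projector's single-versus-multi-column
#' convention).
#'
#' @param model a `gene_embedding`.
#' @param dir output directory.
#' @param space `"gene"` or `"sample"`.
#' @param labels optional named character vector of per-entity labels.
#' @return `dir`, invisibly.
#' @export
export_projector <- function(model, dir, space = c("gene", "sample"),
                             labels = NULL) {
  space <- match.arg(space)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  V <- entity_vectors(model, space)
  vec_path <- file.path(dir, paste0(space, "_vectors.tsv"))
  con <- file(vec_path, open = "wb")
  writeLines(apply(V, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  close(con)
  meta_path <- file.path(dir, paste0(space, "_metadata.tsv"))
  ids <- rownames(V)
  con <- file(meta_path, open = "wb")
  if (is.null(labels)) {
    writeLines(ids, con)
  } else {
    writeLines(c("id\tlabel", paste(ids, labels[ids], sep = "\t")), con)
  }
  close(con)
  invisible(dir)
}
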