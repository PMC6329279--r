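#' Per-group centroid matrix over embedding dimensions
#'
#' One row per sample group (e.g. cancer type): the centroid of that
#' group's sample entity vectors. The heatmap of this matrix is what makes
#' group preferences for particular embedding dimensions visible.
#'
#' @param model a `gene_embedding`.
#' @param annotations data.frame with columns `sample_id` and `group_label`
#'   (see [sample_annotations()]).
#' @return numeric matrix, groups x m, rows named by group label.
#' @export
group_dimension_matrix <- function(model, annotations) {
  ann <- annotations[annotations$sample_id %in% model$sample_ids, ,
                     drop = FALSE]
  missing <- setdiff(annotations$sample_id, model$sample_ids)
  if (length(missing)) {
    warning("annotations for samples absent from the model skipped: ",
            paste(missing, collapse = ", "))
  }
  if (!nrow(ann)) stop("no annotated samples in the model")
  groups <- unique(ann$group_label)
  rows <- t(vapply(groups, function(g) {
    ids <- ann$sample_id[ann$group_label == g]
    colMeans(model$S[ids, , drop = FALSE])
  }, numeric(model$dim)))
  rownames(rows) <- groups
  rows
}

#' Differentially hot embedding dimensions of a group
#'
#' Scores every dimension by how far the group's centroid coordinate lies
#' from the mean of the other groups' coordinates, in units of the
#' across-group standard deviation of that coordinate. Large |score| marks
#' the dimensions in which the group is differentially weighted.
#'
#' @param dgm matrix from [group_dimension_matrix()].
#' @param group_label one of its row names.
#' @param top_n number of dimensions to return.
#' @return data.frame with columns `dimension` (1-based) and `score`
#'   (signed), ordered by decreasing |score|, ties broken by lower index.
#' @export
hot_dimensions <- function(dgm, group_label, top_n = 5L) {
  if (nrow(dgm) < 2L) stop("need at least 2 groups for a contrast")
  gi <- match(group_label, rownames(dgm))
  if (is.na(gi)) stop("unknown group: ", group_label)
  others <- dgm[-gi, , drop = FALSE]
  sds <- apply(dgm, 2L, stats::sd)
  score <- (dgm[gi, ] - colMeans(others)) / sds
  score[sds == 0] <- 0
  ord <- order(-abs(score), seq_along(score))
  out <- data.frame(dimension = ord[seq_len(min(top_n, length(score)))],
                    score = score[ord[seq_len(min(top_n, length(score)))]])
  rownames(out) <- NULL
  out
}

#' Top genes of an embedding dimension
#'
#' @param model a `gene_embedding`.
#' @param dimension dimension index (1-based, in 1..m).
#' @param k number of genes (default 100).
#' @param direction ranking statistic of the coordinate: `"absolute"`
#'   (default), `"positive"` (largest), or `"negative"` (smallest).
#' @return character vector of k gene ids; ties broken by id.
#' @export
top_genes_by_dimension <- function(model, dimension, k = 100L,
                                   direction = c("absolute", "positive",
                                                 "negative")) {
  direction <- match.arg(direction)
  if (dimension < 1L || dimension > model$dim) {
    stop("dimension out of range: ", dimension)
  }
  if (k > length(model$gene_ids)) stop("k exceeds the number of genes")
  x <- model$G[, dimension]
  key <- switch(direction, absolute = -abs(x), positive = -x, negative = x)
  model$gene_ids[order(key, model$gene_ids)][seq_len(k)]
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#'
#' @param path path to the .gmt file.
#' @return named list of character vectors (one per set), with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                     paste(which(bad), collapse = ", "))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate GMT term ids")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), ids)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors; an optional `descriptions`
#'   attribute supplies the second column (default `"na"`).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  if (!length(sets) || is.null(names(sets))) stop("sets must be a named list")
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' One-sided Fisher (hypergeometric upper-tail) test of the overlap between
#' a gene list and each gene set, against a stated gene universe, with
#' Benjamini-Hochberg correction across the tested sets. A set is flagged
#' significant when p < 0.01 and FDR < 0.05.
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param sets named list of character vectors (see [read_gmt()]); each set
#'   is intersected with the universe before testing, and sets empty after
#'   intersection are skipped with a warning.
#' @param universe character vector of background gene ids (typically all
#'   genes in the model).
#' @param p_cutoff,fdr_cutoff significance thresholds (defaults 0.01, 0.05).
#' @return data.frame with one row per tested set: `term_id`, `term_name`,
#'   `overlap`, `list_size`, `set_size`, `universe_size`, `p_value`, `fdr`,
#'   `significant`, ordered by p-value.
#' @export
fisher_enrichment <- function(gene_list, sets, universe,
                              p_cutoff = 0.01, fdr_cutoff = 0.05) {
  if (!length(gene_list)) stop("gene_list is empty")
  if (!length(universe)) stop("universe is empty")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  out <- setdiff(gene_list, universe)
  if (length(out)) stop("gene_list not contained in universe: ",
                        paste(utils::head(out, 5L), collapse = ", "))
  U <- length(universe)
  L <- length(gene_list)
  desc <- attr(sets, "descriptions")
  trimmed <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(trimmed) == 0L
  if (any(empty)) {
    warning("sets with no members in the universe skipped: ",
            paste(names(sets)[empty], collapse = ", "))
    trimmed <- trimmed[!empty]
  }
  if (!length(trimmed)) stop("no testable sets")
  K <- lengths(trimmed)
  ov <- vapply(trimmed, function(s) length(intersect(s, gene_list)), 0L)
  # P(X >= overlap), X ~ Hypergeometric(U, K, L)
  p <- stats::phyper(ov - 1L, K, U - K, L, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  res <- data.frame(term_id = names(trimmed),
                    term_name = if (!is.null(desc))
                      unname(desc[names(trimmed)]) else names(trimmed),
                    overlap = ov, list_size = L, set_size = K,
                    universe_size = U, p_value = p, fdr = fdr,
                    significant = p < p_cutoff & fdr < fdr_cutoff,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Signature dimension of each signature gene
#'
#' For each signature gene, the embedding dimension carrying the largest
#' absolute coordinate of its gene vector — the dimension in which the gene
#' is most disparately weighted. Ties resolve to the lower index; an
#' all-zero vector maps to dimension 1 with a warning.
#'
#' @param model a `gene_embedding`.
#' @param signature_gene_ids character vector of gene ids.
#' @return named integer vector of 1-based dimension indices.
#' @export
select_signature_dimensions <- function(model, signature_gene_ids) {
  miss <- setdiff(signature_gene_ids, model$gene_ids)
  if (length(miss)) stop("unknown genes: ", paste(miss, collapse = ", "))
  vapply(signature_gene_ids, function(g) {
    v <- abs(model$G[g, ])
    if (all(v == 0)) {
      warning("gene ", g, " has an all-zero vector; dimension 1 assigned")
      return(1L)
    }
    which.max(v)
  }, 1L)
}

#' Dimensions with above-average spread across samples
#'
#' Keeps the dimensions whose standard deviation across the given samples
#' is strictly greater than the mean of all per-dimension standard
#' deviations — the display filter used before subtype clustering.
#'
#' @param S_sub samples x m numeric matrix (rows of a sample entity matrix).
#' @return integer vector of 1-based dimension indices.
#' @export
dimension_sd_filter <- function(S_sub) {
  S_sub <- as.matrix(S_sub)
  if (nrow(S_sub) < 2L) stop("need at least 2 samples")
  sds <- apply(S_sub, 2L, stats::sd)
  which(sds > mean(sds))
}

#' UPGMA clustering
#'
#' Agglomerative clustering of the rows of a coordinate matrix on Euclidean
#' distances with average linkage, where the distance between merged
#' clusters is the unweighted mean of all cross-pair distances (UPGMA).
#' Flat labels come from cutting the tree at `n_clusters`.
#'
#' @param points items x coordinates numeric matrix.
#' @param n_clusters number of flat clusters (1..items).
#' @return list with `tree` (an [stats::hclust] object), `labels` (named
#'   integer cluster assignment) and `heights` (merge heights).
#' @export
upgma_cluster <- function(points, n_clusters) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 items")
  if (n_clusters < 1L || n_clusters > nrow(points)) {
    stop("n_clusters must be in 1..", nrow(points))
  }
  hc <- stats::hclust(stats::dist(points, method = "euclidean"),
                      method = "average")
  labels <- stats::cutree(hc, k = n_clusters)
  list(tree = hc, labels = labels, heights = hc$height)
}

#' Signature-dimension molecular subtyping
#'
#' Extracts the signature dimension of each signature gene
#' ([select_signature_dimensions()]), pulls those dimensions out of the
#' sample entity matrix, and resolves subtypes by UPGMA clustering of the
#' samples on the selected coordinates.
#'
#' @param model a `gene_embedding`.
#' @param signature_gene_ids signature genes (e.g. markers known to
#'   distinguish subtypes).
#' @param n_clusters number of subtypes to resolve.
#' @param samples optional subset of sample ids (default: all).
#' @return list with `dimensions` (named, per signature gene), `labels`
#'   (cluster per sample) and `tree`.
#' @export
molecular_subtype <- function(model, signature_gene_ids, n_clusters,
                              samples = NULL) {
  dims <- select_signature_dimensions(model, signature_gene_ids)
  S <- model$S
  if (!is.null(samples)) S <- S[samples, , drop = FALSE]
  cl <- upgma_cluster(S[, unique(dims), drop = FALSE], n_clusters)
  list(dimensions = dims, labels = cl$labels, tree = cl$tree)
}
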