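#' Entity vectors of a model
#'
#' @param model a `gene_embedding`.
#' @param space `"gene"` or `"sample"`.
#' @return the k x m (or n x m) entity matrix, rows named by id.
#' @export
entity_vectors <- function(model, space = c("gene", "sample")) {
  space <- match.arg(space)
  if (space == "gene") model$G else model$S
}

entity_vector <- function(model, id, space) {
  V <- entity_vectors(model, space)
  i <- match(id, rownames(V))
  if (is.na(i)) stop("unknown ", space, " id: ", id)
  V[i, ]
}

#' Euclidean distance between two entities
#'
#' @param model a `gene_embedding`.
#' @param id_a,id_b entity ids.
#' @param space `"gene"` or `"sample"`.
#' @return non-negative scalar distance in embedding units.
#' @export
embedding_distance <- function(model, id_a, id_b,
                               space = c("gene", "sample")) {
  space <- match.arg(space)
  sqrt(sum((entity_vector(model, id_a, space) -
              entity_vector(model, id_b, space))^2))
}

#' Close neighbors of an entity under a Euclidean threshold
#'
#' An entity is a close neighbor of the anchor when its Euclidean distance
#' is strictly smaller than the threshold (0.1 by default). The anchor
#' itself is excluded; results are sorted by ascending distance with ties
#' broken lexicographically by id.
#'
#' @param model a `gene_embedding`.
#' @param anchor_id anchor entity id.
#' @param threshold strict distance cutoff (default 0.1).
#' @param space `"gene"` or `"sample"`.
#' @return data.frame with columns `id` and `distance`.
#' @export
close_neighbors <- function(model, anchor_id, threshold = 0.1,
                            space = c("gene", "sample")) {
  space <- match.arg(space)
  V <- entity_vectors(model, space)
  a <- entity_vector(model, anchor_id, space)
  d <- sqrt(rowSums(sweep(V, 2L, a)^2))
  keep <- d < threshold & rownames(V) != anchor_id
  hits <- data.frame(id = rownames(V)[keep], distance = d[keep],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$distance, hits$id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Vector offset between two entities
#'
#' `vector(a) - vector(b)`; approximately equal offsets between different
#' entity pairs indicate analogous relationships in the embedding space.
#'
#' @inheritParams embedding_distance
#' @return length-m numeric vector.
#' @export
analogy_offset <- function(model, id_a, id_b, space = c("gene", "sample")) {
  space <- match.arg(space)
  entity_vector(model, id_a, space) - entity_vector(model, id_b, space)
}

#' Euclidean norm of an offset
#'
#' @param offset numeric vector as returned by [analogy_offset()].
#' @return scalar norm.
#' @export
offset_norm <- function(offset) sqrt(sum(offset^2))

#' Centroid of a sample group in the entity space
#'
#' @param model a `gene_embedding`.
#' @param sample_ids non-empty vector of sample ids.
#' @param group_label optional label carried on the result.
#' @return object of class `centroid_profile`: the coordinate-wise mean of
#'   the member sample vectors, member count, member ids, and label.
#' @export
group_centroid <- function(model, sample_ids, group_label = NA_character_) {
  if (!length(sample_ids)) stop("sample_ids must be non-empty")
  miss <- setdiff(sample_ids, model$sample_ids)
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  V <- model$S[sample_ids, , drop = FALSE]
  structure(list(group_label = group_label,
                 centroid = colMeans(V),
                 member_count = length(sample_ids),
                 member_ids = sample_ids),
            class = "centroid_profile")
}

#' @export
print.centroid_profile <- function(x, ...) {
  cat(sprintf("centroid_profile '%s': %d samples, dimension %d\n",
              x$group_label, x$member_count, length(x$centroid)))
  invisible(x)
}

#' Predicted expression profile under a group centroid
#'
#' Multiplies the centroid of the sample entity matrix with the gene entity
#' matrix: the value for gene a is `dot(centroid, G_a)`. Biases are excluded
#' by default; with `include_biases = TRUE` the gene bias plus the mean of
#' the member sample biases is added.
#'
#' @param model a `gene_embedding`.
#' @param centroid a `centroid_profile` (or bare length-m numeric vector).
#' @param include_biases logical (default `FALSE`).
#' @return named numeric vector over all genes in the model, of class
#'   `predicted_profile`, with the group label and bias flag as attributes.
#' @export
predicted_profile <- function(model, centroid, include_biases = FALSE) {
  lab <- NA_character_
  mean_bs <- 0
  if (inherits(centroid, "centroid_profile")) {
    lab <- centroid$group_label
    mean_bs <- mean(model$b_sample[centroid$member_ids])
    centroid <- centroid$centroid
  }
  if (length(centroid) != model$dim) {
    stop("centroid dimension does not match the model")
  }
  v <- drop(model$G %*% centroid)
  if (include_biases) v <- v + model$b_gene + mean_bs
  names(v) <- model$gene_ids
  structure(v, class = c("predicted_profile", "numeric"),
            group_label = lab, include_biases = include_biases)
}
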