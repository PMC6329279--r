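#' Responder/non-responder group specification
#'
#' Bundles the two disjoint sample groups, the anchor genes (e.g. the
#' immune checkpoint genes PDCD1, CD274, CTLA4) and the neighbor threshold
#' used by the discovery workflow.
#'
#' @param responder_sample_ids,nonresponder_sample_ids disjoint, non-empty
#'   character vectors of sample ids.
#' @param anchor_gene_ids non-empty character vector of anchor genes.
#' @param threshold strict Euclidean neighbor cutoff (default 0.1).
#' @return object of class `group_spec`.
#' @export
group_spec <- function(responder_sample_ids, nonresponder_sample_ids,
                       anchor_gene_ids, threshold = 0.1) {
  if (!length(responder_sample_ids) || !length(nonresponder_sample_ids)) {
    stop("both sample lists must be non-empty")
  }
  both <- intersect(responder_sample_ids, nonresponder_sample_ids)
  if (length(both)) {
    stop("responder and non-responder lists must be disjoint; shared: ",
         paste(utils::head(both, 5L), collapse = ", "))
  }
  if (!length(anchor_gene_ids)) stop("at least one anchor gene is required")
  if (!is.numeric(threshold) || threshold < 0) {
    stop("threshold must be a non-negative number")
  }
  structure(list(responder_sample_ids = unique(responder_sample_ids),
                 nonresponder_sample_ids = unique(nonresponder_sample_ids),
                 anchor_gene_ids = unique(anchor_gene_ids),
                 threshold = threshold),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("group_spec: %d responders, %d non-responders, anchors %s, threshold %g\n",
              length(x$responder_sample_ids),
              length(x$nonresponder_sample_ids),
              paste(x$anchor_gene_ids, collapse = ","), x$threshold))
  invisible(x)
}

#' Close neighbors of an anchor within a predicted profile
#'
#' A predicted profile assigns one scalar per gene, so the Euclidean
#' distance between two genes in the profile is the absolute difference of
#' their values. Genes strictly closer than the threshold to the anchor's
#' value (anchor excluded) are its profile neighbors.
#'
#' @param profile named numeric vector (see [predicted_profile()]).
#' @param anchor_gene anchor gene id, present in the profile.
#' @param threshold strict cutoff (default 0.1).
#' @return character vector of gene ids, ordered by ascending distance,
#'   ties by id.
#' @export
profile_neighbors <- function(profile, anchor_gene, threshold = 0.1) {
  v <- unclass(profile)
  if (is.null(names(v))) stop("profile must be a named vector")
  if (!anchor_gene %in% names(v)) stop("unknown anchor gene: ", anchor_gene)
  d <- abs(v - v[[anchor_gene]])
  keep <- d < threshold & names(v) != anchor_gene
  ids <- names(v)[keep]
  ids[order(d[keep], ids)]
}

#' Responder-exclusive profile neighbors
#'
#' Genes close to the anchor in the responder profile but not in the
#' non-responder profile.
#'
#' @param resp_profile,nonresp_profile named numeric vectors over the same
#'   gene universe.
#' @param anchor_gene anchor gene id.
#' @param threshold strict cutoff (default 0.1).
#' @return character vector of gene ids (responder-profile ordering).
#' @export
exclusive_neighbors <- function(resp_profile, nonresp_profile, anchor_gene,
                                threshold = 0.1) {
  if (!setequal(names(resp_profile), names(nonresp_profile))) {
    stop("profiles cover different gene universes")
  }
  setdiff(profile_neighbors(resp_profile, anchor_gene, threshold),
          profile_neighbors(nonresp_profile, anchor_gene, threshold))
}

#' Exclusive-neighbor biomarker discovery
#'
#' The responder/non-responder simulation workflow: compute the centroid of
#' each group's sample entity vectors, multiply each centroid with the gene
#' entity matrix to obtain the group's predicted expression profile, take
#' the anchor's close neighbors present exclusively in the responder
#' profile, and intersect them with the anchor's close neighbors in the
#' gene entity space. Surviving genes are the candidates; each is scored by
#' Pearson correlation with the anchor's log2 expression across responder
#' samples.
#'
#' @param model a `gene_embedding`.
#' @param expr an [expr_matrix] aligned to the model (for the correlation
#'   check).
#' @param spec a [group_spec()].
#' @param include_biases forwarded to [predicted_profile()] (default
#'   `FALSE`).
#' @return object of class `candidate_report`: per-anchor lists of
#'   exclusive profile neighbors, entity-space neighbors, candidates, and
#'   per-candidate statistics, plus the deduplicated union of candidates
#'   over anchors.
#' @export
discover_candidates <- function(model, expr, spec, include_biases = FALSE) {
  stopifnot(inherits(spec, "group_spec"))
  check_alignment(model, expr)
  miss <- setdiff(spec$anchor_gene_ids, model$gene_ids)
  if (length(miss)) stop("anchor genes absent from the model: ",
                         paste(miss, collapse = ", "))
  resp_c <- group_centroid(model, spec$responder_sample_ids, "responder")
  non_c <- group_centroid(model, spec$nonresponder_sample_ids,
                          "nonresponder")
  resp_p <- predicted_profile(model, resp_c, include_biases)
  non_p <- predicted_profile(model, non_c, include_biases)
  resp_X <- expr$values[spec$responder_sample_ids, , drop = FALSE]

  per_anchor <- lapply(spec$anchor_gene_ids, function(anchor) {
    excl <- exclusive_neighbors(resp_p, non_p, anchor, spec$threshold)
    ent <- close_neighbors(model, anchor, spec$threshold, "gene")$id
    cand <- sort(intersect(excl, ent))
    r <- if (length(cand)) {
      vapply(cand, function(g) stats::cor(resp_X[, g], resp_X[, anchor]),
             numeric(1))
    } else numeric(0)
    list(anchor = anchor,
         responder_exclusive_neighbors = excl,
         entity_neighbors = ent,
         candidates = cand,
         pearson_r = r,
         profile_delta_resp = abs(resp_p[cand] - resp_p[[anchor]]),
         profile_delta_nonresp = abs(non_p[cand] - non_p[[anchor]]),
         entity_distance = if (length(cand))
           vapply(cand, function(g) embedding_distance(model, anchor, g,
                                                       "gene"), numeric(1))
         else numeric(0))
  })
  names(per_anchor) <- spec$anchor_gene_ids
  union_cand <- sort(unique(unlist(lapply(per_anchor, `[[`, "candidates"))))
  structure(list(anchors = per_anchor,
                 union_candidates = union_cand,
                 union_candidate_count = length(union_cand),
                 threshold = spec$threshold,
                 include_biases = include_biases),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate_report (threshold %g):\n", x$threshold))
  for (a in x$anchors) {
    cat(sprintf("  %s: %d responder-exclusive, %d entity neighbors, %d candidates\n",
                a$anchor, length(a$responder_exclusive_neighbors),
                length(a$entity_neighbors), length(a$candidates)))
  }
  cat(sprintf("  union over anchors: %d candidate gene(s)\n",
              x$union_candidate_count))
  invisible(x)
}

#' Flatten a candidate report to a data.frame
#'
#' @param x a `candidate_report`.
#' @param ... unused.
#' @return data.frame with columns anchor, candidate, profile_delta_resp,
#'   profile_delta_nonresp, entity_distance, pearson_r.
#' @export
as.data.frame.candidate_report <- function(x, ...) {
  rows <- lapply(x$anchors, function(a) {
    if (!length(a$candidates)) return(NULL)
    data.frame(anchor = a$anchor, candidate = a$candidates,
               profile_delta_resp = unname(a$profile_delta_resp),
               profile_delta_nonresp = unname(a$profile_delta_nonresp),
               entity_distance = unname(a$entity_distance),
               pearson_r = unname(a$pearson_r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(anchor = character(0), candidate = character(0),
                      profile_delta_resp = numeric(0),
                      profile_delta_nonresp = numeric(0),
                      entity_distance = numeric(0), pearson_r = numeric(0))
  }
  rownames(out) <- NULL
  out
}
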