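# Independent reference implementations used as oracles. These are kept
# deliberately naive (loops, exhaustive sums) and separate from the package
# code paths they check.

# build a gene_embedding directly from given parameters
toy_model <- function(G, S, b_gene = rep(0, nrow(G)),
                      b_sample = rep(0, nrow(S)),
                      gene_ids = sprintf("g%02d", seq_len(nrow(G))),
                      sample_ids = sprintf("s%02d", seq_len(nrow(S)))) {
  rownames(G) <- gene_ids
  rownames(S) <- sample_ids
  names(b_gene) <- gene_ids
  names(b_sample) <- sample_ids
  as_embedding(list(G = G, S = S, b_gene = b_gene, b_sample = b_sample,
                    config = list(seed = 1L)))
}

random_model <- function(k, n, m, seed = 1) {
  set.seed(seed)
  toy_model(matrix(rnorm(k * m), k, m), matrix(rnorm(n * m), n, m),
            rnorm(k), rnorm(n))
}

# double-loop prediction: dot(G_a, S_i) + b_a + b_i, one cell at a time
loop_predict <- function(model) {
  n <- length(model$sample_ids)
  k <- length(model$gene_ids)
  out <- matrix(NA_real_, n, k,
                dimnames = list(model$sample_ids, model$gene_ids))
  for (i in seq_len(n)) {
    for (a in seq_len(k)) {
      acc <- 0
      for (t in seq_len(model$dim)) acc <- acc + model$G[a, t] * model$S[i, t]
      out[i, a] <- acc + model$b_gene[[a]] + model$b_sample[[i]]
    }
  }
  out
}

# hypergeometric upper tail P(X >= ov) by exhaustive summation of the
# probability mass over all attainable overlap counts
hyper_tail_enum <- function(ov, universe, set_size, list_size) {
  js <- max(ov, 0):min(set_size, list_size)
  if (!length(js) || ov > min(set_size, list_size)) return(0)
  sum(choose(set_size, js) * choose(universe - set_size, list_size - js)) /
    choose(universe, list_size)
}

# Benjamini-Hochberg step-up: q_i = min_{j >= i} p_(j) * T / j, clipped to 1
bh_bruteforce <- function(p) {
  T_ <- length(p)
  ord <- order(p)
  q_sorted <- numeric(T_)
  for (i in seq_len(T_)) {
    cands <- vapply(i:T_, function(j) p[ord[j]] * T_ / j, 0)
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(T_)
  q[ord] <- q_sorted
  q
}

# naive O(n^3) UPGMA on the Euclidean distances of a point matrix; returns
# merge heights (ascending) and the cophenetic distance matrix
naive_upgma <- function(points) {
  n <- nrow(points)
  D <- as.matrix(dist(points))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    for (i in clusters[[best[1]]]) {
      for (j in clusters[[best[2]]]) coph[i, j] <- coph[j, i] <- best_d
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# brute-force close-neighbor filter over all pairwise distances
brute_neighbors <- function(model, anchor, threshold, space = "gene") {
  V <- entity_vectors(model, space)
  ids <- rownames(V)
  d <- vapply(ids, function(id) sqrt(sum((V[id, ] - V[anchor, ])^2)), 0)
  keep <- ids[d < threshold & ids != anchor]
  keep[order(d[keep], keep)]
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# hand-built 8-gene, 6-sample fixture planted so that exactly one gene is
# responder-exclusive-close AND entity-close to the anchor:
#   anchor g1 at origin (dim 2); responder samples along +e1, non-responders
#   along +e2; gene coordinates chosen so the three filters differ.
toy_discovery_fixture <- function() {
  # responder centroid (1, 0): responder profile = first coordinate;
  # non-responder centroid (0, 10): non-responder profile = 10 x second
  # coordinate, so a gene can sit within 0.1 of the anchor in entity space
  # yet more than 0.1 away in the non-responder profile
  G <- rbind(g1 = c(0.00, 0.000), # anchor
             g2 = c(0.05, 0.030), # entity-close, resp-close, non-far -> HIT
             g3 = c(0.05, 0.002), # entity-close but close in BOTH profiles
             g4 = c(0.02, 0.250), # resp-exclusive but entity-far
             g5 = c(3.00, 0.001), # resp-far
             g6 = c(3.00, 3.000), # far everywhere
             g7 = c(0.08, 0.005), # entity-close, close in both profiles
             g8 = c(0.09, 0.500)) # resp-exclusive, entity-far
  S <- rbind(r1 = c(1, 0), r2 = c(1, 0), r3 = c(1, 0),
             n1 = c(0, 10), n2 = c(0, 10), n3 = c(0, 10))
  model <- toy_model(G = G, S = S, gene_ids = rownames(G),
                     sample_ids = rownames(S))
  vals <- predict(model)
  vals <- vals - min(vals)
  expr <- expr_matrix(vals, is_log2 = TRUE)
  spec <- group_spec(c("r1", "r2", "r3"), c("n1", "n2", "n3"), "g1",
                     threshold = 0.1)
  list(model = model, expr = expr, spec = spec)
}
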