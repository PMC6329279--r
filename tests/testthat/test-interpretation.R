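test_that("group-dimension matrix rows are per-group sample-vector means", {
  r <- random_model(k = 5, n = 9, m = 4, seed = 21)
  ann <- sample_annotations(r$sample_ids,
                            rep(c("A", "B", "C"), each = 3))
  dgm <- group_dimension_matrix(r, ann)
  expect_equal(rownames(dgm), c("A", "B", "C"))
  for (g in c("A", "B", "C")) {
    ids <- ann$sample_id[ann$group_label == g]
    acc <- rep(0, 4)
    for (id in ids) acc <- acc + r$S[id, ]
    expect_equal(unname(dgm[g, ]), unname(acc / 3))
  }
  one <- group_dimension_matrix(r, sample_annotations(r$sample_ids,
                                                      rep("ALL", 9)))
  expect_equal(unname(one[1, ]), unname(colMeans(r$S)))
  expect_warning(
    group_dimension_matrix(r, sample_annotations(c(r$sample_ids, "ghost"),
                                                 rep("A", 10))),
    "ghost")
})

test_that("hot dimensions rank standardized group-vs-rest contrasts", {
  # two groups differing only in dimension 3
  dgm <- rbind(A = c(0, 0, 5, 0), B = c(0, 0, 0, 0))
  expect_equal(hot_dimensions(dgm, "A", 1)$dimension, 3L)
  # identical centroids -> all scores 0, stable order by index
  same <- rbind(A = c(1, 2), B = c(1, 2), C = c(1, 2))
  hd <- hot_dimensions(same, "B", 2)
  expect_equal(hd$score, c(0, 0))
  expect_equal(hd$dimension, c(1L, 2L))
  # 4-group random matrix vs brute-force score computation
  set.seed(33)
  dgm4 <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(c("W", "X", "Y", "Z"), NULL))
  got <- hot_dimensions(dgm4, "Y", 6)
  for (d in seq_len(6)) {
    manual <- (dgm4["Y", d] - mean(dgm4[c("W", "X", "Z"), d])) /
      sd(dgm4[, d])
    expect_equal(got$score[got$dimension == d], unname(manual))
  }
  expect_true(all(diff(abs(got$score)) <= 1e-12))  # decreasing |score|
  expect_error(hot_dimensions(dgm["A", , drop = FALSE], "A", 1),
               "at least 2 groups")
})

test_that("top genes per dimension follow the chosen ranking statistic", {
  G <- rbind(c(0, 10), c(0, -3), c(0, 2), c(0, -12))
  m <- toy_model(G = G, S = matrix(0, 2, 2))
  expect_equal(top_genes_by_dimension(m, 2, 1, "positive"), "g01")
  expect_equal(top_genes_by_dimension(m, 2, 1, "negative"), "g04")
  expect_equal(top_genes_by_dimension(m, 2, 2, "absolute"), c("g04", "g01"))
  expect_setequal(top_genes_by_dimension(m, 1, 4), m$gene_ids)
  # random model against a full-sort oracle
  r <- random_model(k = 40, n = 3, m = 5, seed = 14)
  ids <- r$gene_ids
  expect_equal(top_genes_by_dimension(r, 4, 10, "absolute"),
               ids[order(-abs(r$G[, 4]), ids)][1:10])
  expect_equal(top_genes_by_dimension(r, 2, 7, "positive"),
               ids[order(-r$G[, 2], ids)][1:7])
  expect_error(top_genes_by_dimension(r, 9, 5), "out of range")
  expect_error(top_genes_by_dimension(r, 1, 99), "exceeds")
})

test_that("enrichment p-values equal exhaustive hypergeometric tails", {
  universe <- sprintf("u%02d", 1:40)
  sets <- list(SET = universe[1:10])
  # sweep every attainable overlap for list size 8, set size 10, universe 40
  for (ov in 0:8) {
    gl <- c(universe[seq_len(ov)], universe[11:(11 + (8 - ov - 1))])
    if (ov == 8) gl <- universe[1:8]
    res <- fisher_enrichment(gl, sets, universe)
    expect_equal(res$p_value, hyper_tail_enum(ov, 40, 10, 8),
                 tolerance = 1e-12)
    expect_equal(res$overlap, ov)
  }
  # random tables with universe <= 60
  set.seed(41)
  for (rep in 1:20) {
    U <- sample(10:60, 1)
    uni <- sprintf("x%03d", seq_len(U))
    K <- sample(seq_len(U), 1)
    L <- sample(seq_len(U), 1)
    s <- list(S1 = sample(uni, K))
    gl <- sample(uni, L)
    res <- fisher_enrichment(gl, s, uni)
    expect_equal(res$p_value,
                 hyper_tail_enum(length(intersect(s$S1, gl)), U, K, L),
                 tolerance = 1e-12)
  }
})

test_that("enrichment edge cases and BH correction behave as stated", {
  universe <- sprintf("u%02d", 1:30)
  sets <- list(A = universe[1:5], B = universe[3:12], C = universe[20:29])
  # list = universe -> every overlap is the whole set, p = 1 everywhere
  res <- fisher_enrichment(universe, sets, universe)
  expect_equal(res$overlap, res$set_size)
  expect_equal(res$p_value, rep(1, 3))
  # worked BH case: p = (0.01, 0.02, 0.03, 0.04) -> all FDR 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(bh_bruteforce(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # implementation FDRs equal the brute-force step-up on real output
  set.seed(52)
  many <- lapply(1:8, function(i) sample(universe, sample(3:12, 1)))
  names(many) <- paste0("T", 1:8)
  gl <- sample(universe, 10)
  out <- fisher_enrichment(gl, many, universe)
  expect_equal(out$fdr, bh_bruteforce(out$p_value))
  # FDRs are monotone in sorted-p order and bounded by [p, 1]
  expect_true(all(diff(out$fdr[order(out$p_value)]) >= -1e-15))
  expect_true(all(out$fdr >= out$p_value - 1e-15 & out$fdr <= 1))
  expect_equal(out$significant, out$p_value < 0.01 & out$fdr < 0.05)
  # invariance to ordering of sets and genes
  out2 <- fisher_enrichment(rev(gl), rev(many), sample(universe))
  expect_equal(out, out2)
  expect_error(fisher_enrichment(character(0), sets, universe), "empty")
  expect_warning(fisher_enrichment(universe[1:3],
                                   list(A = universe[1:4], Z = "absent"),
                                   universe),
                 "skipped: Z")
})

test_that("GMT collections round-trip through the writer and reader", {
  sets <- list(M1 = c("a", "b", "c"), M2 = c("d", "e"))
  attr(sets, "descriptions") <- c(M1 = "first", M2 = "second")
  p <- tempfile(fileext = ".gmt")
  write_gmt(sets, p)
  back <- read_gmt(p)
  expect_equal(back[["M1"]], sets[["M1"]])
  expect_equal(back[["M2"]], sets[["M2"]])
  expect_equal(attr(back, "descriptions"),
               c(M1 = "first", M2 = "second"))
  expect_error(read_gmt(write_tsv_fixture("only\ttwo")), "fewer than 3")
})

test_that("signature dimensions are the argmax of absolute coordinates", {
  G <- rbind(c(0.1, -3, 0.2), c(2, -2, 0), c(0, 0, 0))
  m <- toy_model(G = G, S = matrix(0, 2, 3))
  expect_equal(select_signature_dimensions(m, "g01"), c(g01 = 2L))
  # tie |2| vs |-2| resolves to the lower index
  expect_equal(select_signature_dimensions(m, "g02"), c(g02 = 1L))
  expect_warning(zero <- select_signature_dimensions(m, "g03"),
                 "all-zero")
  expect_equal(zero, c(g03 = 1L))
  r <- random_model(k = 25, n = 2, m = 7, seed = 17)
  got <- select_signature_dimensions(m = r, r$gene_ids)
  for (g in r$gene_ids) {
    best <- 1L
    for (d in 2:7) if (abs(r$G[g, d]) > abs(r$G[g, best])) best <- d
    expect_equal(unname(got[g]), best)
  }
  expect_error(select_signature_dimensions(r, "nope"), "unknown genes")
})

test_that("the SD filter keeps dimensions with above-average spread", {
  flat <- matrix(rep(c(1, 2, 3), 4), 3, 4)  # equal sd everywhere
  expect_length(dimension_sd_filter(flat), 0L)
  one_hot <- cbind(c(0, 0, 0), c(0, 0, 0), c(-5, 0, 5))
  expect_equal(dimension_sd_filter(one_hot), 3L)
  set.seed(19)
  X <- matrix(rnorm(8 * 6), 8, 6)
  sds <- numeric(6)
  for (d in 1:6) sds[d] <- sd(X[, d])
  expect_equal(dimension_sd_filter(X), which(sds > mean(sds)))
  expect_error(dimension_sd_filter(X[1, , drop = FALSE]), "at least 2")
})

test_that("UPGMA merges match hand computation and the naive oracle", {
  # 1-D points {0, 1, 10}: merge {0,1} at height 1, then at mean(10, 9) = 9.5
  res <- upgma_cluster(matrix(c(0, 1, 10), 3, 1), 2)
  expect_equal(sort(res$heights), c(1, 9.5))
  expect_equal(unname(res$labels), c(1L, 1L, 2L))
  # duplicated points merge first at height 0
  dup <- upgma_cluster(rbind(c(5, 5), c(0, 0), c(5, 5)), 2)
  expect_equal(min(dup$heights), 0)
  expect_equal(dup$labels[1], dup$labels[3])
  # n_clusters = item count -> singletons
  sing <- upgma_cluster(matrix(rnorm(8), 4, 2), 4)
  expect_equal(sort(unique(unname(sing$labels))), 1:4)
  expect_error(upgma_cluster(matrix(rnorm(8), 4, 2), 0), "n_clusters")

  set.seed(23)
  for (rep in 1:50) {
    pts <- matrix(rnorm(6 * 3), 6, 3)
    got <- upgma_cluster(pts, 1)
    ref <- naive_upgma(pts)
    expect_equal(sort(got$heights), sort(ref$heights), tolerance = 1e-9)
    expect_equal(as.matrix(stats::cophenetic(got$tree)),
                 ref$cophenetic, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("dimension enrichment recovers a planted module", {
  sc <- make_responder_scenario(synth_config(seed = 5))
  model <- as_embedding(sc$truth)
  act_dim <- model$dim  # the planted module loads on the last dimension
  top <- top_genes_by_dimension(model, act_dim,
                                length(sc$truth$module_gene_ids))
  sets <- make_gmt(sc$truth)
  res <- fisher_enrichment(top, sets, model$gene_ids)
  row <- res[res$term_id == "MODULE_1", ]
  expect_true(row$significant)
  expect_gt(row$overlap, 0.8 * length(sc$truth$module_gene_ids))
  expect_false(res$significant[res$term_id == "MODULE_2"])
})

test_that("subtype workflow clusters samples on signature dimensions", {
  sim <- simulate_expression(synth_config(n_samples = 40, k_genes = 60,
                                          latent_rank = 4, n_groups = 2,
                                          group_separation = 4,
                                          modules = list(), seed = 9))
  model <- as_embedding(sim$truth)
  st <- molecular_subtype(model, model$gene_ids[1:3], 2)
  expect_length(st$labels, 40L)
  expect_equal(sort(unique(unname(st$labels))), 1:2)
  expect_length(st$dimensions, 3L)
})
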