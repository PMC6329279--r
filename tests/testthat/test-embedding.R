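small_log2_expr <- function(n, k, seed = 1, noise_sd = 0, rank = 3) {
  sim <- simulate_expression(synth_config(
    n_samples = n, k_genes = k, latent_rank = rank, n_groups = 2,
    modules = list(), noise_sd = noise_sd, seed = seed))
  sim$expr
}

test_that("initialization is uniform within bounds and seed-deterministic", {
  expr <- small_log2_expr(12, 15)
  a <- gene_embed(expr, dim = 4, epochs = 0, seed = 1)
  b <- gene_embed(expr, dim = 4, epochs = 0, seed = 1)
  expect_identical(coef(a), coef(b))
  expect_equal(dim(a$G), c(15L, 4L))
  expect_equal(dim(a$S), c(12L, 4L))
  pars <- c(a$G, a$S, a$b_gene, a$b_sample)
  expect_true(all(abs(pars) <= 0.05))
  expect_gt(max(abs(pars)), 0.03)  # actually random, not all zero
  c_ <- gene_embed(expr, dim = 4, epochs = 0, seed = 2)
  expect_false(identical(a$G, c_$G))
  expect_equal(nrow(a$history), 0L)
})

test_that("single-cell prediction follows the dot-product-plus-biases rule", {
  m <- toy_model(G = matrix(c(1, 2), 1, 2), S = matrix(c(3, 4), 1, 2),
                 b_gene = 0.5, b_sample = -0.5)
  expect_equal(predict_cell(m, 1, 1), 1 * 3 + 2 * 4 + 0.5 - 0.5)
  z <- toy_model(G = matrix(0, 1, 2), S = matrix(0, 1, 2),
                 b_gene = 2, b_sample = 3)
  expect_equal(predict_cell(z, "s01", "g01"), 5)
  expect_error(predict_cell(m, 1, 99), "out of range")
  expect_error(predict_cell(m, "nope", 1), "unknown sample")
})

test_that("matrix prediction equals the per-cell double-loop oracle", {
  m <- random_model(k = 8, n = 10, m = 5, seed = 42)
  expect_lt(max(abs(predict(m) - loop_predict(m))), 1e-12)
  # rank-1 special case: outer product when biases vanish
  r1 <- toy_model(G = matrix(1:4, 4, 1), S = matrix(c(2, 3), 2, 1))
  expect_equal(unname(predict(r1)), outer(c(2, 3), 1:4))
})

test_that("model MSE matches closed forms and the loop oracle", {
  m <- random_model(k = 6, n = 5, m = 3, seed = 3)
  m$b_gene <- m$b_gene + 20  # keep predictions on a valid log2 scale
  # model predicting expr exactly -> 0
  perfect <- expr_matrix(predict(m), is_log2 = TRUE)
  expect_equal(embedding_mse(m, perfect), 0, tolerance = 1e-24)
  # constant offset delta on every prediction -> delta^2
  delta <- 0.7
  off <- m
  off$b_sample <- off$b_sample + delta
  expect_equal(embedding_mse(off, perfect), delta^2)
  # random case equals the brute-force two-loop computation
  set.seed(9)
  obs <- expr_matrix(matrix(runif(30, 0, 8), 5, 6,
                            dimnames = list(m$sample_ids, m$gene_ids)),
                     is_log2 = TRUE)
  expect_equal(embedding_mse(m, obs), mean((obs$values - loop_predict(m))^2))
  bad <- expr_matrix(matrix(1, 2, 2, dimnames = list(c("x", "y"),
                                                     c("u", "v"))),
                     is_log2 = TRUE)
  expect_error(embedding_mse(m, bad), "do not match")
})

test_that("analytic batch gradients match central finite differences", {
  model <- random_model(k = 5, n = 4, m = 3, seed = 11)
  set.seed(12)
  cells <- data.frame(sample = sample(4, 10, TRUE),
                      gene = sample(5, 10, TRUE),
                      value = runif(10, 0, 6))
  gr <- embedding_gradient(model, cells)
  batch_mse <- function(mod) {
    mean(vapply(seq_len(nrow(cells)), function(j)
      (predict_cell(mod, cells$sample[j], cells$gene[j]) - cells$value[j])^2,
      0))
  }
  h <- 1e-6
  check <- function(analytic, get, set) {
    for (idx in seq_along(analytic)) {
      up <- set(model, idx, get(model, idx) + h)
      dn <- set(model, idx, get(model, idx) - h)
      fd <- (batch_mse(up) - batch_mse(dn)) / (2 * h)
      denom <- max(abs(fd), abs(analytic[idx]), 1e-8)
      expect_lt(abs(fd - analytic[idx]) / denom, 1e-5)
    }
  }
  check(as.vector(gr$gG),
        function(m, i) m$G[i], function(m, i, v) { m$G[i] <- v; m })
  check(as.vector(gr$gS),
        function(m, i) m$S[i], function(m, i, v) { m$S[i] <- v; m })
  check(gr$gbg,
        function(m, i) m$b_gene[i], function(m, i, v) { m$b_gene[i] <- v; m })
  check(gr$gbs,
        function(m, i) m$b_sample[i],
        function(m, i, v) { m$b_sample[i] <- v; m })
})

test_that("training fits noiseless low-rank data and is seed-deterministic", {
  expr <- small_log2_expr(60, 80, seed = 5, noise_sd = 0, rank = 3)
  init <- gene_embed(expr, dim = 3, epochs = 0, seed = 21,
                     validation_fraction = 0)
  initial_mse <- embedding_mse(init, expr)
  fit <- gene_embed(expr, dim = 3, learning_rate = 0.02, epochs = 60,
                    seed = 21, validation_fraction = 0.1)
  expect_lt(tail(fit$history$train_mse, 1), 0.01 * initial_mse)
  # held-out cells are recovered when m >= true rank (noiseless floor)
  expect_lt(tail(fit$history$val_mse, 1), 0.01)
  fit2 <- gene_embed(expr, dim = 3, learning_rate = 0.02, epochs = 60,
                     seed = 21, validation_fraction = 0.1)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$history, fit2$history)
})

test_that("an additive constant is absorbed by the bias terms", {
  expr <- small_log2_expr(50, 60, seed = 6, noise_sd = 0.1)
  shifted <- expr
  shifted$values <- expr$values + 3
  f1 <- gene_embed(expr, dim = 5, learning_rate = 0.02, epochs = 60,
                   seed = 31)
  f2 <- gene_embed(shifted, dim = 5, learning_rate = 0.02, epochs = 60,
                   seed = 31)
  l1 <- tail(f1$history$train_mse, 1)
  l2 <- tail(f2$history$train_mse, 1)
  expect_lt(abs(l1 - l2) / l1, 0.10)
})

test_that("gene and sample roles are exchangeable under transposition", {
  expr <- small_log2_expr(6, 9, seed = 8, noise_sd = 0.05)
  n <- 6L; k <- 9L; N <- n * k
  texpr <- expr_matrix(t(expr$values), is_log2 = TRUE)
  set.seed(77)
  G0 <- matrix(runif(k * 4, -0.05, 0.05), k, 4)
  S0 <- matrix(runif(n * 4, -0.05, 0.05), n, 4)
  bg0 <- runif(k, -0.05, 0.05); bs0 <- runif(n, -0.05, 0.05)
  pairs <- expand.grid(i = seq_len(n), a = seq_len(k))
  hold_rows <- sample(N, 5)
  cell_fwd <- (pairs$a - 1L) * n + pairs$i        # index into n x k matrix
  cell_rev <- (pairs$i - 1L) * k + pairs$a        # same cell, transposed
  train_rows <- setdiff(seq_len(N), hold_rows)
  visit <- sample(train_rows)                      # physical visit order
  orders_fwd <- list(match(cell_fwd[visit], sort(cell_fwd[train_rows])),
                     match(cell_fwd[rev(visit)], sort(cell_fwd[train_rows])))
  orders_rev <- list(match(cell_rev[visit], sort(cell_rev[train_rows])),
                     match(cell_rev[rev(visit)], sort(cell_rev[train_rows])))
  f <- gene_embed(expr, dim = 4, learning_rate = 0.05, epochs = 2,
                  batch_size = 7, seed = 1,
                  init = list(G = G0, S = S0, b_gene = bg0, b_sample = bs0),
                  holdout = sort(cell_fwd[hold_rows]),
                  epoch_orders = orders_fwd)
  g <- gene_embed(texpr, dim = 4, learning_rate = 0.05, epochs = 2,
                  batch_size = 7, seed = 1,
                  init = list(G = S0, S = G0, b_gene = bs0, b_sample = bg0),
                  holdout = sort(cell_rev[hold_rows]),
                  epoch_orders = orders_rev)
  expect_equal(f$history$train_mse, g$history$train_mse, tolerance = 0)
  expect_equal(f$history$val_mse, g$history$val_mse, tolerance = 0)
  expect_equal(unname(f$G), unname(g$S), tolerance = 0)
  expect_equal(unname(f$b_sample), unname(g$b_gene), tolerance = 0)
})

test_that("zero-epoch fits equal the initialization and methods behave", {
  expr <- small_log2_expr(10, 12)
  fit <- gene_embed(expr, dim = 3, epochs = 0, seed = 5)
  expect_equal(nrow(fit$history), 0L)
  expect_output(print(fit), "untrained")
  r <- residuals(fit)
  expect_equal(r, expr$values - predict(fit))
  sims <- simulate(fit, nsim = 2, seed = 3, noise_sd = 0.05)
  expect_length(sims, 2L)
  expect_true(all(sims[[1]]$values >= 0))
  s <- summary(fit)
  expect_output(print(s), "m = 3")
})

test_that("a runaway learning rate raises a diagnosable error", {
  expr <- small_log2_expr(20, 25, seed = 2, noise_sd = 0.1)
  expect_error(gene_embed(expr, dim = 3, learning_rate = 1e150, epochs = 5,
                          seed = 1),
               "learning rate")
})

test_that("learning-rate finder sweeps geometrically and suggests a usable rate", {
  expr <- small_log2_expr(60, 80, seed = 5, noise_sd = 0, rank = 3)
  res <- lr_find(expr, dim = 3, lr_min = 1e-4, lr_max = 1, steps = 60,
                 seed = 9)
  expect_lte(nrow(res$curve), 60L)
  ratios <- res$curve$lr[-1] / res$curve$lr[-nrow(res$curve)]
  expect_true(all(abs(ratios - ratios[1]) < 1e-8))
  expect_true(all(diff(res$curve$lr) > 0))
  fit_sugg <- gene_embed(expr, dim = 3, learning_rate = res$suggested_lr,
                         epochs = 20, seed = 13)
  loss_sugg <- tail(fit_sugg$history$train_mse, 1)
  loss_max <- tryCatch({
    fit_max <- gene_embed(expr, dim = 3, learning_rate = 1, epochs = 20,
                          seed = 13)
    tail(fit_max$history$train_mse, 1)
  }, error = function(e) Inf)
  expect_lt(loss_sugg, loss_max)
})
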