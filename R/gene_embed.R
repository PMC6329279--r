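#' Fit a gene/sample embedding by biased matrix factorization
#'
#' Learns an m-dimensional entity vector for every gene and every sample of
#' a log2 expression matrix, plus per-gene and per-sample biases, under the
#' collaborative-filtering model
#' \deqn{\hat{G}_{ai} = G_a \cdot S_i^T + b_a + b_i}
#' fitted by mini-batch Adam on the mean squared error between predicted and
#' observed expression. Training examples are individual
#' (sample, gene, value) cells; each epoch reshuffles all cells with the
#' seeded generator and consumes them in mini-batches. All weights are
#' initialized uniformly at random in `[-init_half_range, init_half_range]`.
#'
#' @param expr an [expr_matrix] with `is_log2 = TRUE` (samples x genes).
#' @param dim embedding dimension m (default 50).
#' @param learning_rate Adam step size; see [lr_find()] for a data-driven
#'   suggestion.
#' @param batch_size mini-batch size (default 64).
#' @param epochs number of passes over the training cells (default 3).
#'   `epochs = 0` returns the untouched random initialization.
#' @param init_half_range half-width of the uniform initialization interval
#'   (default 0.05).
#' @param seed integer seed governing initialization, the validation split
#'   and the per-epoch shuffles.
#' @param validation_fraction fraction of cells (in `[0, 0.5)`) held out of
#'   training and scored after every epoch.
#' @param adam_beta1,adam_beta2,adam_epsilon Adam moment decay rates and
#'   numerical-stability constant.
#' @param weight_decay L2 penalty coefficient added to every gradient
#'   (default 0: no regularization).
#' @param keep_data keep a reference to `expr` on the fitted object (used by
#'   [residuals.gene_embedding()]); default `TRUE`.
#' @param init optional list with elements `G` (k x m), `S` (n x m),
#'   `b_gene`, `b_sample` overriding the random initialization.
#' @param holdout optional integer vector of cell indices (1-based, column
#'   major over the samples x genes matrix) to use as the validation set,
#'   overriding the seeded split.
#' @param epoch_orders optional list of `epochs` permutations of the
#'   training cells, overriding the seeded shuffles. Together with `init`
#'   and `holdout` this makes a run fully explicit, e.g. to verify that
#'   transposing the input and exchanging gene/sample roles reproduces the
#'   same loss trajectory.
#'
#' @return An object of class `gene_embedding`: a list with the gene entity
#'   matrix `G` (k x m), sample entity matrix `S` (n x m), bias vectors
#'   `b_gene` and `b_sample`, `dim`, the effective `config`, and a `history`
#'   data.frame of per-epoch training and validation MSE.
#' @seealso [predict.gene_embedding()], [close_neighbors()],
#'   [write_embedding()], [lr_find()]
#' @export
gene_embed <- function(expr, dim = 50L, learning_rate = 1e-2,
                       batch_size = 64L, epochs = 3L,
                       init_half_range = 0.05, seed = 1L,
                       validation_fraction = 0.1,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       adam_epsilon = 1e-8, weight_decay = 0,
                       keep_data = TRUE, init = NULL, holdout = NULL,
                       epoch_orders = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$is_log2) stop("expr must be log2-transformed (see preprocess_expression)")
  config <- validate_config(dim = dim, learning_rate = learning_rate,
                            batch_size = batch_size, epochs = epochs,
                            init_half_range = init_half_range, seed = seed,
                            validation_fraction = validation_fraction,
                            adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                            adam_epsilon = adam_epsilon,
                            weight_decay = weight_decay)
  X <- expr$values
  n <- nrow(X); k <- ncol(X)
  if (n == 0L || k == 0L) stop("expression matrix is empty")
  m <- as.integer(dim)

  run <- local_rng(seed, {
    par <- if (is.null(init)) draw_init(k, n, m, init_half_range) else check_init(init, k, n, m)
    N <- n * k
    if (is.null(holdout)) {
      n_val <- floor(validation_fraction * N)
      holdout <- if (n_val > 0L) sort(sample.int(N, n_val)) else integer(0)
    } else {
      holdout <- as.integer(holdout)
      stopifnot(all(holdout >= 1L), all(holdout <= N), !anyDuplicated(holdout))
    }
    train_cells <- if (length(holdout)) seq_len(N)[-holdout] else seq_len(N)
    if (is.null(epoch_orders)) {
      epoch_orders <- lapply(seq_len(epochs),
                             function(e) sample.int(length(train_cells)))
    } else {
      stopifnot(length(epoch_orders) == epochs)
    }
    list(par = par, holdout = holdout, train_cells = train_cells,
         epoch_orders = epoch_orders)
  })

  par <- run$par
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  if (epochs > 0L) {
    tr <- run$train_cells
    # 0-based (sample, gene) coordinates of column-major cell indices
    tr_s <- (tr - 1L) %% n
    tr_g <- (tr - 1L) %/% n
    vl <- run$holdout
    vl_s <- (vl - 1L) %% n
    vl_g <- (vl - 1L) %/% n
    fit <- cf_train(par$G, par$S, par$b_gene, par$b_sample,
                    tr_s, tr_g, X[tr],
                    vl_s, vl_g, X[vl],
                    lapply(run$epoch_orders, function(o) as.integer(o) - 1L),
                    as.integer(batch_size), learning_rate,
                    adam_beta1, adam_beta2, adam_epsilon, weight_decay)
    par <- list(G = fit$G, S = fit$S, b_gene = fit$b_gene,
                b_sample = fit$b_sample)
    history <- data.frame(epoch = seq_len(epochs),
                          train_mse = fit$train_mse, val_mse = fit$val_mse)
  }

  dimnames(par$G) <- list(colnames(X), paste0("d", seq_len(m)))
  dimnames(par$S) <- list(rownames(X), paste0("d", seq_len(m)))
  names(par$b_gene) <- colnames(X)
  names(par$b_sample) <- rownames(X)
  if (any(!is.finite(par$G)) || any(!is.finite(par$S)) ||
      any(!is.finite(par$b_gene)) || any(!is.finite(par$b_sample))) {
    stop("fitted parameters are non-finite; lower the learning rate")
  }

  structure(list(gene_ids = colnames(X), sample_ids = rownames(X),
                 G = par$G, S = par$S, b_gene = par$b_gene,
                 b_sample = par$b_sample, dim = m, config = config,
                 history = history,
                 data = if (keep_data) expr else NULL,
                 call = match.call()),
            class = "gene_embedding")
}

validate_config <- function(dim, learning_rate, batch_size, epochs,
                            init_half_range, seed, validation_fraction,
                            adam_beta1, adam_beta2, adam_epsilon,
                            weight_decay) {
  stopifnot(dim >= 1L, batch_size >= 1L, epochs >= 0L,
            init_half_range > 0, learning_rate > 0,
            validation_fraction >= 0, validation_fraction < 0.5,
            adam_beta1 >= 0, adam_beta1 < 1, adam_beta2 >= 0, adam_beta2 < 1,
            adam_epsilon > 0, weight_decay >= 0)
  list(dim = as.integer(dim), learning_rate = learning_rate,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       init_half_range = init_half_range, seed = as.integer(seed),
       validation_fraction = validation_fraction, adam_beta1 = adam_beta1,
       adam_beta2 = adam_beta2, adam_epsilon = adam_epsilon,
       weight_decay = weight_decay)
}

draw_init <- function(k, n, m, h) {
  list(G = matrix(stats::runif(k * m, -h, h), k, m),
       S = matrix(stats::runif(n * m, -h, h), n, m),
       b_gene = stats::runif(k, -h, h),
       b_sample = stats::runif(n, -h, h))
}

check_init <- function(init, k, n, m) {
  stopifnot(is.list(init),
            all(c("G", "S", "b_gene", "b_sample") %in% names(init)),
            nrow(init$G) == k, ncol(init$G) == m,
            nrow(init$S) == n, ncol(init$S) == m,
            length(init$b_gene) == k, length(init$b_sample) == n)
  init[c("G", "S", "b_gene", "b_sample")]
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.gene_embedding <- function(x, ...) {
  cat(sprintf("gene_embedding: %d genes, %d samples, dimension %d\n",
              length(x$gene_ids), length(x$sample_ids), x$dim))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  epochs run: %d  final train MSE: %.4g  validation MSE: %.4g\n",
                nrow(x$history), last$train_mse, last$val_mse))
  } else {
    cat("  untrained (random initialization)\n")
  }
  invisible(x)
}

#' @export
summary.gene_embedding <- function(object, ...) {
  out <- list(n_genes = length(object$gene_ids),
              n_samples = length(object$sample_ids),
              dim = object$dim, config = object$config,
              history = object$history)
  class(out) <- "summary.gene_embedding"
  out
}

#' @export
print.summary.gene_embedding <- function(x, ...) {
  cat(sprintf("Biased matrix factorization embedding\n"))
  cat(sprintf("  %d genes x %d samples, m = %d\n", x$n_genes, x$n_samples,
              x$dim))
  cat(sprintf("  Adam lr %.3g, batch %d, %d epoch(s), seed %d\n",
              x$config$learning_rate, x$config$batch_size, x$config$epochs,
              x$config$seed))
  if (nrow(x$history)) {
    cat("  loss history (MSE):\n")
    print(x$history, row.names = FALSE)
  }
  invisible(x)
}

#' Extract embedding parameters
#'
#' @param object a fitted `gene_embedding`.
#' @param ... unused.
#' @return List with `G`, `S`, `b_gene`, `b_sample`.
#' @export
coef.gene_embedding <- function(object, ...) {
  object[c("G", "S", "b_gene", "b_sample")]
}

#' Predicted expression matrix
#'
#' Reconstructs predicted log2 expression for every (sample, gene) pair:
#' `S %*% t(G)` plus the bias outer sum.
#'
#' @param object a `gene_embedding`.
#' @param samples,genes optional subsets of ids (or indices).
#' @param ... unused.
#' @return numeric matrix, samples x genes.
#' @export
predict.gene_embedding <- function(object, samples = NULL, genes = NULL, ...) {
  S <- object$S; G <- object$G
  bs <- object$b_sample; bg <- object$b_gene
  if (!is.null(samples)) { S <- S[samples, , drop = FALSE]; bs <- bs[samples] }
  if (!is.null(genes)) { G <- G[genes, , drop = FALSE]; bg <- bg[genes] }
  tcrossprod(S, G) + outer(bs, bg, `+`)
}

#' @export
fitted.gene_embedding <- function(object, ...) predict(object)

#' Single-cell prediction
#'
#' `dot(G_a, S_i) + b_a + b_i` for one sample and one gene, addressed by id
#' or index.
#'
#' @param model a `gene_embedding`.
#' @param sample,gene id (character) or index (numeric).
#' @return scalar predicted log2 expression.
#' @export
predict_cell <- function(model, sample, gene) {
  i <- resolve_index(sample, model$sample_ids, "sample")
  a <- resolve_index(gene, model$gene_ids, "gene")
  sum(model$G[a, ] * model$S[i, ]) + model$b_gene[[a]] + model$b_sample[[i]]
}

resolve_index <- function(x, ids, what) {
  if (is.character(x)) {
    i <- match(x, ids)
    if (is.na(i)) stop("unknown ", what, " id: ", x)
    return(i)
  }
  i <- as.integer(x)
  if (is.na(i) || i < 1L || i > length(ids)) {
    stop(what, " index out of range: ", x)
  }
  i
}

#' Residuals of the embedding fit
#'
#' @param object a `gene_embedding` fitted with `keep_data = TRUE`, or
#'   supply `expr`.
#' @param expr an [expr_matrix] aligned with the model.
#' @param ... unused.
#' @return matrix of observed minus predicted values.
#' @export
residuals.gene_embedding <- function(object, expr = object$data, ...) {
  if (is.null(expr)) stop("no data stored; pass expr")
  check_alignment(object, expr)
  expr$values - predict(object)
}

#' Mean squared error of a model on an expression matrix
#'
#' Mean over all n x k cells of the squared difference between predicted
#' and observed expression.
#'
#' @param model a `gene_embedding`.
#' @param expr an [expr_matrix] with matching sample and gene ids.
#' @return scalar MSE.
#' @export
embedding_mse <- function(model, expr = model$data) {
  if (is.null(expr)) stop("no data stored; pass expr")
  check_alignment(model, expr)
  mean((expr$values - predict(model))^2)
}

check_alignment <- function(model, expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!identical(rownames(expr$values), model$sample_ids) ||
      !identical(colnames(expr$values), model$gene_ids)) {
    stop("expression matrix ids do not match the model")
  }
  invisible(TRUE)
}

#' Loss-history plot
#'
#' @param x a trained `gene_embedding`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gene_embedding <- function(x, ...) {
  if (!nrow(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", legend = c("training", "validation"),
                   pch = c(1, 2), lty = 1, col = 1:2)
  invisible(x)
}

#' Simulate expression from a fitted embedding
#'
#' Draws expression matrices from the model: predicted values plus i.i.d.
#' Gaussian noise, floored at 0 to stay on a valid log2 scale.
#'
#' @param object a `gene_embedding`.
#' @param nsim number of matrices.
#' @param seed integer seed.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param ... unused.
#' @return list of [expr_matrix] objects of length `nsim`.
#' @export
simulate.gene_embedding <- function(object, nsim = 1, seed = NULL,
                                    noise_sd = 0.1, ...) {
  mu <- predict(object)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(s) {
    v <- pmax(mu + stats::rnorm(length(mu), 0, noise_sd), 0)
    expr_matrix(matrix(v, nrow(mu), ncol(mu), dimnames = dimnames(mu)),
                is_log2 = TRUE)
  })
}

#' Batch gradient of the embedding loss
#'
#' Analytic gradient of the mean squared error of a set of
#' (sample, gene, value) cells with respect to all model parameters. This is
#' the same gradient the trainer applies; exposed so it can be verified
#' against finite differences.
#'
#' @param model a `gene_embedding`.
#' @param cells data.frame with columns `sample` (index or id), `gene`
#'   (index or id) and `value`.
#' @return list with `gG`, `gS`, `gbg`, `gbs` and the batch `mse`.
#' @export
embedding_gradient <- function(model, cells) {
  si <- vapply(cells$sample, resolve_index, 1L, ids = model$sample_ids,
               what = "sample")
  gi <- vapply(cells$gene, resolve_index, 1L, ids = model$gene_ids,
               what = "gene")
  cf_batch_gradient(model$G, model$S, model$b_gene, model$b_sample,
                    as.integer(si) - 1L, as.integer(gi) - 1L,
                    as.numeric(cells$value), model$config$weight_decay)
}

#' Learning-rate range finder
#'
#' Runs single Adam steps on successive mini-batches while the learning
#' rate grows geometrically from `lr_min` to `lr_max`, from a fresh seeded
#' initialization, and records the exponentially smoothed batch loss. The
#' suggested rate is one order of magnitude below the rate at the smoothed
#' loss minimum, read off a loss-versus-learning-rate curve.
#'
#' @param expr an [expr_matrix] with `is_log2 = TRUE`.
#' @param dim embedding dimension.
#' @param lr_min,lr_max range endpoints (`0 < lr_min < lr_max`).
#' @param steps maximum number of mini-batches.
#' @param batch_size mini-batch size.
#' @param seed integer seed for the initialization and shuffle.
#' @param init_half_range,adam_beta1,adam_beta2,adam_epsilon as in
#'   [gene_embed()].
#' @param smooth_beta smoothing factor of the loss EMA.
#' @return list with `curve` (data.frame of step, lr, loss, smoothed loss),
#'   `suggested_lr`, and `diverged` (TRUE when the sweep stopped early
#'   because the smoothed loss exploded).
#' @export
lr_find <- function(expr, dim = 50L, lr_min = 1e-5, lr_max = 1, steps = 100L,
                    batch_size = 64L, seed = 1L, init_half_range = 0.05,
                    adam_beta1 = 0.9, adam_beta2 = 0.999,
                    adam_epsilon = 1e-8, smooth_beta = 0.98) {
  stopifnot(inherits(expr, "expr_matrix"), expr$is_log2,
            lr_min > 0, lr_min < lr_max, steps >= 2L)
  X <- expr$values
  n <- nrow(X); k <- ncol(X); m <- as.integer(dim)
  run <- local_rng(seed, {
    par <- draw_init(k, n, m, init_half_range)
    ord <- sample.int(n * k)
    list(par = par, ord = ord)
  })
  par <- run$par
  ord <- run$ord
  N <- length(ord)
  rates <- lr_min * (lr_max / lr_min)^(seq(0, 1, length.out = steps))
  adam <- list(mG = par$G * 0, vG = par$G * 0, mS = par$S * 0, vS = par$S * 0,
               mbg = par$b_gene * 0, vbg = par$b_gene * 0,
               mbs = par$b_sample * 0, vbs = par$b_sample * 0)
  losses <- smoothed <- numeric(0)
  best <- Inf
  diverged <- FALSE
  ema <- 0
  for (t in seq_len(steps)) {
    lo <- ((t - 1L) * batch_size) %% N
    idx <- ord[(lo + seq_len(min(batch_size, N)) - 1L) %% N + 1L]
    si <- (idx - 1L) %% n
    gi <- (idx - 1L) %/% n
    gr <- cf_batch_gradient(par$G, par$S, par$b_gene, par$b_sample,
                            as.integer(si), as.integer(gi), X[idx], 0)
    losses[t] <- gr$mse
    ema <- smooth_beta * ema + (1 - smooth_beta) * gr$mse
    smoothed[t] <- ema / (1 - smooth_beta^t)
    if (!is.finite(smoothed[t]) || smoothed[t] > 4 * best) {
      diverged <- TRUE
      if (t < 10L) warning("loss diverged before 10 steps; curve truncated")
      break
    }
    best <- min(best, smoothed[t])
    step_adam <- function(p, g, mname, vname) {
      adam[[mname]] <<- adam_beta1 * adam[[mname]] + (1 - adam_beta1) * g
      adam[[vname]] <<- adam_beta2 * adam[[vname]] + (1 - adam_beta2) * g^2
      p - rates[t] * (adam[[mname]] / (1 - adam_beta1^t)) /
        (sqrt(adam[[vname]] / (1 - adam_beta2^t)) + adam_epsilon)
    }
    par$G <- step_adam(par$G, gr$gG, "mG", "vG")
    par$S <- step_adam(par$S, gr$gS, "mS", "vS")
    par$b_gene <- step_adam(par$b_gene, gr$gbg, "mbg", "vbg")
    par$b_sample <- step_adam(par$b_sample, gr$gbs, "mbs", "vbs")
  }
  ran <- seq_along(losses)
  curve <- data.frame(step = ran, lr = rates[ran], loss = losses,
                      smoothed = smoothed[ran])
  suggested <- curve$lr[which.min(curve$smoothed)] / 10
  list(curve = curve, suggested_lr = suggested, diverged = diverged)
}
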