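#' Configuration of the synthetic expression generator
#'
#' The generator draws a low-rank log2 expression matrix with planted
#' structure: sample vectors scattered around group centers (emulating
#' cancer types), gene vectors scattered around module centers (emulating
#' co-regulated gene modules) or i.i.d. for background genes, per-gene and
#' per-sample biases, and Gaussian noise on the log2 scale.
#'
#' @param n_samples,k_genes matrix size (default 200 x 500).
#' @param latent_rank true rank of the structure (default 5).
#' @param n_groups number of sample groups (default 4).
#' @param group_separation expected Euclidean distance between group
#'   centers in latent space (default 2).
#' @param modules list of planted modules, each `c(size, spread)`: number
#'   of member genes and the standard deviation of member vectors around
#'   the module center (default two modules of 30 genes, spread 0.1).
#' @param noise_sd cell-level Gaussian noise SD, log2 units (default 0.1).
#' @param bias_sd_gene,bias_sd_sample bias SDs (defaults 0.5, 0.2).
#' @param sample_jitter SD of sample vectors around their group center
#'   (default 0.3).
#' @param gene_sd per-coordinate SD of background gene vectors and module
#'   centers (default 0.5).
#' @param seed integer seed; all output is reproducible from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 200L, k_genes = 500L, latent_rank = 5L,
                         n_groups = 4L, group_separation = 2,
                         modules = list(c(30L, 0.1), c(30L, 0.1)),
                         noise_sd = 0.1, bias_sd_gene = 0.5,
                         bias_sd_sample = 0.2, sample_jitter = 0.3,
                         gene_sd = 0.5, seed = 1L) {
  stopifnot(n_samples >= 1L, k_genes >= 1L, latent_rank >= 1L,
            n_groups >= 1L, group_separation > 0, noise_sd >= 0,
            bias_sd_gene >= 0, bias_sd_sample >= 0, sample_jitter >= 0,
            gene_sd > 0)
  sizes <- vapply(modules, `[`, 0, 1L)
  if (sum(sizes) > k_genes) stop("module sizes exceed the number of genes")
  structure(list(n_samples = as.integer(n_samples),
                 k_genes = as.integer(k_genes),
                 latent_rank = as.integer(latent_rank),
                 n_groups = as.integer(n_groups),
                 group_separation = group_separation, modules = modules,
                 noise_sd = noise_sd, bias_sd_gene = bias_sd_gene,
                 bias_sd_sample = bias_sd_sample,
                 sample_jitter = sample_jitter, gene_sd = gene_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# group centers with expected pairwise distance ~ separation:
# random unit directions scaled by separation/sqrt(2)
draw_group_centers <- function(n_groups, rank, separation) {
  centers <- matrix(stats::rnorm(n_groups * rank), n_groups, rank)
  norms <- sqrt(rowSums(centers^2))
  centers / norms * separation / sqrt(2)
}

draw_samples <- function(config, rank, centers) {
  n <- config$n_samples
  group <- rep(seq_len(config$n_groups), length.out = n)
  group <- sort(group)
  S <- centers[group, , drop = FALSE] +
    matrix(stats::rnorm(n * rank, 0, config$sample_jitter), n, rank)
  list(S = S, group = paste0("GRP", group))
}

#' Generate a synthetic expression matrix with known truth
#'
#' Cell values are `dot(G*_a, S*_i) + b_a + b_i + N(0, noise_sd)`, shifted
#' by a constant so the minimum is exactly 0 (a valid log2 scale while
#' keeping the planted low-rank structure intact).
#'
#' @param config a [synth_config()].
#' @return list with `expr` (an [expr_matrix], `is_log2 = TRUE`) and
#'   `truth` (true vectors `G`, `S`, biases, `group` per sample, `module`
#'   per gene with NA for background, the applied `shift`, and the config).
#' @export
simulate_expression <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  r <- config$latent_rank
  local_rng(config$seed, {
    centers <- draw_group_centers(config$n_groups, r,
                                  config$group_separation)
    smp <- draw_samples(config, r, centers)
    k <- config$k_genes
    G <- matrix(stats::rnorm(k * r, 0, config$gene_sd), k, r)
    module <- rep(NA_character_, k)
    at <- 1L
    for (mi in seq_along(config$modules)) {
      size <- as.integer(config$modules[[mi]][1L])
      spread <- config$modules[[mi]][2L]
      center <- stats::rnorm(r, 0, config$gene_sd)
      idx <- at:(at + size - 1L)
      G[idx, ] <- matrix(rep(center, each = size), size, r) +
        matrix(stats::rnorm(size * r, 0, spread), size, r)
      module[idx] <- paste0("MODULE_", mi)
      at <- at + size
    }
    b_gene <- stats::rnorm(k, 0, config$bias_sd_gene)
    b_sample <- stats::rnorm(config$n_samples, 0, config$bias_sd_sample)
    assemble_synth(G, smp$S, b_gene, b_sample, smp$group, module, config)
  })
}

# build ids, add noise + non-negativity shift, pack expr + truth
assemble_synth <- function(G, S, b_gene, b_sample, group, module, config,
                           extra = list()) {
  n <- nrow(S); k <- nrow(G)
  gids <- sprintf("G%04d", seq_len(k))
  sids <- sprintf("S%04d", seq_len(n))
  vals <- tcrossprod(S, G) + outer(b_sample, b_gene, `+`)
  if (config$noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(n * k, 0, config$noise_sd), n, k)
  }
  shift <- max(0, -min(vals))
  vals <- vals - min(vals)  # minimum exactly 0
  dimnames(vals) <- list(sids, gids)
  rownames(G) <- gids; rownames(S) <- sids
  names(b_gene) <- gids; names(b_sample) <- sids
  truth <- c(list(G = G, S = S, b_gene = b_gene, b_sample = b_sample,
                  group = stats::setNames(group, sids),
                  module = stats::setNames(module, gids),
                  shift = shift, config = config),
             extra)
  list(expr = expr_matrix(vals, sids, gids, is_log2 = TRUE), truth = truth)
}

#' Wrap generator ground truth as an embedding model
#'
#' Builds a `gene_embedding` object directly from the true vectors and
#' biases of a synthetic data set, so geometry and discovery operations can
#' run on exactly known coordinates.
#'
#' @param truth the `truth` element returned by [simulate_expression()] or
#'   [make_responder_scenario()].
#' @return a `gene_embedding` (untrained; history empty).
#' @export
as_embedding <- function(truth) {
  m <- ncol(truth$G)
  cfg <- validate_config(dim = m, learning_rate = 1e-2, batch_size = 64L,
                         epochs = 0L, init_half_range = 0.05,
                         seed = truth$config$seed, validation_fraction = 0,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_epsilon = 1e-8, weight_decay = 0)
  G <- truth$G; S <- truth$S
  colnames(G) <- colnames(S) <- paste0("d", seq_len(m))
  structure(list(gene_ids = rownames(G), sample_ids = rownames(S),
                 G = G, S = S, b_gene = truth$b_gene,
                 b_sample = truth$b_sample, dim = m, config = cfg,
                 history = data.frame(epoch = integer(0),
                                      train_mse = numeric(0),
                                      val_mse = numeric(0)),
                 data = NULL, call = quote(as_embedding(truth))),
            class = "gene_embedding")
}

#' Generate a responder/non-responder scenario with a planted anchor module
#'
#' Extends the base generator with one latent "activity" coordinate that is
#' active (mean 1, SD 0.3) in responder-group samples and exactly 0
#' elsewhere. The first planted module — whose first gene is the anchor —
#' loads on that coordinate with weight `module_effect`, so module genes
#' co-vary with the anchor in responder samples but not in non-responder
#' samples. Each non-anchor module gene additionally carries a small offset
#' along a direction chosen orthogonal to the responder centroid but not to
#' the non-responder centroid; the offsets keep module genes within the
#' neighbor threshold of the anchor in the responder predicted profile and
#' in the gene entity space while pushing them outside it in the
#' non-responder profile, which is precisely the geometry the
#' exclusive-neighbor workflow is designed to detect. Non-responder group
#' centers are displaced by `nonresp_offset` along a fixed latent axis (a
#' strong lineage signal) so that direction is well conditioned.
#'
#' @param config a [synth_config()]; needs `n_groups >= 2`. The first half
#'   of the groups (rounded up) are responders.
#' @param module_effect loading of module genes on the activity coordinate
#'   (> 0, default 1).
#' @param nonresp_offset displacement of non-responder centers (default 8).
#' @return list with `expr`, `truth` (additionally: `anchor_id`,
#'   `module_gene_ids`, `planted_candidates` = module genes minus anchor)
#'   and `spec` (a ready-to-use [group_spec()], threshold 0.1).
#' @export
make_responder_scenario <- function(config = synth_config(),
                                    module_effect = 1, nonresp_offset = 8) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_groups < 2L) stop("need at least 2 groups")
  if (module_effect <= 0) stop("module_effect must be positive")
  r <- config$latent_rank
  m <- r + 1L  # last coordinate = responder activity
  resp_groups <- seq_len(ceiling(config$n_groups / 2))

  local_rng(config$seed, {
    centers <- cbind(draw_group_centers(config$n_groups, r,
                                        config$group_separation), 0)
    nonresp <- setdiff(seq_len(config$n_groups), resp_groups)
    centers[nonresp, 1L] <- centers[nonresp, 1L] + nonresp_offset
    smp <- draw_samples(config, m, centers)
    is_resp <- smp$group %in% paste0("GRP", resp_groups)
    smp$S[, m] <- 0
    smp$S[is_resp, m] <- stats::rnorm(sum(is_resp), 1, 0.3)

    c_resp <- colMeans(smp$S[is_resp, , drop = FALSE])
    c_non <- colMeans(smp$S[!is_resp, , drop = FALSE])
    # minimum-norm w with w . c_resp = 0 and w . c_non = 1, additionally
    # orthogonal to the differences between non-responder group centers so
    # the offsets do not induce shared variation within non-responders
    non_groups <- unique(smp$group[!is_resp])
    gmeans <- t(vapply(non_groups, function(g)
      colMeans(smp$S[smp$group == g, , drop = FALSE]), numeric(m)))
    C <- rbind(c_resp, c_non)
    rhs <- c(0, 1)
    if (nrow(gmeans) > 1L) {
      diffs <- sweep(gmeans[-1L, , drop = FALSE], 2L, gmeans[1L, ])
      C <- rbind(C, diffs)
      rhs <- c(rhs, rep(0, nrow(diffs)))
    }
    w <- drop(t(C) %*% solve(C %*% t(C), rhs))

    k <- config$k_genes
    G <- cbind(matrix(stats::rnorm(k * r, 0, config$gene_sd), k, r), 0)
    module <- rep(NA_character_, k)
    at <- 1L
    for (mi in seq_along(config$modules)) {
      size <- as.integer(config$modules[[mi]][1L])
      spread <- config$modules[[mi]][2L]
      idx <- at:(at + size - 1L)
      if (mi == 1L) {
        beta <- c(0, seq(0.15, 0.35, length.out = size - 1L))
        base <- module_effect * c(rep(0, r), 1)
        G[idx, ] <- matrix(rep(base, each = size), size, m) +
          outer(beta, w) +
          matrix(stats::rnorm(size * m, 0, 0.005), size, m)
      } else {
        center <- c(stats::rnorm(r, 0, config$gene_sd), 0)
        G[idx, ] <- matrix(rep(center, each = size), size, m) +
          cbind(matrix(stats::rnorm(size * r, 0, spread), size, r), 0)
      }
      module[idx] <- paste0("MODULE_", mi)
      at <- at + size
    }
    b_gene <- stats::rnorm(k, 0, config$bias_sd_gene)
    b_sample <- stats::rnorm(config$n_samples, 0, config$bias_sd_sample)

    out <- assemble_synth(G, smp$S, b_gene, b_sample, smp$group, module,
                          config)
    gids <- rownames(out$truth$G)
    sids <- rownames(out$truth$S)
    msize <- as.integer(config$modules[[1L]][1L])
    out$truth$anchor_id <- gids[1L]
    out$truth$module_gene_ids <- gids[seq_len(msize)]
    out$truth$planted_candidates <- gids[2:msize]
    out$truth$responder_direction <- w
    spec <- group_spec(sids[is_resp], sids[!is_resp], gids[1L],
                       threshold = 0.1)
    c(out, list(spec = spec))
  })
}

#' Gene-set collection from planted modules
#'
#' One gene set per planted module, named MODULE_1, MODULE_2, ...;
#' background genes are excluded.
#'
#' @param truth a generator `truth` with at least one planted module.
#' @return named list of character vectors compatible with [write_gmt()].
#' @export
make_gmt <- function(truth) {
  mods <- truth$module[!is.na(truth$module)]
  if (!length(mods)) stop("truth contains no planted modules")
  sets <- split(names(mods), mods)
  attr(sets, "descriptions") <- stats::setNames(
    paste("planted module", names(sets)), names(sets))
  sets
}

#' Back-transform a log2 matrix to raw-count scale
#'
#' Values become `2^v`, so [preprocess_expression()] applied to the result
#' reproduces the input exactly (all log2 values are >= 0).
#'
#' @param expr an [expr_matrix] with `is_log2 = TRUE`.
#' @return an [expr_matrix] with `is_log2 = FALSE`.
#' @export
export_raw_counts <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$is_log2) stop("expr is already on the raw scale")
  out <- expr
  out$values <- 2^expr$values
  out$is_log2 <- FALSE
  out
}
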