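#' Candidate-gene prioritization by similarity to known disease genes
#'
#' A small feed-forward neural network (two ReLU hidden layers of 128
#' units, sigmoid output, Adam, binary cross-entropy, mini-batches of
#' 5, 5 epochs) scores genes by similarity to a known-gene positive
#' class over gene-level predictors (constraint metrics, expression and
#' network enrichment encodings, CDS length). Scores are converted to
#' true-positive posterior probabilities with a naive-Bayes update:
#' kernel-density estimates of the score distributions in independent
#' positive and negative gene sets give a likelihood ratio, combined
#' with a prior.
#'
#' @name prioritize
NULL

#' Encode raw gene annotations into the NN feature matrix
#'
#' Encodings: numeric predictors (pLI, LOEUF, missense z, CDS length,
#' brain-coordinate count, GO-term count) standardized with
#' training-set statistics; brain-tissue specificity and PPI-cluster
#' membership as 0/1; co-expression module as one-hot over M1, M4, M7,
#' M13, Others (unlisted or missing modules map to Others). Missing
#' brain-coordinate counts are imputed with 1 (the observed median in
#' candidate sets); genes missing any of pLI, LOEUF or missense z are
#' excluded with a message.
#'
#' @param raw data.frame with columns gene_id, pli, loeuf, missense_z,
#'   cds_length, tsea_brain (0/1), brain_coord_count, module,
#'   go_term_count, string_member (0/1).
#' @param center,scale optional named standardization statistics from a
#'   previous call (to encode test genes on the training scale).
#' @param modules module levels kept as themselves (default M1, M4,
#'   M7, M13).
#' @return list of class `predictor_matrix`: `x` (numeric matrix),
#'   `gene_id`, `center`, `scale`.
#' @export
preprocess_predictors <- function(raw, center = NULL, scale = NULL,
                                  modules = c("M1", "M4", "M7", "M13")) {
  need <- c("gene_id", "pli", "loeuf", "missense_z", "cds_length",
            "tsea_brain", "brain_coord_count", "module", "go_term_count",
            "string_member")
  stop_if_not(all(need %in% names(raw)),
              paste("raw table needs columns:", paste(need, collapse = ", ")))
  keep <- !is.na(raw$pli) & !is.na(raw$loeuf) & !is.na(raw$missense_z)
  if (any(!keep))
    dn_msg("preprocess_predictors: ", sum(!keep),
           " gene(s) missing constraint values excluded")
  raw <- raw[keep, , drop = FALSE]

  bcc <- raw$brain_coord_count
  bcc[is.na(bcc)] <- 1
  mod <- as.character(raw$module)
  mod[is.na(mod) | !mod %in% modules] <- "Others"
  mod <- factor(mod, levels = c(modules, "Others"))
  onehot <- stats::model.matrix(~ 0 + mod)
  colnames(onehot) <- paste0("module_", levels(mod))

  num <- cbind(pli = raw$pli, loeuf = raw$loeuf,
               missense_z = raw$missense_z,
               cds_length = raw$cds_length,
               brain_coord_count = bcc,
               go_term_count = raw$go_term_count)
  if (is.null(center)) {
    center <- colMeans(num)
    scale <- apply(num, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  num <- sweep(sweep(num, 2, center), 2, scale, "/")
  x <- cbind(num, tsea_brain = as.numeric(raw$tsea_brain),
             string_member = as.numeric(raw$string_member), onehot)
  structure(list(x = x, gene_id = raw$gene_id, center = center,
                 scale = scale),
            class = "predictor_matrix")
}

#' Neural-network hyperparameters
#'
#' @param hidden_width units per hidden layer (default 128).
#' @param n_hidden number of hidden layers (default 2).
#' @param batch mini-batch size (default 5).
#' @param epochs passes over the training set (default 5).
#' @param lr Adam learning rate (default 1e-3, with beta1 = 0.9, beta2
#'   = 0.999, eps = 1e-8).
#' @param seed integer seed controlling initialization and shuffling.
#' @return list of class `nn_config`.
#' @export
nn_config <- function(hidden_width = 128L, n_hidden = 2L, batch = 5L,
                      epochs = 5L, lr = 1e-3, seed = 1L) {
  stop_if_not(batch >= 1 && epochs >= 1, "batch and epochs must be >= 1")
  structure(list(hidden_width = as.integer(hidden_width),
                 n_hidden = as.integer(n_hidden), batch = as.integer(batch),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "nn_config")
}

nn_init <- function(d_in, config) {
  dims <- c(d_in, rep(config$hidden_width, config$n_hidden), 1L)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    # He initialization for the ReLU stack
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                  sd = sqrt(2 / dims[l])),
                     nrow = dims[l])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

nn_forward <- function(par, x) {
  L <- length(par$W)
  a <- list(x)
  z <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    a[[l + 1]] <- if (l < L) pmax(z[[l]], 0) else
      1 / (1 + exp(-z[[l]]))
  }
  list(a = a, z = z, out = as.numeric(a[[L + 1]]))
}

nn_backward <- function(par, fw, y) {
  L <- length(par$W)
  n <- length(y)
  gW <- vector("list", L); gb <- vector("list", L)
  # BCE + sigmoid: delta at the output is (p - y) / n
  delta <- matrix((fw$out - y) / n, ncol = 1)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1)
      delta <- (delta %*% t(par$W[[l]])) * (fw$z[[l - 1]] > 0)
  }
  list(W = gW, b = gb)
}

#' Train the prioritization network
#'
#' Mini-batch Adam on binary cross-entropy; gene order is reshuffled
#' each epoch with the config seed, so training is deterministic given
#' the seed. Both classes must be present.
#'
#' @param features a `predictor_matrix` (training genes) or bare
#'   numeric matrix.
#' @param labels 0/1 (or logical) vector: 1 = known disease gene.
#' @param config an [nn_config()].
#' @return list of class `nn_model`: parameters, config, feature
#'   column names, per-epoch mean training loss.
#' @export
train_nn <- function(features, labels, config = nn_config()) {
  x <- if (inherits(features, "predictor_matrix")) features$x else features
  y <- as.numeric(labels)
  stop_if_not(all(y %in% c(0, 1)), "labels must be binary")
  stop_if_not(length(unique(y)) == 2, "both classes must be present")
  stop_if_not(all(is.finite(x)), "non-finite feature values")
  set.seed(config$seed)
  par <- nn_init(ncol(x), config)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(v) v * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  n <- nrow(x)
  epoch_loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1, n)]
      fw <- nn_forward(par, x[idx, , drop = FALSE])
      p <- pmin(pmax(fw$out, 1e-12), 1 - 1e-12)
      losses <- c(losses, -mean(y[idx] * log(p) +
                                  (1 - y[idx]) * log(1 - p)))
      g <- nn_backward(par, fw, y[idx])
      t <- t + 1L
      for (l in seq_along(par$W)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
        mhW <- mW[[l]] / (1 - b1^t); vhW <- vW[[l]] / (1 - b2^t)
        mhb <- mb[[l]] / (1 - b1^t); vhb <- vb[[l]] / (1 - b2^t)
        par$W[[l]] <- par$W[[l]] - config$lr * mhW / (sqrt(vhW) + eps)
        par$b[[l]] <- par$b[[l]] - config$lr * mhb / (sqrt(vhb) + eps)
      }
    }
    epoch_loss[ep] <- mean(losses)
  }
  structure(list(par = par, config = config,
                 feature_names = colnames(x), epoch_loss = epoch_loss),
            class = "nn_model")
}

#' Score genes with a trained network
#'
#' @param model an `nn_model` from [train_nn()].
#' @param features a `predictor_matrix` or numeric matrix encoded with
#'   the training statistics (same columns, same order).
#' @return named numeric vector of scores in (0, 1).
#' @export
score_genes <- function(model, features) {
  x <- if (inherits(features, "predictor_matrix")) features$x else features
  ids <- if (inherits(features, "predictor_matrix")) features$gene_id
  else rownames(x)
  if (!is.null(colnames(x)) && !is.null(model$feature_names) &&
      !identical(colnames(x), model$feature_names))
    stop("feature columns do not match the training encoding: ",
         paste(setdiff(colnames(x), model$feature_names), collapse = ","),
         call. = FALSE)
  out <- nn_forward(model$par, x)$out
  stats::setNames(out, ids)
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Midranks handle ties, so identical scores for all genes give 0.5.
#'
#' @param scores numeric vector.
#' @param labels binary vector, 1 = positive.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  y <- as.numeric(labels)
  stop_if_not(all(y %in% c(0, 1)), "labels must be binary")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stop_if_not(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical p-value for an AUC difference by retraining
#'
#' Retrains the network `n_retrains` times with different seeds,
#' collects the AUC distribution on the evaluation set, and returns the
#' proportion of retrained AUCs at or below the comparator's AUC (i.e.
#' the probability that the network does not beat the comparator).
#'
#' @param comparator_auc AUC of the competing score on the same
#'   evaluation set.
#' @param train_features,train_labels training data.
#' @param eval_features,eval_labels evaluation data (encoded with the
#'   training statistics).
#' @param config base [nn_config()]; seeds `config$seed + 1 ..
#'   config$seed + n_retrains` are used.
#' @param n_retrains number of retrained models (default 500).
#' @return list with p, aucs (the retraining distribution).
#' @export
auc_empirical_p <- function(comparator_auc, train_features, train_labels,
                            eval_features, eval_labels,
                            config = nn_config(), n_retrains = 500) {
  aucs <- vapply(seq_len(n_retrains), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    m <- train_nn(train_features, train_labels, cfg)
    auc_score(score_genes(m, eval_features), eval_labels)
  }, numeric(1))
  list(p = mean(aucs <= comparator_auc), aucs = aucs)
}

#' Gaussian kernel density estimate at query points
#'
#' @param x sample values.
#' @param at query points.
#' @param bw bandwidth; default Scott's rule via [stats::bw.nrd()].
#' @return density values at `at`.
#' @export
kde_density <- function(x, at, bw = stats::bw.nrd(x)) {
  vapply(at, function(q) mean(stats::dnorm(q, mean = x, sd = bw)),
         numeric(1))
}

#' Likelihood ratio of a score from positive and negative score samples
#'
#' `LR(q) = f_pos(q) / f_neg(q)` with Gaussian KDEs; both densities are
#' floored at `eps` so the ratio never blows up on empty support.
#'
#' @param pos_scores,neg_scores score samples (>= 10 each).
#' @param query score(s) to evaluate.
#' @param eps density floor (default 1e-12).
#' @param bw_pos,bw_neg bandwidths (default Scott's rule per sample).
#' @return likelihood ratio(s).
#' @export
kde_likelihood_ratio <- function(pos_scores, neg_scores, query,
                                 eps = 1e-12,
                                 bw_pos = stats::bw.nrd(pos_scores),
                                 bw_neg = stats::bw.nrd(neg_scores)) {
  stop_if_not(length(pos_scores) >= 10 && length(neg_scores) >= 10,
              "need >= 10 scores per class")
  fp <- pmax(kde_density(pos_scores, query, bw_pos), eps)
  fn <- pmax(kde_density(neg_scores, query, bw_neg), eps)
  fp / fn
}

#' Naive-Bayes posterior from a prior and a likelihood ratio
#'
#' `posterior = prior * LR / (prior * LR + 1 - prior)`; strictly
#' increasing in both arguments, and equal to the prior when LR = 1.
#'
#' @param prior prior true-positive probability in (0, 1).
#' @param lr likelihood ratio(s) (> 0).
#' @return posterior probability(ies).
#' @export
posterior_probability <- function(prior, lr) {
  stop_if_not(all(prior > 0 & prior < 1), "prior must be in (0,1)")
  stop_if_not(all(lr > 0), "likelihood ratio must be > 0")
  prior * lr / (prior * lr + 1 - prior)
}

#' Median posterior over an ensemble of retrained networks
#'
#' Retrains the model `n_models` times (seeds `config$seed + 1 ..`),
#' computes each gene's posterior per model from the KDE likelihood
#' ratio of its score against positive/negative reference scores, and
#' returns the per-gene median.
#'
#' @param train_features,train_labels training data.
#' @param query_features genes to prioritize (encoded with training
#'   statistics).
#' @param pos_features,neg_features reference gene sets whose score
#'   distributions define the likelihood ratio.
#' @param prior prior true-positive probability.
#' @param config base [nn_config()].
#' @param n_models ensemble size (default 100).
#' @return data.frame: gene_id, median_score, median_posterior.
#' @export
ensemble_posteriors <- function(train_features, train_labels,
                                query_features, pos_features,
                                neg_features, prior,
                                config = nn_config(), n_models = 100) {
  qs <- matrix(NA_real_, nrow = n_models,
               ncol = nrow(if (inherits(query_features,
                                        "predictor_matrix"))
                 query_features$x else query_features))
  post <- qs
  for (i in seq_len(n_models)) {
    cfg <- config
    cfg$seed <- config$seed + i
    m <- train_nn(train_features, train_labels, cfg)
    sq <- score_genes(m, query_features)
    sp <- score_genes(m, pos_features)
    sn <- score_genes(m, neg_features)
    lr <- kde_likelihood_ratio(sp, sn, sq)
    qs[i, ] <- sq
    post[i, ] <- posterior_probability(prior, lr)
  }
  ids <- if (inherits(query_features, "predictor_matrix"))
    query_features$gene_id else rownames(query_features)
  data.frame(gene_id = ids,
             median_score = apply(qs, 2, stats::median),
             median_posterior = apply(post, 2, stats::median),
             stringsAsFactors = FALSE)
}
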