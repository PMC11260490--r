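#' One-hot encode a DNA sequence
#'
#' @param seq character string over A/C/G/T/N (case-insensitive); `N`
#'   encodes as an all-zero column.
#' @param L padded length; the sequence is right-padded with all-zero
#'   columns. Longer sequences are an error.
#' @return 4 x L binary matrix with rows A, C, G, T.
#' @export
encode_onehot <- function(seq, L) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  if (n > L) stop("sequence length ", n, " exceeds padded length ", L)
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("invalid nucleotide(s): ", paste(bad, collapse = ""))
  m <- matrix(0, nrow = 4L, ncol = L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  if (n > 0L) {
    ridx <- match(chars, c("A", "C", "G", "T")) # N -> NA -> skipped
    ok <- !is.na(ridx)
    m[cbind(ridx[ok], which(ok))] <- 1
  }
  m
}

# Feature names for the flattened encoding.
feature_names <- function(L_p, L_t) {
  bases <- c("A", "C", "G", "T")
  c(sprintf("prom_%d_%s", rep(seq_len(L_p), each = 4L), bases),
    sprintf("tfcr_%d_%s", rep(seq_len(L_t), each = 4L), bases),
    "distance")
}

#' Encode one gene's promoter, TFCR sequence and distance as a feature
#' vector
#'
#' The promoter one-hot (4 x `L_p`, column-major) is followed by the
#' TFCR one-hot (4 x `L_t`) and the TFCR-to-promoter distance as the
#' final scalar feature, giving `4 L_p + 4 L_t + 1` features.
#'
#' @param promoter_seq,tfcr_seq DNA strings (may be shorter than their
#'   padded lengths, never longer).
#' @param distance TFCR-to-promoter gap in bp.
#' @param L_p,L_t padded lengths; defaults 4000 and 11113 are the
#'   maximum promoter and TFCR sequence lengths of the full-scale
#'   setting.
#' @return named numeric vector of length `4 L_p + 4 L_t + 1`.
#' @export
encode_features <- function(promoter_seq, tfcr_seq, distance,
                            L_p = 4000L, L_t = 11113L) {
  v <- c(as.numeric(encode_onehot(promoter_seq, L_p)),
         as.numeric(encode_onehot(tfcr_seq, L_t)),
         as.numeric(distance))
  names(v) <- feature_names(L_p, L_t)
  v
}

#' Encode a table of genes into a feature matrix
#'
#' @param records data.frame with columns `promoter_seq`, `tfcr_seq`,
#'   `distance`.
#' @inheritParams encode_features
#' @return numeric matrix, one row per record.
#' @export
encode_feature_matrix <- function(records, L_p = 4000L, L_t = 11113L) {
  X <- matrix(0, nrow = nrow(records), ncol = 4L * L_p + 4L * L_t + 1L)
  for (i in seq_len(nrow(records))) {
    X[i, ] <- encode_features(records$promoter_seq[i], records$tfcr_seq[i],
                              records$distance[i], L_p, L_t)
  }
  colnames(X) <- feature_names(L_p, L_t)
  X
}

#' Random 80/20 train/test split
#'
#' @param records data.frame (or matrix) of samples; needs >= 10 rows.
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with `train` and `test` subsets (disjoint, exhaustive)
#'   and the index vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(records, train_frac = 0.8, seed = 1L) {
  n <- nrow(records)
  if (is.null(n)) stop("records must be a data.frame or matrix")
  if (n < 10L) stop("need at least 10 records to split, got ", n)
  n_train <- round(train_frac * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = records[idx, , drop = FALSE],
       test = records[-idx, , drop = FALSE],
       train_idx = sort(idx), test_idx = setdiff(seq_len(n), idx))
}

#' Pool per-species, per-stage training sets by resampling
#'
#' Each species contributes exactly `per_species_total` samples: with
#' `S` stages, `floor(total / S)` samples are drawn with replacement
#' from each stage's training set and the remainder is assigned to the
#' first stage. Six species at the default 30 000 per species give the
#' 180 000-sample pooled set.
#'
#' @param species_stages named list: species -> named list of stage
#'   data.frames (training records).
#' @param per_species_total samples per species (default 30000).
#' @param seed integer seed.
#' @return data.frame of pooled records with added `species` and
#'   `stage` columns.
#' @export
build_pooled_training_set <- function(species_stages,
                                      per_species_total = 30000L,
                                      seed = 1L) {
  if (length(species_stages) == 0L) stop("no species supplied")
  with_seed(seed, {
    out <- list()
    for (sp in names(species_stages)) {
      stages <- species_stages[[sp]]
      if (length(stages) == 0L) stop("species ", sp, " has no stages")
      S <- length(stages)
      base_n <- per_species_total %/% S
      extra <- per_species_total - base_n * S
      for (si in seq_len(S)) {
        st <- stages[[si]]
        if (is.null(nrow(st)) || nrow(st) == 0L) {
          stop("empty stage training set for species ", sp)
        }
        n_draw <- base_n + if (si == 1L) extra else 0L
        idx <- sample.int(nrow(st), n_draw, replace = TRUE)
        chunk <- st[idx, , drop = FALSE]
        chunk$species <- sp
        chunk$stage <- names(stages)[si] %||% sprintf("stage%02d", si)
        out[[length(out) + 1L]] <- chunk
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Registry of the eleven regression methods
#'
#' Methods marked unsupported (`svr` is linear-kernel only; `cnn` needs
#' a deep-learning backend and is excluded from deterministic
#' evaluation) are listed for bookkeeping and raise an informative
#' error when trained if unavailable.
#'
#' @return data.frame with columns `method`, `label`, `tree_based`,
#'   `supported`.
#' @export
ml_method_registry <- function() {
  data.frame(
    method = c("gb_trees", "svr", "mlp", "knn", "dtree", "rforest",
               "adaboost", "gbdt", "xgb", "lgbm", "cnn"),
    label = c("Gradient-boosted trees (reference)",
              "Support vector regression (linear)",
              "Multi-layer perceptron", "K-nearest neighbours",
              "Decision tree", "Random forest", "AdaBoost.R2",
              "Gradient boosting (GBDT profile)",
              "Gradient boosting (XGB profile)",
              "Gradient boosting (LGBM profile)",
              "Convolutional neural network"),
    tree_based = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE, FALSE),
    supported = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Specification of one regression model
#'
#' @param method one of the names in [ml_method_registry()].
#' @param hyperparams named list overriding the method's defaults. The
#'   reference tree-ensemble defaults follow the published full-scale
#'   configuration (loss = RMSE, iterations = 2000, learning rate 0.1,
#'   L2 leaf regularisation 5, depth 12, Bernoulli row subsampling);
#'   border_count and ordered boosting are backend-specific knobs the
#'   in-package engine does not have and are accepted but ignored with
#'   a message. Desk-scale runs should lower `iterations`/`depth`.
#' @param seed integer seed controlling all randomness in training.
#' @return a `model_spec` object.
#' @export
model_spec <- function(method, hyperparams = list(), seed = 1L) {
  reg <- ml_method_registry()
  if (!method %in% reg$method) {
    stop("unknown method '", method, "'; see ml_method_registry()")
  }
  defaults <- switch(method,
    gb_trees = list(iterations = 2000L, learning_rate = 0.1, depth = 12L,
                    l2 = 5, subsample = 0.8, colsample = 1.0,
                    min_child = 5L),
    gbdt = list(iterations = 300L, learning_rate = 0.1, depth = 4L,
                l2 = 1, subsample = 1.0, colsample = 1.0, min_child = 5L),
    xgb = list(iterations = 300L, learning_rate = 0.1, depth = 6L,
               l2 = 1, subsample = 0.8, colsample = 0.8, min_child = 5L),
    lgbm = list(iterations = 300L, learning_rate = 0.1, depth = 8L,
                l2 = 1, subsample = 0.8, colsample = 0.8, min_child = 20L),
    dtree = list(depth = 8L, l2 = 0, min_child = 5L),
    rforest = list(n_trees = 200L, depth = 10L, colsample = 0.5,
                   l2 = 0, min_child = 5L),
    adaboost = list(iterations = 50L, depth = 4L, l2 = 0, min_child = 5L),
    knn = list(k = 5L),
    mlp = list(hidden = 16L, epochs = 300L, learning_rate = 0.01,
               weight_decay = 1e-4),
    svr = list(epsilon = 0.05, cost = 1, epochs = 200L,
               learning_rate = 0.01),
    cnn = list()
  )
  ignored <- intersect(names(hyperparams),
                       c("border_count", "boosting_type", "bootstrap_type",
                         "loss_function"))
  if (length(ignored)) {
    message("ignoring backend-specific hyperparameters: ",
            paste(ignored, collapse = ", "))
    hyperparams[ignored] <- NULL
  }
  hp <- utils::modifyList(defaults, hyperparams)
  structure(list(method = method, hyperparams = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

gbt_like <- c("gb_trees", "gbdt", "xgb", "lgbm")

#' Train a RegulatoryScore regressor
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (rows = samples).
#' @param y numeric target vector.
#' @return a `tfcr_model`; use [predict()] on new feature matrices and
#'   [attribute_shap()] for tree-based models.
#' @export
train_regressor <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("features and targets must be finite")
  }
  reg <- ml_method_registry()
  if (!reg$supported[reg$method == spec$method]) {
    stop("method '", spec$method,
         "' is registered but has no offline backend in this build")
  }
  hp <- spec$hyperparams
  fit <- switch(spec$method,
    gb_trees = , gbdt = , xgb = , lgbm = {
      f <- fit_gbt_cpp(X, y, as.integer(hp$iterations), hp$learning_rate,
                       as.integer(hp$depth), hp$l2, hp$subsample,
                       hp$colsample, as.integer(hp$min_child), spec$seed)
      list(kind = "forest", trees = f$trees, base = f$base_score,
           weights = rep(hp$learning_rate, length(f$trees)))
    },
    dtree = {
      f <- fit_gbt_cpp(X, y, 1L, 1.0, as.integer(hp$depth), hp$l2, 1.0,
                       1.0, as.integer(hp$min_child), spec$seed)
      list(kind = "forest", trees = f$trees, base = f$base_score,
           weights = 1.0)
    },
    rforest = fit_rforest(X, y, hp, spec$seed),
    adaboost = fit_adaboost(X, y, hp, spec$seed),
    knn = list(kind = "knn", X = X, y = y, k = as.integer(hp$k)),
    mlp = fit_mlp(X, y, hp, spec$seed),
    svr = fit_svr(X, y, hp, spec$seed)
  )
  structure(list(spec = spec, fit = fit,
                 feature_names = colnames(X) %||%
                   sprintf("f%d", seq_len(ncol(X)))),
            class = "tfcr_model")
}

fit_rforest <- function(X, y, hp, seed) {
  n <- nrow(X)
  trees <- vector("list", hp$n_trees)
  bases <- numeric(hp$n_trees)
  with_seed(seed, {
    for (b in seq_len(hp$n_trees)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- fit_gbt_cpp(X[idx, , drop = FALSE], y[idx], 1L, 1.0,
                       as.integer(hp$depth), hp$l2, 1.0, hp$colsample,
                       as.integer(hp$min_child),
                       as.integer(child_seed(seed, paste0("rf", b))))
      trees[[b]] <- f$trees[[1L]]
      bases[b] <- f$base_score
    }
  })
  list(kind = "forest", trees = trees, base = mean(bases),
       weights = rep(1 / hp$n_trees, hp$n_trees))
}

# AdaBoost.R2 with weight-resampling and a linear (weighted-mean)
# combination so attributions stay additive.
fit_adaboost <- function(X, y, hp, seed) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list()
  bases <- numeric(0)
  betas <- numeric(0)
  with_seed(seed, {
    for (t in seq_len(hp$iterations)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      f <- fit_gbt_cpp(X[idx, , drop = FALSE], y[idx], 1L, 1.0,
                       as.integer(hp$depth), hp$l2, 1.0, 1.0,
                       as.integer(hp$min_child),
                       as.integer(child_seed(seed, paste0("ab", t))))
      pred <- predict_forest_cpp(f$trees, X, f$base_score, 1.0)
      err <- abs(pred - y)
      D <- max(err)
      if (D == 0) {
        trees[[length(trees) + 1L]] <- f$trees[[1L]]
        bases <- c(bases, f$base_score)
        betas <- c(betas, 1e-10)
        break
      }
      L <- err / D
      ebar <- sum(w * L)
      if (ebar >= 0.5) break
      beta <- ebar / (1 - ebar)
      trees[[length(trees) + 1L]] <- f$trees[[1L]]
      bases <- c(bases, f$base_score)
      betas <- c(betas, beta)
      w <- w * beta^(1 - L)
      w <- w / sum(w)
    }
  })
  if (length(trees) == 0L) stop("adaboost failed to fit any tree")
  a <- log(1 / betas)
  a <- a / sum(a)
  list(kind = "forest", trees = trees, base = sum(a * bases), weights = a)
}

fit_mlp <- function(X, y, hp, seed) {
  p <- ncol(X)
  H <- hp$hidden
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(p * H, 0, 1 / sqrt(p)), p, H)
    b1 <- rep(0, H)
    W2 <- stats::rnorm(H, 0, 1 / sqrt(H))
    b2 <- mean(y)
    lr <- hp$learning_rate
    for (e in seq_len(hp$epochs)) {
      Z <- tanh(sweep(X %*% W1, 2, b1, `+`))
      pred <- as.numeric(Z %*% W2) + b2
      d <- 2 * (pred - y) / length(y)
      gW2 <- as.numeric(t(Z) %*% d) + hp$weight_decay * W2
      gb2 <- sum(d)
      dZ <- outer(d, W2) * (1 - Z^2)
      gW1 <- t(X) %*% dZ + hp$weight_decay * W1
      gb1 <- colSums(dZ)
      W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
      W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
    }
    list(kind = "mlp", W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
}

# Linear epsilon-insensitive SVR by averaged subgradient descent.
fit_svr <- function(X, y, hp, seed) {
  p <- ncol(X)
  with_seed(seed, {
    w <- rep(0, p)
    b <- mean(y)
    w_acc <- w; b_acc <- b
    lr <- hp$learning_rate
    for (e in seq_len(hp$epochs)) {
      pred <- as.numeric(X %*% w) + b
      r <- pred - y
      s <- ifelse(r > hp$epsilon, 1, ifelse(r < -hp$epsilon, -1, 0))
      gw <- w / hp$cost + as.numeric(t(X) %*% s) / length(y)
      gb <- sum(s) / length(y)
      w <- w - lr * gw
      b <- b - lr * gb
      w_acc <- w_acc + w; b_acc <- b_acc + b
    }
    list(kind = "linear", w = w_acc / (hp$epochs + 1),
         b = b_acc / (hp$epochs + 1))
  })
}

#' @export
predict.tfcr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  fit <- object$fit
  switch(fit$kind,
    forest = as.numeric(predict_forest_cpp(fit$trees, X, fit$base,
                                           fit$weights)),
    knn = {
      tr <- fit$X
      d2 <- outer(rowSums(X^2), rowSums(tr^2), `+`) - 2 * X %*% t(tr)
      apply(d2, 1L, function(di) {
        mean(fit$y[order(di)[seq_len(min(fit$k, length(di)))]])
      })
    },
    mlp = {
      Z <- tanh(sweep(X %*% fit$W1, 2, fit$b1, `+`))
      as.numeric(Z %*% fit$W2) + fit$b2
    },
    linear = as.numeric(X %*% fit$w) + fit$b
  )
}

#' Evaluate predictions with the five standard metrics
#'
#' @param model a `tfcr_model`, or a numeric vector of predictions.
#' @param X feature matrix (ignored when `model` is already a
#'   prediction vector; pass `NULL`).
#' @param y actual targets.
#' @return list with `pearson_r`, `spearman_R`, `r_squared`, `mae`,
#'   `rmse`. Constant predictions give `NA` correlations with a
#'   warning.
#' @export
evaluate_regressor <- function(model, X, y) {
  pred <- if (inherits(model, "tfcr_model")) predict(model, X) else
    as.numeric(model)
  if (length(pred) != length(y) || length(y) == 0L) {
    stop("predictions and targets must be equal-length and non-empty")
  }
  const <- stats::sd(pred) == 0 || stats::sd(y) == 0
  if (const) {
    warning("constant predictions or targets: correlations undefined")
  }
  r <- if (const) NA_real_ else stats::cor(pred, y)
  R <- if (const) NA_real_ else stats::cor(pred, y, method = "spearman")
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(
    pearson_r = r,
    spearman_R = R,
    r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
    mae = mean(abs(y - pred)),
    rmse = sqrt(mean((y - pred)^2))
  )
}

#' k-fold cross-validation of a model specification
#'
#' @param spec a [model_spec()].
#' @param X,y training data.
#' @param k number of folds (default 5).
#' @return data.frame of per-fold metrics.
#' @export
cross_validate <- function(spec, X, y, k = 5L) {
  n <- nrow(X)
  if (n < k) stop("fewer samples than folds")
  folds <- with_seed(spec$seed, sample(rep_len(seq_len(k), n)))
  res <- lapply(seq_len(k), function(f) {
    te <- folds == f
    m <- train_regressor(spec, X[!te, , drop = FALSE], y[!te])
    met <- evaluate_regressor(m, X[te, , drop = FALSE], y[te])
    cbind(data.frame(fold = f), as.data.frame(met))
  })
  do.call(rbind, res)
}

#' Exact TreeSHAP attributions for a tree-based model
#'
#' Path-dependent TreeSHAP: for every sample, the base value plus the
#' per-feature attributions reconstruct the model's prediction exactly
#' (local accuracy); positive values push the prediction above the
#' base. Features are ranked by mean absolute attribution.
#'
#' @param model a tree-based `tfcr_model` (`gb_trees`, `gbdt`, `xgb`,
#'   `lgbm`, `dtree`, `rforest`, `adaboost`).
#' @param X feature matrix to explain.
#' @return list with `phi` (n x p attribution matrix), `base` (scalar
#'   expected prediction), `prediction` (per-sample reconstruction),
#'   and `importance` (named, sorted mean |attribution|).
#' @export
attribute_shap <- function(model, X) {
  stopifnot(inherits(model, "tfcr_model"))
  if (model$fit$kind != "forest") {
    stop("SHAP attribution is defined for tree-ensemble models only; '",
         model$spec$method, "' is not tree-based")
  }
  X <- as.matrix(X)
  res <- treeshap_cpp(model$fit$trees, X, model$fit$base,
                      model$fit$weights)
  phi <- res$phi
  colnames(phi) <- model$feature_names
  imp <- sort(colMeans(abs(phi)), decreasing = TRUE)
  list(phi = phi, base = res$base,
       prediction = res$base + rowSums(phi),
       importance = imp)
}

#' Permutation feature importance (loss-function change)
#'
#' Model-agnostic stand-in for per-feature loss-change diagnostics:
#' the increase in test loss when one feature column is permuted,
#' averaged over `n_repeats` permutations.
#'
#' @param model a `tfcr_model`.
#' @param X,y evaluation data.
#' @param metric `"rmse"` or `"mae"`.
#' @param n_repeats permutations per feature (>= 1).
#' @param seed integer seed.
#' @param features optional subset of feature indices or names.
#' @return named numeric vector of mean loss increases, sorted
#'   decreasing.
#' @export
importance_by_permutation <- function(model, X, y, metric = c("rmse", "mae"),
                                      n_repeats = 5L, seed = 1L,
                                      features = NULL) {
  metric <- match.arg(metric)
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  X <- as.matrix(X)
  lossf <- function(pred) {
    if (metric == "rmse") sqrt(mean((pred - y)^2)) else mean(abs(pred - y))
  }
  base_loss <- lossf(predict(model, X))
  feats <- if (is.null(features)) seq_len(ncol(X)) else {
    if (is.character(features)) match(features, model$feature_names)
    else features
  }
  out <- with_seed(seed, {
    vapply(feats, function(f) {
      mean(vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, f] <- Xp[sample.int(nrow(X)), f]
        lossf(predict(model, Xp)) - base_loss
      }, numeric(1)))
    }, numeric(1))
  })
  names(out) <- model$feature_names[feats]
  sort(out, decreasing = TRUE)
}

#' Extract promoter and TFCR sequences for the regression features
#'
#' Builds the `promoter_seq` / `tfcr_seq` / `distance` record table for
#' [encode_feature_matrix()] from a gene table and a genome sequence.
#' TFCR sequences longer than `L_t` are trimmed symmetrically around
#' the interval midpoint; promoters are at most 2 x 2000 bp by
#' construction.
#'
#' @param gene_table data.frame from [build_gene_table()] (scored rows
#'   are used).
#' @param genes annotated gene `GRanges`.
#' @param tfcrs TFCR `GRanges` the table was built from.
#' @param sequence genome `DNAStringSet` named by chromosome.
#' @param L_p,L_t padded lengths (trim bounds); promoters wider than
#'   `L_p` (the full-scale window is 4000 bp) are likewise trimmed
#'   around their midpoint for desk-scale runs.
#' @return data.frame with `gene_id`, `promoter_seq`, `tfcr_seq`,
#'   `distance`, `score`.
#' @export
build_feature_records <- function(gene_table, genes, tfcrs, sequence,
                                  L_p = 4000L, L_t = 11113L) {
  tab <- gene_table[!is.na(gene_table$score), , drop = FALSE]
  gi <- match(tab$gene_id, genes$gene_id)
  ti <- match(tab$tfcr_id, tfcrs$tfcr_id)
  seqs <- stats::setNames(as.character(sequence), names(sequence))
  get_seq <- function(chrom, start, end) {
    substring(seqs[[chrom]], max(1L, start),
              min(nchar(seqs[[chrom]]), end))
  }
  prom <- promoter_ranges(genes)
  records <- data.frame(gene_id = tab$gene_id, promoter_seq = "",
                        tfcr_seq = "", distance = tab$distance,
                        score = tab$score, stringsAsFactors = FALSE)
  trim <- function(s, e, L) {
    if (e - s + 1L > L) {
      mid <- floor((s + e) / 2)
      s <- mid - floor((L - 1) / 2)
      e <- s + L - 1L
    }
    c(s, e)
  }
  for (r in seq_len(nrow(tab))) {
    g <- gi[r]; t <- ti[r]
    pw <- trim(GenomicRanges::start(prom)[g],
               GenomicRanges::end(prom)[g], L_p)
    records$promoter_seq[r] <- get_seq(
      as.character(GenomicRanges::seqnames(prom))[g], pw[1L], pw[2L])
    tw <- trim(GenomicRanges::start(tfcrs)[t],
               GenomicRanges::end(tfcrs)[t], L_t)
    records$tfcr_seq[r] <- get_seq(
      as.character(GenomicRanges::seqnames(tfcrs))[t], tw[1L], tw[2L])
  }
  records
}
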