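#' Model configuration for the graph-convolutional edge classifier
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 0.005 and weight decay 1e-4, dropout after the propagation layer, and
#' early stopping once the validation loss has failed to improve for
#' `patience` consecutive epochs.
#'
#' @param feature_len length every node's expression vector is pooled to
#'   (this is what makes models transferable across datasets with different
#'   sample counts).
#' @param hidden_dim width of the affine input map and the first graph
#'   convolution.
#' @param embed_dim node embedding width `d`; edge embeddings are `d x d`
#'   outer products (must be at least 5 for the convolutional head).
#' @param dropout dropout rate in `[0, 1)` applied after the first
#'   graph-convolution layer.
#' @param lr,weight_decay Adam learning rate and L2 weight decay.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs hard cap on training epochs.
#' @param select_metric validation quantity that drives early stopping and
#'   checkpoint selection: `"loss"` (cross-entropy, default) or `"auc"`
#'   (rank AUC, steadier on small validation splits).
#' @param conv_channels channels of the two 3x3 convolution layers of the
#'   edge-classification head.
#' @param log1p_features log1p-scale raw expression before pooling (for
#'   numerical stability; disable to feed raw values).
#' @param seed RNG seed for initialization, dropout and splits.
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(feature_len = 256, hidden_dim = 64, embed_dim = 64,
                       dropout = 0.5, lr = 0.005, weight_decay = 1e-4,
                       patience = 200, max_epochs = 1000,
                       conv_channels = c(8, 16), log1p_features = TRUE,
                       select_metric = c("loss", "auc"), seed = 1) {
  assert_that(embed_dim >= 5, "embed_dim must be at least 5 for two 3x3 convolutions")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0,1)")
  assert_that(lr > 0, "lr must be positive")
  structure(list(feature_len = feature_len, hidden_dim = hidden_dim,
                 embed_dim = embed_dim, dropout = dropout, lr = lr,
                 weight_decay = weight_decay, patience = patience,
                 max_epochs = max_epochs, conv_channels = conv_channels,
                 log1p_features = log1p_features,
                 select_metric = match.arg(select_metric), seed = seed),
            class = "gcn_config")
}

#' Build the regulatory graph for the edge classifier
#'
#' Nodes are the union of edge endpoints; node features are the genes' raw
#' per-sample expression vectors. Message passing uses the symmetrized
#' adjacency with self-loops under the usual degree normalization
#' `D^(-1/2) (A + I) D^(-1/2)`; edge direction is preserved downstream by
#' the asymmetric outer-product edge embedding.
#'
#' @param edges candidate edge tibble (`tf`, `target`); duplicates collapse.
#' @param expr an `expr_matrix` containing every endpoint gene.
#' @return A `reg_graph` with elements `nodes`, `edges`, `X` and the
#'   normalized adjacency `A`.
#' @export
build_graph <- function(edges, expr) {
  assert_that(nrow(edges) > 0, "empty edge set")
  edges <- edges |> distinct(.data$tf, .data$target, .keep_all = TRUE)
  assert_that(all(edges$tf != edges$target), "self-loops are not allowed")
  nodes <- union(edges$tf, edges$target)
  assert_that(all(nodes %in% rownames(expr)), "all edge genes must be in expr")
  idx <- stats::setNames(seq_along(nodes), nodes)
  A <- normalized_adjacency(idx[edges$tf], idx[edges$target], length(nodes))
  structure(list(nodes = nodes, node_index = idx,
                 edges = edges |> select("tf", "target"),
                 edge_table = edges,
                 X = unclass(expr)[nodes, , drop = FALSE], A = A),
            class = "reg_graph")
}

normalized_adjacency <- function(from, to, n) {
  A <- Matrix::sparseMatrix(i = c(from, to, seq_len(n)),
                            j = c(to, from, seq_len(n)),
                            x = 1, dims = c(n, n))
  A@x[] <- 1  # duplicate entries collapse to unweighted
  dinv <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(n, dinv) %*% A %*% Matrix::Diagonal(n, dinv)
}

#' @export
#' @method print reg_graph
print.reg_graph <- function(x, ...) {
  cat(sprintf("<reg_graph> %d nodes, %d directed edges, %d feature(s)/node\n",
              length(x$nodes), nrow(x$edges), ncol(x$X)))
  invisible(x)
}

#' Per-TF neighbour set in the candidate graph
#' @param graph a `reg_graph`.
#' @param tf a TF gene id.
#' @return Character vector of targets of `tf`.
#' @export
graph_neighbors <- function(graph, tf) {
  graph$edges$target[graph$edges$tf == tf]
}

#' Sample balanced negative pairs and split edges 8:1:1
#'
#' For each TF `t` with positive edges, negatives are drawn without
#' replacement from `V - N(t) - {t}` (`N(t)` = the TF's neighbours in the
#' candidate graph, so negatives are never candidate edges), matched in
#' count to the TF's positives where enough eligible nodes exist. The
#' pooled positives and negatives are then split into train/validation/test
#' partitions at 8:1:1, stratified by label.
#'
#' @param graph a `reg_graph`.
#' @param positives tibble (`tf`, `target`) of supervised positive edges,
#'   a subset of the candidate edges.
#' @param seed RNG seed.
#' @return An `edge_split` tibble: `tf`, `target`, `label` (1/0),
#'   `partition` (`train`/`val`/`test`).
#' @export
sample_negatives <- function(graph, positives, seed = 1) {
  assert_that(nrow(positives) > 0, "no positive edges")
  withr::with_seed(derive_seed(seed, "negatives"), {
    neg <- purrr::map(unique(positives$tf), function(t) {
      n_pos <- sum(positives$tf == t)
      eligible <- setdiff(graph$nodes, c(graph_neighbors(graph, t), t))
      if (length(eligible) == 0L) {
        rlang::warn(paste0("TF ", t, " has no eligible non-targets; zero negatives sampled"))
        return(NULL)
      }
      k <- min(n_pos, length(eligible))
      tibble(tf = t, target = sample(eligible, k))
    }) |> purrr::list_rbind()
    all_edges <- bind_rows(positives |> select("tf", "target") |> mutate(label = 1L),
                           neg |> mutate(label = 0L))
    split_811(all_edges)
  })
}

# stratified 8:1:1 split; proportions hold within +-1 edge per class
split_811 <- function(edges) {
  part <- character(nrow(edges))
  for (ix in split(seq_len(nrow(edges)), edges$label)) {
    ix <- sample(ix)
    n <- length(ix)
    n_va <- round(n / 10)
    n_te <- round(n / 10)
    p <- rep("train", n)
    if (n_va > 0) p[seq_len(n_va)] <- "val"
    if (n_te > 0) p[n_va + seq_len(n_te)] <- "test"
    part[ix] <- p
  }
  edges$partition <- part
  class(edges) <- c("edge_split", class(edges))
  edges
}

#' Adaptive average pooling of node feature vectors
#'
#' Every node's expression vector is pooled to a fixed `feature_len`:
#' output slot `i` averages input positions `floor((i-1) n / L) + 1` through
#' `ceiling(i n / L)`. When `feature_len` exceeds the sample count the
#' pooling degenerates to padding-free interpolation (input values repeat).
#'
#' @param X numeric matrix, nodes in rows.
#' @param feature_len output length.
#' @param log1p_scale apply `log1p` before pooling.
#' @return Matrix with `feature_len` columns.
#' @export
reduce_features <- function(X, feature_len, log1p_scale = TRUE) {
  assert_that(ncol(X) >= 1, "every node needs at least one feature")
  if (log1p_scale) X <- log1p(X)
  n <- ncol(X)
  M <- matrix(0, n, feature_len)
  for (i in seq_len(feature_len)) {
    s <- floor((i - 1) * n / feature_len) + 1L
    e <- ceiling(i * n / feature_len)
    M[s:e, i] <- 1 / (e - s + 1L)
  }
  X %*% M
}

# pooled + standardized node inputs; standardization (per pooled feature,
# zero mean / unit variance over nodes) is part of the model's feature
# normalization step — without it the pooled log-counts are nearly constant
# across nodes and the rectifier layers can die at initialization
pooled_features <- function(graph, cfg) {
  Xp <- reduce_features(graph$X, cfg$feature_len, cfg$log1p_features)
  mu <- colMeans(Xp)
  sdv <- apply(Xp, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  scaled <- sweep(sweep(Xp, 2, mu), 2, sdv, "/")
  # all-zero feature matrices (ablation) stay exactly zero
  scaled[, colSums(abs(Xp)) == 0] <- 0
  scaled
}

# ---- parameter initialization and the forward/backward core ----------------

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

# biases start small but nonzero (uniform +-1/sqrt(fan-in), the usual linear
# layer convention); an all-zero bias stack would leave the zero-feature
# ablation with no gradient path at all, since every rectifier sits exactly
# on its kink
bias_init <- function(n, fan_in) {
  stats::runif(n, -1, 1) / sqrt(fan_in)
}

init_params <- function(cfg) {
  H <- cfg$hidden_dim; d <- cfg$embed_dim
  C1 <- cfg$conv_channels[1]; C2 <- cfg$conv_channels[2]
  list(W0 = glorot(cfg$feature_len, H), b0 = bias_init(H, cfg$feature_len),
       W1 = glorot(H, H), b1 = bias_init(H, H),
       W2 = glorot(H, d), b2 = bias_init(d, H),
       K1 = glorot(9, C1), c1 = bias_init(C1, 9),
       K2 = glorot(9 * C1, C2), c2 = bias_init(C2, 9 * C1),
       Wf = glorot(C2, 1), bf = bias_init(1, C2))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# node-embedding forward pass (pooled inputs -> affine -> 2-layer GCN)
embed_nodes <- function(params, A, Xp, dropout_mask = NULL) {
  X0 <- sweep(Xp %*% params$W0, 2, params$b0, "+")
  Z1 <- as.matrix(A %*% X0)
  pre1 <- sweep(Z1 %*% params$W1, 2, params$b1, "+")
  H1 <- pmax(pre1, 0)
  D1 <- if (is.null(dropout_mask)) H1 else H1 * dropout_mask
  Z2 <- as.matrix(A %*% D1)
  H2 <- sweep(Z2 %*% params$W2, 2, params$b2, "+")
  list(X0 = X0, Z1 = Z1, pre1 = pre1, D1 = D1, Z2 = Z2, H2 = H2,
       dropout_mask = dropout_mask)
}

# full forward: edge probabilities under given weights (no dropout unless
# a mask is supplied)
gcn_forward <- function(params, A, Xp, ti, ui, cfg, dropout_mask = NULL) {
  emb <- embed_nodes(params, A, Xp, dropout_mask)
  head <- conv_head_cpp(emb$H2[ti, , drop = FALSE], emb$H2[ui, , drop = FALSE],
                        params$K1, params$c1, params$K2, params$c2,
                        as.vector(params$Wf), params$bf,
                        numeric(length(ti)), FALSE)
  list(prob = as.numeric(head$prob), emb = emb)
}

# one training step: probabilities, loss and all parameter gradients
gcn_step <- function(params, A, Xp, ti, ui, y, cfg, dropout_mask = NULL) {
  emb <- embed_nodes(params, A, Xp, dropout_mask)
  head <- conv_head_cpp(emb$H2[ti, , drop = FALSE], emb$H2[ui, , drop = FALSE],
                        params$K1, params$c1, params$K2, params$c2,
                        as.vector(params$Wf), params$bf, y, TRUE)
  d <- cfg$embed_dim
  dH2 <- matrix(0, nrow(emb$H2), d)
  rt <- rowsum(head$dHt, ti)
  dH2[as.integer(rownames(rt)), ] <- dH2[as.integer(rownames(rt)), ] + rt
  ru <- rowsum(head$dHu, ui)
  dH2[as.integer(rownames(ru)), ] <- dH2[as.integer(rownames(ru)), ] + ru

  dW2 <- crossprod(emb$Z2, dH2)
  db2 <- colSums(dH2)
  dD1 <- as.matrix(A %*% (dH2 %*% t(params$W2)))  # A is symmetric
  dH1 <- if (is.null(emb$dropout_mask)) dD1 else dD1 * emb$dropout_mask
  dpre1 <- dH1 * (emb$pre1 > 0)
  dW1 <- crossprod(emb$Z1, dpre1)
  db1 <- colSums(dpre1)
  dX0 <- as.matrix(A %*% (dpre1 %*% t(params$W1)))
  dW0 <- crossprod(Xp, dX0)
  db0 <- colSums(dX0)

  list(prob = as.numeric(head$prob),
       loss = bce_loss(as.numeric(head$prob), y),
       grads = list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    K1 = head$dK1, c1 = as.numeric(head$dc1), K2 = head$dK2,
                    c2 = as.numeric(head$dc2),
                    Wf = matrix(head$dWf, ncol = 1), bf = head$dbf))
}

#' Outer-product edge embedding
#'
#' `e(t,u)[i,j] = h_t[i] * h_u[j]` — a rank-1 `d x d` matrix that is
#' asymmetric in its arguments, which is how edge direction survives the
#' undirected message passing.
#'
#' @param h_t,h_u node embedding vectors of equal length.
#' @return A `length(h_t) x length(h_u)` matrix.
#' @export
edge_embedding <- function(h_t, h_u) {
  assert_that(length(h_t) == length(h_u), "embedding length mismatch")
  outer(h_t, h_u)
}

adam_step <- function(params, grads, state, cfg, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    g <- grads[[nm]] + cfg$weight_decay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the graph-convolutional edge classifier
#'
#' Minimizes binary cross-entropy over the labelled edge split with Adam
#' (full batch). Training stops early when validation loss has not improved
#' for `patience` epochs; the best-validation weights are returned together
#' with per-partition metrics (accuracy, precision, recall, F1 and AUC at
#' the default 0.5 threshold).
#'
#' @param graph a `reg_graph` from [build_graph()].
#' @param split an `edge_split` from [sample_negatives()].
#' @param cfg a [gcn_config()].
#' @return A `gcn_fit`; see [tidy.gcn_fit()] and [glance.gcn_fit()].
#' @export
train_gcn <- function(graph, split, cfg = gcn_config()) {
  for (prt in c("train", "val", "test")) {
    labs <- split$label[split$partition == prt]
    assert_that(length(unique(labs)) == 2L,
                paste0("partition '", prt, "' does not contain both classes"))
  }
  Xp <- pooled_features(graph, cfg)
  ti <- unname(graph$node_index[split$tf])
  ui <- unname(graph$node_index[split$target])
  is_tr <- split$partition == "train"
  is_va <- split$partition == "val"
  y_tr <- split$label[is_tr]
  y_va <- split$label[is_va]

  withr::with_seed(derive_seed(cfg$seed, "train"), {
    params <- init_params(cfg)
    state <- list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0))
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    history <- numeric(0)
    train_history <- numeric(0)
    for (epoch in seq_len(cfg$max_epochs)) {
      mask <- if (cfg$dropout > 0) {
        (matrix(stats::runif(length(graph$nodes) * cfg$hidden_dim),
                length(graph$nodes)) >= cfg$dropout) / (1 - cfg$dropout)
      } else NULL
      step <- gcn_step(params, graph$A, Xp, ti[is_tr], ui[is_tr], y_tr, cfg, mask)
      train_history <- c(train_history, step$loss)
      upd <- adam_step(params, step$grads, state, cfg, epoch)
      params <- upd$params
      state <- upd$state

      va <- gcn_forward(params, graph$A, Xp, ti[is_va], ui[is_va], cfg, NULL)
      val_loss <- bce_loss(va$prob, y_va)
      crit <- if (identical(cfg$select_metric %||% "loss", "auc")) {
        -rank_auc(va$prob, y_va)
      } else {
        val_loss
      }
      history <- c(history, val_loss)
      if (crit < best$loss - 1e-8) {
        best <- list(loss = crit, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  scores <- gcn_forward(best$params, graph$A, Xp, ti, ui, cfg, NULL)$prob
  split$gcn_score <- as.numeric(scores)
  metrics <- split |>
    group_by(.data$partition) |>
    summarise(classification_metrics(.data$gcn_score, .data$label), .groups = "drop")
  structure(list(params = best$params, cfg = cfg, split = split,
                 metrics = metrics, best_epoch = best$epoch,
                 val_history = history, train_history = train_history,
                 threshold = 0.5),
            class = "gcn_fit")
}

#' @export
#' @method print gcn_fit
print.gcn_fit <- function(x, ...) {
  te <- x$metrics |> filter(.data$partition == "test")
  cat(sprintf("<gcn_fit> best epoch %d; test AUC %.3f, F1 %.3f; threshold %.2f\n",
              x$best_epoch, te$auc, te$f1, x$threshold))
  invisible(x)
}

#' Classification metrics at a threshold
#' @param scores probabilities in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`, `auc`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(accuracy = mean(pred == (labels == 1)), precision = precision,
         recall = recall, f1 = f1, auc = rank_auc(scores, labels))
}

#' Score edges with a trained model
#'
#' @param fit a `gcn_fit`.
#' @param graph a `reg_graph` (the training graph or a new one).
#' @param edges edges to score (default: the graph's candidate edges).
#' @return Edge tibble with `gcn_score` and `predicted` (score at or above
#'   the fit's threshold).
#' @export
predict_edges <- function(fit, graph, edges = graph$edges) {
  Xp <- pooled_features(graph, fit$cfg)
  assert_that(ncol(Xp) == fit$cfg$feature_len, "feature_len mismatch with stored config")
  assert_that(ncol(fit$params$W0) == fit$cfg$hidden_dim, "stored weights inconsistent with config")
  ti <- unname(graph$node_index[edges$tf])
  ui <- unname(graph$node_index[edges$target])
  assert_that(!anyNA(ti) && !anyNA(ui), "edge endpoints missing from graph")
  prob <- gcn_forward(fit$params, graph$A, Xp, ti, ui, fit$cfg, NULL)$prob
  edges |> mutate(gcn_score = as.numeric(prob),
                  predicted = .data$gcn_score >= fit$threshold)
}

#' Apply a pre-trained model to a new dataset
#'
#' Because node features are pooled to the model's fixed `feature_len`,
#' a model trained on one dataset scores candidate edges of another —
#' even with a different sample count or a disjoint gene namespace
#' (features, not gene identity, drive prediction).
#'
#' @param model a `gcn_fit`.
#' @param new_graph a `reg_graph` built from the new dataset.
#' @param edges candidate edges of the new graph (default: all).
#' @return Scored edge tibble (`gcn_score`, `predicted`).
#' @export
transfer_predict <- function(model, new_graph, edges = new_graph$edges) {
  predict_edges(model, new_graph, edges)
}

#' Sweep the decision threshold and pick the highest one keeping F1 afloat
#'
#' Metrics are computed along `seq(grid_start, grid_end, grid_step)`; the
#' chosen threshold is the largest grid value whose F1 is at least
#' `f1_floor`. If no grid point reaches the floor the default 0.5 is
#' returned with a warning.
#'
#' @param scores probabilities in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param grid_start,grid_end,grid_step threshold grid (0.5 to 1 by 0.01).
#' @param f1_floor minimal acceptable F1 (default 0.8).
#' @return A `threshold_sweep` list: `threshold` and a `curves` tibble of
#'   metrics along the grid.
#' @export
threshold_postprocess <- function(scores, labels, grid_start = 0.5,
                                  grid_end = 1.0, grid_step = 0.01,
                                  f1_floor = 0.8) {
  assert_that(all(scores >= 0 & scores <= 1), "scores must be in [0,1]")
  grid <- seq(grid_start, grid_end, by = grid_step)
  curves <- purrr::map(grid, function(th) {
    classification_metrics(scores, labels, threshold = th) |>
      mutate(threshold = th, .before = 1)
  }) |> purrr::list_rbind()
  ok <- curves$threshold[curves$f1 >= f1_floor]
  if (length(ok) == 0) {
    rlang::warn("no grid threshold reaches the F1 floor; falling back to 0.5")
    chosen <- 0.5
  } else {
    chosen <- max(ok)
  }
  structure(list(threshold = chosen, curves = curves, f1_floor = f1_floor),
            class = "threshold_sweep")
}

#' Tidy a threshold sweep into its metric curves
#' @param x a `threshold_sweep`.
#' @param ... unused.
#' @return Tibble of metrics along the threshold grid.
#' @export
tidy.threshold_sweep <- function(x, ...) x$curves

#' One-row summary of a threshold sweep
#' @param x a `threshold_sweep`.
#' @param ... unused.
#' @return One-row tibble: chosen `threshold`, `f1_floor`, and the metrics
#'   at the chosen threshold.
#' @export
glance.threshold_sweep <- function(x, ...) {
  at <- x$curves[which.min(abs(x$curves$threshold - x$threshold)), ]
  at |> mutate(f1_floor = x$f1_floor)
}

#' Ablation experiments for the edge classifier
#'
#' `shuffle_graph` rewires the message-passing edges uniformly at random
#' (preserving edge count, no self-loops) so structure is destroyed while
#' features remain; `zero_features` zeroes every node feature so only
#' structure remains; `shuffle_labels` permutes the training labels as a
#' null calibration. The model is retrained under the given config.
#'
#' @param graph a `reg_graph`.
#' @param split an `edge_split`.
#' @param cfg a [gcn_config()].
#' @param mode one of `"shuffle_graph"`, `"zero_features"`, `"shuffle_labels"`.
#' @return A `gcn_fit` of the ablated model.
#' @export
ablate_gcn <- function(graph, split, cfg = gcn_config(),
                       mode = c("shuffle_graph", "zero_features", "shuffle_labels")) {
  mode <- match.arg(mode)
  withr::with_seed(derive_seed(cfg$seed, paste0("ablate_", mode)), {
    if (mode == "shuffle_graph") {
      n <- length(graph$nodes)
      m <- nrow(graph$edges)
      pairs <- integer(0)
      while (length(pairs) < m) {
        from <- sample.int(n, 2L * m, replace = TRUE)
        to <- sample.int(n, 2L * m, replace = TRUE)
        keep <- from != to
        pairs <- unique(c(pairs, (from[keep] - 1L) * n + to[keep]))
      }
      pairs <- pairs[seq_len(m)]  # exactly |E| distinct directed pairs
      from <- (pairs - 1L) %/% n + 1L
      to <- (pairs - 1L) %% n + 1L
      graph$A <- normalized_adjacency(from, to, n)
      graph$rewired <- tibble(from = graph$nodes[from], to = graph$nodes[to])
    } else if (mode == "zero_features") {
      graph$X <- graph$X * 0
    } else {
      split$label <- sample(split$label)
      for (prt in c("train", "val", "test")) {
        if (length(unique(split$label[split$partition == prt])) < 2L) {
          flip <- which(split$partition == prt)[1]
          split$label[flip] <- 1L - split$label[flip]
        }
      }
    }
  })
  fit <- train_gcn(graph, split, cfg)
  fit$ablation <- list(mode = mode, rewired = graph$rewired)
  fit
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted edge classifier into one row per labelled edge
#' @param x a `gcn_fit`.
#' @param ... unused.
#' @return Tibble: `tf`, `target`, `label`, `partition`, `gcn_score`.
#' @export
tidy.gcn_fit <- function(x, ...) {
  tibble::as_tibble(x$split)
}

#' One-row summary of a fitted edge classifier (test-set metrics)
#' @param x a `gcn_fit`.
#' @param ... unused.
#' @return One-row tibble of test metrics plus `best_epoch` and `threshold`.
#' @export
glance.gcn_fit <- function(x, ...) {
  x$metrics |> filter(.data$partition == "test") |>
    select(-"partition") |>
    mutate(best_epoch = x$best_epoch, threshold = x$threshold)
}
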