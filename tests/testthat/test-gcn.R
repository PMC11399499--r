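# a small trained fit shared across tests in this file
trained_small <- function() {
  memo("trained_small", {
    w <- simulate_world(strong_sim_config(n_tfs = 30, n_genes = 300,
                                          n_tissues = 2,
                                          samples_per_tissue = 15, seed = 45))
    ed <- w$truth$edges[, c("tf", "target")]
    g <- build_graph(ed, w$expr)
    sp <- sample_negatives(g, ed, seed = 1)
    cfg <- gcn_config(feature_len = 32, hidden_dim = 24, embed_dim = 12,
                      patience = 40, max_epochs = 250, seed = 1)
    list(world = w, graph = g, split = sp, cfg = cfg,
         fit = train_gcn(g, sp, cfg))
  })
}

# AUC over the held-out (val + test) edges, a steadier readout than the
# handful of test edges alone at this problem size
holdout_auc <- function(fit) {
  held <- fit$split[fit$split$partition != "train", ]
  regulonet:::rank_auc(held$gcn_score, held$label)
}

test_that("graphs are built from edge endpoints with duplicates collapsed", {
  ex <- random_expr(6, 8, seed = 1)
  edges <- tibble::tibble(tf = c("g001", "g001", "g002", "g001"),
                          target = c("g003", "g004", "g005", "g003"))
  g <- build_graph(edges, ex)
  expect_equal(length(g$nodes), 5)
  expect_equal(nrow(g$edges), 3)
  expect_error(build_graph(edges[0, ], ex), "empty edge set")

  # N(t) matches a brute-force adjacency scan
  for (t in unique(edges$tf)) {
    expect_setequal(graph_neighbors(g, t),
                    unique(edges$target[edges$tf == t]))
  }

  # normalized adjacency is symmetric with spectral radius <= 1
  withr::with_seed(12, {
    for (i in 1:20) {
      nn <- sample(4:12, 1)
      ee <- tibble::tibble(tf = sprintf("g%03d", sample(3, 6, TRUE)),
                           target = sprintf("g%03d", sample(4:nn, 6, TRUE))) |>
        dplyr::distinct()
      gg <- build_graph(ee, random_expr(12, 5, seed = i))
      Ad <- as.matrix(gg$A)
      expect_equal(Ad, t(Ad), tolerance = 1e-12)
      expect_lte(max(abs(eigen(Ad, only.values = TRUE)$values)), 1 + 1e-10)
    }
  })
})

test_that("negative sampling matches its counting contract", {
  ex <- random_expr(6, 8, seed = 2)
  edges <- tibble::tibble(tf = "g001", target = c("g002", "g003"))
  extra <- tibble::tibble(tf = "g002", target = c("g004", "g005", "g006"))
  g <- build_graph(dplyr::bind_rows(edges, extra), ex)
  sp <- sample_negatives(g, edges, seed = 1)
  neg <- sp[sp$label == 0, ]
  # |V| = 6, N(g001) = {g002, g003} -> 2 negatives from 3 eligible
  expect_equal(nrow(neg), 2)
  expect_true(all(neg$target %in% c("g004", "g005", "g006")))

  # a TF regulating all other nodes yields zero negatives, with a warning
  all_edges <- tibble::tibble(tf = "g001",
                              target = sprintf("g%03d", 2:6))
  g2 <- build_graph(all_edges, ex)
  expect_warning(sp2 <- sample_negatives(g2, all_edges, seed = 1),
                 "no eligible")
  expect_equal(sum(sp2$label == 0), 0)
})

test_that("negative sets avoid positives and keep parity on random graphs", {
  withr::with_seed(99, {
    for (i in 1:100) {
      n_tf <- sample(2:5, 1)
      n_g <- sample(8:16, 1)
      ee <- tibble::tibble(
        tf = sprintf("g%03d", sample(n_tf, 12, TRUE)),
        target = sprintf("g%03d", sample((n_tf + 1):n_g, 12, TRUE))) |>
        dplyr::distinct()
      gg <- build_graph(ee, random_expr(16, 4, seed = i))
      sp <- suppressWarnings(sample_negatives(gg, ee, seed = i))
      pos_keys <- paste(ee$tf, ee$target)
      neg <- sp[sp$label == 0, ]
      expect_false(any(paste(neg$tf, neg$target) %in% pos_keys))
      expect_false(any(neg$tf == neg$target))
      for (t in unique(ee$tf)) {
        eligible <- length(setdiff(gg$nodes, c(graph_neighbors(gg, t), t)))
        expect_equal(sum(neg$tf == t), min(sum(ee$tf == t), eligible))
      }
    }
  })
})

test_that("the 8:1:1 split is stratified within one edge per class", {
  w <- trained_small()
  sp <- w$split
  for (lab in 0:1) {
    counts <- table(sp$partition[sp$label == lab])
    n <- sum(counts)
    expect_lte(abs(counts[["val"]] - n / 10), 1)
    expect_lte(abs(counts[["test"]] - n / 10), 1)
  }
  expect_setequal(unique(sp$partition), c("train", "val", "test"))
})

test_that("adaptive pooling averages exactly and fixes the output length", {
  expect_equal(drop(reduce_features(matrix(1:4, 1), 2, log1p_scale = FALSE)),
               c(1.5, 3.5))
  expect_equal(drop(reduce_features(matrix(rep(7, 10), 1), 4, log1p_scale = FALSE)),
               rep(7, 4))
  # different sample counts pool to the same fixed length
  long <- reduce_features(matrix(rnorm(3400), 1), 256, log1p_scale = FALSE)
  short <- reduce_features(matrix(rnorm(833), 1), 256, log1p_scale = FALSE)
  expect_equal(ncol(long), 256)
  expect_equal(ncol(short), 256)
  # upsampling interpolates without padding
  up <- reduce_features(matrix(c(1, 2), 1), 4, log1p_scale = FALSE)
  expect_equal(drop(up), c(1, 1, 2, 2))
})

test_that("the rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    for (r in 1:5) {
      labels <- rbinom(60, 1, 0.4)
      if (length(unique(labels)) < 2) next
      scores <- runif(60) + 0.5 * labels
      expect_equal(regulonet:::rank_auc(scores, labels),
                   as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
                   tolerance = 1e-12)
    }
  })
})

test_that("edge embeddings are asymmetric outer products", {
  expect_equal(edge_embedding(c(1, 0), c(0, 1)),
               matrix(c(0, 0, 1, 0), 2, 2))
  h1 <- c(1, 2, 3); h2 <- c(-1, 0.5, 2)
  e12 <- edge_embedding(h1, h2)
  expect_false(isTRUE(all.equal(e12, edge_embedding(h2, h1))))
  expect_equal(norm(e12, "F"), sqrt(sum(h1^2)) * sqrt(sum(h2^2)))
  expect_error(edge_embedding(1:3, 1:4), "length mismatch")
})

test_that("analytic gradients match finite differences", {
  withr::with_seed(4, {
    n <- 9; S <- 6
    X <- matrix(rpois(n * S, 30), n, S,
                dimnames = list(paste0("g", 1:n), paste0("s", 1:S)))
    ed <- tibble::tibble(tf = c("g1", "g1", "g2", "g3"),
                         target = c("g3", "g4", "g5", "g6"))
    g <- build_graph(ed, tiny_expr(X))
    cfg <- gcn_config(feature_len = 4, hidden_dim = 3, embed_dim = 6,
                      dropout = 0, seed = 1)
    Xp <- regulonet:::pooled_features(g, cfg)
    params <- regulonet:::init_params(cfg)
    ti <- c(1L, 1L, 2L, 3L); ui <- c(3L, 4L, 5L, 6L); y <- c(1, 0, 1, 0)
    st <- regulonet:::gcn_step(params, g$A, Xp, ti, ui, y, cfg, NULL)
    loss_at <- function(p) {
      regulonet:::bce_loss(
        regulonet:::gcn_forward(p, g$A, Xp, ti, ui, cfg, NULL)$prob, y)
    }
    eps <- 1e-6
    for (nm in names(params)) {
      for (r in 1:2) {
        p2 <- params
        i <- sample(length(p2[[nm]]), 1)
        p2[[nm]][i] <- p2[[nm]][i] + eps
        num <- (loss_at(p2) - loss_at(params)) / eps
        expect_equal(st$grads[[nm]][i], num, tolerance = 5e-3,
                     label = paste("grad", nm))
      }
    }
  })
})

test_that("classifier outputs are probabilities and deterministic", {
  tw <- trained_small()
  fit <- tw$fit
  sc <- predict_edges(fit, tw$graph)
  expect_true(all(sc$gcn_score >= 0 & sc$gcn_score <= 1))
  sc2 <- predict_edges(fit, tw$graph)
  expect_identical(sc$gcn_score, sc2$gcn_score)
  # training-split scores reproduce bit-for-bit under the stored weights
  resc <- predict_edges(fit, tw$graph, fit$split[, c("tf", "target")])
  expect_identical(resc$gcn_score, fit$split$gcn_score)

  # a zero edge embedding with zero conv biases scores sigmoid of the
  # output bias (every rectifier sits at zero)
  cfg <- tw$cfg
  p0 <- regulonet:::init_params(cfg)
  p0$c1[] <- 0
  p0$c2[] <- 0
  z <- conv_head_cpp(matrix(0, 1, cfg$embed_dim), matrix(0, 1, cfg$embed_dim),
                     p0$K1, p0$c1, p0$K2, p0$c2, as.vector(p0$Wf), p0$bf,
                     0, FALSE)
  expect_equal(as.numeric(z$prob), regulonet:::sigmoid(as.numeric(p0$bf)))
})

test_that("training learns the planted network and stays reproducible", {
  tw <- trained_small()
  fit <- tw$fit
  expect_gt(holdout_auc(fit), 0.7)
  # net decrease of training loss over the first 10 epochs
  expect_lt(fit$train_history[10], fit$train_history[1])
  # determinism under a fixed seed
  fit2 <- train_gcn(tw$graph, tw$split, tw$cfg)
  expect_identical(fit$split$gcn_score, fit2$split$gcn_score)
  expect_identical(fit$best_epoch, fit2$best_epoch)

  # single-class partitions are rejected before training
  bad <- tw$split
  bad$label[bad$partition == "val"] <- 1L
  expect_error(train_gcn(tw$graph, bad, tw$cfg), "both classes")
})

test_that("tidy and glance summarize a fit the broom way", {
  fit <- trained_small()$fit
  td <- tidy(fit)
  expect_true(all(c("tf", "target", "label", "partition", "gcn_score") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("auc", "f1", "best_epoch", "threshold") %in% names(gl)))
})

test_that("threshold post-processing picks the highest F1-preserving cut", {
  scores <- c(0.95, 0.9, 0.85, 0.2, 0.1, 0.15)
  labels <- c(1, 1, 1, 0, 0, 0)
  sw <- threshold_postprocess(scores, labels)
  # at 0.90 recall drops to 2/3 but F1 = 0.8 still meets the floor
  expect_equal(sw$threshold, 0.90)
  expect_true(all(diff(sw$curves$recall) <= 1e-12))

  expect_warning(sw0 <- threshold_postprocess(rep(0.4, 6), labels),
                 "F1 floor")
  expect_equal(sw0$threshold, 0.5)

  # raising the cut to the swept threshold does not cost precision,
  # judged over all labelled edges (the validation slice alone is tiny)
  fit <- trained_small()$fit
  val <- fit$split[fit$split$partition == "val", ]
  sww <- suppressWarnings(threshold_postprocess(val$gcn_score, val$label))
  m_chosen <- classification_metrics(fit$split$gcn_score, fit$split$label,
                                     sww$threshold)
  m_half <- classification_metrics(fit$split$gcn_score, fit$split$label, 0.5)
  expect_gte(m_chosen$precision, m_half$precision)
})

test_that("transfer prediction works across datasets and namespaces", {
  tw <- trained_small()
  fit <- tw$fit
  # a second world with a different sample count and disjoint gene names
  w2 <- simulate_world(strong_sim_config(n_tfs = 8, n_genes = 100,
                                         n_tissues = 2,
                                         samples_per_tissue = 8, seed = 77))
  m2 <- unclass(w2$expr)
  rownames(m2) <- paste0("rice_", rownames(m2))
  ex2 <- tiny_expr(m2, unname(tissue_labels(w2$expr)))
  ed2 <- tibble::tibble(tf = paste0("rice_", w2$truth$edges$tf),
                        target = paste0("rice_", w2$truth$edges$target))
  g2 <- build_graph(ed2, ex2)
  sc <- transfer_predict(fit, g2)
  expect_equal(nrow(sc), nrow(ed2))
  expect_true(all(sc$gcn_score >= 0 & sc$gcn_score <= 1))

  # true edges of the sibling world outscore its sampled non-edges
  sp2 <- sample_negatives(g2, ed2, seed = 5)
  sc_all <- transfer_predict(fit, g2, sp2[, c("tf", "target")])
  auc <- regulonet:::rank_auc(sc_all$gcn_score, sp2$label)
  expect_gt(auc, 0.7)
})

test_that("ablations rewire, zero and shuffle as specified", {
  tw <- trained_small()
  full_auc <- holdout_auc(tw$fit)
  fit_sh <- ablate_gcn(tw$graph, tw$split, tw$cfg, mode = "shuffle_graph")
  # rewiring preserves the edge count exactly, with no self-loops
  expect_equal(nrow(fit_sh$ablation$rewired), nrow(tw$graph$edges))
  expect_false(any(fit_sh$ablation$rewired$from == fit_sh$ablation$rewired$to))
  expect_lt(holdout_auc(fit_sh), full_auc)

  fit_zf <- ablate_gcn(tw$graph, tw$split, tw$cfg, mode = "zero_features")
  expect_true(all(is.finite(glance(fit_zf)$auc)))

  fit_lab <- ablate_gcn(tw$graph, tw$split, tw$cfg, mode = "shuffle_labels")
  expect_lt(holdout_auc(fit_lab), full_auc)
})
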