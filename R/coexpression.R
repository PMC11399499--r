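#' Filter thresholds for the co-expression stage
#'
#' @param im_min minimum tree-ensemble importance kept (inclusive);
#'   default 0.005.
#' @param rho_min Spearman correlation threshold (strict, signed);
#'   default 0.03.
#' @param rho_absolute if `TRUE`, filter on `|rho|` instead of signed `rho`
#'   so repressive (negative) correlations are kept.
#' @return A `filter_config` list.
#' @export
filter_config <- function(im_min = 0.005, rho_min = 0.03, rho_absolute = FALSE) {
  assert_that(im_min >= 0, "im_min must be non-negative")
  structure(list(im_min = im_min, rho_min = rho_min, rho_absolute = rho_absolute),
            class = "filter_config")
}

log1p_cpm <- function(expr) {
  libsize <- colSums(expr)
  assert_that(all(libsize > 0), "sample with zero library size")
  log1p(sweep(unclass(expr), 2, libsize, "/") * 1e6)
}

#' Score candidate TF-to-target edges by tree-ensemble importance
#'
#' For every target gene a stochastic gradient-boosted tree ensemble
#' (50 trees, learning rate 0.1, subsample 0.9, early stopping on a 10%
#' holdout) regresses the target's log1p-CPM expression on all TF
#' expressions. The importance of TF `t` for target `u` is the total
#' split gain attributed to `t`, normalized to sum to one over TFs per
#' target; only pairs with positive importance are emitted.
#'
#' Targets with zero variance are skipped with a message (their importance
#' rows are simply absent).
#'
#' @param expr an `expr_matrix` (raw counts).
#' @param tf_ids character vector of TF gene ids, all present in `expr`.
#' @param targets genes to score (default: all genes).
#' @param n_trees,eta,subsample,holdout,early_stopping_rounds,max_depth
#'   ensemble hyperparameters; trees are shallow (depth 3) so that split
#'   gain concentrates on the strongest regulator rather than spreading
#'   across correlated TFs.
#' @param seed RNG seed controlling holdout splits and tree subsampling.
#' @return Edge tibble with columns `tf`, `target`, `importance`.
#' @export
importance_scores <- function(expr, tf_ids, targets = rownames(expr),
                              n_trees = 50, eta = 0.1, subsample = 0.9,
                              holdout = 0.1, early_stopping_rounds = 10,
                              max_depth = 3, seed = 1) {
  assert_that(all(tf_ids %in% rownames(expr)), "every tf_id must be present in expr")
  assert_that(ncol(expr) >= 2, "need at least 2 samples")
  E <- log1p_cpm(expr)
  n <- ncol(E)
  skipped <- character()
  rows <- withr::with_seed(derive_seed(seed, "importance"), {
    purrr::map(targets, function(tg) {
      if (stats::sd(expr[tg, ]) == 0) {
        skipped <<- c(skipped, tg)
        return(NULL)
      }
      y <- E[tg, ]
      feats <- setdiff(tf_ids, tg)
      X <- t(E[feats, , drop = FALSE])
      if (ncol(X) < 2) {
        # a constant pad column; never split on, so it draws no importance
        X <- cbind(X, `..const` = 0)
      }
      n_hold <- max(1L, round(holdout * n))
      hold <- sample.int(n, n_hold)
      dtrain <- xgboost::xgb.DMatrix(X[-hold, , drop = FALSE], label = y[-hold])
      dvalid <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE], label = y[hold])
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = eta,
                      subsample = subsample, max_depth = max_depth, nthread = 1,
                      seed = sample.int(.Machine$integer.max, 1)),
        data = dtrain, nrounds = n_trees,
        evals = list(valid = dvalid),
        early_stopping_rounds = early_stopping_rounds, verbose = 0)
      imp <- xgboost::xgb.importance(model = fit)
      if (is.null(imp)) return(NULL)
      imp <- imp[imp$Feature %in% feats, , drop = FALSE]
      if (nrow(imp) == 0) return(NULL)
      gain <- imp$Gain / sum(imp$Gain)
      tibble(tf = imp$Feature, target = tg, importance = gain)
    })
  })
  if (length(skipped)) {
    rlang::inform(paste0("skipped zero-variance target(s): ",
                         paste(utils::head(skipped, 5), collapse = ", "),
                         if (length(skipped) > 5) " ..."))
  }
  purrr::list_rbind(rows) |>
    empty_as(tibble(tf = character(), target = character(), importance = double()))
}

#' Keep edges whose importance clears the threshold
#'
#' Inclusive rule: rows with `importance >= im_min` survive, input order
#' preserved.
#'
#' @param edges edge tibble with an `importance` column.
#' @param cfg a [filter_config()].
#' @return Filtered edge tibble.
#' @export
filter_importance <- function(edges, cfg = filter_config()) {
  assert_that("importance" %in% names(edges), "edges must carry 'importance'")
  edges |> filter(.data$importance >= cfg$im_min)
}

#' Filter edges by pooled Spearman correlation
#'
#' The tie-corrected Spearman rank correlation between TF and target is
#' computed over all samples pooled; rows with `rho > rho_min` survive
#' (strict, signed by default — negative, repressive correlations are
#' discarded; set `rho_absolute` in the config to filter on `|rho|`).
#' Edges involving a constant gene have undefined correlation and are
#' dropped with a message.
#'
#' @param edges edge tibble.
#' @param expr an `expr_matrix` containing every gene in `edges`.
#' @param cfg a [filter_config()].
#' @return Edge tibble with a populated `spearman_rho` column.
#' @export
spearman_filter <- function(edges, expr, cfg = filter_config()) {
  genes <- unique(c(edges$tf, edges$target))
  assert_that(all(genes %in% rownames(expr)), "all edge genes must be in expr")
  R <- t(apply(unclass(expr)[genes, , drop = FALSE], 1, rank))
  Rc <- R - rowMeans(R)
  ss <- sqrt(rowSums(Rc^2))
  rho <- rowSums(Rc[edges$tf, , drop = FALSE] * Rc[edges$target, , drop = FALSE]) /
    (ss[edges$tf] * ss[edges$target])
  edges$spearman_rho <- as.numeric(rho)
  n_const <- sum(is.na(edges$spearman_rho))
  if (n_const > 0) {
    rlang::inform(sprintf("dropped %d edge(s) with undefined correlation (constant gene)",
                          n_const))
  }
  crit <- if (isTRUE(cfg$rho_absolute)) abs(edges$spearman_rho) else edges$spearman_rho
  edges |> filter(!is.na(.data$spearman_rho) & crit > cfg$rho_min)
}
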