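#' Log counts per million
#'
#' `log2((count + 0.5) / (libsize + 1) * 1e6)` — the standard offset form
#' that keeps zeros finite and is suitable for linear modelling.
#'
#' @param expr an `expr_matrix` (raw counts) or a plain count matrix.
#' @return Numeric matrix of log2-CPM values, same dimensions.
#' @export
logcpm <- function(expr) {
  counts <- unclass(expr)
  libsize <- colSums(counts)
  assert_that(all(libsize > 0), "sample with zero library size")
  log2(sweep(counts + 0.5, 2, libsize + 1, "/") * 1e6)
}

#' Precision weights from the mean-variance trend
#'
#' Fits a per-gene linear model under `design`, lowess-smooths
#' `sqrt(residual SD)` against average log-count, predicts the trend at
#' every observation's fitted log-count, and returns `trend^(-4)` as the
#' observation weight (clipped to `[1e-6, 1e6]`). Count data have variance
#' decreasing with the mean on the log scale, so low-count observations
#' are down-weighted in the fit.
#'
#' @param E log-CPM matrix from [logcpm()].
#' @param design model matrix (samples x coefficients).
#' @param libsize library sizes used to translate log-CPM back to
#'   log-counts for the trend x-axis.
#' @param span lowess span (default 0.5).
#' @return Weight matrix, same dimensions as `E`.
#' @export
voom_weights <- function(E, design, libsize, span = 0.5) {
  n <- ncol(E)
  p <- qr(design)$rank
  assert_that(n - p >= 1, "fewer than 1 residual degree of freedom")
  fit <- stats::lm.fit(design, t(E))
  resid_sd <- sqrt(colSums(fit$residuals^2) / (n - p))
  fitted_vals <- t(fit$fitted.values)
  # x-axis: average log2-count; shift log-CPM by the (log) typical libsize
  shift <- mean(log2(libsize + 1)) - log2(1e6)
  xbar <- rowMeans(E) + shift
  lo <- stats::lowess(xbar, sqrt(resid_sd), f = span)
  trend <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_vals) + shift,
                         rule = 2)$y
  w <- matrix(trend, nrow(E), n)^(-4)
  pmin(pmax(w, 1e-6), 1e6)
}

# inverse of trigamma by Newton iteration (monotone decreasing function)
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

#' Weighted per-gene contrasts with empirical-Bayes moderation
#'
#' Fits a weighted least-squares group-means model per gene, forms for each
#' tissue the contrast `tissue mean - mean of the other tissue means`, and
#' moderates the residual variances empirically: prior degrees of freedom
#' and prior variance are estimated by method of moments on the
#' log residual variances, each gene's posterior variance is the
#' df-weighted convex combination of its own and the prior, and the
#' moderated t gains the prior degrees of freedom.
#'
#' @param E log-CPM matrix.
#' @param weights observation weight matrix from [voom_weights()].
#' @param tissue_labels character vector of tissues, one per sample.
#' @return Tibble: `gene_id`, `contrast` (the tissue), `logFC`,
#'   `moderated_t`, `pvalue`, `fdr` (Benjamini-Hochberg within contrast).
#' @export
fit_contrasts <- function(E, weights, tissue_labels) {
  tissues <- sort(unique(tissue_labels))
  k <- length(tissues)
  assert_that(k >= 2, "need at least 2 tissues")
  design <- stats::model.matrix(~ 0 + factor(tissue_labels, levels = tissues))
  colnames(design) <- tissues
  assert_that(qr(design)$rank == k, "singular design")
  n <- ncol(E)
  df_resid <- n - k

  G <- nrow(E)
  beta <- matrix(NA_real_, G, k)
  unscaled <- matrix(NA_real_, G, k)  # c' (X'WX)^-1 c per contrast
  s2 <- numeric(G)
  contrasts <- sapply(seq_len(k), function(j) {
    cvec <- rep(-1 / (k - 1), k)
    cvec[j] <- 1
    cvec
  })
  for (g in seq_len(G)) {
    w <- weights[g, ]
    xtwx <- crossprod(design * w, design)
    xtwy <- crossprod(design * w, E[g, ])
    V <- solve(xtwx)
    b <- drop(V %*% xtwy)
    res <- E[g, ] - drop(design %*% b)
    s2[g] <- sum(w * res^2) / df_resid
    beta[g, ] <- b
    unscaled[g, ] <- diag(t(contrasts) %*% V %*% contrasts)
  }

  # method-of-moments moderation on log variances
  ok <- s2 > 0
  z <- log(s2[ok])
  var_z <- stats::var(z)
  expected_var <- trigamma(df_resid / 2)
  if (is.finite(var_z) && var_z > expected_var) {
    df_prior <- 2 * trigamma_inverse(var_z - expected_var)
    s0_log <- mean(z) - digamma(df_resid / 2) + log(df_resid / 2) +
      digamma(df_prior / 2) - log(df_prior / 2)
    s0_2 <- exp(s0_log)
    s2_post <- (df_prior * s0_2 + df_resid * s2) / (df_prior + df_resid)
    df_total <- df_prior + df_resid
  } else {
    s0_2 <- exp(mean(z) - digamma(df_resid / 2) + log(df_resid / 2))
    s2_post <- rep(s0_2, G)
    df_total <- Inf
  }

  lfc <- beta %*% contrasts
  se <- sqrt(unscaled * s2_post)
  tstat <- lfc / se
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- purrr::map(seq_len(k), function(j) {
    tibble(gene_id = rownames(E), contrast = tissues[j],
           logFC = lfc[, j], moderated_t = tstat[, j], pvalue = pval[, j],
           fdr = stats::p.adjust(pval[, j], method = "BH"))
  }) |> purrr::list_rbind()
  attr(out, "moderation") <- list(s2 = s2, s2_post = s2_post, s0_2 = s0_2,
                                  df_prior = df_total - df_resid,
                                  df_resid = df_resid)
  out
}

#' Call upregulated tissue DEGs
#'
#' A gene is a DEG of a tissue when its BH-adjusted FDR is below `fdr_max`
#' AND its log2 fold change exceeds `lfc_min` — upregulated genes only, as
#' tissue identity is defined by what a tissue switches on.
#'
#' @param results tibble from [fit_contrasts()].
#' @param fdr_max FDR cutoff (default 0.01).
#' @param lfc_min log2-fold-change cutoff (default 1).
#' @return Tibble `tissue`, `gene_id`.
#' @export
call_degs <- function(results, fdr_max = 0.01, lfc_min = 1.0) {
  results |>
    filter(.data$fdr < fdr_max, .data$logFC > lfc_min) |>
    transmute(tissue = .data$contrast, .data$gene_id)
}

#' Convenience wrapper: counts to DE results
#'
#' @param expr an `expr_matrix`.
#' @param span lowess span for the mean-variance trend.
#' @return Tibble as from [fit_contrasts()].
#' @export
de_tissues <- function(expr, span = 0.5) {
  E <- logcpm(expr)
  labels <- unname(tissue_labels(expr))
  design <- stats::model.matrix(~ 0 + factor(labels))
  W <- voom_weights(E, design, colSums(unclass(expr)), span = span)
  fit_contrasts(E, W, labels)
}

#' Assemble tissue-specific regulons from DEGs and predicted edges
#'
#' For each tissue, `regulon(TF) = { u : (TF, u) predicted, TF and u both
#' DEGs of the tissue }`; empty regulons are dropped. The same TF can
#' appear in several tissues with different target sets.
#'
#' @param degs tibble (`tissue`, `gene_id`) from [call_degs()].
#' @param predicted_edges edge tibble with a logical `predicted` column
#'   (e.g. from [predict_edges()]).
#' @return A `regulon_set`: tibble `tissue`, `tf`, `target` plus any edge
#'   annotation columns (e.g. `gcn_score`).
#' @export
assemble_regulons <- function(degs, predicted_edges) {
  pred <- predicted_edges |> filter(.data$predicted %in% TRUE)
  out <- purrr::map(unique(degs$tissue), function(ts) {
    dg <- degs$gene_id[degs$tissue == ts]
    pred |>
      filter(.data$tf %in% dg, .data$target %in% dg) |>
      mutate(tissue = ts, .before = 1)
  }) |> purrr::list_rbind() |>
    empty_as(tibble(tissue = character(), tf = character(), target = character()))
  class(out) <- c("regulon_set", class(out))
  out
}
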