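# shared fixtures and independent oracles, built in code at test time

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a small but complete world: enough edges to train on, quick to simulate
small_world <- function() {
  memo("small_world", simulate_world(strong_sim_config(
    n_tfs = 12, n_genes = 150, n_tissues = 2, samples_per_tissue = 12, seed = 42)))
}

# tiny expression matrix built by hand
tiny_expr <- function(counts, tissues = NULL) {
  if (is.null(tissues)) tissues <- rep("t1", ncol(counts))
  expression_matrix(counts, stats::setNames(tissues, colnames(counts)))
}

random_expr <- function(n_genes, n_samples, seed = 1, tissues = NULL) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 10),
                n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    tiny_expr(m, tissues)
  })
}

# --- independent oracles -----------------------------------------------------

# Spearman via explicit rank-then-Pearson
bf_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Benjamini-Hochberg by the textbook algorithm
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive PWM score distribution over all 4^L words
bf_pwm_survival <- function(kmat, bg) {
  L <- ncol(kmat)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- integer(nrow(words))
  probs <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    scores[i] <- sum(kmat[cbind(words[i, ], seq_len(L))])
    probs[i] <- prod(bg[words[i, ]])
  }
  function(s) sum(probs[scores >= s])
}

# all-pairs shortest paths and path counts by BFS enumeration (unweighted)
bf_shortest_paths <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  SIG <- matrix(0, n, n)  # number of shortest paths
  for (s in seq_len(n)) {
    D[s, s] <- 0
    SIG[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (is.infinite(D[s, w])) {
            D[s, w] <- D[s, v] + 1
            nxt <- c(nxt, w)
          }
          if (D[s, w] == D[s, v] + 1) SIG[s, w] <- SIG[s, w] + SIG[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(D = D, SIG = SIG)
}

# directed betweenness by explicit pair enumeration
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  sp <- bf_shortest_paths(adj)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (is.finite(sp$D[s, t]) && sp$D[s, v] + sp$D[v, t] == sp$D[s, t]) {
          btw[v] <- btw[v] + sp$SIG[s, v] * sp$SIG[v, t] / sp$SIG[s, t]
        }
      }
    }
  }
  btw
}

# Wasserman-Faust out-closeness from the distance matrix
bf_closeness <- function(adj) {
  n <- nrow(adj)
  sp <- bf_shortest_paths(adj)
  vapply(seq_len(n), function(u) {
    d <- sp$D[u, -u]
    reach <- d[is.finite(d)]
    r <- length(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, 0)
}

# hypergeometric upper tail by direct summation of binomial coefficients
bf_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, 0))
}
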