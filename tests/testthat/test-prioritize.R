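toy_regulons <- function() {
  reg <- tibble::tibble(
    tissue = "root",
    tf = c("tfA", "tfA", "tfA", "tfB", "tfB"),
    target = c("g1", "g2", "g3", "g1", "g4"))
  class(reg) <- c("regulon_set", class(reg))
  reg
}

test_that("the regulon network mirrors the regulon listing", {
  g <- regulon_network(toy_regulons(), "root")
  expect_equal(igraph::vcount(g), 6)  # tfA, tfB, g1..g4
  expect_equal(igraph::degree(g, "g1", mode = "in"), c(g1 = 2))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  reg <- toy_regulons()
  for (i in seq_len(nrow(reg))) {
    expect_equal(adj[reg$tf[i], reg$target[i]], 1)
  }
  expect_equal(sum(adj), nrow(reg))
  expect_error(regulon_network(toy_regulons(), "shoot"), "no regulons")
})

test_that("centralities match hand-derived values on stars and paths", {
  star <- tibble::tibble(tissue = "t", tf = "hub", target = c("a", "b", "c"))
  class(star) <- c("regulon_set", class(star))
  cs <- centrality_scores(regulon_network(star, "t"))
  expect_equal(cs$out_degree[cs$tf == "hub"], 3)

  path <- igraph::graph_from_data_frame(
    tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  cp <- centrality_scores(path, tfs = c("a", "b", "c"))
  expect_equal(cp$betweenness, c(0, 1, 0))
  # a reaches {b, c} with d = 1, 2: closeness (2/2) * (2/3)
  expect_equal(cp$closeness[cp$tf == "a"], (2 / 2) * (2 / 3))
  expect_equal(cp$closeness[cp$tf == "c"], 0)
})

test_that("centralities agree with brute-force enumeration on random digraphs", {
  withr::with_seed(41, {
    for (rep in 1:200) {
      n <- sample(3:8, 1)
      adj <- matrix(rbinom(n * n, 1, 0.3), n, n)
      diag(adj) <- 0
      if (sum(adj) == 0) next
      ids <- sprintf("n%d", seq_len(n))
      dimnames(adj) <- list(ids, ids)
      ed <- which(adj == 1, arr.ind = TRUE)
      g <- igraph::graph_from_data_frame(
        tibble::tibble(from = ids[ed[, 1]], to = ids[ed[, 2]]),
        vertices = ids)
      cs <- centrality_scores(g, tfs = ids)
      expect_equal(cs$out_degree, unname(rowSums(adj)))
      expect_equal(cs$betweenness, bf_betweenness(adj), tolerance = 1e-10)
      expect_equal(cs$closeness, bf_closeness(adj), tolerance = 1e-12)
    }
  })
})

test_that("GO specificity is the hypergeometric tail", {
  # N = 100, K = 10, n = 5, k = 3 by direct summation
  p_direct <- bf_hyper_tail(3, 10, 100, 5)
  expect_equal(p_direct, 499752 / 75287520, tolerance = 1e-12)

  reg <- tibble::tibble(tissue = "root", tf = "tfA",
                        target = sprintf("g%03d", 1:5))
  class(reg) <- c("regulon_set", class(reg))
  universe <- c(sprintf("g%03d", 1:99), "tfA")
  gold <- list(root = c(sprintf("g%03d", c(1, 2, 3)), sprintf("x%d", 1:20),
                        sprintf("g%03d", 50:56)))
  # gold within universe: g001..g003 + g050..g056 = 10 genes, overlap k = 3
  sc <- go_specificity(reg, "root", gold, universe)
  expect_equal(sc$go_score, -log10(p_direct), tolerance = 1e-10)

  # zero overlap scores zero
  gold0 <- list(root = sprintf("g%03d", 90:99))
  sc0 <- go_specificity(reg, "root", gold0, universe)
  expect_equal(sc0$go_score, 0)

  # monotone in the overlap
  ks <- vapply(0:5, function(k) bf_hyper_tail(max(k, 0), 10, 100, 5), 0)
  expect_true(all(diff(-log10(ks[-1])) >= 0))

  expect_error(go_specificity(reg, "root", list(root = character()), universe),
               "empty gold set")
})

test_that("ranks average ties and survive affine transforms", {
  expect_equal(rank_metrics(c(10, 5, 10)), c(1.5, 3, 1.5))
  expect_equal(rank_metrics(c(9, 7, 5)), c(1, 2, 3))
  withr::with_seed(3, {
    x <- rnorm(20)
    expect_equal(rank_metrics(x), rank_metrics(3 * x + 7))
  })
})

test_that("Borda combination is the geometric mean of ranks", {
  rk <- tibble::tibble(m1 = c(4, 1), m2 = c(2, 1), m3 = c(1, 1), m4 = c(5, 1))
  b <- borda_combine(rk)
  expect_equal(b$borda_geomean[1], 40^(1 / 4), tolerance = 1e-12)
  expect_equal(b$borda_geomean[2], 1)
  expect_equal(b$final_rank, c(2, 1))
  expect_error(borda_combine(tibble::tibble(m1 = c(0, 1))), "positive")

  # permuting rows permutes the output consistently
  rk3 <- tibble::tibble(m1 = c(3, 1, 2), m2 = c(2, 1, 3),
                        m3 = c(3, 2, 1), m4 = c(1, 2, 3))
  b3 <- borda_combine(rk3)
  perm <- c(2, 3, 1)
  expect_equal(borda_combine(rk3[perm, ])$borda_geomean, b3$borda_geomean[perm])
})

test_that("Borda order is invariant to monotone re-scoring of metrics", {
  withr::with_seed(8, {
    scores <- tibble::tibble(a = runif(10), b = runif(10),
                             c = runif(10), d = runif(10))
    rk1 <- dplyr::mutate(scores, dplyr::across(dplyr::everything(), rank_metrics))
    rescored <- dplyr::mutate(scores, a = exp(a), b = 10 * b + 3,
                              c = c^3, d = atan(d))
    rk2 <- dplyr::mutate(rescored, dplyr::across(dplyr::everything(), rank_metrics))
    expect_equal(borda_combine(rk1)$final_rank, borda_combine(rk2)$final_rank)
  })
})

test_that("R50 retrieval curves count gold hits", {
  gold <- list(root = c("A", "B"))
  r <- r50_curve(c("C", "A", "D", "B"), gold, "root")
  expect_equal(r$curve$hits, c(0, 1, 1, 2))
  expect_equal(r$r50, 2)

  # gold at the very top retrieves half immediately
  gold2 <- list(root = c("A", "B", "C", "D"))
  r2 <- r50_curve(c("A", "B", "C", "D", "E"), gold2, "root")
  expect_equal(r2$r50, 2)

  r3 <- r50_curve(c("X", "Y"), gold, "root")
  expect_true(is.na(r3$r50))
  expect_true(all(diff(r3$curve$hits) >= 0))
  expect_lte(max(r3$curve$hits), length(gold$root))
})

test_that("rank-table summaries reproduce mean and sample SD", {
  tbl <- tibble::tibble(tissue = c("a", "b", "c", "d", "e"),
                        out_deg = c(4, 4, 3, 5, 5),
                        closeness = c(2, 3, 4, 1, 1))
  s <- rank_table_summary(tbl)
  expect_equal(s$mean, c(4.2, 2.2))
  expect_equal(round(s$sd, 2), c(0.84, 1.30))
  expect_equal(rank_table_summary(tibble::tibble(m = rep(3, 4)))$sd, 0)
  expect_true(is.na(rank_table_summary(tibble::tibble(m = 3))$sd))
})

test_that("the GO gold standard honours keywords and evidence codes", {
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    term_name = c("root development", "Root hair elongation",
                  "root morphogenesis", "flower development"),
    evidence = c("IDA", "IEA", "TAS", "IMP"))
  gold <- build_go_gold_standard(ann)
  expect_setequal(gold$root, c("g1", "g3"))  # g2 is IEA, g4 no keyword match
  expect_setequal(gold$flower, "g4")
  expect_equal(length(gold$seed), 0)
  expect_error(build_go_gold_standard(ann, keywords = list()), "empty keyword")
})

test_that("prioritization produces a full rank table", {
  w <- small_world()
  # build regulons directly from the ground truth for a deterministic table
  ed <- w$truth$edges |> tidyr::unnest(tissues)
  reg <- tibble::tibble(tissue = ed$tissues, tf = ed$tf, target = ed$target)
  class(reg) <- c("regulon_set", class(reg))
  ts <- reg$tissue[1]
  universe <- w$truth$genes$gene_id
  gold <- list(stats::setNames(list(unique(reg$tf[reg$tissue == ts])), ts))[[1]]
  rt <- prioritize_regulons(reg, ts, gold, universe)
  expect_true(all(c("out_degree", "closeness", "betweenness", "go_score",
                    "borda_geomean", "final_rank") %in% names(rt)))
  expect_equal(sort(rt$final_rank), sort(rank(rt$borda_geomean, ties.method = "average")))
  r50 <- r50_curve(rt, gold, ts)
  expect_false(is.na(r50$r50))
})
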