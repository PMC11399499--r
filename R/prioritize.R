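#' Directed regulatory network of one tissue's regulons
#'
#' @param regulons a `regulon_set` from [assemble_regulons()].
#' @param tissue tissue name present in the set.
#' @return An [igraph] directed graph with TF to target edges.
#' @export
regulon_network <- function(regulons, tissue) {
  sub <- regulons |> filter(.data$tissue == !!tissue)
  assert_that(nrow(sub) > 0, paste0("no regulons for tissue '", tissue, "'"))
  igraph::graph_from_data_frame(sub |> select("tf", "target"), directed = TRUE)
}

#' Out-degree, closeness and betweenness per TF
#'
#' Closeness uses outgoing shortest paths with the Wasserman-Faust
#' correction for disconnected graphs:
#' `(r / (n - 1)) * (r / total distance)` where `r` is the number of nodes
#' reachable from the TF. Betweenness is standard directed shortest-path
#' betweenness, unnormalized.
#'
#' @param graph directed igraph, e.g. from [regulon_network()].
#' @param tfs nodes to report (default: all nodes with out-degree > 0).
#' @return Tibble: `tf`, `out_degree`, `closeness`, `betweenness`.
#' @export
centrality_scores <- function(graph, tfs = NULL) {
  assert_that(igraph::vcount(graph) > 0, "empty graph")
  vs <- igraph::V(graph)$name
  if (is.null(tfs)) tfs <- vs[igraph::degree(graph, mode = "out") > 0]
  n <- length(vs)
  D <- igraph::distances(graph, v = tfs, mode = "out")
  closeness <- vapply(seq_along(tfs), function(i) {
    d <- D[i, setdiff(vs, tfs[i])]
    reach <- d[is.finite(d)]
    r <- length(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, 0)
  btw <- igraph::betweenness(graph, v = tfs, directed = TRUE, normalized = FALSE)
  tibble(tf = tfs,
         out_degree = as.numeric(igraph::degree(graph, v = tfs, mode = "out")),
         closeness = closeness,
         betweenness = as.numeric(btw))
}

#' GO functional specificity of a regulon
#'
#' One-sided hypergeometric enrichment of the regulon's target set against
#' the tissue's gold-standard gene set within a gene universe:
#' `p = P(X >= k)` for `k` overlaps among `n` targets, `K` tissue genes,
#' universe size `N`; the score is `-log10 p`.
#'
#' @param regulons a `regulon_set`.
#' @param tissue tissue name.
#' @param gold a named list of tissue gene sets (see
#'   [build_go_gold_standard()]).
#' @param universe character vector of all considered genes (must contain
#'   every regulon gene).
#' @return Tibble: `tf`, `go_score`.
#' @export
go_specificity <- function(regulons, tissue, gold, universe) {
  gold_set <- intersect(gold[[tissue]], universe)
  assert_that(length(gold_set) > 0,
              paste0("empty gold set for tissue '", tissue, "'"))
  sub <- regulons |> filter(.data$tissue == !!tissue)
  genes <- unique(c(sub$tf, sub$target))
  assert_that(all(genes %in% universe), "universe must contain every regulon gene")
  N <- length(universe)
  K <- length(gold_set)
  sub |>
    group_by(tf = .data$tf) |>
    summarise(n_tg = dplyr::n_distinct(.data$target),
              k = dplyr::n_distinct(intersect(.data$target, gold_set)),
              .groups = "drop") |>
    mutate(pvalue = stats::phyper(.data$k - 1, K, N - K, .data$n_tg,
                                  lower.tail = FALSE),
           go_score = -log10(.data$pvalue)) |>
    select("tf", "go_score")
}

#' Ranks from scores, best first, ties averaged
#'
#' Descending scores map to ascending ranks starting at 1; tied scores
#' receive the average of the rank positions they span.
#'
#' @param scores numeric vector.
#' @return Numeric rank vector.
#' @export
rank_metrics <- function(scores) {
  rank(-scores, ties.method = "average")
}

#' Borda combination of per-metric ranks
#'
#' The Borda score of a regulon is the geometric mean of its ranks across
#' metrics; the final order ascends in that geometric mean, ties averaged.
#'
#' @param rank_df data frame whose columns are per-metric rank vectors
#'   (all ranks positive).
#' @return Tibble: `borda_geomean`, `final_rank`.
#' @export
borda_combine <- function(rank_df) {
  m <- as.matrix(rank_df)
  assert_that(all(m > 0), "ranks must be positive")
  gm <- apply(m, 1, geomean)
  tibble(borda_geomean = gm, final_rank = rank(gm, ties.method = "average"))
}

#' Rank one tissue's regulons by four metrics plus Borda
#'
#' Computes out-degree, closeness, betweenness and GO specificity for
#' every regulon TF of the tissue, ranks each metric (best = 1, ties
#' averaged) and combines the four ranks by Borda geometric mean.
#'
#' @param regulons a `regulon_set`.
#' @param tissue tissue name.
#' @param gold named list of tissue gold-standard gene sets.
#' @param universe gene universe for the enrichment test.
#' @return A `rank_table` tibble: raw metric scores, per-metric ranks,
#'   `borda_geomean` and `final_rank`.
#' @export
prioritize_regulons <- function(regulons, tissue, gold, universe) {
  g <- regulon_network(regulons, tissue)
  cent <- centrality_scores(g)
  go <- go_specificity(regulons, tissue, gold, universe)
  tbl <- cent |>
    inner_join(go, by = "tf") |>
    mutate(rank_out_degree = rank_metrics(.data$out_degree),
           rank_closeness = rank_metrics(.data$closeness),
           rank_betweenness = rank_metrics(.data$betweenness),
           rank_go = rank_metrics(.data$go_score))
  tbl <- bind_cols(tbl, borda_combine(tbl |> select(dplyr::starts_with("rank_")))) |>
    arrange(.data$final_rank)
  class(tbl) <- c("rank_table", class(tbl))
  tbl
}

#' Retrieval curve and R50 of a ranking against a gold standard
#'
#' `curve(k)` counts gold-standard TFs among the top `k` of the ranking;
#' R50 is the smallest depth at which half (rounded up) of the gold set is
#' retrieved, or `NA` if the ranking never reaches it.
#'
#' @param ranking character vector of TFs, best first (or a `rank_table`,
#'   whose `final_rank` order is used).
#' @param gold named list of tissue gene sets.
#' @param tissue tissue name.
#' @return List: `curve` (tibble `k`, `hits`) and `r50`.
#' @export
r50_curve <- function(ranking, gold, tissue) {
  if (inherits(ranking, "rank_table")) {
    ranking <- ranking$tf[order(ranking$final_rank)]
  }
  gold_set <- gold[[tissue]]
  assert_that(length(gold_set) > 0, "gold set is empty")
  hits <- cumsum(ranking %in% gold_set)
  need <- ceiling(length(gold_set) / 2)
  r50 <- if (any(hits >= need)) min(which(hits >= need)) else NA_integer_
  list(curve = tibble(k = seq_along(ranking), hits = hits), r50 = r50)
}

#' Column means and sample SDs of a tissue-by-metric rank table
#'
#' @param table data frame of per-tissue metric ranks (one row per tissue,
#'   one column per metric; non-numeric columns such as a tissue name are
#'   ignored).
#' @return Tibble: `metric`, `mean`, `sd` (sample SD, n-1 denominator;
#'   `NA` for a single row).
#' @export
rank_table_summary <- function(table) {
  num <- tibble::as_tibble(table)[vapply(table, is.numeric, TRUE)]
  assert_that(ncol(num) > 0, "no numeric metric columns")
  tibble(metric = names(num),
         mean = unname(purrr::map_dbl(num, mean)),
         sd = unname(purrr::map_dbl(num, ~ if (length(.x) > 1) stats::sd(.x) else NA_real_)))
}

#' Tissue keyword sets for the GO gold standard
#'
#' The default per-tissue keyword lists used to pull tissue-associated
#' genes out of a GO annotation table.
#'
#' @return Named list of character vectors.
#' @export
default_tissue_keywords <- function() {
  list(
    flower = c("flower", "floral", "inflorescence", "anther", "stamen",
               "pistil", "carpel", "petal", "sepal", "pollen", "pollination",
               "fertilization"),
    leaf = c("leaf", "foliage", "photosynthesis", "chloroplast", "stomata",
             "mesophyll", "cuticle"),
    root = c("root", "xylem", "phloem", "vascular", "trichoblast", "trichome",
             "vasculature", "stele", "tracheary", "procambium", "sieve"),
    seed = c("seed", "embryo", "endosperm", "aleurone", "maturation", "testa",
             "embryogenesis"),
    seedling = c("seedling", "cotyledon", "hypocotyl", "epicotyl",
                 "germination", "plumule", "radicle", "shoot"))
}

go_evidence_whitelist <- c("EXP", "IMP", "IDA", "IPI", "IGI", "IEP",
                          "TAS", "NAS", "IC")

#' Build a tissue gold standard from GO annotations
#'
#' A gene enters a tissue's gold set when it carries at least one
#' annotation whose term name matches any of the tissue's keywords
#' (case-insensitive substring) AND whose evidence code is experimental or
#' curated (EXP, IMP, IDA, IPI, IGI, IEP, TAS, NAS, IC); electronically
#' inferred annotations (IEA) are excluded.
#'
#' @param annotations tibble with columns `gene_id`, `term_name`,
#'   `evidence`.
#' @param keywords named list of keyword vectors per tissue (default
#'   [default_tissue_keywords()]).
#' @return Named list of character gene-id vectors.
#' @export
build_go_gold_standard <- function(annotations, keywords = default_tissue_keywords()) {
  assert_that(length(keywords) > 0 && all(lengths(keywords) > 0),
              "empty keyword list")
  trusted <- annotations |> filter(.data$evidence %in% go_evidence_whitelist)
  purrr::map(keywords, function(kw) {
    pat <- paste(kw, collapse = "|")
    unique(trusted$gene_id[grepl(pat, trusted$term_name, ignore.case = TRUE)])
  })
}
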