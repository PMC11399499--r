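#' Pipeline configuration
#'
#' Gathers every stage's tunables with their defaults: importance filter
#' 0.005 (inclusive), Spearman filter 0.03 (strict, signed), 2000 bp
#' promoters, site scan at p <= 1e-4, cluster scan window 200 bp with
#' cluster score 5 and motif score 6, ChIP overlap of at least 1 bp,
#' threshold sweep 0.5-1.0 by 0.01 with F1 floor 0.8, and DEG calling at
#' FDR < 0.01 with log2FC > 1. One master seed fans out deterministically
#' to every stochastic stage.
#'
#' @param im_min,rho_min co-expression filter thresholds.
#' @param upstream_bp promoter length.
#' @param p_max site-scan p-value cutoff.
#' @param window_bp,cluster_min,motif_min cluster-scan parameters.
#' @param match_level `"motif"` or `"tf"` (see [tfbs_filter()]).
#' @param min_overlap_bp ChIP peak / promoter overlap.
#' @param drop_unsupported drop profiled-TF edges without peak support.
#' @param gcn a [gcn_config()].
#' @param grid_step,f1_floor threshold post-processing.
#' @param fdr_max,lfc_min DEG thresholds.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(im_min = 0.005, rho_min = 0.03, upstream_bp = 2000,
                            p_max = 1e-4, window_bp = 200, cluster_min = 5,
                            motif_min = 6, match_level = "motif",
                            min_overlap_bp = 1, drop_unsupported = FALSE,
                            gcn = gcn_config(), grid_step = 0.01,
                            f1_floor = 0.8, fdr_max = 0.01, lfc_min = 1.0,
                            seed = 1) {
  structure(list(im_min = im_min, rho_min = rho_min, upstream_bp = upstream_bp,
                 p_max = p_max, window_bp = window_bp, cluster_min = cluster_min,
                 motif_min = motif_min, match_level = match_level,
                 min_overlap_bp = min_overlap_bp,
                 drop_unsupported = drop_unsupported, gcn = gcn,
                 grid_step = grid_step, f1_floor = f1_floor, fdr_max = fdr_max,
                 lfc_min = lfc_min, seed = seed),
            class = "pipeline_config")
}

#' Run the full inference pipeline on in-memory objects
#'
#' Chains every stage: tree-ensemble importances, importance and Spearman
#' filters, dual motif scan with family sharing, ChIP labelling, GCN
#' training with balanced negative sampling and threshold post-processing,
#' tissue differential expression, and regulon assembly. Candidate edge
#' counts are checked to be non-increasing through the filter stages.
#'
#' @param expr an `expr_matrix`.
#' @param tf_table tibble (`gene_id`, `family`) of TFs.
#' @param annotations gene annotation tibble (with TSS and strand).
#' @param genome a [Biostrings::DNAStringSet].
#' @param motifs list of `motif_model`s.
#' @param peaks peak tibble (`tf_id`, `chrom`, `start`, `end`).
#' @param config a [pipeline_config()].
#' @return List of stage artifacts: `edges` (fully annotated edge table),
#'   `fit`, `sweep`, `de`, `degs`, `regulons` and a `report` tibble of
#'   per-stage edge counts and durations.
#' @export
run_pipeline_objects <- function(expr, tf_table, annotations, genome, motifs,
                                 peaks, config = pipeline_config()) {
  report <- list()
  tick <- function(stage, n) {
    report[[length(report) + 1]] <<- tibble(stage = stage, edges = n,
                                           seconds = round(as.numeric(Sys.time()) - t0, 2))
  }
  t0 <- as.numeric(Sys.time())
  tf_ids <- intersect(tf_table$gene_id, rownames(expr))

  edges <- importance_scores(expr, tf_ids, seed = derive_seed(config$seed, "coexpr"))
  tick("importance", nrow(edges))

  fcfg <- filter_config(im_min = config$im_min, rho_min = config$rho_min)
  edges_im <- filter_importance(edges, fcfg)
  tick("im_filter", nrow(edges_im))
  edges_rho <- spearman_filter(edges_im, expr, fcfg)
  tick("spearman_filter", nrow(edges_rho))

  ann <- annotations
  if (!any(ann$is_tf)) {
    ann <- ann |>
      mutate(is_tf = .data$gene_id %in% tf_table$gene_id,
             family = ifelse(.data$is_tf,
                             tf_table$family[match(.data$gene_id, tf_table$gene_id)],
                             ""))
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  promoters <- promoter_regions(ann, chrom_len, upstream_bp = config$upstream_bp)
  motif_map <- share_family_motifs(motifs, ann)
  hits <- scan_sites(promoters, genome, motifs, p_max = config$p_max)
  site_confirmed <- hits |> distinct(.data$motif_id, .data$gene_id)
  cluster_confirmed <- scan_clusters(hits, window_bp = config$window_bp,
                                     cluster_min = config$cluster_min,
                                     motif_min = config$motif_min)
  edges_tfbs <- tfbs_filter(edges_rho, site_confirmed, cluster_confirmed,
                            motif_map, match_level = config$match_level)
  tick("tfbs_filter", nrow(edges_tfbs))

  edges_lab <- label_edges(edges_tfbs, promoters, peaks,
                           min_overlap_bp = config$min_overlap_bp,
                           drop_unsupported = config$drop_unsupported)
  tick("chip_label", nrow(edges_lab))

  counts <- purrr::map_int(report, ~ .x$edges[1])
  filt <- counts[2:min(5, length(counts))]
  assert_that(all(diff(filt) <= 0),
              "edge counts must be non-increasing through the filter stages")

  positives <- edges_lab |> filter(.data$chip_label %in% "positive") |>
    select("tf", "target")
  graph <- build_graph(edges_lab, expr)
  split <- sample_negatives(graph, positives,
                            seed = derive_seed(config$seed, "negatives"))
  gcfg <- config$gcn
  gcfg$seed <- derive_seed(config$seed, "gcn")
  fit <- train_gcn(graph, split, gcfg)
  val <- fit$split |> filter(.data$partition == "val")
  sweep <- threshold_postprocess(val$gcn_score, val$label,
                                 grid_step = config$grid_step,
                                 f1_floor = config$f1_floor)
  fit$threshold <- sweep$threshold
  edges_scored <- predict_edges(fit, graph, edges_lab)
  tick("gcn_predict", sum(edges_scored$predicted))

  de <- de_tissues(expr)
  degs <- call_degs(de, fdr_max = config$fdr_max, lfc_min = config$lfc_min)
  regulons <- assemble_regulons(degs, edges_scored)
  tick("regulons", nrow(regulons))

  list(edges = edges_scored, fit = fit, sweep = sweep, de = de, degs = degs,
       regulons = regulons, promoters = promoters,
       report = purrr::list_rbind(report) |>
         mutate(config_hash = rlang::hash(unclass(config))))
}

#' Run the pipeline from a fixture-bundle directory
#'
#' Reads the plain-file bundle written by [write_fixture_bundle()]
#' (`counts.tsv`, `tissues.tsv`, `tfs.tsv`, `genome.fa`, `genes.gff3`,
#' `motifs.meme`, `motif_tf_map.tsv`, `peaks/`), runs
#' [run_pipeline_objects()], and writes the stage artifacts
#' (`edges_scored.tsv`, `degs.tsv`, `regulons.tsv`, `report.json`) under
#' `out_dir`.
#'
#' @param dir input bundle directory.
#' @param out_dir artifact directory (default `<dir>/out`).
#' @param config a [pipeline_config()].
#' @return The artifact list, invisibly.
#' @export
run_pipeline <- function(dir, out_dir = file.path(dir, "out"),
                         config = pipeline_config()) {
  need <- c("counts.tsv", "tissues.tsv", "tfs.tsv", "genome.fa", "genes.gff3",
            "motifs.meme")
  missing <- need[!file.exists(file.path(dir, need))]
  assert_that(length(missing) == 0L,
              paste0("missing pipeline input(s): ", paste(missing, collapse = ", "),
                     " — run the simulate/export stage first"))
  expr <- read_expression(file.path(dir, "counts.tsv"), file.path(dir, "tissues.tsv"))
  tf_table <- read_tf_table(file.path(dir, "tfs.tsv"))
  annotations <- read_annotation(file.path(dir, "genes.gff3"), tf_table)
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  map_path <- file.path(dir, "motif_tf_map.tsv")
  motifs <- read_motifs(file.path(dir, "motifs.meme"),
                        tf_map = if (file.exists(map_path)) map_path else NULL)
  peaks <- read_peaks_dir(file.path(dir, "peaks"))

  res <- run_pipeline_objects(expr, tf_table, annotations, genome, motifs,
                              peaks, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_edges(res$edges, file.path(out_dir, "edges_scored.tsv"))
  readr::write_tsv(res$degs, file.path(out_dir, "degs.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(res$regulons),
                   file.path(out_dir, "regulons.tsv"), progress = FALSE)
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Bundled example: per-tissue metric ranks of five tissues
#'
#' A small worked example shipped with the package: the final ranks of the
#' five prioritization metrics (out-degree, closeness, betweenness, GO
#' specificity, Borda) across five Arabidopsis tissues, used to
#' demonstrate [rank_table_summary()].
#'
#' @return Tibble with a `tissue` column and one numeric column per metric.
#' @export
example_rank_table <- function() {
  readr::read_tsv(system.file("extdata", "tissue_metric_ranks.tsv",
                              package = "regulonet"),
                  col_types = "cddddd", progress = FALSE)
}
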