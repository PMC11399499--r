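#' Label candidate edges against ChIP-seq peak overlap
#'
#' An edge is labelled `positive` when any peak of its TF overlaps the
#' target's promoter by at least `min_overlap_bp` (intervals are 0-based
#' half-open, so adjacent intervals do not overlap). Edges of TFs that have
#' no peaks at all remain unlabelled (`NA`) — they are eligible prediction
#' targets but never training positives; edges of profiled TFs without an
#' overlapping peak get `"unlabelled"`. Labelling is idempotent and
#' independent of edge order. Peaks on chromosomes absent from the promoter
#' set are ignored with a warning.
#'
#' @param edges candidate edge tibble (normally the motif-supported set).
#' @param promoters promoter tibble from [promoter_regions()].
#' @param peaks peak tibble (`tf_id`, `chrom`, `start`, `end`), e.g. from
#'   [read_peaks_dir()] or [emit_chip_peaks()].
#' @param min_overlap_bp minimal overlap in bp (default 1).
#' @param drop_unsupported drop edges of profiled TFs that lack an
#'   overlapping peak instead of labelling them `"unlabelled"`.
#' @return Edge tibble with a populated `chip_label` column.
#' @export
label_edges <- function(edges, promoters, peaks, min_overlap_bp = 1,
                        drop_unsupported = FALSE) {
  known_chrom <- unique(promoters$chrom)
  stray <- setdiff(unique(peaks$chrom), known_chrom)
  if (length(stray)) {
    rlang::warn(paste0("ignoring peaks on chromosome(s) absent from annotation: ",
                       paste(stray, collapse = ", ")))
    peaks <- peaks |> filter(.data$chrom %in% known_chrom)
  }
  profiled <- unique(peaks$tf_id)
  if (nrow(peaks)) {
    pk_gr <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$start + 1L, peaks$end))
    pr_gr <- GenomicRanges::GRanges(promoters$chrom,
                                    IRanges::IRanges(promoters$start + 1L, promoters$end))
    ov <- GenomicRanges::findOverlaps(pk_gr, pr_gr, minoverlap = min_overlap_bp)
    pos_pairs <- tibble(
      tf = peaks$tf_id[S4Vectors::queryHits(ov)],
      target = promoters$gene_id[S4Vectors::subjectHits(ov)]) |>
      distinct()
  } else {
    pos_pairs <- tibble(tf = character(), target = character())
  }
  out <- edges |>
    mutate(chip_label = case_when(
      paste(.data$tf, .data$target) %in% paste(pos_pairs$tf, pos_pairs$target) ~ "positive",
      .data$tf %in% profiled ~ "unlabelled",
      TRUE ~ NA_character_))
  if (isTRUE(drop_unsupported)) {
    out <- out |> filter(is.na(.data$chip_label) | .data$chip_label == "positive")
  }
  out
}
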