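#' Promoter windows upstream of each TSS
#'
#' Promoters are the `upstream_bp` window upstream of the 1-based TSS in
#' internal 0-based half-open coordinates: `[tss-1-up, tss-1)` on the `+`
#' strand and `[tss, tss+up)` on `-` (reverse-complemented at scan time).
#' Windows are clipped at chromosome bounds, so a promoter near a
#' chromosome start is shorter than `upstream_bp`.
#'
#' @param annotations gene annotation tibble (see [read_annotation()]).
#' @param genome_lengths named vector of chromosome lengths.
#' @param upstream_bp promoter length (default 2000).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_regions <- function(annotations, genome_lengths, upstream_bp = 2000) {
  missing <- setdiff(unique(annotations$chrom), names(genome_lengths))
  assert_that(length(missing) == 0L,
              paste0("unknown chromosome(s): ", paste(missing, collapse = ", ")))
  len <- unname(genome_lengths[annotations$chrom])
  start <- ifelse(annotations$strand == "+",
                  annotations$tss - 1L - upstream_bp, annotations$tss)
  end <- start + upstream_bp
  tibble(gene_id = annotations$gene_id, chrom = annotations$chrom,
         start = pmax(0L, as.integer(start)),
         end = pmin(as.integer(len), as.integer(end)),
         strand = annotations$strand) |>
    filter(.data$end > .data$start)
}

#' Exact p-value table for PWM log-odds scores
#'
#' Per-position log2-odds contributions `log2(p/bg)` are discretized at
#' `granularity` bits and the exact distribution of the score of a random
#' background word is obtained by dynamic-programming convolution across
#' motif positions. The returned survival function gives
#' `p(s) = P(score >= s)` exactly for the discretized scores, which are the
#' same discretized scores the scanner assigns, so lookups are exact rather
#' than bounded. Discretization moves any individual score by at most
#' `granularity / 2` per position.
#'
#' @param motif a `motif_model`.
#' @param granularity discretization step in bits (default 1e-3).
#' @param background optional length-4 background overriding the motif's own.
#' @return A `pwm_score_table`: integerized score matrix `kmat` (4 x L),
#'   `gamma` (the step), `min_int`/`max_int` score bounds and a `survival`
#'   vector; use [pwm_pvalue()] to look up p-values.
#' @export
pwm_pvalue_table <- function(motif, granularity = 1e-3, background = NULL) {
  bg <- background %||% motif$background
  assert_that(all(bg > 0), "degenerate background (zero entry)")
  s <- log2(motif$pfm / bg)
  kmat <- round(s / granularity)
  storage.mode(kmat) <- "integer"
  L <- ncol(kmat)
  mins <- apply(kmat, 2, min)
  maxs <- apply(kmat, 2, max)
  min_int <- sum(mins)
  width <- sum(maxs - mins) + 1L
  dist <- numeric(width)
  dist[1] <- 1
  cur_min <- 0L
  cur_len <- 1L
  for (j in seq_len(L)) {
    new_min <- cur_min + mins[j]
    new_len <- cur_len + (maxs[j] - mins[j])
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- kmat[b, j] - mins[j]
      idx <- (1L + off):(cur_len + off)
      new[idx] <- new[idx] + bg[b] * dist[seq_len(cur_len)]
    }
    dist <- new
    cur_min <- new_min
    cur_len <- new_len
  }
  survival <- rev(cumsum(rev(dist)))
  structure(list(kmat = kmat, gamma = granularity, min_int = cur_min,
                 max_int = cur_min + cur_len - 1L, survival = survival,
                 background = bg, motif_id = motif$motif_id),
            class = "pwm_score_table")
}

#' Look up `P(score >= s)` in a PWM score table
#' @param table a `pwm_score_table`.
#' @param score_int integer (discretized) scores.
#' @return p-values in (0, 1].
#' @export
pwm_pvalue <- function(table, score_int) {
  idx <- pmin(pmax(score_int, table$min_int), table$max_int) - table$min_int + 1L
  p <- table$survival[idx]
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# DNA string to integer codes: A=1 C=2 G=3 T=4, anything else 0 (scores as 0)
dna_codes <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  v
}

# integerized per-offset scores of one strand; codes 0 (N) contribute 0
scan_scores_int <- function(codes, kmat) {
  L <- ncol(kmat)
  n <- length(codes)
  if (n < L) return(integer(0))
  sc <- integer(n - L + 1L)
  for (j in seq_len(L)) {
    col <- c(0L, unname(kmat[, j]))  # index 1 is the N row
    sc <- sc + col[codes[j:(n - L + j)] + 1L]
  }
  sc
}

#' Scan promoters for motif sites with exact p-values
#'
#' Both strands of every promoter are scanned with discretized log2-odds
#' scores; a hit is emitted where the exact background p-value is at most
#' `p_max`. Ambiguous bases score zero. Promoters of minus-strand genes are
#' reverse-complemented before scanning, so offsets are relative to the
#' oriented (5' to 3' towards the TSS) promoter. By default the scan
#' background is estimated from the promoter set itself.
#'
#' @param promoters promoter tibble from [promoter_regions()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param motifs list of `motif_model` objects.
#' @param p_max p-value cutoff (default 1e-4, the usual site-scan default).
#' @param granularity score discretization in bits.
#' @param background `"promoters"` (estimate from scanned sequence, default),
#'   `"motif"` (each motif's own background), or a length-4 vector.
#' @return Tibble of hits: `motif_id`, `gene_id`, `offset` (1-based within
#'   the oriented promoter), `strand`, `score` (bits), `pvalue`.
#' @export
scan_sites <- function(promoters, genome, motifs, p_max = 1e-4,
                       granularity = 1e-3, background = "promoters") {
  missing <- setdiff(unique(promoters$chrom), names(genome))
  assert_that(length(missing) == 0L,
              paste0("promoter chromosome(s) absent from FASTA: ",
                     paste(missing, collapse = ", ")))
  assert_that(all(promoters$end <= Biostrings::width(genome)[match(promoters$chrom, names(genome))]),
              "promoter outside FASTA sequence")
  seqs <- as.character(Biostrings::subseq(
    genome[promoters$chrom],
    start = promoters$start + 1L, end = promoters$end))
  flip <- promoters$strand == "-"
  seqs[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[flip])))
  names(seqs) <- promoters$gene_id
  codes <- purrr::map(seqs, dna_codes)

  bg <- if (is.numeric(background)) {
    background / sum(background)
  } else if (identical(background, "promoters")) {
    tab <- tabulate(unlist(codes), nbins = 4)
    tab / sum(tab)
  } else NULL

  purrr::map(motifs, function(m) {
    tb <- pwm_pvalue_table(m, granularity = granularity, background = bg)
    km_rc <- tb$kmat[4:1, ncol(tb$kmat):1, drop = FALSE]
    L <- ncol(tb$kmat)
    purrr::imap(codes, function(cv, gid) {
      n <- length(cv)
      if (n < L) return(NULL)
      fw <- scan_scores_int(cv, tb$kmat)
      rc <- scan_scores_int(cv, km_rc)
      pf <- pwm_pvalue(tb, fw)
      pr <- pwm_pvalue(tb, rc)
      keep_f <- which(pf <= p_max)
      keep_r <- which(pr <= p_max)
      if (!length(keep_f) && !length(keep_r)) return(NULL)
      bind_rows(
        if (length(keep_f)) tibble(motif_id = m$motif_id, gene_id = gid,
                                   offset = keep_f, strand = "+",
                                   score = fw[keep_f] * tb$gamma,
                                   pvalue = pf[keep_f]),
        if (length(keep_r)) tibble(motif_id = m$motif_id, gene_id = gid,
                                   offset = keep_r, strand = "-",
                                   score = rc[keep_r] * tb$gamma,
                                   pvalue = pr[keep_r]))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind() |>
    empty_as(tibble(motif_id = character(), gene_id = character(),
                    offset = integer(), strand = character(),
                    score = double(), pvalue = double()))
}

#' Confirm motif-gene pairs by windowed cluster score
#'
#' A stand-in for cis-regulatory-module scanners: hits below `motif_min`
#' bits are discarded, a `window_bp` window slides over the promoter, and
#' the cluster score is the sum of retained hit scores whose start falls in
#' the window. A (motif, gene) pair is confirmed when the maximal window
#' score reaches `cluster_min`. The defaults mirror the common
#' `-c 5 -m 6` cluster/motif score thresholds.
#'
#' @param hits hit tibble from [scan_sites()].
#' @param window_bp sliding-window width (default 200).
#' @param cluster_min minimal window score (default 5).
#' @param motif_min minimal individual hit score (default 6).
#' @return Tibble of confirmed pairs: `motif_id`, `gene_id`.
#' @export
scan_clusters <- function(hits, window_bp = 200, cluster_min = 5, motif_min = 6) {
  kept <- hits |> filter(.data$score >= motif_min)
  if (nrow(kept) == 0) return(tibble(motif_id = character(), gene_id = character()))
  kept |>
    group_by(.data$motif_id, .data$gene_id) |>
    summarise(best = {
      o <- sort(.data$offset)
      s <- .data$score[order(.data$offset)]
      max(vapply(seq_along(o), function(i) {
        sum(s[o >= o[i] & o < o[i] + window_bp])
      }, 0))
    }, .groups = "drop") |>
    filter(.data$best >= cluster_min) |>
    select("motif_id", "gene_id")
}

#' Share motifs among TFs of the same family
#'
#' Every motif is remapped to the union of TFs in all families of its
#' originally mapped TFs; TFs without a family annotation keep their
#' original mapping (noted with a message). The mapping never shrinks.
#'
#' @param motifs list of `motif_model` objects.
#' @param annotations annotation tibble with `is_tf` and `family`.
#' @return Tibble mapping `motif_id` to `tf_id` after family expansion.
#' @export
share_family_motifs <- function(motifs, annotations) {
  fams <- annotations |> filter(.data$is_tf) |> select("gene_id", "family")
  base <- purrr::map(motifs, function(m) {
    if (!length(m$tf_ids)) return(NULL)
    tibble(motif_id = m$motif_id, tf_id = m$tf_ids)
  }) |> purrr::list_rbind()
  if (is.null(base) || nrow(base) == 0) {
    return(tibble(motif_id = character(), tf_id = character()))
  }
  with_fam <- base |> left_join(fams, by = c(tf_id = "gene_id"))
  n_unknown <- sum(is.na(with_fam$family) | with_fam$family == "")
  if (n_unknown > 0) {
    rlang::inform(sprintf("%d motif-TF mapping(s) kept unexpanded (TF without family)",
                          n_unknown))
  }
  expanded <- with_fam |>
    filter(!is.na(.data$family) & .data$family != "") |>
    distinct(.data$motif_id, .data$family) |>
    inner_join(fams |> filter(.data$family != ""), by = "family",
               relationship = "many-to-many") |>
    select("motif_id", tf_id = "gene_id")
  bind_rows(base, expanded) |> distinct(.data$motif_id, .data$tf_id)
}

#' Keep edges whose TF has motif support in the target promoter
#'
#' An edge keeps `motif_support = TRUE` (and survives) iff some motif
#' mapped to its TF is confirmed for its target by BOTH the site-level scan
#' and the cluster scan (`match_level = "motif"`, the default, requires the
#' same motif in both; `"tf"` merely requires the same TF-gene pair). TFs
#' with no motif at all after family sharing lose all their edges (noted
#' with a message).
#'
#' @param edges candidate edge tibble.
#' @param site_confirmed tibble (`motif_id`, `gene_id`) of site-scan
#'   confirmations, e.g. `distinct(scan_sites(...), motif_id, gene_id)`.
#' @param cluster_confirmed tibble (`motif_id`, `gene_id`) from
#'   [scan_clusters()].
#' @param motif_tf_map tibble (`motif_id`, `tf_id`), typically after
#'   [share_family_motifs()].
#' @param match_level `"motif"` or `"tf"`.
#' @return Edge tibble restricted to supported edges, `motif_support = TRUE`.
#' @export
tfbs_filter <- function(edges, site_confirmed, cluster_confirmed, motif_tf_map,
                        match_level = c("motif", "tf")) {
  match_level <- match.arg(match_level)
  no_motif <- setdiff(unique(edges$tf), motif_tf_map$tf_id)
  if (length(no_motif)) {
    rlang::inform(sprintf("%d TF(s) have no motif after sharing; their edges are dropped",
                          length(no_motif)))
  }
  supported <- if (match_level == "motif") {
    inner_join(distinct(site_confirmed), distinct(cluster_confirmed),
               by = c("motif_id", "gene_id")) |>
      inner_join(motif_tf_map, by = "motif_id", relationship = "many-to-many") |>
      distinct(tf = .data$tf_id, target = .data$gene_id)
  } else {
    site_tf <- site_confirmed |>
      inner_join(motif_tf_map, by = "motif_id", relationship = "many-to-many") |>
      distinct(tf = .data$tf_id, target = .data$gene_id)
    clus_tf <- cluster_confirmed |>
      inner_join(motif_tf_map, by = "motif_id", relationship = "many-to-many") |>
      distinct(tf = .data$tf_id, target = .data$gene_id)
    inner_join(site_tf, clus_tf, by = c("tf", "target"))
  }
  edges |>
    semi_join(supported, by = c("tf", "target")) |>
    mutate(motif_support = TRUE)
}
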