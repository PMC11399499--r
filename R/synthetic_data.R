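#' Configuration for the synthetic regulatory world
#'
#' The generator builds a fully ground-truthed world — a regulatory network,
#' tissue-structured negative-binomial counts, a genome with motif instances
#' planted in target promoters, and noisy ChIP-seq peaks — so every pipeline
#' stage can be checked against known truth.
#'
#' @param n_tfs,n_genes,n_tissues,samples_per_tissue world dimensions; TFs are
#'   the first `n_tfs` genes.
#' @param dispersion negative-binomial dispersion (1/size) of the counts.
#' @param promoter_len promoter length in bp upstream of the TSS.
#' @param motif_plant_rate probability that a true edge's motif is planted in
#'   the target promoter.
#' @param peak_fpr per-(TF, promoter) false-peak probability.
#' @param peak_fnr probability that a true edge's peak is missed.
#' @param tf_logfc_range range of the uniform tissue-specific log2 fold change
#'   given to an active TF.
#' @param edge_weight_range range of the uniform multiplier that scales a
#'   TF's log fold change onto each of its active targets.
#' @param coupling_sd standard deviation (log2 scale) of per-sample TF
#'   activity fluctuations that propagate to active targets, scaled by the
#'   edge weight. This within-tissue covariation between a TF and its own
#'   targets is what co-expression scoring detects; without it every TF
#'   active in the same tissue would be statistically interchangeable.
#' @param n_families number of TF families; `NULL` (default) gives every TF
#'   its own singleton family.
#' @param seed master seed; child seeds are derived per generator stage so
#'   stages can be regenerated independently.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tfs = 40, n_genes = 500, n_tissues = 3,
                       samples_per_tissue = 20, dispersion = 0.1,
                       promoter_len = 2000, motif_plant_rate = 0.9,
                       peak_fpr = 0.05, peak_fnr = 0.1,
                       tf_logfc_range = c(1.5, 3),
                       edge_weight_range = c(0.6, 1),
                       coupling_sd = 0.5,
                       n_families = NULL, seed = 1) {
  cfg <- list(n_tfs = n_tfs, n_genes = n_genes, n_tissues = n_tissues,
              samples_per_tissue = samples_per_tissue, dispersion = dispersion,
              promoter_len = promoter_len, motif_plant_rate = motif_plant_rate,
              peak_fpr = peak_fpr, peak_fnr = peak_fnr,
              tf_logfc_range = tf_logfc_range,
              edge_weight_range = edge_weight_range,
              coupling_sd = coupling_sd,
              n_families = n_families, seed = seed)
  assert_that(n_tfs >= 1, "n_tfs must be positive")
  assert_that(n_tfs < n_genes, "n_tfs must be smaller than n_genes")
  probs <- c(motif_plant_rate, peak_fpr, peak_fnr)
  assert_that(all(probs >= 0 & probs <= 1), "rates must be probabilities in [0,1]")
  assert_that(dispersion > 0, "dispersion must be positive")
  structure(cfg, class = "sim_config")
}

#' Strong-signal preset of the simulator
#'
#' Same world as [sim_config()] but with planted log2 fold changes of at
#' least 2, tight TF-target activity coupling, 90% motif planting and 10%
#' peak false-negative rate — strong signal at every evidence layer, the
#' conditions under which end-to-end recovery of the planted network is
#' expected.
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
strong_sim_config <- function(...) {
  sim_config(tf_logfc_range = c(2, 3), coupling_sd = 0.8,
             motif_plant_rate = 0.9, peak_fnr = 0.1, peak_fpr = 0.05, ...)
}

# draw from a discrete power law p(k) ~ k^-alpha on 1..kmax
rpowerlaw <- function(n, alpha = 2, kmax) {
  p <- (1:kmax)^(-alpha)
  sample.int(kmax, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a ground-truth regulatory network
#'
#' Each TF receives a target count drawn from a truncated discrete power law
#' (exponent 2, maximum `n_genes / 2`), giving the heavy-tailed out-degree
#' distribution typical of regulatory networks. Regulon activity is
#' organized per TF: a TF is active in one tissue (p = 0.7) or two
#' (p = 0.3), and every edge activates in a non-empty subset of its TF's
#' active tissues, so that regulons are predominantly tissue-specific.
#'
#' @param config a [sim_config()].
#' @return A `grn_truth` object with elements `genes` (tibble: `gene_id`,
#'   `is_tf`, `family`), `edges` (tibble: `tf`, `target`, `weight`, plus a
#'   list-column `tissues` of active tissue names), `tf_activity`
#'   (tibble: `tf`, `tissue`, `logfc`), and `config`.
#' @export
generate_grn <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  withr::with_seed(derive_seed(config$seed, "grn"), {
    n <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(n))
    tf_ids <- gene_ids[seq_len(config$n_tfs)]
    fams <- if (is.null(config$n_families)) {
      sprintf("FAM%03d", seq_len(config$n_tfs))
    } else {
      sprintf("FAM%03d", sample.int(config$n_families, config$n_tfs, replace = TRUE))
    }
    genes <- tibble(gene_id = gene_ids,
                    is_tf = gene_ids %in% tf_ids,
                    family = ifelse(gene_ids %in% tf_ids, fams[match(gene_ids, tf_ids)], ""))

    tissues <- sprintf("tissue%d", seq_len(config$n_tissues))
    deg <- rpowerlaw(config$n_tfs, alpha = 2, kmax = max(1L, floor(n / 2)))
    # per-TF active tissue set: regulons are predominantly single-tissue
    tf_tissues <- purrr::map(seq_len(config$n_tfs), function(i) {
      k <- if (config$n_tissues >= 2 && stats::runif(1) < 0.3) 2L else 1L
      sample(tissues, k)
    })
    edges <- purrr::map(seq_len(config$n_tfs), function(i) {
      tgt <- sample(setdiff(gene_ids, tf_ids[i]), deg[i])
      act <- purrr::map(seq_along(tgt), function(j) {
        tt <- tf_tissues[[i]]
        if (length(tt) == 1L) return(tt)
        # uniform over non-empty subsets of the TF's active set
        keep <- stats::runif(length(tt)) < 0.5
        if (!any(keep)) sample(tt, 1) else tt[keep]
      })
      tibble(tf = tf_ids[i], target = tgt,
             weight = stats::runif(deg[i], config$edge_weight_range[1],
                                   config$edge_weight_range[2]),
             tissues = act)
    }) |> purrr::list_rbind()

    tf_activity <- edges |>
      select("tf", "tissues") |>
      tidyr::unnest("tissues") |>
      distinct(.data$tf, tissue = .data$tissues) |>
      mutate(logfc = stats::runif(n(), config$tf_logfc_range[1],
                                  config$tf_logfc_range[2]))

    structure(list(genes = genes, edges = edges, tf_activity = tf_activity,
                   config = config),
              class = "grn_truth")
  })
}

#' @export
#' @method print grn_truth
print.grn_truth <- function(x, ...) {
  cat(sprintf("<grn_truth> %d genes (%d TFs), %d edges, %d tissues\n",
              nrow(x$genes), sum(x$genes$is_tf), nrow(x$edges),
              x$config$n_tissues))
  invisible(x)
}

#' Planted per-gene, per-tissue log2 fold changes
#'
#' A TF carries its own activity log2 fold change in each tissue where it is
#' active; a target carries, per tissue, the strongest incoming
#' `TF logFC x edge weight` among its active edges. When a gene is both
#' (an active TF and a regulated target) the larger effect wins.
#'
#' @param truth a `grn_truth`.
#' @return Tibble `gene_id`, `tissue`, `logfc` (absent rows mean 0).
#' @export
planted_logfc <- function(truth) {
  tf_part <- truth$tf_activity |>
    transmute(gene_id = .data$tf, .data$tissue, logfc = .data$logfc)
  tg_part <- truth$edges |>
    tidyr::unnest(tissues) |>
    rename(tissue = "tissues") |>
    inner_join(truth$tf_activity, by = c("tf", "tissue")) |>
    transmute(gene_id = .data$target, .data$tissue,
              logfc = .data$logfc * .data$weight)
  both <- bind_rows(tf_part, tg_part)
  if (nrow(both) == 0) {
    return(tibble(gene_id = character(), tissue = character(),
                  logfc = double()))
  }
  both |>
    group_by(.data$gene_id, .data$tissue) |>
    summarise(logfc = max(.data$logfc), .groups = "drop")
}

#' Simulate tissue-structured RNA-seq counts from the ground truth
#'
#' Counts are negative binomial around gene base means drawn log-normal
#' (meanlog 4, sdlog 1); planted effects act multiplicatively on the mean
#' (`mu * 2^logfc`), matching the log2-fold-change semantics of the
#' differential-expression module. On top of the tissue-level effects,
#' every TF fluctuates per sample (log2 SD `coupling_sd`) and its active
#' targets follow the fluctuation scaled by the edge weight, in the
#' tissues where the edge is active — the regulator-driven covariation
#' that co-expression inference relies on (one propagation level, no
#' cascades through TF-of-TF chains).
#'
#' @param truth a `grn_truth`.
#' @param config the same [sim_config()] used to build `truth`.
#' @return An `expr_matrix` with `samples_per_tissue` samples per tissue.
#' @export
simulate_expression <- function(truth, config = truth$config) {
  withr::with_seed(derive_seed(config$seed, "expression"), {
    genes <- truth$genes$gene_id
    tissues <- sprintf("tissue%d", seq_len(config$n_tissues))
    base <- stats::rlnorm(length(genes), meanlog = 4, sdlog = 1)
    names(base) <- genes

    lfc <- planted_logfc(truth)
    lfc_mat <- matrix(0, length(genes), length(tissues),
                      dimnames = list(genes, tissues))
    if (nrow(lfc)) lfc_mat[cbind(lfc$gene_id, lfc$tissue)] <- lfc$logfc

    sample_tissue <- rep(tissues, each = config$samples_per_tissue)
    sample_ids <- sprintf("%s_s%02d", sample_tissue,
                          sequence(rep(config$samples_per_tissue, length(tissues))))
    mu <- base * 2^lfc_mat[, sample_tissue, drop = FALSE]

    if (config$coupling_sd > 0) {
      tf_ids_all <- unique(truth$edges$tf)
      n_samp <- length(sample_tissue)
      act <- matrix(stats::rnorm(length(tf_ids_all) * n_samp, 0,
                                 config$coupling_sd),
                    length(tf_ids_all), n_samp,
                    dimnames = list(tf_ids_all, NULL))
      for (tf in tf_ids_all) mu[tf, ] <- mu[tf, ] * 2^act[tf, ]
      for (i in seq_len(nrow(truth$edges))) {
        e_tiss <- truth$edges$tissues[[i]]
        on <- sample_tissue %in% e_tiss
        if (!any(on)) next
        tg <- truth$edges$target[i]
        w <- truth$edges$weight[i]
        mu[tg, on] <- mu[tg, on] * 2^(w * act[truth$edges$tf[i], on])
      }
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                     nrow = length(genes),
                     dimnames = list(genes, sample_ids))
    expression_matrix(counts, stats::setNames(sample_tissue, sample_ids))
  })
}

# random informative PWM: one dominant base per column, resampled until the
# information content reaches ic_min bits
random_pwm <- function(len = 8, ic_min = 8) {
  repeat {
    dom <- sample.int(4, len, replace = TRUE)
    pfm <- matrix(0.05, 4, len)
    pfm[cbind(dom, seq_len(len))] <- 0.85
    # sharpen a random subset of columns
    sharp <- stats::runif(len) < 0.5
    pfm[, sharp] <- 0.01
    pfm[cbind(dom[sharp], which(sharp))] <- 0.97
    ic <- sum(pfm * log2(pfm * 4))
    if (ic >= ic_min) return(pfm)
  }
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Lay out a synthetic genome and plant motif instances
#'
#' One chromosome is created per 50 genes; every gene owns a private slot
#' holding its promoter so promoter windows never overlap. Each TF gets a
#' random informative PWM (information content >= 8 bits); for every true
#' edge the TF's consensus site is planted at a random non-overlapping
#' offset in the target promoter (on a random strand) with probability
#' `motif_plant_rate`. Background sequence is i.i.d. uniform.
#'
#' @param truth a `grn_truth`.
#' @param config the matching [sim_config()].
#' @return The `truth` object extended with `$genome`
#'   (a [Biostrings::DNAStringSet]), `$motifs` (list of `motif_model`,
#'   one per TF, ids `M_<tf>`), `$annotations` (gene annotation tibble) and
#'   `$motif_sites` (tibble of planted sites, 0-based half-open).
#' @export
emit_genome_and_motifs <- function(truth, config = truth$config) {
  withr::with_seed(derive_seed(config$seed, "genome"), {
    genes <- truth$genes
    n <- nrow(genes)
    per_chrom <- 50L
    margin <- 400L
    slot <- config$promoter_len + 2L * margin
    assert_that(margin >= 200L, "gene spacing cannot fit promoter windows")
    chrom_idx <- (seq_len(n) - 1L) %/% per_chrom
    within_idx <- (seq_len(n) - 1L) %% per_chrom
    strands <- sample(c("+", "-"), n, replace = TRUE)
    slot_start <- within_idx * slot + margin
    tss <- ifelse(strands == "+",
                  slot_start + config$promoter_len + 1L,  # 1-based
                  slot_start)
    ann <- tibble(gene_id = genes$gene_id,
                  chrom = sprintf("chr%d", chrom_idx + 1L),
                  strand = strands, tss = as.integer(tss),
                  is_tf = genes$is_tf, family = genes$family)
    # gene body, 1-based inclusive, for GFF emission
    ann$start <- ifelse(strands == "+", ann$tss, pmax(1L, ann$tss - 199L))
    ann$end <- ifelse(strands == "+", ann$tss + 199L, pmax(ann$tss, 1L))

    chrom_names <- sprintf("chr%d", seq_len(max(chrom_idx) + 1L))
    chrom_len <- per_chrom * slot + margin
    seqs <- lapply(chrom_names, function(cn) {
      sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    })
    names(seqs) <- chrom_names

    tf_ids <- genes$gene_id[genes$is_tf]
    motifs <- purrr::map(tf_ids, function(tf) {
      motif_model(paste0("M_", tf), random_pwm(8, 8), tf_ids = tf)
    })
    names(motifs) <- paste0("M_", tf_ids)
    consensus <- purrr::map_chr(motifs, function(m) {
      paste(c("A", "C", "G", "T")[apply(m$pfm, 2, which.max)], collapse = "")
    })

    # promoter window of each gene in 0-based half-open coords
    prom <- promoter_regions(ann, stats::setNames(rep(chrom_len, length(chrom_names)),
                                                  chrom_names),
                             upstream_bp = config$promoter_len)
    prom_by_gene <- split(prom, prom$gene_id)

    sites <- list()
    occupied <- stats::setNames(vector("list", n), genes$gene_id)
    for (i in seq_len(nrow(truth$edges))) {
      if (stats::runif(1) > config$motif_plant_rate) next
      tf <- truth$edges$tf[i]
      tg <- truth$edges$target[i]
      motif_id <- paste0("M_", tf)
      word <- consensus[[motif_id]]
      L <- nchar(word)
      p <- prom_by_gene[[tg]]
      # non-overlapping placement within the promoter (up to 50 attempts)
      placed <- FALSE
      for (try in 1:50) {
        off <- sample.int(p$end - p$start - L + 1L, 1L) - 1L
        s0 <- p$start + off
        busy <- occupied[[tg]]
        if (is.null(busy) || !any(s0 < busy[, 2] & s0 + L > busy[, 1])) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") word else revcomp_chr(word)
      seqs[[p$chrom]][(s0 + 1L):(s0 + L)] <- strsplit(ins, "")[[1]]
      occupied[[tg]] <- rbind(occupied[[tg]], c(s0, s0 + L))
      sites[[length(sites) + 1L]] <- tibble(
        motif_id = motif_id, tf = tf, gene_id = tg, chrom = p$chrom,
        start = s0, end = s0 + L, strand = strand)
    }
    site_tbl <- if (length(sites)) purrr::list_rbind(sites) else
      tibble(motif_id = character(), tf = character(), gene_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character())

    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
    names(genome) <- chrom_names
    truth$genome <- genome
    truth$motifs <- motifs
    truth$annotations <- ann
    truth$motif_sites <- site_tbl
    truth
  })
}

#' Emit noisy ChIP-seq peaks consistent with the ground truth
#'
#' For every true edge a 200 bp peak covering the planted site (or a random
#' promoter window when no site was planted) is emitted with probability
#' `1 - peak_fnr`; additional false peaks appear per (TF, promoter) pair at
#' rate `peak_fpr`.
#'
#' @param truth a `grn_truth` that has been through [emit_genome_and_motifs()].
#' @param config the matching [sim_config()].
#' @return Tibble of peaks (`tf_id`, `chrom`, `start`, `end`, 0-based
#'   half-open), sorted within TF.
#' @export
emit_chip_peaks <- function(truth, config = truth$config) {
  assert_that(!is.null(truth$annotations), "run emit_genome_and_motifs() first")
  withr::with_seed(derive_seed(config$seed, "chip"), {
    chrom_len <- Biostrings::width(truth$genome)
    names(chrom_len) <- names(truth$genome)
    prom <- promoter_regions(truth$annotations, chrom_len,
                             upstream_bp = config$promoter_len)
    sites_by_edge <- truth$motif_sites |>
      mutate(key = paste(.data$tf, .data$gene_id))

    true_peaks <- purrr::map(seq_len(nrow(truth$edges)), function(i) {
      if (stats::runif(1) < config$peak_fnr) return(NULL)
      tf <- truth$edges$tf[i]
      tg <- truth$edges$target[i]
      site <- sites_by_edge[sites_by_edge$key == paste(tf, tg), ]
      p <- prom[prom$gene_id == tg, ]
      if (nrow(site)) {
        centre <- (site$start[1] + site$end[1]) %/% 2L
      } else {
        centre <- p$start + sample.int(p$end - p$start, 1L) - 1L
      }
      s <- max(0L, centre - 100L)
      tibble(tf_id = tf, chrom = p$chrom, start = s,
             end = min(chrom_len[[p$chrom]], centre + 100L))
    }) |> purrr::list_rbind()

    tf_ids <- truth$genes$gene_id[truth$genes$is_tf]
    n_pairs <- length(tf_ids) * nrow(prom)
    hits <- which(stats::runif(n_pairs) < config$peak_fpr)
    false_peaks <- if (length(hits)) {
      tf_i <- ((hits - 1L) %% length(tf_ids)) + 1L
      pr_i <- ((hits - 1L) %/% length(tf_ids)) + 1L
      centre <- prom$start[pr_i] + floor(stats::runif(length(hits)) * (prom$end[pr_i] - prom$start[pr_i]))
      tibble(tf_id = tf_ids[tf_i], chrom = prom$chrom[pr_i],
             start = pmax(0L, as.integer(centre) - 100L),
             end = pmin(chrom_len[prom$chrom[pr_i]], as.integer(centre) + 100L))
    } else NULL
    bind_rows(true_peaks, false_peaks) |>
      arrange(.data$tf_id, .data$chrom, .data$start)
  })
}

#' Build the whole synthetic world in one call
#'
#' @param config a [sim_config()].
#' @return List with `truth` (including genome, motifs, annotations, sites),
#'   `expr` (an `expr_matrix`) and `peaks` (a peak tibble).
#' @export
simulate_world <- function(config = sim_config()) {
  truth <- generate_grn(config)
  truth <- emit_genome_and_motifs(truth, config)
  list(truth = truth,
       expr = simulate_expression(truth, config),
       peaks = emit_chip_peaks(truth, config))
}

#' Write a synthetic world as a plain-file fixture bundle
#'
#' Creates `genome.fa`, `genes.gff3`, `tfs.tsv`, `motifs.meme`,
#' `peaks/<tf>.bed`, `counts.tsv`, `tissues.tsv` and `truth.json` under
#' `dir`, the exact inputs the file-based pipeline consumes.
#'
#' @param world result of [simulate_world()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- world$truth
  Biostrings::writeXStringSet(truth$genome, file.path(dir, "genome.fa"))

  ann <- truth$annotations
  gff <- sprintf("%s\tregulonet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                 ann$chrom, ann$start, ann$end, ann$strand, ann$gene_id)
  writeLines(c("##gff-version 3", gff), file.path(dir, "genes.gff3"))

  readr::write_tsv(truth$genes |> filter(.data$is_tf) |>
                     select(gene_id = "gene_id", family = "family"),
                   file.path(dir, "tfs.tsv"), progress = FALSE)
  write_motifs_meme(truth$motifs, file.path(dir, "motifs.meme"))
  readr::write_tsv(tibble(motif_id = purrr::map_chr(truth$motifs, "motif_id"),
                          tf_id = purrr::map_chr(truth$motifs, ~ .x$tf_ids[1])),
                   file.path(dir, "motif_tf_map.tsv"), progress = FALSE)

  peak_dir <- file.path(dir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE)
  for (tf in unique(world$peaks$tf_id)) {
    p <- world$peaks |> filter(.data$tf_id == tf)
    writeLines(sprintf("%s\t%d\t%d\t%s_peak%d\t0\t.", p$chrom, p$start, p$end,
                       tf, seq_len(nrow(p))),
               file.path(peak_dir, paste0(tf, ".bed")))
  }

  write_expression(world$expr, file.path(dir, "counts.tsv"),
                   file.path(dir, "tissues.tsv"))

  truth_json <- list(
    edges = truth$edges |> mutate(tissues = purrr::map(.data$tissues, identity)),
    tf_activity = truth$tf_activity,
    motif_sites = truth$motif_sites,
    config = unclass(truth$config))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
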