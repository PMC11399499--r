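ann_row <- function(gene, tss, strand, chrom = "chr1") {
  tibble::tibble(gene_id = gene, chrom = chrom, strand = strand, tss = tss,
                 is_tf = FALSE, family = "")
}

test_that("promoter windows follow the coordinate conventions and clip", {
  lens <- c(chr1 = 10000)
  p <- promoter_regions(ann_row("g1", 5000, "+"), lens)
  expect_equal(c(p$start, p$end), c(2999, 4999))
  p <- promoter_regions(ann_row("g2", 1500, "+"), lens)
  expect_equal(c(p$start, p$end), c(0, 1499))  # clipped at the origin
  p <- promoter_regions(ann_row("g3", 5000, "-"), lens)
  expect_equal(c(p$start, p$end), c(5000, 7000))
  p <- promoter_regions(ann_row("g4", 9500, "-"), lens)
  expect_equal(c(p$start, p$end), c(9500, 10000))  # clipped at the end
  expect_error(promoter_regions(ann_row("g5", 10, "+", chrom = "chrX"), lens),
               "unknown chromosome")
})

test_that("a length-1 motif equal to background scores zero with p = 1", {
  m <- motif_model("flat", matrix(0.25, 4, 1) - 0.01)  # pseudocount restores 0.25
  tb <- pwm_pvalue_table(m)
  expect_equal(tb$min_int, 0)
  expect_equal(tb$max_int, 0)
  expect_equal(pwm_pvalue(tb, 0L), 1)
})

test_that("DP p-values equal exhaustive enumeration for short motifs", {
  withr::with_seed(31, {
    for (L in c(2, 3, 6)) {
      pfm <- matrix(stats::rgamma(4 * L, 1), 4, L)
      pfm <- sweep(pfm, 2, colSums(pfm), "/")
      m <- motif_model(paste0("m", L), pfm, background = c(0.3, 0.2, 0.2, 0.3))
      tb <- pwm_pvalue_table(m)
      oracle <- bf_pwm_survival(tb$kmat, m$background)
      for (s in unique(round(seq(tb$min_int, tb$max_int, length.out = 9)))) {
        expect_equal(pwm_pvalue(tb, as.integer(s)), oracle(s), tolerance = 1e-12)
      }
      # survival is non-increasing in the score
      sv <- tb$survival
      expect_true(all(diff(sv) <= 1e-15))
    }
  })
})

make_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("a planted consensus site is found at its offset with minimal p", {
  withr::with_seed(5, {
    pfm <- matrix(0.02, 4, 8)
    cons <- c(1, 3, 3, 2, 4, 1, 2, 3)
    pfm[cbind(cons, 1:8)] <- 0.94
    m <- motif_model("planted", pfm)
    word <- paste(c("A", "C", "G", "T")[cons], collapse = "")
    bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    seqs <- paste0(substr(bg, 1, 100), word, substr(bg, 109, 300))
    genome <- make_genome(c(chr1 = seqs))
    prom <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0,
                           end = nchar(seqs), strand = "+")
    hits <- scan_sites(prom, genome, list(m), p_max = 1e-3,
                       background = c(0.25, 0.25, 0.25, 0.25))
    best <- hits[which.min(hits$pvalue), ]
    expect_equal(best$offset, 101)
    expect_equal(best$strand, "+")

    # reverse-complementing the promoter swaps strands and mirrors offsets
    rc <- as.character(Biostrings::reverseComplement(genome[[1]]))
    hits_rc <- scan_sites(prom, make_genome(c(chr1 = rc)), list(m), p_max = 1e-3,
                          background = c(0.25, 0.25, 0.25, 0.25))
    n <- nchar(seqs); L <- 8
    remapped <- tibble::tibble(offset = n - hits_rc$offset - L + 2,
                               strand = ifelse(hits_rc$strand == "+", "-", "+"),
                               score = hits_rc$score)
    expect_equal(dplyr::arrange(remapped, offset, strand),
                 dplyr::arrange(hits[, c("offset", "strand", "score")], offset, strand))
  })
})

test_that("background hit counts match the exact p-value calibration", {
  withr::with_seed(77, {
    pfm <- matrix(0.03, 4, 8)
    pfm[cbind(sample(1:4, 8, replace = TRUE), 1:8)] <- 0.91
    m <- motif_model("cal", pfm)
    n_prom <- 50; len <- 2000; L <- 8
    seqs <- vapply(seq_len(n_prom), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
    names(seqs) <- sprintf("chr%02d", seq_len(n_prom))
    genome <- make_genome(seqs)
    prom <- tibble::tibble(gene_id = names(seqs), chrom = names(seqs),
                           start = 0, end = len, strand = "+")
    p_max <- 1e-4
    bg <- c(0.25, 0.25, 0.25, 0.25)
    hits <- scan_sites(prom, genome, list(m), p_max = p_max, background = bg)
    # expected per-offset hit probability is the attained p at the cutoff
    tb <- pwm_pvalue_table(m, background = bg)
    p_star <- max(tb$survival[tb$survival <= p_max])
    lambda <- 2 * (len - L + 1) * p_star * n_prom
    expect_lt(abs(nrow(hits) - lambda), 3 * sqrt(lambda) + 1)
  })
})

test_that("cluster confirmation follows the window-sum rules", {
  hits <- tibble::tibble(motif_id = "m", gene_id = "g", offset = c(10, 60),
                         strand = "+", score = c(7, 6), pvalue = 1e-5)
  expect_equal(nrow(scan_clusters(hits)), 1)  # 7 + 6 = 13 >= 5 in one window

  weak <- tibble::tibble(motif_id = "m", gene_id = "g", offset = 10,
                         strand = "+", score = 5.9, pvalue = 1e-5)
  expect_equal(nrow(scan_clusters(weak)), 0)  # below the per-motif floor

  # far-apart hits are scored alone by the sliding window
  far <- tibble::tibble(motif_id = "m", gene_id = "g", offset = c(0, 400),
                        strand = "+", score = c(3.5, 3.5), pvalue = 1e-5)
  expect_equal(nrow(scan_clusters(far, motif_min = 3, cluster_min = 5)), 0)
  near <- dplyr::mutate(far, offset = c(0, 100))
  expect_equal(nrow(scan_clusters(near, motif_min = 3, cluster_min = 5)), 1)
})

test_that("family sharing expands mappings monotonically", {
  motifs <- list(motif_model("m1", matrix(c(10, 0, 0, 0), 4, 1), tf_ids = "tfA"),
                 motif_model("m2", matrix(c(0, 10, 0, 0), 4, 1), tf_ids = "tfC"))
  ann <- tibble::tibble(gene_id = c("tfA", "tfB", "tfC", "g1"),
                        chrom = "chr1", strand = "+", tss = 1:4,
                        is_tf = c(TRUE, TRUE, TRUE, FALSE),
                        family = c("MYB", "MYB", "WRKY", ""))
  map <- share_family_motifs(motifs, ann)
  expect_setequal(map$tf_id[map$motif_id == "m1"], c("tfA", "tfB"))
  expect_setequal(map$tf_id[map$motif_id == "m2"], "tfC")  # singleton family
  # never shrinks the original mapping
  expect_true(all(c("tfA", "tfC") %in% map$tf_id))

  # a TF without family stays put, with a message
  ann2 <- dplyr::mutate(ann, family = dplyr::if_else(gene_id == "tfA", "", family))
  expect_message(map2 <- share_family_motifs(motifs, ann2), "without family")
  expect_setequal(map2$tf_id[map2$motif_id == "m1"], "tfA")
})

test_that("the TFBS filter keeps only dual-confirmed edges", {
  edges <- tibble::tibble(tf = c("tfA", "tfA", "tfB"),
                          target = c("g1", "g2", "g1"),
                          importance = 1, spearman_rho = 0.5)
  map <- tibble::tibble(motif_id = c("m1", "m2"), tf_id = c("tfA", "tfB"))
  site <- tibble::tibble(motif_id = c("m1", "m1", "m2"),
                         gene_id = c("g1", "g2", "g1"))
  clus <- tibble::tibble(motif_id = c("m1"), gene_id = c("g1"))
  expect_message(out <- tfbs_filter(edges, site, clus, map), NA)
  # only (tfA, g1) is confirmed by both scanners
  expect_equal(nrow(out), 1)
  expect_equal(out$tf, "tfA")
  expect_equal(out$target, "g1")
  expect_true(all(out$motif_support))

  # tf-level matching accepts confirmation by different motifs of the same TF
  map2 <- tibble::tibble(motif_id = c("m1", "m3"), tf_id = c("tfA", "tfA"))
  clus2 <- tibble::tibble(motif_id = "m3", gene_id = "g2")
  out_motif <- tfbs_filter(edges, site, clus2, map2, match_level = "motif")
  out_tf <- tfbs_filter(edges, site, clus2, map2, match_level = "tf")
  expect_equal(nrow(out_motif), 0)
  expect_equal(nrow(out_tf), 1)

  # a TF with no motif loses its edges, with a message
  expect_message(out3 <- tfbs_filter(edges, site, clus,
                                     map[map$tf_id != "tfB", ]),
                 "no motif")
  expect_false("tfB" %in% out3$tf)
})
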