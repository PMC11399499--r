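#' Read a gene-by-sample count matrix with tissue labels
#'
#' The counts file is a TSV whose first column holds gene identifiers and whose
#' header row holds sample identifiers; the companion tissue file maps every
#' sample to a tissue name. Both files are validated strictly: a cell that is
#' not a number is a parse error naming its row and column, a duplicated gene
#' identifier is an error, and a sample without a tissue label is an error.
#'
#' @param path path to the counts TSV.
#' @param tissue_path path to a two-column TSV (`sample`, `tissue`).
#' @return An `expr_matrix` object: a numeric matrix of non-negative counts
#'   (genes in rows) with a `tissues` attribute, a named character vector
#'   keyed by sample id.
#' @export
read_expression <- function(path, tissue_path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  assert_that(ncol(raw) >= 2L, "counts file needs a gene-id column plus at least one sample")
  gene_ids <- raw[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  assert_that(length(dup) == 0L,
              paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "malformed numeric cell '%s' at gene '%s' (row %d), sample '%s'",
      vals[bad[1], bad[2]], gene_ids[bad[1]], bad[1], colnames(raw)[-1][bad[2]]))
  }
  assert_that(all(num >= 0), "counts must be non-negative")
  dimnames(num) <- list(gene_ids, colnames(raw)[-1])

  tl <- readr::read_tsv(tissue_path, col_types = "cc", progress = FALSE)
  assert_that(all(c("sample", "tissue") %in% names(tl)),
              "tissue file needs columns 'sample' and 'tissue'")
  tissues <- stats::setNames(tl$tissue, tl$sample)
  missing <- setdiff(colnames(num), names(tissues))
  assert_that(length(missing) == 0L,
              paste0("samples without a tissue label: ", paste(missing, collapse = ", ")))
  expression_matrix(num, tissues[colnames(num)])
}

#' Construct an expression matrix object
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @param tissues named character vector mapping every sample id to a tissue.
#' @return An `expr_matrix`.
#' @export
expression_matrix <- function(counts, tissues) {
  assert_that(is.matrix(counts) && is.numeric(counts), "counts must be a numeric matrix")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must carry gene and sample names")
  assert_that(all(colnames(counts) %in% names(tissues)),
              "every sample needs a tissue label")
  structure(counts, tissues = tissues[colnames(counts)], class = c("expr_matrix", "matrix", "array"))
}

#' @export
#' @method print expr_matrix
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, %d tissue(s)\n",
              nrow(x), ncol(x), length(unique(attr(x, "tissues")))))
  invisible(x)
}

#' Tissue labels of an expression matrix
#' @param expr an `expr_matrix`.
#' @return Named character vector, one tissue per sample.
#' @export
tissue_labels <- function(expr) attr(expr, "tissues")

#' Write an expression matrix (and its tissue labels) back to TSV
#' @param expr an `expr_matrix`.
#' @param path counts TSV destination.
#' @param tissue_path tissue TSV destination.
#' @export
write_expression <- function(expr, path, tissue_path = NULL) {
  df <- tibble::as_tibble(unclass(expr), rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(tissue_path)) {
    tl <- tibble(sample = colnames(expr), tissue = unname(tissue_labels(expr)))
    readr::write_tsv(tl, tissue_path, progress = FALSE)
  }
  invisible(path)
}

#' Read gene annotations from GFF3 or BED
#'
#' Coordinates are converted to a single 1-based transcription start site per
#' gene: feature start on the `+` strand, feature end on `-`. GFF3 input is
#' 1-based inclusive, BED is 0-based half-open. An optional TF table
#' (columns `gene_id`, `family`) flags transcription factors.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @param tf_table optional tibble with columns `gene_id` and `family`.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `tss`, `is_tf`, `family`.
#' @export
read_annotation <- function(path, tf_table = NULL) {
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  if (is_bed) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) rlang::abort(paste0("failed to parse BED: ", conditionMessage(e))))
    assert_that(all(GenomicRanges::start(gr) >= 1L), "negative BED coordinate")
    ids <- gr$name %||% paste0("feature", seq_along(gr))
  } else {
    df <- tryCatch(rtracklayer::readGFF(path),
                   error = function(e) rlang::abort(paste0("failed to parse GFF3: ", conditionMessage(e))))
    assert_that(all(df$end >= df$start), "GFF3 feature with end < start")
    gr <- GenomicRanges::GRanges(df$seqid, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    ids <- df$ID %||% df$gene_id %||% paste0("feature", seq_len(nrow(df)))
  }
  strands <- as.character(GenomicRanges::strand(gr))
  assert_that(all(strands %in% c("+", "-")),
              "annotation strand must be '+' or '-' for every gene")
  ann <- tibble(
    gene_id = as.character(ids),
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    strand  = strands,
    tss     = ifelse(strands == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
  )
  assert_that(!anyDuplicated(ann$gene_id), "duplicate gene id in annotation")
  if (!is.null(tf_table)) {
    ann <- ann |>
      left_join(tf_table |> select("gene_id", "family"), by = "gene_id") |>
      mutate(is_tf = .data$gene_id %in% tf_table$gene_id,
             family = ifelse(is.na(.data$family), "", .data$family))
  } else {
    ann$is_tf <- FALSE
    ann$family <- ""
  }
  ann
}

#' Read a TF list (gene_id, family) from TSV
#' @param path TSV with columns `gene_id` and `family`.
#' @return Tibble.
#' @export
read_tf_table <- function(path) {
  tf <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  assert_that(all(c("gene_id", "family") %in% names(tf)),
              "tf table needs columns 'gene_id' and 'family'")
  tf
}

# ---- motif models ----------------------------------------------------------

#' Construct a motif model
#'
#' Columns of `pfm` (rows A, C, G, T) may be counts or probabilities; a
#' pseudocount of 0.01 is added to every cell before column normalization so
#' that log-odds scores stay finite.
#'
#' @param motif_id motif identifier.
#' @param pfm 4 x L numeric matrix (rows A, C, G, T).
#' @param tf_ids character vector of TF gene ids mapped to the motif.
#' @param background length-4 base probability vector (A, C, G, T).
#' @return A `motif_model`.
#' @export
motif_model <- function(motif_id, pfm, tf_ids = character(),
                        background = rep(0.25, 4)) {
  assert_that(is.matrix(pfm) && nrow(pfm) == 4L,
              paste0("motif '", motif_id, "': pfm must have 4 rows (A,C,G,T)"))
  assert_that(all(colSums(pfm) > 0),
              paste0("motif '", motif_id, "': column of all zeros"))
  assert_that(abs(sum(background) - 1) < 1e-6, "background must sum to 1")
  pfm <- pfm + 0.01
  pfm <- sweep(pfm, 2, colSums(pfm), "/")
  rownames(pfm) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, pfm = pfm, tf_ids = unique(tf_ids),
                 background = background, mapped = length(tf_ids) > 0),
            class = "motif_model")
}

#' @export
#' @method print motif_model
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s: length %d, %d TF(s), IC %.1f bits\n",
              x$motif_id, ncol(x$pfm), length(x$tf_ids), motif_ic(x)))
  invisible(x)
}

#' Information content of a motif (bits)
#' @param motif a `motif_model`.
#' @return Total information content in bits relative to a uniform background.
#' @export
motif_ic <- function(motif) {
  p <- motif$pfm
  sum(p * log2(p * 4))
}

#' Read motif models from JASPAR PFM or MEME minimal files
#'
#' The format is detected from the file content (`MEME version` header for
#' MEME minimal, `>` records for JASPAR). Counts and probabilities are both
#' accepted; see [motif_model()] for the pseudocount convention. Motifs that
#' have no entry in the TF map are retained with `mapped = FALSE`.
#'
#' @param path motif file.
#' @param tf_map optional path to a TSV mapping (`motif_id`, `tf_id`); the
#'   mapping may be many-to-many.
#' @return List of `motif_model` objects.
#' @export
read_motifs <- function(path, tf_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  map_tbl <- NULL
  if (!is.null(tf_map)) {
    map_tbl <- readr::read_tsv(tf_map, col_types = "cc", progress = FALSE)
    assert_that(all(c("motif_id", "tf_id") %in% names(map_tbl)),
                "tf map needs columns 'motif_id' and 'tf_id'")
  }
  parsed <- if (any(grepl("^MEME version", lines))) parse_meme(lines) else parse_jaspar(lines)
  purrr::map(parsed, function(m) {
    tfs <- if (is.null(map_tbl)) character() else map_tbl$tf_id[map_tbl$motif_id == m$motif_id]
    motif_model(m$motif_id, m$pfm, tf_ids = tfs, background = m$background)
  })
}

parse_jaspar <- function(lines) {
  heads <- grep("^>", lines)
  assert_that(length(heads) > 0L, "no JASPAR records ('>' headers) found")
  bounds <- c(heads, length(lines) + 1L)
  purrr::map(seq_along(heads), function(i) {
    id <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    assert_that(length(body) == 4L,
                paste0("motif '", id, "': expected 4 matrix rows, got ", length(body)))
    rows <- purrr::map(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    assert_that(length(L) == 1L, paste0("motif '", id, "': ragged matrix rows"))
    list(motif_id = id, pfm = do.call(rbind, rows), background = rep(0.25, 4))
  })
}

parse_meme <- function(lines) {
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    freq <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(freq) <- toks[seq(1, length(toks), by = 2)]
    bg <- unname(freq[c("A", "C", "G", "T")])
  }
  starts <- grep("^MOTIF\\b", lines)
  assert_that(length(starts) > 0L, "no MOTIF records found in MEME file")
  bounds <- c(starts, length(lines) + 1L)
  purrr::map(seq_along(starts), function(i) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[starts[i]])), "\\s+")[[1]][1]
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    hdr <- grep("^letter-probability matrix", block)
    assert_that(length(hdr) == 1L, paste0("motif '", id, "': missing letter-probability matrix"))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr]))
    rows <- block[(hdr + 1L):(hdr + w)]
    mat <- do.call(rbind, purrr::map(rows, ~ as.numeric(strsplit(trimws(.x), "\\s+")[[1]])))
    assert_that(ncol(mat) == 4L, paste0("motif '", id, "': matrix rows must have 4 columns"))
    list(motif_id = id, pfm = t(mat), background = bg)
  })
}

#' Write motif models to a MEME minimal file
#' @param motifs list of `motif_model` objects.
#' @param path destination file.
#' @export
write_motifs_meme <- function(motifs, path) {
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m$pfm)), con)
    writeLines(apply(m$pfm, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- ChIP peaks ------------------------------------------------------------

#' Read ChIP-seq peaks for one TF from a BED file
#'
#' Peaks are stored 0-based half-open and returned sorted by (chrom, start);
#' overlapping peaks are preserved, never merged.
#'
#' @param path BED file (3+ columns).
#' @param tf_id the profiled TF's gene id.
#' @return Tibble with `tf_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks <- function(path, tf_id) {
  if (file.size(path) == 0L) {
    return(tibble(tf_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) rlang::abort(paste0("failed to parse BED: ", conditionMessage(e))))
  start0 <- GenomicRanges::start(gr) - 1L
  assert_that(all(start0 >= 0L), "negative peak coordinate")
  tibble(tf_id = tf_id, chrom = as.character(GenomicRanges::seqnames(gr)),
         start = start0, end = GenomicRanges::end(gr)) |>
    arrange(.data$chrom, .data$start)
}

#' Read every `<tf>.bed` file in a peaks directory
#' @param dir directory of BED files named by TF gene id.
#' @return Tibble of peaks for all profiled TFs.
#' @export
read_peaks_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  purrr::map(files, ~ read_peaks(.x, sub("\\.bed$", "", basename(.x)))) |>
    purrr::list_rbind()
}

# ---- edge tables -----------------------------------------------------------

edge_columns <- c("tf", "target", "importance", "spearman_rho",
                  "motif_support", "chip_label", "gcn_score", "predicted")

edge_col_types <- readr::cols(
  tf = readr::col_character(), target = readr::col_character(),
  importance = readr::col_double(), spearman_rho = readr::col_double(),
  motif_support = readr::col_logical(), chip_label = readr::col_character(),
  gcn_score = readr::col_double(), predicted = readr::col_logical())

#' Write / read a candidate-edge table
#'
#' The on-disk format is a TSV with the fixed column set `tf`, `target`,
#' `importance`, `spearman_rho`, `motif_support`, `chip_label`, `gcn_score`,
#' `predicted`; columns not yet populated are written as NA. Floats are
#' written with 10 significant digits and round-trip losslessly at that
#' precision.
#'
#' @param edges tibble of candidate edges.
#' @param path TSV destination / source.
#' @return `read_edges` returns the edge tibble.
#' @export
write_edges <- function(edges, path) {
  unknown <- setdiff(names(edges), edge_columns)
  assert_that(length(unknown) == 0L,
              paste0("unknown edge column(s): ", paste(unknown, collapse = ", ")))
  for (col in setdiff(edge_columns, names(edges))) edges[[col]] <- NA
  out <- edges[edge_columns]
  for (col in c("importance", "spearman_rho", "gcn_score")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.10g", as.numeric(out[[col]])))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  unknown <- setdiff(hdr, edge_columns)
  assert_that(length(unknown) == 0L,
              paste0("unknown edge column(s): ", paste(unknown, collapse = ", ")))
  missing <- setdiff(c("tf", "target"), hdr)
  assert_that(length(missing) == 0L,
              paste0("edge file missing required column(s): ", paste(missing, collapse = ", ")))
  readr::read_tsv(path, col_types = edge_col_types, progress = FALSE)
}
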