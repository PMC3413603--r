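#' Gene model container
#'
#' A `gene_models` object describes candidate genes on a toy reference:
#' per-gene exon structure plus the transcript-level partition into 5' UTR,
#' CDS and 3' UTR. It is the unit over which coverage completeness and
#' variant consequences are assessed. All genes are modelled on the plus
#' strand; coordinates are 1-based inclusive.
#'
#' @param genes data frame with columns `gene_id`, `contig`, `strand`,
#'   `start`, `end`, `utr5_len`, `cds_len`, `utr3_len`.
#' @param exons data frame with columns `gene_id`, `exon_rank`, `start`, `end`.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "contig", "strand", "start", "end",
                  "utr5_len", "cds_len", "utr3_len") %in% names(genes)),
            all(c("gene_id", "exon_rank", "start", "end") %in% names(exons)))
  for (g in genes$gene_id) {
    ex <- exons[exons$gene_id == g, , drop = FALSE]
    if (!nrow(ex)) stopf("gene model error: gene %s has no exons", g)
    ex <- ex[order(ex$exon_rank), ]
    if (any(diff(ex$start) <= 0) || any(ex$end < ex$start))
      stopf("gene model error: exons of %s are unsorted or degenerate", g)
    txl <- sum(ex$end - ex$start + 1L)
    gi <- genes[genes$gene_id == g, ]
    if (gi$utr5_len + gi$cds_len + gi$utr3_len != txl)
      stopf("gene model error: UTR/CDS lengths of %s do not tile the transcript", g)
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d contigs, %d exons total\n",
              nrow(x$genes), length(unique(x$genes$contig)), nrow(x$exons)))
  invisible(x)
}

gene_exons <- function(models, gene_id) {
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex)) stopf("gene model error: gene %s has no exons", gene_id)
  ex[order(ex$exon_rank), , drop = FALSE]
}

gene_info <- function(models, gene_id) {
  gi <- models$genes[models$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(gi)) stopf("unknown gene: %s", gene_id)
  gi
}

# transcript-coordinate offsets of each exon: exon i covers tx
# [offset[i] + 1, offset[i] + width[i]]
exon_tx_offsets <- function(ex) {
  w <- ex$end - ex$start + 1L
  list(width = w, offset = cumsum(c(0L, w[-length(w)])))
}

#' Project coordinates between transcript and genome space
#'
#' @param models a `gene_models` object.
#' @param gene_id gene identifier.
#' @param tx_pos,g_pos integer vectors of positions (1-based).
#' @return `tx_to_genome()` returns genomic positions; `genome_to_tx()`
#'   returns transcript positions with `NA` for intronic/flanking bases.
#' @export
tx_to_genome <- function(models, gene_id, tx_pos) {
  ex <- gene_exons(models, gene_id)
  o <- exon_tx_offsets(ex)
  idx <- findInterval(tx_pos - 1L, o$offset)
  bad <- tx_pos < 1L | tx_pos > sum(o$width)
  if (any(bad)) stopf("transcript position out of range for gene %s", gene_id)
  ex$start[idx] + (tx_pos - o$offset[idx] - 1L)
}

#' @rdname tx_to_genome
#' @export
genome_to_tx <- function(models, gene_id, g_pos) {
  ex <- gene_exons(models, gene_id)
  o <- exon_tx_offsets(ex)
  out <- rep(NA_integer_, length(g_pos))
  for (i in seq_len(nrow(ex))) {
    in_ex <- g_pos >= ex$start[i] & g_pos <= ex$end[i]
    out[in_ex] <- o$offset[i] + (g_pos[in_ex] - ex$start[i] + 1L)
  }
  out
}

#' Extract the spliced transcript sequence of a gene
#'
#' @param reference named character vector of contig sequences.
#' @param models a `gene_models` object.
#' @param gene_id gene identifier.
#' @return a character scalar (exon-joined transcript sequence).
#' @export
gene_transcript <- function(reference, models, gene_id) {
  gi <- gene_info(models, gene_id)
  ex <- gene_exons(models, gene_id)
  paste(substring(reference[[gi$contig]], ex$start, ex$end), collapse = "")
}

# transcript-coordinate CDS interval of a gene
cds_tx_range <- function(models, gene_id) {
  gi <- gene_info(models, gene_id)
  c(start = gi$utr5_len + 1L, end = gi$utr5_len + gi$cds_len)
}

#' Extract the coding sequence of a gene
#'
#' @inheritParams gene_transcript
#' @export
gene_cds <- function(reference, models, gene_id) {
  tx <- gene_transcript(reference, models, gene_id)
  r <- cds_tx_range(models, gene_id)
  substr(tx, r["start"], r["end"])
}

# genomic exon intervals as a regions data.frame (used for pileup regions)
exon_regions <- function(models) {
  data.frame(contig = models$genes$contig[match(models$exons$gene_id,
                                                models$genes$gene_id)],
             start = models$exons$start, end = models$exons$end,
             gene_id = models$exons$gene_id, stringsAsFactors = FALSE)
}

# ----------------------------------------------------------------------- GFF3

#' Write and read gene models as GFF3
#'
#' Gene, mRNA, exon and CDS features with 1-based inclusive coordinates,
#' written through rtracklayer. Reading reconstructs the `gene_models`
#' object, recovering the UTR/CDS transcript partition from the CDS features.
#'
#' @param models a `gene_models` object.
#' @param path file path.
#' @return `read_gff3()` returns a `gene_models` object.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  for (g in models$genes$gene_id) {
    gi <- gene_info(models, g)
    ex <- gene_exons(models, g)
    mrna_id <- paste0(g, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      contig = gi$contig, start = gi$start, end = gi$end, type = "gene",
      ID = g, Parent = NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = gi$contig, start = gi$start, end = gi$end, type = "mRNA",
      ID = mrna_id, Parent = g, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = gi$contig, start = ex$start, end = ex$end, type = "exon",
      ID = sprintf("%s.exon%d", g, ex$exon_rank), Parent = mrna_id,
      stringsAsFactors = FALSE)
    # genomic CDS intervals: exon pieces intersected with the CDS tx range
    cr <- cds_tx_range(models, g)
    o <- exon_tx_offsets(ex)
    cds_seen <- 0L
    for (i in seq_len(nrow(ex))) {
      lo <- max(cr["start"], o$offset[i] + 1L)
      hi <- min(cr["end"], o$offset[i] + o$width[i])
      if (lo <= hi) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = gi$contig,
          start = ex$start[i] + (lo - o$offset[i] - 1L),
          end = ex$start[i] + (hi - o$offset[i] - 1L),
          type = "CDS", ID = paste0(g, ".cds"), Parent = mrna_id,
          phase = (3L - cds_seen %% 3L) %% 3L, stringsAsFactors = FALSE)
        cds_seen <- cds_seen + (hi - lo + 1L)
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$phase)) r$phase <- NA_integer_
    r
  }))
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end),
                               strand = "+")
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   type = as.character(gr$type),
                   ID = as.character(gr$ID),
                   Parent = vapply(gr$Parent, function(p)
                     if (length(p)) p[[1L]] else NA_character_, ""),
                   stringsAsFactors = FALSE)
  genes_df <- df[df$type == "gene", ]
  mrna <- df[df$type == "mRNA", ]
  gene_of_mrna <- stats::setNames(mrna$Parent, mrna$ID)
  exons_df <- df[df$type == "exon", ]
  exons_df$gene_id <- gene_of_mrna[exons_df$Parent]
  cds_df <- df[df$type == "CDS", ]
  cds_df$gene_id <- gene_of_mrna[cds_df$Parent]

  exons <- do.call(rbind, lapply(genes_df$ID, function(g) {
    ex <- exons_df[exons_df$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    data.frame(gene_id = g, exon_rank = seq_len(nrow(ex)),
               start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  }))
  genes <- do.call(rbind, lapply(seq_len(nrow(genes_df)), function(i) {
    g <- genes_df$ID[i]
    ex <- exons[exons$gene_id == g, ]
    tx_len <- sum(ex$end - ex$start + 1L)
    cds <- cds_df[cds_df$gene_id == g, ]
    cds <- cds[order(cds$start), ]
    tmp <- gene_models(
      data.frame(gene_id = g, contig = genes_df$contig[i], strand = "+",
                 start = genes_df$start[i], end = genes_df$end[i],
                 utr5_len = 0L, cds_len = tx_len, utr3_len = 0L,
                 stringsAsFactors = FALSE), ex)
    cds_len <- sum(cds$end - cds$start + 1L)
    utr5 <- genome_to_tx(tmp, g, cds$start[1L]) - 1L
    data.frame(gene_id = g, contig = genes_df$contig[i], strand = "+",
               start = genes_df$start[i], end = genes_df$end[i],
               utr5_len = utr5, cds_len = cds_len,
               utr3_len = tx_len - utr5 - cds_len, stringsAsFactors = FALSE)
  }))
  gene_models(genes, exons)
}
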