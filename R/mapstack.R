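#' Toy spliced read mapper and pileup builder
#'
#' Replaces the aligner/recalibration/viewer triad of a production pipeline
#' at desk scale. Reads are anchored by two end k-mer seeds (k = 20 by
#' default) against an exact index of the annotated spliced transcripts;
#' discordant seed spacing implies an indel. When only one end seed anchors
#' uniquely (a planted allele sits inside the other seed), the read is
#' rescued by affine-gap alignment against the local transcript window and
#' accepted under a strict edit cap. Transcript alignments are projected to
#' genomic coordinates, introducing `N` CIGAR operations at exon junctions;
#' intron gaps are therefore resolved only against the annotated gene
#' models, never discovered de novo. Ambiguous multi-hit seeds leave a read
#' unmapped (no random placement), keeping the pipeline deterministic.
#'
#' @name mapstack
NULL

#' @import data.table
NULL

# ---------------------------------------------------------------- index

#' Build the exact k-mer transcript index
#'
#' @param reference named character vector of contig sequences.
#' @param models a `gene_models` object.
#' @param k seed length (default 20).
#' @return an object of class `tx_index`.
#' @export
transcript_index <- function(reference, models, k = 20L) {
  genes <- models$genes$gene_id
  tx <- vapply(genes, function(g) gene_transcript(reference, models, g), "")
  tabs <- lapply(seq_along(genes), function(i) {
    L <- nchar(tx[i])
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(tx[i], starts, starts + k - 1L),
                           gene = i, tpos = starts)
  })
  idx <- data.table::rbindlist(tabs)
  idx[, n := .N, by = kmer]
  data.table::setkey(idx, kmer)
  ex_cache <- lapply(genes, function(g) {
    ex <- gene_exons(models, g)
    o <- exon_tx_offsets(ex)
    list(start = ex$start, end = ex$end, offset = o$offset, width = o$width,
         contig = gene_info(models, g)$contig)
  })
  structure(list(idx = idx, k = k, genes = genes, tx = tx,
                 exons = ex_cache), class = "tx_index")
}

#' @export
print.tx_index <- function(x, ...) {
  cat(sprintf("tx_index: %d transcripts, k = %d, %d k-mers\n",
              length(x$genes), x$k, nrow(x$idx)))
  invisible(x)
}

count_mismatches <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# project a transcript-space alignment (tx_start + ops with M/D/I) to the
# genome, splitting reference-consuming ops across exons with N gaps
project_to_genome <- function(excache, tx_start, ops) {
  offset <- excache$offset; width <- excache$width
  gstart <- excache$start; gend <- excache$end
  cur <- tx_start
  out_len <- integer(0); out_op <- character(0)
  for (r in seq_len(nrow(ops))) {
    op <- ops$op[r]; len <- ops$len[r]
    if (op == "I") {
      out_len <- c(out_len, len); out_op <- c(out_op, "I")
      next
    }
    remaining <- len
    while (remaining > 0L) {
      ei <- findInterval(cur - 1L, offset)
      space <- offset[ei] + width[ei] - cur + 1L
      take <- min(space, remaining)
      out_len <- c(out_len, take); out_op <- c(out_op, op)
      cur <- cur + take; remaining <- remaining - take
      if (remaining > 0L) {
        intron <- gstart[ei + 1L] - gend[ei] - 1L
        out_len <- c(out_len, intron); out_op <- c(out_op, "N")
      }
    }
  }
  ei0 <- findInterval(tx_start - 1L, offset)
  list(pos = gstart[ei0] + (tx_start - offset[ei0] - 1L),
       cigar = cigar_string(data.frame(len = out_len, op = out_op)))
}

# rescue a read anchored by a single seed: affine-gap alignment of the read
# against a local window of the reference transcript
rescue_align <- function(read, txseq, win_start, win_end,
                         max_mismatch = 3L, max_gap = 50L) {
  win_start <- max(1L, win_start)
  win_end <- min(nchar(txseq), win_end)
  if (win_end - win_start + 1L < nchar(read)) return(NULL)
  window <- substr(txseq, win_start, win_end)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(window),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -6),
    gapOpening = 5, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::subject(al)), "")[[1L]]
  ops <- ifelse(pa == "-", "D", ifelse(sa == "-", "I", "M"))
  n_mm <- sum(ops == "M" & pa != sa)
  rle_ops <- rle(ops)
  gap_events <- sum(rle_ops$values %in% c("D", "I"))
  gap_len <- sum(rle_ops$lengths[rle_ops$values %in% c("D", "I")])
  if (n_mm > max_mismatch || gap_events > 1L || gap_len > max_gap) return(NULL)
  # an indel needs a solid match flank on both sides to be trustworthy
  if (gap_events == 1L &&
      (rle_ops$values[1L] != "M" || rle_ops$lengths[1L] < 8L ||
       rle_ops$values[length(rle_ops$values)] != "M" ||
       rle_ops$lengths[length(rle_ops$values)] < 8L)) return(NULL)
  list(tx_start = win_start + Biostrings::start(Biostrings::subject(al)) - 1L,
       ops = data.frame(len = rle_ops$lengths, op = rle_ops$values,
                        stringsAsFactors = FALSE),
       nm = n_mm + gap_len)
}

# shift a single indel in a transcript-space alignment to its leftmost
# equivalent placement, so every read reports the same anchor for an indel
# inside a repeat (the genomic record is additionally left-normalized at
# variant-calling time)
normalize_tx_ops <- function(seq, txseq, tx_start, ops) {
  ind <- which(ops$op %in% c("D", "I"))
  if (length(ind) != 1L) return(ops)
  pre <- sum(ops$len[seq_len(ind - 1L)][ops$op[seq_len(ind - 1L)] %in%
                                          c("M", "I")])
  g <- ops$len[ind]
  rl <- nchar(seq)
  if (pre < 1L || (ops$op[ind] == "D" && rl - pre < 1L) ||
      (ops$op[ind] == "I" && rl - pre - g < 1L)) return(ops)
  base <- function(s, i) substr(s, i, i)
  if (ops$op[ind] == "D") {
    while (pre > 1L &&
           base(seq, pre) == base(txseq, tx_start + pre - 1L) &&
           base(txseq, tx_start + pre - 1L) ==
             base(txseq, tx_start + pre + g - 1L)) {
      pre <- pre - 1L
    }
    data.frame(len = c(pre, g, rl - pre), op = c("M", "D", "M"))
  } else {
    while (pre > 1L &&
           base(seq, pre) == base(txseq, tx_start + pre - 1L) &&
           base(seq, pre + g) == base(txseq, tx_start + pre - 1L)) {
      pre <- pre - 1L
    }
    data.frame(len = c(pre, g, rl - pre - g), op = c("M", "I", "M"))
  }
}

# resolve one oriented read given its two seed hits (either may be NA);
# returns NULL if unmapped, else list(gene, tx_start, ops, nm)
resolve_read <- function(seq, g1, p1, g2, p2, index) {
  k <- index$k; rl <- nchar(seq)
  have1 <- !is.na(g1); have2 <- !is.na(g2)
  if (have1 && have2 && g1 == g2) {
    gap <- p2 - p1 - (rl - k)
    txseq <- index$tx[g1]
    if (gap == 0L) {
      refsub <- substr(txseq, p1, p1 + rl - 1L)
      nm <- count_mismatches(seq, refsub)
      if (nm <= 3L)
        return(list(gene = g1, tx_start = p1,
                    ops = data.frame(len = rl, op = "M"), nm = nm))
    } else if (gap > 0L && gap <= 50L) {
      # deletion of `gap` reference bases; split at the longest exact prefix
      refdel <- substr(txseq, p1, p1 + rl + gap - 1L)
      for (j in (k:(rl - k))) {
        pre_ok <- substr(seq, 1L, j) == substr(refdel, 1L, j)
        suf_ok <- substr(seq, j + 1L, rl) == substr(refdel, j + gap + 1L,
                                                    rl + gap)
        if (pre_ok && suf_ok)
          return(list(gene = g1, tx_start = p1,
                      ops = data.frame(len = c(j, gap, rl - j),
                                       op = c("M", "D", "M")), nm = gap))
      }
    } else if (gap < 0L && gap >= -50L) {
      ins <- -gap
      refins <- substr(txseq, p1, p1 + rl - ins - 1L)
      for (j in (k:(rl - k - ins))) {
        pre_ok <- substr(seq, 1L, j) == substr(refins, 1L, j)
        suf_ok <- substr(seq, j + ins + 1L, rl) == substr(refins, j + 1L,
                                                          rl - ins)
        if (pre_ok && suf_ok)
          return(list(gene = g1, tx_start = p1,
                      ops = data.frame(len = c(j, ins, rl - j - ins),
                                       op = c("M", "I", "M")), nm = ins))
      }
    }
  }
  # single-seed rescue (also reached when two-seed verification failed)
  if (have1) {
    r <- rescue_align(seq, index$tx[g1], p1 - 5L, p1 + rl + 60L)
    if (!is.null(r)) return(c(list(gene = g1), r))
  }
  if (have2) {
    anchor_end <- p2 + k - 1L      # tx position of the read's last base
    r <- rescue_align(seq, index$tx[g2], anchor_end - rl - 60L, anchor_end + 5L)
    if (!is.null(r)) return(c(list(gene = g2), r))
  }
  NULL
}

#' Map paired reads against the indexed transcripts
#'
#' @param reads a `read_set` from [simulate_reads()], or a data frame with
#'   columns id, seq1, qual1, seq2, qual2.
#' @param index a [transcript_index()].
#' @param models the matching `gene_models`.
#' @return an `alignments` data frame (SAM-like columns plus `gene_id`),
#'   with the mapped fraction in `attr(, "mapped_fraction")`.
#' @export
map_reads <- function(reads, index, models) {
  r <- if (inherits(reads, "read_set")) reads$reads else reads
  k <- index$k
  n <- nrow(r)
  # long form: one row per mate, primary orientation = generating orientation
  long <- data.table::data.table(
    qname = rep(r$id, 2L),
    mate = rep(c(1L, 2L), each = n),
    raw = c(r$seq1, r$seq2),
    qual = c(r$qual1, r$qual2))
  long[, seq := raw]
  long[mate == 2L, seq := revcomp(raw)]
  rl <- nchar(long$seq)
  if (any(rl < k + 1L)) stopf("reads shorter than seed length + 1")
  look <- function(seeds) {
    hit <- index$idx[data.table::data.table(kmer = seeds), on = "kmer",
                     mult = "first"]
    hit[!is.na(n) & n > 1L, `:=`(gene = NA_integer_, tpos = NA_integer_)]
    hit
  }
  h1 <- look(substr(long$seq, 1L, k))
  h2 <- look(substr(long$seq, rl - k + 1L, rl))
  long[, `:=`(g1 = h1$gene, p1 = h1$tpos, g2 = h2$gene, p2 = h2$tpos)]

  # fast path: both seeds agree on an ungapped placement
  long[, gap := p2 - p1 - (rl - k)]
  fast <- long[!is.na(g1) & !is.na(g2) & g1 == g2 & gap == 0L, which = TRUE]
  long[, `:=`(mapped = FALSE, gene = NA_integer_, tx_start = NA_integer_,
              nm = NA_integer_, cigar_tx = NA_character_)]
  if (length(fast)) {
    refsub <- substr(index$tx[long$g1[fast]], long$p1[fast],
                     long$p1[fast] + rl[fast] - 1L)
    mm <- count_mismatches(long$seq[fast], refsub)
    ok <- fast[mm <= 3L]
    mm_ok <- mm[mm <= 3L]
    long[ok, `:=`(mapped = TRUE, gene = g1, tx_start = p1,
                  nm = mm_ok, cigar_tx = paste0(rl[ok], "M"))]
  }
  # slow path: gapped / single-seed / failed verification, then the reverse
  # orientation as a fallback
  slow <- which(!long$mapped)
  ops_store <- vector("list", nrow(long))
  for (i in slow) {
    res <- NULL
    if (!is.na(long$g1[i]) || !is.na(long$g2[i]))
      res <- resolve_read(long$seq[i], long$g1[i], long$p1[i],
                          long$g2[i], long$p2[i], index)
    flip <- FALSE
    if (is.null(res)) {
      rc <- revcomp(long$seq[i])
      s1 <- substr(rc, 1L, k); s2 <- substr(rc, nchar(rc) - k + 1L, nchar(rc))
      hh1 <- index$idx[data.table::data.table(kmer = s1), on = "kmer",
                       mult = "first"]
      hh2 <- index$idx[data.table::data.table(kmer = s2), on = "kmer",
                       mult = "first"]
      u <- function(h) {
        if (!is.na(h$n) && h$n == 1L) c(h$gene, h$tpos)
        else c(NA_integer_, NA_integer_)
      }
      a <- u(hh1); b <- u(hh2)
      if (!is.na(a[1L]) || !is.na(b[1L])) {
        res <- resolve_read(rc, a[1L], a[2L], b[1L], b[2L], index)
        flip <- TRUE
      }
    }
    if (!is.null(res)) {
      aligned_seq <- if (flip) rc else long$seq[i]
      res$ops <- normalize_tx_ops(aligned_seq, index$tx[res$gene],
                                  res$tx_start, res$ops)
      data.table::set(long, i, "mapped", TRUE)
      data.table::set(long, i, "gene", res$gene)
      data.table::set(long, i, "tx_start", res$tx_start)
      data.table::set(long, i, "nm", res$nm)
      if (flip) {
        data.table::set(long, i, "seq", revcomp(long$seq[i]))
        data.table::set(long, i, "mate",
                        ifelse(long$mate[i] == 1L, -1L, -2L))
      }
      ops_store[[i]] <- res$ops
    }
  }

  # genomic projection
  m <- which(long$mapped)
  contig <- rep(NA_character_, nrow(long))
  gpos <- rep(NA_integer_, nrow(long))
  gcigar <- rep("*", nrow(long))
  for (i in m) {
    exc <- index$exons[[long$gene[i]]]
    ops <- ops_store[[i]] %||%
      data.frame(len = nchar(long$seq[i]), op = "M")
    pr <- project_to_genome(exc, long$tx_start[i], ops)
    contig[i] <- exc$contig
    gpos[i] <- pr$pos
    gcigar[i] <- pr$cigar
  }
  long[, `:=`(contig = contig, pos = gpos, cigar = gcigar)]

  # flags + mate fields (mate < 0 encodes an orientation flip)
  long[, is_r2 := abs(mate) == 2L]
  long[, reverse := (is_r2 & mate > 0L) | (!is_r2 & mate < 0L)]
  d1 <- long[is_r2 == FALSE]
  d2 <- long[is_r2 == TRUE]
  data.table::setkey(d1, qname); data.table::setkey(d2, qname)
  d2 <- d2[d1$qname]
  reflen_of <- function(cig) {
    u <- unique(cig)
    vapply(u, cigar_ref_len, 1L)[match(cig, u)]
  }
  build <- function(a, b, first) {
    flag <- 1L + 64L * first + 128L * (1L - first)
    flag <- flag + 4L * (!a$mapped) + 8L * (!b$mapped) +
      16L * (a$mapped & a$reverse) + 32L * (b$mapped & b$reverse)
    same_ctg <- !is.na(a$contig) & !is.na(b$contig) & a$contig == b$contig
    both <- a$mapped & b$mapped & same_ctg
    flag <- flag + 2L * both
    tlen <- ifelse(both,
                   pmax(a$pos + reflen_of(a$cigar),
                        b$pos + reflen_of(b$cigar)) - pmin(a$pos, b$pos),
                   0L)
    tlen <- ifelse(both & a$pos > b$pos, -tlen, tlen)
    data.frame(qname = a$qname, flag = flag,
               contig = ifelse(a$mapped, a$contig, "*"),
               pos = ifelse(a$mapped, a$pos, 0L),
               mapq = ifelse(a$mapped, 60L, 0L),
               cigar = ifelse(a$mapped, a$cigar, "*"),
               rnext = ifelse(b$mapped & both, "=",
                              ifelse(b$mapped, b$contig, "*")),
               pnext = ifelse(b$mapped, b$pos, 0L),
               tlen = as.integer(tlen),
               seq = a$seq, qual = a$qual,
               nm = ifelse(a$mapped, a$nm, 0L),
               gene_id = ifelse(a$mapped, index$genes[a$gene], NA_character_),
               stringsAsFactors = FALSE)
  }
  out <- rbind(build(d1, d2, 1L), build(d2, d1, 0L))
  attr(out, "mapped_fraction") <- mean(long$mapped)
  class(out) <- c("alignments", "data.frame")
  out
}

#' Sort alignments by contig and position
#'
#' @param aln an alignments data frame.
#' @export
sort_alignments <- function(aln) {
  out <- aln[order(aln$contig, aln$pos), , drop = FALSE]
  attr(out, "mapped_fraction") <- attr(aln, "mapped_fraction")
  attr(out, "sorted") <- TRUE
  class(out) <- c("alignments", "data.frame")
  out
}

#' @export
print.alignments <- function(x, ...) {
  mf <- attr(x, "mapped_fraction")
  cat(sprintf("alignments: %d records%s\n", nrow(x),
              if (!is.null(mf)) sprintf(", mapped fraction %.3f", mf) else ""))
  invisible(x)
}

# ---------------------------------------------------------------- pileup

#' Build a pileup from sorted alignments
#'
#' Per-column multisets of observed alleles. Deleted reference bases are
#' recorded as `-` calls at every deleted position (so they contribute to
#' depth) and additionally as a single deletion event at the deletion's
#' anchor (its leftmost deleted base as reported by the alignment; indel
#' records are left-normalized later, at variant-calling time). Insertions
#' are recorded as events anchored at the base before the inserted sequence.
#'
#' @param aln sorted alignments (see [sort_alignments()]); unsorted input is
#'   a named error.
#' @param regions optional data frame (contig, start, end) restricting the
#'   pileup; columns outside the regions are dropped.
#' @return an object of class `pileup`: list with `base_calls`
#'   (contig, pos, call, count) and `events` (contig, pos, type, len, seq,
#'   count) data tables.
#' @export
build_pileup <- function(aln, regions = NULL) {
  mapped <- aln[aln$cigar != "*", , drop = FALSE]
  if (nrow(mapped)) {
    o <- order(mapped$contig, mapped$pos)
    if (any(o != seq_len(nrow(mapped))))
      stopf("unsorted alignments: run sort_alignments() first")
  }
  ctg_l <- list(); pos_l <- list(); call_l <- list()
  ev <- list()
  cig_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(mapped))) {
    cg <- mapped$cigar[i]
    ops <- get0(cg, envir = cig_cache) %||% {
      p <- cigar_parse(cg); assign(cg, p, envir = cig_cache); p
    }
    rp <- mapped$pos[i]     # reference cursor
    qp <- 1L                # query cursor
    seqi <- mapped$seq[i]
    for (r in seq_len(nrow(ops))) {
      len <- ops$len[r]; op <- ops$op[r]
      if (op == "M") {
        idx <- length(pos_l) + 1L
        pos_l[[idx]] <- rp:(rp + len - 1L)
        call_l[[idx]] <- strsplit(substr(seqi, qp, qp + len - 1L), "")[[1L]]
        ctg_l[[idx]] <- rep(mapped$contig[i], len)
        rp <- rp + len; qp <- qp + len
      } else if (op == "D") {
        idx <- length(pos_l) + 1L
        pos_l[[idx]] <- rp:(rp + len - 1L)
        call_l[[idx]] <- rep("-", len)
        ctg_l[[idx]] <- rep(mapped$contig[i], len)
        ev[[length(ev) + 1L]] <- data.frame(contig = mapped$contig[i],
                                            pos = rp, type = "D", len = len,
                                            seq = NA_character_)
        rp <- rp + len
      } else if (op == "I") {
        ev[[length(ev) + 1L]] <- data.frame(
          contig = mapped$contig[i], pos = rp - 1L, type = "I", len = len,
          seq = substr(seqi, qp, qp + len - 1L))
        qp <- qp + len
      } else if (op == "N") {
        rp <- rp + len
      } else if (op == "S") {
        qp <- qp + len
      }
    }
  }
  bc <- data.table::data.table(contig = unlist(ctg_l),
                               pos = unlist(pos_l), call = unlist(call_l))
  if (nrow(bc)) bc <- bc[, .(count = .N), by = .(contig, pos, call)]
  else bc <- data.table::data.table(contig = character(0), pos = integer(0),
                                    call = character(0), count = integer(0))
  evd <- if (length(ev)) data.table::rbindlist(ev)[
    , .(count = .N), by = .(contig, pos, type, len, seq)]
  else data.table::data.table(contig = character(0), pos = integer(0),
                              type = character(0), len = integer(0),
                              seq = character(0), count = integer(0))
  if (!is.null(regions)) {
    keep_pos <- function(dt) {
      if (!nrow(dt)) return(dt)
      ok <- rep(FALSE, nrow(dt))
      for (ctg in unique(regions$contig)) {
        rr <- regions[regions$contig == ctg, , drop = FALSE]
        sel <- dt$contig == ctg
        if (!any(sel)) next
        p <- dt$pos[sel]
        inside <- rep(FALSE, length(p))
        for (j in seq_len(nrow(rr)))
          inside <- inside | (p >= rr$start[j] & p <= rr$end[j])
        ok[sel] <- inside
      }
      dt[ok]
    }
    bc <- keep_pos(bc)
    evd <- keep_pos(evd)
  }
  data.table::setkey(bc, contig, pos)
  structure(list(base_calls = bc, events = evd, regions = regions),
            class = "pileup")
}

#' Per-column depth of a pileup
#'
#' Depth counts every recorded call at a column, including deletion markers.
#'
#' @param pile a `pileup`.
#' @return data table (contig, pos, depth).
#' @export
pileup_depth <- function(pile) {
  d <- pile$base_calls[, .(depth = sum(count)), by = .(contig, pos)]
  data.table::setkey(d, contig, pos)
  d
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: %d columns, %d indel events\n",
              nrow(unique(x$base_calls[, .(contig, pos)])), nrow(x$events)))
  invisible(x)
}
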