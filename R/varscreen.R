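#' Coverage, variant detection and the recessive-model filter cascade
#'
#' The analytical core of the screen: a coverage-completeness census over
#' the candidate genes, pileup-based SNV/indel detection with zygosity from
#' allele fractions, indel left-normalization, coding-consequence
#' annotation, and the exclusion cascade that, under an autosomal recessive
#' model with a single sequenced affected individual, removes genes whose
#' variants cannot be causal and leaves the candidate.
#'
#' @name varscreen
NULL

# ------------------------------------------------------------------- census

#' Coverage-completeness census over candidate genes
#'
#' A gene is complete iff every exonic base has pileup depth >=
#' `min_depth`; deleted bases covered by deletion-spanning reads count as
#' covered (their deletion markers contribute to depth). Uncovered exonic
#' intervals are reported 1-based inclusive.
#'
#' @param pile a `pileup` (built over at least the exonic regions).
#' @param models `gene_models`.
#' @param min_depth minimum depth for a base to count as covered (default 1).
#' @return data frame (gene_id, coverage_status, n_uncovered) with the
#'   uncovered intervals in `attr(, "uncovered")`.
#' @export
coverage_census <- function(pile, models, min_depth = 1L) {
  if (min_depth < 1L) stopf("min_depth must be >= 1")
  dp <- pileup_depth(pile)
  res <- list(); unc <- list()
  for (g in models$genes$gene_id) {
    gi <- gene_info(models, g)
    ex <- gene_exons(models, g)   # errors if the gene has no exons
    pos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
    want <- data.table::data.table(contig = gi$contig, pos = pos)
    d <- dp[want, on = c("contig", "pos")]$depth
    d[is.na(d)] <- 0L
    bad <- pos[d < min_depth]
    if (length(bad)) {
      grp <- cumsum(c(TRUE, diff(bad) != 1L))  # runs of consecutive positions
      iv <- data.frame(gene_id = g, contig = gi$contig,
                       start = tapply(bad, grp, min),
                       end = tapply(bad, grp, max), row.names = NULL)
      unc[[length(unc) + 1L]] <- iv
    }
    res[[length(res) + 1L]] <- data.frame(
      gene_id = g,
      coverage_status = if (length(bad)) "incomplete" else "complete",
      n_uncovered = length(bad), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "uncovered") <- if (length(unc)) do.call(rbind, unc) else NULL
  out
}

# ------------------------------------------------------------- left_normalize

#' Left-normalize an indel against the reference
#'
#' Shifts an anchored indel to its leftmost equivalent placement (the
#' standard left-alignment used so that all tools report the same
#' coordinates for indels inside repeats). SNVs pass through unchanged; the
#' operation is idempotent.
#'
#' @param variant one-row data frame with columns contig, pos, ref, alt.
#' @param reference named character vector of contig sequences.
#' @return the variant with normalized pos/ref/alt.
#' @export
left_normalize <- function(variant, reference) {
  seqs <- reference[[variant$contig]]
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  if (substr(seqs, pos, pos + nchar(ref) - 1L) != ref)
    stopf("allele/reference mismatch at %s:%d", variant$contig, pos)
  if (nchar(ref) == nchar(alt)) return(variant)  # SNV/MNV: nothing to do
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    # trim identical trailing base, re-extending left when an allele empties
    if (nchar(ref) > 0L && nchar(alt) > 0L && last(ref) == last(alt)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) stopf("indel cannot be left-anchored at contig start")
        pos <- pos - 1L
        b <- substr(seqs, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  # trim identical leading bases beyond the single anchor
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  variant$pos <- pos; variant$ref <- ref; variant$alt <- alt
  variant
}

# ------------------------------------------------------------ detect_variants

#' Detect variants from a pileup
#'
#' At columns with depth >= `min_depth`, a non-reference allele whose
#' fraction of the column depth is at least `hom_threshold` yields a
#' homozygous call, and a fraction inside `het_band` (left-closed,
#' right-open) a heterozygous call; weaker evidence is silently reference.
#' Indel events are assembled from the pileup's event records into single
#' anchored records and left-normalized.
#'
#' @param pile a `pileup`.
#' @param reference named character vector of contig sequences.
#' @param min_depth minimum column depth to call (default 3).
#' @param het_band heterozygous allele-fraction band (default `[0.2, 0.8)`).
#' @param hom_threshold homozygous allele-fraction threshold (default 0.8).
#' @return variant data frame (contig, pos, ref, alt, genotype, type, depth,
#'   alt_count).
#' @export
detect_variants <- function(pile, reference, min_depth = 3L,
                            het_band = c(0.2, 0.8), hom_threshold = 0.8) {
  stopifnot(het_band[1L] > 0, het_band[2L] <= 1, hom_threshold > 0,
            hom_threshold <= 1)
  if (min_depth < 3L) stopf("min_depth must be >= 3")
  dp <- pileup_depth(pile)
  bc <- merge(pile$base_calls, dp, by = c("contig", "pos"))
  bc <- bc[depth >= min_depth & call %in% DNA_BASES]
  # reference base per column
  bc[, ref := substring(reference[contig], pos, pos), by = contig]
  snv <- bc[call != ref]
  snv[, frac := count / depth]
  snv <- snv[frac >= het_band[1L]]
  rows <- list()
  if (nrow(snv)) {
    snv[, genotype := ifelse(frac >= hom_threshold, "hom",
                             ifelse(frac < het_band[2L], "het", "hom"))]
    # fraction in [het_band[2], hom_threshold) is ambiguous; call het only
    # if inside the band, hom only at/above the threshold
    snv <- snv[frac >= hom_threshold | frac < het_band[2L]]
    rows[[1L]] <- data.frame(contig = snv$contig, pos = snv$pos,
                             ref = snv$ref, alt = snv$call,
                             genotype = snv$genotype, type = "snv",
                             depth = snv$depth, alt_count = snv$count,
                             stringsAsFactors = FALSE)
  }
  ev <- pile$events
  if (nrow(ev)) {
    # equivalent placements of the same indel inside a repeat are merged by
    # left-normalizing every event before aggregation and thresholding
    anch <- lapply(seq_len(nrow(ev)), function(r) {
      e <- ev[r]
      ctg_seq <- reference[[e$contig]]
      if (e$type == "D") {
        v <- data.frame(contig = e$contig, pos = e$pos - 1L,
                        ref = substr(ctg_seq, e$pos - 1L, e$pos + e$len - 1L),
                        alt = substr(ctg_seq, e$pos - 1L, e$pos - 1L),
                        type = "del", stringsAsFactors = FALSE)
      } else {
        v <- data.frame(contig = e$contig, pos = e$pos,
                        ref = substr(ctg_seq, e$pos, e$pos),
                        alt = paste0(substr(ctg_seq, e$pos, e$pos), e$seq),
                        type = "ins", stringsAsFactors = FALSE)
      }
      cbind(left_normalize(v, reference), count = e$count)
    })
    anch <- data.table::rbindlist(anch)
    anch <- anch[, .(count = sum(count)), by = .(contig, pos, ref, alt, type)]
    # effective depth: event support plus reads that truly contradict it.
    # For a deletion inside a repeat, reads ending within the repeat are
    # reference-consistent yet uninformative; a read only contradicts the
    # deletion if it shows a base at every deleted column, so the
    # reference-supporting depth is the minimum non-marker depth across the
    # deleted columns. Insertions use the depth at their anchor column.
    bc <- pile$base_calls
    eff <- vapply(seq_len(nrow(anch)), function(r) {
      a <- anch[r]
      if (a$type == "del") {
        len <- nchar(a$ref) - nchar(a$alt)
        cols <- (a$pos + 1L):(a$pos + len)
        refb <- substring(reference[[a$contig]], cols, cols)
        want <- data.table::data.table(contig = a$contig, pos = cols,
                                       call = refb)
        per_col <- bc[want, on = c("contig", "pos", "call")]$count
        per_col[is.na(per_col)] <- 0L
        a$count + min(per_col)
      } else {
        d <- dp[data.table::data.table(contig = a$contig, pos = a$pos),
                on = c("contig", "pos")]$depth
        if (is.na(d)) a$count else max(d, a$count)
      }
    }, 1)
    anch[, depth := as.integer(eff)]
    anch <- anch[depth >= min_depth]
    anch[, frac := count / depth]
    anch <- anch[frac >= hom_threshold |
                   (frac >= het_band[1L] & frac < het_band[2L])]
    if (nrow(anch)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = anch$contig, pos = anch$pos, ref = anch$ref, alt = anch$alt,
        genotype = ifelse(anch$frac >= hom_threshold, "hom", "het"),
        type = anch$type, depth = anch$depth, alt_count = anch$count,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), genotype = character(0),
               type = character(0), depth = integer(0),
               alt_count = integer(0), stringsAsFactors = FALSE)
  # a homozygously deleted interval has no sequence to carry an SNV: stray
  # alt calls there come from repeat-register misalignments
  homdel <- out[out$type == "del" & out$genotype == "hom", , drop = FALSE]
  if (nrow(homdel) && nrow(out)) {
    drop <- rep(FALSE, nrow(out))
    for (r in seq_len(nrow(homdel))) {
      len <- nchar(homdel$ref[r]) - nchar(homdel$alt[r])
      drop <- drop | (out$type == "snv" & out$contig == homdel$contig[r] &
                        out$pos > homdel$pos[r] &
                        out$pos <= homdel$pos[r] + len)
    }
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ------------------------------------------------------------ annotate_coding

#' Annotate variants with their coding consequence
#'
#' Locates each (normalized) variant in the gene models and classifies it:
#' region (cds / utr / intronic / intergenic) and, for CDS variants, the
#' effect computed by codon-table translation of the reference versus
#' mutant codon (synonymous / missense / nonsense); CDS indels whose length
#' is not a multiple of 3 are frameshifts, others in-frame indels. Emits
#' HGVS c. strings and p. strings for SNVs.
#'
#' @param variants variant data frame from [detect_variants()].
#' @param models `gene_models`.
#' @param reference named character vector of contig sequences.
#' @return the variants with annotation columns appended (gene_id, region,
#'   effect, codon_index, ref_aa, alt_aa, hgvs_c, hgvs_p).
#' @export
annotate_coding <- function(variants, models, reference) {
  n <- nrow(variants)
  ann <- data.frame(gene_id = rep(NA_character_, n), region = "intergenic",
                    effect = NA_character_, codon_index = NA_integer_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    hgvs_c = NA_character_, hgvs_p = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    gsel <- models$genes[models$genes$contig == v$contig &
                           models$genes$start <= v$pos &
                           models$genes$end >= v$pos, , drop = FALSE]
    if (!nrow(gsel)) next
    g <- gsel$gene_id[1L]
    ann$gene_id[i] <- g
    cr <- cds_tx_range(models, g)
    indel_len <- nchar(v$ref) - nchar(v$alt)
    if (v$type == "snv" || indel_len == 0L) {
      txp <- genome_to_tx(models, g, v$pos)
      if (is.na(txp)) { ann$region[i] <- "intronic"; next }
      if (txp < cr["start"] || txp > cr["end"]) {
        ann$region[i] <- "utr"
        next
      }
      ann$region[i] <- "cds"
      cds_pos <- txp - cr["start"] + 1L
      cds <- gene_cds(reference, models, g)
      ch <- snv_codon_change(cds, cds_pos, v$alt)
      ann$codon_index[i] <- ch$codon_index
      ann$ref_aa[i] <- ch$ref_aa
      ann$alt_aa[i] <- ch$alt_aa
      ann$effect[i] <- if (ch$ref_aa == ch$alt_aa) "synonymous"
        else if (ch$alt_aa == "*") "nonsense" else "missense"
      ann$hgvs_c[i] <- sprintf("c.%d%s>%s", cds_pos, v$ref, v$alt)
      ann$hgvs_p[i] <- sprintf("p.%s%d%s", ch$ref_aa, ch$codon_index,
                               ch$alt_aa)
    } else {
      # indel: affected reference bases are pos+1 .. pos+|len| for deletions,
      # the anchor base for insertions
      aff <- if (indel_len > 0L) (v$pos + 1L):(v$pos + indel_len) else v$pos
      txp <- genome_to_tx(models, g, aff)
      if (all(is.na(txp))) { ann$region[i] <- "intronic"; next }
      txp_in <- txp[!is.na(txp)]
      in_cds <- any(txp_in >= cr["start"] & txp_in <= cr["end"])
      if (!in_cds) { ann$region[i] <- "utr"; next }
      ann$region[i] <- "cds"
      ann$effect[i] <- if (abs(indel_len) %% 3L != 0L) "frameshift"
        else "inframe_indel"
      cds_from <- txp_in[1L] - cr["start"] + 1L
      if (indel_len > 0L) {
        ann$hgvs_c[i] <- sprintf("c.%d_%ddel", cds_from,
                                 cds_from + indel_len - 1L)
      } else {
        ann$hgvs_c[i] <- sprintf("c.%d_%dins%s", cds_from, cds_from + 1L,
                                 substr(v$alt, 2L, nchar(v$alt)))
      }
    }
  }
  cbind(variants, ann)
}

# ------------------------------------------------------------- filter_cascade

#' Recessive-model exclusion cascade over candidate genes
#'
#' Classifies every gene from its annotated variants, in fixed order:
#' no variants -> `no_polymorphisms`; all variants outside the CDS ->
#' `noncoding_only`; all CDS variants heterozygous ->
#' `excluded_heterozygous` (a recessive causal variant must be homozygous
#' in the affected); all CDS variants synonymous -> `excluded_synonymous`;
#' every non-synonymous CDS variant a missense whose alternate residue is
#' observed in the ortholog panel at that codon ->
#' `excluded_nonsynonymous_tolerated` (covers both the conserved-alternate
#' and natural-variation situations); anything remaining (homozygous
#' loss-of-function or non-tolerated missense) -> `candidate_causal`.
#' Categories partition the genes and do not depend on variant input order.
#'
#' @param variants annotated variant data frame from [annotate_coding()].
#' @param models `gene_models`.
#' @param conservation a `conservation_matrix` (or NULL: no missense is
#'   considered tolerated).
#' @param census optional coverage census to carry coverage_status along.
#' @return data frame of class `gene_reports`: gene_id, coverage_status,
#'   n_variants, category, rationale.
#' @export
filter_cascade <- function(variants, models, conservation = NULL,
                           census = NULL) {
  known <- models$genes$gene_id
  seen <- unique(stats::na.omit(variants$gene_id))
  if (length(setdiff(seen, known)))
    stopf("variant gene %s absent from the gene models",
          setdiff(seen, known)[1L])
  rows <- lapply(known, function(g) {
    gv <- variants[!is.na(variants$gene_id) & variants$gene_id == g, ,
                   drop = FALSE]
    gv <- gv[gv$region != "intergenic", , drop = FALSE]
    cat_ <- NULL; why <- NULL
    if (!nrow(gv)) {
      cat_ <- "no_polymorphisms"; why <- "no variants detected"
    } else {
      cds_v <- gv[gv$region == "cds", , drop = FALSE]
      if (!nrow(cds_v)) {
        cat_ <- "noncoding_only"
        why <- "variants in non-coding (UTR/intronic) regions only"
      } else if (all(cds_v$genotype == "het")) {
        cat_ <- "excluded_heterozygous"
        why <- "only heterozygous coding variants; recessive model requires homozygosity in the affected"
      } else if (all(cds_v$effect == "synonymous")) {
        cat_ <- "excluded_synonymous"
        why <- "all coding variants synonymous"
      } else {
        nonsyn <- cds_v[cds_v$effect != "synonymous", , drop = FALSE]
        tol <- nrow(nonsyn) > 0L && all(nonsyn$effect == "missense") &&
          !is.null(conservation) &&
          all(vapply(seq_len(nrow(nonsyn)), function(k)
            residue_observed(conservation, g, nonsyn$codon_index[k],
                             nonsyn$alt_aa[k]), TRUE))
        if (tol) {
          cat_ <- "excluded_nonsynonymous_tolerated"
          why <- "alternate residue observed in the ortholog panel at that codon"
        } else {
          cat_ <- "candidate_causal"
          why <- "homozygous loss-of-function or non-tolerated missense variant"
        }
      }
    }
    data.frame(gene_id = g, n_variants = nrow(gv), category = cat_,
               rationale = why, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$coverage_status <- if (!is.null(census))
    census$coverage_status[match(out$gene_id, census$gene_id)]
  else NA_character_
  out <- out[, c("gene_id", "coverage_status", "n_variants", "category",
                 "rationale")]
  class(out) <- c("gene_reports", "data.frame")
  out
}

#' @export
print.gene_reports <- function(x, ...) {
  cat("candidate-gene screen:\n")
  print(table(x$category))
  invisible(x)
}

#' Tabulate cascade categories
#'
#' @param reports a `gene_reports` data frame.
#' @param complete_only count only coverage-complete genes (the convention
#'   used when comparing with a screen that classifies covered genes).
#' @return named integer vector of category counts.
#' @export
category_counts <- function(reports, complete_only = FALSE) {
  r <- reports
  if (complete_only && !all(is.na(r$coverage_status)))
    r <- r[r$coverage_status == "complete", , drop = FALSE]
  lv <- c("no_polymorphisms", "noncoding_only", "excluded_heterozygous",
          "excluded_synonymous", "excluded_nonsynonymous_tolerated",
          "candidate_causal")
  table(factor(r$category, levels = lv))
}
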