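#' Scenario specification for the synthetic candidate-gene screen
#'
#' A scenario describes the study conditions the generator emulates: how many
#' candidate genes exist, which planted-variant category each gene carries,
#' which genes are fully covered by the read set, and the sequencing
#' parameters. The default 27-gene plan reproduces the published single-case
#' screen: 24 genes fully covered, of which 11 carry no polymorphism, 3 carry
#' non-coding (UTR) variants only, 4 carry heterozygous coding SNVs, 2 carry
#' homozygous synonymous SNVs, 3 carry homozygous missense changes whose
#' alternate residue is tolerated across an ortholog panel, and exactly 1
#' carries the causal homozygous 8 bp frameshift deletion sitting in a
#' tandem repeat with a linked SNV 18 bp downstream; the remaining 3 genes
#' have a zero-coverage exonic window and carry no variants.
#'
#' @param seed integer seed; all generators derive their randomness from it.
#' @param n_genes number of candidate genes (default 27).
#' @param category_plan character vector (length `n_genes`) of planted-variant
#'   categories; see Details for the allowed values.
#' @param coverage_plan logical vector (length `n_genes`): is the gene fully
#'   covered by reads?
#' @param read_length read length in bases (default 51, paired-end).
#' @param mean_depth target mean fold-coverage of the random fragment layer
#'   (default 30).
#' @param frag_len fragment length of the random layer in bases.
#' @param error_rate uniform per-base substitution error rate (default 0:
#'   callers are exercised on clean signal).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed, n_genes = 27L,
                          category_plan = default_category_plan(n_genes),
                          coverage_plan = default_coverage_plan(n_genes),
                          read_length = 51L, mean_depth = 30,
                          frag_len = 160L, error_rate = 0) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stopf("seed must be a non-negative integer")
  allowed <- c("none", "noncoding_only", "heterozygous_snv", "synonymous_snv",
               "nonsynonymous_tolerated", "causal_frameshift_deletion")
  if (length(category_plan) != n_genes || !all(category_plan %in% allowed))
    stopf("category_plan must give one allowed category per gene")
  if (sum(category_plan == "causal_frameshift_deletion") > 1L)
    stopf("at most one gene may carry the causal frameshift deletion")
  if (length(coverage_plan) != n_genes || !is.logical(coverage_plan))
    stopf("coverage_plan must be a logical vector of length n_genes")
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  structure(list(seed = seed, n_genes = as.integer(n_genes),
                 category_plan = category_plan, coverage_plan = coverage_plan,
                 read_length = as.integer(read_length),
                 mean_depth = mean_depth, frag_len = as.integer(frag_len),
                 error_rate = error_rate),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
default_category_plan <- function(n_genes) {
  if (n_genes == 27L) {
    c(rep("none", 11), rep("noncoding_only", 3), rep("heterozygous_snv", 4),
      rep("synonymous_snv", 2), rep("nonsynonymous_tolerated", 3),
      "causal_frameshift_deletion", rep("none", 3))
  } else {
    pool <- c("causal_frameshift_deletion", "heterozygous_snv",
              "synonymous_snv", "nonsynonymous_tolerated",
              "noncoding_only", "none")
    c("causal_frameshift_deletion",
      rep_len(pool[-1L], max(0L, n_genes - 1L)))[seq_len(n_genes)]
  }
}

#' @rdname scenario_spec
#' @export
default_coverage_plan <- function(n_genes) {
  if (n_genes == 27L) c(rep(TRUE, 24), rep(FALSE, 3)) else rep(TRUE, n_genes)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec: %d genes, %d fully covered, read length %d, depth %g, seed %d\n",
              x$n_genes, sum(x$coverage_plan), x$read_length, x$mean_depth,
              x$seed))
  print(table(x$category_plan))
  invisible(x)
}

scenario_gene_ids <- function(spec) sprintf("GENE%02d", seq_len(spec$n_genes))

# ------------------------------------------------------------ build_reference

#' Build the toy reference genome and gene models of a scenario
#'
#' Each gene sits on its own contig, has 3-6 exons (widths 90-240 bp) with
#' GT..AG introns, a CDS that starts with ATG, has length divisible by 3 and
#' a single in-frame stop at its end, and 5'/3' UTRs. Deterministic for a
#' fixed scenario seed.
#'
#' @param spec a [scenario_spec()].
#' @return `list(reference = named character vector, models = gene_models)`.
#' @export
build_reference <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(sub_seed(spec$seed, 101L))
  ids <- scenario_gene_ids(spec)
  sense <- sense_codons()
  flank <- 200L
  ref <- character(spec$n_genes)
  names(ref) <- sprintf("chr%02d", seq_len(spec$n_genes))
  genes_rows <- vector("list", spec$n_genes)
  exons_rows <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    n_ex <- sample(3:6, 1L)
    widths <- sample(90:240, n_ex, replace = TRUE)
    if (spec$read_length > min(widths))
      stopf("read_length %d exceeds the shortest exon (%d bp)",
            spec$read_length, min(widths))
    introns <- sample(200:500, n_ex - 1L, replace = TRUE)
    tx_len <- sum(widths)
    utr5 <- sample(30:80, 1L)
    cds_len <- 3L * ((tx_len - utr5 - 30L) %/% 3L)
    utr3 <- tx_len - utr5 - cds_len
    n_codons <- cds_len %/% 3L
    cds <- paste0("ATG",
                  paste(sample(sense, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    tx <- paste0(rand_dna(utr5), cds, rand_dna(utr3))
    # slice the transcript into exons, interleave GT..AG introns
    offs <- cumsum(c(0L, widths[-n_ex]))
    exon_seqs <- substring(tx, offs + 1L, offs + widths)
    intron_seqs <- if (n_ex > 1L)
      paste0("GT", vapply(introns - 4L, rand_dna, ""), "AG") else character(0)
    pieces <- character(2L * n_ex - 1L)
    pieces[seq(1L, by = 2L, length.out = n_ex)] <- exon_seqs
    if (n_ex > 1L) pieces[seq(2L, by = 2L, length.out = n_ex - 1L)] <- intron_seqs
    body <- paste(pieces, collapse = "")
    ref[i] <- paste0(rand_dna(flank), body, rand_dna(flank))
    ex_starts <- flank + 1L + cumsum(c(0L, (widths + c(introns, 0L))[-n_ex]))
    exons_rows[[i]] <- data.frame(gene_id = ids[i], exon_rank = seq_len(n_ex),
                                  start = ex_starts,
                                  end = ex_starts + widths - 1L,
                                  stringsAsFactors = FALSE)
    genes_rows[[i]] <- data.frame(gene_id = ids[i], contig = names(ref)[i],
                                  strand = "+", start = flank + 1L,
                                  end = flank + nchar(body),
                                  utr5_len = utr5, cds_len = cds_len,
                                  utr3_len = utr3, stringsAsFactors = FALSE)
  }
  models <- gene_models(do.call(rbind, genes_rows), do.call(rbind, exons_rows))
  list(reference = ref, models = models)
}

# ------------------------------------------------------------- plant_variants

snv_codon_change <- function(cds, cds_pos, alt_base) {
  ci <- (cds_pos - 1L) %/% 3L + 1L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon <- substr(cds, 3L * ci - 2L, 3L * ci)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_base
  list(codon_index = ci,
       ref_aa = unname(Biostrings::GENETIC_CODE[codon]),
       alt_aa = unname(Biostrings::GENETIC_CODE[alt_codon]))
}

# pick a CDS SNV of the requested kind; returns NULL if no draw succeeded
draw_cds_snv <- function(cds, kind, tries = 200L) {
  n_codons <- nchar(cds) %/% 3L
  for (t in seq_len(tries)) {
    ci <- sample(5:(n_codons - 5L), 1L)
    within <- sample(1:3, 1L)
    cds_pos <- 3L * (ci - 1L) + within
    ref_base <- substr(cds, cds_pos, cds_pos)
    for (alt in sample(setdiff(DNA_BASES, ref_base))) {
      ch <- snv_codon_change(cds, cds_pos, alt)
      ok <- switch(kind,
                   synonymous = ch$ref_aa == ch$alt_aa,
                   missense = ch$ref_aa != ch$alt_aa && ch$alt_aa != "*")
      if (ok) return(c(list(cds_pos = cds_pos, ref = ref_base, alt = alt), ch))
    }
  }
  NULL
}

planted_variant_row <- function(gene_id, contig, pos, ref, alt, zygosity,
                                region, type, tx_pos, codon_index = NA_integer_,
                                ref_aa = NA_character_, alt_aa = NA_character_,
                                del_start = NA_integer_, del_end = NA_integer_) {
  data.frame(gene_id = gene_id, contig = contig, pos = pos, ref = ref,
             alt = alt, zygosity = zygosity, region = region, type = type,
             tx_pos = tx_pos, codon_index = codon_index, ref_aa = ref_aa,
             alt_aa = alt_aa, del_start = del_start, del_end = del_end,
             stringsAsFactors = FALSE)
}

#' Plant the scenario's variants into the reference (truth set)
#'
#' Plants one variant per gene according to the scenario's category plan
#' (UTR SNVs for the non-coding category; heterozygous missense, homozygous
#' synonymous, homozygous tolerated-missense coding SNVs; and for the causal
#' gene a homozygous 8 bp exonic deletion plus a linked homozygous SNV 18 bp
#' downstream). For the causal gene the reference itself is edited so that
#' the 8 bases immediately 5' of the deleted bases are an identical copy
#' (a tandem repeat, mimicking a homologous-recombination deletion), which is
#' why the possibly modified reference is returned alongside the truth set.
#'
#' @param reference named character vector from [build_reference()].
#' @param models the matching `gene_models`.
#' @param spec the [scenario_spec()].
#' @return `list(variants = data.frame truth set, reference = reference with
#'   the engineered tandem repeat)`.
#' @export
plant_variants <- function(reference, models, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(sub_seed(spec$seed, 202L))
  ids <- scenario_gene_ids(spec)
  rows <- list()
  for (i in seq_len(spec$n_genes)) {
    cat_i <- spec$category_plan[i]
    if (cat_i == "none") next
    g <- ids[i]
    gi <- gene_info(models, g)
    tx <- gene_transcript(reference, models, g)
    cr <- cds_tx_range(models, g)
    cds <- substr(tx, cr["start"], cr["end"])

    if (cat_i == "noncoding_only") {
      # UTR variant: transcribed, hence visible to mRNA reads
      u3 <- int_range(cr["end"] + 5L, nchar(tx) - 5L)
      tx_pos <- sample(u3, 1L)
      ref_base <- substr(tx, tx_pos, tx_pos)
      alt <- sample(setdiff(DNA_BASES, ref_base), 1L)
      rows[[length(rows) + 1L]] <- planted_variant_row(
        g, gi$contig, tx_to_genome(models, g, tx_pos), ref_base, alt,
        "het", "utr", "snv", tx_pos)
    } else if (cat_i %in% c("heterozygous_snv", "synonymous_snv",
                            "nonsynonymous_tolerated")) {
      kind <- if (cat_i == "synonymous_snv") "synonymous" else "missense"
      zyg <- if (cat_i == "heterozygous_snv") "het" else "hom"
      d <- draw_cds_snv(cds, kind)
      if (is.null(d))
        stopf("could not place a %s SNV in gene %s", kind, g)
      tx_pos <- cr["start"] + d$cds_pos - 1L
      rows[[length(rows) + 1L]] <- planted_variant_row(
        g, gi$contig, tx_to_genome(models, g, tx_pos), d$ref, d$alt,
        zyg, "exonic_cds", "snv", tx_pos, d$codon_index, d$ref_aa, d$alt_aa)
    } else if (cat_i == "causal_frameshift_deletion") {
      planted <- plant_causal_deletion(reference, models, g)
      reference <- planted$reference
      rows[[length(rows) + 1L]] <- planted$del_row
      rows[[length(rows) + 1L]] <- planted$snv_row
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), contig = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               zygosity = character(0), region = character(0),
               type = character(0), tx_pos = integer(0),
               codon_index = integer(0), ref_aa = character(0),
               alt_aa = character(0), del_start = integer(0),
               del_end = integer(0), stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  list(variants = variants, reference = reference)
}

# Engineer the tandem repeat and the 8 bp deletion + linked SNV for one gene.
# Everything (repeat, deleted bases, downstream SNV) lies in one exon inside
# the CDS so genomic projections stay contiguous.
plant_causal_deletion <- function(reference, models, g) {
  gi <- gene_info(models, g)
  ex <- gene_exons(models, g)
  o <- exon_tx_offsets(ex)
  cr <- cds_tx_range(models, g)
  # exon windows intersected with the CDS; need room for [d-9, d+25]
  cand <- NULL
  for (j in order(o$width, decreasing = TRUE)) {
    lo <- max(cr["start"], o$offset[j] + 1L)
    hi <- min(cr["end"], o$offset[j] + o$width[j])
    if (hi - lo + 1L >= 40L) { cand <- c(lo, hi); break }
  }
  if (is.null(cand)) stopf("no exon of %s can host the engineered deletion", g)
  d <- (cand[1L] + cand[2L]) %/% 2L          # first deleted base, tx coords
  d <- max(cand[1L] + 9L, min(d, cand[2L] - 25L))
  tx <- gene_transcript(reference, models, g)
  g_from <- tx_to_genome(models, g, d - 9L)  # contiguous block d-9 .. d+25
  contig_seq <- reference[[gi$contig]]
  ok <- FALSE
  for (t in 1:200) {
    unit <- rand_dna(8L)
    guard <- sample(setdiff(DNA_BASES, substr(unit, 8L, 8L)), 1L)
    tx_try <- tx
    substr(tx_try, d - 9L, d - 9L) <- guard   # stop run-on of the repeat
    substr(tx_try, d - 8L, d - 1L) <- unit
    substr(tx_try, d, d + 7L) <- unit
    cds_try <- substr(tx_try, cr["start"], cr["end"])
    tr <- translate_cds(cds_try)
    # CDS must stay clean: single stop, and it must remain the final codon
    if (tr$terminated && tr$stop_codon_index == nchar(cds_try) %/% 3L) {
      tx <- tx_try; ok <- TRUE; break
    }
  }
  if (!ok) stopf("failed to engineer a stop-free tandem repeat in %s", g)
  # write the edited block back into the contig
  block <- substr(tx, d - 9L, d + 7L)
  substr(contig_seq, g_from, g_from + 16L) <- block
  # linked SNV 18 bp downstream of the deleted sequence
  snv_tx <- d + 7L + 18L
  ref_base <- substr(tx, snv_tx, snv_tx)
  snv_alt <- NA_character_
  for (alt in sample(setdiff(DNA_BASES, ref_base))) {
    ch <- snv_codon_change(substr(tx, cr["start"], cr["end"]),
                           snv_tx - cr["start"] + 1L, alt)
    if (ch$alt_aa != "*") { snv_alt <- alt; snv_ch <- ch; break }
  }
  reference[[gi$contig]] <- contig_seq
  g_d <- tx_to_genome(models, g, d)
  del_row <- planted_variant_row(
    g, gi$contig, pos = g_d - 1L,
    ref = substr(contig_seq, g_d - 1L, g_d + 7L),
    alt = substr(contig_seq, g_d - 1L, g_d - 1L),
    "hom", "exonic_cds", "del", tx_pos = d - 1L,
    del_start = g_d, del_end = g_d + 7L)
  g_s <- tx_to_genome(models, g, snv_tx)
  snv_row <- planted_variant_row(
    g, gi$contig, g_s, ref_base, snv_alt, "hom", "exonic_cds", "snv",
    snv_tx, snv_ch$codon_index, snv_ch$ref_aa, snv_ch$alt_aa)
  list(reference = reference, del_row = del_row, snv_row = snv_row)
}

# ------------------------------------------------------------- simulate_reads

# apply a gene's planted variants (tx coordinates) to its transcript
apply_variants_tx <- function(tx, vars) {
  if (!nrow(vars)) return(tx)
  vars <- vars[order(vars$tx_pos, decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(vars))) {
    v <- vars[k, ]
    if (v$type == "snv") {
      substr(tx, v$tx_pos, v$tx_pos) <- v$alt
    } else if (v$type == "del") {
      len <- nchar(v$ref) - nchar(v$alt)
      tx <- paste0(substr(tx, 1L, v$tx_pos), substr(tx, v$tx_pos + len + 1L,
                                                    nchar(tx)))
    } else if (v$type == "ins") {
      insert <- substr(v$alt, 2L, nchar(v$alt))
      tx <- paste0(substr(tx, 1L, v$tx_pos), insert,
                   substr(tx, v$tx_pos + 1L, nchar(tx)))
    }
  }
  tx
}

#' Simulate paired-end reads from the scenario's spliced transcripts
#'
#' Fragments are sampled from per-gene haplotype transcripts (homozygous
#' planted variants on both haplotypes, heterozygous ones on one, drawn
#' 50/50 per fragment), so exon-junction reads exist and carry planted
#' alleles at the planted zygosity. A deterministic fragment tiling
#' (reads abutting, overlapping steps) underlies the random layer so that
#' every exonic base of a fully covered gene receives at least one read;
#' genes flagged not fully covered get a zero-coverage exonic window at
#' least one read length wide (fragments touching it are dropped).
#' Base qualities are constant Q35.
#'
#' @param reference named character vector (after [plant_variants()]).
#' @param models `gene_models`.
#' @param variants planted truth set from [plant_variants()].
#' @param spec the [scenario_spec()].
#' @return an object of class `read_set`: list with `reads` (data frame:
#'   id, gene_id, hap, start, frag_len, seq1, qual1, seq2, qual2),
#'   `uncovered_windows` (data frame), and `read_length`.
#' @export
simulate_reads <- function(reference, models, variants, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(sub_seed(spec$seed, 303L))
  rl <- spec$read_length
  ids <- scenario_gene_ids(spec)
  qual <- strrep(rawToChar(as.raw(33L + 35L)), rl)  # Q35
  all_reads <- list()
  windows <- list()
  for (i in seq_len(spec$n_genes)) {
    g <- ids[i]
    gi <- gene_info(models, g)
    tx <- gene_transcript(reference, models, g)
    gv <- variants[variants$gene_id == g, , drop = FALSE]
    hapA <- apply_variants_tx(tx, gv[gv$zygosity == "hom", , drop = FALSE])
    hapB <- apply_variants_tx(tx, gv)   # hom + het
    haps <- c(A = hapA, B = hapB)

    win <- NULL
    if (!spec$coverage_plan[i]) {
      # zero-coverage window in the middle exon (reference tx coords; these
      # genes carry no indels so haplotype coords coincide)
      ex <- gene_exons(models, g)
      o <- exon_tx_offsets(ex)
      j <- (nrow(ex) + 1L) %/% 2L
      w <- max(rl + 9L, 60L)
      mid <- o$offset[j] + o$width[j] %/% 2L
      win <- c(start = mid - w %/% 2L, end = mid - w %/% 2L + w - 1L)
      win[1L] <- max(win[1L], o$offset[j] + 1L)
      win[2L] <- min(win[2L], o$offset[j] + o$width[j])
      windows[[length(windows) + 1L]] <- data.frame(
        gene_id = g, contig = gi$contig, tx_start = win[1L], tx_end = win[2L],
        g_start = tx_to_genome(models, g, win[1L]),
        g_end = tx_to_genome(models, g, win[2L]), stringsAsFactors = FALSE)
    }

    frags <- list()
    for (h in c("A", "B")) {
      L <- nchar(haps[[h]])
      tile_fl <- 2L * rl                     # reads abut: contiguous coverage
      starts <- unique(c(seq.int(1L, max(1L, L - tile_fl + 1L), by = 2L * rl - 12L),
                         max(1L, L - tile_fl + 1L)))
      frags[[h]] <- data.frame(hap = h, start = starts,
                               frag_len = pmin(tile_fl, L - starts + 1L))
    }
    L_A <- nchar(hapA)
    fl <- min(spec$frag_len, L_A)
    n_rand <- max(0L, round(spec$mean_depth * L_A / (2 * rl)))
    if (n_rand > 0L) {
      hap_draw <- ifelse(stats::runif(n_rand) < 0.5, "A", "B")
      Ls <- nchar(haps[hap_draw])
      starts <- 1L + floor(stats::runif(n_rand) * (Ls - fl + 1L))
      frags$R <- data.frame(hap = hap_draw, start = as.integer(starts),
                            frag_len = fl)
    }
    fr <- do.call(rbind, frags)
    if (!is.null(win)) {
      r1_hit <- fr$start <= win[2L] & (fr$start + rl - 1L) >= win[1L]
      r2s <- fr$start + fr$frag_len - rl
      r2_hit <- r2s <= win[2L] & (r2s + rl - 1L) >= win[1L]
      fr <- fr[!(r1_hit | r2_hit), , drop = FALSE]
    }
    if (!nrow(fr)) next
    hseq <- haps[fr$hap]
    seq1 <- substr(hseq, fr$start, fr$start + rl - 1L)
    e <- fr$start + fr$frag_len - 1L
    seq2 <- revcomp(substr(hseq, e - rl + 1L, e))
    if (spec$error_rate > 0) {
      seq1 <- inject_errors(seq1, spec$error_rate)
      seq2 <- inject_errors(seq2, spec$error_rate)
    }
    all_reads[[length(all_reads) + 1L]] <- data.frame(
      id = sprintf("%s_F%05d", g, seq_len(nrow(fr))),
      gene_id = g, hap = fr$hap, start = fr$start, frag_len = fr$frag_len,
      seq1 = seq1, qual1 = qual, seq2 = seq2, qual2 = qual,
      stringsAsFactors = FALSE)
  }
  structure(list(reads = do.call(rbind, all_reads),
                 uncovered_windows = if (length(windows))
                   do.call(rbind, windows) else NULL,
                 read_length = rl),
            class = "read_set")
}

inject_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    for (p in hit) {
      substr(s, p, p) <- sample(setdiff(DNA_BASES, substr(s, p, p)), 1L)
    }
    s
  }, "", USE.NAMES = FALSE)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d read pairs (%d bp) over %d genes\n",
              nrow(x$reads), x$read_length, length(unique(x$reads$gene_id))))
  invisible(x)
}

#' Write a read set as paired FASTQ files
#'
#' @param reads a `read_set`.
#' @param prefix path prefix; `<prefix>_1.fastq` and `<prefix>_2.fastq` are
#'   written with `/1` and `/2` read-name suffixes.
#' @export
write_read_set <- function(reads, prefix) {
  r <- reads$reads
  write_fastq(data.frame(id = paste0(r$id, "/1"), seq = r$seq1,
                         qual = r$qual1), paste0(prefix, "_1.fastq"))
  write_fastq(data.frame(id = paste0(r$id, "/2"), seq = r$seq2,
                         qual = r$qual2), paste0(prefix, "_2.fastq"))
  invisible(prefix)
}

# ------------------------------------------------------------ ortholog panel

#' Simulate an ortholog protein panel and build a conservation matrix
#'
#' For every gene the wild-type CDS is translated and `n_orthologs` diverged
#' protein sequences are generated (random substitutions at `divergence` per
#' residue). Codons carrying planted variants are protected: for
#' tolerated-missense variants the alternate residue is written into the
#' orthologs (the conserved-alternate situation that rules a variant out),
#' while for all other planted variants the orthologs keep the reference
#' residue, so their alternates are never observed in the panel.
#'
#' @param reference,models,variants scenario objects after planting.
#' @param spec the [scenario_spec()] (its seed drives the divergence draws).
#' @param n_orthologs panel size (default 5).
#' @param divergence per-residue substitution probability (default 0.03).
#' @return an object of class `conservation_matrix`: per gene a character
#'   matrix (orthologs x codons) of observed residues.
#' @export
simulate_ortholog_panel <- function(reference, models, variants, spec,
                                    n_orthologs = 5L, divergence = 0.03) {
  set.seed(sub_seed(spec$seed, 404L))
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  panels <- list()
  for (g in models$genes$gene_id) {
    prot <- translate_cds(gene_cds(reference, models, g))$protein
    res <- strsplit(prot, "")[[1L]]
    m <- matrix(rep(res, each = n_orthologs), nrow = n_orthologs)
    hit <- matrix(stats::runif(length(m)) < divergence, nrow = n_orthologs)
    m[hit] <- sample(aa20, sum(hit), replace = TRUE)
    gv <- variants[variants$gene_id == g & !is.na(variants$codon_index), ,
                   drop = FALSE]
    for (k in seq_len(nrow(gv))) {
      ci <- gv$codon_index[k]
      cat_tol <- gv$zygosity[k] == "hom" && !is.na(gv$alt_aa[k]) &&
        gv$ref_aa[k] != gv$alt_aa[k] && gv$type[k] == "snv" &&
        spec$category_plan[match(g, scenario_gene_ids(spec))] ==
          "nonsynonymous_tolerated"
      m[, ci] <- if (cat_tol) gv$alt_aa[k] else res[ci]
    }
    panels[[g]] <- m
  }
  structure(list(panels = panels, n_orthologs = n_orthologs),
            class = "conservation_matrix")
}

#' Query a conservation matrix
#'
#' @param cons a `conservation_matrix`.
#' @param gene_id gene identifier.
#' @param codon_index 1-based CDS codon index.
#' @param aa single-letter residue.
#' @return `TRUE` if the residue is observed at that codon in the panel.
#' @export
residue_observed <- function(cons, gene_id, codon_index, aa) {
  m <- cons$panels[[gene_id]]
  if (is.null(m) || codon_index > ncol(m)) return(FALSE)
  any(m[, codon_index] == aa)
}

# -------------------------------------------------------------- panel + qPCR

#' Simulate a fragment-analysis genotyping panel
#'
#' Each individual yields one (homozygote) or two (heterozygote) expected
#' peak sizes for the genotyping amplicon (wild type 268 bp, deletion allele
#' 260 bp) plus Gaussian size noise mimicking capillary precision. The truth
#' genotype column is retained for testing.
#'
#' @param n_individuals panel size.
#' @param n_carriers number of heterozygous carriers.
#' @param n_hom_mutant number of deletion homozygotes.
#' @param wt_size,del_size expected product sizes in bp; the deletion allele
#'   must be exactly 8 bp shorter.
#' @param size_noise_sd Gaussian peak-size noise in bp (default 0.15).
#' @param seed integer seed.
#' @return data frame with columns id, truth_genotype, peak1, peak2.
#' @export
simulate_panel <- function(n_individuals, n_carriers, n_hom_mutant = 0L,
                           wt_size = 268, del_size = 260,
                           size_noise_sd = 0.15, seed = 1L) {
  if (n_carriers + n_hom_mutant > n_individuals)
    stopf("n_carriers + n_hom_mutant exceeds the panel size")
  if (del_size != wt_size - 8)
    stopf("deletion allele must be 8 bp shorter than wild type")
  set.seed(sub_seed(seed, 505L))
  geno <- sample(c(rep("del/del", n_hom_mutant), rep("wt/del", n_carriers),
                   rep("wt/wt", n_individuals - n_carriers - n_hom_mutant)))
  noise <- function(n) stats::rnorm(n, 0, size_noise_sd)
  peak1 <- ifelse(geno == "del/del", del_size, wt_size) + noise(n_individuals)
  peak2 <- ifelse(geno == "wt/del", del_size + noise(n_individuals), NA_real_)
  data.frame(id = sprintf("DOG%04d", seq_len(n_individuals)),
             truth_genotype = geno, peak1 = peak1, peak2 = peak2,
             stringsAsFactors = FALSE)
}

#' Simulate a qPCR experiment (plate + dilution series)
#'
#' Ct values follow the efficiency model
#' `Ct = Ct0 - log(quantity) / log(1 + E)` plus Gaussian technical noise.
#' The case sample expresses the target at `1 / fold_change` of the control
#' level; reference assays are unchanged. A seven-point 2x serial dilution
#' per assay is emitted for standard-curve fitting.
#'
#' @param fold_change true fold reduction of the target in the case sample.
#' @param efficiencies named numeric vector of per-assay amplification
#'   efficiencies (fractions); the first entry is the target assay.
#' @param n_replicates technical replicates per (sample, assay) cell.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed integer seed.
#' @return object of class `qpcr_sim`: list with `plate` (sample, assay,
#'   replicate, ct), `dilution` (assay, log2_quantity, ct), `efficiencies`,
#'   and the true `fold_change`.
#' @export
simulate_qpcr <- function(fold_change = 68,
                          efficiencies = c(target = 0.993, ref1 = 0.943,
                                           ref2 = 1.003),
                          n_replicates = 3L, noise_sd = 0.1, seed = 1L) {
  if (is.null(names(efficiencies)) || any(!nzchar(names(efficiencies))))
    stopf("efficiencies must be a named vector (target first)")
  set.seed(sub_seed(seed, 606L))
  assays <- names(efficiencies)
  ct0 <- stats::setNames(rep_len(c(22, 19, 24, 21, 20), length(assays)), assays)
  rows <- list()
  for (s in c("control", "case")) {
    for (a in assays) {
      q <- if (s == "case" && a == assays[1L]) 1 / fold_change else 1
      ct <- ct0[a] - log(q) / log(1 + efficiencies[a]) +
        stats::rnorm(n_replicates, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, assay = a, replicate = seq_len(n_replicates), ct = ct,
        stringsAsFactors = FALSE)
    }
  }
  dil <- do.call(rbind, lapply(assays, function(a) {
    lq <- -(0:6)   # 2x serial dilution, 7 points, log2 relative quantity
    data.frame(assay = a, log2_quantity = lq,
               ct = ct0[a] - lq / log2(1 + efficiencies[a]) +
                 stats::rnorm(7L, 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  structure(list(plate = do.call(rbind, rows), dilution = dil,
                 efficiencies = efficiencies, fold_change = fold_change),
            class = "qpcr_sim")
}

# ------------------------------------------------------------------ pedigree

#' The study pedigree with genotypes at the deletion locus
#'
#' Builds the 18-member pedigree of the screening study: heterozygous sire
#' and dam, two litters of seven full siblings (three affected in total, the
#' genotyped ones homozygous for the deletion; of the unaffected ones seven
#' heterozygous and three wild-type homozygous, the remainder ungenotyped),
#' plus seven clinically unaffected paternal half-siblings (heterozygous or
#' wild type) and their ungenotyped dam.
#'
#' @return pedigree data frame (columns id, sire, dam, sex, affection,
#'   genotype, litter).
#' @export
study_pedigree <- function() {
  row <- function(id, sire, dam, sex, aff, gt, litter)
    data.frame(id = id, sire = sire, dam = dam, sex = sex, affection = aff,
               genotype = gt, litter = litter, stringsAsFactors = FALSE)
  ped <- rbind(
    row("SIRE", NA, NA, "male", "unaffected", "wt/del", NA),
    row("DAM1", NA, NA, "female", "unaffected", "wt/del", NA),
    row("DAM2", NA, NA, "female", "unaffected", "missing", NA),
    # litter 1 (previous litter): two affected, one genotyped from FFPE
    row("AFF1", "SIRE", "DAM1", "female", "affected", "del/del", 1L),
    row("AFF2", "SIRE", "DAM1", "male", "affected", "missing", 1L),
    row("U01", "SIRE", "DAM1", "male", "unaffected", "wt/del", 1L),
    row("U02", "SIRE", "DAM1", "female", "unaffected", "wt/del", 1L),
    row("U03", "SIRE", "DAM1", "male", "unaffected", "wt/del", 1L),
    row("U04", "SIRE", "DAM1", "female", "unaffected", "wt/wt", 1L),
    row("U05", "SIRE", "DAM1", "male", "unaffected", "wt/wt", 1L),
    # litter 2: the sequenced case and six unaffected littermates
    row("CASE", "SIRE", "DAM1", "male", "affected", "del/del", 2L),
    row("U06", "SIRE", "DAM1", "female", "unaffected", "wt/del", 2L),
    row("U07", "SIRE", "DAM1", "male", "unaffected", "wt/del", 2L),
    row("U08", "SIRE", "DAM1", "female", "unaffected", "wt/del", 2L),
    row("U09", "SIRE", "DAM1", "male", "unaffected", "wt/del", 2L),
    row("U10", "SIRE", "DAM1", "female", "unaffected", "wt/wt", 2L),
    row("U11", "SIRE", "DAM1", "male", "unaffected", "missing", 2L),
    # paternal half-siblings
    row("H01", "SIRE", "DAM2", "male", "unaffected", "wt/del", 3L),
    row("H02", "SIRE", "DAM2", "female", "unaffected", "wt/del", 3L),
    row("H03", "SIRE", "DAM2", "male", "unaffected", "wt/del", 3L),
    row("H04", "SIRE", "DAM2", "female", "unaffected", "wt/wt", 3L),
    row("H05", "SIRE", "DAM2", "male", "unaffected", "wt/wt", 3L),
    row("H06", "SIRE", "DAM2", "female", "unaffected", "wt/wt", 3L),
    row("H07", "SIRE", "DAM2", "male", "unaffected", "wt/wt", 3L))
  ped
}
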