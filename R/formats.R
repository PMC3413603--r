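#' File format readers and writers
#'
#' All modules exchange typed in-memory records (plain data frames and small
#' S3 objects); these functions move them across the standard text formats.
#' Internally every coordinate is 1-based inclusive; formats with other
#' conventions (BED 0-based half-open, VCF anchored indels) are converted at
#' this boundary, and the conversions are involutions.
#'
#' @name formats
NULL

# ---------------------------------------------------------------- FASTA/FASTQ

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings I/O exchanging named character vectors.
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stopf("write_fasta: all sequences must be named")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read and write paired/single FASTQ files
#'
#' `reads` is a data frame with columns `id`, `seq`, `qual`.
#'
#' @param reads data frame with columns id, seq, qual.
#' @param path file path.
#' @return `read_fastq()` returns a data frame with columns id, seq, qual.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stopf("write_fastq: sequence/quality length mismatch")
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ------------------------------------------------------------------------ SAM

# Alignment records travel as a data frame with the mandatory SAM columns
# (qname, flag, contig, pos, mapq, cigar, rnext, pnext, tlen, seq, qual) plus
# an `nm` edit-distance column. Output is minimal text SAM, no BAM.

cigar_parse <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(lens) != length(ops) || !length(ops))
    stopf("malformed CIGAR: %s", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

cigar_string <- function(ops) {
  if (!nrow(ops)) return("*")
  # merge adjacent identical ops
  keep <- c(TRUE, ops$op[-1L] != ops$op[-nrow(ops)])
  grp <- cumsum(keep)
  len <- as.vector(tapply(ops$len, grp, sum))
  op <- ops$op[keep]
  paste0(len, op, collapse = "")
}

cigar_query_len <- function(cigar) {
  p <- cigar_parse(cigar)
  sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
}

cigar_ref_len <- function(cigar) {
  p <- cigar_parse(cigar)
  sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
}

#' Write and read minimal SAM files
#'
#' Mandatory fields plus an NM tag; no BAM/BGZF. Reading validates that
#' query-consuming CIGAR lengths match the sequence length and that mapped
#' records lie within the declared contigs.
#'
#' @param aln alignment data frame (see Details).
#' @param path file path.
#' @param contig_lengths named integer vector for the `@SQ` header lines.
#' @return `read_sam()` returns `list(alignments =, contig_lengths =)`.
#' @export
write_sam <- function(aln, path, contig_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  if (nrow(aln)) {
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d",
                    aln$qname, as.integer(aln$flag), aln$contig,
                    as.integer(aln$pos), as.integer(aln$mapq), aln$cigar,
                    aln$rnext, as.integer(aln$pnext), as.integer(aln$tlen),
                    aln$seq, aln$qual, as.integer(aln$nm))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (!length(sq)) stopf("SAM header error: no @SQ lines")
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  contig_lengths <- stats::setNames(ln, sn)
  if (!length(body)) {
    aln <- data.frame(qname = character(0), flag = integer(0),
                      contig = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), nm = integer(0))
    return(list(alignments = aln, contig_lengths = contig_lengths))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stopf("SAM record error: fewer than 11 mandatory fields")
  get <- function(i) vapply(f, `[[`, "", i)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1L])) else NA_integer_
  }, 1L)
  aln <- data.frame(qname = get(1), flag = as.integer(get(2)), contig = get(3),
                    pos = as.integer(get(4)), mapq = as.integer(get(5)),
                    cigar = get(6), rnext = get(7), pnext = as.integer(get(8)),
                    tlen = as.integer(get(9)), seq = get(10), qual = get(11),
                    nm = nm, stringsAsFactors = FALSE)
  mapped <- aln$cigar != "*"
  qlen <- vapply(aln$cigar[mapped], cigar_query_len, 1L)
  if (any(qlen != nchar(aln$seq[mapped])))
    stopf("SAM CIGAR/sequence length mismatch (e.g. read %s)",
          aln$qname[mapped][which(qlen != nchar(aln$seq[mapped]))[1L]])
  bad <- mapped & (!aln$contig %in% names(contig_lengths) |
                     aln$pos < 1L)
  if (any(bad)) stopf("SAM coordinate out of bounds for read %s",
                      aln$qname[which(bad)[1L]])
  end <- aln$pos[mapped] + vapply(aln$cigar[mapped], cigar_ref_len, 1L) - 1L
  if (any(end > contig_lengths[aln$contig[mapped]]))
    stopf("SAM coordinate out of bounds: alignment past contig end")
  list(alignments = aln, contig_lengths = contig_lengths)
}

# ------------------------------------------------------------------------ VCF

#' Write and read minimal VCF v4.2 files
#'
#' Variant records are data frames with columns `contig`, `pos`, `ref`,
#' `alt`, `genotype` (`"het"` or `"hom"`). Indels are left-anchored on a
#' shared leading base per the VCF convention.
#'
#' @param variants variant data frame.
#' @param path file path.
#' @param contig_lengths optional named integer vector for `##contig` lines.
#' @param sample sample column name.
#' @return `read_vcf()` returns a variant data frame.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL, sample = "CASE") {
  if (nrow(variants)) {
    if (any(!nzchar(variants$ref))) stopf("VCF record error: empty REF")
    if (any(variants$pos < 1L)) stopf("VCF coordinate out of bounds: POS < 1")
    indel <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L
    anchored <- substr(variants$ref, 1L, 1L) == substr(variants$alt, 1L, 1L)
    if (any(indel & !anchored))
      stopf("VCF record error: indel not anchored on a shared leading base")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample), con)
  if (nrow(variants)) {
    gt <- ifelse(variants$genotype == "hom", "1/1", "0/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                       variants$contig, as.integer(variants$pos),
                       variants$ref, variants$alt, gt), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF"))
    stopf("VCF header error: missing ##fileformat line")
  chrom_line <- grep("^#CHROM\t", lines)
  if (!length(chrom_line)) stopf("VCF header error: missing #CHROM line")
  body <- lines[-seq_len(chrom_line[1L])]
  body <- body[nzchar(body)]
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 8L)) stopf("VCF record error: fewer than 8 fields")
  get <- function(i) vapply(f, `[[`, "", i)
  gt_raw <- vapply(f, function(x) if (length(x) >= 10L) x[[10L]] else "0/1", "")
  gt <- sub(":.*$", "", gt_raw)
  ref <- get(4)
  if (any(!nzchar(ref) | ref == ".")) stopf("VCF record error: empty REF")
  pos <- as.integer(get(2))
  if (any(is.na(pos) | pos < 1L)) stopf("VCF coordinate out of bounds")
  data.frame(contig = get(1), pos = pos, ref = ref, alt = get(5),
             genotype = ifelse(gt %in% c("1/1", "1|1"), "hom", "het"),
             stringsAsFactors = FALSE)
}

# ------------------------------------------------------------------------ BED

#' Write and read BED regions
#'
#' Regions are data frames with columns `contig`, `start`, `end`, 1-based
#' inclusive in memory; on disk BED's 0-based half-open convention is used
#' (via rtracklayer).
#'
#' @param regions region data frame.
#' @param path file path.
#' @return `read_bed()` returns a region data frame (1-based inclusive).
#' @export
write_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(regions$contig,
                               IRanges::IRanges(regions$start, regions$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# ------------------------------------------------------------------------ PED

PED_SEX_CODE <- c(male = 1L, female = 2L, unknown = 0L)
PED_AFF_CODE <- c(unaffected = 1L, affected = 2L, unknown = 0L)
PED_ALLELES <- c(wt = "1", del = "2")

genotype_to_alleles <- function(g) {
  switch(g,
         "wt/wt" = c("1", "1"), "wt/del" = c("1", "2"),
         "del/del" = c("2", "2"), "missing" = c("0", "0"),
         stopf("unknown genotype label: %s", g))
}

alleles_to_genotype <- function(a1, a2) {
  a <- sort(c(a1, a2))
  if (any(a == "0")) return("missing")
  key <- paste(a, collapse = "/")
  c("1/1" = "wt/wt", "1/2" = "wt/del", "2/2" = "del/del")[[key]]
}

#' Write and read PED pedigree files
#'
#' Columns: family, id, sire, dam, sex, phenotype plus one genotype as two
#' allele fields (1 = wild type, 2 = deletion, 0 = missing). A pedigree in
#' memory is a data frame with columns `id`, `sire`, `dam`, `sex`,
#' `affection`, `genotype` (labels `wt/wt`, `wt/del`, `del/del`, `missing`).
#'
#' @param ped pedigree data frame.
#' @param path file path.
#' @param family family identifier written to column 1.
#' @return `read_ped()` returns a pedigree data frame.
#' @export
write_ped <- function(ped, path, family = "FAM1") {
  al <- t(vapply(ped$genotype, genotype_to_alleles, character(2)))
  lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%s\t%s",
                   family, ped$id,
                   ifelse(is.na(ped$sire), "0", ped$sire),
                   ifelse(is.na(ped$dam), "0", ped$dam),
                   PED_SEX_CODE[ped$sex], PED_AFF_CODE[ped$affection],
                   al[, 1L], al[, 2L])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ped
#' @export
read_ped <- function(path) {
  f <- strsplit(readLines(path), "\t", fixed = TRUE)
  if (any(lengths(f) != 8L)) stopf("PED record error: expected 8 columns")
  get <- function(i) vapply(f, `[[`, "", i)
  id <- get(2); sire <- get(3); dam <- get(4)
  if (any(id == sire | id == dam))
    stopf("PED pedigree error: individual %s lists itself as parent",
          id[which(id == sire | id == dam)[1L]])
  ped <- data.frame(
    id = id,
    sire = ifelse(sire == "0", NA_character_, sire),
    dam = ifelse(dam == "0", NA_character_, dam),
    sex = names(PED_SEX_CODE)[match(as.integer(get(5)), PED_SEX_CODE)],
    affection = names(PED_AFF_CODE)[match(as.integer(get(6)), PED_AFF_CODE)],
    genotype = mapply(alleles_to_genotype, get(7), get(8), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  ped
}

# --------------------------------------------------- coordinate conversions

#' Convert between genomic deletion ranges and anchored VCF records
#'
#' A deletion of bases `start..end` (1-based inclusive) is represented in VCF
#' as POS = `start - 1` with REF = anchor base + deleted bases and ALT =
#' anchor base. The two conversions are inverses of each other.
#'
#' @param contig contig name.
#' @param start,end first and last deleted base, 1-based inclusive.
#' @param reference named character vector of contig sequences.
#' @return `del_range_to_vcf()` returns a one-row variant data frame;
#'   `vcf_to_del_range()` returns `list(contig, start, end)`.
#' @export
del_range_to_vcf <- function(contig, start, end, reference) {
  if (start < 2L) stopf("deletion at contig start cannot be left-anchored")
  seqs <- reference[[contig]]
  data.frame(contig = contig, pos = start - 1L,
             ref = substr(seqs, start - 1L, end),
             alt = substr(seqs, start - 1L, start - 1L),
             stringsAsFactors = FALSE)
}

#' @rdname del_range_to_vcf
#' @param pos,ref,alt anchored VCF fields of a deletion record.
#' @export
vcf_to_del_range <- function(contig, pos, ref, alt) {
  if (nchar(ref) <= nchar(alt)) stopf("not a deletion record")
  list(contig = contig, start = pos + nchar(alt), end = pos + nchar(ref) - 1L)
}

#' Format a deletion in genomic range notation
#'
#' Produces the human-readable `contig:start_enddel` spelling with grouped
#' digits, e.g. `chr18:53,691,704_53,691,711del`.
#'
#' @param contig contig name.
#' @param start,end deleted range, 1-based inclusive.
#' @export
format_genomic_del <- function(contig, start, end) {
  fmt <- function(x) formatC(x, big.mark = ",", format = "d")
  sprintf("%s:%s_%sdel", contig, fmt(start), fmt(end))
}

# 0-based half-open <-> 1-based inclusive interval helpers (involutions)

#' Interval convention conversions
#'
#' @param start0,end0 0-based half-open interval bounds.
#' @param start1,end1 1-based inclusive interval bounds.
#' @return a list with the converted bounds.
#' @export
interval_0h_to_1i <- function(start0, end0) list(start = start0 + 1L, end = end0)

#' @rdname interval_0h_to_1i
#' @export
interval_1i_to_0h <- function(start1, end1) list(start = start1 - 1L, end = end1)
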