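#' Protein-level consequence prediction and assay design helpers
#'
#' Applies coding variants jointly to a CDS and translates the result,
#' reporting the aberrant peptide a frameshift produces, where it starts,
#' how long it runs before a premature stop, and how much shorter the
#' mutant protein is — together with HGVS-style annotations. Variants are
#' applied jointly because a downstream SNV can destroy a stop codon that
#' the shifted frame would otherwise meet, lengthening the aberrant run.
#' Also provides exact-match in-silico PCR for genotyping-assay design.
#'
#' @name consequence
NULL

# --------------------------------------------------------- apply_and_translate

apply_variants_cds <- function(cds, variants) {
  if (!nrow(variants)) return(cds)
  v <- variants[order(variants$pos), , drop = FALSE]
  ref_end <- v$pos + nchar(v$ref) - 1L
  if (any(v$pos < 1L) || any(ref_end > nchar(cds)))
    stopf("variant outside the CDS (c.%d)", v$pos[which(ref_end > nchar(cds) |
                                                          v$pos < 1L)[1L]])
  if (nrow(v) > 1L && any(v$pos[-1L] <= ref_end[-nrow(v)]))
    stopf("overlapping variants cannot be applied jointly")
  for (k in rev(seq_len(nrow(v)))) {
    obs <- substr(cds, v$pos[k], ref_end[k])
    if (obs != v$ref[k])
      stopf("reference allele mismatch at c.%d: expected %s, found %s",
            v$pos[k], v$ref[k], obs)
    cds <- paste0(substr(cds, 1L, v$pos[k] - 1L), v$alt[k],
                  substr(cds, ref_end[k] + 1L, nchar(cds)))
  }
  cds
}

#' Apply CDS variants and predict the protein consequence
#'
#' @param cds coding sequence (starts ATG), a character scalar.
#' @param variants data frame with columns `pos`, `ref`, `alt` in CDS (c.)
#'   coordinates, 1-based from the A of ATG; indels anchored on a shared
#'   leading base. Variants must not overlap.
#' @return an object of class `consequence_report`: list with
#'   `wildtype_protein`, `mutant_protein`, `first_aberrant_residue_index`,
#'   `aberrant_run_length`, `truncation_length`, `non_stop` flag,
#'   `hgvs_p_run` (anchor-insertion dialect) and `hgvs_p_standard`.
#' @export
apply_and_translate <- function(cds, variants) {
  if (substr(cds, 1L, 3L) != "ATG") stopf("CDS must start with ATG")
  wt <- translate_cds(cds)
  mut_cds <- apply_variants_cds(cds, variants)
  mut <- translate_cds(mut_cds)
  wt_res <- strsplit(wt$protein, "")[[1L]]
  mut_res <- strsplit(mut$protein, "")[[1L]]
  n_common <- min(length(wt_res), length(mut_res))
  same <- if (n_common) wt_res[seq_len(n_common)] == mut_res[seq_len(n_common)]
    else logical(0)
  first_ab <- if (all(same) && length(mut_res) <= length(wt_res)) {
    length(mut_res) + 1L   # pure truncation / identity
  } else if (all(same)) {
    length(wt_res) + 1L    # extension beyond the wild type
  } else {
    which(!same)[1L]
  }
  run <- max(0L, length(mut_res) - (first_ab - 1L))
  report <- list(
    wildtype_protein = wt$protein,
    mutant_protein = mut$protein,
    first_aberrant_residue_index = first_ab,
    aberrant_run_length = run,
    truncation_length = length(wt_res) - length(mut_res),
    non_stop = !mut$terminated,
    applied_variants = variants)
  report$hgvs_p_run <- emit_ins_notation(
    anchor_aa = if (first_ab > 1L) wt_res[first_ab - 1L] else NA_character_,
    anchor_index = first_ab - 1L,
    peptide = paste(mut_res[int_range(first_ab, length(mut_res))],
                    collapse = ""),
    terminated = mut$terminated)
  report$hgvs_p_standard <- if (run > 0L && mut$terminated) {
    sprintf("p.%s%d%sfsTer%d",
            if (first_ab <= length(wt_res)) wt_res[first_ab] else "*",
            first_ab, mut_res[first_ab], run + 1L)
  } else if (run == 0L && report$truncation_length > 0L) {
    sprintf("p.%s%dTer",
            if (first_ab <= length(wt_res)) wt_res[first_ab] else "*",
            first_ab)
  } else {
    "p.(=)"
  }
  class(report) <- "consequence_report"
  report
}

#' @export
print.consequence_report <- function(x, ...) {
  cat("protein consequence report\n")
  cat(sprintf("  wild-type length : %d aa\n", nchar(x$wildtype_protein)))
  cat(sprintf("  mutant length    : %d aa%s\n", nchar(x$mutant_protein),
              if (x$non_stop) " (no stop reached)" else ""))
  cat(sprintf("  first aberrant   : residue %d\n",
              x$first_aberrant_residue_index))
  cat(sprintf("  aberrant run     : %d aa\n", x$aberrant_run_length))
  cat(sprintf("  truncation       : %d aa\n", x$truncation_length))
  cat(sprintf("  notation (run)   : %s\n", x$hgvs_p_run))
  cat(sprintf("  notation (HGVS)  : %s\n", x$hgvs_p_standard))
  invisible(x)
}

# ------------------------------------------------- anchor-insertion notation

#' Parse and emit the anchor-insertion frameshift notation
#'
#' Frameshift consequences are sometimes written as a last-wild-type anchor
#' residue followed by the full aberrant peptide, e.g.
#' `p.G1952insRDRGQGRPLLLMHRHGAGAACQEPLCS*` (a trailing `*` marks premature
#' termination). This dialect differs from standard HGVS frameshift
#' notation (`p.<Res><idx><Res>fsTer<n>`); both are supported and
#' inter-convertible, and `parse/emit` are exact inverses.
#'
#' @param text annotation string in the anchor-insertion dialect.
#' @return `parse_ins_notation()` returns `list(anchor_aa, anchor_index,
#'   peptide, run_length, terminated)`.
#' @export
parse_ins_notation <- function(text) {
  m <- regmatches(text, regexec("^p\\.([A-Z])([0-9]+)ins([A-Z]*)(\\*?)$", text))[[1L]]
  if (!length(m)) stopf("malformed anchor-insertion annotation: %s", text)
  list(anchor_aa = m[2L], anchor_index = as.integer(m[3L]), peptide = m[4L],
       run_length = nchar(m[4L]), terminated = m[5L] == "*")
}

#' @rdname parse_ins_notation
#' @param anchor_aa single-letter residue of the last wild-type position.
#' @param anchor_index its 1-based position in the wild-type protein.
#' @param peptide the aberrant peptide (may be empty).
#' @param terminated does the mutant protein end at a premature stop?
#' @export
emit_ins_notation <- function(anchor_aa, anchor_index, peptide, terminated) {
  if (is.na(anchor_aa)) return(NA_character_)
  paste0("p.", anchor_aa, anchor_index, "ins", peptide,
         if (terminated) "*" else "")
}

#' Convert anchor-insertion notation to standard HGVS frameshift form
#'
#' @param text annotation in the anchor-insertion dialect.
#' @return a string `p.<first aberrant residue><index>fs` or
#'   `...fsTer<n>` when terminated.
#' @export
ins_notation_to_hgvs <- function(text) {
  p <- parse_ins_notation(text)
  idx <- p$anchor_index + 1L
  first_new <- if (p$run_length > 0L) substr(p$peptide, 1L, 1L) else "Ter"
  if (p$terminated)
    sprintf("p.%s%dfsTer%d", first_new, idx, p$run_length + 1L)
  else
    sprintf("p.%s%dfs", first_new, idx)
}

# -------------------------------------------------------------- in-silico PCR

#' In-silico PCR: exact primer binding and product sizes
#'
#' Finds exact matches of the forward primer and of the reverse complement
#' of the reverse primer on the template; every forward match paired with
#' every downstream reverse match yields a product whose size spans both
#' primers inclusively. No binding yields an empty result (not an error).
#' A deletion allele in the template shifts product sizes accordingly.
#'
#' @param template template sequence (character scalar).
#' @param forward,reverse primer sequences, both 5'->3', length >= 15.
#' @return data frame (start, end, size); zero rows if no product.
#' @export
in_silico_pcr <- function(template, forward, reverse) {
  if (nchar(forward) < 15L || nchar(reverse) < 15L)
    stopf("primers must be at least 15 bases long")
  if (nchar(template) < nchar(forward) + nchar(reverse))
    stopf("template shorter than the combined primer length")
  tpl <- Biostrings::DNAString(template)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(forward), tpl)
  rhits <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse)), tpl)
  out <- list()
  for (fs in Biostrings::start(fhits)) {
    for (re in Biostrings::end(rhits)) {
      if (re > fs + nchar(forward) - 1L) {
        out[[length(out) + 1L]] <- data.frame(start = fs, end = re,
                                              size = re - fs + 1L)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(0), end = integer(0), size = integer(0))
}
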