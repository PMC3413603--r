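# Internal sequence / interval helpers shared across modules.
# Coordinates are 1-based inclusive throughout the package; file formats that
# use other conventions are converted at the format boundary (see formats.R).

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement GENETIC_CODE
NULL

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate a CDS string codon by codon up to (not including) the first stop.
# Returns list(protein, terminated, stop_codon_index). This stepper is the
# package's own; Biostrings::translate is used only as an independent check in
# the test suite.
translate_cds <- function(cds, to_first_stop = TRUE) {
  n <- nchar(cds)
  n_codons <- n %/% 3L
  if (n_codons == 0L) {
    return(list(protein = "", terminated = FALSE, stop_codon_index = NA_integer_))
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("CDS contains a non-ACGT codon: ", codons[which(is.na(aa))[1L]])
  stop_at <- which(aa == "*")
  if (length(stop_at) && to_first_stop) {
    k <- stop_at[1L]
    list(protein = paste(aa[seq_len(k - 1L)], collapse = ""),
         terminated = TRUE, stop_codon_index = k)
  } else {
    list(protein = paste(aa[aa != "*"], collapse = ""),
         terminated = length(stop_at) > 0L,
         stop_codon_index = if (length(stop_at)) stop_at[1L] else NA_integer_)
  }
}

# Sense codons (no stops), used by the reference generator.
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# seq_len-like integer range that is empty when from > to
int_range <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Derive a sub-seed for an operation from the scenario seed, keeping the
# result a valid 32-bit integer.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7L + offset) %% 2147483629)
}
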