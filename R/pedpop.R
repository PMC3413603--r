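#' Pedigree and population genotyping analysis
#'
#' Genotype calling from fragment-analysis peak sizes, Mendelian
#' segregation concordance under an autosomal recessive model, an exact
#' binomial test of the expected 1:3 affected ratio, and carrier-frequency
#' summaries for population panels.
#'
#' @name pedpop
NULL

#' Call a genotype from fragment-analysis peaks
#'
#' Peaks are assigned to the nearest expected allele size within
#' `tolerance`; one assigned allele gives a homozygote, two a heterozygote.
#' A peak assignable to neither allele yields `missing` (with a diagnostic
#' attribute); more than two distinct assigned alleles is a contamination
#' signal and a named error.
#'
#' @param peaks numeric vector of observed peak sizes (bp), 1 or 2 per
#'   individual at a biallelic locus.
#' @param expected named numeric vector `c(wt = , del = )` of expected
#'   product sizes.
#' @param tolerance assignment tolerance in bp; must be positive and
#'   smaller than half the allele size difference (default 1.0).
#' @return genotype label `wt/wt`, `wt/del`, `del/del` or `missing`.
#' @export
call_genotype <- function(peaks, expected = c(wt = 268, del = 260),
                          tolerance = 1.0) {
  if (tolerance <= 0 || tolerance >= abs(diff(expected)) / 2)
    stopf("tolerance must lie in (0, |wt - del| / 2)")
  peaks <- peaks[!is.na(peaks)]
  if (!length(peaks)) return("missing")
  d <- abs(outer(peaks, expected, "-"))
  nearest <- colnames(d)[apply(d, 1L, which.min)]
  within <- apply(d, 1L, min) <= tolerance
  if (any(!within)) {
    out <- "missing"
    attr(out, "diagnostic") <- sprintf(
      "peak %.2f bp outside both allele windows", peaks[!within][1L])
    return(out)
  }
  alleles <- unique(nearest)
  if (length(alleles) > 2L)
    stopf("more than two alleles assigned: contamination signal")
  if (length(alleles) == 2L) "wt/del"
  else if (alleles == "wt") "wt/wt" else "del/del"
}

#' Call genotypes for a whole fragment-analysis panel
#'
#' @param panel data frame with columns `id`, `peak1`, `peak2` (NA when
#'   absent), as produced by [simulate_panel()].
#' @inheritParams call_genotype
#' @return the panel with a `genotype` column appended.
#' @export
call_panel <- function(panel, expected = c(wt = 268, del = 260),
                       tolerance = 1.0) {
  panel$genotype <- vapply(seq_len(nrow(panel)), function(i)
    as.character(call_genotype(c(panel$peak1[i], panel$peak2[i]),
                               expected, tolerance)), "")
  panel
}

# ---------------------------------------------------------- segregation

ped_ancestor_check <- function(ped) {
  # walk each individual's ancestry; revisiting it is a cycle
  parents <- function(id) {
    r <- ped[ped$id == id, ]
    c(r$sire, r$dam)
  }
  for (id in ped$id) {
    stack <- stats::na.omit(parents(id))
    seen <- character(0)
    while (length(stack)) {
      p <- stack[[1L]]; stack <- stack[-1L]
      if (identical(p, id)) stopf("cyclic pedigree: %s is its own ancestor", id)
      if (p %in% seen) next
      seen <- c(seen, p)
      if (p %in% ped$id) stack <- c(stack, stats::na.omit(parents(p)))
    }
  }
  invisible(TRUE)
}

geno_alleles <- function(g) {
  switch(g, "wt/wt" = c("wt", "wt"), "wt/del" = c("wt", "del"),
         "del/del" = c("del", "del"), NULL)
}

#' Check segregation of a genotype with affection under a recessive model
#'
#' Discordant individuals are affected ones not homozygous for the deletion
#' or deletion homozygotes not affected (unknown affection and missing
#' genotypes are ignored). Mendelian errors are parent-offspring allele
#' impossibilities at the biallelic locus, assessed where all three
#' genotypes are known.
#'
#' @param ped pedigree data frame (columns id, sire, dam, affection,
#'   genotype).
#' @param model inheritance model; only `"recessive"` is implemented.
#' @return list with `discordant` (ids), `mendelian_errors` (ids),
#'   `concordant` flag.
#' @export
segregation_check <- function(ped, model = c("recessive")) {
  model <- match.arg(model)
  ped_ancestor_check(ped)
  if (!any(ped$affection == "affected" & ped$genotype != "missing"))
    stopf("segregation check needs at least one genotyped affected individual")
  gt <- ped$genotype
  disc <- ped$id[(ped$affection == "affected" & gt %in%
                    c("wt/wt", "wt/del")) |
                   (ped$affection == "unaffected" & gt == "del/del")]
  mend <- character(0)
  for (i in seq_len(nrow(ped))) {
    kid <- geno_alleles(gt[i])
    if (is.null(kid)) next
    for (side in c("sire", "dam")) {
      pid <- ped[[side]][i]
      if (is.na(pid) || !pid %in% ped$id) next
      pg <- geno_alleles(gt[match(pid, ped$id)])
      if (is.null(pg)) next
      other <- ped[[setdiff(c("sire", "dam"), side)]][i]
      og <- if (!is.na(other) && other %in% ped$id)
        geno_alleles(gt[match(other, ped$id)]) else NULL
      if (!is.null(og)) {
        # full trio: one allele from each parent must explain the offspring
        ok <- any(vapply(pg, function(a) {
          any(vapply(og, function(b)
            setequal_multiset(c(a, b), kid), TRUE))
        }, TRUE))
        if (!ok) mend <- c(mend, ped$id[i])
        break   # trio already assessed; skip the symmetric pass
      } else {
        if (!any(pg %in% kid)) mend <- c(mend, ped$id[i])
      }
    }
  }
  mend <- unique(mend)
  list(discordant = disc, mendelian_errors = mend,
       concordant = length(disc) == 0L && length(mend) == 0L)
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))

# ------------------------------------------------------- recessive ratio

#' Exact binomial test of the recessive 1:3 affected ratio
#'
#' Two-sided exact binomial p-value by the minimum-likelihood method (the
#' sum of the probabilities of all outcomes no more likely than the
#' observed one), as implemented by [stats::binom.test()]. The observed
#' litter composition is "consistent" with the expected recessive fraction
#' when p >= alpha.
#'
#' @param n_offspring litter/pedigree offspring count.
#' @param n_affected affected offspring count.
#' @param p expected affected fraction under the model (default 0.25).
#' @param alpha significance level for the consistency verdict.
#' @return list with `p_value`, `consistent`, `expected`, `observed`.
#' @export
recessive_ratio_test <- function(n_offspring, n_affected, p = 0.25,
                                 alpha = 0.05) {
  if (p <= 0 || p >= 1) stopf("expected fraction must lie in (0, 1)")
  if (n_affected < 0L || n_affected > n_offspring)
    stopf("n_affected must lie in [0, n_offspring]")
  pv <- if (n_offspring == 0L) 1
    else stats::binom.test(n_affected, n_offspring, p = p,
                           alternative = "two.sided")$p.value
  list(p_value = pv, consistent = pv >= alpha,
       expected = p * n_offspring, observed = n_affected)
}

# ---------------------------------------------------------- panel summary

#' Summarize genotype counts and allele/carrier frequencies in a panel
#'
#' Missing genotypes are excluded from frequency denominators. An empty (or
#' all-missing) panel returns zero counts with frequencies flagged
#' undefined (NA).
#'
#' @param genotypes character vector of genotype labels.
#' @return list with `n_wt`, `n_het`, `n_hom_mut`, `n_missing`,
#'   `allele_freq` (deletion allele), `carrier_freq`.
#' @export
panel_summary <- function(genotypes) {
  n_wt <- sum(genotypes == "wt/wt")
  n_het <- sum(genotypes == "wt/del")
  n_hom <- sum(genotypes == "del/del")
  n_missing <- sum(genotypes == "missing")
  n_typed <- n_wt + n_het + n_hom
  list(n_wt = n_wt, n_het = n_het, n_hom_mut = n_hom, n_missing = n_missing,
       allele_freq = if (n_typed) (n_het + 2L * n_hom) / (2L * n_typed)
         else NA_real_,
       carrier_freq = if (n_typed) (n_het + n_hom) / n_typed else NA_real_)
}
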