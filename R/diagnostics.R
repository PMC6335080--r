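# Species-diagnostic SNP discovery and hybrid genome composition.

#' Find species-diagnostic SNPs between two progenitor panels
#'
#' A locus is diagnostic for a species when one allele is present (dosage of
#' that allele >= 1) in at least `purity` of the genotyped accessions of that
#' species' panel and absent from at least `purity` of the other panel, with
#' call rate at least `min_call_rate` in both panels. Both alleles are
#' examined: at a fixed difference the alternate allele marks one species and
#' the reference allele the other, and the locus is recorded once as
#' `dual = TRUE` (direction label taken from the alternate allele).
#'
#' @param dm a [dosage_matrix()].
#' @param panel_a,panel_b disjoint accession id vectors, each with at least
#'   5 members (smaller panels risk spurious fixation and are refused).
#' @param min_call_rate minimum per-panel call rate at discovery.
#' @param purity required fixation fraction; the default 1.0 demands strict
#'   presence/absence.
#' @return data.frame of class `diagnostic_marker_set`: `site` (row index
#'   into `dm`), `chrom`, `pos0`, `direction` (`A`/`B`), `allele`
#'   (`ref`/`alt`, the diagnostic allele of that direction), `dual`,
#'   `call_rate_a`, `call_rate_b`; discovery thresholds kept as attributes.
#' @export
find_diagnostic_snps <- function(dm, panel_a, panel_b, min_call_rate = 0.8,
                                 purity = 1.0) {
  ia <- if (is.character(panel_a)) match(panel_a, dm$samples) else panel_a
  ib <- if (is.character(panel_b)) match(panel_b, dm$samples) else panel_b
  if (anyNA(ia) || anyNA(ib)) stop("unknown accession id in panels")
  if (length(intersect(ia, ib))) stop("panels must be disjoint")
  if (length(ia) < 5 || length(ib) < 5)
    stop("panels of fewer than 5 accessions risk spurious fixation")
  DA <- dm$dosage[, ia, drop = FALSE]; DB <- dm$dosage[, ib, drop = FALSE]
  PA <- rep(dm$ploidy[ia], each = nrow(DA)); PB <- rep(dm$ploidy[ib], each = nrow(DB))
  cr_a <- rowMeans(!is.na(DA)); cr_b <- rowMeans(!is.na(DB))
  ok_cr <- cr_a >= min_call_rate & cr_b >= min_call_rate &
    rowSums(!is.na(DA)) > 0 & rowSums(!is.na(DB)) > 0
  frac <- function(cond, D) rowSums(cond & !is.na(D)) / rowSums(!is.na(D))
  alt_a <- frac(DA >= 1, DA); alt_b <- frac(DB >= 1, DB)     # alt present
  ref_a <- frac(DA < PA, DA); ref_b <- frac(DB < PB, DB)     # ref present
  alt_diag_a <- alt_a >= purity & (1 - alt_b) >= purity
  alt_diag_b <- alt_b >= purity & (1 - alt_a) >= purity
  ref_diag_a <- ref_a >= purity & (1 - ref_b) >= purity
  ref_diag_b <- ref_b >= purity & (1 - ref_a) >= purity
  sel <- ok_cr & (alt_diag_a | alt_diag_b | ref_diag_a | ref_diag_b)
  idx <- which(sel)
  # direction from the alt allele where it qualifies, else from ref
  dir <- ifelse(alt_diag_a[idx], "A", ifelse(alt_diag_b[idx], "B",
                ifelse(ref_diag_a[idx], "A", "B")))
  allele <- ifelse(alt_diag_a[idx] | alt_diag_b[idx], "alt", "ref")
  dual <- (alt_diag_a & ref_diag_b | alt_diag_b & ref_diag_a)[idx]
  out <- data.frame(site = idx,
                    chrom = dm$sites$chrom[idx], pos0 = dm$sites$pos0[idx],
                    direction = dir, allele = allele, dual = dual,
                    call_rate_a = cr_a[idx], call_rate_b = cr_b[idx])
  attr(out, "min_call_rate") <- min_call_rate
  attr(out, "purity") <- purity
  class(out) <- c("diagnostic_marker_set", "data.frame")
  out
}

#' Genome composition of hybrids from diagnostic markers
#'
#' Every genotyped diagnostic locus of a hybrid is classed by the evidence
#' it carries. At a dual-direction locus (fixed difference) the alternate
#' allele marks one species and the reference allele the other: dosage `p`
#' shows only the first species' allele, dosage `0` only the second, and
#' intermediate dosages show both (`both`). At a single-direction locus only
#' presence of the diagnostic allele is informative; absence classes the
#' locus `neither`. `fracA` etc. are locus-class fractions over the
#' genotyped diagnostic loci, so the four fractions sum to one but `fracA`
#' and `fracB` need not be complementary - mirroring composition
#' percentages reported for real hybrid panels that do not add to 100%.
#'
#' @param dm a [dosage_matrix()] (hybrids included).
#' @param markers a `diagnostic_marker_set` from [find_diagnostic_snps()].
#' @param hybrids accession ids to profile.
#' @param min_loci minimum genotyped diagnostic loci; below it the
#'   composition is reported missing with a reason.
#' @return data.frame of class `composition_result`: `id`, `fracA`, `fracB`,
#'   `frac_both`, `frac_neither`, `n_loci`, `reason`.
#' @export
genome_composition <- function(dm, markers, hybrids, min_loci = 50L) {
  ih <- if (is.character(hybrids)) match(hybrids, dm$samples) else hybrids
  if (anyNA(ih)) stop("unknown hybrid id")
  rows <- lapply(seq_along(ih), function(k) {
    j <- ih[k]
    d <- dm$dosage[markers$site, j]
    p <- dm$ploidy[j]
    gt <- !is.na(d)
    n <- sum(gt)
    if (n < min_loci)
      return(data.frame(id = dm$samples[j], fracA = NA_real_, fracB = NA_real_,
                        frac_both = NA_real_, frac_neither = NA_real_,
                        n_loci = n, reason = "insufficient loci"))
    dirn <- markers$direction[gt]
    allele <- markers$allele[gt]
    dual <- markers$dual[gt]
    dg <- d[gt]
    present <- ifelse(allele == "alt", dg >= 1, dg <= p - 1)   # diagnostic allele seen
    other <- ifelse(allele == "alt", dg <= p - 1, dg >= 1)     # complementary allele seen
    cls <- ifelse(dual & present & other, "both",
           ifelse(dual & !present, ifelse(dirn == "A", "B", "A"),
           ifelse(present, dirn, "neither")))
    data.frame(id = dm$samples[j],
               fracA = mean(cls == "A"), fracB = mean(cls == "B"),
               frac_both = mean(cls == "both"),
               frac_neither = mean(cls == "neither"),
               n_loci = n, reason = "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("composition_result", "data.frame")
  out
}
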