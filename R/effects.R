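# Coding-effect annotation of SNPs against gene models + reference CDS.

.comp <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate coding effects of biallelic SNPs
#'
#' Classifies each variant as `intergenic`, `UTR5`, `UTR3`, `intron`,
#' `synonymous`, `missense`, `stop_gain` or `stop_loss` by substituting the
#' alternate base into the reference codon under the standard nuclear code.
#' Minus-strand variants are complemented before codon lookup. Variants in
#' the CDS of a gene flagged incomplete, or whose reference base disagrees
#' with the supplied CDS sequence, are classed `coding_unresolved`.
#'
#' @param sites data.frame (`chrom`, `pos0`, `ref`, `alt`), single-base
#'   alleles.
#' @param gm a [gene_model_set()] with UTR/CDS/intron features.
#' @param cds_seqs named character vector (or `Biostrings::DNAStringSet`) of
#'   spliced CDS sequences in transcription direction, one per coding gene.
#' @return character vector of effect classes, with attribute `gene_id`
#'   (containing gene or NA).
#' @export
annotate_effect <- function(sites, gm, cds_seqs) {
  if (methods::is(cds_seqs, "DNAStringSet")) cds_seqs <- as.character(cds_seqs)
  code <- Biostrings::GENETIC_CODE
  n <- nrow(sites)
  eff <- rep("intergenic", n)
  gene_of <- rep(NA_character_, n)
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos0 + 1L, width = 1L))
  gr_genes <- GenomicRanges::GRanges(gm$genes$chrom,
                                     IRanges::IRanges(gm$genes$start + 1L, gm$genes$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_genes, select = "first")
  hit <- which(!is.na(ov))
  for (i in hit) {
    g <- gm$genes[ov[i], ]
    gene_of[i] <- g$gene_id
    fe <- gm$features[gm$features$gene_id == g$gene_id, , drop = FALSE]
    pos <- sites$pos0[i]
    inside <- fe$start <= pos & pos < fe$end
    if (!any(inside)) { eff[i] <- "intron"; next }
    ftype <- fe$type[which(inside)[1]]
    if (ftype == "five_prime_UTR") { eff[i] <- if (g$strand == "+") "UTR5" else "UTR3" }
    else if (ftype == "three_prime_UTR") { eff[i] <- if (g$strand == "+") "UTR3" else "UTR5" }
    else if (ftype == "intron") { eff[i] <- "intron" }
    else { # CDS
      if (!isTRUE(g$complete) || !g$gene_id %in% names(cds_seqs)) {
        eff[i] <- "coding_unresolved"; next
      }
      cds <- fe[fe$type == "CDS", , drop = FALSE]
      cds <- cds[order(cds$start), ]
      ci <- which(cds$start <= pos & pos < cds$end)
      offset <- if (g$strand == "+") {
        sum(pmax(0L, cds$end[seq_len(ci - 1)] - cds$start[seq_len(ci - 1)])) +
          (pos - cds$start[ci])
      } else {
        after <- which(seq_len(nrow(cds)) > ci)
        sum(cds$end[after] - cds$start[after]) + (cds$end[ci] - 1L - pos)
      }
      seqg <- toupper(cds_seqs[[g$gene_id]])
      cidx <- offset %/% 3
      within <- offset %% 3
      codon <- substr(seqg, cidx * 3 + 1, cidx * 3 + 3)
      if (nchar(codon) < 3) { eff[i] <- "coding_unresolved"; next }
      refb <- toupper(sites$ref[i]); altb <- toupper(sites$alt[i])
      if (g$strand == "-") { refb <- .comp[[refb]]; altb <- .comp[[altb]] }
      if (substr(codon, within + 1, within + 1) != refb) {
        eff[i] <- "coding_unresolved"; next
      }
      alt_codon <- codon
      substr(alt_codon, within + 1, within + 1) <- altb
      aa_ref <- code[[codon]]; aa_alt <- code[[alt_codon]]
      eff[i] <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_ref != "*" && aa_alt == "*") "stop_gain"
      else if (aa_ref == "*" && aa_alt != "*") "stop_loss"
      else "missense"
    }
  }
  attr(eff, "gene_id") <- gene_of
  eff
}

#' Transition/transversion and nonsynonymous/synonymous ratios
#'
#' Transitions are `A<->G` and `C<->T`; everything else is a transversion.
#' N counts missense + stop_gain + stop_loss, S counts synonymous.
#'
#' @param sites data.frame (`ref`, `alt`) of biallelic SNPs.
#' @param effects effect classes from [annotate_effect()] (optional; without
#'   it only Ti/Tv is computed).
#' @return list with `titv`, `ns` (NA when a denominator is zero) and a
#'   `counts` data.frame.
#' @export
titv_and_ns <- function(sites, effects = NULL) {
  r <- toupper(sites$ref); a <- toupper(sites$alt)
  ti <- sum((r == "A" & a == "G") | (r == "G" & a == "A") |
              (r == "C" & a == "T") | (r == "T" & a == "C"))
  tv <- nrow(sites) - ti
  out <- list(titv = if (tv > 0) ti / tv else NA_real_, ns = NA_real_,
              counts = data.frame(ti = ti, tv = tv, n = NA_integer_,
                                  s = NA_integer_))
  if (!is.null(effects)) {
    nn <- sum(effects %in% c("missense", "stop_gain", "stop_loss"))
    ss <- sum(effects == "synonymous")
    out$ns <- if (ss > 0) nn / ss else NA_real_
    out$counts$n <- nn; out$counts$s <- ss
  }
  out
}
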