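# shared fixtures, built in code

# dosage_matrix straight from simulator truth (no read noise)
truth_dm <- function(co) {
  dosage_matrix(co$truth$dosages,
                matrix(Inf, nrow(co$truth$dosages), ncol(co$truth$dosages)),
                co$truth$ploidy, co$variants$sites)
}

# tiny hand-built dosage matrix
toy_dm <- function(D, ploidy, chrom = "chr01") {
  n <- nrow(D)
  sites <- data.frame(chrom = chrom, pos0 = seq_len(n) * 100L,
                      ref = "A", alt = "G", multiallelic = FALSE)
  dosage_matrix(D, matrix(Inf, n, ncol(D)), ploidy, sites)
}

# site key helper for matching across filtered views
site_key <- function(sites) paste(sites$chrom, sites$pos0)

# gene models with one 2-exon coding gene on the given strand
toy_gene <- function(strand = "+", chrom = "chr01", start = 100L) {
  feats <- data.frame(
    gene_id = "g1",
    type = c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR"),
    start = start + c(0L, 10L, 22L, 30L, 45L),
    end = start + c(10L, 22L, 30L, 45L, 55L),
    phase = c(NA, 0L, NA, NA, NA))
  # phases in transcription order
  len1 <- 12L; len2 <- 15L
  if (strand == "+") {
    feats$phase[2] <- 0L; feats$phase[4] <- (3 - len1 %% 3) %% 3
  } else {
    feats$phase[4] <- 0L; feats$phase[2] <- (3 - len2 %% 3) %% 3
  }
  genes <- data.frame(gene_id = "g1", chrom = chrom, start = start,
                      end = start + 55L, strand = strand, complete = TRUE)
  gene_model_set(genes, feats)
}

# random CDS of n codons without stops
random_cds <- function(ncodon) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste(sample(codons, ncodon, replace = TRUE), collapse = "")
}
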