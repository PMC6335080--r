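# Internal coordinate convention: all positions are 0-based, intervals are
# half-open [start, end). VCF (1-based) and GFF3 (1-based inclusive) are
# converted on read and on write; BED is already 0-based half-open.

#' Construct a variant table
#'
#' Container for biallelic/multiallelic site records with per-sample read
#' depths (`AD` ref/alt split and total `DP`). Positions are stored 0-based.
#'
#' @param sites data.frame with columns `chrom`, `pos0` (0-based), `ref`,
#'   `alt`. An optional logical column `multiallelic` flags records whose ALT
#'   held more than one allele; for those `alt` keeps the first allele.
#' @param ad_ref,ad_alt,dp integer matrices (sites x samples) of reference
#'   depth, alternate depth and total depth.
#' @param samples character vector of sample (accession) ids.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, ad_ref, ad_alt, dp, samples) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos0", "ref", "alt") %in% names(sites)),
            nrow(ad_ref) == nrow(sites), nrow(ad_alt) == nrow(sites),
            nrow(dp) == nrow(sites), ncol(ad_ref) == length(samples))
  if (is.null(sites$multiallelic)) sites$multiallelic <- FALSE
  storage.mode(ad_ref) <- "integer"
  storage.mode(ad_alt) <- "integer"
  storage.mode(dp) <- "integer"
  bad <- which(ad_ref + ad_alt > dp)
  if (length(bad)) stop("AD components exceed DP at ", length(bad), " genotypes")
  ord_ok <- all(unlist(tapply(sites$pos0, sites$chrom, function(p) !is.unsorted(p, strictly = TRUE))))
  if (!ord_ok) stop("positions must be strictly increasing within a chromosome")
  dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(dp) <- list(NULL, samples)
  structure(list(sites = sites, ad_ref = ad_ref, ad_alt = ad_alt,
                 dp = dp, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x", length(x$samples), "samples;",
      sum(x$sites$multiallelic), "multiallelic\n")
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Read a VCF into a variant table
#'
#' Parses a VCF 4.2 file with per-sample `AD` (ref,alt depths) and `DP`
#' FORMAT fields. Multiallelic records are flagged and their first alternate
#' allele retained; genotypes without usable `AD` become missing (depth 0).
#'
#' @param path VCF file (plain text or gzipped).
#' @param ad_order order of the `AD` components, default `c("ref", "alt")`;
#'   pass `c("alt", "ref")` for dialects that emit them swapped.
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path, ad_order = c("ref", "alt")) {
  if (!file.exists(path)) stop("no such file: ", path)
  ad_order <- match.arg(ad_order[1], c("ref", "alt"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  fx <- matrix(fx, ncol = 7, dimnames = list(NULL, colnames(fx)))
  alt_raw <- fx[, "ALT"]
  multi <- grepl(",", alt_raw, fixed = TRUE)
  sites <- data.frame(chrom = fx[, "CHROM"],
                      pos0 = as.integer(fx[, "POS"]) - 1L,
                      ref = toupper(fx[, "REF"]),
                      alt = toupper(sub(",.*$", "", alt_raw)),
                      multiallelic = multi,
                      stringsAsFactors = FALSE)
  fmt <- unique(v@gt[, "FORMAT"])
  has_ad <- any(grepl("(^|:)AD(:|$)", fmt))
  n <- nrow(sites)
  samples <- colnames(v@gt)[-1]
  if (!has_ad) {
    warning("no AD FORMAT field: all genotypes set missing")
    z <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
    dpm <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE),
                    error = function(e) z)
    dpm[is.na(dpm)] <- 0
    return(variant_table(sites, z, z, matrix(as.integer(dpm), n), samples))
  }
  ad <- vcfR::extract.gt(v, "AD")
  a1 <- vcfR::masplit(ad, record = 1L, sort = 0)
  a2 <- vcfR::masplit(ad, record = 2L, sort = 0)
  a1[is.na(a1)] <- 0; a2[is.na(a2)] <- 0
  ad_ref <- if (ad_order == "ref") a1 else a2
  ad_alt <- if (ad_order == "ref") a2 else a1
  dpm <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE),
                  error = function(e) ad_ref + ad_alt)
  dpm[is.na(dpm)] <- (ad_ref + ad_alt)[is.na(dpm)]
  variant_table(sites,
                matrix(as.integer(ad_ref), n), matrix(as.integer(ad_alt), n),
                matrix(as.integer(dpm), n), samples)
}

#' Write a variant table as VCF 4.2
#'
#' Emits `AD` and `DP` per sample (no `GT`, dosage is called downstream).
#'
#' @param x a [variant_table()].
#' @param path output path.
#' @param provenance optional character vector written as `##` header lines.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "variant_table"))
  contigs <- unique(x$sites$chrom)
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(provenance)) paste0("##", provenance),
           paste0("##contig=<ID=", contigs, ">"),
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  gt <- matrix(paste0(x$ad_ref, ",", x$ad_alt, ":", x$dp), nrow = nrow(x$sites))
  body <- paste(x$sites$chrom, x$sites$pos0 + 1L, ".", x$sites$ref,
                x$sites$alt, ".", "PASS", ".", "AD:DP",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a gene model set
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`), logical `complete` (CDS chain intact and
#'   length divisible by 3).
#' @param features data.frame with `gene_id`, `type` (one of
#'   `five_prime_UTR`, `CDS`, `intron`, `three_prime_UTR`), `start`, `end`,
#'   `phase` (CDS only, else NA).
#' @return Object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, features) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  if (nrow(features)) {
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
  }
  if (is.null(genes$complete)) genes$complete <- TRUE
  if (nrow(features)) {
    stopifnot(all(features$type %in%
                    c("five_prime_UTR", "CDS", "intron", "three_prime_UTR")))
    sp <- genes[match(features$gene_id, genes$gene_id), ]
    if (any(features$start < sp$start | features$end > sp$end))
      stop("feature intervals outside gene span")
  }
  structure(list(genes = genes, features = features), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x$genes), "genes,", nrow(x$features),
      "features;", sum(!x$genes$complete), "incomplete\n")
  invisible(x)
}

# derive introns as gaps between exon-level (UTR/CDS) features of one gene
.derive_introns <- function(gene_id, feats) {
  ex <- feats[feats$type != "intron", , drop = FALSE]
  if (nrow(ex) < 2) return(NULL)
  ex <- ex[order(ex$start), ]
  gs <- ex$end[-nrow(ex)]
  ge <- ex$start[-1]
  keep <- ge > gs
  if (!any(keep)) return(NULL)
  data.frame(gene_id = gene_id, type = "intron",
             start = gs[keep], end = ge[keep], phase = NA_integer_)
}

# CDS phase chain check: phase[i+1] == (3 - (cumlen_i - phase_1?)) ; we verify
# the declared phases are consistent with cumulative CDS length in
# transcription order.
.phase_consistent <- function(cds, strand) {
  if (nrow(cds) < 1) return(TRUE)
  cds <- cds[order(cds$start, decreasing = (strand == "-")), , drop = FALSE]
  ph <- cds$phase
  if (any(is.na(ph))) return(FALSE)
  len <- cds$end - cds$start
  expect <- ph[1]
  for (i in seq_len(nrow(cds))) {
    if (ph[i] != expect) return(FALSE)
    expect <- (3 - (len[i] - expect) %% 3) %% 3
  }
  TRUE
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) both map onto the
#' internal 0-based half-open convention. For GFF3, `five_prime_UTR`, `CDS`
#' and `three_prime_UTR` features are attached to genes through their
#' `Parent` transcript; introns absent from the file are derived as gaps
#' between exon-level features. BED input yields plain gene spans without
#' substructure (flagged incomplete). Genes whose CDS phase chain is
#' inconsistent, or whose total CDS length is not divisible by 3, are warned
#' about and flagged incomplete.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A [gene_model_set()].
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- gr$name
    if (is.null(nm) || anyNA(nm)) nm <- paste0("region", seq_along(gr))
    genes <- data.frame(gene_id = nm,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = "+", complete = FALSE,
                        stringsAsFactors = FALSE)
    return(gene_model_set(genes, data.frame(gene_id = character(), type = character(),
                                            start = integer(), end = integer(),
                                            phase = integer())))
  }
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  gid <- as.character(g$ID)
  parent <- vapply(g$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, "")
  is_gene <- g$type == "gene"
  is_tx <- g$type %in% c("mRNA", "transcript")
  tx2gene <- stats::setNames(parent[is_tx], gid[is_tx])
  genes <- data.frame(gene_id = gid[is_gene],
                      chrom = as.character(g$seqid)[is_gene],
                      start = g$start[is_gene] - 1L,
                      end = g$end[is_gene],
                      strand = as.character(g$strand)[is_gene],
                      complete = TRUE, stringsAsFactors = FALSE)
  ftypes <- c("five_prime_UTR", "CDS", "three_prime_UTR", "intron")
  fsel <- g$type %in% ftypes
  fgene <- parent[fsel]
  via_tx <- fgene %in% names(tx2gene)
  fgene[via_tx] <- tx2gene[fgene[via_tx]]
  features <- data.frame(gene_id = fgene,
                         type = as.character(g$type)[fsel],
                         start = g$start[fsel] - 1L,
                         end = g$end[fsel],
                         phase = suppressWarnings(as.integer(as.character(g$phase)[fsel])),
                         stringsAsFactors = FALSE)
  features <- features[features$gene_id %in% genes$gene_id, , drop = FALSE]
  # derive missing introns, check CDS phase chains
  extra <- list()
  for (id in unique(features$gene_id)) {
    fg <- features[features$gene_id == id, , drop = FALSE]
    if (!any(fg$type == "intron")) extra[[id]] <- .derive_introns(id, fg)
    cds <- fg[fg$type == "CDS", , drop = FALSE]
    strand <- genes$strand[genes$gene_id == id]
    ok <- nrow(cds) == 0 ||
      (.phase_consistent(cds, strand) && sum(cds$end - cds$start) %% 3 == 0)
    if (!ok) {
      warning("gene ", id, ": inconsistent CDS phase chain; flagged incomplete")
      genes$complete[genes$gene_id == id] <- FALSE
    }
  }
  extra <- do.call(rbind, extra)
  if (!is.null(extra)) features <- rbind(features, extra)
  features <- features[order(match(features$gene_id, genes$gene_id), features$start), ]
  rownames(features) <- NULL
  gene_model_set(genes, features)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()] for models produced by the simulator:
#' one transcript per gene, UTR/CDS features with phases.
#'
#' @param gm a [gene_model_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  stopifnot(inherits(gm, "gene_model_set"))
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               paste(g$chrom, "polycane", "gene", g$start + 1L, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"),
               paste(g$chrom, "polycane", "mRNA", g$start + 1L, g$end, ".",
                     g$strand, ".", paste0("ID=", tid, ";Parent=", g$gene_id),
                     sep = "\t"))
    fe <- gm$features[gm$features$gene_id == g$gene_id &
                        gm$features$type != "intron", , drop = FALSE]
    if (nrow(fe)) {
      fe <- fe[order(fe$start), ]
      lines <- c(lines,
                 paste(g$chrom, "polycane", fe$type, fe$start + 1L, fe$end, ".",
                       g$strand, ifelse(is.na(fe$phase), ".", fe$phase),
                       paste0("Parent=", tid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optional `name`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- if (!is.null(intervals$name)) intervals$name else "."
  sc <- if (!is.null(intervals$score)) format(intervals$score, trim = TRUE) else "0"
  writeLines(paste(intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   nm, sc, sep = "\t"), path)
  invisible(path)
}

#' Write a table as TSV with an optional provenance header
#'
#' @param x data.frame.
#' @param path output path.
#' @param provenance optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a sample metadata table
#'
#' Expects columns `id`, `group` (one of `speciesA`, `speciesB`, `hybrid`,
#' `outgroup`, `unknown`), `ploidy` (even, 2-12) and optional `lon`, `lat`.
#' Ploidy is an experimental input (e.g. flow cytometry), never estimated.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  m <- read_tsv(path)
  stopifnot(all(c("id", "group", "ploidy") %in% names(m)))
  m$ploidy <- as.integer(m$ploidy)
  if (anyDuplicated(m$id)) stop("duplicate accession ids")
  if (any(m$ploidy %% 2 != 0 | m$ploidy < 2 | m$ploidy > 12))
    stop("ploidy must be even and within 2-12")
  bad <- setdiff(unique(m$group), c("speciesA", "speciesB", "hybrid", "outgroup", "unknown"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  m
}

#' Write a phylogenetic tree as newick
#' @param tree an `ape` `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
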