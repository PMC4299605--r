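# Plain-text interchange: TSV matrices, GFF3/BED via rtracklayer, and a
# minimal VCF site-table writer/reader (variant site tables only; rich
# multi-sample VCF ingestion goes through vcfR when available).

#' Write a matrix as TSV (rownames in the first column)
#' @param mat Matrix.
#' @param path Output path.
#' @param rowname_col Header for the rownames column.
#' @export
write_matrix_tsv <- function(mat, path, rowname_col = "id") {
  df <- data.frame(rownames(mat) %||% seq_len(nrow(mat)), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Matrix with rownames from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export gene annotation as GFF3
#'
#' Writes gene and CDS records (1-based inclusive coordinates).
#'
#' @param genome A `genome_model` (or a compatible `genes` data.frame).
#' @param path Output `.gff3` path.
#' @export
write_genome_gff3 <- function(genome, path) {
  g <- if (inherits(genome, "genome_model")) genome$genes else genome
  gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$cds_start, g$cds_end),
    strand = g$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- g$gene_id
  gr$source <- "segqtl"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export read placements as BED6
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand` (and
#'   optionally `gene_id` used as the name field).
#' @param path Output `.bed` path.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start, reads$end),
                               strand = reads$strand)
  gr$name <- reads$gene_id %||% "."
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a variant site table as a minimal VCF
#'
#' Emits a sites-only VCFv4.2 body (CHROM, POS, ID, REF, ALT, QUAL, FILTER,
#' INFO) suitable for re-ingestion by standard VCF readers.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `type`).
#' @param path Output `.vcf` path.
#' @param contigs Optional named vector of chromosome lengths for the
#'   header.
#' @export
write_variants_vcf <- function(variants, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=segqtl"), con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"), con)
  info <- if ("type" %in% names(variants))
    paste0("TYPE=", variants$type) else "."
  writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                   variants$alt, ".", "PASS", info, sep = "\t"), con)
  invisible(path)
}

#' Read a variant site table from a VCF
#'
#' Minimal reader for sites-only VCFs of the kind written by
#' [write_variants_vcf()]; computes indel type and length delta from the
#' allele strings.
#'
#' @param path Input `.vcf` path.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `type`, `delta`.
#' @export
read_variants_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1)
  pos <- as.numeric(vapply(parts, `[`, "", 2))
  ref <- vapply(parts, `[`, "", 4)
  alt <- vapply(parts, `[`, "", 5)
  delta <- nchar(alt) - nchar(ref)
  type <- ifelse(delta == 0, "SNP", ifelse(delta > 0, "insertion",
                                           "deletion"))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, type = type,
             delta = as.integer(delta), stringsAsFactors = FALSE)
}

#' Read per-strain genotype calls from a long-format TSV
#'
#' Expected columns: `strain`, `chrom`, `pos`, `allele` ("ref", "alt" or
#' "het") and `quality`. Sites are taken from the parental variant table so
#' every call site is validated against it.
#'
#' @param path Input TSV path.
#' @param variants Parental variant table (`chrom`, `pos`, ...).
#' @param p1_allele Which allele parent P1 carries, `"ref"` per-site vector
#'   or scalar.
#' @return A `genotype_calls` object.
#' @export
read_calls_tsv <- function(path, variants, p1_allele = "ref") {
  d <- read.delim(path, stringsAsFactors = FALSE)
  sid <- site_id(variants$chrom, variants$pos)
  key <- site_id(d$chrom, d$pos)
  if (!all(key %in% sid))
    stop("calls contain sites absent from the parental variant table")
  strains <- sort(unique(d$strain))
  call <- matrix(NA_character_, length(strains), length(sid),
                 dimnames = list(strains, sid))
  qual <- matrix(NA_real_, length(strains), length(sid),
                 dimnames = list(strains, sid))
  ii <- cbind(match(d$strain, strains), match(key, sid))
  call[ii] <- d$allele
  qual[ii] <- d$quality
  structure(list(call = call, quality = qual,
                 sites = data.frame(chrom = variants$chrom,
                                    pos = variants$pos,
                                    p1_allele = rep_len(p1_allele,
                                                        nrow(variants)),
                                    stringsAsFactors = FALSE)),
            class = "genotype_calls")
}

#' Write an inheritance matrix as TSV (P1/P2/NA labels)
#' @param inh An `inheritance_matrix`.
#' @param path Output path.
#' @export
write_inheritance_tsv <- function(inh, path) {
  lab <- matrix(c("P1", "P2")[inh$inh + 1L], nrow(inh$inh),
                dimnames = dimnames(inh$inh))
  write_matrix_tsv(lab, path, rowname_col = "strain")
}

#' Write a long-format linkage table
#'
#' One row per trait-marker pair with selection frequency, empirical p and
#' q-value.
#'
#' @param res A `linkage_result`.
#' @param path Output TSV path.
#' @param only_linked Write only pairs linked at the result's FDR level.
#' @export
write_linkage_tsv <- function(res, path, only_linked = FALSE) {
  df <- data.frame(
    trait = rep(rownames(res$scores), ncol(res$scores)),
    marker = rep(colnames(res$scores), each = nrow(res$scores)),
    score = as.vector(res$scores), p = as.vector(res$p),
    q = as.vector(res$q), linked = as.vector(res$linked),
    stringsAsFactors = FALSE)
  if (only_linked) df <- df[df$linked, , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
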