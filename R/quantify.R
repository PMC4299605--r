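# Strand-specific quantification over CDS intervals and the normalization
# chain: gene dropping, zero replacement, library-size scaling, log2, and
# per-batch mean-centering.

#' Strand-specific sense/antisense quantification
#'
#' Each read increments at most one gene per strand orientation: the CDS
#' containing the read midpoint. A read on the same strand as the gene
#' counts as sense; a read on the opposite strand counts as antisense (for
#' convergent overlapping pairs one read can be sense for one gene and
#' antisense for the other). Reads whose midpoint lies outside every CDS are
#' not counted. Only CDS intervals are used, avoiding variable UTR lengths.
#'
#' @param reads data.frame of read placements with `chrom`, `start`, `end`,
#'   `strand` and a `sample` column (or pass `sample_id`).
#' @param annotation Gene annotation data.frame (`gene_id`, `chrom`,
#'   `strand`, `cds_start`, `cds_end`), in the same coordinate frame as the
#'   reads. Genes with identical coordinates and strand are rejected.
#' @param sample_id Optional single sample name when `reads` has no
#'   `sample` column.
#' @return List with `sense` and `antisense` integer count matrices
#'   (genes x samples).
#' @export
quantify <- function(reads, annotation, sample_id = NULL) {
  g <- annotation
  dup <- duplicated(g[, c("chrom", "strand", "cds_start", "cds_end")])
  if (any(dup)) stop("annotation contains genes with identical coordinates",
                     " and strand")
  if (!("sample" %in% names(reads))) {
    reads$sample <- sample_id %||% "sample1"
  }
  samples <- unique(reads$sample)
  sense <- matrix(0L, nrow(g), length(samples),
                  dimnames = list(g$gene_id, samples))
  anti <- sense
  if (!nrow(reads)) return(list(sense = sense, antisense = anti))
  mid <- floor((reads$start + reads$end) / 2)
  gr_mid <- GenomicRanges::GRanges(reads$chrom,
                                   IRanges::IRanges(mid, width = 1))
  gr_cds <- GenomicRanges::GRanges(g$chrom,
                                   IRanges::IRanges(g$cds_start, g$cds_end))
  ov <- GenomicRanges::findOverlaps(gr_mid, gr_cds, ignore.strand = TRUE)
  ri <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  same <- reads$strand[ri] == g$strand[gi]
  si <- match(reads$sample[ri], samples)
  # a read may hit several overlapping CDS; keep one sense and one antisense
  # assignment per read (first by genomic order within each orientation)
  key_s <- paste(ri, si)[same]
  keep_s <- !duplicated(key_s)
  key_a <- paste(ri, si)[!same]
  keep_a <- !duplicated(key_a)
  inc <- function(mat, gidx, sidx) {
    if (!length(gidx)) return(mat)
    tab <- table(factor(gidx, levels = seq_len(nrow(g))),
                 factor(sidx, levels = seq_along(samples)))
    mat + matrix(as.integer(tab), nrow(g), length(samples))
  }
  sense <- inc(sense, gi[same][keep_s], si[same][keep_s])
  anti <- inc(anti, gi[!same][keep_a], si[!same][keep_a])
  dimnames(sense) <- dimnames(anti) <- list(g$gene_id, samples)
  list(sense = sense, antisense = anti)
}

#' Normalize sense expression counts
#'
#' The normalization chain: (1) drop genes with a zero count in more than
#' half of the samples; (2) replace remaining zeros by 0.1; (3) scale each
#' sample to the total number of mapped reads (`e_i * mean(t) / t_i`);
#' (4) log2-transform; (5) remove batch effects by per-gene per-batch
#' mean-centering (one-way ANOVA adjustment), computing each batch mean
#' without `excluded_samples` but subtracting it from all samples of the
#' batch. Centering is done on the log2 scale by default
#' (`center_before_log = TRUE` centers the scaled counts instead).
#'
#' @param counts Genes x samples count matrix.
#' @param batches Batch label per sample.
#' @param excluded_samples Sample names/indices excluded from batch means
#'   (e.g. samples of a different genetic background).
#' @param total_reads Optional per-sample totals `t_i`; defaults to the
#'   column sums of `counts` (all > 0 required).
#' @param center_before_log Apply the mean-centering to scaled counts, then
#'   log2 (the literal order), instead of log2 then centering.
#' @return List with `norm` (normalized log2 matrix over retained genes),
#'   `dropped` (gene ids removed by the zero rule), `scaled` (pre-log scaled
#'   matrix), and `batches`.
#' @export
normalize_sense <- function(counts, batches = NULL, excluded_samples = NULL,
                            total_reads = NULL, center_before_log = FALSE) {
  .normalize(counts, batches, excluded_samples, total_reads,
             zeros_missing = FALSE, center_before_log = center_before_log)
}

#' Normalize antisense expression counts
#'
#' Same chain as [normalize_sense()], but zero counts are treated as missing
#' values rather than replaced by 0.1 (antisense coverage is much sparser),
#' and batch centering uses available values only. Genes whose antisense
#' counts are all zero become all-missing rows.
#'
#' @inheritParams normalize_sense
#' @return As [normalize_sense()]; `norm` may contain `NA`.
#' @export
normalize_antisense <- function(counts, batches = NULL,
                                excluded_samples = NULL, total_reads = NULL,
                                center_before_log = FALSE) {
  .normalize(counts, batches, excluded_samples, total_reads,
             zeros_missing = TRUE, center_before_log = center_before_log)
}

.normalize <- function(counts, batches, excluded_samples, total_reads,
                       zeros_missing, center_before_log) {
  stopifnot(is.matrix(counts))
  n_s <- ncol(counts)
  batches <- factor(rep_len(batches %||% "b1", n_s))
  t_i <- total_reads %||% colSums(counts)
  if (any(t_i <= 0)) stop("sample with zero total mapped reads", call. = FALSE)
  drop <- rowMeans(counts == 0) > 0.5
  dropped <- rownames(counts)[drop]
  x <- counts[!drop, , drop = FALSE]
  x <- if (zeros_missing) ifelse(x == 0, NA_real_, x) else
    ifelse(x == 0, 0.1, x)
  scaled <- sweep(x, 2, mean(t_i) / t_i, `*`)
  excl <- .sample_index(excluded_samples, colnames(counts), n_s)
  center <- function(mat) {
    for (b in levels(batches)) {
      cols <- which(batches == b)
      use <- setdiff(cols, excl)
      if (!length(use)) use <- cols
      mu <- rowMeans(mat[, use, drop = FALSE], na.rm = TRUE)
      mu[!is.finite(mu)] <- 0
      mat[, cols] <- mat[, cols, drop = FALSE] - mu
    }
    mat
  }
  norm <- if (center_before_log) {
    cen <- center(scaled)
    # centered counts can be non-positive; shift-free log is impossible, so
    # the literal order clips at a small positive floor before log2
    log2(pmax(cen, 1e-6))
  } else {
    center(log2(scaled))
  }
  list(norm = norm, dropped = dropped, scaled = scaled, batches = batches)
}

.sample_index <- function(sel, nm, n) {
  if (is.null(sel)) return(integer(0))
  if (is.character(sel)) which(nm %in% sel) else as.integer(sel)
}
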