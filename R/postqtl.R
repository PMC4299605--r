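# Downstream statistics on linkages: hotspot detection in genomic bins,
# cis/trans classification, effect directionality, candidate regulator
# prediction, and gene-pair-orientation enrichment.

#' Cut a genome into fixed-size bins
#'
#' Bins of `bin_size` bp per chromosome; the remainder is absorbed into the
#' last bin of each chromosome, so end bins are bigger.
#'
#' @param genome A `genome_model` (or data.frame with name/length).
#' @param bin_size Bin width in bp.
#' @return data.frame with `chrom`, `start`, `end`, `bin_id`.
#' @export
genome_bins <- function(genome, bin_size = 50000) {
  chroms <- if (inherits(genome, "genome_model")) genome$chromosomes else
    genome
  out <- list()
  for (i in seq_len(nrow(chroms))) {
    L <- chroms$length[i]
    n <- max(1L, floor(L / bin_size))
    start <- bin_size * (seq_len(n) - 1L) + 1
    end <- c(start[-1] - 1, L)
    out[[i]] <- data.frame(chrom = chroms$name[i], start = start, end = end,
                           stringsAsFactors = FALSE)
  }
  b <- do.call(rbind, out)
  b$bin_id <- seq_len(nrow(b))
  b
}

#' Detect eQTL hotspots in genomic bins
#'
#' eQTLs are assigned to 50-kb bins by their peak-marker position; a bin is
#' a hotspot candidate when its count exceeds the genome-wide Poisson
#' expectation (lambda = total eQTLs / number of bins) with upper-tail
#' `P(X >= observed) < alpha`. Consecutive significant bins sharing at least
#' one target trait are merged into one hotspot.
#'
#' @param qtl_positions data.frame with `chrom`, `pos` (peak marker
#'   position) and `trait` per eQTL.
#' @param genome A `genome_model` (for chromosome lengths).
#' @param bin_size Bin width (bp).
#' @param alpha Poisson tail threshold.
#' @param share `"any"` (default: merge when >= 1 shared target) or
#'   `"identical"`.
#' @return data.frame of hotspots: `chrom`, `start`, `end`, `n_qtl`,
#'   `expected`, `p`, `targets` (list-column), `n_bins`. Empty for zero
#'   eQTLs.
#' @export
detect_hotspots <- function(qtl_positions, genome, bin_size = 50000,
                            alpha = 8e-4, share = c("any", "identical")) {
  share <- match.arg(share)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_qtl = integer(),
                      expected = numeric(), p = numeric(),
                      n_bins = integer())
  if (!nrow(qtl_positions)) return(empty)
  bins <- genome_bins(genome, bin_size)
  bi <- rep(NA_integer_, nrow(qtl_positions))
  for (i in seq_len(nrow(bins))) {
    hit <- qtl_positions$chrom == bins$chrom[i] &
      qtl_positions$pos >= bins$start[i] & qtl_positions$pos <= bins$end[i]
    bi[hit] <- i
  }
  counts <- tabulate(bi, nbins = nrow(bins))
  lambda <- sum(counts) / nrow(bins)
  pvals <- ppois(counts - 1, lambda, lower.tail = FALSE)
  sig <- which(pvals < alpha & counts > lambda)
  if (!length(sig)) return(empty)
  targets <- lapply(seq_len(nrow(bins)), function(i)
    unique(qtl_positions$trait[which(bi == i)]))
  # merge runs of consecutive significant bins with shared targets
  groups <- list(); cur <- sig[1]
  for (k in seq_along(sig)[-1]) {
    b <- sig[k]; prev <- cur[length(cur)]
    consecutive <- b == prev + 1L && bins$chrom[b] == bins$chrom[prev]
    shared <- if (share == "any")
      length(intersect(targets[[b]], targets[[prev]])) > 0 else
        setequal(targets[[b]], targets[[prev]])
    if (consecutive && shared) cur <- c(cur, b) else {
      groups[[length(groups) + 1L]] <- cur; cur <- b
    }
  }
  groups[[length(groups) + 1L]] <- cur
  out <- do.call(rbind, lapply(groups, function(g) data.frame(
    chrom = bins$chrom[g[1]], start = bins$start[g[1]],
    end = bins$end[g[length(g)]],
    n_qtl = sum(counts[g]),
    expected = lambda * length(g),
    p = min(pvals[g]),
    n_bins = length(g), stringsAsFactors = FALSE)))
  out$targets <- I(lapply(groups, function(g)
    unique(unlist(targets[g]))))
  out
}

#' Classify a QTL as cis- or trans-acting
#'
#' The QTL acts in cis when the QTL member marker most correlated with the
#' markers surrounding the target gene (the nearest markers flanking its
#' CDS on its chromosome) has `|Pearson r| > r_min` with one of them.
#' Absolute correlation is used so the call is invariant to relabeling of
#' the parental alleles. Genes on chromosomes without any marker are
#' classified trans.
#'
#' @param qtl_members Integer indices of the QTL's member markers.
#' @param gene_chrom,gene_start,gene_end Target gene location.
#' @param marker_info data.frame `chrom`, `start`, `end` per marker
#'   (genomic order).
#' @param geno Strains x markers matrix for the correlations.
#' @param r_min Correlation threshold.
#' @return `"cis"` or `"trans"`.
#' @export
classify_cis_trans <- function(qtl_members, gene_chrom, gene_start,
                               gene_end, marker_info, geno, r_min = 0.8) {
  on_chr <- which(marker_info$chrom == gene_chrom)
  if (!length(on_chr)) return("trans")
  left <- on_chr[marker_info$end[on_chr] < gene_start]
  right <- on_chr[marker_info$start[on_chr] > gene_end]
  surround <- c(if (length(left)) max(left),
                if (length(right)) min(right))
  if (!length(surround)) {  # gene inside a marker interval or lone marker
    surround <- on_chr[which.min(pmin(abs(marker_info$start[on_chr] -
                                            gene_end),
                                      abs(marker_info$end[on_chr] -
                                            gene_start)))]
  }
  r <- abs(suppressWarnings(
    cor(geno[, qtl_members, drop = FALSE],
        geno[, surround, drop = FALSE], use = "pairwise.complete.obs")))
  if (!any(is.finite(r))) return("trans")
  if (max(r, na.rm = TRUE) > r_min) "cis" else "trans"
}

#' Directionality of a QTL effect
#'
#' Sign of the trait difference between allele groups, expressed relative
#' to the P1 (reference) parent: +1 when strains carrying the P2 allele
#' have the higher mean trait level, -1 when lower, 0 for equal means.
#' Strains with missing genotype or trait are excluded. No new test is
#' performed; the linkage is assumed already significant.
#'
#' @param trait Numeric trait vector over strains.
#' @param genotype Integer 0/1/NA genotype at the QTL marker.
#' @return -1, 0 or +1 (NA when a group is empty).
#' @export
directionality <- function(trait, genotype) {
  ok <- !is.na(trait) & !is.na(genotype)
  g <- genotype[ok]; y <- trait[ok]
  if (!any(g == P1_CODE) || !any(g == P2_CODE)) return(NA_real_)
  sign(mean(y[g == P2_CODE]) - mean(y[g == P1_CODE]))
}

#' Strongest candidate regulator gene for one QTL target
#'
#' Among annotated genes located inside the QTL interval(s) with available
#' expression, returns the gene maximizing the squared Pearson correlation
#' with the target trait. The target gene itself is excluded when it lies
#' inside its own QTL; ties break to the smaller genomic coordinate.
#'
#' @param target_trait Numeric trait vector over samples.
#' @param qtl_regions data.frame `chrom`, `start_pos`, `end_pos` (e.g. a
#'   `qtl_group$regions`).
#' @param annotation Gene annotation (`gene_id`, `chrom`, `cds_start`,
#'   `cds_end`).
#' @param expression Genes x samples normalized expression matrix.
#' @param target_gene Optional id of the target gene (to exclude).
#' @return List with `gene_id` (NA if no expressed gene in the QTL) and
#'   `r2`.
#' @export
candidate_regulator <- function(target_trait, qtl_regions, annotation,
                                expression, target_gene = NULL) {
  inside <- rep(FALSE, nrow(annotation))
  for (i in seq_len(nrow(qtl_regions))) {
    inside <- inside | (annotation$chrom == qtl_regions$chrom[i] &
                          annotation$cds_start <= qtl_regions$end_pos[i] &
                          annotation$cds_end >= qtl_regions$start_pos[i])
  }
  cand <- annotation[inside, , drop = FALSE]
  if (!is.null(target_gene))
    cand <- cand[cand$gene_id != target_gene, , drop = FALSE]
  cand <- cand[cand$gene_id %in% rownames(expression), , drop = FALSE]
  if (!nrow(cand)) return(list(gene_id = NA_character_, r2 = NA_real_))
  cand <- cand[order(cand$chrom, cand$cds_start), , drop = FALSE]
  r2 <- vapply(cand$gene_id, function(g)
    suppressWarnings(cor(target_trait, expression[g, ],
                         use = "pairwise.complete.obs"))^2, numeric(1))
  r2[!is.finite(r2)] <- -Inf
  best <- which.max(r2)  # first maximum = smaller coordinate on ties
  list(gene_id = cand$gene_id[best], r2 = r2[best])
}

#' Vote for the regulator of a hotspot
#'
#' The modal candidate regulator over the hotspot's targets; ties break to
#' the gene with the smaller genomic coordinate.
#'
#' @param candidates Character vector of per-target candidate gene ids
#'   (NAs ignored).
#' @param annotation Gene annotation for the coordinate tie-break.
#' @return The winning gene id (NA if no candidates).
#' @export
hotspot_regulator_vote <- function(candidates, annotation) {
  candidates <- candidates[!is.na(candidates)]
  if (!length(candidates)) return(NA_character_)
  tab <- table(candidates)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  idx <- match(top, annotation$gene_id)
  ord <- order(annotation$chrom[idx], annotation$cds_start[idx])
  top[ord[1]]
}

#' Classify adjacent gene pairs by orientation and overlap
#'
#' Coding genes are ordered by TSS position per chromosome; each pair of
#' successive genes is classified into one of six categories: orientation
#' (+,-) convergent, (-,+) divergent, (+,+)/(-,-) tandem, crossed with
#' whether the CDS intervals overlap (UTR-only overlaps do not count, since
#' only CDS intervals are compared).
#'
#' @param annotation Gene annotation (`gene_id`, `chrom`, `strand`, `tss`,
#'   `cds_start`, `cds_end`, `coding`).
#' @param coding_only Restrict to coding genes (default TRUE).
#' @return data.frame with `gene_a`, `gene_b`, `orientation`, `overlapping`,
#'   `category`.
#' @export
classify_gene_pairs <- function(annotation, coding_only = TRUE) {
  g <- annotation
  if (coding_only && "coding" %in% names(g)) g <- g[g$coding, , drop = FALSE]
  out <- list()
  for (cn in unique(g$chrom)) {
    gc <- g[g$chrom == cn, , drop = FALSE]
    if (nrow(gc) < 2) next
    gc <- gc[order(gc$tss), , drop = FALSE]
    a <- seq_len(nrow(gc) - 1); b <- a + 1L
    ori <- ifelse(gc$strand[a] == "+" & gc$strand[b] == "-", "convergent",
                  ifelse(gc$strand[a] == "-" & gc$strand[b] == "+",
                         "divergent", "tandem"))
    ovl <- gc$cds_start[b] <= gc$cds_end[a] & gc$cds_end[b] >= gc$cds_start[a]
    out[[length(out) + 1L]] <- data.frame(
      gene_a = gc$gene_id[a], gene_b = gc$gene_id[b], orientation = ori,
      overlapping = ovl,
      category = paste0(ori, ifelse(ovl, "_overlapping",
                                    "_nonoverlapping")),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_a = character(), gene_b = character(),
               orientation = character(), overlapping = logical(),
               category = character())
}

#' Gene-pair category labels
#' @return Character vector of the six categories.
#' @export
pair_categories <- function() {
  as.vector(outer(c("convergent", "divergent", "tandem"),
                  c("_overlapping", "_nonoverlapping"), paste0))
}

#' Permutation enrichment of gene-pair categories among target genes
#'
#' Counts, per category, the adjacencies of the target genes falling in
#' that category (an interior gene contributes both its flanking pairs),
#' then draws random target sets of the same size from the trait universe
#' to build empirical null distributions. Enrichment and depletion p-values
#' use the plus-one estimator.
#'
#' @param targets Character vector of target gene ids (subset of
#'   `universe`).
#' @param pairs data.frame from [classify_gene_pairs()].
#' @param universe Character vector of genes the targets were drawn from
#'   (the trait universe).
#' @param n_perm Number of random target sets.
#' @param seed Integer seed.
#' @return data.frame per category: `observed`, `expected`, `p_enrich`,
#'   `p_deplete`.
#' @export
pair_enrichment <- function(targets, pairs, universe, n_perm = 1e4,
                            seed = 1L) {
  if (!length(targets)) stop("empty target set", call. = FALSE)
  stopifnot(all(targets %in% universe))
  cats <- pair_categories()
  count_cats <- function(set) {
    hit <- pairs$gene_a %in% set
    hitb <- pairs$gene_b %in% set
    n <- integer(length(cats)); names(n) <- cats
    tab <- table(factor(c(pairs$category[hit], pairs$category[hitb]),
                        levels = cats))
    n + as.integer(tab)
  }
  obs <- count_cats(targets)
  k <- length(targets)
  null <- with_seed(substream_seed(seed, "pair-enrichment"), {
    vapply(seq_len(n_perm),
           function(i) count_cats(sample(universe, k)),
           integer(length(cats)))
  })
  p_enr <- (1 + rowSums(null >= obs)) / (1 + n_perm)
  p_dep <- (1 + rowSums(null <= obs)) / (1 + n_perm)
  data.frame(category = cats, observed = as.integer(obs),
             expected = rowMeans(null), p_enrich = p_enr,
             p_deplete = p_dep, stringsAsFactors = FALSE, row.names = NULL)
}
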