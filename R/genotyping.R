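# RNA-seq-based genotyping of segregants: from per-site variant calls to a
# collapsed marker map. Parental-origin coding: 0 = P1, 1 = P2, NA = unknown.

#' Infer parental origin from segregant genotype calls
#'
#' Maps each called allele to the parent carrying it. Heterozygous calls
#' (impossible in haploids) and calls with quality below `min_quality` are
#' set to unknown; so are calls matching neither parental allele (counted in
#' the `n_unmatched` attribute, with a warning).
#'
#' @param calls A `genotype_calls` object: `call` (strains x sites character
#'   matrix with values "ref", "alt", "het" or NA), `quality`, and `sites`
#'   with a `p1_allele` column ("ref"/"alt": the allele parent P1 carries).
#' @param min_quality Minimum genotype quality for a call to be used.
#' @return An `inheritance_matrix`: list with `inh` (integer matrix, 0 = P1,
#'   1 = P2, NA = unknown) and `sites`.
#' @export
infer_inheritance <- function(calls, min_quality = 20) {
  cl <- calls$call
  q <- calls$quality
  p1 <- calls$sites$p1_allele
  stopifnot(all(p1 %in% c("ref", "alt")))
  inh <- matrix(NA_integer_, nrow(cl), ncol(cl), dimnames = dimnames(cl))
  ok <- !is.na(cl) & cl %in% c("ref", "alt") & !is.na(q) & q >= min_quality
  # allele == p1_allele -> P1, else P2
  p1m <- matrix(rep(p1, each = nrow(cl)), nrow(cl), ncol(cl))
  inh[ok] <- ifelse(cl[ok] == p1m[ok], P1_CODE, P2_CODE)
  n_unmatched <- sum(!is.na(cl) & !(cl %in% c("ref", "alt", "het")))
  if (n_unmatched > 0)
    warning(n_unmatched, " call(s) matched neither parental allele")
  structure(list(inh = inh, sites = calls$sites, n_unmatched = n_unmatched),
            class = "inheritance_matrix")
}

#' @export
print.inheritance_matrix <- function(x, ...) {
  cat("inheritance_matrix:", nrow(x$inh), "strains x", ncol(x$inh), "sites;",
      sprintf("%.1f%%", 100 * mean(!is.na(x$inh))), "called\n")
  invisible(x)
}

#' Filter polymorphic sites for potential genotyping errors
#'
#' A site is discarded when it both fails the parental consistency check and
#' has a minor allele frequency (over called entries) below `maf_min`
#' (conjunction; set `rule = "or"` for the disjunctive reading). Sites with
#' no called entry at all are discarded and reported separately.
#'
#' @param inh An `inheritance_matrix`.
#' @param parental_check Logical per site: `TRUE` if the site was correctly
#'   called in the parental strains.
#' @param maf_min Minor allele frequency threshold.
#' @param rule `"and"` (default) or `"or"`.
#' @return An `inheritance_matrix` restricted to retained sites, with a
#'   `discarded` attribute (data.frame site index, chrom, pos, reason).
#' @export
filter_sites <- function(inh, parental_check, maf_min = 0.10,
                         rule = c("and", "or")) {
  rule <- match.arg(rule)
  m <- inh$inh
  stopifnot(length(parental_check) == ncol(m))
  called <- colSums(!is.na(m))
  p2 <- colSums(m == P2_CODE, na.rm = TRUE)
  maf <- ifelse(called > 0, pmin(p2, called - p2) / called, NA_real_)
  all_unknown <- called == 0
  fail <- if (rule == "and") (!parental_check) & (maf < maf_min) else
    (!parental_check) | (maf < maf_min)
  fail[all_unknown] <- TRUE
  reason <- ifelse(all_unknown, "all_unknown", "parental_maf")
  keep <- !fail
  discarded <- data.frame(site = which(fail),
                          chrom = inh$sites$chrom[fail],
                          pos = inh$sites$pos[fail],
                          reason = reason[fail], stringsAsFactors = FALSE)
  out <- structure(list(inh = m[, keep, drop = FALSE],
                        sites = inh$sites[keep, , drop = FALSE]),
                   class = "inheritance_matrix")
  attr(out, "discarded") <- discarded
  out
}

#' Correct isolated discordant genotype calls
#'
#' A called site whose two flanking called sites (same strain, same
#' chromosome) agree with each other but disagree with the focal call is
#' likely a genotyping error when the flanks are close: if the distance
#' between the two flanking sites is below `max_flank_distance`, the focal
#' call is overwritten with the flank label. Decisions are taken against the
#' original matrix in a single left-to-right pass (no cascading).
#'
#' @param inh An `inheritance_matrix`.
#' @param max_flank_distance Maximum flank-to-flank distance in bp.
#' @return The corrected `inheritance_matrix` with an `n_corrected`
#'   attribute.
#' @export
correct_isolated_discordant <- function(inh, max_flank_distance = 50000) {
  m <- inh$inh
  out <- m
  n_corr <- 0L
  pos <- inh$sites$pos
  for (cn in unique(inh$sites$chrom)) {
    idx <- which(inh$sites$chrom == cn)
    idx <- idx[order(pos[idx])]
    for (s in seq_len(nrow(m))) {
      called <- idx[!is.na(m[s, idx])]
      if (length(called) < 3) next
      for (k in 2:(length(called) - 1)) {
        i <- called[k]; l <- called[k - 1]; r <- called[k + 1]
        if (m[s, l] == m[s, r] && m[s, i] != m[s, l] &&
            (pos[r] - pos[l]) < max_flank_distance) {
          out[s, i] <- m[s, l]
          n_corr <- n_corr + 1L
        }
      }
    }
  }
  res <- structure(list(inh = out, sites = inh$sites),
                   class = "inheritance_matrix")
  attr(res, "n_corrected") <- n_corr
  res
}

#' Impute missing genotypes within haplotype blocks
#'
#' An unknown entry is filled with the shared label of its nearest called
#' flanking sites (same strain and chromosome) when both flanks agree and
#' the distance between them is below `max_flank_distance`, assuming no
#' recombination event took place in between. Entries at chromosome ends
#' (single flank), or between disagreeing or distant flanks, stay unknown.
#' Called entries are never modified. With `single_only = TRUE` only
#' isolated unknowns (runs of length 1) are filled.
#'
#' @param inh An `inheritance_matrix`.
#' @param max_flank_distance Maximum flank-to-flank distance in bp.
#' @param single_only Restrict filling to single-site unknown runs.
#' @return The imputed `inheritance_matrix` with an `n_imputed` attribute.
#' @export
impute_missing <- function(inh, max_flank_distance = 50000,
                           single_only = FALSE) {
  m <- inh$inh
  pos <- inh$sites$pos
  n_imp <- 0L
  for (cn in unique(inh$sites$chrom)) {
    idx <- which(inh$sites$chrom == cn)
    idx <- idx[order(pos[idx])]
    p <- pos[idx]
    for (s in seq_len(nrow(m))) {
      x <- m[s, idx]
      miss <- which(is.na(x))
      if (!length(miss)) next
      called <- which(!is.na(x))
      if (length(called) < 2) next
      left <- findInterval(miss, called)           # index into called, 0 if none
      right <- left + 1L
      okb <- left >= 1L & right <= length(called)
      for (t in which(okb)) {
        l <- called[left[t]]; r <- called[right[t]]
        if (x[l] == x[r] && (p[r] - p[l]) < max_flank_distance) {
          if (single_only && (r - l) != 2L) next
          m[s, idx[miss[t]]] <- x[l]
          n_imp <- n_imp + 1L
        }
      }
    }
  }
  res <- structure(list(inh = m, sites = inh$sites),
                   class = "inheritance_matrix")
  attr(res, "n_imputed") <- n_imp
  res
}

#' Collapse sites into unique mapping markers
#'
#' Sites called in fewer than `min_called_fraction` of strains (after
#' imputation) are discarded; maximal runs of adjacent sites with identical
#' segregation vectors across all strains (unknown entries must match too)
#' are collapsed into one marker spanning their positions. Each marker is a
#' genomic interval whose member polymorphisms are in full linkage
#' disequilibrium in the cross.
#'
#' @param inh An `inheritance_matrix` (imputation already applied).
#' @param min_called_fraction Minimum fraction of strains with a call.
#' @return A `marker_map`: list with `markers` (data.frame marker_id, chrom,
#'   start, end, n_sites), `geno` (strains x markers integer matrix),
#'   `members` (list of member site positions).
#' @export
build_markers <- function(inh, min_called_fraction = 0.5) {
  m <- inh$inh
  if (ncol(m) == 0) {
    return(structure(list(markers = data.frame(marker_id = character(),
                                               chrom = character(),
                                               start = numeric(),
                                               end = numeric(),
                                               n_sites = integer()),
                          geno = m[, 0, drop = FALSE], members = list()),
                     class = "marker_map"))
  }
  frac <- colMeans(!is.na(m))
  keep <- frac >= min_called_fraction
  m <- m[, keep, drop = FALSE]
  sites <- inh$sites[keep, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  m <- m[, ord, drop = FALSE]
  sites <- sites[ord, , drop = FALSE]
  if (ncol(m) == 0)
    return(build_markers(structure(list(inh = m, sites = sites),
                                   class = "inheritance_matrix")))
  key <- apply(m, 2, function(col) paste(ifelse(is.na(col), "u", col),
                                         collapse = ""))
  new_run <- c(TRUE, key[-1] != key[-length(key)] |
                 sites$chrom[-1] != sites$chrom[-nrow(sites)])
  run_id <- cumsum(new_run)
  n_mark <- max(run_id)
  geno <- m[, new_run, drop = FALSE]
  members <- split(sites$pos, run_id)
  markers <- data.frame(
    marker_id = sprintf("m%04d", seq_len(n_mark)),
    chrom = sites$chrom[new_run],
    start = vapply(members, min, numeric(1)),
    end = vapply(members, max, numeric(1)),
    n_sites = as.integer(table(run_id)),
    stringsAsFactors = FALSE, row.names = NULL)
  colnames(geno) <- markers$marker_id
  structure(list(markers = markers, geno = geno,
                 members = unname(members)),
            class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat("marker_map:", nrow(x$markers), "markers over",
      length(unique(x$markers$chrom)), "chromosome(s);",
      nrow(x$geno), "strains\n")
  invisible(x)
}

#' Detect recombination breakpoints
#'
#' One breakpoint is reported for every adjacent pair of called sites with
#' different parental labels (per strain and chromosome); the breakpoint
#' interval is bounded by the two flanking informative sites.
#'
#' @param inh An `inheritance_matrix` or `marker_map`.
#' @return data.frame with `strain`, `chrom`, `left_pos`, `right_pos`.
#' @export
detect_breakpoints <- function(inh) {
  if (inherits(inh, "marker_map")) {
    m <- inh$geno
    sites <- data.frame(chrom = inh$markers$chrom, pos = inh$markers$start)
  } else {
    m <- inh$inh
    sites <- inh$sites
  }
  out <- list()
  strains <- rownames(m) %||% as.character(seq_len(nrow(m)))
  for (cn in unique(sites$chrom)) {
    idx <- which(sites$chrom == cn)
    idx <- idx[order(sites$pos[idx])]
    p <- sites$pos[idx]
    for (s in seq_len(nrow(m))) {
      x <- m[s, idx]
      called <- which(!is.na(x))
      if (length(called) < 2) next
      d <- which(diff(x[called]) != 0L)
      if (length(d))
        out[[length(out) + 1L]] <- data.frame(
          strain = strains[s], chrom = cn,
          left_pos = p[called[d]], right_pos = p[called[d + 1L]],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(strain = character(), chrom = character(),
               left_pos = numeric(), right_pos = numeric())
}

#' Check genotype concordance between replicates of one strain
#'
#' Replicates of the same strain must yield near-identical genotypes;
#' completely different genotypes indicate a sample swap. Pairwise
#' concordance is the fraction of co-called sites with identical labels;
#' if the minimum pairwise concordance is below `concordance_min` (or there
#' are no co-called sites), all replicates of the strain are flagged.
#'
#' @param replicate_rows List (length >= 2) of per-replicate inheritance
#'   vectors over the same sites (integer 0/1/NA).
#' @param concordance_min Threshold below which the strain is flagged.
#' @return List with `pass` (logical), `concordance` (min pairwise), and
#'   `pairwise` (matrix).
#' @export
check_replicates <- function(replicate_rows, concordance_min = 0.9) {
  stopifnot(length(replicate_rows) >= 2)
  k <- length(replicate_rows)
  pw <- matrix(NA_real_, k, k)
  diag(pw) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- replicate_rows[[i]]; b <- replicate_rows[[j]]
    co <- !is.na(a) & !is.na(b)
    pw[i, j] <- pw[j, i] <- if (!any(co)) NA_real_ else mean(a[co] == b[co])
  }
  mn <- suppressWarnings(min(pw[upper.tri(pw)], na.rm = TRUE))
  flagged <- any(is.na(pw[upper.tri(pw)])) || !is.finite(mn) ||
    mn < concordance_min
  list(pass = !flagged,
       concordance = if (is.finite(mn)) mn else NA_real_,
       pairwise = pw)
}

#' Run the full genotyping chain on a call matrix
#'
#' Convenience wrapper: [infer_inheritance()] -> [filter_sites()] ->
#' [correct_isolated_discordant()] -> [impute_missing()] ->
#' [build_markers()] + [detect_breakpoints()].
#'
#' @param calls A `genotype_calls`.
#' @param parental_check Logical per site (default: all pass).
#' @param min_quality,maf_min,max_flank_distance,min_called_fraction
#'   Stage parameters (see the individual functions).
#' @return List with `inheritance` (post-imputation), `markers`,
#'   `breakpoints`, and the intermediate `raw` inheritance matrix.
#' @export
genotype_pipeline <- function(calls, parental_check = NULL, min_quality = 20,
                              maf_min = 0.10, max_flank_distance = 50000,
                              min_called_fraction = 0.5) {
  inh <- infer_inheritance(calls, min_quality = min_quality)
  if (is.null(parental_check)) parental_check <- rep(TRUE, ncol(inh$inh))
  flt <- filter_sites(inh, parental_check, maf_min = maf_min)
  cor <- correct_isolated_discordant(flt, max_flank_distance)
  imp <- impute_missing(cor, max_flank_distance)
  list(raw = inh, inheritance = imp,
       markers = build_markers(imp, min_called_fraction),
       breakpoints = detect_breakpoints(imp))
}
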