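# Random-forest QTL mapping: allele-sharing kinship + eigenvector
# covariates, missing-genotype randomized forests scored by predictor
# selection frequency, a shared permutation null, and a permutation-based
# empirical FDR.

#' Allele-sharing kinship matrix
#'
#' Entry (i, j) is the fraction of markers co-called in strains i and j at
#' which the two strains carry the same parental allele; the diagonal is 1.
#'
#' @param markers Strains x markers matrix with entries 0 (P1), 1 (P2) or NA.
#' @return A `kinship_model`: list with `K` (symmetric matrix), `values`
#'   (eigenvalues, descending) and `vectors` (orthonormal eigenvectors).
#' @export
kinship <- function(markers) {
  n <- nrow(markers)
  stopifnot(n >= 2)
  K <- matrix(1, n, n, dimnames = list(rownames(markers), rownames(markers)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    co <- !is.na(markers[i, ]) & !is.na(markers[j, ])
    if (!any(co)) stop("strain pair with zero co-called markers: ",
                       i, ", ", j)
    K[i, j] <- K[j, i] <- mean(markers[i, co] == markers[j, co])
  }
  e <- eigen(K, symmetric = TRUE)
  structure(list(K = K, values = e$values, vectors = e$vectors),
            class = "kinship_model")
}

#' Population-structure covariates from the kinship spectrum
#'
#' Returns the eigenvectors corresponding to the top eigenvalues of the
#' kinship matrix: either a fixed number `fixed_k`, or the smallest k whose
#' cumulative eigenvalue fraction strictly exceeds `variance_target`.
#' Negative eigenvalues (possible for an allele-sharing matrix) are treated
#' as zero variance.
#'
#' @param kin A `kinship_model`.
#' @param variance_target Fraction of genotype variance to capture.
#' @param fixed_k Optional fixed number of eigenvectors.
#' @return Matrix (strains x k) of covariates, with attribute
#'   `"variance_explained"`.
#' @export
structure_covariates <- function(kin, variance_target = 0.80,
                                 fixed_k = NULL) {
  vals <- pmax(kin$values, 0)
  frac <- cumsum(vals) / sum(vals)
  k <- if (!is.null(fixed_k)) as.integer(fixed_k) else
    which(frac > variance_target)[1]
  k <- min(k, ncol(kin$vectors))
  out <- kin$vectors[, seq_len(k), drop = FALSE]
  colnames(out) <- paste0("PC", seq_len(k))
  rownames(out) <- rownames(kin$K)
  attr(out, "variance_explained") <- frac[k]
  out
}

#' Default RF mapping settings
#'
#' `expression` mirrors the full-study profile scaled to desk size; the
#' totals (trees = n_forests x trees_per_forest) are what matter, since
#' forests are additive in split counts. `growth` uses a larger budget, as
#' growth traits are mapped with more trees and permutations.
#'
#' @param profile `"expression"`, `"growth"` or `"test"`.
#' @return List of settings.
#' @export
rf_settings <- function(profile = c("expression", "growth", "test")) {
  profile <- match.arg(profile)
  switch(profile,
    expression = list(n_forests = 10L, trees_per_forest = 50L,
                      n_missing_assignments = 50L, n_perm = 200L),
    growth = list(n_forests = 20L, trees_per_forest = 50L,
                  n_missing_assignments = 50L, n_perm = 500L),
    test = list(n_forests = 2L, trees_per_forest = 25L,
                n_missing_assignments = 5L, n_perm = 50L))
}

#' Selection frequency of markers for one trait
#'
#' Grows regression forests with markers and structure covariates as
#' predictors and scores each marker by its selection frequency: the
#' fraction of split nodes (over all trees of all combined forests) that
#' split on the marker. Missing marker genotypes are handled by randomized
#' ensembling: the total tree budget is split into `n_missing_assignments`
#' chunks, each grown after an independent random fill of every missing
#' entry (Bernoulli(0.5) alleles by default, allele-frequency weighted with
#' `freq_weighted = TRUE`), and the resulting forests are combined. With no
#' missing entries a single forest of the full budget is grown, so the
#' result does not depend on `n_missing_assignments`.
#'
#' @param trait Numeric trait vector over strains; strains with missing
#'   trait values are dropped (with their predictor rows).
#' @param markers Strains x markers matrix (0/1/NA).
#' @param covariates Optional strains x k numeric covariate matrix; the
#'   covariates participate as predictors but are excluded from the
#'   returned scores.
#' @param n_forests,trees_per_forest Total tree budget.
#' @param n_missing_assignments Number of random genotype re-assignments.
#' @param mtry Predictors tried per split; default one third of the total
#'   number of predictors.
#' @param freq_weighted Fill missing genotypes by column allele frequency.
#' @param seed Integer seed (bit-reproducible scores).
#' @return Named numeric vector of per-marker selection frequencies, with
#'   attribute `"all_frequencies"` (markers + covariates, summing to 1).
#' @export
rf_selection_frequency <- function(trait, markers, covariates = NULL,
                                   n_forests = 10L, trees_per_forest = 50L,
                                   n_missing_assignments = 50L,
                                   mtry = NULL, freq_weighted = FALSE,
                                   seed = 1L) {
  keep <- !is.na(trait)
  y <- trait[keep]
  if (length(unique(y)) < 2) stop("constant trait", call. = FALSE)
  x_mark <- markers[keep, , drop = FALSE]
  x_cov <- if (!is.null(covariates)) covariates[keep, , drop = FALSE] else
    NULL
  all_missing <- colSums(!is.na(x_mark)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing marker column(s) scored 0")
    x_mark[, all_missing] <- 0
  }
  total_trees <- as.integer(n_forests) * as.integer(trees_per_forest)
  has_missing <- anyNA(x_mark)
  n_chunks <- if (has_missing) as.integer(n_missing_assignments) else 1L
  ntree_chunk <- pmax(1L, as.integer(round(total_trees / n_chunks)))
  p_mark <- ncol(x_mark)
  p_all <- p_mark + if (is.null(x_cov)) 0L else ncol(x_cov)
  mtry <- mtry %||% max(1L, floor(p_all / 3))
  fill_prob <- if (freq_weighted)
    colMeans(x_mark, na.rm = TRUE) else rep(0.5, p_mark)
  fill_prob[is.na(fill_prob)] <- 0.5

  counts <- numeric(p_all)
  set.seed(seed)
  for (chunk in seq_len(n_chunks)) {
    xm <- x_mark
    if (has_missing) {
      na_idx <- which(is.na(xm))
      cols <- ((na_idx - 1L) %/% nrow(xm)) + 1L
      xm[na_idx] <- rbinom(length(na_idx), 1L, fill_prob[cols])
    }
    x <- if (is.null(x_cov)) xm else cbind(xm, x_cov)
    rf <- randomForest::randomForest(x, y, ntree = ntree_chunk, mtry = mtry)
    counts <- counts + randomForest::varUsed(rf, by.tree = FALSE,
                                             count = TRUE)
  }
  freq_all <- counts / sum(counts)
  names(freq_all) <- c(colnames(x_mark),
                       if (!is.null(x_cov)) colnames(x_cov))
  out <- freq_all[seq_len(p_mark)]
  out[all_missing] <- 0
  attr(out, "all_frequencies") <- freq_all
  out
}

#' Shared-permutation null selection frequencies
#'
#' Draws `n_perm` strain-index permutations once and applies the same
#' permutations to every trait (preserving inter-trait correlation in the
#' null). Trait values are shuffled across strains while marker and
#' covariate rows stay fixed to strains, so the trait-covariate
#' correspondence of the observed analysis is maintained under the shuffle.
#'
#' @param traits Traits x strains numeric matrix (rownames = trait ids).
#' @param markers,covariates As in [rf_selection_frequency()].
#' @param n_perm Number of permutations (a warning is issued below 20).
#' @param settings List from [rf_settings()] (tree budget etc.).
#' @param perms Optional precomputed permutation matrix (n_perm x strains);
#'   mainly for tests.
#' @param seed Integer seed.
#' @return 3-d array `[trait, perm, marker]` of null selection frequencies,
#'   with attribute `"perms"`.
#' @export
permutation_null <- function(traits, markers, covariates = NULL,
                             n_perm = 1000L, settings = rf_settings(),
                             perms = NULL, seed = 1L) {
  n_s <- ncol(traits)
  if (is.null(perms)) {
    if (n_perm < 20) warning("fewer than 20 permutations: unstable tails")
    perms <- with_seed(substream_seed(seed, "perm-scheme"),
                       t(replicate(n_perm, sample.int(n_s))))
  }
  n_perm <- nrow(perms)
  n_m <- ncol(markers)
  out <- array(NA_real_, c(nrow(traits), n_perm, n_m),
               dimnames = list(rownames(traits), NULL, colnames(markers)))
  for (b in seq_len(n_perm)) {
    for (t in seq_len(nrow(traits))) {
      y <- traits[t, perms[b, ]]
      out[t, b, ] <- rf_selection_frequency(
        y, markers, covariates,
        n_forests = settings$n_forests,
        trees_per_forest = settings$trees_per_forest,
        n_missing_assignments = settings$n_missing_assignments,
        seed = substream_seed(seed, paste0("perm", b, "t", t)))
    }
  }
  attr(out, "perms") <- perms
  out
}

#' Empirical p-values and permutation FDR for selection frequencies
#'
#' Null selection frequencies are pooled over traits and permutations per
#' marker; the empirical p-value uses the plus-one estimator
#' `p = (1 + #null >= observed) / (1 + #null)`. The permutation results are
#' reused to compute p-values for every permuted trait, giving a null
#' p-value distribution from which the FDR at threshold p0 is estimated as
#' `mean_b #{null p(b) <= p0} / #{observed p <= p0}` (clipped to [0, 1] and
#' monotonized in p0). The linked set at level `fdr` contains the
#' trait-marker pairs whose q-value is <= `fdr`.
#'
#' @param observed Traits x markers matrix of observed selection
#'   frequencies.
#' @param null_scores Array from [permutation_null()].
#' @param fdr FDR level for the reported linked set.
#' @return A `linkage_result`: list with `scores`, `p` (traits x markers),
#'   `q`, `linked` (logical traits x markers), and `fdr_level`.
#' @export
empirical_p_and_fdr <- function(observed, null_scores, fdr = 0.10) {
  n_t <- nrow(observed); n_m <- ncol(observed)
  n_perm <- dim(null_scores)[2]
  stopifnot(dim(null_scores)[3] == n_m)
  # pooled null per marker, sorted for rank lookups
  p_obs <- matrix(NA_real_, n_t, n_m, dimnames = dimnames(observed))
  p_null <- array(NA_real_, dim(null_scores))
  n_null <- dim(null_scores)[1] * n_perm
  for (m in seq_len(n_m)) {
    pool <- sort(as.vector(null_scores[, , m]))
    # #null >= x  ==  n_null - #null < x
    p_obs[, m] <- (1 + n_null -
                     findInterval(observed[, m], pool, left.open = TRUE)) /
      (1 + n_null)
    p_null[, , m] <- (1 + n_null -
                        findInterval(null_scores[, , m], pool,
                                     left.open = TRUE)) / (1 + n_null)
  }
  # FDR: compare observed p's with the per-permutation null p's
  obs_p_vec <- as.vector(p_obs)
  ord <- order(obs_p_vec)
  thresholds <- obs_p_vec[ord]
  n_disc <- seq_along(thresholds)               # #observed p <= p0 at p0
  # mean over permutations of #{null p <= p0} equals the pooled count / n_perm
  pool_null_p <- sort(as.vector(p_null))
  mean_null_disc <- findInterval(thresholds, pool_null_p) / n_perm
  q_sorted <- pmin(1, mean_null_disc / n_disc)
  q_sorted <- rev(cummin(rev(q_sorted)))        # monotonize
  q <- matrix(NA_real_, n_t, n_m, dimnames = dimnames(observed))
  q[ord] <- q_sorted
  structure(list(scores = observed, p = p_obs, q = q,
                 linked = q <= fdr, fdr_level = fdr),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("linkage_result:", nrow(x$scores), "traits x", ncol(x$scores),
      "markers;", sum(x$linked), "linked pairs at FDR", x$fdr_level, "\n")
  invisible(x)
}

#' Map QTLs for a set of traits
#'
#' End-to-end wrapper: kinship covariates, observed selection frequencies,
#' shared-permutation null, empirical p and FDR.
#'
#' @param traits Traits x strains matrix (antisense traits may contain NA;
#'   those strains are dropped per trait).
#' @param markers Strains x markers matrix (0/1/NA).
#' @param covariates Optional covariates; if `NULL` they are computed from
#'   the kinship spectrum with `fixed_k` eigenvectors (default 8).
#' @param settings [rf_settings()] list.
#' @param fdr FDR level.
#' @param fixed_k Number of kinship eigenvectors when `covariates` is NULL.
#' @param seed Integer master seed.
#' @return A `linkage_result` (see [empirical_p_and_fdr()]) with the null
#'   array attached as attribute `"null_scores"`.
#' @export
map_qtls <- function(traits, markers, covariates = NULL,
                     settings = rf_settings(), fdr = 0.10, fixed_k = 8L,
                     seed = 1L) {
  if (is.null(covariates)) {
    kin <- kinship(markers)
    covariates <- structure_covariates(kin, fixed_k = min(fixed_k,
                                                          nrow(markers)))
  }
  obs <- t(vapply(seq_len(nrow(traits)), function(t)
    as.numeric(rf_selection_frequency(
      traits[t, ], markers, covariates,
      n_forests = settings$n_forests,
      trees_per_forest = settings$trees_per_forest,
      n_missing_assignments = settings$n_missing_assignments,
      seed = substream_seed(seed, paste0("obs", t)))),
    numeric(ncol(markers))))
  dimnames(obs) <- list(rownames(traits), colnames(markers))
  null_scores <- permutation_null(traits, markers, covariates,
                                  n_perm = settings$n_perm,
                                  settings = settings, seed = seed)
  res <- empirical_p_and_fdr(obs, null_scores, fdr = fdr)
  attr(res, "null_scores") <- null_scores
  res
}

#' Group linked markers into QTL regions and QTL groups
#'
#' Consecutive linked markers span one region. Two regions on the same
#' chromosome are merged (absorbing the intermediate non-linked markers)
#' when their linked members are in high LD (`|r| > ld_min` for every
#' cross-region pair) and separated by at most `max_gap` non-linked markers.
#' Regions that cannot be merged stay separate but the whole set is counted
#' as a single linkage (one multi-region QTL group), since it is a priori
#' unknown which region holds the causal variant. Reported intervals span
#' between the first non-linked flanking polymorphisms; terminal linked
#' markers extend the interval to the chromosome end (enclosing the entire
#' telomere).
#'
#' @param linked_idx Integer indices (genomic order) of markers linked to
#'   the trait.
#' @param marker_info data.frame with `chrom`, `start`, `end` per marker in
#'   genomic order.
#' @param geno Strains x markers matrix used for LD (Pearson correlation of
#'   allele codes over co-called strains).
#' @param chrom_lengths Named vector of chromosome lengths (for the
#'   telomere rule); optional.
#' @param max_gap Maximum number of intermediate non-linked markers.
#' @param ld_min LD threshold for merging.
#' @return A `qtl_group`: list with `regions` (data.frame chrom, start_pos,
#'   end_pos, marker indices as a list-column `members`), `multi_region`,
#'   and `linked_idx`. NULL when `linked_idx` is empty.
#' @export
group_qtls <- function(linked_idx, marker_info, geno, chrom_lengths = NULL,
                       max_gap = 10L, ld_min = 0.8) {
  if (!length(linked_idx)) return(NULL)
  linked_idx <- sort(unique(as.integer(linked_idx)))
  # seed regions: runs of consecutive linked markers on one chromosome
  brk <- c(TRUE, diff(linked_idx) != 1L |
             marker_info$chrom[linked_idx[-1]] !=
             marker_info$chrom[linked_idx[-length(linked_idx)]])
  regions <- split(linked_idx, cumsum(brk))
  # merge pass: absorb gaps when LD is high and the gap is small
  merged <- TRUE
  while (merged && length(regions) > 1) {
    merged <- FALSE
    for (i in seq_len(length(regions) - 1)) {
      a <- regions[[i]]; b <- regions[[i + 1]]
      same_chr <- marker_info$chrom[max(a)] == marker_info$chrom[min(b)]
      gap <- min(b) - max(a) - 1L
      if (same_chr && gap <= max_gap) {
        la <- intersect(a, linked_idx); lb <- intersect(b, linked_idx)
        r <- abs(suppressWarnings(
          cor(geno[, la, drop = FALSE], geno[, lb, drop = FALSE],
              use = "pairwise.complete.obs")))
        if (all(is.finite(r)) && all(r > ld_min)) {
          regions[[i]] <- seq(min(a), max(b))
          regions[[i + 1]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
  }
  reg_df <- do.call(rbind, lapply(regions, function(idx) {
    cn <- marker_info$chrom[idx[1]]
    on_chr <- which(marker_info$chrom == cn)
    prev_nl <- on_chr[on_chr < min(idx)]
    next_nl <- on_chr[on_chr > max(idx)]
    start_pos <- if (length(prev_nl)) marker_info$end[max(prev_nl)] else 1
    end_pos <- if (length(next_nl)) marker_info$start[min(next_nl)] else
      (chrom_lengths[cn] %||% marker_info$end[max(idx)])
    data.frame(chrom = cn, start_pos = as.numeric(start_pos),
               end_pos = as.numeric(end_pos), stringsAsFactors = FALSE)
  }))
  reg_df$members <- I(regions)
  rownames(reg_df) <- NULL
  structure(list(regions = reg_df, multi_region = nrow(reg_df) > 1,
                 linked_idx = linked_idx),
            class = "qtl_group")
}

#' @export
print.qtl_group <- function(x, ...) {
  cat("qtl_group:", nrow(x$regions), "region(s);",
      length(x$linked_idx), "linked marker(s)",
      if (x$multi_region) "[multi-region]" else "", "\n")
  invisible(x)
}
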