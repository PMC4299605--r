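#' Simulate a haploid two-parent cross
#'
#' Draws recombinant haploid segregants from a P1 x P2 cross. Crossovers per
#' chromosome per meiosis are Poisson with mean proportional to chromosome
#' length; crossover positions are uniform, and positions falling inside the
#' genome's inversion interval are retained only with probability
#' `inversion_suppression` (recombination suppression in inversion
#' heterozygotes). F1 segregants arise from one meiosis of the P1/P2 hybrid;
#' F2 segregants from mating two random F1 segregants and one further meiosis,
#' so they accumulate more breakpoints.
#'
#' @param genome A `genome_model`.
#' @param n_segregants Number of segregants (>= 1).
#' @param generation `"F1"` or `"F2"`.
#' @param crossover_rate_per_mb Expected crossovers per Mb per meiosis.
#' @param inversion_suppression Retention probability in `[0,1]` for
#'   crossovers inside the inversion.
#' @param interference_bp Crossover interference distance: two effective
#'   breakpoints of one segregant chromosome are never closer than this
#'   (later breakpoints of a too-close pair are removed). Set 0 to disable.
#' @param seed Integer seed.
#' @return A `true_genotypes` object: list with `alleles` (integer matrix
#'   strains x variant sites, 0 = P1, 1 = P2; column names `chrom:pos`),
#'   `breakpoints` (data.frame strain/chrom/pos of label changes between
#'   consecutive segments), and `sites` (the genome's variant table).
#' @export
simulate_cross <- function(genome, n_segregants,
                           generation = c("F2", "F1"),
                           crossover_rate_per_mb = 6,
                           inversion_suppression = 1,
                           interference_bp = 50000,
                           seed = 1L) {
  generation <- match.arg(generation)
  stopifnot(n_segregants >= 1, crossover_rate_per_mb >= 0,
            inversion_suppression >= 0, inversion_suppression <= 1)
  chroms <- genome$chromosomes
  v <- genome$variants
  with_seed(substream_seed(seed, "cross"), {
    strains <- sprintf("S%03d", seq_len(n_segregants))
    alleles <- matrix(NA_integer_, n_segregants, nrow(v),
                      dimnames = list(strains, site_id(v$chrom, v$pos)))
    bp <- list()
    for (s in seq_len(n_segregants)) {
      for (ci in seq_len(nrow(chroms))) {
        cn <- chroms$name[ci]; L <- chroms$length[ci]
        mos <- .draw_mosaic(cn, L, genome$inversion, crossover_rate_per_mb,
                            inversion_suppression, generation)
        mos <- .apply_interference(mos, interference_bp)
        sites <- which(v$chrom == cn)
        if (length(sites)) {
          seg <- findInterval(v$pos[sites], mos$cuts)  # 0..k segments
          alleles[s, sites] <- mos$labels[seg + 1L]
        }
        # effective breakpoints: segment boundaries where the label changes
        if (length(mos$cuts)) {
          chg <- which(diff(mos$labels) != 0L)
          if (length(chg))
            bp[[length(bp) + 1L]] <- data.frame(
              strain = strains[s], chrom = cn, pos = mos$cuts[chg],
              stringsAsFactors = FALSE)
        }
      }
    }
    breakpoints <- if (length(bp)) do.call(rbind, bp) else
      data.frame(strain = character(), chrom = character(), pos = numeric())
    structure(list(alleles = alleles, breakpoints = breakpoints,
                   sites = v, generation = generation),
              class = "true_genotypes")
  })
}

# one recombinant haploid chromosome as cut positions + per-segment labels
.draw_mosaic <- function(chrom, L, inversion, rate_per_mb, suppression,
                         generation) {
  hap1 <- list(cuts = numeric(0), labels = P1_CODE)
  hap2 <- list(cuts = numeric(0), labels = P2_CODE)
  child <- .meiosis(hap1, hap2, chrom, L, inversion, rate_per_mb, suppression)
  if (generation == "F1") return(child)
  # F2: two independent F1 gametes mated, then one more meiosis
  f1a <- .meiosis(hap1, hap2, chrom, L, inversion, rate_per_mb, suppression)
  f1b <- .meiosis(hap1, hap2, chrom, L, inversion, rate_per_mb, suppression)
  .meiosis(f1a, f1b, chrom, L, inversion, rate_per_mb, suppression)
}

# recombine two parental haplotypes: crossover positions Poisson-uniform,
# thinned inside the inversion; alternate between haplotypes at each cut
.meiosis <- function(hapA, hapB, chrom, L, inversion, rate_per_mb,
                     suppression) {
  k <- rpois(1, rate_per_mb * L / 1e6)
  cuts <- sort(runif(k, 1, L))
  if (!is.null(inversion) && length(cuts) && inversion$chrom == chrom) {
    inside <- cuts >= inversion$start & cuts <= inversion$end
    keep <- !inside | (runif(length(cuts)) < suppression)
    cuts <- cuts[keep]
  }
  if (runif(1) < 0.5) { tmp <- hapA; hapA <- hapB; hapB <- tmp }
  all_cuts <- sort(unique(c(cuts, hapA$cuts, hapB$cuts)))
  if (!length(all_cuts))
    return(list(cuts = numeric(0), labels = hapA$labels[1]))
  mids <- c((c(0, all_cuts) + c(all_cuts, L)) / 2)  # one point per segment
  from_b <- (findInterval(mids, cuts) %% 2) == 1    # active haplotype
  lab <- ifelse(from_b,
                vapply(mids, function(p) .hap_label(hapB, p), integer(1)),
                vapply(mids, function(p) .hap_label(hapA, p), integer(1)))
  # drop cuts that do not change the label
  keep <- diff(lab) != 0L
  list(cuts = all_cuts[keep], labels = lab[c(TRUE, keep)])
}

# enforce a minimum distance between effective breakpoints: of any pair
# closer than min_bp the later one is removed (its segment merges leftward)
.apply_interference <- function(mos, min_bp) {
  if (min_bp <= 0 || length(mos$cuts) < 2) return(mos)
  cuts <- mos$cuts; labels <- mos$labels
  repeat {
    close <- which(diff(cuts) < min_bp)
    if (!length(close)) break
    drop <- close[1] + 1L          # remove the later cut of the pair
    cuts <- cuts[-drop]
    labels <- labels[-(drop + 1L)] # segment after it merges into the left
    keep <- c(TRUE, diff(labels) != 0L)
    cuts <- cuts[keep[-1]]
    labels <- labels[keep]
    if (length(cuts) < 2) break
  }
  list(cuts = cuts, labels = labels)
}

.hap_label <- function(hap, pos) {
  hap$labels[findInterval(pos, hap$cuts) + 1L]
}

#' @export
print.true_genotypes <- function(x, ...) {
  cat("true_genotypes:", nrow(x$alleles), "strains x", ncol(x$alleles),
      "sites;", nrow(x$breakpoints), "breakpoints (",
      sprintf("%.1f", nrow(x$breakpoints) / nrow(x$alleles)),
      "per strain )\n")
  invisible(x)
}

#' Count recombination breakpoints per strain
#'
#' @param genotypes A `true_genotypes` object.
#' @return Named integer vector of breakpoint counts per strain.
#' @export
breakpoints_per_strain <- function(genotypes) {
  n <- table(factor(genotypes$breakpoints$strain,
                    levels = rownames(genotypes$alleles)))
  setNames(as.integer(n), names(n))
}
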