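# Strain-specific genome coordinates: indels shift everything downstream of
# them, so per-strain annotation must be lifted through a cumulative offset
# map. Insertions of k bases at pos add k after pos; deletions of k bases at
# pos remove reference positions pos+1 .. pos+k.

#' Personalize a genome for one strain
#'
#' Builds the coordinate offset map implied by the indels the strain carries
#' and lifts the gene/CDS annotation into strain coordinates. SNPs change
#' sequence only and do not shift coordinates. An annotation boundary that
#' falls inside a deleted region is clamped to the deletion edge (with a
#' warning).
#'
#' @param genome A `genome_model` (reference frame).
#' @param strain_alleles Integer 0/1 vector over the genome's variant sites
#'   (1 = strain carries the alt allele), or a character vector of
#'   `"chrom:pos"` ids of carried alt sites.
#' @return A `strain_genome`: list with `indels` (carried indels), `genes`
#'   (annotation lifted to strain coordinates), and the reference `genome`.
#' @export
personalize_genome <- function(genome, strain_alleles) {
  v <- genome$variants
  sid <- site_id(v$chrom, v$pos)
  carried <- if (is.character(strain_alleles)) sid %in% strain_alleles else {
    stopifnot(length(strain_alleles) == nrow(v))
    strain_alleles == 1L
  }
  ind <- v[carried & v$type != "SNP", , drop = FALSE]
  ind <- ind[order(ind$chrom, ind$pos), , drop = FALSE]
  genes <- genome$genes
  warn_clamped <- 0L
  lift1 <- function(chrom, p) {
    r <- lift_position(ind, chrom, p)
    if (attr(r, "clamped")) warn_clamped <<- warn_clamped + 1L
    as.numeric(r)
  }
  for (i in seq_len(nrow(genes))) {
    cn <- genes$chrom[i]
    genes$cds_start[i] <- lift1(cn, genes$cds_start[i])
    genes$cds_end[i] <- lift1(cn, genes$cds_end[i])
    genes$tss[i] <- lift1(cn, genes$tss[i])
  }
  if (warn_clamped > 0)
    warning(warn_clamped, " annotation boundary(ies) inside deleted regions",
            " were clamped to the deletion edge")
  structure(list(indels = ind, genes = genes, genome = genome),
            class = "strain_genome")
}

# lift one reference position into strain coordinates
lift_position <- function(indels, chrom, p) {
  idx <- which(indels$chrom == chrom)
  off <- 0; clamped <- FALSE
  for (i in idx) {
    ip <- indels$pos[i]; d <- indels$delta[i]
    if (d > 0) {               # insertion after ip
      if (p > ip) off <- off + d
    } else {                   # deletion of positions ip+1 .. ip-d
      if (p > ip - d) off <- off + d
      else if (p > ip) {       # inside the deleted run: clamp to edge
        return(structure(ip + .cum_off(indels, chrom, ip), clamped = TRUE))
      }
    }
  }
  structure(p + off, clamped = clamped)
}

.cum_off <- function(indels, chrom, p) {
  idx <- which(indels$chrom == chrom)
  off <- 0
  for (i in idx) {
    ip <- indels$pos[i]; d <- indels$delta[i]
    if (d > 0) { if (p > ip) off <- off + d } else if (p > ip - d)
      off <- off + d
  }
  off
}

#' Lift reference positions to strain coordinates (vectorized)
#'
#' @param sg A `strain_genome`.
#' @param chrom Chromosome name(s).
#' @param pos Reference position(s).
#' @return Numeric vector of strain coordinates (NA for deleted positions).
#' @export
lift_over <- function(sg, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  vapply(seq_along(pos), function(i) {
    r <- lift_position(sg$indels, chrom[i], pos[i])
    if (attr(r, "clamped")) NA_real_ else as.numeric(r)
  }, numeric(1))
}

#' Inverse liftover: strain coordinates back to the reference
#'
#' @param sg A `strain_genome`.
#' @param chrom Chromosome name(s).
#' @param pos Strain position(s).
#' @return Numeric vector of reference positions (NA inside insertions).
#' @export
lift_back <- function(sg, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  ind <- sg$indels
  vapply(seq_along(pos), function(i) {
    idx <- which(ind$chrom == chrom[i])
    p <- pos[i]; off <- 0
    for (k in idx) {
      ip_strain <- ind$pos[k] + off   # indel anchor in strain coordinates
      d <- ind$delta[k]
      if (d > 0) {
        if (p > ip_strain + d) off <- off + d
        else if (p > ip_strain) return(NA_real_)  # inside inserted bases
      } else {
        if (p > ip_strain) off <- off + d
      }
    }
    p - off
  }, numeric(1))
}

#' @export
print.strain_genome <- function(x, ...) {
  cat("strain_genome:", nrow(x$indels), "carried indels;",
      nrow(x$genes), "lifted genes\n")
  invisible(x)
}
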