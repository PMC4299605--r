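#' Build a synthetic two-parent genome model
#'
#' Generates chromosomes, non-overlapping gene annotations (optionally with
#' convergent overlapping pairs), and a sorted set of polymorphic sites
#' (SNPs and small indels) distinguishing the two parental strains P1 and P2.
#' P1 carries the reference allele at every site; P2 carries the alternative.
#' Coordinates are 1-based inclusive throughout (VCF/GFF convention).
#'
#' @param config A list of simulation parameters; see [sim_config()] for the
#'   defaults and the meaning of each field. Fields used here:
#'   `chrom_lengths` (named numeric), `n_genes`, `n_variants`,
#'   `frac_variants_in_cds` (fraction of sites placed inside coding
#'   sequences), `frac_indel` (fraction of sites that are indels),
#'   `max_indel` (maximum indel length in bp), `n_convergent_overlap`
#'   (number of convergent gene pairs with overlapping CDS),
#'   `mean_cds_len`, `tss_offset`, and optional `inversion`
#'   (list(chrom, start, end)).
#' @param seed Integer seed; the model is deterministic given `config` + `seed`.
#' @return A `genome_model` object: list with `chromosomes` (data.frame
#'   name/length), `genes` (data.frame gene_id/chrom/strand/tss/cds_start/
#'   cds_end/coding), `variants` (data.frame chrom/pos/ref/alt/type/delta,
#'   sorted, unique positions) and `inversion`.
#' @export
#' @examples
#' gm <- make_genome(sim_config(n_genes = 50, n_variants = 80), seed = 1)
#' nrow(gm$genes)
make_genome <- function(config, seed = 1L) {
  cfg <- config
  chrom_lengths <- cfg$chrom_lengths
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  n_genes <- cfg$n_genes
  n_variants <- cfg$n_variants

  with_seed(substream_seed(seed, "genome"), {
    genes <- .place_genes(chrom_lengths, n_genes,
                          mean_cds_len = cfg$mean_cds_len %||% 1200,
                          tss_offset = cfg$tss_offset %||% 120,
                          n_convergent_overlap = cfg$n_convergent_overlap %||% 0,
                          margin = 200L)
    variants <- .place_variants(chrom_lengths, genes, n_variants,
                                frac_in_cds = cfg$frac_variants_in_cds %||% 0.8,
                                frac_indel = cfg$frac_indel %||% 0.15,
                                max_indel = cfg$max_indel %||% 3)
  })

  gm <- structure(list(
    chromosomes = data.frame(name = names(chrom_lengths),
                             length = as.numeric(chrom_lengths),
                             stringsAsFactors = FALSE),
    genes = genes,
    variants = variants,
    inversion = cfg$inversion
  ), class = "genome_model")
  validate_genome(gm)
  gm
}

#' Default simulation configuration (desk profile)
#'
#' The defaults emulate a small fission-yeast-like cross: three chromosomes,
#' a few hundred genes and variant sites, a pericentric inversion on the
#' first chromosome with strongly suppressed recombination, negative-binomial
#' count noise, and genotype-call observability tied to expression level.
#'
#' @param ... Named overrides of any default field.
#' @return A list of simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chr1 = 1.4e6, chr2 = 1.2e6, chr3 = 1.0e6),
    n_genes = 300,
    n_variants = 1000,
    frac_variants_in_cds = 0.8,
    frac_indel = 0.15,
    max_indel = 3,
    n_convergent_overlap = 6,
    mean_cds_len = 1200,
    tss_offset = 120,
    inversion = list(chrom = "chr1", start = 2e5, end = 5e5),
    # cross
    n_segregants = 44,
    generation = "F2",
    crossover_rate_per_mb = 6,
    inversion_suppression = 0.1,
    interference_bp = 50000,
    # expression
    baseline_mean = 5, baseline_sd = 1.5,
    antisense_shift = -4,
    dispersion = 0.05,
    batch_sd = 0.3,
    n_batches = 2,
    libsize_sd = 0.15,
    # genotype calls: P(called) = 1 - exp(-count / theta)
    call_theta = 32,
    call_error = 0.002,
    quality_mean = 60, quality_sd = 15,
    # reads
    read_length = 48L,
    polyA = 48L,
    base_error_rate = 0.01,
    mismatch_tolerance = 3L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.place_genes <- function(chrom_lengths, n_genes, mean_cds_len, tss_offset,
                         n_convergent_overlap, margin) {
  # apportion genes to chromosomes by length
  n_chrom <- length(chrom_lengths)
  per <- round(n_genes * chrom_lengths / sum(chrom_lengths))
  per[n_chrom] <- n_genes - sum(per[-n_chrom])
  rows <- list(); gid <- 0L
  overlap_left <- n_convergent_overlap
  for (ci in seq_len(n_chrom)) {
    chrom <- names(chrom_lengths)[ci]
    L <- chrom_lengths[ci]
    ng <- per[ci]
    if (ng == 0) next
    # lay genes on an even grid with jitter, CDS length ~ gamma
    slots <- floor((L - 2 * margin) / ng)
    if (slots < mean_cds_len / 2)
      stop("chromosome ", chrom, " too short for requested gene count")
    start_grid <- margin + slots * (seq_len(ng) - 1L)
    for (k in seq_len(ng)) {
      gid <- gid + 1L
      len <- max(300L, round(rgamma_len(mean_cds_len)))
      len <- min(len, slots - 150L)
      s <- start_grid[k] + sample.int(max(1L, slots - len - 120L), 1L)
      e <- s + len - 1L
      strand <- sample(c("+", "-"), 1L)
      tss <- if (strand == "+") s - min(tss_offset, s - 1L) else
        min(e + tss_offset, L - margin)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("g%04d", gid), chrom = chrom, strand = strand,
        tss = tss, cds_start = s, cds_end = e, coding = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$cds_start), , drop = FALSE]
  rownames(genes) <- NULL
  # convert some adjacent pairs into convergent overlapping pairs
  if (overlap_left > 0) {
    i <- 1L
    while (overlap_left > 0 && i < nrow(genes)) {
      a <- i; b <- i + 1L
      if (genes$chrom[a] == genes$chrom[b]) {
        genes$strand[a] <- "+"; genes$strand[b] <- "-"
        gap <- genes$cds_start[b] - genes$cds_end[a]
        shift <- gap + 60L  # overlap CDS by ~60 bp
        genes$cds_end[a] <- genes$cds_end[a] + shift
        genes$tss[a] <- min(genes$tss[a], genes$cds_start[a] - 1L)
        genes$tss[b] <- genes$cds_end[b] + 100L
        overlap_left <- overlap_left - 1L
        i <- i + 5L  # space the overlapping pairs out
      } else i <- i + 1L
    }
  }
  # fix TSS invariant after edits
  genes$tss <- ifelse(genes$strand == "+",
                      pmin(genes$tss, genes$cds_start - 1L),
                      pmax(genes$tss, genes$cds_end + 1L))
  genes
}

rgamma_len <- function(mean_len) stats::rgamma(1, shape = 4, scale = mean_len / 4)

.place_variants <- function(chrom_lengths, genes, n_variants, frac_in_cds,
                            frac_indel, max_indel) {
  n_cds <- round(n_variants * frac_in_cds)
  pos_cds <- if (n_cds > 0) {
    idx <- sample.int(nrow(genes), n_cds, replace = TRUE)
    # avoid the outer read-length of the CDS so indels stay inside
    p <- mapply(function(s, e) if (e - s > 120) sample(seq(s + 50, e - 50), 1)
                else sample(seq(s, e), 1),
                genes$cds_start[idx], genes$cds_end[idx])
    data.frame(chrom = genes$chrom[idx], pos = p, stringsAsFactors = FALSE)
  } else NULL
  n_inter <- n_variants - n_cds
  pos_inter <- if (n_inter > 0) {
    ch <- sample(names(chrom_lengths), n_inter, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    data.frame(chrom = ch,
               pos = floor(runif(n_inter, 100, chrom_lengths[ch] - 100)),
               stringsAsFactors = FALSE)
  } else NULL
  v <- rbind(pos_cds, pos_inter)
  v <- v[!duplicated(paste(v$chrom, v$pos)), , drop = FALSE]
  tries <- 0L
  while (nrow(v) < n_variants && tries < 50L) {
    need <- n_variants - nrow(v)
    ch <- sample(names(chrom_lengths), need, replace = TRUE)
    extra <- data.frame(chrom = ch,
                        pos = floor(runif(need, 100, chrom_lengths[ch] - 100)),
                        stringsAsFactors = FALSE)
    v <- rbind(v, extra)
    v <- v[!duplicated(paste(v$chrom, v$pos)), , drop = FALSE]
    tries <- tries + 1L
  }
  if (nrow(v) < n_variants)
    stop("cannot place ", n_variants, " distinct variant positions")
  v <- v[seq_len(n_variants), ]
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  n <- nrow(v)
  bases <- c("A", "C", "G", "T")
  is_indel <- runif(n) < frac_indel
  type <- ifelse(is_indel, sample(c("insertion", "deletion"), n, replace = TRUE),
                 "SNP")
  delta <- integer(n)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    if (type[i] == "SNP") {
      ref[i] <- sample(bases, 1)
      alt[i] <- sample(setdiff(bases, ref[i]), 1)
    } else {
      k <- sample.int(max_indel, 1)
      anchor <- sample(bases, 1)
      ins <- paste(sample(bases, k, replace = TRUE), collapse = "")
      if (type[i] == "insertion") {
        ref[i] <- anchor; alt[i] <- paste0(anchor, ins); delta[i] <- k
      } else {
        ref[i] <- paste0(anchor, ins); alt[i] <- anchor; delta[i] <- -k
      }
    }
  }
  data.frame(chrom = v$chrom, pos = v$pos, ref = ref, alt = alt,
             type = type, delta = delta, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$variants), "variant sites\n")
  if (!is.null(x$inversion))
    cat("  inversion:", x$inversion$chrom, x$inversion$start, "-",
        x$inversion$end, "\n")
  invisible(x)
}

validate_genome <- function(gm) {
  ch <- setNames(gm$chromosomes$length, gm$chromosomes$name)
  g <- gm$genes
  stopifnot(all(g$cds_start <= g$cds_end),
            all(g$cds_start >= 1), all(g$cds_end <= ch[g$chrom]),
            !anyDuplicated(g$gene_id))
  plus <- g$strand == "+"
  stopifnot(all(g$tss[plus] < g$cds_start[plus]),
            all(g$tss[!plus] > g$cds_end[!plus]))
  v <- gm$variants
  for (cn in unique(v$chrom)) {
    p <- v$pos[v$chrom == cn]
    if (any(diff(p) <= 0)) stop("variant positions not strictly increasing")
  }
  stopifnot(all(v$delta[v$type == "SNP"] == 0),
            all(v$delta[v$type == "deletion"] < 0),
            all(v$delta[v$type == "insertion"] > 0))
  invisible(gm)
}

#' Map each variant site to its host gene
#'
#' Returns, per variant site, the id of the gene whose CDS contains it
#' (NA for intergenic sites). Intragenic sites are the only ones observable
#' through RNA-seq genotyping.
#'
#' @param genome A `genome_model`.
#' @return Character vector along `genome$variants`.
#' @export
variant_host_gene <- function(genome) {
  v <- genome$variants; g <- genome$genes
  host <- rep(NA_character_, nrow(v))
  for (i in seq_len(nrow(g))) {
    hit <- v$chrom == g$chrom[i] & v$pos >= g$cds_start[i] & v$pos <= g$cds_end[i]
    host[hit & is.na(host)] <- g$gene_id[i]
  }
  host
}
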