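#' Construct an effect configuration for expression simulation
#'
#' Describes the genetic architecture planted into simulated expression:
#' cis effects (a gene responds to its own local variant), trans effects
#' (a distant marker site drives a target gene), and an optional hotspot (one
#' marker site with many targets, sense effects negative and antisense
#' effects positive for the P2 allele, emulating a locus that represses sense
#' transcription while boosting antisense). Effect sizes are in units of the
#' per-gene residual standard deviation of normalized log2 expression implied
#' by the count-noise model (see [trait_sd_unit()]).
#'
#' @param cis data.frame with columns `gene_id`, `effect` (SD units).
#' @param trans data.frame with columns `site` (`"chrom:pos"`), `gene_id`,
#'   `effect` (signed, SD units).
#' @param hotspot Optional list with `site`, `sense_targets` (gene ids),
#'   `antisense_targets`, `sense_effect` (< 0), `antisense_effect` (> 0).
#' @param batches Factor/character of batch labels per sample (recycled to
#'   the number of segregants if length 1..n).
#' @param dispersion Negative-binomial dispersion of counts (0 = noise-free).
#' @param baseline Optional numeric vector of per-gene baseline log2
#'   expression (named by gene); drawn from the config if `NULL`.
#' @return An `effect_config` list.
#' @export
effect_config <- function(cis = NULL, trans = NULL, hotspot = NULL,
                          batches = NULL, dispersion = 0.05,
                          baseline = NULL) {
  structure(list(cis = cis, trans = trans, hotspot = hotspot,
                 batches = batches, dispersion = dispersion,
                 baseline = baseline),
            class = "effect_config")
}

#' Default planted architecture for a simulated cross
#'
#' Picks cis genes (genes hosting a variant in their CDS), trans target
#' genes and driver sites on other chromosomes, and optionally a hotspot
#' site with opposed sense/antisense target sets.
#'
#' @param genome A `genome_model`.
#' @param n_cis,n_trans Numbers of planted cis and trans effects.
#' @param cis_effect,trans_effect Effect sizes (SD units); trans effects get
#'   alternating signs.
#' @param hotspot_n_sense,hotspot_n_anti Target counts for the hotspot
#'   (0 to disable).
#' @param seed Integer seed for the picks.
#' @inheritParams effect_config
#' @return An `effect_config`.
#' @export
default_effect_config <- function(genome, n_cis = 5, n_trans = 10,
                                  cis_effect = 2, trans_effect = 1.5,
                                  hotspot_n_sense = 0, hotspot_n_anti = 0,
                                  batches = NULL, dispersion = 0.05,
                                  seed = 1L) {
  host <- variant_host_gene(genome)
  v <- genome$variants
  sid <- site_id(v$chrom, v$pos)
  with_seed(substream_seed(seed, "effects"), {
    cis_pool <- unique(host[!is.na(host)])
    cis_genes <- if (n_cis > 0) sample(cis_pool, n_cis) else character(0)
    cis <- if (n_cis > 0)
      data.frame(gene_id = cis_genes, effect = cis_effect,
                 stringsAsFactors = FALSE) else NULL
    used <- cis_genes
    trans <- NULL
    if (n_trans > 0) {
      tg <- sample(setdiff(genome$genes$gene_id, used), n_trans)
      drv <- character(n_trans)
      for (i in seq_len(n_trans)) {
        gch <- genome$genes$chrom[genome$genes$gene_id == tg[i]]
        pool <- which(v$chrom != gch)
        drv[i] <- sid[sample(pool, 1)]
      }
      trans <- data.frame(site = drv, gene_id = tg,
                          effect = trans_effect * rep_len(c(1, -1), n_trans),
                          stringsAsFactors = FALSE)
      used <- c(used, tg)
    }
    hotspot <- NULL
    if (hotspot_n_sense > 0 || hotspot_n_anti > 0) {
      hs_site <- sid[sample.int(nrow(v), 1)]
      pool <- setdiff(genome$genes$gene_id, used)
      sense_t <- sample(pool, hotspot_n_sense)
      anti_t <- sample(setdiff(pool, sense_t), hotspot_n_anti)
      hotspot <- list(site = hs_site, sense_targets = sense_t,
                      antisense_targets = anti_t,
                      sense_effect = -1, antisense_effect = 1)
    }
    effect_config(cis = cis, trans = trans, hotspot = hotspot,
                  batches = batches, dispersion = dispersion)
  })
}

#' Residual SD of normalized log2 expression implied by the count model
#'
#' Delta-method approximation: a negative-binomial count with mean `m` and
#' dispersion `phi` has variance `m + phi m^2`, hence
#' `sd(log2 count) ~ sqrt(1/m + phi) / ln 2`. Used to express planted effect
#' sizes in SD units.
#'
#' @param baseline_log2 Baseline log2 expression (mean count = 2^baseline).
#' @param dispersion NB dispersion.
#' @return SD of log2 expression (per element).
#' @export
trait_sd_unit <- function(baseline_log2, dispersion) {
  m <- 2^baseline_log2
  sqrt(1 / m + dispersion) / log(2)
}

#' Simulate sense and antisense expression for a segregant panel
#'
#' Per gene and sample the mean log2 expression is
#' baseline + sum(allele-coded planted effects) + batch offset; counts are
#' drawn negative-binomial around `2^mean * library-size factor`
#' (`dispersion = 0` gives noise-free counts equal to the mean). Hotspot
#' targets receive coupled effects: for strains carrying the P2 allele at the
#' hotspot site, sense targets go down and antisense targets go up.
#'
#' @param genome A `genome_model`.
#' @param genotypes A `true_genotypes` from [simulate_cross()].
#' @param effects An `effect_config`.
#' @param config A [sim_config()] list (baseline/batch/library-size knobs).
#' @param seed Integer seed.
#' @return List with `sense`, `antisense` (integer count matrices genes x
#'   samples), `mu_sense`, `mu_antisense` (true mean log2 matrices),
#'   `batches`, `lib_factors`, `baseline`, and `truth` (planted effect table
#'   with realized log2 shifts, for recovery tests).
#' @export
simulate_expression <- function(genome, genotypes, effects,
                                config = sim_config(), seed = 1L) {
  g <- genome$genes
  strains <- rownames(genotypes$alleles)
  n_g <- nrow(g); n_s <- length(strains)
  sid <- colnames(genotypes$alleles)
  disp <- effects$dispersion %||% 0.05

  with_seed(substream_seed(seed, "expression"), {
    baseline <- effects$baseline %||%
      setNames(rnorm(n_g, config$baseline_mean, config$baseline_sd), g$gene_id)
    batches <- effects$batches %||%
      rep_len(paste0("b", seq_len(config$n_batches)), n_s)
    batches <- factor(rep_len(batches, n_s))
    batch_off <- matrix(rnorm(n_g * nlevels(batches), 0, config$batch_sd),
                        n_g, nlevels(batches),
                        dimnames = list(g$gene_id, levels(batches)))
    lib <- exp(rnorm(n_s, 0, config$libsize_sd))

    sd_unit <- trait_sd_unit(baseline, disp)
    mu_s <- matrix(rep(baseline, n_s), n_g, n_s,
                   dimnames = list(g$gene_id, strains))
    mu_a <- mu_s + config$antisense_shift
    sd_unit_a <- trait_sd_unit(baseline + config$antisense_shift, disp)

    allele_at <- function(site) genotypes$alleles[, site]
    truth <- list()
    host <- variant_host_gene(genome)
    add_truth <- function(kind, gene, site, eff_sd, eff_log2, strand) {
      truth[[length(truth) + 1L]] <<- data.frame(
        kind = kind, gene_id = gene, site = site, effect_sd = eff_sd,
        effect_log2 = eff_log2, strand = strand, stringsAsFactors = FALSE)
    }

    if (!is.null(effects$cis)) {
      for (i in seq_len(nrow(effects$cis))) {
        gene <- effects$cis$gene_id[i]
        own <- sid[which(host == gene)]
        if (!length(own)) {  # nearest site on the gene's chromosome
          gi <- match(gene, g$gene_id)
          cand <- which(genome$variants$chrom == g$chrom[gi])
          own <- sid[cand[which.min(abs(genome$variants$pos[cand] -
                                          g$cds_start[gi]))]]
        }
        site <- own[1]
        shift <- effects$cis$effect[i] * sd_unit[gene]
        mu_s[gene, ] <- mu_s[gene, ] + shift * allele_at(site)
        add_truth("cis", gene, site, effects$cis$effect[i], shift, "sense")
      }
    }
    if (!is.null(effects$trans)) {
      for (i in seq_len(nrow(effects$trans))) {
        gene <- effects$trans$gene_id[i]; site <- effects$trans$site[i]
        shift <- effects$trans$effect[i] * sd_unit[gene]
        mu_s[gene, ] <- mu_s[gene, ] + shift * allele_at(site)
        add_truth("trans", gene, site, effects$trans$effect[i], shift, "sense")
      }
    }
    if (!is.null(effects$hotspot)) {
      hs <- effects$hotspot
      a <- allele_at(hs$site)
      for (gene in hs$sense_targets) {
        shift <- hs$sense_effect * sd_unit[gene]
        mu_s[gene, ] <- mu_s[gene, ] + shift * a
        add_truth("hotspot_sense", gene, hs$site, hs$sense_effect, shift,
                  "sense")
      }
      for (gene in hs$antisense_targets) {
        shift <- hs$antisense_effect * sd_unit_a[gene]
        mu_a[gene, ] <- mu_a[gene, ] + shift * a
        add_truth("hotspot_antisense", gene, hs$site, hs$antisense_effect,
                  shift, "antisense")
      }
    }

    mu_s <- mu_s + batch_off[, as.integer(batches)]
    mu_a <- mu_a + batch_off[, as.integer(batches)]

    draw <- function(mu) {
      m <- sweep(2^mu, 2, lib, `*`)
      if (disp == 0) return(m)
      matrix(rnbinom(length(m), mu = as.vector(m), size = 1 / disp),
             nrow(m), ncol(m), dimnames = dimnames(m))
    }
    sense <- draw(mu_s)
    anti <- draw(mu_a)

    list(sense = sense, antisense = anti, mu_sense = mu_s, mu_antisense = mu_a,
         batches = batches, lib_factors = lib, baseline = baseline,
         truth = if (length(truth)) do.call(rbind, truth) else NULL)
  })
}

#' Number of reads to simulate for a gene
#'
#' The normalized log2 expression value is transformed back to the natural
#' scale, multiplied by 10 and ceiled; values below 1 are set to 1:
#' `NR = max(1, ceiling(10 * 2^expression))`.
#'
#' @param norm_log_expression Numeric vector of normalized log2 values.
#' @return Integer vector of read counts (>= 1), monotone in the input.
#' @export
#' @examples
#' reads_per_gene(c(0, -10, 3.1))  # 10, 1, 86
reads_per_gene <- function(norm_log_expression) {
  if (any(is.nan(norm_log_expression)))
    stop("NaN expression value", call. = FALSE)
  stopifnot(is.numeric(norm_log_expression),
            all(is.finite(norm_log_expression)))
  pmax(1, as.integer(ceiling(10 * 2^norm_log_expression)))
}

#' Position-dependent sequencing error model
#'
#' @param rates Per-read-position mismatch probability vector; recycled to
#'   `read_length` if scalar.
#' @param read_length Read length in bases.
#' @return An `error_model` numeric vector.
#' @export
error_model <- function(rates = 0.01, read_length = 48L) {
  p <- rep_len(rates, read_length)
  stopifnot(all(p >= 0), all(p <= 1))
  structure(p, class = "error_model")
}

#' Simulate read placements for one strain
#'
#' Reads of `read_length` bases are placed uniformly over each gene's
#' strain-specific transcript (CDS length adjusted for carried indels, plus a
#' 48-base poly-A tail), with per-base sequencing errors drawn from the error
#' model. Read strand equals the gene strand. Covered variant sites are
#' tallied against the strain's alleles: `n_alt_snp` / `n_alt_indel` count
#' covered sites where the strain carries the non-reference allele.
#'
#' @param genome A `genome_model`.
#' @param strain_alleles Integer vector (0/1) over the genome's variant
#'   sites for one strain (a row of `true_genotypes$alleles`).
#' @param nr Named integer vector of reads per gene (names = gene ids).
#' @param err An [error_model()].
#' @param read_length Read length (bases).
#' @param polyA Poly-A tail length appended to every transcript.
#' @param seed Integer seed.
#' @return data.frame of read placements: `chrom, start, end, strand,
#'   gene_id, n_var, n_alt_snp, n_alt_indel, n_errors, has_error`.
#' @export
simulate_reads <- function(genome, strain_alleles, nr, err = error_model(),
                           read_length = 48L, polyA = 48L, seed = 1L) {
  stopifnot(all(nr >= 1))
  g <- genome$genes
  v <- genome$variants
  sid <- site_id(v$chrom, v$pos)
  if (is.null(names(strain_alleles))) names(strain_alleles) <- sid
  host <- variant_host_gene(genome)
  p_err <- rep_len(unclass(err), read_length)

  with_seed(substream_seed(seed, "reads"), {
    out <- vector("list", length(nr))
    for (k in seq_along(nr)) {
      gene <- names(nr)[k]
      gi <- match(gene, g$gene_id)
      if (is.na(gi)) stop("unknown gene: ", gene)
      n <- nr[[k]]
      idx_v <- which(host == gene)
      carries_alt <- strain_alleles[sid[idx_v]] == 1L
      len_ref <- g$cds_end[gi] - g$cds_start[gi] + 1L
      len_strain <- len_ref + sum(v$delta[idx_v][carries_alt])
      span <- len_strain + polyA - read_length + 1L
      tpos <- if (span < 1L) rep(1L, n) else
        sample.int(span, n, replace = TRUE)
      # map transcript position to reference coordinates (bookkeeping frame)
      tpos_ref <- pmin(tpos, len_ref)
      if (g$strand[gi] == "+") {
        start <- g$cds_start[gi] + tpos_ref - 1L
      } else {
        start <- g$cds_end[gi] - tpos_ref + 1L - (read_length - 1L)
      }
      end <- start + read_length - 1L
      # sequencing errors: Poisson-binomial via per-position Bernoulli draws
      n_errors <- integer(n)
      for (j in seq_len(read_length))
        if (p_err[j] > 0) n_errors <- n_errors + rbinom(n, 1L, p_err[j])
      # covered variant sites (within the CDS portion of the read)
      n_var <- integer(n); n_alt_snp <- integer(n); n_alt_indel <- integer(n)
      if (length(idx_v)) {
        vp <- v$pos[idx_v]
        cds_lo <- pmax(start, g$cds_start[gi]); cds_hi <- pmin(end, g$cds_end[gi])
        for (m in seq_along(idx_v)) {
          covered <- vp[m] >= cds_lo & vp[m] <= cds_hi
          n_var <- n_var + covered
          if (carries_alt[m]) {
            if (v$type[idx_v[m]] == "SNP") n_alt_snp <- n_alt_snp + covered
            else n_alt_indel <- n_alt_indel + covered
          }
        }
      }
      out[[k]] <- data.frame(
        chrom = g$chrom[gi], start = start, end = end,
        strand = g$strand[gi], gene_id = gene, n_var = n_var,
        n_alt_snp = n_alt_snp, n_alt_indel = n_alt_indel,
        n_errors = n_errors, has_error = n_errors > 0L,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Analytic mapping-bias filter for simulated reads
#'
#' Models the mismatch budget of an ungapped aligner. In `strain_specific`
#' mode (reads aligned to the strain's own genome) a read is dropped only
#' when its sequencing errors exceed `tolerance`. In `reference` mode every
#' covered alt-allele SNP base also counts as a mismatch, and a read covering
#' an alt-allele indel cannot be placed at all (indels break ungapped
#' alignment), so reference mode always retains a subset of the
#' strain-specific read set.
#'
#' @param reads data.frame from [simulate_reads()].
#' @param tolerance Maximum tolerated mismatches (>= 0).
#' @param mode `"strain_specific"` or `"reference"`.
#' @return The retained subset of `reads`.
#' @export
reference_mapping_filter <- function(reads, tolerance = 3L,
                                     mode = c("strain_specific", "reference")) {
  mode <- match.arg(mode)
  stopifnot(tolerance >= 0)
  keep <- if (mode == "strain_specific") {
    reads$n_errors <= tolerance
  } else {
    reads$n_alt_indel == 0L & (reads$n_errors + reads$n_alt_snp) <= tolerance
  }
  reads[keep, , drop = FALSE]
}

#' Simulate per-site genotype calls with expression-tied missingness
#'
#' A variant site can only be observed through reads of its host gene, so a
#' site is called in a strain with probability `1 - exp(-count / theta)`
#' where `count` is the host gene's sense read count in that strain
#' (`theta = 0` forces full coverage of intragenic sites). Intergenic sites
#' are never called. Called alleles flip with probability `call_error`; each
#' call carries a Gaussian-ish quality score.
#'
#' @param genotypes A `true_genotypes`.
#' @param genome The `genome_model` (for variant-to-gene assignment).
#' @param sense_counts Genes x samples sense count matrix.
#' @param theta Coverage scale of the observability curve (reads).
#' @param call_error Per-call allele flip probability.
#' @param quality_mean,quality_sd Quality score distribution (truncated >= 0).
#' @param seed Integer seed.
#' @return A `genotype_calls` object: list with `call` (character matrix
#'   strains x sites: "ref", "alt" or NA), `quality` (numeric matrix), and
#'   `sites` (chrom, pos, p1_allele, host_gene).
#' @export
simulate_genotype_calls <- function(genotypes, genome, sense_counts,
                                    theta = 60, call_error = 0.002,
                                    quality_mean = 60, quality_sd = 15,
                                    seed = 1L) {
  truth <- genotypes$alleles
  strains <- rownames(truth)
  v <- genome$variants
  host <- variant_host_gene(genome)
  n_s <- length(strains); n_v <- nrow(v)
  with_seed(substream_seed(seed, "calls"), {
    call <- matrix(NA_character_, n_s, n_v,
                   dimnames = dimnames(truth))
    qual <- matrix(NA_real_, n_s, n_v, dimnames = dimnames(truth))
    for (j in seq_len(n_v)) {
      if (is.na(host[j])) next
      counts <- sense_counts[host[j], strains]
      p <- if (theta == 0) rep(1, n_s) else 1 - exp(-counts / theta)
      obs <- runif(n_s) < p
      if (!any(obs)) next
      allele <- truth[obs, j]
      flip <- runif(sum(obs)) < call_error
      allele[flip] <- 1L - allele[flip]
      # P1 carries ref in the simulator, so allele 0 -> "ref", 1 -> "alt"
      call[obs, j] <- ifelse(allele == 1L, "alt", "ref")
      qual[obs, j] <- pmax(0, rnorm(sum(obs), quality_mean, quality_sd))
    }
    structure(list(call = call, quality = qual,
                   sites = data.frame(chrom = v$chrom, pos = v$pos,
                                      p1_allele = "ref", host_gene = host,
                                      stringsAsFactors = FALSE)),
              class = "genotype_calls")
  })
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat("genotype_calls:", nrow(x$call), "strains x", ncol(x$call), "sites;",
      sprintf("%.1f%%", 100 * mean(!is.na(x$call))), "called\n")
  invisible(x)
}
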