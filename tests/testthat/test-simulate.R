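test_that("make_genome honours config counts, inversion and seed", {
  gm <- tiny_genome(seed = 1)
  expect_s3_class(gm, "genome_model")
  expect_equal(nrow(gm$genes), 40)
  expect_equal(nrow(gm$variants), 60)
  expect_equal(gm$inversion$chrom, "chrA")
  # variants sorted, unique within chromosome
  for (cn in unique(gm$variants$chrom))
    expect_true(all(diff(gm$variants$pos[gm$variants$chrom == cn]) > 0))
  # same config, different seeds: same counts, different positions
  gm2 <- tiny_genome(seed = 2)
  expect_equal(nrow(gm2$variants), nrow(gm$variants))
  expect_false(identical(gm$variants$pos, gm2$variants$pos))
  # determinism
  expect_identical(tiny_genome(seed = 1), gm)
  # indel deltas respect type
  v <- gm$variants
  expect_true(all(v$delta[v$type == "SNP"] == 0))
  expect_true(all(v$delta[v$type == "deletion"] < 0))
  expect_true(all(v$delta[v$type == "insertion"] > 0))
})

test_that("make_genome errors when variants cannot be placed", {
  expect_error(make_genome(sim_config(chrom_lengths = c(c1 = 2000),
                                      n_genes = 1, n_variants = 5000,
                                      inversion = NULL,
                                      n_convergent_overlap = 0), 1))
})

test_that("crossover rate zero gives monomorphic chromosomes", {
  gm <- tiny_genome()
  cr <- simulate_cross(gm, 10, crossover_rate_per_mb = 0, seed = 3)
  expect_equal(nrow(cr$breakpoints), 0)
  for (cn in unique(gm$variants$chrom)) {
    cols <- which(gm$variants$chrom == cn)
    per_strain <- apply(cr$alleles[, cols, drop = FALSE], 1,
                        function(x) length(unique(x)))
    expect_true(all(per_strain == 1))
  }
})

test_that("full inversion suppression keeps breakpoints out of the inversion", {
  gm <- tiny_genome()
  for (seed in 1:5) {
    cr <- simulate_cross(gm, 20, crossover_rate_per_mb = 8,
                         inversion_suppression = 0, seed = seed)
    bp <- cr$breakpoints
    inside <- bp$chrom == gm$inversion$chrom &
      bp$pos >= gm$inversion$start & bp$pos <= gm$inversion$end
    expect_equal(sum(inside), 0)
  }
})

test_that("breakpoint density tracks the inversion suppression factor", {
  gm <- make_genome(sim_config(chrom_lengths = c(chrA = 1e6),
                               n_genes = 50, n_variants = 300,
                               n_convergent_overlap = 0,
                               inversion = list(chrom = "chrA",
                                                start = 2e5, end = 6e5)),
                    seed = 1)
  supp <- 0.3
  n_in <- 0; n_out <- 0
  for (seed in 1:50) {
    cr <- simulate_cross(gm, 10, generation = "F1",
                         crossover_rate_per_mb = 6,
                         inversion_suppression = supp, seed = seed)
    bp <- cr$breakpoints
    inside <- bp$pos >= 2e5 & bp$pos <= 6e5
    n_in <- n_in + sum(inside); n_out <- n_out + sum(!inside)
  }
  # inversion covers 0.4 Mb of 1 Mb: density ratio estimates suppression
  ratio <- (n_in / 0.4) / (n_out / 0.6)
  expect_gt(ratio, supp * 0.6)
  expect_lt(ratio, supp * 1.5)
})

test_that("F2 segregants accumulate more breakpoints than F1", {
  gm <- tiny_genome()
  b1 <- b2 <- 0
  for (seed in 1:10) {
    b1 <- b1 + nrow(simulate_cross(gm, 10, "F1", 6, seed = seed)$breakpoints)
    b2 <- b2 + nrow(simulate_cross(gm, 10, "F2", 6, seed = seed)$breakpoints)
  }
  expect_gt(b2, b1)
})

test_that("genome-wide breakpoint count matches the tuned expectation", {
  # desk defaults are tuned to the study-scale ~17 breakpoints per strain
  cfg <- sim_config()
  gm <- make_genome(cfg, seed = 5)
  m <- mean(vapply(1:20, function(s)
    mean(breakpoints_per_strain(
      simulate_cross(gm, 44, "F2", cfg$crossover_rate_per_mb,
                     cfg$inversion_suppression, seed = s))), numeric(1)))
  expect_gt(m, 15.4); expect_lt(m, 19.4)
})

test_that("reads_per_gene follows the natural-scale-times-ten rule", {
  expect_equal(reads_per_gene(0), 10L)
  expect_equal(reads_per_gene(-10), 1L)
  expect_equal(reads_per_gene(3.1), 86L)
  grid <- seq(-12, 12, by = 0.37)
  nr <- reads_per_gene(grid)
  expect_true(all(nr >= 1))
  expect_true(all(diff(nr) >= 0))
  expect_error(reads_per_gene(NaN))
})

test_that("simulated expression with no effects varies only by library size", {
  gm <- tiny_genome()
  cr <- tiny_cross(gm, n = 8)
  eff <- effect_config(dispersion = 0)
  cfg <- tiny_config(batch_sd = 0, n_batches = 1)
  ex <- simulate_expression(gm, cr, eff, cfg, seed = 2)
  ratio <- sweep(ex$sense, 2, ex$lib_factors, `/`)
  expect_true(all(abs(ratio - ratio[, 1]) < 1e-9))
})

test_that("a planted cis effect shifts allele-group means by its size", {
  gm <- tiny_genome()
  cr <- tiny_cross(gm, n = 30)
  host <- gm$genes$gene_id[1]
  # pick a gene hosting a variant so the cis site is its own
  eff <- default_effect_config(gm, n_cis = 1, n_trans = 0, cis_effect = 2,
                               dispersion = 0.05, seed = 4)
  ex <- simulate_expression(gm, cr, eff, tiny_config(batch_sd = 0), seed = 4)
  tr <- ex$truth
  g <- tr$gene_id[1]; site <- tr$site[1]
  a <- cr$alleles[, site]
  y <- log2(pmax(ex$sense[g, ] / ex$lib_factors, 0.1))
  diff_obs <- mean(y[a == 1]) - mean(y[a == 0])
  expect_equal(diff_obs, tr$effect_log2[1], tolerance = 0.5)
})

test_that("hotspot targets receive opposed sense/antisense effects", {
  gm <- make_genome(sim_config(n_genes = 200, n_variants = 200,
                               n_convergent_overlap = 0), seed = 2)
  cr <- simulate_cross(gm, 40, seed = 2)
  eff <- default_effect_config(gm, n_cis = 0, n_trans = 0,
                               hotspot_n_sense = 50, hotspot_n_anti = 80,
                               dispersion = 0.05, seed = 2)
  ex <- simulate_expression(gm, cr, eff, sim_config(batch_sd = 0), seed = 2)
  a <- cr$alleles[, eff$hotspot$site]
  ok_sense <- vapply(eff$hotspot$sense_targets, function(g) {
    y <- log2(pmax(ex$sense[g, ] / ex$lib_factors, 0.1))
    mean(y[a == 1]) < mean(y[a == 0])
  }, logical(1))
  ok_anti <- vapply(eff$hotspot$antisense_targets, function(g) {
    y <- log2(pmax(ex$antisense[g, ] / ex$lib_factors, 0.1))
    mean(y[a == 1]) > mean(y[a == 0])
  }, logical(1))
  expect_gte(mean(c(ok_sense, ok_anti)), 0.95)
})

test_that("read simulation places, errors and conserves reads as specified", {
  gm <- tiny_genome()
  alleles <- setNames(rep(0L, nrow(gm$variants)),
                      paste0(gm$variants$chrom, ":", gm$variants$pos))
  # exactly one read for one gene, inside its transcript
  nr1 <- setNames(1L, gm$genes$gene_id[1])
  r1 <- simulate_reads(gm, alleles, nr1, error_model(0), seed = 1)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$gene_id, gm$genes$gene_id[1])
  expect_equal(r1$end - r1$start + 1, 48)
  expect_false(r1$has_error)
  # conservation + zero error model
  nr <- setNames(rep(5L, 10), gm$genes$gene_id[1:10])
  rr <- simulate_reads(gm, alleles, nr, error_model(0), seed = 2)
  expect_equal(nrow(rr), sum(nr))
  expect_true(all(!rr$has_error))
  expect_equal(as.vector(table(factor(rr$gene_id, names(nr)))),
               rep(5L, 10))
})

test_that("per-read error fraction matches the binomial closed form", {
  gm <- make_genome(sim_config(chrom_lengths = c(c1 = 1e5), n_genes = 2,
                               n_variants = 4, inversion = NULL,
                               n_convergent_overlap = 0,
                               mean_cds_len = 4000), seed = 1)
  alleles <- setNames(rep(0L, 4), paste0(gm$variants$chrom, ":",
                                         gm$variants$pos))
  nr <- setNames(10000L, gm$genes$gene_id[1])
  rr <- simulate_reads(gm, alleles, nr, error_model(0.01), seed = 3)
  expected <- 1 - 0.99^48
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_equal(mean(rr$has_error), expected, tolerance = 5 * se / expected)
})

test_that("mapping-bias filter drops only what the mismatch budget implies", {
  reads <- data.frame(chrom = "c1", start = 1, end = 48, strand = "+",
                      gene_id = "g", n_var = c(0, 4, 1, 0),
                      n_alt_snp = c(0, 4, 1, 0),
                      n_alt_indel = c(0, 0, 0, 1),
                      n_errors = c(0, 0, 3, 0),
                      has_error = c(FALSE, FALSE, TRUE, FALSE))
  ss <- reference_mapping_filter(reads, 3, "strain_specific")
  rf <- reference_mapping_filter(reads, 3, "reference")
  expect_equal(nrow(ss), 4)           # no read exceeds 3 errors
  expect_equal(nrow(rf), 1)           # 4 alt SNPs > 3; 3 err + 1 alt > 3; indel
  # reference-allele-only strain: identical retention
  ref_only <- reads[reads$n_alt_snp == 0 & reads$n_alt_indel == 0, ]
  expect_identical(reference_mapping_filter(ref_only, 3, "strain_specific"),
                   reference_mapping_filter(ref_only, 3, "reference"))
})

test_that("strain-specific retention is a superset of reference retention", {
  gm <- tiny_genome()
  cr <- tiny_cross(gm, n = 4)
  for (s in 1:4) {
    nr <- setNames(rep(20L, nrow(gm$genes)), gm$genes$gene_id)
    rr <- simulate_reads(gm, cr$alleles[s, ], nr, error_model(0.02),
                         seed = s)
    ss <- reference_mapping_filter(rr, 3, "strain_specific")
    rf <- reference_mapping_filter(rr, 3, "reference")
    expect_lte(nrow(rf), nrow(ss))
    key <- function(d) paste(d$chrom, d$start, d$gene_id, d$n_errors)
    expect_true(all(key(rf) %in% key(ss)))
  }
})

test_that("genotype calls mirror truth under full coverage and zero error", {
  gm <- tiny_genome()
  cr <- tiny_cross(gm, n = 10)
  counts <- matrix(50, nrow(gm$genes), 10,
                   dimnames = list(gm$genes$gene_id,
                                   rownames(cr$alleles)))
  calls <- simulate_genotype_calls(cr, gm, counts, theta = 0,
                                   call_error = 0, seed = 1)
  host <- calls$sites$host_gene
  intra <- which(!is.na(host))
  expect_true(all(!is.na(calls$call[, intra])))
  expect_true(all(is.na(calls$call[, -intra])))
  truth_lab <- ifelse(cr$alleles[, intra] == 1L, "alt", "ref")
  expect_equal(calls$call[, intra], truth_lab)
})

test_that("silencing a gene blanks calls at its sites", {
  gm <- tiny_genome()
  cr <- tiny_cross(gm, n = 6)
  counts <- matrix(80, nrow(gm$genes), 6,
                   dimnames = list(gm$genes$gene_id, rownames(cr$alleles)))
  host <- variant_host <- simulate_genotype_calls(cr, gm, counts, theta = 20,
                                                  seed = 1)$sites$host_gene
  silenced <- host[!is.na(host)][1]
  counts[silenced, ] <- 0
  calls <- simulate_genotype_calls(cr, gm, counts, theta = 20, seed = 1)
  expect_true(all(is.na(calls$call[, which(host == silenced)])))
})

test_that("call error rate reproduces the observed discordance", {
  gm <- make_genome(sim_config(chrom_lengths = c(c1 = 5e5), n_genes = 60,
                               n_variants = 300, inversion = NULL,
                               frac_variants_in_cds = 1,
                               n_convergent_overlap = 0), seed = 1)
  cr <- simulate_cross(gm, 40, seed = 1)
  counts <- matrix(200, nrow(gm$genes), 40,
                   dimnames = list(gm$genes$gene_id, rownames(cr$alleles)))
  calls <- simulate_genotype_calls(cr, gm, counts, theta = 0,
                                   call_error = 0.01, seed = 2)
  called <- !is.na(calls$call)
  obs <- ifelse(calls$call == "alt", 1L, 0L)
  disc <- mean(obs[called] != cr$alleles[called])
  expect_equal(disc, 0.01, tolerance = 0.4)
})

test_that("total simulated reads equal the per-gene budget", {
  gm <- tiny_genome()
  alleles <- rep(0L, nrow(gm$variants))
  nr <- reads_per_gene(rnorm(5, 2, 1))
  names(nr) <- gm$genes$gene_id[1:5]
  rr <- simulate_reads(gm, alleles, nr, seed = 9)
  expect_equal(nrow(rr), sum(nr))
})
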