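toy_genome <- function() {
  structure(list(
    chromosomes = data.frame(name = c("c1", "c2"),
                             length = c(6.2e5, 4.1e5)),
    genes = NULL, variants = NULL, inversion = NULL),
    class = "genome_model")
}

test_that("genome bins are 50 kb with bigger end bins", {
  b <- genome_bins(toy_genome())
  expect_equal(nrow(b), 12 + 8)
  last_c1 <- b[b$chrom == "c1", ][12, ]
  expect_equal(last_c1$end - last_c1$start + 1, 70000)  # absorbs remainder
  expect_true(all(b$end[b$chrom == "c1"][-12] - b$start[b$chrom ==
                                                          "c1"][-12] + 1
                  == 50000))
})

test_that("hotspot Poisson tails match brute-force summation to 1e-12", {
  brute_tail <- function(k, lambda)
    sum(exp(-lambda) * lambda^(k:(k + 400)) / factorial(k:(k + 400)))
  for (lambda in c(0.4, 1, 2.7)) for (k in c(1, 3, 10)) {
    expect_lt(abs(ppois(k - 1, lambda, lower.tail = FALSE) -
                    brute_tail(k, lambda)), 1e-12)
  }
  # the quoted closed-form cases
  expect_equal(ppois(0, 1, lower.tail = FALSE), 1 - exp(-1),
               tolerance = 1e-12)          # ~0.632, not significant
  expect_lt(ppois(9, 1, lower.tail = FALSE), 8e-4)  # 10 in a lambda=1 bin
  expect_equal(ppois(9, 1, lower.tail = FALSE), 1.1142e-7,
               tolerance = 1e-3)
})

test_that("hotspot detection flags enriched bins and merges on shared targets", {
  gm <- toy_genome()
  # 250-ish eQTLs spread thin + one loaded bin
  set.seed(1)
  qtl <- data.frame(
    chrom = sample(c("c1", "c2"), 60, TRUE, prob = c(0.6, 0.4)),
    pos = NA, trait = paste0("t", 1:60), stringsAsFactors = FALSE)
  qtl$pos <- ifelse(qtl$chrom == "c1", sample.int(6.2e5, 60, TRUE),
                    sample.int(4.1e5, 60, TRUE))
  hot <- data.frame(chrom = "c1", pos = 120000 + seq_len(25) * 100,
                    trait = paste0("h", 1:25), stringsAsFactors = FALSE)
  hs <- detect_hotspots(rbind(qtl, hot), gm)
  expect_gte(nrow(hs), 1)
  top <- hs[which.max(hs$n_qtl), ]
  expect_equal(top$chrom, "c1")
  expect_true(top$start <= 120100 && top$end >= 122500)
  expect_true(all(paste0("h", 1:25) %in% top$targets[[1]]))
  # empty input
  expect_equal(nrow(detect_hotspots(qtl[0, ], gm)), 0)
})

test_that("adjacent significant bins with disjoint targets stay separate", {
  gm <- toy_genome()
  a <- data.frame(chrom = "c1", pos = 110000 + seq_len(20),
                  trait = paste0("a", 1:20), stringsAsFactors = FALSE)
  b <- data.frame(chrom = "c1", pos = 160000 + seq_len(20),
                  trait = paste0("b", 1:20), stringsAsFactors = FALSE)
  filler <- data.frame(chrom = "c2", pos = seq(1e4, 4e5, length.out = 30),
                       trait = paste0("f", 1:30), stringsAsFactors = FALSE)
  hs <- detect_hotspots(rbind(a, b, filler), gm)
  expect_equal(sum(hs$chrom == "c1"), 2)
  shared <- rbind(a, b)
  shared$trait <- rep(paste0("s", 1:20), 2)   # same targets in both bins
  hs2 <- detect_hotspots(rbind(shared, filler), gm)
  expect_equal(sum(hs2$chrom == "c1"), 1)
  expect_equal(hs2$n_bins[hs2$chrom == "c1"], 2)
})

test_that("cis/trans classification obeys the LD rule and its invariances", {
  set.seed(2)
  n <- 40
  info <- data.frame(chrom = rep(c("c1", "c2"), each = 10),
                     start = rep(seq(2e4, 2e5, by = 2e4), 2),
                     end = rep(seq(2e4, 2e5, by = 2e4), 2) + 500)
  geno <- matrix(rbinom(n * 20, 1, 0.5), n, 20)
  # QTL peak marker IS a flanking marker of the gene -> r = 1 -> cis
  expect_equal(classify_cis_trans(3, "c1", 65000, 70000, info, geno), "cis")
  # QTL on the other chromosome with independent segregation -> trans
  expect_equal(classify_cis_trans(15, "c1", 65000, 70000, info, geno),
               "trans")
  # gene on a chromosome without markers -> trans
  expect_equal(classify_cis_trans(3, "c9", 1000, 2000, info, geno), "trans")
  # invariance to allele relabeling and to marker column reordering
  flip <- geno; flip[, 3] <- 1L - flip[, 3]
  expect_equal(classify_cis_trans(3, "c1", 65000, 70000, info, flip), "cis")
})

test_that("directionality is the sign of the P2-P1 group difference", {
  g <- c(0L, 0L, 1L, 1L, NA)
  expect_equal(directionality(c(3, 3, 5, 5, 99), g), 1)
  expect_equal(directionality(c(5, 5, 3, 3, 99), g), -1)
  expect_equal(directionality(c(4, 4, 4, 4, 99), g), 0)
  expect_true(is.na(directionality(c(1, 2, 3, 4, 5), rep(0L, 5))))
  # planted negative trans effect recovers a negative sign almost always
  gm <- tiny_genome()
  cr <- tiny_cross(gm, n = 30)
  ok <- vapply(1:20, function(seed) {
    eff <- default_effect_config(gm, n_cis = 0, n_trans = 1,
                                 trans_effect = -1.5, seed = seed)
    ex <- simulate_expression(gm, cr, eff, tiny_config(batch_sd = 0),
                              seed = seed)
    tr <- ex$truth
    y <- log2(pmax(ex$sense[tr$gene_id[1], ] / ex$lib_factors, 0.1))
    directionality(y, cr$alleles[, tr$site[1]]) == -1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("candidate regulator maximises squared correlation with tie-breaks", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "c1",
                    cds_start = c(1e4, 3e4, 5e4),
                    cds_end = c(1.5e4, 3.5e4, 5.5e4),
                    stringsAsFactors = FALSE)
  set.seed(4)
  reg <- rnorm(50)
  expr <- rbind(gA = reg + rnorm(50, 0, 0.5),
                gB = rnorm(50), gC = rnorm(50))
  regions <- data.frame(chrom = "c1", start_pos = 5000, end_pos = 6e4)
  got <- candidate_regulator(reg, regions, ann, expr)
  expect_equal(got$gene_id, "gA")
  expect_gt(got$r2, 0.5)
  # single-gene QTL returns that gene
  one <- data.frame(chrom = "c1", start_pos = 2.8e4, end_pos = 3.6e4)
  expect_equal(candidate_regulator(reg, one, ann, expr)$gene_id, "gB")
  # no expressed gene inside -> NA
  none <- data.frame(chrom = "c1", start_pos = 8e4, end_pos = 9e4)
  expect_true(is.na(candidate_regulator(reg, none, ann, expr)$gene_id))
  # the target itself is excluded from its own QTL
  expect_equal(candidate_regulator(expr["gA", ], regions, ann, expr,
                                   target_gene = "gA")$gene_id, "gB")
})

test_that("planted regulators win the recovery and hotspot vote", {
  expect_equal(hotspot_regulator_vote(c("A", "A", "B"),
                                      data.frame(gene_id = c("A", "B"),
                                                 chrom = "c1",
                                                 cds_start = c(1, 2))), "A")
  ann <- data.frame(gene_id = c("B", "A"), chrom = "c1",
                    cds_start = c(100, 500), stringsAsFactors = FALSE)
  expect_equal(hotspot_regulator_vote(c("A", "B"), ann), "B")  # tie: smaller
  set.seed(6)
  wins <- vapply(1:30, function(i) {
    reg <- rnorm(40)
    expr <- rbind(gR = reg + rnorm(40, 0, sqrt(0.5) / sqrt(2)),
                  gX = rnorm(40), gY = rnorm(40))
    ann2 <- data.frame(gene_id = c("gR", "gX", "gY"), chrom = "c1",
                       cds_start = c(1e4, 2e4, 3e4),
                       cds_end = c(1.4e4, 2.4e4, 3.4e4),
                       stringsAsFactors = FALSE)
    regions <- data.frame(chrom = "c1", start_pos = 5e3, end_pos = 4e4)
    target <- reg + rnorm(40, 0, 0.5)   # regulator drives the target, SNR 2
    candidate_regulator(target, regions, ann2, expr)$gene_id == "gR"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("gene pairs fall into exactly six orientation/overlap categories", {
  ann <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"), chrom = "c1",
    strand = c("+", "-", "+", "+", "-"),
    tss = c(90, 330, 420, 590, 850),
    cds_start = c(100, 210, 430, 600, 710),
    cds_end = c(220, 320, 530, 700, 800),
    coding = TRUE, stringsAsFactors = FALSE)
  pr <- classify_gene_pairs(ann)
  expect_equal(nrow(pr), 4)
  expect_equal(pr$category[1], "convergent_overlapping")   # g1+ g2- overlap
  expect_equal(pr$category[2], "divergent_nonoverlapping") # g2- g3+
  expect_equal(pr$category[3], "tandem_nonoverlapping")    # g3+ g4+
  # g4 (+) CDS 600-700, g5 (-) CDS 710-800: convergent, no CDS overlap
  expect_equal(pr$category[4], "convergent_nonoverlapping")
  # a chromosome with a single gene yields no pairs
  single <- ann[1, ]; single$chrom <- "c9"
  expect_equal(nrow(classify_gene_pairs(single)), 0)
})

test_that("pair classification matches a brute-force oracle on random annotations", {
  set.seed(9)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    starts <- sort(sample.int(5000, n)) * 10
    len <- sample(200:800, n, replace = TRUE)
    ann <- data.frame(gene_id = paste0("g", 1:n), chrom = "cX",
                      strand = sample(c("+", "-"), n, TRUE),
                      tss = starts - 5, cds_start = starts,
                      cds_end = starts + len, coding = TRUE,
                      stringsAsFactors = FALSE)
    ann$tss <- ifelse(ann$strand == "+", ann$cds_start - 5,
                      ann$cds_end + 5)
    pr <- classify_gene_pairs(ann)
    ord <- ann[order(ann$tss), ]
    for (i in seq_len(nrow(ord) - 1)) {
      s <- paste0(ord$strand[i], ord$strand[i + 1])
      want_ori <- switch(s, "+-" = "convergent", "-+" = "divergent",
                         "tandem")
      want_ovl <- ord$cds_start[i + 1] <= ord$cds_end[i] &&
        ord$cds_end[i + 1] >= ord$cds_start[i]
      row <- pr[pr$gene_a == ord$gene_id[i] &
                  pr$gene_b == ord$gene_id[i + 1], ]
      expect_equal(row$orientation, want_ori)
      expect_equal(row$overlapping, want_ovl)
    }
    expect_equal(nrow(pr), nrow(ord) - 1)
  }
})

test_that("pair enrichment p-values behave at the boundaries", {
  # 10 disjoint pairs: two genes per chromosome
  ann <- data.frame(
    gene_id = paste0("g", 1:20), chrom = rep(paste0("c", 1:10), each = 2),
    strand = rep(c("+", "-"), 10),
    tss = rep(c(95, 510), 10),
    cds_start = rep(c(100, 320), 10),
    cds_end = rep(c(300, 500), 10),
    coding = TRUE, stringsAsFactors = FALSE)
  # make 4 chromosomes convergent-overlapping, 6 convergent-nonoverlapping
  ann$cds_end[ann$chrom %in% paste0("c", 1:4) & ann$strand == "+"] <- 340
  pairs <- classify_gene_pairs(ann)
  expect_equal(sort(unique(pairs$category)),
               c("convergent_nonoverlapping", "convergent_overlapping"))
  universe <- ann$gene_id
  # targets = whole universe: observed equals every permutation, p = 1
  res_all <- pair_enrichment(universe, pairs, universe, n_perm = 200,
                             seed = 1)
  expect_true(all(res_all$p_enrich[res_all$observed > 0] == 1))
  # targets exclusively in overlapping pairs: maximal statistic
  ovl_genes <- unique(c(pairs$gene_a[pairs$overlapping],
                        pairs$gene_b[pairs$overlapping]))
  res_ovl <- pair_enrichment(ovl_genes, pairs, universe, n_perm = 400,
                             seed = 2)
  row <- res_ovl[res_ovl$category == "convergent_overlapping", ]
  expect_lte(row$p_enrich, 2 / 401)
  expect_error(pair_enrichment(character(0), pairs, universe), "empty")
})

test_that("pair enrichment agrees with the exact hypergeometric tail", {
  # disjoint pairs: each gene sits in exactly one pair, so the per-category
  # count of a random target set is hypergeometric in the gene colours
  ann <- data.frame(
    gene_id = paste0("g", 1:20), chrom = rep(paste0("c", 1:10), each = 2),
    strand = rep(c("+", "-"), 10),
    tss = rep(c(95, 510), 10),
    cds_start = rep(c(100, 320), 10),
    cds_end = rep(c(300, 500), 10),
    coding = TRUE, stringsAsFactors = FALSE)
  ann$cds_end[ann$chrom %in% paste0("c", 1:4) & ann$strand == "+"] <- 340
  pairs <- classify_gene_pairs(ann)
  universe <- ann$gene_id
  set.seed(3)
  targets <- sample(universe, 8)
  n_perm <- 4000
  res <- pair_enrichment(targets, pairs, universe, n_perm = n_perm,
                         seed = 4)
  row <- res[res$category == "convergent_overlapping", ]
  # 8 genes (one colour) of 20; draw 8; observed count of that colour
  exact <- phyper(row$observed - 1, 8, 12, 8, lower.tail = FALSE)
  se <- sqrt(exact * (1 - exact) / n_perm)
  expect_lt(abs(row$p_enrich - exact), 2 * se + 1 / n_perm)
})

test_that("pair enrichment p-values are uniform under random target sets", {
  ann <- data.frame(
    gene_id = paste0("g", 1:20), chrom = rep(paste0("c", 1:10), each = 2),
    strand = rep(c("+", "-"), 10),
    tss = rep(c(95, 510), 10),
    cds_start = rep(c(100, 320), 10),
    cds_end = rep(c(300, 500), 10),
    coding = TRUE, stringsAsFactors = FALSE)
  ann$cds_end[ann$chrom %in% paste0("c", 1:4) & ann$strand == "+"] <- 340
  pairs <- classify_gene_pairs(ann)
  universe <- ann$gene_id
  set.seed(5)
  ps <- vapply(1:400, function(i) {
    tg <- sample(universe, 8)
    res <- pair_enrichment(tg, pairs, universe, n_perm = 300,
                           seed = 100 + i)
    res$p_enrich[res$category == "convergent_overlapping"]
  }, numeric(1))
  # permutation p-values are discrete, so exact uniformity is tested as
  # validity (super-uniformity) at several levels plus non-degeneracy
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(mean(ps <= alpha), alpha + 3 * se + 1 / 300)
  }
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.75)
})
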