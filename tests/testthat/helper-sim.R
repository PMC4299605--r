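# Shared fixtures, built in code. Small enough to keep every test fast.

tiny_config <- function(...) {
  sim_config(chrom_lengths = c(chrA = 3e5, chrB = 2e5),
             n_genes = 40, n_variants = 60, n_convergent_overlap = 2,
             inversion = list(chrom = "chrA", start = 5e4, end = 1.2e5),
             ...)
}

tiny_genome <- function(seed = 1, ...) make_genome(tiny_config(...), seed)

tiny_cross <- function(genome = tiny_genome(), n = 12, seed = 1, ...) {
  simulate_cross(genome, n, seed = seed, ...)
}

# hand-built inheritance matrix: one chromosome, explicit positions
manual_inheritance <- function(mat, pos, chrom = "chr1") {
  structure(list(inh = mat,
                 sites = data.frame(chrom = chrom, pos = pos,
                                    stringsAsFactors = FALSE)),
            class = "inheritance_matrix")
}

# hand-built call matrix over explicit sites
manual_calls <- function(call, quality, chrom, pos, p1_allele = "ref") {
  structure(list(call = call, quality = quality,
                 sites = data.frame(chrom = chrom, pos = pos,
                                    p1_allele = rep_len(p1_allele,
                                                        length(pos)),
                                    stringsAsFactors = FALSE)),
            class = "genotype_calls")
}

# brute-force interval scan: which CDS contains this midpoint, per strand
oracle_quantify <- function(reads, annotation) {
  sense <- matrix(0L, nrow(annotation), 1,
                  dimnames = list(annotation$gene_id, "sample1"))
  anti <- sense
  for (r in seq_len(nrow(reads))) {
    mid <- floor((reads$start[r] + reads$end[r]) / 2)
    for (g in seq_len(nrow(annotation))) {
      if (annotation$chrom[g] == reads$chrom[r] &&
          mid >= annotation$cds_start[g] && mid <= annotation$cds_end[g]) {
        if (annotation$strand[g] == reads$strand[r])
          sense[g, 1] <- sense[g, 1] + 1L
        else anti[g, 1] <- anti[g, 1] + 1L
      }
    }
  }
  list(sense = sense, antisense = anti)
}
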