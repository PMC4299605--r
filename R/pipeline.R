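# One reproducible run: simulate -> genotype -> normalize -> map ->
# downstream, driven by a single config and master seed, with a manifest of
# every output.

#' Build a pipeline configuration
#'
#' A nested list with per-stage sections; any field can be overridden. The
#' configuration round-trips through YAML unchanged
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param stages Character vector of enabled stages, in order, from
#'   `c("simulate", "genotype", "normalize", "map", "hotspots")`.
#' @param sim [sim_config()] overrides (list).
#' @param effects Arguments for [default_effect_config()] (list).
#' @param map List: `settings_profile`, `fdr`, `fixed_k`, `max_traits`.
#' @param genotype List: `min_quality`, `maf_min`, `max_flank_distance`,
#'   `min_called_fraction`.
#' @param hotspots List: `bin_size`, `alpha`.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "genotype", "normalize",
                                       "map", "hotspots"),
                            sim = list(), effects = list(),
                            genotype = list(), map = list(),
                            hotspots = list(), seed = 1L) {
  structure(list(
    stages = stages,
    sim = utils::modifyList(sim_config(), sim),
    effects = utils::modifyList(
      list(n_cis = 5, n_trans = 10, cis_effect = 2, trans_effect = 1.5,
           hotspot_n_sense = 0, hotspot_n_anti = 0, dispersion = 0.05),
      effects),
    genotype = utils::modifyList(
      list(min_quality = 20, maf_min = 0.10, max_flank_distance = 50000,
           min_called_fraction = 0.5), genotype),
    map = utils::modifyList(
      list(settings_profile = "expression", fdr = 0.10, fixed_k = 8,
           max_traits = 20), map),
    hotspots = utils::modifyList(list(bin_size = 50000, alpha = 8e-4),
                                 hotspots),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return [read_pipeline_config()]: a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(raw), names(cfg))) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]]))
      utils::modifyList(cfg[[nm]], raw[[nm]]) else raw[[nm]]
  }
  # YAML maps come back as lists; chromosome lengths are a named vector
  cfg$sim$chrom_lengths <- unlist(cfg$sim$chrom_lengths)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  # a length-1 named vector would lose its name in YAML; store as a map
  out$sim$chrom_lengths <- as.list(out$sim$chrom_lengths)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order, writing every stage's outputs as
#' plain-text files under `outdir` plus a JSON manifest recording the
#' package version, master seed, per-stage parameters and the MD5 of every
#' output file. Identical config + seed produce byte-identical outputs.
#' A stage failure aborts with the failing stage named; outputs of earlier
#' stages are retained.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- list()
  outputs <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(outdir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
  }
  stage <- function(name, expr) {
    message("[segqtl] stage: ", name)
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  if ("simulate" %in% config$stages) {
    res$sim <- stage("simulate", {
      genome <- make_genome(config$sim, seed = seed)
      cross <- simulate_cross(genome, config$sim$n_segregants,
                              generation = config$sim$generation,
                              crossover_rate_per_mb =
                                config$sim$crossover_rate_per_mb,
                              inversion_suppression =
                                config$sim$inversion_suppression,
                              interference_bp = config$sim$interference_bp,
                              seed = seed)
      eff <- do.call(default_effect_config,
                     c(list(genome = genome, seed = seed), config$effects))
      expr <- simulate_expression(genome, cross, eff, config = config$sim,
                                  seed = seed)
      calls <- simulate_genotype_calls(cross, genome, expr$sense,
                                       theta = config$sim$call_theta,
                                       call_error = config$sim$call_error,
                                       quality_mean = config$sim$quality_mean,
                                       quality_sd = config$sim$quality_sd,
                                       seed = seed)
      emit(write_genome_gff3, genome, "annotation.gff3")
      emit(function(o, p) write_variants_vcf(
        o$variants, p, contigs = setNames(o$chromosomes$length,
                                          o$chromosomes$name)),
        genome, "variants.vcf")
      emit(function(o, p) write_matrix_tsv(
        matrix(c("P1", "P2")[o$alleles + 1L], nrow(o$alleles),
               dimnames = dimnames(o$alleles)), p, "strain"),
        cross, "true_genotypes.tsv")
      emit(function(o, p) write_matrix_tsv(o, p, "gene"), expr$sense,
           "sense_counts.tsv")
      emit(function(o, p) write_matrix_tsv(o, p, "gene"), expr$antisense,
           "antisense_counts.tsv")
      list(genome = genome, cross = cross, effects = eff, expr = expr,
           calls = calls)
    })
  }

  if ("genotype" %in% config$stages) {
    res$genotype <- stage("genotype", {
      gt <- genotype_pipeline(
        res$sim$calls,
        min_quality = config$genotype$min_quality,
        maf_min = config$genotype$maf_min,
        max_flank_distance = config$genotype$max_flank_distance,
        min_called_fraction = config$genotype$min_called_fraction)
      emit(write_inheritance_tsv, gt$inheritance, "inheritance.tsv")
      emit(function(o, p) write.table(o$markers, p, sep = "\t",
                                      quote = FALSE, row.names = FALSE),
           gt$markers, "markers.tsv")
      emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE),
           gt$breakpoints, "breakpoints.tsv")
      gt
    })
  }

  if ("normalize" %in% config$stages) {
    res$norm <- stage("normalize", {
      batches <- res$sim$expr$batches
      ns <- normalize_sense(res$sim$expr$sense, batches)
      na <- normalize_antisense(res$sim$expr$antisense, batches)
      emit(function(o, p) write_matrix_tsv(o, p, "gene"), ns$norm,
           "sense_normalized.tsv")
      emit(function(o, p) write_matrix_tsv(o, p, "gene"), na$norm,
           "antisense_normalized.tsv")
      list(sense = ns, antisense = na)
    })
  }

  if ("map" %in% config$stages) {
    res$map <- stage("map", {
      truth <- res$sim$expr$truth
      sense_traits <- intersect(unique(truth$gene_id[truth$strand ==
                                                       "sense"]),
                                rownames(res$norm$sense$norm))
      extra <- setdiff(rownames(res$norm$sense$norm), sense_traits)
      n_extra <- max(0, config$map$max_traits - length(sense_traits))
      traits <- res$norm$sense$norm[c(sense_traits,
                                      head(extra, n_extra)), ,
                                    drop = FALSE]
      mm <- res$genotype$markers
      settings <- rf_settings(config$map$settings_profile)
      lr <- map_qtls(traits, mm$geno, settings = settings,
                     fdr = config$map$fdr, fixed_k = config$map$fixed_k,
                     seed = seed)
      emit(write_linkage_tsv, lr, "linkage.tsv")
      # per-trait QTL groups + cis/trans + direction
      chrom_len <- setNames(res$sim$genome$chromosomes$length,
                            res$sim$genome$chromosomes$name)
      groups <- lapply(rownames(lr$scores), function(tr) {
        group_qtls(which(lr$linked[tr, ]), mm$markers, mm$geno,
                   chrom_lengths = chrom_len)
      })
      names(groups) <- rownames(lr$scores)
      ann <- res$sim$genome$genes
      rows <- list()
      for (tr in names(groups)) {
        grp <- groups[[tr]]
        if (is.null(grp)) next
        gi <- match(tr, ann$gene_id)
        ct <- classify_cis_trans(grp$linked_idx, ann$chrom[gi],
                                 ann$cds_start[gi], ann$cds_end[gi],
                                 mm$markers, mm$geno)
        peak <- grp$linked_idx[which.max(lr$scores[tr, grp$linked_idx])]
        dir <- directionality(traits[tr, ], mm$geno[, peak])
        for (ri in seq_len(nrow(grp$regions)))
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tr, chrom = grp$regions$chrom[ri],
            start = grp$regions$start_pos[ri],
            end = grp$regions$end_pos[ri],
            peak_marker = mm$markers$marker_id[peak],
            cis_trans = ct, direction = dir,
            multi_region = grp$multi_region, stringsAsFactors = FALSE)
      }
      qtl_table <- if (length(rows)) do.call(rbind, rows) else
        data.frame(trait = character(), chrom = character(),
                   start = numeric(), end = numeric(),
                   peak_marker = character(), cis_trans = character(),
                   direction = numeric(), multi_region = logical())
      emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE),
           qtl_table, "qtl_groups.tsv")
      list(linkage = lr, groups = groups, qtl_table = qtl_table,
           traits = traits)
    })
  }

  if ("hotspots" %in% config$stages) {
    res$hotspots <- stage("hotspots", {
      qt <- res$map$qtl_table
      mm <- res$genotype$markers
      peaks <- data.frame(
        chrom = qt$chrom, pos = (qt$start + qt$end) / 2, trait = qt$trait,
        stringsAsFactors = FALSE)
      pk <- match(qt$peak_marker, mm$markers$marker_id)
      ok <- !is.na(pk)
      peaks$chrom[ok] <- mm$markers$chrom[pk[ok]]
      peaks$pos[ok] <- (mm$markers$start[pk[ok]] +
                          mm$markers$end[pk[ok]]) / 2
      hs <- detect_hotspots(peaks, res$sim$genome,
                            bin_size = config$hotspots$bin_size,
                            alpha = config$hotspots$alpha)
      emit(function(o, p) {
        o$targets <- vapply(o$targets, paste, "", collapse = ",")
        write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE)
      }, hs, "hotspots.tsv")
      hs
    })
  }

  manifest <- list(
    package = "segqtl",
    version = as.character(utils::packageVersion("segqtl")),
    seed = seed,
    stages = config$stages,
    parameters = unclass(config),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = res, manifest = manifest))
}
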