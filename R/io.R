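#' File formats and the end-to-end pipeline driver
#'
#' Plain-CSV readers and writers for the pipeline's tables (every file
#' opens with a comment line naming units and conventions), a VCF reader
#' for genotype input, and \code{run_pipeline()}, which chains
#' simulate -> spatial correction -> growth curves -> MET -> haplotypes
#' and writes a machine-readable run manifest.
#'
#' @name io_cli
NULL

write_table_commented <- function(d, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.csv(d, con, row.names = FALSE)
}

read_table_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a genotype matrix as CSV
#'
#' The dosage file holds genotypes in rows (first column \code{genotype})
#' and markers in columns, dosages coded as minor-allele counts 0/1/2; the
#' map file holds marker, chromosome and 1-based bp position.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param dosage_path,map_path output paths.
#' @export
write_genotypes_csv <- function(genotypes, dosage_path, map_path) {
  d <- data.frame(genotype = rownames(genotypes$dosage),
                  genotypes$dosage, check.names = FALSE)
  write_table_commented(d, dosage_path,
                        "dosage = minor-allele count in {0,1,2}; NA = missing")
  write_table_commented(genotypes$map, map_path,
                        "marker map; pos = 1-based bp position")
  invisible(c(dosage_path, map_path))
}

#' @rdname write_genotypes_csv
#' @return a \code{genotype_matrix} with markers ordered by (chrom, pos).
#' @export
read_genotypes_csv <- function(dosage_path, map_path) {
  d <- read_table_commented(dosage_path)
  map <- read_table_commented(map_path)
  M <- as.matrix(d[, -1, drop = FALSE])
  rownames(M) <- d$genotype
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  M <- M[, map$marker, drop = FALSE]
  structure(list(dosage = M, map = map), class = "genotype_matrix")
}

#' Read genotypes from a VCF file
#'
#' Biallelic SNP records are converted to ALT-allele dosages (GT fields
#' \code{0/0}, \code{0/1}, \code{1/1} to 0, 1, 2; \code{./.} to missing)
#' and then recoded to minor-allele counts; multiallelic records are
#' skipped with a message.
#'
#' @param path VCF path.
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT)
  if (any(!biallelic))
    message(sum(!biallelic), " multiallelic records skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(x %in% c("0/0"), 0,
           ifelse(x %in% c("0/1", "1/0"), 1,
                  ifelse(x == "1/1", 2, NA_real_)))
  }
  M <- t(apply(gt, 2, code))
  dim(M) <- c(ncol(gt), nrow(gt))
  dimnames(M) <- list(colnames(gt), rownames(gt))
  # recode to minor allele
  p <- colMeans(M, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  M[, flip] <- 2 - M[, flip]
  map <- data.frame(marker = rownames(gt), chrom = fix$CHROM,
                    pos = as.numeric(fix$POS), stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  structure(list(dosage = M[, ord, drop = FALSE], map = map[ord, ]),
            class = "genotype_matrix")
}

#' Write LD blocks as a BED-like table
#'
#' Half-open, 0-based start coordinates (standard BED convention); the
#' center column stays 1-based bp as reported in block summaries.
#'
#' @param blocks block table from \code{\link{build_ld_blocks}}.
#' @param path output path.
#' @export
write_blocks_bed <- function(blocks, path) {
  d <- data.frame(chrom = blocks$chrom, start = blocks$start_pos - 1,
                  end = blocks$end_pos, block = blocks$block,
                  center = blocks$center_pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED-like: 0-based half-open start/end; center = 1-based bp", con)
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full stay-green analysis pipeline
#'
#' Executes simulate -> spatial correction -> growth curves -> MET ->
#' haplotype discovery over a synthetic study (or user-supplied tables),
#' writing each stage's outputs under \code{outdir} together with a JSON
#' manifest of parameters, seeds, completed stages and per-file MD5
#' checksums.
#'
#' @param config list: \code{sim} (a \code{\link{sim_config}} or arguments
#'   for one), \code{outdir}, \code{stages} (subset of
#'   \code{c("simulate", "spatial", "curves", "met", "haplo")}),
#'   \code{spatial_model}, \code{met_structures}, \code{r2_threshold},
#'   \code{tolerance}, \code{sig_threshold}, \code{window}.  May also be a
#'   path to a YAML file with these entries.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% "results/pipeline"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "spatial", "curves", "met", "haplo")
  cfg <- if (inherits(config$sim, "sim_config")) config$sim
  else do.call(sim_config, config$sim %||% list())
  manifest <- list(package = "staygreen",
                   version = as.character(utils::packageVersion("staygreen")),
                   seed = cfg$seed, stages = list(), files = list())
  t_all <- Sys.time()
  paths <- character(0)
  say <- function(...) message(sprintf(...))

  study <- NULL
  if ("simulate" %in% stages) {
    say("[simulate] generating synthetic study (seed %d)", cfg$seed)
    study <- simulate_study(cfg)
    write_genotypes_csv(study$genotypes, file.path(outdir, "genotypes.csv"),
                        file.path(outdir, "marker_map.csv"))
    write_table_commented(study$ndre, file.path(outdir, "ndre_long.csv"),
                          "thermal_time = GDD base 0C; ndre unitless")
    write_table_commented(study$yield, file.path(outdir, "yield.csv"),
                          "yield in t/ha")
    paths <- c(paths, file.path(outdir, c("genotypes.csv", "marker_map.csv",
                                          "ndre_long.csv", "yield.csv")))
    manifest$stages$simulate <- list(n_genotypes = cfg$n_genotypes,
                                     n_markers = ncol(study$genotypes$dosage),
                                     n_environments = cfg$n_environments)
  } else {
    stopf("running from external tables requires the simulate stage for now")
  }

  corrected <- NULL; h2_tables <- list(); blue_list <- list()
  if ("spatial" %in% stages) {
    say("[spatial] per-flight spatial correction")
    model <- config$spatial_model %||% "auto"
    cors <- list()
    for (tr in unique(study$ndre$trial)) {
      res <- spatial_correct_trial(study$ndre[study$ndre$trial == tr, ],
                                   model = model)
      cors[[tr]] <- res$corrected
      h2_tables[[tr]] <- data.frame(trial = tr, res$h2_table,
                                    model = res$model)
      yb <- yield_blues(study$yield[study$yield$trial == tr, ])
      blue_list[[tr]] <- data.frame(trial = tr, yb,
                                    h2 = attr(yb, "h2"))
    }
    corrected <- do.call(rbind, cors)
    write_table_commented(corrected, file.path(outdir, "ndre_corrected.csv"),
                          "ndre_corrected = NDRE minus estimated spatial and design effects")
    write_table_commented(do.call(rbind, h2_tables),
                          file.path(outdir, "h2_by_timepoint.csv"),
                          "broad-sense heritability per flight and model")
    write_table_commented(do.call(rbind, blue_list),
                          file.path(outdir, "yield_blues.csv"),
                          "yield BLUEs (t/ha), genotype fixed, AR1xAR1 residual")
    paths <- c(paths, file.path(outdir, c("ndre_corrected.csv",
                                          "h2_by_timepoint.csv", "yield_blues.csv")))
    manifest$stages$spatial <- list(model = model)
  }

  traits <- NULL
  if ("curves" %in% stages && !is.null(corrected)) {
    say("[curves] hierarchical growth curves and trait extraction")
    window <- config$window %||% cfg$curve$window
    gc <- growth_curves_by_trial(corrected, window = window)
    traits <- gc$traits
    write_table_commented(traits, file.path(outdir, "traits.csv"),
                          "scsAUC in NDRE x GDD; rAUC = integral of |dNDRE/dt|")
    paths <- c(paths, file.path(outdir, "traits.csv"))
    manifest$stages$curves <- list(window = window,
                                   trials = length(gc$curves))
  }

  met <- NULL
  if ("met" %in% stages && !is.null(traits)) {
    say("[met] multi-environment covariance models")
    structures <- config$met_structures %||%
      c("DIAG", "CorV", "CorH", "FA1", "FA2", "FA3")
    scs <- traits[traits$trait == "scsAUC", c("genotype", "env", "value")]
    fits <- lapply(structures, function(s)
      tryCatch(fit_met(scs, s, seed = cfg$seed), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    met <- select_met_model(fits)
    cmp <- attr(met, "comparison")
    write_table_commented(cmp, file.path(outdir, "met_models.csv"),
                          "REML model comparison; pct_var = % genetic variance accounted")
    if (!is.null(met$Lambda)) {
      va <- variance_accounted(met)
      ic <- assign_iclasses(met)
      write_table_commented(cbind(va, loading = met$Lambda, iclass = ic$iclass),
                            file.path(outdir, "met_fa_summary.csv"),
                            "per-factor % variance and loadings of selected FA model")
      icb <- iclass_blues(met, ic)
      write_table_commented(icb, file.path(outdir, "iclass_blues.csv"),
                            "per-iClass genotype means of predicted effects")
      paths <- c(paths, file.path(outdir, c("met_fa_summary.csv", "iclass_blues.csv")))
    }
    paths <- c(paths, file.path(outdir, "met_models.csv"))
    manifest$stages$met <- list(selected = met$structure,
                                structures = structures)
  }

  if ("haplo" %in% stages && !is.null(traits)) {
    say("[haplo] LD blocks, localGEBVs and stacking")
    cur <- curate_markers(study$genotypes)
    blocks <- build_ld_blocks(cur, config$r2_threshold %||% 0.7,
                              config$tolerance %||% 2)
    haps <- call_haplotypes(cur, blocks)
    scs <- traits[traits$trait == "scsAUC", ]
    met_blue <- tapply(scs$value, scs$genotype, mean)
    eff <- rrblup_effects(cur, met_blue)
    et <- local_gebv(eff, blocks, haps,
                     sig_threshold = config$sig_threshold %||% 0.3)
    st <- stack_haplotypes(et, haps, met_blue)
    write_blocks_bed(blocks, file.path(outdir, "ld_blocks.bed"))
    write_table_commented(as.data.frame(et), file.path(outdir, "haplotype_effects.csv"),
                          "localGEBV effects in trait units; scaled_variance in [0,1]")
    write_table_commented(st$groups, file.path(outdir, "stacking.csv"),
                          "mean trait by count of beneficial haplotypes at significant blocks")
    paths <- c(paths, file.path(outdir, c("ld_blocks.bed", "haplotype_effects.csv",
                                          "stacking.csv")))
    manifest$stages$haplo <- list(n_blocks = nrow(blocks),
                                  n_significant = st$n_significant,
                                  stacking_slope = st$slope)
  }

  manifest$files <- as.list(tools::md5sum(paths))
  manifest$elapsed_s <- as.numeric(Sys.time() - t_all, units = "secs")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
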