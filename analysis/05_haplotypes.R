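#!/usr/bin/env Rscript
# Stage 5: marker curation, diversity, LD blocks, localGEBV haplotype
# effects and in-silico stacking.
#
# Haplotype detection runs on the MET-level scsAUC BLUEs and on each
# iClass's BLUEs, mirroring the study design: RRBLUP marker effects are
# summed within LD blocks (r2 threshold 0.7, marker tolerance 2) into
# localGEBVs, blocks pass the scaled min-max variance threshold 0.3, and
# beneficial haplotypes (positive scsAUC effect) are stacked per genotype.

suppressPackageStartupMessages(library(staygreen))

outdir <- "results/haplotypes"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

geno <- read_genotypes_csv("results/data/genotypes.csv",
                           "results/data/marker_map.csv")
traits <- staygreen:::read_table_commented("results/curves/traits.csv")
icb <- staygreen:::read_table_commented("results/met/iclass_blues.csv")

cur <- curate_markers(geno)
rep_ <- attr(cur, "report")
message(sprintf("curation: %d -> %d markers (%d MAF <= 0.05, %d het > 10%%)",
                rep_$n_input, rep_$n_kept, rep_$removed_maf, rep_$removed_het))

message("population structure ...")
D <- rogers_distance(cur)
dc <- diversity_clusters(D, k = 3)
message(sprintf("principal coordinates 1+2 carry %.1f%% + %.1f%% of variation",
                dc$pct_var[1], dc$pct_var[2]))
staygreen:::write_table_commented(
  data.frame(genotype = rownames(dc$scores), dc$scores,
             cluster = dc$cluster),
  file.path(outdir, "pcoa_scores.csv"),
  "principal coordinates of Rogers' distance; UPGMA clusters (k = 3)")

blocks <- build_ld_blocks(cur, r2_threshold = 0.7, tolerance = 2)
message(sprintf("%d LD blocks over %d curated markers", nrow(blocks),
                ncol(cur$dosage)))
write_blocks_bed(blocks, file.path(outdir, "ld_blocks.bed"))
haps <- call_haplotypes(cur, blocks)

detect <- function(y, label) {
  eff <- rrblup_effects(cur, y)
  et <- local_gebv(eff, blocks, haps, sig_threshold = 0.3)
  st <- stack_haplotypes(et, haps, y)
  message(sprintf("  %-12s significant blocks: %2d  stacking slope: %.2f",
                  label, st$n_significant, st$slope))
  list(effects = data.frame(analysis = label, as.data.frame(et)),
       stacking = if (nrow(st$groups)) data.frame(analysis = label, st$groups))
}

scs <- traits[traits$trait == "scsAUC", ]
met_blue <- tapply(scs$value, scs$genotype, mean)
res <- list(detect(met_blue, "MET_scsAUC"))
for (cl in unique(icb$env)) {
  y <- with(icb[icb$env == cl, ], stats::setNames(value, genotype))
  res <- c(res, list(detect(y, paste0(cl, "_scsAUC"))))
}
# rate trait in the densest-flight trial
rauc <- traits[traits$trait == "rAUC", ]
ndre <- staygreen:::read_table_commented("results/data/ndre_long.csv")
flights <- tapply(ndre$thermal_time, ndre$trial, function(x) length(unique(x)))
env_r <- names(which.max(flights))
yr <- with(rauc[rauc$env == env_r, ], stats::setNames(value, genotype))
effr <- rrblup_effects(cur, yr)
etr <- local_gebv(effr, blocks, haps, trait_direction = "negative")
str_ <- stack_haplotypes(etr, haps, yr)
message(sprintf("  %-12s significant blocks: %2d (beneficial = negative effect)",
                paste0(env_r, "_rAUC"), str_$n_significant))
res <- c(res, list(list(effects = data.frame(analysis = paste0(env_r, "_rAUC"),
                                             as.data.frame(etr)),
                        stacking = if (nrow(str_$groups))
                          data.frame(analysis = paste0(env_r, "_rAUC"), str_$groups))))

staygreen:::write_table_commented(
  do.call(rbind, lapply(res, `[[`, "effects")),
  file.path(outdir, "haplotype_effects.csv"),
  "localGEBV haplotype effects; scaled_variance in [0,1], significant at >= 0.3")
staygreen:::write_table_commented(
  do.call(rbind, Filter(Negate(is.null), lapply(res, `[[`, "stacking"))),
  file.path(outdir, "stacking.csv"),
  "mean trait by number of beneficial haplotypes at significant blocks")
message("wrote ", outdir)
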