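#!/usr/bin/env Rscript
# Stage 4: multi-environment covariance modeling of scsAUC, iClasses, and
# genetic correlation of stay-green with yield.
#
# The genotype x environment table of scsAUC values is fitted with DIAG,
# CorV, CorH and FA(1..3) covariance structures by REML; the model
# accounting for the most genetic variance within the AIC window is
# retained, its loading polarities define the interaction classes, and
# per-iClass BLUEs are computed.  A VanRaden kinship matrix then feeds a
# bivariate mixed model per environment for the genetic correlation
# between scsAUC and yield.

suppressPackageStartupMessages(library(staygreen))

outdir <- "results/met"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

traits <- staygreen:::read_table_commented("results/curves/traits.csv")
ybl <- staygreen:::read_table_commented("results/spatial/yield_blues.csv")
geno <- read_genotypes_csv("results/data/genotypes.csv",
                           "results/data/marker_map.csv")

scs <- traits[traits$trait == "scsAUC", c("genotype", "env", "value")]

# trials whose sparse flight schedule left no usable genetic variance in
# the fitted curves are set aside (the study likewise trialed removal of
# its lowest-heritability environment)
env_sd <- tapply(scs$value, scs$env, stats::sd)
drop_env <- names(env_sd)[env_sd < 0.05 * max(env_sd)]
if (length(drop_env)) {
  message("dropping environment(s) without usable genetic variance: ",
          paste(drop_env, collapse = ", "))
  scs <- scs[!scs$env %in% drop_env, ]
}

structures <- c("DIAG", "CorV", "CorH", "FA1", "FA2", "FA3")
message("fitting MET structures: ", paste(structures, collapse = ", "))
fits <- lapply(structures, function(s) {
  f <- fit_met(scs, s, seed = 1)
  message(sprintf("  %-5s logL %10.2f  AIC %10.1f  npar %2d", f$structure,
                  f$loglik, f$AIC, f$n_par))
  f
})
sel <- select_met_model(fits)
cmp <- attr(sel, "comparison")
message("selected structure: ", sel$structure)
staygreen:::write_table_commented(
  cmp, file.path(outdir, "met_models.csv"),
  "REML goodness of fit per covariance structure")

if (is.null(sel$Lambda)) {
  # fall back to the best FA fit for the iClass stage
  fa_fits <- Filter(function(f) !is.null(f$Lambda), fits)
  sel_fa <- fa_fits[[which.min(vapply(fa_fits, function(f) f$AIC, numeric(1)))]]
  message("iClass derivation uses the best FA fit: ", sel_fa$structure)
} else sel_fa <- sel
va <- variance_accounted(sel_fa)
ic <- assign_iclasses(sel_fa)
fa_summary <- cbind(va, loading = sel_fa$Lambda, iclass = ic$iclass)
print(fa_summary, digits = 3)
message(sprintf("overall %% variance accounted: %.1f", attr(va, "overall")))
message("iClasses: ", paste(unique(ic$iclass), collapse = ", "))
staygreen:::write_table_commented(
  fa_summary, file.path(outdir, "fa_summary.csv"),
  "per-factor % variance accounted, loadings, iClass of the selected FA model")

icb <- iclass_blues(sel_fa, ic)
staygreen:::write_table_commented(
  icb, file.path(outdir, "iclass_blues.csv"),
  "per-iClass genotype values (mean predicted effect over member trials)")

# genetic + phenotypic correlation with yield, per environment
G <- grm_vanraden(geno)
cors <- do.call(rbind, lapply(unique(scs$env), function(e) {
  y1 <- with(scs[scs$env == e, ], stats::setNames(value, genotype))
  yb <- ybl[ybl$trial == e, ]
  y2 <- stats::setNames(yb$blue, yb$genotype)
  rg <- genetic_correlation(y1, y2, G)
  data.frame(env = e, r_g = rg$r_g, r_p = phenotypic_correlation(y1, y2))
}))
print(cors, digits = 2)
staygreen:::write_table_commented(
  cors, file.path(outdir, "correlations.csv"),
  "genetic (kinship bivariate REML) and phenotypic (Pearson) scsAUC-yield correlations")
message("wrote ", outdir)
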