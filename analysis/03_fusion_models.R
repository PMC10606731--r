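#!/usr/bin/env Rscript
# Spectral side of the workflow: average instrument replicates, fix one
# stratified Kennard-Stone 70/30 split on the low-level fused space, run
# the three NIR+MIR fusion strategies with their standard latent-variable
# counts (23 / 22 / 12), and validate each final model by permutation.

library(spicefuse)

seed <- 42
n_perm <- 50   # permutations per fused model; the content-table model in
               # 02 runs the full 200 — here each refit carries a 7-fold CV
               # over >1000 channels, so a reduced count keeps the driver
               # interactive while the intercepts are already stable
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed)
tab <- generate_metabolite_table(default_class_specs(), cfg)
nir <- average_replicates(generate_spectra(tab, "NIR", cfg))
mir <- average_replicates(generate_spectra(tab, "MIR", cfg))
blocks <- list(NIR = nir, MIR = mir)
lab <- nir$labels

## one split, shared by every strategy -------------------------------------
fused_space <- cbind(scale_variables(nir$intensities, "mean-center")$X,
                     scale_variables(mir$intensities, "mean-center")$X)
split <- stratified_split(fused_space, lab, 0.7)
message(sprintf("Kennard-Stone split: %d calibration / %d validation",
                length(split$calibration), length(split$validation)))
write_split(split, nir$sample_ids, "results/03_split.csv")

## the three strategies -----------------------------------------------------
results <- lapply(c("low_level", "mid_level_vip", "mid_level_lv"),
                  function(strat) {
  r <- run_strategy(blocks, lab, split, fusion_config(strat),
                    n_permutations = n_perm, seed = seed)
  message(sprintf(
    "%-14s: %4d fused columns, LV=%2d, R2Y=%.3f, Q2=%.3f, acc=%g/%g, Q2 intercept=%.3f",
    strat, ncol(r$fused$train), r$metrics$LV, r$metrics$R2Y, r$metrics$Q2,
    r$metrics$accuracy_train, r$metrics$accuracy_test,
    r$permutation$q2_intercept))
  r
})

report <- fusion_report(results)
write.csv(report, "results/03_fusion_comparison.csv", row.names = FALSE)
print(report, digits = 3)

perm_summary <- do.call(rbind, lapply(results, function(r)
  data.frame(strategy = r$config$strategy,
             n_permutations = r$permutation$n_permutations,
             r2_intercept = r$permutation$r2_intercept,
             q2_intercept = r$permutation$q2_intercept,
             original_r2 = r$permutation$original_r2,
             original_q2 = r$permutation$original_q2)))
write.csv(perm_summary, "results/03_permutation_summary.csv",
          row.names = FALSE)
message("all permutation Q2 intercepts below the original Q2: ",
        all(perm_summary$q2_intercept < perm_summary$original_q2))
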