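#!/usr/bin/env Rscript
# GC-MS side of the workflow on the synthetic study: hierarchical
# clustering with per-class upregulation counts, compound-class
# composition, PCA and OPLS-DA of the relative-content table, VIP >= 1
# screening, and permutation validation of the OPLS-DA model.

library(spicefuse)

seed <- 42
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed)
tab <- generate_metabolite_table(default_class_specs(), cfg)
X <- tab$contents
lab <- tab$labels

## clustered heatmap computation + upregulation counts --------------------
h <- hca(tab)
write.csv(data.frame(class = names(h$upregulated),
                     upregulated = as.integer(h$upregulated)),
          "results/02_upregulated_counts.csv", row.names = FALSE)
message("upregulated metabolites per class: ",
        paste(names(h$upregulated), h$upregulated, sep = ":",
              collapse = " "))

## compound-class composition ---------------------------------------------
comp <- compound_class_composition(tab)
write.csv(comp$composition, "results/02_compound_classes.csv",
          row.names = FALSE)
message("terpenoid share of all ", ncol(X), " metabolites: ",
        comp$terpenoid_percent, " %")

## PCA and OPLS-DA of the autoscaled content table -------------------------
pca <- fit_pca(X, 5, x_scale = "autoscale")
message(sprintf("PCA: first two components explain %.2f %% (PC1 %.3f, PC2 %.3f)",
                explained_two_components(pca$r2x_per_component),
                pca$r2x_per_component[1], pca$r2x_per_component[2]))

opls <- fit_oplsda(X, lab, n_pred = 2, n_orth = 3, x_scale = "autoscale")
r2y <- sum(opls$ssy_per_component) / opls$ssy_total
message(sprintf("OPLS-DA (2 predictive + 3 orthogonal): R2X %.3f, R2Y %.3f",
                sum(opls$r2x_per_component, opls$r2x_orth_per_component),
                r2y))

## VIP screening -----------------------------------------------------------
vip <- vip_scores(opls)
sel <- screen_by_vip(vip, 1)     # inclusive cut, the screening convention
message(length(sel), " of ", ncol(X), " metabolites pass VIP >= 1")
scr <- compound_class_composition(tab, selected = sel)
message("terpenoid share of the screened set: ", scr$terpenoid_percent, " %")
write.csv(data.frame(metabolite = colnames(X), vip = round(vip, 4),
                     selected = seq_len(ncol(X)) %in% sel,
                     compound_class = tab$compound_class),
          "results/02_vip_screen.csv", row.names = FALSE)

## permutation validation (n = 200, the study's setting) -------------------
perm <- permutation_test(X, lab, n_permutations = 200, seed = seed,
                         kind = "plsda", n_components = 2,
                         x_scale = "autoscale")
print(perm)
write.csv(data.frame(correlation = perm$correlations,
                     r2 = perm$r2_values, q2 = perm$q2_values),
          "results/02_permutation_points.csv", row.names = FALSE)
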