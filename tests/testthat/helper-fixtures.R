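# Small in-code fixtures shared across test files.

# a tiny well-separated multi-class dataset (class means far apart relative
# to unit noise)
make_separable <- function(n_per_class = 8, n_classes = 4, p = 12,
                           shift = 4, seed = 11) {
  withr::local_seed(seed)
  lab <- rep(LETTERS[seq_len(n_classes)], each = n_per_class)
  X <- matrix(rnorm(length(lab) * p), length(lab), p)
  for (k in seq_len(n_classes)) {
    cols <- ((k - 1) * 2 + 1):min(k * 2, p)
    X[lab == LETTERS[k], cols] <- X[lab == LETTERS[k], cols] + shift
  }
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, labels = lab)
}

# a small valid metabolite_table
make_small_table <- function(seed = 5) {
  withr::local_seed(seed)
  contents <- matrix(abs(rnorm(8 * 4, 2)), 8, 4,
                     dimnames = list(NULL, c("m1", "m2", "m3", "m4")))
  metabolite_table(contents, sample_ids = paste0("s", 1:8),
                   labels = rep(c("A", "B"), each = 4),
                   compound_class = c(m1 = "Monoterpenes",
                                      m2 = "Sesquiterpenes",
                                      m3 = "Esters", m4 = "Acids"))
}

# full default-design synthetic study, memoised so the expensive pieces are
# built once per test run
study_cache <- new.env(parent = emptyenv())
make_study <- function(seed = 42) {
  key <- paste0("s", seed)
  if (!is.null(study_cache[[key]])) return(study_cache[[key]])
  cfg <- generator_config(seed = seed)
  tab <- generate_metabolite_table(default_class_specs(), cfg)
  nir <- average_replicates(generate_spectra(tab, "NIR", cfg))
  mir <- average_replicates(generate_spectra(tab, "MIR", cfg))
  fused <- cbind(scale_variables(nir$intensities, "mean-center")$X,
                 scale_variables(mir$intensities, "mean-center")$X)
  split <- stratified_split(fused, nir$labels, 0.7)
  study_cache[[key]] <- list(config = cfg, table = tab, nir = nir,
                             mir = mir, split = split, labels = nir$labels)
  study_cache[[key]]
}
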