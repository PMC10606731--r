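# Synthetic-data generator. The study design it emulates: 13 species x 15
# samples (195 in total), 3 instrument replicates per sample for each of NIR
# and MIR, and a GC-MS relative-content table whose per-species means/SDs are
# the packaged reference summaries. Spectra are sums of Gaussian bands at the
# modality's characteristic positions; band amplitudes are an affine function
# of the sample's metabolite contents, so class differences in composition
# propagate to class-specific band intensities.

.band_centers <- list(
  NIR = c(8330, 6803, 5696, 5179, 4693),
  MIR = c(3289, 2921, 2854, 1623, 1425, 1369, 1315, 1240, 1010)
)

# Fixed internal seed for the metabolite -> band response map. The map is a
# property of the simulated "instrument + chemistry", deliberately
# independent of the data seed in generator_config().
.RESPONSE_SEED <- 1013L

#' Generator configuration
#'
#' Holds the study-design counts and noise magnitudes for the synthetic
#' generator. Defaults mirror the emulated design: 13 species, 15 samples
#' each, 3 instrument replicates, and FT-instrument-scale noise (white noise
#' 0.005 AU, smooth baseline drift 0.01 AU).
#'
#' @param n_classes number of species classes (<= 13 with the default specs).
#' @param n_samples_per_class samples per species.
#' @param n_replicates instrument replicates per sample and modality.
#' @param noise_sd standard deviation of white channel noise, absorbance
#'   units.
#' @param baseline_drift_sd scale of the smooth random baseline component,
#'   absorbance units.
#' @param seed integer seed; identical config implies bit-identical output.
#' @param nir_fwhm,mir_fwhm Gaussian band full width at half maximum, cm^-1.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_classes = 13, n_samples_per_class = 15,
                             n_replicates = 3, noise_sd = 0.005,
                             baseline_drift_sd = 0.01, seed = 42,
                             nir_fwhm = 120, mir_fwhm = 40) {
  stopifnot(n_classes >= 1, n_samples_per_class >= 1, n_replicates >= 1,
            noise_sd >= 0, baseline_drift_sd >= 0,
            nir_fwhm > 0, mir_fwhm > 0)
  structure(list(n_classes = as.integer(n_classes),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, baseline_drift_sd = baseline_drift_sd,
                 seed = as.integer(seed),
                 fwhm = c(NIR = nir_fwhm, MIR = mir_fwhm)),
            class = "generator_config")
}

# metabolite -> band response, one map per modality, plus per-band base
# amplitudes. Each metabolite loads its 3 strongest bands (sparse, as a
# compound has few characteristic absorptions); loadings are nonnegative and
# scaled to 0.06 AU per percent relative content. Each compound's bands sit
# at its own positions near the shared class-common centers (offsets within
# about half a bandwidth), the way overlapping compound absorptions produce
# the family-common peaks while remaining compound-specific in detail.
.band_offset_scale <- c(NIR = 60, MIR = 20)   # cm^-1

.band_response <- function(metabolites) {
  with_seed(.RESPONSE_SEED, {
    out <- lapply(names(.band_centers), function(modality) {
      centers <- .band_centers[[modality]]
      k <- length(centers)
      L <- vapply(metabolites, function(m) {
        e <- stats::rexp(k)
        keep <- order(e, decreasing = TRUE)[seq_len(min(3, k))]
        w <- numeric(k)
        w[keep] <- e[keep] / sum(e[keep])
        w * 0.06
      }, numeric(k))
      off <- matrix(stats::runif(k * length(metabolites), -1, 1) *
                      .band_offset_scale[[modality]],
                    nrow = k, dimnames = list(NULL, metabolites))
      base <- stats::runif(k, 0.1, 0.4)
      # species-specific matrix contribution: the non-volatile bulk
      # (saccharides, pectin, ...) differs between species and modulates
      # the common bands' intensities by ~15% relative
      class_base <- matrix(stats::rnorm(13 * k, 0, 0.15), nrow = 13,
                           dimnames = list(LETTERS[1:13], NULL))
      list(loadings = matrix(L, nrow = k,
                             dimnames = list(NULL, metabolites)),
           offsets = off, base = base, class_base = class_base,
           centers = centers)
    })
    names(out) <- names(.band_centers)
    out
  })
}

#' Default per-species class specifications
#'
#' Builds the thirteen class specifications (codes A-M) from the packaged
#' per-species metabolite summaries. Each spec carries mean and SD of
#' relative content for every metabolite in the union across species (a
#' metabolite absent from a species' six main components gets mean 0, SD 0),
#' plus the implied mean band amplitudes per modality.
#'
#' @return Named list of `class_spec` objects, one per species code.
#' @export
default_class_specs <- function() {
  tab <- load_table1_fixture()
  metabolites <- unique(tab$metabolite)
  # metabolite-level compound class: modal value across printed rows
  cls <- vapply(metabolites, function(m) {
    v <- tab$compound_class[tab$metabolite == m]
    names(sort(table(v), decreasing = TRUE))[1]
  }, character(1))
  response <- .band_response(metabolites)
  legend <- species_legend()
  specs <- lapply(names(legend), function(code) {
    rows <- tab[tab$code == code, ]
    mu <- stats::setNames(numeric(length(metabolites)), metabolites)
    sd <- mu
    mu[rows$metabolite] <- rows$mean_pct
    sd[rows$metabolite] <- rows$sd_pct
    band_amplitudes <- lapply(response, function(r)
      as.numeric(r$base * (1 + r$class_base[code, ]) + r$loadings %*% mu))
    structure(list(species_code = code, species = unname(legend[code]),
                   metabolite_means = mu, metabolite_sds = sd,
                   compound_class = cls,
                   band_amplitudes = band_amplitudes),
              class = "class_spec")
  })
  names(specs) <- names(legend)
  specs
}

# vectorized normal truncated at zero by rejection; preserves determinism
# under a fixed stream
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(neg <- x < 0)) x[neg] <- stats::rnorm(sum(neg), mean, sd)
  x
}

#' Generate a synthetic metabolite table
#'
#' Draws each sample's relative content of metabolite m in class c from a
#' normal distribution with that class's (mean, SD), truncated at zero
#' (relative contents cannot be negative). Classes with SD 0 for a
#' metabolite are constant at the mean.
#'
#' @param specs list of class specs, as from [default_class_specs()].
#' @param config a [generator_config()].
#' @return A `metabolite_table` with
#'   `n_classes * n_samples_per_class` rows.
#' @export
generate_metabolite_table <- function(specs, config) {
  stopifnot(inherits(config, "generator_config"), length(specs) >= 1,
            config$n_classes <= length(specs))
  specs <- specs[seq_len(config$n_classes)]
  if (any(vapply(specs, function(s) any(s$metabolite_sds < 0), logical(1))))
    stop("negative metabolite SDs are not allowed")
  metabolites <- names(specs[[1]]$metabolite_means)
  ns <- config$n_samples_per_class
  with_seed(config$seed, {
    blocks <- lapply(specs, function(s) {
      vapply(metabolites, function(m)
        .rtruncnorm0(ns, s$metabolite_means[[m]], s$metabolite_sds[[m]]),
        numeric(ns))
    })
  })
  contents <- do.call(rbind, blocks)
  colnames(contents) <- metabolites
  codes <- vapply(specs, `[[`, character(1), "species_code")
  labels <- rep(codes, each = ns)
  sample_ids <- paste0(labels, sprintf("%02d", rep(seq_len(ns),
                                                   length(specs))))
  metabolite_table(contents, sample_ids, labels,
                   specs[[1]]$compound_class[metabolites])
}

#' Wavenumber grid for a modality
#'
#' NIR spans 12,000-4000 cm^-1 at 8 cm^-1 steps (1001 channels); MIR spans
#' 4000-400 cm^-1 at 16 cm^-1 steps (226 channels). Stored descending.
#'
#' @param modality `"NIR"` or `"MIR"`.
#' @return Numeric vector of wavenumbers, cm^-1.
#' @export
wavenumber_grid <- function(modality) {
  modality <- match.arg(modality, names(.modalities))
  m <- .modalities[[modality]]
  seq(m$range[2], m$range[1], by = -m$step)
}

#' Generate synthetic NIR or MIR spectra for a metabolite table
#'
#' Each sample's spectrum is a sum of Gaussian bands centred at the
#' modality's characteristic peak positions. The amplitude of band k for
#' sample i is `base_k + sum_m loading[k, m] * content[i, m]` with a fixed
#' nonnegative sparse loading map; each compound's contribution sits at its
#' own position within about half a bandwidth of the shared centre. The
#' common bands additionally carry a species-specific matrix contribution
#' (the non-volatile bulk differs between species; ~15% relative between
#' classes, ~3% within), so every species shows the family-common peaks
#' with class-specific intensities and fine structure — the pattern the
#' real spectra of related species exhibit. `n_replicates` spectra are
#' emitted per
#' sample; replicates share the sample's composition and differ only in the
#' smooth random baseline and white channel noise.
#'
#' @param table a `metabolite_table`.
#' @param modality `"NIR"` or `"MIR"`.
#' @param config a [generator_config()].
#' @return A `spectra_block` with `nrow(table) * n_replicates` rows.
#' @export
generate_spectra <- function(table, modality, config) {
  stopifnot(inherits(table, "metabolite_table"),
            inherits(config, "generator_config"))
  modality <- match.arg(modality, names(.modalities))
  if (nrow(table$contents) == 0) stop("empty metabolite table")
  response <- .band_response(table$metabolite_names)[[modality]]
  grid <- wavenumber_grid(modality)
  sigma <- config$fwhm[[modality]] / (2 * sqrt(2 * log(2)))
  gauss <- function(c0) exp(-0.5 * ((grid - c0) / sigma)^2)
  # common-band profiles (bands x channels) for the matrix contribution
  Gc <- t(vapply(response$centers, gauss, numeric(length(grid))))
  # per-metabolite channel profile: its loaded bands at offset positions
  M <- t(vapply(seq_along(table$metabolite_names), function(m) {
    prof <- numeric(length(grid))
    for (k in which(response$loadings[, m] > 0))
      prof <- prof + response$loadings[k, m] *
        gauss(response$centers[k] + response$offsets[k, m])
    prof
  }, numeric(length(grid))))
  n <- nrow(table$contents); nc <- length(grid)
  nrep <- config$n_replicates; nb <- length(response$centers)
  cls_delta <- response$class_base[table$labels, , drop = FALSE]
  u <- seq(-1, 1, length.out = nc)         # unit coordinate for drift
  drift_basis <- cbind(1, u, 2 * u^2 - 1, 4 * u^3 - 3 * u)
  with_seed(config$seed + match(modality, names(.modalities)), {
    # per-sample matrix state: class offset plus ~3% within-class relative
    # variation, shared by a sample's replicates
    base_amp <- outer(rep(1, n), response$base) *
      (1 + cls_delta + matrix(stats::rnorm(n * nb, 0, 0.03), n, nb))
    clean <- table$contents %*% M + base_amp %*% Gc
    rows <- clean[rep(seq_len(n), each = nrep), , drop = FALSE]
    if (config$baseline_drift_sd > 0) {
      coef <- matrix(stats::rnorm(n * nrep * 4, 0, config$baseline_drift_sd),
                     ncol = 4)
      rows <- rows + coef %*% t(drift_basis)
    }
    if (config$noise_sd > 0)
      rows <- rows + matrix(stats::rnorm(length(rows), 0, config$noise_sd),
                            nrow = nrow(rows))
  })
  spectra_block(rows, grid,
                sample_ids = rep(table$sample_ids, each = nrep),
                labels = rep(table$labels, each = nrep),
                modality = modality,
                replicate_index = rep(seq_len(nrep), n))
}
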