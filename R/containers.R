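#' @keywords internal
"_PACKAGE"

# Spectral ranges (cm^-1) and acquisition step per modality. NIR is scanned
# 12,000 -> 4000 cm^-1 at 8 cm^-1 resolution, MIR 4000 -> 400 cm^-1 at
# 16 cm^-1; wavenumbers are stored descending, the plotting convention.
.modalities <- list(
  NIR = list(range = c(4000, 12000), step = 8),
  MIR = list(range = c(400, 4000), step = 16)
)

.compound_classes <- c("Monoterpenes", "Sesquiterpenes", "Aldehydes",
                       "Esters", "Acids", "Hydrocarbons", "other")

#' Construct a spectra block
#'
#' A `spectra_block` bundles one modality's samples-by-channels absorbance
#' matrix with its wavenumber grid, sample identifiers and species labels.
#' All type invariants (dimension agreement, finite intensities, wavenumbers
#' descending and within the modality's range) are enforced at construction;
#' violating any of them is an error.
#'
#' @param intensities numeric matrix, samples x channels, absorbance
#'   (arbitrary units).
#' @param wavenumbers numeric vector of channel positions in cm^-1, strictly
#'   decreasing.
#' @param sample_ids character vector of sample identifiers (one per row;
#'   repeated across instrument replicates of the same sample).
#' @param labels character vector of species codes (A-M in the packaged
#'   legend), one per row.
#' @param modality `"NIR"` or `"MIR"`.
#' @param replicate_index optional integer vector giving the instrument
#'   replicate each row belongs to.
#'
#' @return An object of class `spectra_block`.
#' @seealso [generate_spectra()], [read_spectra_matrix()],
#'   [average_replicates()]
#' @export
spectra_block <- function(intensities, wavenumbers, sample_ids, labels,
                          modality, replicate_index = NULL) {
  modality <- match.arg(modality, names(.modalities))
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  n <- nrow(intensities)
  if (length(sample_ids) != n || length(labels) != n)
    stop("sample_ids and labels must have one entry per intensity row")
  if (ncol(intensities) != length(wavenumbers))
    stop("intensity columns must match the wavenumber grid")
  if (any(!is.finite(intensities)))
    stop("all intensities must be finite")
  if (length(wavenumbers) > 1 && any(diff(wavenumbers) >= 0))
    stop("wavenumbers must be strictly decreasing")
  rng <- .modalities[[modality]]$range
  if (any(wavenumbers < rng[1] | wavenumbers > rng[2]))
    stop(sprintf("%s wavenumbers must lie within [%g, %g] cm^-1",
                 modality, rng[1], rng[2]))
  if (!is.null(replicate_index)) {
    replicate_index <- as.integer(replicate_index)
    if (length(replicate_index) != n)
      stop("replicate_index must have one entry per row")
  }
  structure(
    list(modality = modality, wavenumbers = wavenumbers,
         intensities = intensities, sample_ids = as.character(sample_ids),
         labels = as.character(labels), replicate_index = replicate_index),
    class = "spectra_block")
}

#' @export
print.spectra_block <- function(x, ...) {
  cat(sprintf("spectra_block: %s, %d spectra x %d channels (%g-%g cm^-1)\n",
              x$modality, nrow(x$intensities), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  %d distinct samples, %d classes%s\n",
              length(unique(x$sample_ids)), length(unique(x$labels)),
              if (is.null(x$replicate_index)) "" else
                sprintf(", replicates %d-%d", min(x$replicate_index),
                        max(x$replicate_index))))
  invisible(x)
}

#' Construct a metabolite relative-content table
#'
#' Samples-by-metabolites matrix of GC-MS relative contents (%), with a
#' compound-class annotation per metabolite. Compound classes outside the
#' recognised vocabulary (Monoterpenes, Sesquiterpenes, Aldehydes, Esters,
#' Acids, Hydrocarbons) are mapped to `"other"` with a warning.
#'
#' @param contents numeric matrix, samples x metabolites, relative content in
#'   percent; column names are the metabolite names and must be unique.
#' @param sample_ids,labels character vectors, one entry per row.
#' @param compound_class character vector, one compound class per metabolite
#'   (recycled names are matched to `colnames(contents)` when named).
#'
#' @return An object of class `metabolite_table`.
#' @export
metabolite_table <- function(contents, sample_ids, labels, compound_class) {
  contents <- as.matrix(contents)
  storage.mode(contents) <- "double"
  mets <- colnames(contents)
  if (is.null(mets) || anyDuplicated(mets))
    stop("contents must have unique metabolite column names")
  n <- nrow(contents)
  if (length(sample_ids) != n || length(labels) != n)
    stop("sample_ids and labels must have one entry per row")
  if (any(!is.finite(contents)) || any(contents < 0))
    stop("relative contents must be finite and >= 0")
  if (!is.null(names(compound_class)))
    compound_class <- compound_class[mets]
  if (length(compound_class) != ncol(contents))
    stop("compound_class must annotate every metabolite")
  compound_class <- as.character(compound_class)
  unknown <- !(compound_class %in% .compound_classes) | is.na(compound_class)
  if (any(unknown)) {
    warning(sprintf("unrecognised compound class for %s; mapped to 'other'",
                    paste(mets[unknown], collapse = ", ")))
    compound_class[unknown] <- "other"
  }
  names(compound_class) <- mets
  structure(
    list(contents = contents, sample_ids = as.character(sample_ids),
         labels = as.character(labels), metabolite_names = mets,
         compound_class = compound_class),
    class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d samples x %d metabolites, %d classes\n",
              nrow(x$contents), ncol(x$contents), length(unique(x$labels))))
  print(table(x$compound_class))
  invisible(x)
}

# evaluate expr under a temporary RNG state so generators do not disturb
# (and are not disturbed by) the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
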