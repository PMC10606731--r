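# Delimited-text I/O for spectra blocks and metabolite tables, plus the
# packaged reference fixtures (per-species metabolite means/SDs and the
# species-letter legend). Canonical on-disk dialect: comma-separated, UTF-8,
# "." decimal, samples as rows.

#' Species-letter legend
#'
#' The thirteen Zingiberaceae species and their one-letter codes used
#' throughout as class labels.
#'
#' @return Named character vector: code (A-M) -> binomial species name.
#' @export
species_legend <- function() {
  path <- system.file("extdata", "species_legend.csv", package = "spicefuse",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$species, df$code)
}

#' Packaged per-species metabolite summary
#'
#' The six main volatile metabolites of each of the thirteen species, with
#' their mean and standard deviation of relative content (%) and their
#' compound classification; 78 records in total. These summaries seed the
#' synthetic-data generator.
#'
#' @return data.frame with columns `species`, `code`, `metabolite`,
#'   `compound_class`, `mean_pct`, `sd_pct`.
#' @seealso [default_class_specs()]
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_metabolites.csv",
                      package = "spicefuse", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(df) == 78, !any(is.na(df$mean_pct)), all(df$sd_pct >= 0))
  df
}

#' Write / read a spectra block as delimited text
#'
#' The on-disk layout is one header row holding `sample_id`, `label`,
#' `replicate` and then the wavenumber grid (cm^-1, descending), followed by
#' one row per spectrum. `read_spectra_matrix()` validates every
#' `spectra_block` invariant on load; a malformed file is an error, never a
#' silently repaired object.
#'
#' @param block a `spectra_block`.
#' @param path file path (relative or absolute).
#' @param modality declared modality of the file being read.
#' @return `read_spectra_matrix()` returns a validated `spectra_block`;
#'   `write_spectra_matrix()` returns `path` invisibly.
#' @export
write_spectra_matrix <- function(block, path) {
  stopifnot(inherits(block, "spectra_block"))
  rep_idx <- block$replicate_index
  if (is.null(rep_idx)) rep_idx <- rep(1L, nrow(block$intensities))
  df <- data.frame(sample_id = block$sample_ids, label = block$labels,
                   replicate = rep_idx, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.data.frame(block$intensities)
  names(mat) <- format(block$wavenumbers, trim = TRUE, scientific = FALSE)
  utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_matrix
#' @export
read_spectra_matrix <- function(path, modality) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "replicate")
  if (!all(need %in% names(df)))
    stop("spectra file must carry columns: ", paste(need, collapse = ", "))
  wn_cols <- setdiff(names(df), need)
  wavenumbers <- suppressWarnings(as.numeric(wn_cols))
  if (any(is.na(wavenumbers)))
    stop("non-numeric wavenumber column headers in ", path)
  mat <- as.matrix(df[wn_cols])
  if (!is.numeric(mat)) stop("non-numeric intensity cells in ", path)
  spectra_block(mat, wavenumbers, df$sample_id, df$label, modality,
                replicate_index = df$replicate)
}

#' Write / read a metabolite table as delimited text
#'
#' Layout: a standard CSV header (`sample_id`, `label`, metabolite names),
#' then one annotation row whose `sample_id` field is `#class` carrying each
#' metabolite's compound class, then the sample rows.
#'
#' @param table a `metabolite_table`.
#' @param path file path.
#' @return `read_metabolite_table()` returns a validated `metabolite_table`;
#'   the writer returns `path` invisibly.
#' @export
write_metabolite_table <- function(table, path) {
  stopifnot(inherits(table, "metabolite_table"))
  header <- data.frame(sample_id = "#class", label = "",
                       stringsAsFactors = FALSE)
  cls <- as.data.frame(as.list(table$compound_class),
                       check.names = FALSE, stringsAsFactors = FALSE)
  body <- data.frame(sample_id = table$sample_ids, label = table$labels,
                     stringsAsFactors = FALSE, check.names = FALSE)
  out <- rbind(cbind(header, cls),
               cbind(body, as.data.frame(table$contents,
                                         check.names = FALSE)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolite_table
#' @export
read_metabolite_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(df)))
    stop("metabolite file must carry sample_id and label columns")
  cls_row <- which(df$sample_id == "#class")
  if (length(cls_row) != 1)
    stop("metabolite file must carry exactly one '#class' annotation row")
  mets <- setdiff(names(df), c("sample_id", "label"))
  if (anyDuplicated(mets)) stop("duplicate metabolite names in ", path)
  compound_class <- stats::setNames(unlist(df[cls_row, mets]), mets)
  body <- df[-cls_row, , drop = FALSE]
  mat <- vapply(mets, function(m) {
    v <- suppressWarnings(as.numeric(body[[m]]))
    if (any(is.na(v))) stop("non-numeric content cells in column ", m)
    v
  }, numeric(nrow(body)))
  mat <- matrix(mat, nrow = nrow(body), dimnames = list(NULL, mets))
  metabolite_table(mat, body$sample_id, body$label, compound_class)
}

#' Serialize a calibration/validation split for audit
#'
#' @param split a `split_assignment` (see [stratified_split()]).
#' @param sample_ids sample identifiers the split indexes into.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, sample_ids, path) {
  stopifnot(inherits(split, "split_assignment"))
  set <- rep("validation", length(sample_ids))
  set[split$calibration] <- "calibration"
  utils::write.csv(data.frame(sample_id = sample_ids, set = set),
                   path, row.names = FALSE)
  invisible(path)
}
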