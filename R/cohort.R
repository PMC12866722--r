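# The labeled cohort container and its delimited-text serialization.
# One CSV row per spectrum: spectrum_id, sample_id, class, stage, then one
# column per wavenumber channel (header = the wavenumber). A ground-truth
# sidecar in the same format carries per-spectrum spike channels and
# amplitude jitter so downstream oracles can be scored.

#' Labeled cohort of SERS spectra
#'
#' Rows of `intensities` are spectra on the shared `grid`; `info` carries
#' one row of metadata per spectrum (`spectrum_id`, `sample_id`, `class`,
#' `stage`). `spike_truth` (optional) is a list of ground-truth cosmic-ray
#' channel indices per spectrum.
#'
#' @param grid a [wavenumber_grid()]
#' @param intensities numeric matrix, spectra in rows
#' @param info data.frame with columns `spectrum_id`, `sample_id`, `class`
#'   and optionally `stage`
#' @param spike_truth optional list of integer vectors, one per spectrum
#' @param truth optional list of generator ground truth (planted deltas, ...)
#' @param preprocessed character vector of preprocessing steps already
#'   applied
#' @return an object of class `sers_cohort`
#' @export
sers_cohort <- function(grid, intensities, info, spike_truth = NULL,
                        truth = NULL, preprocessed = character(0)) {
  stopifnot(inherits(grid, "wavenumber_grid"), is.matrix(intensities))
  if (nrow(intensities) != nrow(info))
    stop("info must have one row per spectrum")
  if (ncol(intensities) != length(grid$values))
    stop("intensity columns must match grid length")
  need <- c("spectrum_id", "sample_id", "class")
  if (!all(need %in% names(info)))
    stop("info needs columns: ", paste(need, collapse = ", "))
  if (!"stage" %in% names(info)) info$stage <- NA_character_
  dup <- info$spectrum_id[duplicated(info$spectrum_id)]
  if (length(dup))
    stop("duplicate spectrum_id: ", paste(unique(dup), collapse = ", "))
  if (!is.null(spike_truth) && length(spike_truth) != nrow(info))
    stop("spike_truth must have one entry per spectrum")
  rownames(intensities) <- info$spectrum_id
  structure(list(grid = grid, intensities = intensities, info = info,
                 spike_truth = spike_truth, truth = truth,
                 preprocessed = preprocessed),
            class = "sers_cohort")
}

#' @export
print.sers_cohort <- function(x, ...) {
  cat(sprintf(
    "<sers_cohort> %d spectra / %d samples / %d classes, %d channels\n",
    nrow(x$intensities), length(unique(x$info$sample_id)),
    length(unique(x$info$class)), ncol(x$intensities)))
  if (length(x$preprocessed))
    cat("  preprocessed:", paste(x$preprocessed, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of spectra / samples in a cohort
#' @param ds a [sers_cohort()]
#' @return integer count
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' @rdname n_spectra
#' @export
n_samples <- function(ds) length(unique(ds$info$sample_id))

#' Subset a cohort
#'
#' @param ds a [sers_cohort()]
#' @param spectra logical/integer index over spectra, or `NULL`
#' @param samples character sample_ids to keep, or `NULL`
#' @param classes character class labels to keep, or `NULL`
#' @return a [sers_cohort()]
#' @export
subset_cohort <- function(ds, spectra = NULL, samples = NULL,
                          classes = NULL) {
  keep <- rep(TRUE, n_spectra(ds))
  if (!is.null(spectra)) {
    sel <- rep(FALSE, n_spectra(ds))
    sel[spectra] <- TRUE
    keep <- keep & sel
  }
  if (!is.null(samples)) keep <- keep & ds$info$sample_id %in% samples
  if (!is.null(classes)) keep <- keep & ds$info$class %in% classes
  sers_cohort(ds$grid, ds$intensities[keep, , drop = FALSE],
              ds$info[keep, , drop = FALSE],
              spike_truth = if (!is.null(ds$spike_truth))
                ds$spike_truth[keep],
              truth = ds$truth, preprocessed = ds$preprocessed)
}

#' Extract one spectrum from a cohort
#'
#' @param ds a [sers_cohort()]
#' @param i spectrum row index or spectrum_id
#' @return a [raman_spectrum()]
#' @export
get_spectrum <- function(ds, i) {
  if (is.character(i)) i <- match(i, ds$info$spectrum_id)
  if (is.na(i) || i < 1 || i > n_spectra(ds)) stop("unknown spectrum")
  raman_spectrum(ds$grid, ds$intensities[i, ],
                 spectrum_id = ds$info$spectrum_id[i],
                 sample_id = ds$info$sample_id[i],
                 meta = list(class = ds$info$class[i],
                             spike_channels =
                               if (!is.null(ds$spike_truth))
                                 ds$spike_truth[[i]] else integer(0)))
}

#' Write a cohort to delimited text
#'
#' Emits `<name>_spectra.csv` (metadata columns then one intensity column
#' per wavenumber) and, when ground truth is present, `<name>_truth.csv`
#' with per-spectrum spike channels (pipe-separated) and amplitude jitter.
#' Round-trips losslessly through [read_spectra()].
#'
#' @param ds a [sers_cohort()]
#' @param dir output directory (created if absent)
#' @param name file basename stem
#' @return invisibly, the paths written
#' @export
write_cohort <- function(ds, dir, name = "cohort") {
  stopifnot(inherits(ds, "sers_cohort"), n_spectra(ds) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dt <- data.table::as.data.table(ds$info[c("spectrum_id", "sample_id",
                                            "class", "stage")])
  im <- data.table::as.data.table(ds$intensities)
  data.table::setnames(im, as.character(ds$grid$values))
  spectra_path <- file.path(dir, paste0(name, "_spectra.csv"))
  data.table::fwrite(cbind(dt, im), spectra_path)
  paths <- spectra_path
  if (!is.null(ds$spike_truth)) {
    tr <- data.table::data.table(
      spectrum_id = ds$info$spectrum_id,
      sample_id = ds$info$sample_id,
      class = ds$info$class,
      stage = ds$info$stage,
      spike_channels = vapply(ds$spike_truth, paste, "", collapse = "|"),
      jitter = if (!is.null(ds$truth$jitter)) ds$truth$jitter else NA_real_)
    truth_path <- file.path(dir, paste0(name, "_truth.csv"))
    data.table::fwrite(tr, truth_path)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' Read a spectra matrix CSV into a cohort
#'
#' Expects the schema written by [write_cohort()]: `spectrum_id`,
#' `sample_id`, `class`, optional `stage`, then one numeric column per
#' wavenumber with the wavenumber as header. Malformed input (ragged rows,
#' non-numeric intensities, duplicate spectrum ids) is rejected with a
#' pointer to the offending id or column.
#'
#' @param path spectra CSV path
#' @param truth optional path of the ground-truth sidecar
#' @return a [sers_cohort()]
#' @export
read_spectra <- function(path, truth = NULL) {
  dt <- data.table::fread(path, fill = FALSE, header = TRUE)
  need <- c("spectrum_id", "sample_id", "class")
  if (!all(need %in% names(dt)))
    stop("missing required columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  meta_cols <- intersect(c("spectrum_id", "sample_id", "class", "stage"),
                         names(dt))
  wn_cols <- setdiff(names(dt), meta_cols)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn))
    stop("non-numeric wavenumber headers: ",
         paste(head(wn_cols[is.na(wn)], 3), collapse = ", "))
  if (nrow(dt) == 0L) {
    warning("no data rows in ", path, "; returning empty cohort")
    grid <- grid_from_values(wn)
    return(sers_cohort(grid, matrix(0, 0, length(wn)),
                       data.frame(spectrum_id = character(0),
                                  sample_id = character(0),
                                  class = character(0),
                                  stage = character(0))))
  }
  dup <- dt$spectrum_id[duplicated(dt$spectrum_id)]
  if (length(dup))
    stop("duplicate spectrum_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  for (cc in wn_cols) {
    col <- dt[[cc]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))
      stop(sprintf(
        "non-numeric intensities in column '%s' (data rows %s)", cc,
        paste(head(bad, 5), collapse = ", ")))
    }
  }
  grid <- grid_from_values(wn)
  intens <- as.matrix(dt[, wn_cols, with = FALSE])
  info <- as.data.frame(dt[, meta_cols, with = FALSE])
  if (!"stage" %in% names(info)) info$stage <- NA_character_
  info$stage[info$stage == ""] <- NA_character_

  spike_truth <- NULL
  truth_list <- NULL
  if (!is.null(truth)) {
    tr <- data.table::fread(truth, fill = FALSE, header = TRUE)
    ord <- match(info$spectrum_id, tr$spectrum_id)
    if (anyNA(ord)) stop("truth sidecar does not cover every spectrum")
    tr <- tr[ord, ]
    spike_truth <- lapply(strsplit(tr$spike_channels, "|", fixed = TRUE),
                          function(v) as.integer(v[nzchar(v)]))
    truth_list <- list(jitter = tr$jitter)
  }
  sers_cohort(grid, intens, info, spike_truth = spike_truth,
              truth = truth_list)
}
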