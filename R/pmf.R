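# MALDI peak lists: reading, matching against theoretical fingerprints and
# marker panels, taxon assignment, preservation class and deamidation index.

#' Construct a peak list
#'
#' A centroided MALDI-ToF spectrum: (m/z, intensity) pairs sorted by m/z.
#'
#' @param mz Numeric m/z values (Da).
#' @param intensity Non-negative intensities.
#' @param sample_id Sample label.
#' @param site Optional site/locality label.
#' @param metadata Optional named list.
#' @return Object of class `peaklist`.
#' @export
peaklist <- function(mz, intensity, sample_id = "sample", site = NA_character_,
                     metadata = list()) {
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have equal length")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity")
  if (any(intensity < 0)) stop("negative intensity")
  o <- order(mz)
  structure(list(sample_id = sample_id,
                 peaks = data.frame(mz = mz[o], intensity = intensity[o]),
                 site = site, metadata = metadata),
            class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat("MALDI peak list:", x$sample_id,
      if (!is.na(x$site)) paste0("(", x$site, ")"), "\n")
  cat("  ", nrow(x$peaks), "peaks",
      if (nrow(x$peaks) > 0)
        sprintf("spanning m/z %.2f-%.2f", min(x$peaks$mz), max(x$peaks$mz)),
      "\n")
  invisible(x)
}

#' Read a centroided peak list
#'
#' Supports two-column TSV (m/z, intensity; optional header) and mzML/mzXML
#' via the mzR library. Profile-mode spectra are rejected: centroid the data
#' upstream (no peak picking is implemented here).
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"`, `"mzml"` or `"mzxml"`.
#' @param sample_id Sample label; defaults to the file base name.
#' @param scan Scan number for mzML/mzXML files (default first scan).
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, format = c("auto", "tsv", "mzml", "mzxml"),
                          sample_id = NULL, scan = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzml", mzxml = "mzxml",
                     tsv = "tsv", txt = "tsv", csv = "tsv",
                     stop("cannot infer peak-list format from extension '",
                          ext, "'"))
  }
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  if (format == "tsv") {
    if (file.size(path) == 0L) stop("empty peak-list file: ", path)
    first <- readLines(path, n = 1L)
    has_header <- !grepl("^[0-9.+-eE \t,]+$", first)
    tab <- tryCatch(
      utils::read.table(path, header = has_header,
                        sep = if (grepl(",", first)) "," else ""),
      error = function(e) stop("unparseable peak list ", path, ": ",
                               conditionMessage(e)))
    if (ncol(tab) < 2L)
      stop("peak-list TSV must have two columns (m/z, intensity): ", path)
    if (!is.numeric(tab[[1L]]) || !is.numeric(tab[[2L]]))
      stop("non-numeric peak values in ", path)
    return(peaklist(tab[[1L]], tab[[2L]], sample_id = sample_id))
  }
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading ", format, " requires the mzR package")
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hd <- mzR::header(ms, scan)
  if (!is.null(hd$centroided) && isFALSE(hd$centroided))
    stop("spectrum is profile mode; centroid it before loading ",
         "(no peak picking is implemented)")
  pk <- mzR::peaks(ms, scan)
  peaklist(pk[, 1L], pk[, 2L], sample_id = sample_id)
}

#' Write a peak list
#'
#' TSV always works; mzML needs the mzR package.
#'
#' @param pl A [peaklist()].
#' @param path Output file.
#' @param format `"tsv"` or `"mzml"`.
#' @export
write_peaklist <- function(pl, path, format = c("tsv", "mzml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(pl$peaks, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  n <- nrow(pl$peaks)
  hd <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = n, totIonCurrent = sum(pl$peaks$intensity),
    retentionTime = 0, basePeakMZ = pl$peaks$mz[which.max(pl$peaks$intensity)],
    basePeakIntensity = max(pl$peaks$intensity),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(pl$peaks$mz), highMZ = max(pl$peaks$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(list(as.matrix(pl$peaks)), path, header = hd)
  invisible(path)
}

#' Match observed peaks to theoretical m/z values
#'
#' Greedy nearest-neighbour one-to-one matching: candidate pairs within the
#' tolerance are accepted in order of increasing |delta m/z|, each observed
#' and theoretical peak used at most once.
#'
#' @param obs A [peaklist()] or numeric vector of observed m/z.
#' @param theo Numeric vector of theoretical m/z.
#' @param tolerance Maximum |delta m/z| in Da (> 0).
#' @return Data frame `obs_idx`, `theo_idx`, `delta_mz` (observed minus
#'   theoretical), ordered by `theo_idx`.
#' @export
match_peaks <- function(obs, theo, tolerance = 0.2) {
  if (!is.numeric(tolerance) || tolerance <= 0) stop("'tolerance' must be > 0")
  obs_mz <- if (inherits(obs, "peaklist")) obs$peaks$mz else as.numeric(obs)
  empty <- data.frame(obs_idx = integer(), theo_idx = integer(),
                      delta_mz = numeric())
  if (length(obs_mz) == 0L || length(theo) == 0L) return(empty)
  d <- outer(obs_mz, theo, "-")
  cand <- which(abs(d) <= tolerance, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(abs(d[cand])), , drop = FALSE]
  used_o <- logical(length(obs_mz)); used_t <- logical(length(theo))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    o <- cand[i, 1L]; t <- cand[i, 2L]
    if (!used_o[o] && !used_t[t]) {
      keep[i] <- TRUE; used_o[o] <- TRUE; used_t[t] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(obs_idx = cand[, 1L], theo_idx = cand[, 2L],
                    delta_mz = d[cand])
  out[order(out$theo_idx), , drop = FALSE]
}

#' Build a marker panel
#'
#' A marker panel maps each taxon to the m/z values of its diagnostic
#' peptides. Taxa whose panel markers cannot separate them (e.g. closely
#' related wallabies sharing every marker) are declared as ambiguity groups
#' and reported jointly.
#'
#' @param markers Named list: taxon -> numeric m/z vector.
#' @param ambiguity_groups List of character vectors of taxon ids; groups
#'   must be disjoint.
#' @return Object of class `marker_panel`.
#' @export
marker_panel <- function(markers, ambiguity_groups = list()) {
  if (!length(markers) || is.null(names(markers)))
    stop("'markers' must be a named list of m/z vectors")
  for (tx in names(markers))
    if (any(markers[[tx]] <= 0)) stop("non-positive marker m/z for ", tx)
  all_g <- unlist(ambiguity_groups)
  if (anyDuplicated(all_g)) stop("ambiguity groups must be disjoint")
  if (!all(all_g %in% names(markers)))
    stop("ambiguity group member missing from panel")
  structure(list(markers = markers, ambiguity_groups = ambiguity_groups),
            class = "marker_panel")
}

#' Read a marker panel from TSV
#'
#' Columns: `taxon`, `mz`, optional `peptide`, optional `group` (shared
#' non-empty label defines an ambiguity group).
#'
#' @param path TSV file.
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("taxon", "mz") %in% names(tab)))
    stop("panel TSV needs 'taxon' and 'mz' columns")
  markers <- split(tab$mz, tab$taxon)
  groups <- list()
  if ("group" %in% names(tab)) {
    g <- stats::na.omit(unique(tab$group[nzchar(tab$group)]))
    groups <- lapply(g, function(gg) unique(tab$taxon[tab$group %in% gg]))
  }
  marker_panel(markers, groups)
}

ambiguity_label <- function(group) paste(sort(group), collapse = "/")

#' Assign a taxon from a peak list and marker panel
#'
#' Scores each taxon by its count of matched panel markers. The unique
#' top-scoring taxon is assigned when its score reaches `min_markers` and
#' beats every taxon outside its ambiguity group; when the top scorers are
#' exactly (a subset of) one ambiguity group, the group label is returned;
#' anything else is `"indeterminate"`.
#'
#' @param obs A [peaklist()].
#' @param panel A [marker_panel()].
#' @param tolerance Matching tolerance in Da.
#' @param min_markers Minimum matched markers for a positive call.
#' @return One-row data frame: `sample_id`, `assignment`, `n_markers`,
#'   `best_taxon`, plus attribute `"scores"` (named per-taxon counts).
#' @export
classify_taxon <- function(obs, panel, tolerance = 0.2, min_markers = 2L) {
  if (!inherits(panel, "marker_panel")) stop("'panel' must be a marker_panel")
  if (tolerance <= 0) stop("'tolerance' must be > 0")
  scores <- vapply(panel$markers, function(mzs)
    nrow(match_peaks(obs, mzs, tolerance)), integer(1L))
  top <- max(scores)
  winners <- names(scores)[scores == top]
  assignment <- "indeterminate"
  if (top >= min_markers) {
    if (length(winners) == 1L) {
      # must also beat all taxa outside its own ambiguity group
      grp <- Filter(function(g) winners %in% g, panel$ambiguity_groups)
      outside <- setdiff(names(scores),
                         if (length(grp)) grp[[1L]] else winners)
      if (!length(outside) || top > max(scores[outside]))
        assignment <- winners
    } else {
      grp <- Filter(function(g) all(winners %in% g), panel$ambiguity_groups)
      if (length(grp) == 1L) assignment <- ambiguity_label(grp[[1L]])
    }
  }
  out <- data.frame(sample_id = obs$sample_id, assignment = assignment,
                    n_markers = top, best_taxon = winners[1L],
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}

#' Collagen preservation class from the high-mass region
#'
#' A spectrum is called `"good"` when the high-m/z region that taxonomically
#' informative collagen peptides occupy is populated: at least
#' `min_high_peaks` peaks above `high_mz_threshold` whose intensity reaches
#' `min_relative_intensity` of the base peak. Degraded samples lose exactly
#' these peaks first.
#'
#' @param obs A [peaklist()].
#' @param high_mz_threshold m/z cutoff (Da) for the "high" region.
#' @param min_high_peaks Minimum qualifying peaks.
#' @param min_relative_intensity Fraction of base-peak intensity required.
#' @return `"good"` or `"poor"`.
#' @export
preservation_class <- function(obs, high_mz_threshold = 2500,
                               min_high_peaks = 2L,
                               min_relative_intensity = 0.10) {
  if (high_mz_threshold <= 0 || min_high_peaks <= 0 ||
      min_relative_intensity <= 0)
    stop("thresholds must be positive")
  if (nrow(obs$peaks) == 0L) return("poor")
  base <- max(obs$peaks$intensity)
  if (base <= 0) return("poor")
  hi <- obs$peaks$mz > high_mz_threshold &
    obs$peaks$intensity >= min_relative_intensity * base
  if (sum(hi) >= min_high_peaks) "good" else "poor"
}

#' Deamidation index from the 1105/1106 peak pair
#'
#' Ratio of the intensity of the peak nearest the non-deamidated reference
#' m/z to that of the peak nearest the deamidated m/z. Lower values mean
#' more deamidation, i.e. more degraded collagen.
#'
#' @param obs A [peaklist()].
#' @param ref_mz Non-deamidated peptide m/z (default 1105.58).
#' @param deam_mz Deamidated peptide m/z (default 1106.56).
#' @param tolerance Peak lookup tolerance (Da).
#' @return The intensity ratio, or `NA` (with attribute `reason`) when either
#'   peak is absent within tolerance.
#' @export
deamidation_index <- function(obs, ref_mz = 1105.58, deam_mz = 1106.56,
                              tolerance = 0.2) {
  if (tolerance <= 0) stop("'tolerance' must be > 0")
  nearest <- function(target) {
    d <- abs(obs$peaks$mz - target)
    if (!length(d) || min(d) > tolerance) return(NA_real_)
    obs$peaks$intensity[which.min(d)]
  }
  iref <- nearest(ref_mz); idea <- nearest(deam_mz)
  if (is.na(iref) || is.na(idea))
    return(structure(NA_real_, reason = if (is.na(iref))
      "reference peak absent" else "deamidated peak absent"))
  iref / idea
}

#' Screen a batch of samples
#'
#' Runs taxon assignment, preservation classification and the deamidation
#' index over a list of peak lists; one sample's failure does not abort the
#' batch (it is logged and reported `"indeterminate"`).
#'
#' @param peaklists List of [peaklist()] objects.
#' @param panel A [marker_panel()].
#' @param tolerance,min_markers Passed to [classify_taxon()].
#' @param ... Passed to [preservation_class()].
#' @return Data frame, one row per sample: `sample_id`, `assignment`,
#'   `n_markers`, `preservation`, `deamidation_index`.
#' @export
screen_samples <- function(peaklists, panel, tolerance = 0.2,
                           min_markers = 2L, ...) {
  rows <- lapply(peaklists, function(pl) {
    r <- tryCatch({
      cls <- classify_taxon(pl, panel, tolerance, min_markers)
      data.frame(sample_id = pl$sample_id, assignment = cls$assignment,
                 n_markers = cls$n_markers,
                 preservation = preservation_class(pl, ...),
                 deamidation_index = as.numeric(deamidation_index(
                   pl, tolerance = tolerance)),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("sample ", pl$sample_id, " failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(sample_id = pl$sample_id, assignment = "indeterminate",
                 n_markers = 0L, preservation = "poor",
                 deamidation_index = NA_real_, stringsAsFactors = FALSE)
    })
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
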