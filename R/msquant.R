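# Kinetic-trapping MS quantitation: the control-peptide-normalised
# % reduction statistic per cysteine, with replicate mean/SD.

.PEAK_COLUMNS <- c("peptide_id", "cysteine_label", "sample", "replicate_id",
                   "precursor_area")
.SAMPLES <- c("control", "treated", "fully_reduced")

.validatePeakTable <- function(t) {
  miss <- setdiff(.PEAK_COLUMNS, names(t))
  if (length(miss)) {
    stop("peak table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!t$sample %in% .SAMPLES)
  if (length(bad)) {
    stop("invalid sample value in row(s) ", paste(bad, collapse = ", "),
         " (must be control, treated or fully_reduced)")
  }
  neg <- which(!is.finite(t$precursor_area) | t$precursor_area < 0)
  if (length(neg)) {
    stop("negative or non-numeric precursor_area in row(s) ",
         paste(neg, collapse = ", "))
  }
  key <- paste(t$peptide_id, t$sample, t$replicate_id, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicated (peptide, sample, replicate) key in row(s) ",
         paste(dup, collapse = ", "))
  }
  ctrl <- .isControlPeptide(t)
  if (!any(ctrl)) stop("peak table must contain at least one control peptide")
  if (!any(t$sample == "fully_reduced")) {
    stop("peak table must contain the fully_reduced reference sample")
  }
  invisible(t)
}

.isControlPeptide <- function(t) {
  is.na(t$cysteine_label) | t$cysteine_label == ""
}

#' Read a precursor peak-area table
#'
#' Expected columns: \code{peptide_id}, \code{cysteine_label} (empty for
#' control peptides), \code{sample} (control / treated / fully_reduced),
#' \code{replicate_id}, \code{precursor_area}. Validation rejects duplicate
#' keys, negative areas, missing controls and a missing fully-reduced
#' reference.
#'
#' @param path CSV or TSV file (by extension).
#' @return validated data.frame.
#' @export
readPeakTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t"
         else ","
  t <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  t$cysteine_label <- as.character(t$cysteine_label)
  .validatePeakTable(t)
  t
}

#' Write a peak-area table
#'
#' @param t a peak table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePeakTable <- function(t, path) {
  utils::write.csv(t, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.lookupArea <- function(t, peptide, sample, replicate) {
  i <- which(t$peptide_id == peptide & t$sample == sample &
             t$replicate_id == replicate)
  if (length(i) == 0) {
    stop("missing precursor area for peptide ", peptide, ", sample ",
         sample, ", replicate ", replicate)
  }
  t$precursor_area[i]
}

#' Percent reduction of one cysteine peptide in one replicate
#'
#' For each control peptide i the ratio of the cysteine peptide's area to
#' the control's area is formed in the target sample and in the
#' fully-reduced reference; the statistic is the mean over controls of the
#' ratio of those ratios, times 100. Control normalisation makes the value
#' invariant to any common scaling of one sample's areas.
#'
#' @param t a validated peak table.
#' @param cysPeptide peptide_id of the cysteine-containing peptide.
#' @param sample \code{"control"} or \code{"treated"}.
#' @param replicate replicate_id.
#' @return percent reduction (can exceed 100 in noisy data).
#' @export
percentReduction <- function(t, cysPeptide, sample, replicate) {
  .validatePeakTable(t)
  ctrlPeptides <- unique(t$peptide_id[.isControlPeptide(t)])
  aCys <- .lookupArea(t, cysPeptide, sample, replicate)
  aCys100 <- .lookupArea(t, cysPeptide, "fully_reduced", replicate)
  if (aCys100 <= 0) {
    stop("zero fully-reduced area for peptide ", cysPeptide)
  }
  vals <- vapply(ctrlPeptides, function(cp) {
    aCtrl <- .lookupArea(t, cp, sample, replicate)
    aCtrl100 <- .lookupArea(t, cp, "fully_reduced", replicate)
    if (aCtrl <= 0) stop("zero control area for peptide ", cp,
                         " in sample ", sample)
    if (aCtrl100 <= 0) stop("zero fully-reduced area for control peptide ",
                            cp)
    ((aCys / aCtrl) / (aCys100 / aCtrl100)) * 100
  }, numeric(1))
  mean(vals)
}

#' Replicate mean and SD of percent reduction for one cysteine
#'
#' Biological and technical replicates are pooled; the sample standard
#' deviation is reported (0 for a single replicate). Values above 100% are
#' reported as-is with a warning (noise can exceed the fully-reduced
#' reference).
#'
#' @param t a validated peak table.
#' @param cysPeptide peptide_id of the cysteine peptide.
#' @param sample \code{"control"} or \code{"treated"}.
#' @return list with \code{cysteineLabel}, \code{percentMean},
#'   \code{percentSd}, \code{nValues}.
#' @export
summarizeReplicates <- function(t, cysPeptide, sample) {
  .validatePeakTable(t)
  reps <- sort(unique(t$replicate_id[t$peptide_id == cysPeptide &
                                       t$sample == sample]))
  if (length(reps) == 0) {
    stop("no replicates for peptide ", cysPeptide, " in sample ", sample)
  }
  vals <- vapply(reps, function(r) {
    percentReduction(t, cysPeptide, sample, r)
  }, numeric(1))
  if (any(vals > 100)) {
    warning("percent reduction above 100% for ", cysPeptide,
            " (noise exceeding the fully-reduced reference); reported as-is")
  }
  lab <- unique(t$cysteine_label[t$peptide_id == cysPeptide])
  lab <- lab[!is.na(lab) & lab != ""]
  list(cysteineLabel = if (length(lab)) lab[1] else cysPeptide,
       percentMean = mean(vals),
       percentSd = if (length(vals) > 1) stats::sd(vals) else 0,
       nValues = length(vals))
}

#' Percent-reduction estimates for every cysteine peptide
#'
#' @param t a validated peak table.
#' @param sample \code{"control"} or \code{"treated"}.
#' @param residueOffset constant added to numeric cysteine labels in the
#'   output (mass-spectrometry numbering often includes a signal peptide,
#'   e.g. +19 for a 19-residue signal sequence); labels that are not
#'   numeric pass through unchanged.
#' @return data.frame with one row per cysteine peptide: cysteine label,
#'   mean, SD and replicate count.
#' @export
reductionTable <- function(t, sample = "treated", residueOffset = 0) {
  .validatePeakTable(t)
  cysPeptides <- unique(t$peptide_id[!.isControlPeptide(t)])
  rows <- lapply(cysPeptides, function(p) {
    est <- summarizeReplicates(t, p, sample)
    lab <- est$cysteineLabel
    num <- suppressWarnings(as.numeric(lab))
    if (!is.na(num) && residueOffset != 0) {
      lab <- as.character(num + residueOffset)
    }
    data.frame(peptide_id = p, cysteine = lab,
               percent_mean = est$percentMean, percent_sd = est$percentSd,
               n = est$nValues, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
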