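# Dsb enzyme abundance: direct extraction from proteomes and the
# synthesis-rate anchor method for the membrane enzymes DsbB and DsbD,
# which are systematically under-reported in proteomics datasets.

#' Uniprot accessions of the Dsb enzymes
#' @format Named character vector (enzyme -> accession).
#' @export
DSB_UNIPROT <- c(DsbA = "P0AEG4", DsbB = "P0A6M2", DsbC = "P0AEG6",
                 DsbD = "P36655", DsbG = "P77202")

#' Extract Dsb enzyme levels from a proteome
#'
#' Looks up the five Dsb enzymes by Uniprot accession and reports both
#' copies per cell and ppm. Enzymes absent from the proteome get `NA`
#' abundance and provenance `"missing"`.
#'
#' @param proteome A `quantitative_proteome`.
#' @param accessions Enzyme -> accession map (override for non-K12
#'   strains).
#' @return A `dsb_levels` data.frame: `enzyme`, `accession`, `copies`,
#'   `ppm`, `provenance`.
#' @export
extract_dsb_levels <- function(proteome, accessions = DSB_UNIPROT) {
  stopifnot(inherits(proteome, "quantitative_proteome"))
  ppm_all <- to_ppm(proteome$abundances)
  idx <- match(accessions, names(proteome$abundances))
  copies <- unname(proteome$abundances[idx])
  out <- data.frame(
    enzyme = names(accessions),
    accession = unname(accessions),
    copies = unname(copies),
    ppm = unname(ppm_all[idx]),
    provenance = ifelse(is.na(copies), "missing", "measured"),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("dsb_levels", class(out)),
            condition_label = proteome$condition_label)
}

#' Estimate membrane-enzyme abundance from synthesis rates
#'
#' Assumes the ratio between ribosome-footprint synthesis rate and
#' steady-state abundance is similar across the Dsb proteins: the ratio is
#' calibrated on soluble anchor enzymes (DsbA and DsbG by default, both
#' reliably quantified) and applied to the synthesis rates of the
#' membrane-bound DsbB and DsbD.
#'
#' @param synthesis Named numeric vector, enzyme name -> synthesis rate
#'   (arbitrary units).
#' @param levels A `dsb_levels` table with measured anchor abundances.
#' @param anchors Anchor enzyme names.
#' @param targets Enzymes to estimate.
#' @param method `"mean"` (arithmetic mean of per-anchor
#'   abundance/synthesis ratios), `"geometric"`, or `"regression"`
#'   (abundance regressed on synthesis through the origin).
#' @param overwrite_measured Replace already-measured target entries
#'   (default keeps measurements).
#' @return The `dsb_levels` table with estimated entries filled in
#'   (provenance `"estimated"`); the anchor set and ratio are attached as
#'   attributes. A warning flags anchor ratios spreading more than 3-fold.
#' @export
estimate_membrane_abundance <- function(synthesis, levels,
                                        anchors = c("DsbA", "DsbG"),
                                        targets = c("DsbB", "DsbD"),
                                        method = c("mean", "geometric", "regression"),
                                        overwrite_measured = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(levels, "dsb_levels"))
  if (any(synthesis < 0, na.rm = TRUE)) stop("synthesis rates must be >= 0")
  idx <- match(anchors, levels$enzyme)
  usable <- !is.na(idx) & !is.na(levels$copies[idx]) &
    anchors %in% names(synthesis) & synthesis[anchors] > 0
  if (!any(usable)) stop("no usable anchor: need measured abundance and a positive synthesis rate")
  a <- anchors[usable]
  ratios <- levels$copies[match(a, levels$enzyme)] / synthesis[a]
  if (length(ratios) > 1 && max(ratios) / min(ratios) >= 3) {
    warning("anchor abundance/synthesis ratios spread more than 3-fold; estimate is high-variance")
  }
  r <- switch(method,
    mean = mean(ratios),
    geometric = exp(mean(log(ratios))),
    regression = {
      x <- synthesis[a]; y <- levels$copies[match(a, levels$enzyme)]
      sum(x * y) / sum(x * x)
    })
  total <- sum(levels$copies / (levels$ppm / 1e6), na.rm = TRUE) /
    sum(!is.na(levels$copies))  # implied total proteome copies
  for (tg in targets) {
    i <- match(tg, levels$enzyme)
    if (is.na(i)) next
    if (levels$provenance[i] == "measured" && !overwrite_measured) next
    if (!tg %in% names(synthesis)) next
    levels$copies[i] <- r * synthesis[tg]
    levels$ppm[i] <- if (is.finite(total) && total > 0) 1e6 * levels$copies[i] / total else NA
    levels$provenance[i] <- "estimated"
  }
  attr(levels, "anchors") <- a
  attr(levels, "ratio") <- r
  levels
}

#' Summarise Dsb levels across datasets
#'
#' Descriptive statistics per enzyme over a panel of proteomes, the
#' tabular analogue of a concentration-range boxplot.
#'
#' @param levels_list List of `dsb_levels` tables.
#' @param value `"ppm"` or `"copies"`.
#' @return data.frame with per-enzyme `n`, `mean`, `median`, `min`, `max`.
#' @export
summarize_levels <- function(levels_list, value = c("ppm", "copies")) {
  value <- match.arg(value)
  if (inherits(levels_list, "dsb_levels")) levels_list <- list(levels_list)
  stopifnot(length(levels_list) >= 1)
  enzymes <- levels_list[[1]]$enzyme
  rows <- lapply(enzymes, function(e) {
    vals <- vapply(levels_list, function(l) l[[value]][match(e, l$enzyme)], 0.0)
    vals <- vals[!is.na(vals)]
    data.frame(enzyme = e, n = length(vals),
               mean = if (length(vals)) mean(vals) else NA_real_,
               median = if (length(vals)) median(vals) else NA_real_,
               min = if (length(vals)) min(vals) else NA_real_,
               max = if (length(vals)) max(vals) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a two-column synthesis-rate table
#' @param path TSV with header columns `enzyme` (or `protein_id`) and
#'   `synthesis_rate`.
#' @param sep Field separator.
#' @return Named numeric vector.
#' @export
read_synthesis_rates <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  id_col <- intersect(c("enzyme", "protein_id"), names(tab))[1]
  if (is.na(id_col) || !"synthesis_rate" %in% names(tab)) {
    stop("synthesis-rate table needs columns 'enzyme'/'protein_id' and 'synthesis_rate'")
  }
  setNames(as.numeric(tab$synthesis_rate), tab[[id_col]])
}

#' Convert a dsb_levels table to a named copies vector
#'
#' Convenience for handing enzyme levels to the kinetic model.
#' @param levels A `dsb_levels` table.
#' @return Named vector `c(DsbA=, DsbB=, DsbC=, DsbD=, DsbG=)` in copies
#'   per cell.
#' @export
dsb_copies <- function(levels) {
  stopifnot(inherits(levels, "dsb_levels"))
  setNames(levels$copies, levels$enzyme)
}
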