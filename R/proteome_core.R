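#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile cor rlnorm rbinom runif setNames approx
#' @importFrom utils read.delim write.table head
NULL

# Avogadro's number, mol^-1
AVOGADRO <- 6.02214076e23

# Cell-size regressions, um^3 per (h^-1): slope/intercept pairs and the
# growth-rate range over which each was calibrated.
CELL_GEOMETRY_VARIANTS <- list(
  coverage      = list(slope = 1.44, intercept = 1.90, range = c(0.1, 1.9)),
  concentration = list(slope = 1.83, intercept = 1.74, range = c(0.1, 1.0))
)

#' Construct a quantitative proteome
#'
#' A quantitative proteome is one growth condition's worth of absolute
#' protein quantification: a named vector of copies per cell plus the
#' metadata needed downstream (growth rate above all, since synthesis
#' rates are estimated from growth dilution).
#'
#' @param condition_label Condition name, e.g. `"glucose"`.
#' @param growth_rate Specific growth rate in h^-1, or `NA` if unreported.
#' @param abundances Named numeric vector, protein ID -> copies per cell.
#' @param strain,source_study Free-text provenance.
#' @return An object of class `quantitative_proteome`.
#' @export
quantitative_proteome <- function(condition_label, growth_rate, abundances,
                                  strain = NA_character_,
                                  source_study = NA_character_) {
  if (is.null(names(abundances)) || anyNA(names(abundances)) ||
      any(names(abundances) == "")) {
    stop("abundances must be a named vector of copies per cell")
  }
  if (anyDuplicated(names(abundances))) {
    stop("protein IDs must be unique within one proteome")
  }
  if (any(abundances < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  if (!is.na(growth_rate) && growth_rate <= 0) {
    stop("growth_rate must be positive when present")
  }
  structure(
    list(condition_label = condition_label,
         growth_rate = growth_rate,
         abundances = abundances,
         strain = strain,
         source_study = source_study),
    class = "quantitative_proteome"
  )
}

#' @export
print.quantitative_proteome <- function(x, ...) {
  cat("<quantitative_proteome> ", x$condition_label,
      " (mu = ", format(x$growth_rate), " h^-1, ",
      length(x$abundances), " proteins, ",
      format(sum(x$abundances), big.mark = ","), " copies/cell)\n", sep = "")
  invisible(x)
}

#' Estimate cell volume from growth rate
#'
#' E. coli cell volume varies linearly with growth rate. Two calibrations
#' are carried: `"coverage"` (valid 0.1-1.9 h^-1, used when judging
#' proteome coverage) and `"concentration"` (valid 0.1-1.0 h^-1, used when
#' converting reported concentrations to copies per cell).
#'
#' @param mu Growth rate, h^-1. Vectorised.
#' @param variant `"coverage"` or `"concentration"`.
#' @return Cell volume in um^3.
#' @examples
#' cell_size_from_growth_rate(0.5)                  # 2.62
#' cell_size_from_growth_rate(0.5, "concentration") # 2.655
#' @export
cell_size_from_growth_rate <- function(mu,
                                       variant = c("coverage", "concentration")) {
  variant <- match.arg(variant)
  if (any(mu < 0, na.rm = TRUE)) stop("growth rate must be non-negative")
  g <- CELL_GEOMETRY_VARIANTS[[variant]]
  out_of_range <- !is.na(mu) & (mu < g$range[1] | mu > g$range[2])
  if (any(out_of_range)) {
    warning(sprintf(
      "growth rate outside the %s calibration range [%.1f, %.1f] h^-1; extrapolating",
      variant, g$range[1], g$range[2]))
  }
  g$slope * mu + g$intercept
}

#' Convert copies per cell to molar concentration
#'
#' @param copies Protein copies per cell (vectorised).
#' @param volume_um3 Cell volume in um^3.
#' @param compartment_fraction Fraction of cell volume the molecules occupy
#'   (1 for whole-cell, ~0.2 for the periplasm).
#' @return Concentration in mol/L.
#' @examples
#' copies_to_concentration(4000, 2.5)      # ~2.66e-6 M whole-cell
#' copies_to_concentration(4000, 2.5, 0.2) # ~1.33e-5 M periplasmic
#' @export
copies_to_concentration <- function(copies, volume_um3,
                                    compartment_fraction = 1) {
  if (any(copies < 0)) stop("copies must be >= 0")
  if (volume_um3 <= 0) stop("cell volume must be positive")
  if (compartment_fraction <= 0 || compartment_fraction > 1) {
    stop("compartment_fraction must be in (0, 1]")
  }
  litres <- volume_um3 * 1e-15 * compartment_fraction
  copies / (AVOGADRO * litres)
}

#' Convert molar concentration to copies per cell
#'
#' Inverse of [copies_to_concentration()].
#' @inheritParams copies_to_concentration
#' @param conc Concentration in mol/L.
#' @export
concentration_to_copies <- function(conc, volume_um3,
                                    compartment_fraction = 1) {
  if (volume_um3 <= 0) stop("cell volume must be positive")
  conc * AVOGADRO * volume_um3 * 1e-15 * compartment_fraction
}

#' Express abundances as parts per million of total protein
#'
#' ppm here means protein copies per million total cellular protein
#' copies, the unit used for comparing Dsb enzyme levels across proteomes
#' of different depth.
#'
#' @param abundances Named numeric vector of copies per cell (or a
#'   `quantitative_proteome`).
#' @return Named numeric vector summing to 1e6.
#' @export
to_ppm <- function(abundances) {
  if (inherits(abundances, "quantitative_proteome")) {
    abundances <- abundances$abundances
  }
  if (length(abundances) == 0L || all(abundances == 0)) {
    stop("cannot normalise an empty or all-zero proteome")
  }
  if (any(abundances < 0)) stop("abundances must be >= 0")
  1e6 * abundances / sum(abundances)
}

#' Evaluate quantitative proteome coverage
#'
#' Compares the summed reported copies per cell against the theoretical
#' total cellular protein count implied by the condition's growth rate
#' (protein count scales with cell volume at an approximately constant
#' density). Proteomes covering less than half of the theoretical total
#' are flagged as failing and are excluded from kinetic modelling.
#'
#' @param proteome A `quantitative_proteome` with a reported growth rate.
#' @param density Total protein density, proteins per um^3. The default
#'   3e6 approximates published whole-cell protein-count calculations.
#' @return A one-row data.frame of class `coverage_report` with columns
#'   `condition_label`, `growth_rate`, `reported_total`,
#'   `theoretical_total`, `coverage`, `passes`.
#' @export
coverage_report <- function(proteome, density = 3e6) {
  stopifnot(inherits(proteome, "quantitative_proteome"))
  if (is.na(proteome$growth_rate)) {
    stop("proteome without a reported growth rate is excluded from coverage evaluation")
  }
  vol <- cell_size_from_growth_rate(proteome$growth_rate, "coverage")
  theoretical <- density * vol
  reported <- sum(proteome$abundances)
  out <- data.frame(
    condition_label = proteome$condition_label,
    growth_rate = proteome$growth_rate,
    reported_total = reported,
    theoretical_total = theoretical,
    coverage = reported / theoretical,
    passes = reported / theoretical >= 0.5,
    stringsAsFactors = FALSE
  )
  class(out) <- c("coverage_report", class(out))
  out
}

#' Read a quantitative proteome from a delimited table
#'
#' Expects a header row; the protein-ID and abundance columns are
#' identified by name (configurable), unknown columns are ignored.
#'
#' @param path File path (TSV by default).
#' @param condition_label,growth_rate,strain,source_study Metadata for the
#'   resulting proteome.
#' @param id_col,copies_col Column names holding the Uniprot ID and copies
#'   per cell.
#' @param sep Field separator.
#' @return A `quantitative_proteome`.
#' @export
read_proteome_table <- function(path, condition_label, growth_rate,
                                id_col = "protein_id",
                                copies_col = "copies_per_cell",
                                strain = NA_character_,
                                source_study = NA_character_,
                                sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing_cols <- setdiff(c(id_col, copies_col), names(tab))
  if (length(missing_cols)) {
    stop("proteome table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  quantitative_proteome(
    condition_label = condition_label,
    growth_rate = growth_rate,
    abundances = setNames(as.numeric(tab[[copies_col]]), tab[[id_col]]),
    strain = strain, source_study = source_study
  )
}

#' Write a proteome to a two-column TSV
#' @param proteome A `quantitative_proteome`.
#' @param path Output path.
#' @export
write_proteome_table <- function(proteome, path) {
  stopifnot(inherits(proteome, "quantitative_proteome"))
  tab <- data.frame(protein_id = names(proteome$abundances),
                    copies_per_cell = unname(proteome$abundances),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write coverage reports as TSV
#' @param reports A `coverage_report` or an rbind of several.
#' @param path Output path.
#' @export
write_coverage_report <- function(reports, path) {
  write.table(reports, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
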