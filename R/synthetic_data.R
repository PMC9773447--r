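# Synthetic study conditions: proteomes with log-normal abundance
# spectra, disulfide annotations with multi-source detection structure,
# and ground-truth kinetic conditions for parameter-recovery testing.
# Everything is a pure function of (spec, seed).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for synthetic study conditions
#'
#' Defaults emulate the measured E. coli ranges: Dsb enzyme levels at
#' their reported mean ppm, a log-normal protein abundance spectrum
#' summing to a growth-rate-dependent theoretical total, a disulfide
#' sub-proteome split roughly two-thirds category 1, and growth rates in
#' the 0.1-1.9 h^-1 window.
#'
#' @param seed Integer seed; fully determines all generated output.
#' @param growth_rate Growth rate, h^-1.
#' @param n_proteins Proteome size (distinct proteins).
#' @param sdlog Log-normal abundance spread (natural-log scale).
#' @param category_mix Fractions of disulfide proteins in cat1/cat2/cat3.
#' @param n_dsb_proteins Number of disulfide-bonded proteins.
#' @param dsb_fraction Fraction of total protein copies carried by the
#'   disulfide sub-proteome (default 2%, a periplasmic-scale share).
#' @param dsb_ppm Dsb enzyme target levels in ppm.
#' @param density Total protein density, proteins per um^3.
#' @param detection Pseudo-source detection model: logistic in log10
#'   abundance (`slope`, per-source `intercepts` at the median
#'   abundance).
#' @param truth_slack Multiple of the closed-form necessity estimates
#'   used for ground-truth rate constants.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1, growth_rate = 1.0, n_proteins = 1000,
                           sdlog = 2.0,
                           category_mix = c(cat1 = 2/3, cat2 = 0.23,
                                            cat3 = 1 - 2/3 - 0.23),
                           n_dsb_proteins = 80, dsb_fraction = 0.02,
                           dsb_ppm = c(DsbA = 696, DsbB = 139, DsbC = 144,
                                       DsbD = 29, DsbG = 27),
                           density = 3e6,
                           detection = list(slope = 1.5,
                                            intercepts = c(curated = 2,
                                                           ms_study_a = 1,
                                                           ms_study_b = 0.5)),
                           truth_slack = 6) {
  stopifnot(seed == as.integer(seed), growth_rate > 0,
            n_proteins > n_dsb_proteins, dsb_fraction > 0, dsb_fraction < 1)
  category_mix <- category_mix / sum(category_mix)
  structure(list(seed = as.integer(seed), growth_rate = growth_rate,
                 n_proteins = n_proteins, sdlog = sdlog,
                 category_mix = category_mix,
                 n_dsb_proteins = n_dsb_proteins,
                 dsb_fraction = dsb_fraction, dsb_ppm = dsb_ppm,
                 density = density, detection = detection,
                 truth_slack = truth_slack),
            class = "synthetic_spec")
}

#' Generate a synthetic quantitative proteome
#'
#' Draws log-normal abundances, rescales them so the total equals the
#' theoretical total protein count for the spec's growth rate, injects
#' the Dsb enzymes at their target ppm, and rescales a designated
#' disulfide sub-proteome to the spec's copy-number share. The IDs of the
#' disulfide sub-proteome are attached as attribute `"dsb_proteins"`.
#'
#' @param spec A `synthetic_spec`.
#' @return A `quantitative_proteome`.
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    total <- spec$density * cell_size_from_growth_rate(spec$growth_rate,
                                                       "coverage")
    ids <- sprintf("SYNP%04d", seq_len(spec$n_proteins))
    ab <- rlnorm(spec$n_proteins, meanlog = 0, sdlog = spec$sdlog)
    dsb_ids <- sort(sample(ids, spec$n_dsb_proteins))
    is_dsb <- ids %in% dsb_ids
    # budget: enzyme ppm first, then the disulfide share, rest is bulk
    enzyme_total <- sum(spec$dsb_ppm) / 1e6 * total
    dsb_total <- spec$dsb_fraction * total
    bulk_total <- total - enzyme_total - dsb_total
    ab[is_dsb] <- ab[is_dsb] * dsb_total / sum(ab[is_dsb])
    ab[!is_dsb] <- ab[!is_dsb] * bulk_total / sum(ab[!is_dsb])
    abundances <- c(setNames(ab, ids),
                    setNames(spec$dsb_ppm / 1e6 * total,
                             DSB_UNIPROT[names(spec$dsb_ppm)]))
    prot <- quantitative_proteome(
      condition_label = sprintf("synthetic_mu%.2f_seed%d", spec$growth_rate,
                                spec$seed),
      growth_rate = spec$growth_rate,
      abundances = abundances,
      strain = "synthetic", source_study = "dsbfold synthetic generator")
    attr(prot, "dsb_proteins") <- dsb_ids
    prot
  })
}

#' Generate synthetic disulfide annotations
#'
#' Assigns each disulfide protein a folding-difficulty category per the
#' spec's mix, lays out cysteine positions and bonds that realise that
#' category, and observes each bond with three pseudo-sources whose
#' detection probability rises logistically with protein abundance
#' (agreement between sources is better for highly expressed proteins).
#' A small fraction of proteins carry a second bond or an intermolecular
#' self-pairing.
#'
#' @param spec A `synthetic_spec`.
#' @param proteome The matching [generate_proteome()] output.
#' @return List: `bond_tables` (one data.frame per pseudo-source),
#'   `cys_table`, `location_table`, `truth` (per-protein category, bond
#'   count and location actually generated).
#' @export
generate_disulfide_annotations <- function(spec, proteome) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(proteome, "quantitative_proteome"))
  dsb_ids <- attr(proteome, "dsb_proteins")
  if (is.null(dsb_ids)) stop("proteome lacks the dsb_proteins attribute; not a generated proteome?")
  with_seed(spec$seed + 1L, {
    n <- length(dsb_ids)
    category <- sample(names(spec$category_mix), n, replace = TRUE,
                       prob = spec$category_mix)
    two_bonds <- runif(n) < 0.08
    self_extra <- runif(n) < 0.04
    location <- sample(c("secreted", "secreted outer membrane", "cytoplasmic"),
                       n, replace = TRUE, prob = c(0.80, 0.08, 0.12))
    bonds <- list(); cys_rows <- list(); truth_rows <- list()
    for (i in seq_len(n)) {
      id <- dsb_ids[i]
      len <- sample(100:600, 1)
      n_cys <- switch(category[i], cat1 = 2L, cat2 = 4L, cat3 = 3L)
      if (two_bonds[i] && category[i] != "cat1") n_cys <- n_cys + 2L
      cys <- sort(sample(seq_len(len), n_cys))
      b <- switch(category[i],
        cat1 = data.frame(cys_a = cys[1], cys_b = as.character(cys[2])),
        cat2 = data.frame(cys_a = cys[1], cys_b = as.character(cys[2])),
        cat3 = data.frame(cys_a = cys[1], cys_b = as.character(cys[3])))
      if (two_bonds[i] && category[i] != "cat1") {
        extra <- data.frame(cys_a = cys[n_cys - 1],
                            cys_b = as.character(cys[n_cys]))
        b <- rbind(b, extra)
      }
      if (self_extra[i] && category[i] == "cat1") {
        b <- rbind(b, data.frame(cys_a = cys[1], cys_b = "SELF"))
      }
      b$protein_id <- id
      bonds[[i]] <- b[, c("protein_id", "cys_a", "cys_b")]
      cys_rows[[i]] <- data.frame(protein_id = id,
                                  cys_positions = paste(cys, collapse = ","),
                                  stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(protein_id = id, category = category[i],
                                    n_bonds = nrow(b), location = location[i],
                                    stringsAsFactors = FALSE)
    }
    all_bonds <- do.call(rbind, bonds)
    cys_table <- do.call(rbind, cys_rows)
    truth <- do.call(rbind, truth_rows)
    # per-source detection: logistic in log10 copies, centred on the
    # median disulfide-protein abundance
    copies <- proteome$abundances[all_bonds$protein_id]
    centre <- log10(median(proteome$abundances[dsb_ids]))
    det <- spec$detection
    bond_tables <- lapply(names(det$intercepts), function(s) {
      p <- stats::plogis(det$intercepts[[s]] +
                           det$slope * (log10(copies) - centre))
      all_bonds[runif(nrow(all_bonds)) < p, , drop = FALSE]
    })
    names(bond_tables) <- names(det$intercepts)
    # locations for the rest of the proteome (bulk, mostly cytoplasmic)
    rest <- setdiff(names(proteome$abundances), dsb_ids)
    location_table <- rbind(
      data.frame(protein_id = dsb_ids, location = location,
                 stringsAsFactors = FALSE),
      data.frame(protein_id = rest,
                 location = sample(c("cytoplasmic", "inner membrane",
                                     "secreted"),
                                   length(rest), replace = TRUE,
                                   prob = c(0.85, 0.10, 0.05)),
                 stringsAsFactors = FALSE))
    list(bond_tables = bond_tables, cys_table = cys_table,
         location_table = location_table, truth = truth)
  })
}

#' Closed-form feasible rate constants for a condition
#'
#' Builds a generously feasible parameter set from quasi-steady-state
#' necessity estimates: each constant is the value that would exactly
#' exhaust its accumulation budget (0.5% of one doubling's synthesis),
#' multiplied by a slack factor. Used as ground truth in
#' parameter-recovery tests and as a sane starting point for manual
#' exploration.
#'
#' @param condition A `folding_condition`.
#' @param slack Slack multiplier (default 6).
#' @param f_futile,f_success,f_reduce Isomerase outcome fractions.
#' @return Named rate vector over the inferred parameters, capped at the
#'   condition's ceilings.
#' @export
heuristic_feasible_rates <- function(condition, slack = 6, f_futile = 1/3,
                                     f_success = 1/3, f_reduce = 1/3) {
  stopifnot(inherits(condition, "folding_condition"))
  v <- substrate_influx_rates(condition$demand, condition$mu, "minute")
  td <- 60 * log(2) / condition$mu
  e <- condition$enzymes
  A <- e[["DsbA"]]; B <- e[["DsbB"]]
  CG <- e[["DsbC"]] + e[["DsbG"]]; D <- e[["DsbD"]]
  p <- c(cat1 = 1, cat2 = 0.5, cat3 = 0)
  denom <- f_success + f_reduce
  J_ox <- v / pmax(1 - f_reduce * (1 - p) / denom, 1e-6)
  R678 <- (1 - p) * J_ox / denom
  J_red <- f_reduce * sum(R678)
  budget <- 0.005 * v * td
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  k45 <- slack * safe_div(J_ox, A * budget)
  k678 <- slack * safe_div(R678, CG * budget)
  k <- c(k2 = slack * sum(J_ox) / B,
         k3 = 2 * slack * sum(J_ox) / (A * B * (1 - 1 / slack)),
         k45.cat1 = k45[["cat1"]], k45.cat2 = k45[["cat2"]],
         k45.cat3 = k45[["cat3"]],
         k678.cat2 = k678[["cat2"]], k678.cat3 = k678[["cat3"]],
         k9 = 2 * slack * J_red / (CG * D * (1 - 1 / slack)),
         k10 = slack * J_red / D)
  pmin(k, rate_ceilings(condition))
}

#' Generate a ground-truth kinetic condition
#'
#' Runs the full synthetic pipeline (proteome, annotations, merging,
#' classification, periplasmic restriction, demand) and pairs the
#' resulting condition with ground-truth rate constants that are
#' verified feasible by simulation before being returned.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `condition` (a `folding_condition`), `truth` (named rate
#'   vector), `demand`, `enzymes` (`dsb_levels`), `proteome`,
#'   `annotations`.
#' @export
ground_truth_condition <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  proteome <- generate_proteome(spec)
  ann <- generate_disulfide_annotations(spec, proteome)
  records <- merge_bond_sources(ann$bond_tables)
  profiles <- disulfide_profiles(records, ann$cys_table, ann$location_table)
  peri <- periplasmic_subset(profiles)
  demand <- suppressMessages(folding_demand(peri, proteome))
  enzymes <- extract_dsb_levels(proteome)
  condition <- folding_condition(demand, enzymes, spec$growth_rate,
                                 total_protein = sum(proteome$abundances),
                                 condition_label = proteome$condition_label)
  truth <- heuristic_feasible_rates(condition, slack = spec$truth_slack)
  check <- check_feasibility(truth, condition)
  if (!check$feasible) {
    stop(sprintf("generated condition is infeasible under its own rates (binding: %s)",
                 check$binding))
  }
  list(condition = condition, truth = truth, demand = demand,
       enzymes = enzymes, proteome = proteome, annotations = ann)
}

#' Write a synthetic condition's tables to a directory
#'
#' Emits the same TSV schemas the package readers consume.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_condition <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteome <- generate_proteome(spec)
  ann <- generate_disulfide_annotations(spec, proteome)
  write_proteome_table(proteome, file.path(dir, "proteome.tsv"))
  for (s in names(ann$bond_tables)) {
    write.table(ann$bond_tables[[s]], file.path(dir, paste0("bonds_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(ann$cys_table, file.path(dir, "cysteines.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ann$location_table, file.path(dir, "locations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
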