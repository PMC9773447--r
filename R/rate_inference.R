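# Inference of minimal apparent enzyme rate constants per growth
# condition: the smallest mass-action constants for which the modelled
# Dsb system still keeps up with the disulfide demand of a doubling
# proteome.

INFER_PARAM_ORDER <- c("k2", "k3", "k45.cat1", "k45.cat2", "k45.cat3",
                       "k678.cat2", "k678.cat3", "k9", "k10")

#' Bundle one growth condition for kinetic analysis
#'
#' @param demand A `folding_demand` or named vector `c(cat1=,cat2=,cat3=)`
#'   of bonds per cell.
#' @param enzymes A `dsb_levels` table or named copies-per-cell vector
#'   covering DsbA, DsbB, DsbC, DsbD, DsbG.
#' @param mu Growth rate, h^-1.
#' @param total_protein Total protein copies per cell (needed for
#'   expressing recombinant capacity as a percent of total synthesis).
#' @param compartment_fraction Periplasmic volume fraction used for unit
#'   conversions.
#' @param condition_label Condition name.
#' @return A `folding_condition` object.
#' @export
folding_condition <- function(demand, enzymes, mu, total_protein = NULL,
                              compartment_fraction = 0.2,
                              condition_label = "condition") {
  if (inherits(demand, "folding_demand")) {
    condition_label <- attr(demand, "condition_label") %||% condition_label
    demand <- demand_vector(demand)
  }
  demand <- demand[c("cat1", "cat2", "cat3")]
  if (anyNA(demand) || any(demand < 0)) stop("demand must be non-negative for cat1..cat3")
  if (inherits(enzymes, "dsb_levels")) enzymes <- dsb_copies(enzymes)
  need <- c("DsbA", "DsbB", "DsbC", "DsbD", "DsbG")
  if (!all(need %in% names(enzymes)) || anyNA(enzymes[need])) {
    stop("enzymes must provide copies for ", paste(need, collapse = ", "))
  }
  stopifnot(mu > 0)
  structure(list(demand = demand, enzymes = enzymes[need], mu = mu,
                 total_protein = total_protein,
                 volume = cell_size_from_growth_rate(mu, "coverage"),
                 compartment_fraction = compartment_fraction,
                 condition_label = condition_label),
            class = "folding_condition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default biochemical ceilings for the rate search
#'
#' Association constants are capped at a diffusion-scale 1e6 M^-1 s^-1
#' (converted to model units with the condition's periplasmic volume);
#' the pseudo-first-order constants k2 and k10 at 1e3 min^-1.
#'
#' @param condition A `folding_condition`.
#' @param assoc_M_s,first_order Ceiling values to convert.
#' @return Named vector over the searched parameters.
#' @export
rate_ceilings <- function(condition, assoc_M_s = 1e6, first_order = 1e3) {
  ka <- assoc_to_model_units(assoc_M_s, condition$volume,
                             condition$compartment_fraction)
  c(k2 = first_order, k3 = ka,
    k45.cat1 = ka, k45.cat2 = ka, k45.cat3 = ka,
    k678.cat2 = ka, k678.cat3 = ka,
    k9 = ka, k10 = first_order)
}

#' Assemble model parameters from a named rate vector
#'
#' Pairs a rate vector (in the [rate_ceilings()] layout) with a
#' condition's growth-dilution synthesis rates to give a complete
#' `model_parameters` object.
#'
#' @param k Named rate vector (`k2`, `k3`, `k45.cat1..3`,
#'   `k678.cat2..3`, `k9`, `k10`).
#' @param condition A `folding_condition`.
#' @param f_futile,f_success,f_reduce Isomerase outcome fractions.
#' @return A `model_parameters` object.
#' @export
params_from_vector <- function(k, condition, f_futile = 1/3,
                               f_success = 1/3, f_reduce = 1/3) {
  v <- substrate_influx_rates(condition$demand, condition$mu, "minute")
  model_parameters(
    k2 = k[["k2"]], k3 = k[["k3"]],
    k45 = c(cat1 = k[["k45.cat1"]], cat2 = k[["k45.cat2"]],
            cat3 = k[["k45.cat3"]]),
    k678 = c(cat1 = 0, cat2 = k[["k678.cat2"]], cat3 = k[["k678.cat3"]]),
    k9 = k[["k9"]], k10 = k[["k10"]], v_syn = v,
    f_futile = f_futile, f_success = f_success, f_reduce = f_reduce)
}

params_to_vector <- function(params) {
  c(k2 = params$k2, k3 = params$k3,
    k45.cat1 = params$k45[["cat1"]], k45.cat2 = params$k45[["cat2"]],
    k45.cat3 = params$k45[["cat3"]],
    k678.cat2 = params$k678[["cat2"]], k678.cat3 = params$k678[["cat3"]],
    k9 = params$k9, k10 = params$k10)
}

# closed-form quasi-steady-state substrate pools used as warm start; caps
# at one doubling's cumulative synthesis keep degenerate (k ~ 0)
# candidates integrable
steady_substrate_estimate <- function(params, totals, td) {
  p <- params
  cats <- p$categories
  denom_frac <- p$f_success + p$f_reduce
  UF <- MFP <- setNames(numeric(length(cats)), cats)
  for (cc in cats) {
    v <- p$v_syn[[cc]]
    if (v == 0) next
    cap <- v * td
    recycle <- if (denom_frac > 0) p$f_reduce * (1 - p$p_correct[[cc]]) / denom_frac else 0
    J_ox <- v / max(1 - recycle, 1e-6)
    UF[cc] <- min(if (p$k45[[cc]] > 0) J_ox / (p$k45[[cc]] * totals[["A"]]) else cap, cap)
    if (p$p_correct[[cc]] < 1) {
      R678 <- if (denom_frac > 0) (1 - p$p_correct[[cc]]) * J_ox / denom_frac else 0
      MFP[cc] <- min(if (p$k678[[cc]] > 0) R678 / (p$k678[[cc]] * totals[["CG"]]) else cap, cap)
    }
  }
  list(UF = UF, MFP = MFP)
}

#' Check whether a parameter set sustains proteome doubling
#'
#' Simulates the condition over two reported doubling times starting from
#' quasi-steady-state substrate pools, then applies the two stopping
#' criteria: per-species accumulation (unprocessed fraction at one
#' doubling time) must stay at or below `accumulation_threshold`, and the
#' theoretical proteome doubling time must not exceed the reported one by
#' more than `doubling_slack`.
#'
#' @param k Named parameter vector (see [rate_ceilings()] for the names).
#' @param condition A `folding_condition`.
#' @param accumulation_threshold Maximum tolerated unprocessed fraction
#'   per substrate species (default 0.005, i.e. 0.5%).
#' @param doubling_slack Tolerated relative increase of the doubling time
#'   (default 0.05).
#' @param f_futile,f_success,f_reduce Isomerase outcome fractions.
#' @param n_out Trajectory grid size.
#' @return List: `feasible`, `accumulation` (per category),
#'   `doubling_time`, `reported_doubling`, `binding` (which constraint
#'   fails, or `"none"`), and the trajectory.
#' @export
check_feasibility <- function(k, condition, accumulation_threshold = 0.005,
                              doubling_slack = 0.05, f_futile = 1/3,
                              f_success = 1/3, f_reduce = 1/3, n_out = 61) {
  td <- 60 * log(2) / condition$mu
  params <- params_from_vector(k, condition, f_futile, f_success, f_reduce)
  totals <- c(A = condition$enzymes[["DsbA"]], B = condition$enzymes[["DsbB"]],
              CG = condition$enzymes[["DsbC"]] + condition$enzymes[["DsbG"]],
              D = condition$enzymes[["DsbD"]])
  warm <- steady_substrate_estimate(params, totals, td)
  init <- model_initial_state(condition$enzymes, categories = params$categories,
                              UF = warm$UF, MFP = warm$MFP)
  model <- build_model(params, init)
  traj <- tryCatch(simulate_folding(model, horizon = 2 * td, n_out = n_out),
                   error = function(e) NULL)
  if (is.null(traj)) {
    return(list(feasible = FALSE, accumulation = NULL, doubling_time = NA,
                reported_doubling = td, binding = "integration", traj = NULL))
  }
  acc <- accumulation_fraction(traj, at = td)
  tdbl <- proteome_doubling_time(traj, sum(condition$demand))
  acc_ok <- all(acc <= accumulation_threshold + 1e-12)
  dbl_ok <- tdbl <= (1 + doubling_slack) * td
  binding <- if (acc_ok && dbl_ok) "none"
             else if (!acc_ok) paste0("accumulation:", names(acc)[which.max(acc)])
             else "doubling_time"
  list(feasible = acc_ok && dbl_ok, accumulation = acc, doubling_time = tdbl,
       reported_doubling = td, binding = binding, traj = traj)
}

#' Infer minimal enzyme rate constants for a condition
#'
#' Two-stage deterministic search. Stage one gradually reduces each rate
#' constant on its own (all other constants held at their biochemical
#' ceilings), bisecting to the smallest value that still satisfies both
#' stopping criteria (accumulation and doubling time); this yields each
#' reaction's minimal required constant. Stage two restores joint
#' feasibility: a single slack multiplier on the stage-one minima is
#' bisected to the smallest value for which the full parameter set
#' passes both criteria simultaneously. The schedule is deterministic,
#' restart-stable and order-independent.
#'
#' @param condition A `folding_condition`.
#' @param ceilings Named ceiling vector; default [rate_ceilings()].
#' @param rel_tol Relative bisection tolerance (default 1%).
#' @inheritParams check_feasibility
#' @return A `model_parameters` object with attributes `k` (the named
#'   parameter vector), `k_independent` (stage-one minima), `slack`
#'   (stage-two multiplier), `feasibility` (final check), `n_sim`
#'   (simulations used) and `condition_label`.
#' @export
infer_minimal_rates <- function(condition, ceilings = NULL, rel_tol = 0.01,
                                accumulation_threshold = 0.005,
                                doubling_slack = 0.05,
                                f_futile = 1/3, f_success = 1/3,
                                f_reduce = 1/3) {
  stopifnot(inherits(condition, "folding_condition"))
  if (is.null(ceilings)) ceilings <- rate_ceilings(condition)
  ceilings <- ceilings[INFER_PARAM_ORDER]
  n_sim <- 0L
  feas <- function(k) {
    n_sim <<- n_sim + 1L
    check_feasibility(k, condition, accumulation_threshold, doubling_slack,
                      f_futile, f_success, f_reduce)$feasible
  }
  top <- check_feasibility(ceilings, condition, accumulation_threshold,
                           doubling_slack, f_futile, f_success, f_reduce)
  n_sim <- n_sim + 1L
  if (!top$feasible) {
    stop(sprintf(
      "condition '%s' is infeasible even at ceiling rates (binding constraint: %s)",
      condition$condition_label, top$binding))
  }
  # stage one: per-parameter minimum against the ceiling baseline
  L <- ceilings
  for (pn in INFER_PARAM_ORDER) {
    probe <- ceilings
    probe[[pn]] <- 0
    if (feas(probe)) {
      L[[pn]] <- 0
      next
    }
    lo <- 0; hi <- ceilings[[pn]]
    while (hi - lo > rel_tol * hi) {
      mid <- (lo + hi) / 2
      probe[[pn]] <- mid
      if (feas(probe)) hi <- mid else lo <- mid
    }
    L[[pn]] <- hi
  }
  # stage two: joint slack multiplier on the stage-one minima
  k_of <- function(lambda) pmin(lambda * L, ceilings)
  if (feas(k_of(1))) {
    lambda <- 1
  } else {
    pos <- L > 0
    lambda_max <- max(ceilings[pos] / L[pos])
    if (!feas(k_of(lambda_max))) {
      stop(sprintf(
        "condition '%s': joint feasibility not restorable within ceilings",
        condition$condition_label))
    }
    lo <- 1; hi <- lambda_max
    while (hi - lo > rel_tol * hi) {
      mid <- (lo + hi) / 2
      if (feas(k_of(mid))) hi <- mid else lo <- mid
    }
    lambda <- hi
  }
  k <- k_of(lambda)
  final <- check_feasibility(k, condition, accumulation_threshold,
                             doubling_slack, f_futile, f_success, f_reduce)
  n_sim <- n_sim + 1L
  params <- params_from_vector(k, condition, f_futile, f_success, f_reduce)
  attr(params, "k") <- k
  attr(params, "k_independent") <- L
  attr(params, "slack") <- lambda
  attr(params, "feasibility") <- final[c("feasible", "accumulation",
                                         "doubling_time", "reported_doubling",
                                         "binding")]
  attr(params, "n_sim") <- n_sim
  attr(params, "condition_label") <- condition$condition_label
  params
}

#' Pseudo-first-order rate from an association constant
#'
#' Multiplying an apparent association constant by the partner enzyme's
#' concentration gives the rate at which a substrate molecule is
#' processed, in the inverse time unit of the constant.
#'
#' @param k Association constant (conc^-1 time^-1); vectorised.
#' @param conc Enzyme concentration (same concentration unit).
#' @return Pseudo-first-order rate (time^-1).
#' @examples
#' pseudo_first_order(1e5, 5e-6)  # 0.5 s^-1 at 5 uM
#' @export
pseudo_first_order <- function(k, conc) {
  if (any(k < 0) || any(conc < 0)) stop("rates and concentrations must be >= 0")
  k * conc
}

#' Build one row of the per-condition rate table
#'
#' Converts inferred association constants into pseudo-first-order
#' substrate-processing rates by multiplying with the relevant enzyme
#' pools: DsbB for DsbA reoxidation (R3), DsbA for de novo oxidation
#' (R4/R5), the pooled DsbC+DsbG for isomerisation (R6-8). R2 is already
#' first-order.
#'
#' @param params Inferred `model_parameters`.
#' @param condition The matching `folding_condition`.
#' @return One-row data.frame with columns `condition_label`,
#'   `growth_rate`, `R2`, `R3`, `R4_cat1`, `R45_cat2`, `R5_cat3`,
#'   `R678_cat2`, `R678_cat3` (rates in min^-1).
#' @export
rate_table_row <- function(params, condition) {
  e <- condition$enzymes
  cg <- e[["DsbC"]] + e[["DsbG"]]
  data.frame(
    condition_label = condition$condition_label,
    growth_rate = condition$mu,
    R2 = params$k2,
    R3 = pseudo_first_order(params$k3, e[["DsbB"]]),
    R4_cat1 = pseudo_first_order(params$k45[["cat1"]], e[["DsbA"]]),
    R45_cat2 = pseudo_first_order(params$k45[["cat2"]], e[["DsbA"]]),
    R5_cat3 = pseudo_first_order(params$k45[["cat3"]], e[["DsbA"]]),
    R678_cat2 = pseudo_first_order(params$k678[["cat2"]], cg),
    R678_cat3 = pseudo_first_order(params$k678[["cat3"]], cg),
    stringsAsFactors = FALSE
  )
}

RATE_COLUMNS <- c("R2", "R3", "R4_cat1", "R45_cat2", "R5_cat3",
                  "R678_cat2", "R678_cat3")

#' Summarise a per-condition rate table
#'
#' Per rate column: the median (mean of the central order statistics for
#' even n), the fold range (max/min) and the inter-quartile fold (Q3/Q1,
#' linear-interpolation quartiles).
#'
#' @param table Rate table with the columns of [rate_table_row()].
#' @return data.frame with rows `median`, `fold_range`, `iqr_fold`.
#' @export
summarize_rate_table <- function(table) {
  cols <- intersect(RATE_COLUMNS, names(table))
  if (nrow(table) < 2) stop("need at least two conditions to summarise")
  stats <- vapply(cols, function(cl) {
    x <- table[[cl]]
    if (any(x <= 0 | is.na(x))) {
      stop("fold statistics undefined: non-positive entries in ", cl)
    }
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    c(median = median(x), fold_range = max(x) / min(x),
      iqr_fold = q[2] / q[1])
  }, c(median = 0, fold_range = 0, iqr_fold = 0))
  data.frame(statistic = c("median", "fold_range", "iqr_fold"),
             as.data.frame(stats)[, cols, drop = FALSE],
             row.names = NULL, check.names = FALSE)
}

#' Pearson correlation between growth rate and a rate column
#'
#' @param table Rate table (typically the chemostat subset, where growth
#'   rate is the controlled variable).
#' @param column Rate column name, e.g. `"R3"`.
#' @return Pearson product-moment correlation coefficient.
#' @export
correlate_with_growth_rate <- function(table, column = "R3") {
  if (!column %in% names(table)) stop("no column ", column)
  x <- table$growth_rate; y <- table[[column]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least three conditions with growth rates")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance: correlation undefined")
  cor(x, y, method = "pearson")
}

#' Published per-condition oxidative folding rates
#'
#' The bundled reference table of pseudo-first-order oxidative folding
#' rates (min^-1) across twenty E. coli growth conditions (four
#' chemostat dilution rates, high-growth, stress and sub-optimal batch
#' conditions), used for summary statistics and the growth-rate
#' correlation. Growth rates are recorded only for the chemostat rows,
#' where they are set by the dilution rate.
#'
#' @return data.frame in the [rate_table_row()] layout.
#' @export
reference_rate_table <- function() {
  path <- system.file("extdata", "reference_rates.tsv", package = "dsbfold",
                      mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a rate table with summary rows
#'
#' @param table Rate table.
#' @param path Output TSV path.
#' @param summary Append median / fold-range / IQR-fold rows.
#' @export
write_rate_table <- function(table, path, summary = TRUE) {
  out <- table
  if (summary) {
    s <- summarize_rate_table(table)
    pad <- data.frame(condition_label = c("Median", "Range (fold)",
                                          "Inter quartile range (fold)"),
                      growth_rate = NA_real_, stringsAsFactors = FALSE)
    out <- rbind(out, cbind(pad, s[, RATE_COLUMNS]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
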