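# Recombinant production capacity: how much extra disulfide-bonded
# substrate a condition can absorb before the host's own substrates start
# to accumulate. Enzyme levels and rate constants stay fixed (no
# regulatory adaptation); the recombinant protein is modelled as an extra
# substrate species carrying one disulfide bond of a chosen
# folding-difficulty category.

#' Maximum recombinant synthesis rate under an accumulation threshold
#'
#' Bisects the recombinant synthesis rate to the largest value for which
#' every native substrate species' accumulation fraction stays at or
#' below `threshold` (0.5% by default) after one doubling time. The
#' result is reported as a percent of the condition's overall protein
#' production rate mu * (total protein copies).
#'
#' @param condition A `folding_condition` with `total_protein` set.
#' @param params `model_parameters` for the condition (typically from
#'   [infer_minimal_rates()], or measured biochemical constants).
#' @param recombinant_category `"cat1"`, `"cat2"` or `"cat3"`: the
#'   folding difficulty of the recombinant disulfide.
#' @param threshold Accumulation threshold on native species.
#' @param include_recombinant Also hold the recombinant protein's own
#'   accumulation under the threshold (default `FALSE`: only host
#'   disulfides are monitored).
#' @param rel_tol Relative bisection tolerance.
#' @param upper_mult Upper search bound as a multiple of total native
#'   synthesis; if even that bound is feasible the result is capped and
#'   flagged.
#' @return One-row data.frame of class `capacity_result`:
#'   `condition_label`, `recombinant_category`, `max_synthesis_fraction`
#'   (percent), `threshold_used`, `flag` (`"ok"`, `"at_threshold"`, or
#'   `"capped"`).
#' @export
capacity_scan <- function(condition, params,
                          recombinant_category = c("cat1", "cat2", "cat3"),
                          threshold = 0.005, include_recombinant = FALSE,
                          rel_tol = 0.01, upper_mult = 10) {
  recombinant_category <- match.arg(recombinant_category)
  stopifnot(inherits(condition, "folding_condition"),
            inherits(params, "model_parameters"))
  if (is.null(condition$total_protein)) {
    stop("condition needs total_protein to express capacity as a synthesis percentage")
  }
  td <- 60 * log(2) / condition$mu
  v_native <- substrate_influx_rates(condition$demand, condition$mu, "minute")
  totals <- c(A = condition$enzymes[["DsbA"]], B = condition$enzymes[["DsbB"]],
              CG = condition$enzymes[["DsbC"]] + condition$enzymes[["DsbG"]],
              D = condition$enzymes[["DsbD"]])

  native_ok <- function(v_rec) {
    p_ext <- model_parameters(
      k2 = params$k2, k3 = params$k3,
      k45 = c(params$k45, rec = params$k45[[recombinant_category]]),
      k678 = c(params$k678, rec = params$k678[[recombinant_category]]),
      k9 = params$k9, k10 = params$k10,
      v_syn = c(v_native, rec = v_rec),
      p_correct = c(params$p_correct,
                    rec = params$p_correct[[recombinant_category]]),
      f_futile = params$f_futile, f_success = params$f_success,
      f_reduce = params$f_reduce)
    warm <- steady_substrate_estimate(p_ext, totals, td)
    init <- model_initial_state(condition$enzymes,
                                categories = p_ext$categories,
                                UF = warm$UF, MFP = warm$MFP)
    model <- build_model(p_ext, init)
    traj <- tryCatch(simulate_folding(model, horizon = 2 * td, n_out = 61),
                     error = function(e) NULL)
    if (is.null(traj)) return(FALSE)
    watched <- if (include_recombinant) p_ext$categories
               else setdiff(p_ext$categories, "rec")
    acc <- accumulation_fraction(traj, category = watched, at = td)
    all(acc <= threshold + 1e-12)
  }

  # percent of the overall protein production rate mu * total copies
  as_percent <- function(v_rec) {
    total_synth <- condition$mu / 60 * condition$total_protein
    100 * v_rec / total_synth
  }
  result <- function(frac, flag) {
    structure(data.frame(condition_label = condition$condition_label,
                         recombinant_category = recombinant_category,
                         max_synthesis_fraction = frac,
                         threshold_used = threshold, flag = flag,
                         stringsAsFactors = FALSE),
              class = c("capacity_result", "data.frame"))
  }

  if (!native_ok(0)) return(result(0, "at_threshold"))
  upper <- upper_mult * max(sum(v_native), 1e-6)
  if (native_ok(upper)) return(result(as_percent(upper), "capped"))
  lo <- 0; hi <- upper
  while (hi - lo > rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (native_ok(mid)) lo <- mid else hi <- mid
  }
  result(as_percent(lo), "ok")
}

#' Capacity grid over conditions and categories
#'
#' @param conditions List of `folding_condition` objects.
#' @param params_list Matching list of `model_parameters` (one per
#'   condition).
#' @param categories Recombinant difficulty categories to scan.
#' @param ... Passed to [capacity_scan()].
#' @return data.frame of capacity results; conditions whose scan fails
#'   are flagged `"infeasible"` rather than silently zero.
#' @export
capacity_table <- function(conditions, params_list,
                           categories = c("cat1", "cat2", "cat3"), ...) {
  stopifnot(length(conditions) == length(params_list))
  rows <- list()
  for (i in seq_along(conditions)) {
    for (cc in categories) {
      row <- tryCatch(
        capacity_scan(conditions[[i]], params_list[[i]], cc, ...),
        error = function(e) {
          data.frame(condition_label = conditions[[i]]$condition_label,
                     recombinant_category = cc,
                     max_synthesis_fraction = NA_real_,
                     threshold_used = NA_real_, flag = "infeasible",
                     stringsAsFactors = FALSE)
        })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a capacity grid as TSV
#' @param table Output of [capacity_table()].
#' @param path Output path.
#' @export
write_capacity_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
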