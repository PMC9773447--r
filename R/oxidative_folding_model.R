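# Mass-action ODE model of periplasmic oxidative folding.
#
# Substrates enter the periplasm unfolded (UF) and are oxidised by DsbAo
# into folded (FP) or misfolded (MFP) protein with a per-category success
# probability; DsbA is recycled by DsbB, DsbB by quinone. Misfolded
# substrate engages the isomerase pool DsbCG, whose turnovers split into
# successful isomerisation, futile cycles (no net change, but enzyme
# occupancy) and reduction back to UF; only the reduction branch oxidises
# the isomerase, which is then recycled by DsbD and ultimately
# thioredoxin. Quinone and thioredoxin are clamped boundary pools folded
# into the pseudo-first-order constants k2 and k10.
#
# Units: concentrations in molecules per cell, time in minutes.
# Association constants are per (molecule/cell) per minute; see
# assoc_to_model_units() for conversion from M^-1 s^-1.

#' Kinetic parameters of the oxidative folding model
#'
#' @param k2 DsbB reoxidation by quinone, pseudo-first-order, min^-1.
#' @param k3 DsbAr + DsbBo association, (molec/cell)^-1 min^-1.
#' @param k45 Named per-category substrate oxidation constants,
#'   (molec/cell)^-1 min^-1.
#' @param k678 Named per-category isomerase engagement constants,
#'   (molec/cell)^-1 min^-1 (categories with no isomerase need may be 0).
#' @param k9 DsbCGo + DsbDr association, (molec/cell)^-1 min^-1.
#' @param k10 DsbD reduction by thioredoxin, pseudo-first-order, min^-1.
#' @param v_syn Named per-category substrate synthesis rates,
#'   molecules/cell/min.
#' @param p_correct Named per-category probability that DsbA oxidation
#'   immediately yields the correct fold (1 for cat1, 0.5 for cat2, 0 for
#'   cat3).
#' @param f_futile,f_success,f_reduce Outcome fractions of isomerase
#'   turnovers (futile cycle / successful isomerisation / reduction back
#'   to UF); must sum to 1. Default 1/3 each.
#' @return A `model_parameters` list.
#' @export
model_parameters <- function(k2, k3, k45, k678, k9, k10, v_syn,
                             p_correct = c(cat1 = 1, cat2 = 0.5, cat3 = 0),
                             f_futile = 1/3, f_success = 1/3,
                             f_reduce = 1/3) {
  cats <- names(v_syn)
  if (is.null(cats)) stop("v_syn must be a named per-category vector")
  for (nm in c("k45", "k678", "p_correct")) {
    v <- get(nm)
    if (!all(cats %in% names(v))) {
      stop(nm, " must carry an entry for every category in v_syn")
    }
  }
  k45 <- k45[cats]; k678 <- k678[cats]; p_correct <- p_correct[cats]
  rates <- c(k2 = k2, k3 = k3, k45, k678, k9 = k9, k10 = k10, v_syn)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (any(p_correct < 0 | p_correct > 1)) stop("p_correct must be in [0, 1]")
  fr <- c(f_futile, f_success, f_reduce)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("f_futile + f_success + f_reduce must equal 1")
  }
  structure(list(categories = cats, k2 = k2, k3 = k3, k45 = k45,
                 k678 = k678, k9 = k9, k10 = k10, v_syn = v_syn,
                 p_correct = p_correct, f_futile = f_futile,
                 f_success = f_success, f_reduce = f_reduce),
            class = "model_parameters")
}

#' Initial state of the oxidative folding model
#'
#' @param enzymes Named vector of enzyme copies per cell:
#'   `c(DsbA=, DsbB=, DsbC=, DsbD=, DsbG=)` (DsbC and DsbG are pooled
#'   into a single isomerase moiety).
#' @param categories Substrate category names.
#' @param UF,MFP,FP Optional named per-category starting pools
#'   (molecules/cell); default 0.
#' @param oxidised_fraction Fraction of DsbA and DsbB starting oxidised
#'   and of DsbCG/DsbD starting reduced (active forms); default 1.
#' @return Named state vector over the full species set.
#' @export
model_initial_state <- function(enzymes, categories = c("cat1", "cat2", "cat3"),
                                UF = NULL, MFP = NULL, FP = NULL,
                                oxidised_fraction = 1) {
  need <- c("DsbA", "DsbB", "DsbC", "DsbD", "DsbG")
  if (!all(need %in% names(enzymes))) {
    stop("enzymes must name ", paste(need, collapse = ", "))
  }
  if (any(enzymes[need] < 0, na.rm = TRUE)) stop("enzyme copies must be >= 0")
  pool <- function(x) {
    v <- setNames(rep(0, length(categories)), categories)
    if (!is.null(x)) v[names(x)] <- x
    v
  }
  uf <- pool(UF); mfp <- pool(MFP); fp <- pool(FP)
  A <- enzymes[["DsbA"]]; B <- enzymes[["DsbB"]]
  CG <- enzymes[["DsbC"]] + enzymes[["DsbG"]]; D <- enzymes[["DsbD"]]
  of <- oxidised_fraction
  st <- c(setNames(uf, paste0("UF.", categories)),
          setNames(mfp, paste0("MFP.", categories)),
          setNames(fp, paste0("FP.", categories)),
          DsbAo = A * of, DsbAr = A * (1 - of),
          DsbBo = B * of, DsbBr = B * (1 - of),
          DsbCGr = CG * of, DsbCGo = CG * (1 - of),
          DsbDr = D * of, DsbDo = D * (1 - of))
  if (any(st < 0)) stop("state must be non-negative")
  st
}

#' Build the oxidative folding ODE model
#'
#' Assembles the mass-action right-hand side for the reaction scheme
#' R1-R10 over an arbitrary set of substrate categories. Each redox pair
#' (DsbAo/DsbAr, DsbBo/DsbBr, DsbCGr/DsbCGo, DsbDr/DsbDo) is a conserved
#' moiety: only the active form is integrated and the partner is derived
#' from the conserved total, so conservation holds exactly.
#'
#' @param params A `model_parameters` object.
#' @param initial A full named state vector from [model_initial_state()].
#' @return A `dsb_model` object (parameters, initial state, totals, and
#'   the flux map).
#' @export
build_model <- function(params, initial) {
  stopifnot(inherits(params, "model_parameters"))
  cats <- params$categories
  species <- c(paste0("UF.", cats), paste0("MFP.", cats), paste0("FP.", cats),
               "DsbAo", "DsbAr", "DsbBo", "DsbBr",
               "DsbCGr", "DsbCGo", "DsbDr", "DsbDo")
  if (!all(species %in% names(initial))) {
    stop("initial state is missing species: ",
         paste(setdiff(species, names(initial)), collapse = ", "))
  }
  if (any(initial[species] < 0)) stop("initial state must be non-negative")
  totals <- c(A = initial[["DsbAo"]] + initial[["DsbAr"]],
              B = initial[["DsbBo"]] + initial[["DsbBr"]],
              CG = initial[["DsbCGr"]] + initial[["DsbCGo"]],
              D = initial[["DsbDr"]] + initial[["DsbDo"]])
  structure(list(params = params, initial = initial[species],
                 species = species, categories = cats, totals = totals),
            class = "dsb_model")
}

#' @export
print.dsb_model <- function(x, ...) {
  cat("<dsb_model> categories:", paste(x$categories, collapse = ", "), "\n")
  cat("  enzyme totals (copies/cell): DsbA", format(x$totals[["A"]]),
      "DsbB", format(x$totals[["B"]]), "DsbCG", format(x$totals[["CG"]]),
      "DsbD", format(x$totals[["D"]]), "\n")
  cat("  v_syn (molec/cell/min):",
      paste(sprintf("%s=%.3g", x$categories, x$params$v_syn), collapse = " "), "\n")
  invisible(x)
}

# reaction fluxes given the reduced state (active enzyme forms + substrate
# pools); returns the per-reaction engagement rates
model_fluxes <- function(model, red) {
  p <- model$params
  cats <- model$categories
  Ao <- red[["DsbAo"]]; Bo <- red[["DsbBo"]]
  CGr <- red[["DsbCGr"]]; Dr <- red[["DsbDr"]]
  Ar <- model$totals[["A"]] - Ao
  Br <- model$totals[["B"]] - Bo
  CGo <- model$totals[["CG"]] - CGr
  Do <- model$totals[["D"]] - Dr
  UF <- red[paste0("UF.", cats)]
  MFP <- red[paste0("MFP.", cats)]
  c(setNames(p$v_syn, paste0("R1.", cats)),
    R2 = p$k2 * Br,
    R3 = p$k3 * Ar * Bo,
    setNames(p$k45 * UF * Ao, paste0("R45.", cats)),
    setNames(p$k678 * MFP * CGr, paste0("R678.", cats)),
    R9 = p$k9 * CGo * Dr,
    R10 = p$k10 * Do)
}

model_rhs <- function(model) {
  p <- model$params
  nc <- length(model$categories)
  iUF <- seq_len(nc); iMFP <- nc + iUF; iFP <- 2L * nc + iUF
  iAo <- 3L * nc + 1L; iBo <- iAo + 1L; iCGr <- iAo + 2L; iDr <- iAo + 3L
  Atot <- model$totals[["A"]]; Btot <- model$totals[["B"]]
  CGtot <- model$totals[["CG"]]; Dtot <- model$totals[["D"]]
  v <- as.numeric(p$v_syn); k45 <- as.numeric(p$k45)
  k678 <- as.numeric(p$k678); pc <- as.numeric(p$p_correct)
  fs <- p$f_success; fr <- p$f_reduce
  k2 <- p$k2; k3 <- p$k3; k9 <- p$k9; k10 <- p$k10
  function(t, y, parms) {
    Ao <- y[iAo]; Bo <- y[iBo]; CGr <- y[iCGr]; Dr <- y[iDr]
    J45 <- k45 * y[iUF] * Ao
    J678 <- k678 * y[iMFP] * CGr
    J2 <- k2 * (Btot - Bo)
    J3 <- k3 * (Atot - Ao) * Bo
    J9 <- k9 * (CGtot - CGr) * Dr
    J10 <- k10 * (Dtot - Dr)
    d <- numeric(3L * nc + 4L)
    d[iUF] <- v - J45 + fr * J678
    d[iMFP] <- (1 - pc) * J45 - (fs + fr) * J678
    d[iFP] <- pc * J45 + fs * J678
    d[iAo] <- J3 - sum(J45)
    d[iBo] <- J2 - J3
    d[iCGr] <- J9 - fr * sum(J678)
    d[iDr] <- J10 - J9
    list(d)
  }
}

# analytic Jacobian of the reduced-system RHS at state y (same
# coordinate order as model_rhs); exact, for Newton-based steady states
model_jacobian <- function(model, y) {
  p <- model$params
  nc <- length(model$categories)
  iUF <- seq_len(nc); iMFP <- nc + iUF; iFP <- 2L * nc + iUF
  iAo <- 3L * nc + 1L; iBo <- iAo + 1L; iCGr <- iAo + 2L; iDr <- iAo + 3L
  Atot <- model$totals[["A"]]; Btot <- model$totals[["B"]]
  CGtot <- model$totals[["CG"]]; Dtot <- model$totals[["D"]]
  Ao <- y[iAo]; Bo <- y[iBo]; CGr <- y[iCGr]; Dr <- y[iDr]
  fs <- p$f_success; fr <- p$f_reduce
  J <- matrix(0, 3L * nc + 4L, 3L * nc + 4L)
  for (c in seq_len(nc)) {
    a45 <- p$k45[[c]]; a678 <- p$k678[[c]]; pc <- p$p_correct[[c]]
    uf <- y[iUF[c]]; mfp <- y[iMFP[c]]
    J[iUF[c], iUF[c]] <- -a45 * Ao
    J[iUF[c], iAo] <- -a45 * uf
    J[iUF[c], iMFP[c]] <- fr * a678 * CGr
    J[iUF[c], iCGr] <- fr * a678 * mfp
    J[iMFP[c], iUF[c]] <- (1 - pc) * a45 * Ao
    J[iMFP[c], iAo] <- (1 - pc) * a45 * uf
    J[iMFP[c], iMFP[c]] <- -(fs + fr) * a678 * CGr
    J[iMFP[c], iCGr] <- -(fs + fr) * a678 * mfp
    J[iFP[c], iUF[c]] <- pc * a45 * Ao
    J[iFP[c], iAo] <- pc * a45 * uf
    J[iFP[c], iMFP[c]] <- fs * a678 * CGr
    J[iFP[c], iCGr] <- fs * a678 * mfp
    J[iAo, iUF[c]] <- -a45 * Ao
    J[iAo, iAo] <- J[iAo, iAo] - a45 * uf
    J[iCGr, iMFP[c]] <- -fr * a678 * CGr
    J[iCGr, iCGr] <- J[iCGr, iCGr] - fr * a678 * mfp
  }
  J[iAo, iAo] <- J[iAo, iAo] - p$k3 * Bo
  J[iAo, iBo] <- p$k3 * (Atot - Ao)
  J[iBo, iAo] <- p$k3 * Bo
  J[iBo, iBo] <- -p$k2 - p$k3 * (Atot - Ao)
  J[iCGr, iCGr] <- J[iCGr, iCGr] - p$k9 * Dr
  J[iCGr, iDr] <- p$k9 * (CGtot - CGr)
  J[iDr, iCGr] <- p$k9 * Dr
  J[iDr, iDr] <- -p$k10 - p$k9 * (CGtot - CGr)
  J
}

reduced_state <- function(model) {
  cats <- model$categories
  model$initial[c(paste0("UF.", cats), paste0("MFP.", cats),
                  paste0("FP.", cats), "DsbAo", "DsbBo", "DsbCGr", "DsbDr")]
}

#' Integrate the oxidative folding model
#'
#' Integrates with a stiff-capable solver (`deSolve::ode`, lsoda) and
#' reconstructs the full species set, per-reaction fluxes and moiety
#' totals along the trajectory.
#'
#' @param model A `dsb_model`.
#' @param horizon Simulation horizon in minutes.
#' @param n_out Number of saved time points (including t = 0).
#' @param rtol,atol Solver tolerances; `atol` defaults to 1e-9 times the
#'   largest initial concentration.
#' @return A `dsb_trajectory`: list with `time`, `state` (time x species
#'   matrix), `fluxes` (time x reaction matrix) and the model.
#' @export
simulate_folding <- function(model, horizon, n_out = 101,
                             rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(model, "dsb_model"), horizon > 0)
  if (is.null(atol)) atol <- 1e-9 * max(model$initial, 1)
  times <- seq(0, horizon, length.out = n_out)
  y0 <- reduced_state(model)
  sol <- deSolve::ode(y = y0, times = times, func = model_rhs(model),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (nrow(sol) < length(times)) {
    stop(sprintf("integration failed at t = %.3f min; last good state: %s",
                 sol[nrow(sol), 1],
                 paste(sprintf("%s=%.3g", colnames(sol)[-1],
                               sol[nrow(sol), -1]), collapse = " ")))
  }
  red <- sol[, -1, drop = FALSE]
  cats <- model$categories
  state <- cbind(red,
                 DsbAr = model$totals[["A"]] - red[, "DsbAo"],
                 DsbBr = model$totals[["B"]] - red[, "DsbBo"],
                 DsbCGo = model$totals[["CG"]] - red[, "DsbCGr"],
                 DsbDo = model$totals[["D"]] - red[, "DsbDr"])
  state <- state[, model$species, drop = FALSE]
  fluxes <- t(apply(red, 1, function(r) model_fluxes(model, r)))
  structure(list(time = times, state = state, fluxes = fluxes,
                 model = model),
            class = "dsb_trajectory")
}

#' @export
print.dsb_trajectory <- function(x, ...) {
  cat("<dsb_trajectory> ", length(x$time), " points over ",
      format(max(x$time)), " min, ", ncol(x$state), " species\n", sep = "")
  invisible(x)
}
#' Numerically converged steady state of the model
#'
#' At steady state every chain flux is pinned by the synthesis rates
#' (oxidation flux J_ox = v / (1 - f_reduce (1-p)/(f_success+f_reduce))
#' per category, with matching isomerase and electron-transfer fluxes),
#' so the state solves in closed form chain by chain. That analytic
#' state seeds a damped Newton polish (log-space, analytic Jacobian) of
#' the reduced system, which certifies the root numerically.
#'
#' @param model A `dsb_model` with at least one positive synthesis rate.
#' @param tol Convergence tolerance on the residual relative to total
#'   synthesis flux.
#' @return List with `state` (full species vector; the FP pools, which
#'   grow without bound, are reported as 0) and `fluxes` (per-reaction
#'   rates at the steady state).
#' @export
steady_state <- function(model, tol = 1e-12) {
  stopifnot(inherits(model, "dsb_model"))
  p <- model$params
  cats <- model$categories
  tot <- model$totals
  denom <- p$f_success + p$f_reduce
  v <- p$v_syn
  recycle <- if (denom > 0) p$f_reduce * (1 - p$p_correct) / denom else 0 * v
  if (any(recycle >= 1 & v > 0)) {
    stop("no steady state: the isomerase reduce branch returns all flux")
  }
  J_ox <- ifelse(v > 0, v / (1 - recycle), 0)
  R678 <- if (denom > 0) (1 - p$p_correct) * J_ox / denom else 0 * J_ox
  J_chain <- sum(J_ox)             # through DsbA/DsbB and the quinone
  J_red <- p$f_reduce * sum(R678)  # through DsbCG/DsbD and thioredoxin
  need <- function(flux, kk, pool, what) {
    if (flux == 0) return(0)
    if (kk <= 0) stop("no steady state: ", what, " has zero rate constant")
    x <- flux / kk
    if (x >= pool) stop("no steady state: ", what, " saturates its enzyme pool")
    x
  }
  Br <- need(J_chain, p$k2, tot[["B"]], "DsbB reoxidation")
  Bo <- tot[["B"]] - Br
  Ar <- need(J_chain, p$k3 * max(Bo, .Machine$double.xmin), tot[["A"]],
             "DsbA reoxidation")
  Ao <- tot[["A"]] - Ar
  Do <- need(J_red, p$k10, tot[["D"]], "DsbD reduction")
  Dr <- tot[["D"]] - Do
  CGo <- need(J_red, p$k9 * max(Dr, .Machine$double.xmin), tot[["CG"]],
              "isomerase recycling")
  CGr <- tot[["CG"]] - CGo
  UF <- vapply(seq_along(cats), function(i) {
    need(J_ox[i], p$k45[[i]] * Ao, Inf, paste0("oxidation of ", cats[i]))
  }, 0.0)
  MFP <- vapply(seq_along(cats), function(i) {
    need(R678[i], p$k678[[i]] * max(CGr, .Machine$double.xmin), Inf,
         paste0("isomerisation of ", cats[i]))
  }, 0.0)
  red_names <- c(paste0("UF.", cats), paste0("MFP.", cats),
                 paste0("FP.", cats), "DsbAo", "DsbBo", "DsbCGr", "DsbDr")
  y <- setNames(c(UF, MFP, numeric(length(cats)), Ao, Bo, CGr, Dr), red_names)
  # Newton polish of the analytic seed on the non-degenerate coordinates
  rhs <- model_rhs(model)
  f0 <- rhs(0, y, NULL)[[1]]
  free <- setdiff(seq_along(y), grep("^FP\\.", red_names))
  free <- free[!(abs(y[free]) < 1e-12 & abs(f0[free]) < 1e-12)]
  scale <- max(sum(v), 1)
  f_of <- function(x) {
    yy <- y; yy[free] <- x
    rhs(0, yy, NULL)[[1]][free]
  }
  x <- pmax(y[free], 1e-300)
  for (iter in 1:50) {
    f <- f_of(x)
    if (max(abs(f)) / scale < tol) break
    yy <- y; yy[free] <- x
    J <- model_jacobian(model, yy)[free, free, drop = FALSE]
    Ju <- sweep(J, 2, x, `*`)   # chain rule for u = log(x)
    du <- tryCatch(solve(Ju, -f), error = function(e) NULL)
    if (is.null(du)) break
    du <- pmin(pmax(du, -2), 2)
    lambda <- 1
    repeat {
      xnew <- x * exp(lambda * du)
      if (max(abs(f_of(xnew))) <= max(abs(f)) * (1 - 0.25 * lambda) + 1e-300) {
        x <- xnew
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) { x <- xnew; break }
    }
  }
  y[free] <- x
  fl <- model_fluxes(model, y)
  state <- c(y, DsbAr = tot[["A"]] - y[["DsbAo"]],
             DsbBr = tot[["B"]] - y[["DsbBo"]],
             DsbCGo = tot[["CG"]] - y[["DsbCGr"]],
             DsbDo = tot[["D"]] - y[["DsbDr"]])
  list(state = state[model$species], fluxes = fl)
}

#' Substrate influx rates from demand and growth rate
#'
#' At steady state, growth dilution sets the minimum synthesis rate
#' needed to maintain the proteome: v = mu * N for each category's
#' abundance-weighted disulfide pool N.
#'
#' @param demand A `folding_demand` (or a named per-category numeric
#'   vector of bonds per cell).
#' @param mu Growth rate, h^-1.
#' @param time_unit `"hour"` or `"minute"` for the returned rates.
#' @return Named per-category synthesis rates (bonds/cell per time unit).
#' @export
substrate_influx_rates <- function(demand, mu,
                                   time_unit = c("hour", "minute")) {
  time_unit <- match.arg(time_unit)
  stopifnot(mu > 0)
  n <- if (inherits(demand, "folding_demand")) demand_vector(demand) else demand
  v <- mu * n
  if (time_unit == "minute") v <- v / 60
  v
}

#' Fraction of synthesised substrate left unprocessed
#'
#' For each substrate category, the unfolded plus misfolded pool at the
#' evaluation time divided by the cumulative amount synthesised up to
#' that time. Zero-synthesis categories are defined as 0.
#'
#' @param traj A `dsb_trajectory`.
#' @param category Category name(s); default all.
#' @param at Evaluation time (minutes); default the trajectory horizon.
#' @return Named vector of accumulation fractions.
#' @export
accumulation_fraction <- function(traj, category = NULL, at = NULL) {
  stopifnot(inherits(traj, "dsb_trajectory"))
  cats <- traj$model$categories
  if (is.null(category)) category <- cats
  if (is.null(at)) at <- max(traj$time)
  v <- traj$model$params$v_syn
  vapply(category, function(cc) {
    if (v[[cc]] == 0) return(0)
    uf <- approx(traj$time, traj$state[, paste0("UF.", cc)], xout = at)$y
    mfp <- approx(traj$time, traj$state[, paste0("MFP.", cc)], xout = at)$y
    (uf + mfp) / (v[[cc]] * at)
  }, 0.0)
}

#' Theoretical proteome doubling time
#'
#' Time for cumulative correctly-folded output (summed over categories)
#' to reach one proteome-equivalent of disulfide demand. Under balanced
#' exponential growth the influx mu*N replaces ln(2)*N bonds per
#' generation, so one proteome-equivalent is defined as ln(2) times the
#' steady-state disulfide pool; with unconstrained enzymes the result is
#' the reported doubling time ln(2)/mu.
#'
#' @param traj A `dsb_trajectory`.
#' @param demand A `folding_demand` or total bonds per cell (numeric).
#' @return Doubling time in minutes, or `Inf` if the trajectory never
#'   produces a proteome-equivalent within its horizon.
#' @export
proteome_doubling_time <- function(traj, demand) {
  stopifnot(inherits(traj, "dsb_trajectory"))
  n_total <- if (inherits(demand, "folding_demand")) {
    sum(demand_vector(demand))
  } else sum(demand)
  if (n_total <= 0) stop("demand must be positive")
  fp_cols <- paste0("FP.", traj$model$categories)
  cum_fp <- rowSums(traj$state[, fp_cols, drop = FALSE]) -
    sum(traj$state[1, fp_cols])
  target <- log(2) * n_total
  if (max(cum_fp) < target) return(Inf)
  i <- which(cum_fp >= target)[1]
  if (i == 1L) return(0)
  # linear interpolation between bracketing grid points
  t0 <- traj$time[i - 1]; t1 <- traj$time[i]
  f0 <- cum_fp[i - 1]; f1 <- cum_fp[i]
  t0 + (target - f0) / (f1 - f0) * (t1 - t0)
}

#' Convert an association constant to model units
#'
#' Model concentrations are molecules per cell, so a bimolecular constant
#' in M^-1 s^-1 becomes per-(molecule/cell) per-minute by dividing by the
#' number of molecules per mole-per-litre in the reaction compartment.
#'
#' @param k_M_s Association constant, M^-1 s^-1.
#' @param volume_um3 Cell volume, um^3.
#' @param compartment_fraction Fraction of the cell volume hosting the
#'   reaction (default 0.2, the periplasm).
#' @return Constant in (molecules/cell)^-1 min^-1.
#' @export
assoc_to_model_units <- function(k_M_s, volume_um3,
                                 compartment_fraction = 0.2) {
  litres <- volume_um3 * 1e-15 * compartment_fraction
  k_M_s / (AVOGADRO * litres) * 60
}

#' @rdname assoc_to_model_units
#' @param k_model Constant in (molecules/cell)^-1 min^-1.
#' @export
assoc_from_model_units <- function(k_model, volume_um3,
                                   compartment_fraction = 0.2) {
  litres <- volume_um3 * 1e-15 * compartment_fraction
  k_model * AVOGADRO * litres / 60
}
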