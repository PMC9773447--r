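# Shared fixtures: small enzyme complements, parameter sets and an
# independent explicit-Euler integrator used as an oracle for the
# package's solver-based trajectories.

test_enzymes <- function(scale = 1) {
  c(DsbA = 7000, DsbB = 1400, DsbC = 1440, DsbD = 290, DsbG = 270) * scale
}

test_params <- function(v_syn = c(cat1 = 2000, cat2 = 800, cat3 = 300),
                        k45 = c(cat1 = 0.005, cat2 = 0.005, cat3 = 0.008),
                        k678 = c(cat1 = 0, cat2 = 0.02, cat3 = 0.05),
                        k2 = 5, k3 = 0.01, k9 = 0.01, k10 = 5, ...) {
  model_parameters(k2 = k2, k3 = k3, k45 = k45, k678 = k678,
                   k9 = k9, k10 = k10, v_syn = v_syn, ...)
}

test_proteome <- function(n = 50, total = 1e6, mu = 1.0, seed = 42,
                          label = "fixture") {
  set.seed(seed)
  ab <- rlnorm(n, meanlog = 0, sdlog = 1.5)
  ab <- ab * total / sum(ab)
  quantitative_proteome(label, mu,
                        setNames(ab, sprintf("FIXP%03d", seq_len(n))))
}

# explicit-Euler integration of the full (unreduced) reaction scheme,
# written directly from the reaction list, independent of the package's
# reduced-state right-hand side
euler_oracle <- function(params, init, horizon, dt = 1e-3) {
  cats <- params$categories
  y <- init
  t <- 0
  while (t < horizon - dt / 2) {
    d <- setNames(numeric(length(y)), names(y))
    for (cc in cats) {
      uf <- paste0("UF.", cc); mfp <- paste0("MFP.", cc); fp <- paste0("FP.", cc)
      # R1 synthesis
      d[uf] <- d[uf] + params$v_syn[[cc]]
      # R4/R5 oxidation by DsbAo
      J45 <- params$k45[[cc]] * y[uf] * y["DsbAo"]
      d[uf] <- d[uf] - J45
      d[fp] <- d[fp] + params$p_correct[[cc]] * J45
      d[mfp] <- d[mfp] + (1 - params$p_correct[[cc]]) * J45
      d["DsbAo"] <- d["DsbAo"] - J45
      d["DsbAr"] <- d["DsbAr"] + J45
      # R6/R7/R8 isomerase engagement
      J678 <- params$k678[[cc]] * y[mfp] * y["DsbCGr"]
      d[mfp] <- d[mfp] - (params$f_success + params$f_reduce) * J678
      d[fp] <- d[fp] + params$f_success * J678
      d[uf] <- d[uf] + params$f_reduce * J678
      d["DsbCGr"] <- d["DsbCGr"] - params$f_reduce * J678
      d["DsbCGo"] <- d["DsbCGo"] + params$f_reduce * J678
    }
    J3 <- params$k3 * y["DsbAr"] * y["DsbBo"]
    d["DsbAr"] <- d["DsbAr"] - J3; d["DsbAo"] <- d["DsbAo"] + J3
    d["DsbBo"] <- d["DsbBo"] - J3; d["DsbBr"] <- d["DsbBr"] + J3
    J2 <- params$k2 * y["DsbBr"]
    d["DsbBr"] <- d["DsbBr"] - J2; d["DsbBo"] <- d["DsbBo"] + J2
    J9 <- params$k9 * y["DsbCGo"] * y["DsbDr"]
    d["DsbCGo"] <- d["DsbCGo"] - J9; d["DsbCGr"] <- d["DsbCGr"] + J9
    d["DsbDr"] <- d["DsbDr"] - J9; d["DsbDo"] <- d["DsbDo"] + J9
    J10 <- params$k10 * y["DsbDo"]
    d["DsbDo"] <- d["DsbDo"] - J10; d["DsbDr"] <- d["DsbDr"] + J10
    y <- y + dt * d
    t <- t + dt
  }
  y
}
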