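test_that("parameter and state constructors enforce model invariants", {
  expect_error(test_params(f_futile = 0.5, f_success = 0.4, f_reduce = 0.4),
               "must equal 1")
  expect_error(test_params(k2 = -1), ">= 0")
  expect_error(model_parameters(k2 = 1, k3 = 1, k45 = c(cat1 = 1),
                                k678 = c(cat1 = 0), k9 = 1, k10 = 1,
                                v_syn = c(1)), "named")
  st <- model_initial_state(test_enzymes())
  expect_equal(st[["DsbAo"]], 7000)
  expect_equal(st[["DsbCGr"]], 1440 + 270)
  expect_error(model_initial_state(c(DsbA = 1)), "must name")
})

test_that("null dynamics hold a steady constant state", {
  p <- test_params(v_syn = c(cat1 = 0, cat2 = 0, cat3 = 0))
  m <- build_model(p, model_initial_state(test_enzymes()))
  tr <- simulate_folding(m, horizon = 50)
  expect_true(all(abs(sweep(tr$state, 2, tr$state[1, ])) < 1e-6))
})

test_that("a cat1-only influx never engages the isomerase branch", {
  p <- test_params(v_syn = c(cat1 = 2000, cat2 = 0, cat3 = 0))
  m <- build_model(p, model_initial_state(test_enzymes()))
  tr <- simulate_folding(m, horizon = 100)
  expect_true(all(abs(tr$state[, "MFP.cat1"]) < 1e-8))
  expect_true(all(abs(tr$fluxes[, c("R678.cat2", "R678.cat3", "R9", "R10")]) < 1e-6))
  expect_true(all(abs(tr$state[, "DsbCGr"] - tr$state[1, "DsbCGr"]) < 1e-6))
})

test_that("trajectories agree with an independent explicit-Euler oracle", {
  p <- test_params()
  init <- model_initial_state(test_enzymes(),
                              UF = c(cat1 = 500, cat2 = 300, cat3 = 200),
                              MFP = c(cat2 = 100, cat3 = 150))
  m <- build_model(p, init)
  horizon <- 2
  tr <- simulate_folding(m, horizon, n_out = 3, rtol = 1e-10)
  oracle <- euler_oracle(p, init, horizon, dt = 5e-4)
  got <- tr$state[3, m$species]
  want <- oracle[m$species]
  expect_equal(unname(got), unname(want), tolerance = 2e-3)
})

test_that("enzyme redox moieties are conserved on every trajectory", {
  set.seed(21)
  for (rep in 1:5) {
    p <- test_params(v_syn = c(cat1 = runif(1, 0, 3000),
                               cat2 = runif(1, 0, 1000),
                               cat3 = runif(1, 0, 500)),
                     k2 = runif(1, 0.5, 20), k3 = 10^runif(1, -3, -1.5))
    init <- model_initial_state(test_enzymes(), oxidised_fraction = runif(1, 0.5, 1))
    m <- build_model(p, init)
    tr <- simulate_folding(m, horizon = 200)
    pairs <- list(c("DsbAo", "DsbAr"), c("DsbBo", "DsbBr"),
                  c("DsbCGr", "DsbCGo"), c("DsbDr", "DsbDo"))
    for (pr in pairs) {
      tot <- rowSums(tr$state[, pr])
      expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
    }
    expect_true(all(tr$state > -1e-6))
  }
})

test_that("steady-state fluxes balance along the electron path", {
  p <- test_params()
  m <- build_model(p, model_initial_state(test_enzymes()))
  tr <- simulate_folding(m, horizon = 500, rtol = 1e-10)
  fl <- tr$fluxes[nrow(tr$fluxes), ]
  J45 <- sum(fl[paste0("R45.", c("cat1", "cat2", "cat3"))])
  J678 <- sum(fl[paste0("R678.", c("cat2", "cat3"))])
  # oxidation chain: quinone flux = DsbA reoxidation = substrate oxidation
  expect_equal(fl[["R2"]], fl[["R3"]], tolerance = 1e-6)
  expect_equal(fl[["R3"]], J45, tolerance = 1e-6)
  # isomerase reduction chain: reduce branch = DsbCG recycling = thioredoxin
  expect_equal(p$f_reduce * J678, fl[["R9"]], tolerance = 1e-6)
  expect_equal(fl[["R9"]], fl[["R10"]], tolerance = 1e-6)
})

test_that("the closed-form steady state agrees with the integrated limit", {
  p <- test_params()
  m <- build_model(p, model_initial_state(test_enzymes()))
  ss <- steady_state(m)
  tr <- simulate_folding(m, horizon = 2000, n_out = 11, rtol = 1e-10)
  final <- tr$state[11, ]
  keep <- setdiff(m$species, paste0("FP.", m$categories))
  expect_equal(unname(ss$state[keep]), unname(final[keep]), tolerance = 1e-6)
  # fluxes at the root balance to machine precision
  fl <- ss$fluxes
  expect_equal(fl[["R2"]], fl[["R3"]], tolerance = 1e-12)
  expect_equal(fl[["R9"]], fl[["R10"]], tolerance = 1e-12)
  # a chain that cannot carry its required flux has no steady state
  p_bad <- test_params(k2 = 1e-4)
  m_bad <- build_model(p_bad, model_initial_state(test_enzymes()))
  expect_error(steady_state(m_bad), "no steady state")
})

test_that("model output is invariant under category relabeling", {
  p1 <- test_params()
  swap <- c(cat3 = "cat1", cat2 = "cat2", cat1 = "cat3")
  relabel <- function(x) setNames(x[swap], names(swap))
  p2 <- model_parameters(k2 = p1$k2, k3 = p1$k3,
                         k45 = relabel(p1$k45), k678 = relabel(p1$k678),
                         k9 = p1$k9, k10 = p1$k10,
                         v_syn = relabel(p1$v_syn),
                         p_correct = relabel(p1$p_correct))
  init <- model_initial_state(test_enzymes())
  tr1 <- simulate_folding(build_model(p1, init), horizon = 60)
  tr2 <- simulate_folding(build_model(p2, init), horizon = 60)
  expect_equal(tr1$state[, "UF.cat3"], tr2$state[, "UF.cat1"], tolerance = 1e-8)
  expect_equal(tr1$state[, "FP.cat2"], tr2$state[, "FP.cat2"], tolerance = 1e-8)
  expect_equal(tr1$state[, "DsbAo"], tr2$state[, "DsbAo"], tolerance = 1e-8)
})

test_that("substrate influx is the growth-dilution balance", {
  d <- structure(data.frame(category = c("cat1", "cat2", "cat3", "cat4"),
                            bonds_per_cell = c(1000, 400, 100, 50),
                            protein_copies = c(1000, 200, 100, 50)),
                 class = c("folding_demand", "data.frame"))
  v <- substrate_influx_rates(d, mu = 0.6931)
  expect_equal(v[["cat1"]], 693.1)
  expect_equal(substrate_influx_rates(d, 2 * 0.6931), 2 * v)
  expect_equal(substrate_influx_rates(d, 0.6931, "minute"), v / 60)
  # cat4 (intermolecular) is excluded from kinetic demand
  expect_equal(names(v), c("cat1", "cat2", "cat3"))
  set.seed(8)
  nd <- c(cat1 = runif(1, 100, 1e4), cat2 = runif(1, 10, 1e3),
          cat3 = runif(1, 1, 500))
  expect_equal(substrate_influx_rates(nd, 0.77), 0.77 * nd)
})

test_that("accumulation fraction tracks the unprocessed pool", {
  # ample enzymes: essentially everything is folded promptly
  fast <- test_params(k45 = c(cat1 = 1, cat2 = 1, cat3 = 1),
                      k678 = c(cat1 = 0, cat2 = 1, cat3 = 1))
  m_fast <- build_model(fast, model_initial_state(test_enzymes()))
  tr_fast <- simulate_folding(m_fast, horizon = 100)
  expect_true(all(accumulation_fraction(tr_fast) < 1e-3))
  # absent enzymes: nothing is processed, fraction tends to one
  none <- test_params()
  m_none <- build_model(none, model_initial_state(test_enzymes(0)))
  tr_none <- simulate_folding(m_none, horizon = 100)
  expect_equal(unname(accumulation_fraction(tr_none)), c(1, 1, 1),
               tolerance = 1e-6)
  # zero-synthesis categories are defined as zero
  part <- test_params(v_syn = c(cat1 = 1000, cat2 = 0, cat3 = 0))
  tr_part <- simulate_folding(build_model(part, model_initial_state(test_enzymes())), 50)
  expect_equal(accumulation_fraction(tr_part)[["cat2"]], 0)
})

test_that("doubling time recovers ln(2)/mu with unconstrained enzymes", {
  mu <- 0.8
  n_total <- c(cat1 = 2e5, cat2 = 6e4, cat3 = 2e4)
  v <- substrate_influx_rates(n_total, mu, "minute")
  p <- test_params(v_syn = v, k45 = c(cat1 = 0.5, cat2 = 0.5, cat3 = 0.5),
                   k678 = c(cat1 = 0, cat2 = 0.5, cat3 = 0.5), k2 = 100,
                   k3 = 0.1, k9 = 0.1, k10 = 100)
  m <- build_model(p, model_initial_state(test_enzymes()))
  td <- 60 * log(2) / mu
  tr <- simulate_folding(m, horizon = 2 * td, n_out = 401)
  expect_equal(proteome_doubling_time(tr, sum(n_total)), td, tolerance = 0.01)
  # halving the oxidation constant below saturation slows doubling
  p_slow <- test_params(v_syn = v, k45 = c(cat1 = 5e-4, cat2 = 5e-4, cat3 = 5e-4),
                        k678 = c(cat1 = 0, cat2 = 0.5, cat3 = 0.5), k2 = 100,
                        k3 = 0.1, k9 = 0.1, k10 = 100)
  tr_slow <- simulate_folding(build_model(p_slow, model_initial_state(test_enzymes())),
                              2 * td, n_out = 401)
  expect_gt(proteome_doubling_time(tr_slow, sum(n_total)),
            proteome_doubling_time(tr, sum(n_total)))
  # zero influx never produces a proteome equivalent
  p0 <- test_params(v_syn = c(cat1 = 0, cat2 = 0, cat3 = 0))
  tr0 <- simulate_folding(build_model(p0, model_initial_state(test_enzymes())), 100)
  expect_equal(proteome_doubling_time(tr0, sum(n_total)), Inf)
})

test_that("unit conversion between molar and per-cell constants round-trips", {
  k <- assoc_to_model_units(1e6, 3.34, 0.2)
  expect_equal(assoc_from_model_units(k, 3.34, 0.2), 1e6)
  # smaller compartments make a molecule more concentrated, hence faster
  expect_gt(assoc_to_model_units(1e6, 3.34, 0.2),
            assoc_to_model_units(1e6, 3.34, 1.0))
})

test_that("SBML and reaction-list exports describe the full scheme", {
  skip_if_not_installed("xml2")
  p <- test_params()
  m <- build_model(p, model_initial_state(test_enzymes()))
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, path)
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "sbml")
  ns <- xml2::xml_ns(doc)
  species <- xml2::xml_find_all(doc, ".//d1:species", ns)
  expect_equal(length(species), length(m$species))
  reactions <- xml2::xml_find_all(doc, ".//d1:reaction", ns)
  expect_gt(length(reactions), 10)
  lines <- export_reaction_list(m)
  expect_true(any(grepl("quinone clamped", lines)))
  expect_true(any(grepl("futile", lines)))
})
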