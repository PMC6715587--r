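test_that("zero kinases keep every phospho pool at zero along the trajectory", {
  spec <- model_spec(kinases = kinase_inputs(0, 0, 0))
  tr <- integrate_model(spec, times = seq(0, 50, by = 10))
  phospho <- setdiff(species_names(), "PP1act")
  expect_true(all(abs(as.matrix(tr[, phospho])) < 1e-12))
  expect_true(all(tr$pmelt_tot < 1e-12))
  # PP1 docks onto its free RVSF site and settles at binding equilibrium
  expect_true(all(diff(tr$PP1act) >= -1e-6))
  expect_lt(max(abs(derivatives(
    stats::setNames(as.numeric(tr[nrow(tr), species_names()]), species_names()),
    spec))), 1e-6)
})

test_that("a single-time grid returns the initial state", {
  arrest <- steady_state(default_model())
  tr <- integrate_model(default_model(), initial = arrest, times = 0)
  expect_equal(as.numeric(tr[1, species_names()]), as.numeric(arrest),
               tolerance = 1e-10)
})

test_that("conservation holds along trajectories to within solver slack", {
  for (v in c("WT", "dPP2A")) {
    spec <- apply_variant(default_model(), v)
    arrest <- steady_state(spec)
    run <- spec
    run$kinases <- kinase_inputs(MPS1 = 0)
    tr <- integrate_model(run, initial = arrest, times = seq(0, 20, by = 1),
                          rtol = 1e-8, atol = 1e-10)
    eff <- resolve_spec(spec)
    for (i in seq_len(nrow(tr))) {
      st <- stats::setNames(as.numeric(tr[i, species_names()]), species_names())
      fr <- free_amounts(st, eff$totals)
      # reconstruct each total from state + free pool
      expect_equal(st[["PP1act"]] + fr[["PP1free"]], eff$totals[["PP1tot"]],
                   tolerance = 1e-7)
      expect_equal(st[["pNDC80"]] + fr[["NDC80free"]], eff$totals[["NDC80tot"]],
                   tolerance = 1e-7)
      expect_true(all(fr >= -1e-7 * 10))
    }
  }
})

test_that("integration is output-grid invariant", {
  arrest <- steady_state(default_model())
  run <- default_model()
  run$kinases <- kinase_inputs(MPS1 = 0)
  coarse <- integrate_model(run, initial = arrest, times = seq(0, 20, by = 2))
  fine <- integrate_model(run, initial = arrest, times = seq(0, 20, by = 1))
  shared <- match(coarse$time, fine$time)
  expect_lt(max(abs(coarse$pmelt_tot - fine$pmelt_tot[shared])), 1e-6)
})

test_that("steady states satisfy the residual contract for every variant", {
  for (v in c("WT", "dPP1", "dPP2A", "B56CD", "BUBR1_PP2A_fusion",
              "KNL1_PP2A")) {
    spec <- apply_variant(default_model(), v)
    ss <- steady_state(spec)
    expect_lt(attr(ss, "residual"), 1e-9)
    expect_true(all(ss >= 0))
    # feeding the state back into the RHS confirms the residual
    expect_lt(max(abs(derivatives(ss, spec))) / 10, 1e-9)
  }
})

test_that("the double knockout only accumulates phospho-MELT", {
  spec <- model_spec(totals = total_amounts(PP1tot = 0, PP2Atot = 0))
  tr <- integrate_model(spec, times = seq(0, 2000, length.out = 60))
  expect_true(all(diff(tr$pmelt_tot) > -1e-8))
  expect_equal(tr$pmelt_tot[nrow(tr)], 10, tolerance = 1e-3)
})

test_that("inhibition protocols behave as the silencing experiments", {
  wt <- inhibition_timecourse("WT", "MPS1i")
  expect_equal(wt$pmelt_norm[1], 1)
  expect_true(all(diff(wt$pmelt_tot) < 1e-8))   # monotone decay

  # no-phosphatase control: nothing changes when MPS1 is inhibited
  dko <- model_spec(totals = total_amounts(PP1tot = 0, PP2Atot = 0))
  tr <- inhibition_timecourse("WT", "MPS1i", spec = dko,
                              times = seq(0, 10, by = 1))
  expect_equal(tr$pmelt_tot, rep(tr$pmelt_tot[1], nrow(tr)), tolerance = 1e-6)

  expect_error(inhibition_timecourse("WT", "nope"), "MPS1i")
})

test_that("dose-response is monotone in MPS1 and hits its limits", {
  grid <- 10^seq(-2, 1, length.out = 8)
  dr <- dose_response("WT", mps1_grid = grid)
  expect_true(all(diff(dr$pmelt_tot_ss) > -1e-8))

  # no MELT kinase and no Aurora B: PP1 fully recruited, signal collapses
  low <- dose_response("WT", mps1_grid = c(1e-4, 2e-4), aurb = 0)
  expect_lt(low$pmelt_tot_ss[1] / 10, 0.01)

  # without phosphatases every dose saturates the MELTs
  dko <- model_spec(totals = total_amounts(PP1tot = 0, PP2Atot = 0))
  sat <- dose_response("WT", mps1_grid = c(0.01, 1), spec = dko)
  expect_equal(sat$pmelt_tot_ss, c(10, 10), tolerance = 1e-4)

  expect_error(dose_response("WT", mps1_grid = c(1, 0.5)), "increasing")
})

test_that("log-log sensitivity recovers flat and power-law slopes", {
  fake <- function(x, y) {
    d <- data.frame(MPS1 = x, pmelt_tot_ss = y)
    class(d) <- c("kp_doseresponse", "data.frame")
    d
  }
  x <- 10^seq(-1, 1, length.out = 9)
  expect_true(all(abs(sensitivity(fake(x, rep(3, 9)))$slope) < 1e-12))
  expect_equal(sensitivity(fake(x, 5 * x))$slope, rep(1, 7), tolerance = 1e-10)
  expect_error(sensitivity(fake(x, c(rep(1, 8), 0))), "non-positive")
})

test_that("removing feedback lowers arrest phospho-MELT in the expected order", {
  pm <- function(v) {
    spec <- apply_variant(default_model(), v)
    pmelt_total(steady_state(spec), clamp = resolve_spec(spec)$clamp)
  }
  wt <- pm("WT"); fus <- pm("BUBR1_PP2A_fusion"); knl <- pm("KNL1_PP2A")
  expect_gte(wt, fus)
  expect_gte(fus, knl)
})

test_that("Aurora B inhibition steepens the MPS1 dose-response", {
  grid <- 10^seq(-1.5, 0.5, length.out = 9)
  s_wt <- sensitivity(dose_response("WT", mps1_grid = grid, aurb = 1))
  s_ai <- sensitivity(dose_response("WT", mps1_grid = grid, aurb = 0))
  mid <- 3:5
  expect_true(all(s_ai$slope[mid] > s_wt$slope[mid]))
})

test_that("phosphatase knockouts cross-regulate in opposite directions", {
  cr <- cross_regulation()
  get <- function(v, col) cr[cr$variant == v, col]
  expect_equal(get("dPP1", "PP1act"), 0)
  expect_equal(get("dPP2A", "PP2Aact"), 0, tolerance = 1e-12)
  expect_lt(get("dPP2A", "PP1act"), get("WT", "PP1act"))
  expect_gt(get("dPP1", "PP2Aact"), get("WT", "PP2Aact"))
})

test_that("a dead B56 accumulates on kinetochores above wild type", {
  wt <- steady_state(default_model())
  cd <- steady_state(apply_variant(default_model(), "B56CD"))
  expect_gt(cd[["PP2Aact"]], wt[["PP2Aact"]])
})

test_that("NDC80 phosphorylation is differentially elevated in the knockouts", {
  nd <- pndc80_readout()
  get <- function(v) nd[nd$variant == v, "pNDC80_norm"]
  expect_equal(get("WT"), 1)
  expect_gt(get("dPP2A"), get("dPP1"))
  expect_gte(get("dPP1"), get("WT"))

  # with no phosphatase at all the NDC80 pool saturates
  dko <- model_spec(totals = total_amounts(PP1tot = 0, PP2Atot = 0))
  ss <- steady_state(dko)
  expect_equal(ss[["pNDC80"]], 1, tolerance = 1e-6)
})
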