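test_that("default model carries the fitted constants and standard amounts", {
  m <- default_model()
  expect_identical(unname(m$params[c("kbPP1", "kdPP1", "kbPP2A", "kdPP2A",
                                     "kbBUBR1", "kdBUBR1", "kpBUBR1",
                                     "kpBUBR1_free", "kdpBUBR1", "kpMELT",
                                     "kdpMELT", "kpRVSF", "kdpRVSF")]),
                   c(0.13, 0.20, 0.32, 1.86, 0.18, 14.21, 0.076, 0.0076,
                     3.35, 0.37, 0.70, 72.91, 11.95))
  expect_identical(unname(m$totals),  c(10, 10, 10, 10, 1, 1))
  expect_identical(unname(m$kinases), c(1, 1, 1))
  expect_identical(m$variant$label, "WT")
  # the unconstrained NDC80 pair mirrors the RVSF pair
  expect_identical(m$params[["kpNDC80"]], m$params[["kpRVSF"]])
  expect_identical(m$params[["kdpNDC80"]], m$params[["kdpRVSF"]])
  expect_error(parameter_set(nope = 1), "unknown parameter")
  expect_error(total_amounts(PP1tot = -1), "negative")
})

test_that("conservation closures give the free pools", {
  tt <- total_amounts()
  fr0 <- free_amounts(network_state(), tt)
  expect_equal(fr0[["PP1free"]], 10)
  expect_equal(fr0[["RVSFfree"]], 1)
  expect_equal(fr0[["MELTfree"]], 10)

  st <- network_state(PP2Aact = 2, pBUBR1_PP2A = 1)
  expect_equal(free_amounts(st, tt)[["PP2Afree"]], 7)

  st <- network_state(pMELT = 3, pMELT_BUBR1 = 2, pMELT_pBUBR1 = 1, PP2Aact = 1)
  expect_equal(free_amounts(st, tt)[["MELTfree"]], 3)

  # negative values are reported, not masked
  st <- network_state(pRVSF = 1, PP1act = 0.5)
  expect_lt(free_amounts(st, tt)[["RVSFfree"]], 0)

  # a clamped PP2Aact occupies nothing
  st <- network_state(PP2Aact = 1, pMELT = 2)
  expect_equal(free_amounts(st, tt, clamp = 1)[["MELTfree"]], 8)
  expect_equal(free_amounts(st, tt, clamp = 1)[["PP2Afree"]], 10)
})

test_that("pmelt_total sums every phospho-MELT species", {
  expect_equal(pmelt_total(network_state()), 0)
  st <- network_state(pMELT = 2, pMELT_BUBR1 = 1, pMELT_pBUBR1 = 1,
                      PP2Aact = 0.5)
  expect_equal(pmelt_total(st), 4.5)
  # clamped PP2Aact contains no phospho-MELT unless asked for
  expect_equal(pmelt_total(st, clamp = 0.5), 4.0)
  expect_equal(pmelt_total(st, clamp = 0.5, include_clamp = TRUE), 4.5)
})

test_that("derivatives match hand evaluation at the origin", {
  d <- derivatives(network_state(), default_model())
  expect_equal(d[["pMELT"]], 0.37 * 10 * 1)   # kpMELT * MELTtot * MPS1
  expect_equal(d[["pRVSF"]], 72.91 * 1 * 1)   # kpRVSF * RVSFtot * AurB
  expect_equal(d[["pNDC80"]], 72.91)
  expect_equal(d[["PP1act"]], 0.13 * 1 * 10)  # kbPP1 * RVSFfree * PP1free
  expect_equal(d[["PP2Aact"]], 0)
})

test_that("zero kinases leave every phosphorylation state exactly at rest", {
  spec <- model_spec(kinases = kinase_inputs(0, 0, 0))
  d <- derivatives(network_state(), spec)
  # no kinase, no phosphorylation: every phospho species has zero flux; the
  # only motion is kinase-independent PP1 docking onto free RVSF
  phospho <- setdiff(species_names(), "PP1act")
  expect_identical(unname(d[phospho]), rep(0, 8))
  expect_equal(d[["PP1act"]], 0.13 * 1 * 10)
  # the PP1-docking equilibrium completes the exact zero-kinase fixed point
  pp1_eq <- uniroot(function(x) 0.13 * (1 - x) * (10 - x) - 0.2 * x,
                    c(0, 1), tol = 1e-12)$root
  expect_lt(max(abs(derivatives(network_state(PP1act = pp1_eq), spec))), 1e-8)
})

test_that("without phosphatases no dephosphorylation flux exists", {
  spec <- model_spec(totals = total_amounts(PP1tot = 0, PP2Atot = 0))
  set.seed(42)
  for (i in 1:20) {
    st <- random_state(spec$totals)
    st[["PP1act"]] <- 0; st[["PP2Aact"]] <- 0
    st[["pBUBR1_PP2A"]] <- 0
    d <- derivatives(st, spec)
    fr <- free_amounts(st, spec$totals)
    expect_equal(d[["pRVSF"]], 72.91 * fr[["RVSFfree"]] * 1)
    expect_gte(d[["pRVSF"]], 0)
    expect_gte(d[["pNDC80"]], 0)
  }
})

test_that("non-finite states are rejected as solver divergence", {
  st <- network_state()
  st[["pMELT"]] <- NaN
  expect_error(derivatives(st, default_model()), "non-finite")
})

test_that("right-hand side agrees with the reaction-list oracle", {
  variants <- c("WT", "dPP1", "dPP2A", "B56CD", "BUBR1_PP2A_fusion",
                "KNL1_PP2A")
  set.seed(7)
  for (v in variants) {
    spec <- apply_variant(default_model(), v)
    tt <- resolve_spec(spec)$totals
    for (i in 1:25) {
      st <- random_state(tt)
      expect_lt(max(rel_err(derivatives(st, spec), oracle_derivatives(st, spec))),
                1e-12)
    }
  }
})

test_that("a catalytically dead PP2A contributes no dephosphorylation flux", {
  spec <- apply_variant(default_model(), "B56CD")
  set.seed(11)
  st1 <- random_state()
  st2 <- st1
  st2[["PP2Aact"]] <- st1[["PP2Aact"]] + 0.5
  d1 <- derivatives(st1, spec)
  d2 <- derivatives(st2, spec)
  # pRVSF / pNDC80 see PP2Aact only through catalysis, which is off
  expect_identical(d1[["pRVSF"]], d2[["pRVSF"]])
  expect_identical(d1[["pNDC80"]], d2[["pNDC80"]])
  # and the dephosphorylation term of free pMELT is PP1-only: isolate it by
  # also switching PP1act and checking the flux changes exactly as PP1 alone
  st3 <- st1; st3[["PP1act"]] <- st1[["PP1act"]] + 0.25
  dm <- derivatives(st3, spec)[["pMELT"]] - d1[["pMELT"]]
  p <- spec$params
  expect_equal(dm, -p[["kdpMELT"]] * st1[["pMELT"]] * 0.25, tolerance = 1e-10)
})

test_that("variants implement the declared perturbations and only those", {
  expect_equal(make_variant("dPP2A")$totals_overrides[["PP2Atot"]], 0)
  expect_equal(make_variant("dPP1")$totals_overrides[["PP1tot"]], 0)
  expect_equal(make_variant("KNL1_PP2A")$clamped_PP2Aact, 1)
  expect_true(make_variant("B56CD")$catalytically_dead_pp2a)
  fus <- make_variant("BUBR1_PP2A_fusion")$param_overrides
  expect_equal(unname(fus[c("kpBUBR1", "kpBUBR1_free", "kbPP2A")]),
               rep(1e4, 3))
  expect_equal(unname(fus[c("kdpBUBR1", "kdPP2A")]), c(0, 0))

  # WT is the identity
  wt <- resolve_spec(apply_variant(default_model(), "WT"))
  base <- resolve_spec(default_model())
  expect_identical(wt$params, base$params)
  expect_identical(wt$totals, base$totals)

  expect_error(make_variant("nope"), "valid variants.*WT.*dPP1")
})
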