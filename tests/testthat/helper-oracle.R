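# Independent reaction-list oracle for the ODE right-hand side.
#
# The network is enumerated reaction by reaction (binding, dissociation,
# phosphorylation, dephosphorylation) with explicit stoichiometries, and the
# derivative of each species is the stoichiometry-weighted sum of reaction
# fluxes.  This is a deliberately different construction from the package's
# transcription of the nine rate equations.

oracle_derivatives <- function(state, spec) {
  eff <- kinetophos::resolve_spec(spec)
  p <- eff$params; tt <- eff$totals; k <- eff$kinases
  clamped <- !is.na(eff$clamp)
  s <- as.list(state)
  if (clamped) s$PP2Aact <- eff$clamp

  cplx_pp2a <- if (clamped) 0 else s$PP2Aact   # PP2Aact as complex in closures
  free <- list(
    PP1 = tt[["PP1tot"]] - s$PP1act,
    PP2A = tt[["PP2Atot"]] - cplx_pp2a - s$pBUBR1_PP2A,
    BUBR1 = tt[["BUBR1tot"]] - s$pBUBR1free - s$pMELT_BUBR1 -
      s$pMELT_pBUBR1 - s$pBUBR1_PP2A - cplx_pp2a,
    MELT = tt[["MELTtot"]] - s$pMELT - s$pMELT_BUBR1 - s$pMELT_pBUBR1 -
      cplx_pp2a,
    RVSF = tt[["RVSFtot"]] - s$pRVSF - s$PP1act,
    NDC80 = tt[["NDC80tot"]] - s$pNDC80)

  act <- if (eff$dead_pp2a) s$PP1act else s$PP1act + s$PP2Aact

  rxn <- list(
    list(v = p[["kbPP1"]] * free$RVSF * free$PP1,        d = c(PP1act = 1)),
    list(v = p[["kdPP1"]] * s$PP1act,                    d = c(PP1act = -1)),
    list(v = p[["kbPP2A"]] * s$pMELT_pBUBR1 * free$PP2A,
         d = c(PP2Aact = 1, pMELT_pBUBR1 = -1)),
    list(v = p[["kdPP2A"]] * s$PP2Aact,
         d = c(PP2Aact = -1, pMELT_pBUBR1 = 1)),
    list(v = p[["kbBUBR1"]] * s$pBUBR1_PP2A * s$pMELT,
         d = c(PP2Aact = 1, pBUBR1_PP2A = -1, pMELT = -1)),
    list(v = p[["kdBUBR1"]] * s$PP2Aact,
         d = c(PP2Aact = -1, pMELT = 1, pBUBR1_PP2A = 1)),
    list(v = p[["kbPP2A"]] * s$pBUBR1free * free$PP2A,
         d = c(pBUBR1free = -1, pBUBR1_PP2A = 1)),
    list(v = p[["kdPP2A"]] * s$pBUBR1_PP2A,
         d = c(pBUBR1_PP2A = -1, pBUBR1free = 1)),
    list(v = p[["kpBUBR1_free"]] * free$BUBR1 * k[["CDK1"]],
         d = c(pBUBR1free = 1)),
    list(v = p[["kbBUBR1"]] * s$pBUBR1free * s$pMELT,
         d = c(pBUBR1free = -1, pMELT = -1, pMELT_pBUBR1 = 1)),
    list(v = p[["kdBUBR1"]] * s$pMELT_pBUBR1,
         d = c(pMELT_pBUBR1 = -1, pMELT = 1, pBUBR1free = 1)),
    list(v = p[["kbBUBR1"]] * free$BUBR1 * s$pMELT,
         d = c(pMELT = -1, pMELT_BUBR1 = 1)),
    list(v = p[["kdBUBR1"]] * s$pMELT_BUBR1,
         d = c(pMELT_BUBR1 = -1, pMELT = 1)),
    list(v = p[["kpMELT"]] * free$MELT * k[["MPS1"]],    d = c(pMELT = 1)),
    list(v = p[["kdpMELT"]] * s$pMELT * act,             d = c(pMELT = -1)),
    list(v = p[["kpBUBR1"]] * s$pMELT_BUBR1 * k[["CDK1"]],
         d = c(pMELT_BUBR1 = -1, pMELT_pBUBR1 = 1)),
    list(v = p[["kdpBUBR1"]] * s$pMELT_pBUBR1 * act,
         d = c(pMELT_pBUBR1 = -1, pMELT_BUBR1 = 1)),
    list(v = p[["kpRVSF"]] * free$RVSF * k[["AurB"]],    d = c(pRVSF = 1)),
    list(v = p[["kdpRVSF"]] * s$pRVSF * act,             d = c(pRVSF = -1)),
    list(v = p[["kpNDC80"]] * free$NDC80 * k[["AurB"]],  d = c(pNDC80 = 1)),
    list(v = p[["kdpNDC80"]] * s$pNDC80 * act,           d = c(pNDC80 = -1))
  )
  if (clamped) {
    # an exogenous clamped activity is not a complex: no binding/dissociation
    # reactions touch it (3:6), and its own derivative is zero
    rxn <- rxn[-(3:6)]
  }
  d <- stats::setNames(numeric(9), kinetophos::species_names())
  for (r in rxn) d[names(r$d)] <- d[names(r$d)] + r$d * r$v
  if (clamped) d[["PP2Aact"]] <- 0
  d
}

# Random non-negative state respecting the conservation closures.
random_state <- function(totals = kinetophos::total_amounts()) {
  repeat {
    st <- kinetophos::network_state()
    st[["PP1act"]] <- stats::runif(1, 0, min(totals[["RVSFtot"]], totals[["PP1tot"]]))
    st[["pRVSF"]] <- stats::runif(1, 0, totals[["RVSFtot"]] - st[["PP1act"]])
    st[["PP2Aact"]] <- stats::runif(1, 0, min(1, totals[["PP2Atot"]]))
    st[["pBUBR1_PP2A"]] <- stats::runif(1, 0, min(2, max(totals[["PP2Atot"]] -
                                                           st[["PP2Aact"]], 0)))
    m <- stats::runif(3)
    m <- m / sum(m) * stats::runif(1, 0, max(totals[["MELTtot"]] - st[["PP2Aact"]], 0))
    st[["pMELT"]] <- m[1]; st[["pMELT_BUBR1"]] <- m[2]; st[["pMELT_pBUBR1"]] <- m[3]
    st[["pBUBR1free"]] <- stats::runif(1, 0, 3)
    st[["pNDC80"]] <- stats::runif(1, 0, totals[["NDC80tot"]])
    fr <- kinetophos::free_amounts(st, totals)
    if (all(fr >= 0)) return(st)
  }
}

rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(a), abs(b), 1)
}
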