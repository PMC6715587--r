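## Canonical name sets -------------------------------------------------------

#' Names of the nine dynamic species
#'
#' The model integrates nine species: active (KNL1-docked) PP1 and PP2A-B56,
#' free phospho-BUBR1, the pBUBR1:PP2A pre-complex, free phospho-MELT, the
#' MELT-bound BUB complexes (pMELT:BUBR1 and pMELT:pBUBR1) and the two Aurora B
#' substrate pools pRVSF and pNDC80.  `PP2Aact` denotes the full
#' pMELT:pBUBR1:PP2A complex, the only form in which PP2A is catalytically
#' active at the kinetochore.
#'
#' @return Character vector of length 9.
#' @export
species_names <- function() {
  c("PP1act", "PP2Aact", "pBUBR1free", "pBUBR1_PP2A",
    "pMELT", "pMELT_BUBR1", "pMELT_pBUBR1", "pRVSF", "pNDC80")
}

#' Names of the rate constants
#'
#' `kb`/`kd` are binding/dissociation rates, `kp`/`kdp` phosphorylation/
#' dephosphorylation rates for each target (PP1, PP2A, BUBR1, MELT, RVSF,
#' NDC80).  `kpBUBR1_free` is the slower CDK1 phosphorylation of BUBR1 when it
#' is not docked on phospho-MELT.  All rates are dimensionless, matching the
#' model's arbitrary-unit convention.
#'
#' @return Character vector of length 15.
#' @export
parameter_names <- function() {
  c("kbPP1", "kdPP1", "kbPP2A", "kdPP2A", "kbBUBR1", "kdBUBR1",
    "kpBUBR1", "kpBUBR1_free", "kdpBUBR1", "kpMELT", "kdpMELT",
    "kpRVSF", "kdpRVSF", "kpNDC80", "kdpNDC80")
}

total_names <- function() {
  c("PP1tot", "PP2Atot", "MELTtot", "BUBR1tot", "RVSFtot", "NDC80tot")
}

kinase_names <- function() c("MPS1", "AurB", "CDK1")

check_named_nonneg <- function(x, nms, what) {
  if (!is.numeric(x) || is.null(names(x)) || !setequal(names(x), nms))
    stop(what, " must be a named numeric vector with names: ",
         paste(nms, collapse = ", "), call. = FALSE)
  x <- x[nms]
  if (any(!is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  if (any(x < 0)) stop(what, " contains negative values", call. = FALSE)
  x
}

## Constructors ---------------------------------------------------------------

#' Rate-constant set
#'
#' Constructs a full, validated set of the 15 rate constants from the default
#' (fitted) values plus any overrides.  `kpNDC80`/`kdpNDC80` default to
#' `kpRVSF`/`kdpRVSF`: both pRVSF and pNDC80 are Aurora B sites erased by the
#' same pooled phosphatase activity, and pNDC80 feeds back on nothing, so this
#' choice only rescales the pNDC80 readout (which is reported WT-normalised).
#'
#' @param ... Named overrides, e.g. `kpMELT = 0.5`.
#' @return Named numeric vector of length 15.
#' @export
#' @examples
#' parameter_set()["kbPP1"]    # 0.13
#' parameter_set(kpMELT = 1)["kpMELT"]
parameter_set <- function(...) {
  p <- c(kbPP1 = 0.13, kdPP1 = 0.20, kbPP2A = 0.32, kdPP2A = 1.86,
         kbBUBR1 = 0.18, kdBUBR1 = 14.21, kpBUBR1 = 0.076,
         kpBUBR1_free = 0.0076, kdpBUBR1 = 3.35, kpMELT = 0.37,
         kdpMELT = 0.70, kpRVSF = 72.91, kdpRVSF = 11.95,
         kpNDC80 = NA_real_, kdpNDC80 = NA_real_)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), parameter_names())
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(ov)] <- ov
  }
  if (is.na(p[["kpNDC80"]]))  p[["kpNDC80"]]  <- p[["kpRVSF"]]
  if (is.na(p[["kdpNDC80"]])) p[["kdpNDC80"]] <- p[["kdpRVSF"]]
  check_named_nonneg(p, parameter_names(), "parameter set")
}

#' Conserved total amounts
#'
#' Defaults reflect one RVSF site and one NDC80 substrate per KNL1 molecule,
#' ten MELT motifs, and saturating amounts of PP1, PP2A and BUBR1 (all
#' dimensionless).
#'
#' @param ... Named overrides, e.g. `PP2Atot = 0`.
#' @return Named numeric vector of length 6.
#' @export
total_amounts <- function(...) {
  tt <- c(PP1tot = 10, PP2Atot = 10, MELTtot = 10, BUBR1tot = 10,
          RVSFtot = 1, NDC80tot = 1)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), total_names())
    if (length(bad)) stop("unknown total(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    tt[names(ov)] <- ov
  }
  check_named_nonneg(tt, total_names(), "total amounts")
}

#' External kinase activities
#'
#' MPS1 (MELT kinase), Aurora B (RVSF/NDC80 kinase) and CDK1 (BUBR1 kinase)
#' are external inputs, not dynamic species; setting one to zero simulates
#' acute chemical inhibition.
#'
#' @param MPS1,AurB,CDK1 Non-negative activities (default 1, the metaphase
#'   arrest condition).
#' @return Named numeric vector of length 3.
#' @export
kinase_inputs <- function(MPS1 = 1, AurB = 1, CDK1 = 1) {
  check_named_nonneg(c(MPS1 = MPS1, AurB = AurB, CDK1 = CDK1),
                     kinase_names(), "kinase inputs")
}

#' Network state
#'
#' @param ... Named species amounts; unspecified species default to 0
#'   (the fully dephosphorylated, fully unbound state).
#' @return Named numeric vector over [species_names()].
#' @export
network_state <- function(...) {
  s <- stats::setNames(numeric(9), species_names())
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), species_names())
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    s[names(ov)] <- ov
  }
  s
}

#' Model specification
#'
#' Bundles rate constants, totals, kinase inputs and a variant into one object
#' that fully determines the right-hand side of the ODE system.
#'
#' @param params See [parameter_set()].
#' @param totals See [total_amounts()].
#' @param kinases See [kinase_inputs()].
#' @param variant See [model_variant()]; default is the wild type.
#' @return An object of class `kp_model`.
#' @export
model_spec <- function(params = parameter_set(), totals = total_amounts(),
                       kinases = kinase_inputs(), variant = make_variant("WT")) {
  params  <- check_named_nonneg(params,  parameter_names(), "parameter set")
  totals  <- check_named_nonneg(totals,  total_names(),     "total amounts")
  kinases <- check_named_nonneg(kinases, kinase_names(),    "kinase inputs")
  stopifnot(inherits(variant, "kp_variant"))
  structure(list(params = params, totals = totals, kinases = kinases,
                 variant = variant), class = "kp_model")
}

#' Default model: the fitted wild-type parameterisation
#'
#' Returns the model with the published fitted rate constants, the standard
#' total amounts (10, 10, 10, 10, 1, 1) and unit kinase activities -- the
#' metaphase-arrest condition.
#'
#' @return A `kp_model`.
#' @export
#' @examples
#' m <- default_model()
#' m$params["kbPP1"]
default_model <- function() model_spec()

#' @export
print.kp_model <- function(x, ...) {
  cat("<kp_model> kinetochore phosphatase network\n")
  cat("  variant:", x$variant$label, "\n")
  cat("  kinases: MPS1 =", x$kinases[["MPS1"]], " AurB =", x$kinases[["AurB"]],
      " CDK1 =", x$kinases[["CDK1"]], "\n")
  invisible(x)
}

## Resolution of variants into effective parameters --------------------------

#' Resolve a model specification against its variant
#'
#' Applies the variant's total and parameter overrides and extracts the
#' catalytic-dead and clamp flags, producing the effective values used by
#' [derivatives()] and the solvers.
#'
#' @param spec A `kp_model`.
#' @return A list with elements `params`, `totals`, `kinases`, `dead_pp2a`,
#'   `clamp` (NA when PP2Aact is not clamped), of class `kp_model_resolved`.
#' @export
resolve_spec <- function(spec) {
  if (inherits(spec, "kp_model_resolved")) return(spec)
  stopifnot(inherits(spec, "kp_model"))
  v <- spec$variant
  params <- spec$params
  totals <- spec$totals
  if (length(v$param_overrides))  params[names(v$param_overrides)] <- v$param_overrides
  if (length(v$totals_overrides)) totals[names(v$totals_overrides)] <- v$totals_overrides
  structure(list(params = params, totals = totals, kinases = spec$kinases,
                 dead_pp2a = isTRUE(v$catalytically_dead_pp2a),
                 clamp = if (is.null(v$clamped_PP2Aact)) NA_real_ else v$clamped_PP2Aact,
                 label = v$label),
            class = "kp_model_resolved")
}

## Conservation closures ------------------------------------------------------

#' Free (unbound, unphosphorylated) pools implied by conservation
#'
#' Implements the six algebraic closure relations.  The unphosphorylated
#' BUBR1:PP2A complex is neglected in the model (phosphorylation by CDK1
#' raises the binding affinity by an order of magnitude), so `[BUBR1:PP2A]`
#' enters every relation as identically zero; the term is kept explicit in
#' the code for fidelity to the closure's full form.
#'
#' When `clamp` is set (the KNL1-fused PP2A construct), the clamped PP2Aact is
#' exogenous catalytic activity rather than a pMELT:pBUBR1:PP2A complex and
#' does not occupy any PP2A, BUBR1 or MELT from the conserved pools.
#'
#' Negative values are returned as-is: validity is asserted by conservation
#' tests, not masked here.
#'
#' @param state Named species vector, see [network_state()].
#' @param totals Named totals vector, see [total_amounts()].
#' @param clamp `NA` (default) or the clamped PP2Aact amount.
#' @return Named numeric vector with elements `PP1free`, `PP2Afree`,
#'   `BUBR1free`, `MELTfree`, `RVSFfree`, `NDC80free`.
#' @export
#' @examples
#' free_amounts(network_state(), total_amounts())["PP1free"]   # 10
free_amounts <- function(state, totals, clamp = NA_real_) {
  BUBR1_PP2A_unphos <- 0   # neglected species, kept for the closure's shape
  PP2Aact_cplx <- if (is.na(clamp)) state[["PP2Aact"]] else 0
  c(PP1free  = totals[["PP1tot"]]  - state[["PP1act"]],
    PP2Afree = totals[["PP2Atot"]] - PP2Aact_cplx - state[["pBUBR1_PP2A"]] -
               BUBR1_PP2A_unphos,
    BUBR1free = totals[["BUBR1tot"]] - state[["pBUBR1free"]] -
                state[["pMELT_BUBR1"]] - state[["pMELT_pBUBR1"]] -
                state[["pBUBR1_PP2A"]] - BUBR1_PP2A_unphos - PP2Aact_cplx,
    MELTfree = totals[["MELTtot"]] - state[["pMELT"]] - state[["pMELT_BUBR1"]] -
               state[["pMELT_pBUBR1"]] - PP2Aact_cplx,
    RVSFfree = totals[["RVSFtot"]] - state[["pRVSF"]] - state[["PP1act"]],
    NDC80free = totals[["NDC80tot"]] - state[["pNDC80"]])
}

#' Total phosphorylated MELT (the pMELT readout)
#'
#' Sum of all species carrying a phosphorylated MELT motif: free pMELT, the
#' two BUB-bound forms, and the PP2A-bound complex.  The comparison with
#' immunofluorescence intensities (which see all phospho-MELT epitopes) uses
#' this auxiliary readout.  A clamped PP2Aact (KNL1-fused PP2A) contains no
#' phospho-MELT and is excluded by default; set `include_clamp = TRUE` for
#' the alternative convention.
#'
#' @param state Named species vector.
#' @param clamp `NA` or the clamped PP2Aact amount.
#' @param include_clamp Count the clamped PP2Aact as a phospho-MELT species?
#' @return A single non-negative number.
#' @export
pmelt_total <- function(state, clamp = NA_real_, include_clamp = FALSE) {
  pp2a <- if (is.na(clamp) || include_clamp) state[["PP2Aact"]] else 0
  state[["pMELT"]] + state[["pMELT_BUBR1"]] + state[["pMELT_pBUBR1"]] + pp2a
}

## Right-hand side ------------------------------------------------------------

#' Time derivatives of the nine species
#'
#' Direct transcription of the nine mass-action rate equations.  Two variant
#' hooks modify the rate laws: with a catalytically dead PP2A every occurrence
#' of the pooled activity `PP1act + PP2Aact` in a dephosphorylation term is
#' replaced by `PP1act` alone (the dead holoenzyme still binds and occupies
#' pools but erases nothing); with a clamped PP2Aact the clamp value enters
#' the pooled activity while all binding/dissociation reactions that treat
#' PP2Aact as a complex are removed and its derivative is zero.
#'
#' @param state Named species vector.
#' @param spec A `kp_model` or resolved spec.
#' @param t Time (unused; the system is autonomous).
#' @return Named numeric vector of the nine time derivatives.
#' @export
#' @examples
#' d <- derivatives(network_state(), default_model())
#' d["pMELT"]   # kpMELT * MELTtot * MPS1 = 3.7
#' d["pRVSF"]   # kpRVSF * RVSFtot * AurB = 72.91
derivatives <- function(state, spec, t = 0) {
  eff <- resolve_spec(spec)
  if (any(!is.finite(state)))
    stop("non-finite state passed to derivatives (solver divergence?)",
         call. = FALSE)
  stats::setNames(derivs_fast(as.numeric(state[species_names()]), eff),
                  species_names())
}

# Hot path: positional state vector in the species_names() order, plain
# numeric out.  Kept in exact correspondence with the printed rate equations.
derivs_fast <- function(y, eff) {
  p <- eff$params; tt <- eff$totals; k <- eff$kinases
  clamped <- !is.na(eff$clamp)

  PP1act <- y[1L]
  PP2Aact <- if (clamped) eff$clamp else y[2L]
  pBf <- y[3L]; pBP <- y[4L]; pM <- y[5L]; pMB <- y[6L]; pMpB <- y[7L]
  pR <- y[8L]; pN <- y[9L]

  PP2Aact_cplx <- if (clamped) 0 else PP2Aact
  PP1free  <- tt[[1L]] - PP1act
  PP2Afree <- tt[[2L]] - PP2Aact_cplx - pBP
  Mfree <- tt[[3L]] - pM - pMB - pMpB - PP2Aact_cplx
  Bfree <- tt[[4L]] - pBf - pMB - pMpB - pBP - PP2Aact_cplx
  Rfree <- tt[[5L]] - pR - PP1act
  Nfree <- tt[[6L]] - pN

  # pooled dephosphorylation activity; a dead PP2A erases nothing
  pp <- if (eff$dead_pp2a) PP1act else PP1act + PP2Aact

  # PP2Aact complex turnover at the BUBR1 side; absent when PP2Aact is an
  # exogenous clamped activity rather than a pMELT:pBUBR1:PP2A complex
  cplx <- if (clamped) 0 else 1

  dPP1act <- p[["kbPP1"]] * Rfree * PP1free - p[["kdPP1"]] * PP1act

  dPP2Aact <- if (clamped) 0 else
    p[["kbPP2A"]] * pMpB * PP2Afree + p[["kbBUBR1"]] * pBP * pM -
    p[["kdPP2A"]] * PP2Aact - p[["kdBUBR1"]] * PP2Aact

  dpBf <- p[["kdBUBR1"]] * pMpB + p[["kdPP2A"]] * pBP +
    p[["kpBUBR1_free"]] * Bfree * k[["CDK1"]] -
    p[["kbBUBR1"]] * pBf * pM - p[["kbPP2A"]] * pBf * PP2Afree

  dpBP <- p[["kbPP2A"]] * pBf * PP2Afree + cplx * p[["kdBUBR1"]] * PP2Aact -
    p[["kdPP2A"]] * pBP - cplx * p[["kbBUBR1"]] * pBP * pM

  dpM <- p[["kdBUBR1"]] * pMB + p[["kdBUBR1"]] * pMpB +
    cplx * p[["kdBUBR1"]] * PP2Aact + p[["kpMELT"]] * Mfree * k[["MPS1"]] -
    p[["kbBUBR1"]] * Bfree * pM - p[["kbBUBR1"]] * pBf * pM -
    cplx * p[["kbBUBR1"]] * pBP * pM - p[["kdpMELT"]] * pM * pp

  dpMB <- p[["kbBUBR1"]] * Bfree * pM + p[["kdpBUBR1"]] * pMpB * pp -
    p[["kdBUBR1"]] * pMB - p[["kpBUBR1"]] * pMB * k[["CDK1"]]

  dpMpB <- p[["kbBUBR1"]] * pBf * pM + p[["kpBUBR1"]] * pMB * k[["CDK1"]] +
    cplx * p[["kdPP2A"]] * PP2Aact - p[["kdBUBR1"]] * pMpB -
    p[["kdpBUBR1"]] * pMpB * pp - cplx * p[["kbPP2A"]] * pMpB * PP2Afree

  dpR <- p[["kpRVSF"]] * Rfree * k[["AurB"]] - p[["kdpRVSF"]] * pR * pp
  dpN <- p[["kpNDC80"]] * Nfree * k[["AurB"]] - p[["kdpNDC80"]] * pN * pp

  c(dPP1act, dPP2Aact, dpBf, dpBP, dpM, dpMB, dpMpB, dpR, dpN)
}
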