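## ODE integration and steady-state analysis

rhs_desolve <- function(t, y, parms) {
  if (any(!is.finite(y)))
    stop("non-finite state during integration (solver divergence?)",
         call. = FALSE)
  list(derivs_fast(y, parms))
}

## parameter vector for the compiled right-hand side (src/model_rhs.c)
pack_parms <- function(eff) {
  clamped <- !is.na(eff$clamp)
  c(unname(eff$params), unname(eff$totals), unname(eff$kinases),
    as.numeric(eff$dead_pp2a), as.numeric(clamped),
    if (clamped) eff$clamp else 0)
}

#' Integrate the network ODEs
#'
#' Stiff-capable integration (LSODA) of the nine-species system.  The clamped
#' PP2Aact of the KNL1-fused construct is carried in the state at its clamp
#' value with zero derivative.
#'
#' @param spec A `kp_model`.
#' @param initial Initial [network_state()]; default all-zero (fully
#'   dephosphorylated, fully unbound), with a clamped PP2Aact set to its clamp.
#' @param times Strictly increasing output time grid (model time units).
#' @param rtol,atol Solver tolerances.
#' @param check_conservation Error if any free pool goes below `-cons_tol`.
#' @param cons_tol Conservation slack (10x solver rtol by default).
#' @param compiled Use the compiled right-hand side (default) or the
#'   interpreted R one; both implement the same rate equations.
#' @return A `kp_trajectory`: data.frame with `time`, the nine species,
#'   `pmelt_tot`, and the spec as attribute.
#' @export
integrate_model <- function(spec, initial = NULL, times,
                            rtol = 1e-8, atol = 1e-10,
                            check_conservation = TRUE, cons_tol = 10 * rtol,
                            compiled = TRUE) {
  eff <- resolve_spec(spec)
  if (is.null(initial)) initial <- network_state()
  initial <- check_named_nonneg(initial, species_names(), "initial state")
  if (!is.na(eff$clamp)) initial[["PP2Aact"]] <- eff$clamp
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  single <- length(times) == 1L
  tgrid <- if (single) c(times, times + 1) else times

  out <- if (compiled)
    deSolve::lsoda(y = unname(initial), times = tgrid, func = "kp_derivs",
                   dllname = "kinetophos", initfunc = "kp_initmod",
                   parms = pack_parms(eff), rtol = rtol, atol = atol,
                   maxsteps = 5e5)
  else
    deSolve::lsoda(y = unname(initial), times = tgrid, func = rhs_desolve,
                   parms = eff, rtol = rtol, atol = atol, maxsteps = 5e5)
  if (attr(out, "istate")[1L] < 0 || any(!is.finite(out)))
    stop("integration failed for variant '", eff$label, "' at t = ",
         max(out[is.finite(out[, 1L]), 1L]), call. = FALSE)
  if (single) out <- out[1L, , drop = FALSE]
  states <- out[, -1L, drop = FALSE]
  colnames(states) <- species_names()

  if (check_conservation) {
    scale <- max(eff$totals, 1)
    fr <- apply(states, 1L, function(s) min(free_amounts(s, eff$totals, eff$clamp)))
    if (min(fr) < -cons_tol * scale)
      stop("conservation violated (free pool ", signif(min(fr), 3),
           ") for variant '", eff$label, "'", call. = FALSE)
  }

  pm <- apply(states, 1L, function(s) pmelt_total(s, clamp = eff$clamp))
  traj <- data.frame(time = out[, 1L], states, pmelt_tot = pm,
                     check.names = FALSE)
  attr(traj, "spec") <- spec
  class(traj) <- c("kp_trajectory", "data.frame")
  traj
}

## residual scaled to the largest conserved pool
state_residual <- function(state, eff) {
  max(abs(derivs_fast(as.numeric(state), eff))) / max(eff$totals, 1)
}

newton_refine <- function(state, eff, tol = 1e-12, maxit = 25L) {
  free_idx <- if (!is.na(eff$clamp)) which(species_names() != "PP2Aact") else seq_len(9L)
  y <- state
  for (it in seq_len(maxit)) {
    f <- derivs_fast(as.numeric(y), eff)[free_idx]
    if (max(abs(f)) < tol * max(eff$totals, 1)) break
    n <- length(free_idx)
    J <- matrix(0, n, n)
    h <- pmax(1e-7 * abs(y[free_idx]), 1e-9)
    for (j in seq_len(n)) {
      yp <- as.numeric(y); ym <- as.numeric(y)
      yp[free_idx[j]] <- yp[free_idx[j]] + h[j]
      ym[free_idx[j]] <- ym[free_idx[j]] - h[j]
      J[, j] <- (derivs_fast(yp, eff)[free_idx] -
                 derivs_fast(ym, eff)[free_idx]) / (2 * h[j])
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    cand <- y
    cand[free_idx] <- cand[free_idx] + step
    # tiny negative round-off is clipped; a real excursion aborts refinement
    if (any(cand < -1e-8 * max(eff$totals, 1))) return(NULL)
    cand[cand < 0] <- 0
    if (state_residual(cand, eff) > state_residual(y, eff) && it > 1L) break
    y <- cand
  }
  y
}

#' Steady state of the network
#'
#' Relaxes the system by long-horizon integration from the guess (default:
#' the all-dephosphorylated state), extending the horizon until the residual
#' stops improving, then polishes with a damped Newton step on the algebraic
#' system.  If Newton refinement fails or leaves the non-negative orthant, the
#' relaxation endpoint is returned with its residual.
#'
#' @param spec A `kp_model`.
#' @param initial_guess Optional starting [network_state()].
#' @param tol Required residual: `max |dy/dt|` relative to the largest total.
#' @param t_relax Initial relaxation horizon.
#' @return A named species vector with attribute `residual`.
#' @export
#' @examples
#' ss <- steady_state(default_model())
#' pmelt_total(ss)   # arrest phospho-MELT with both phosphatases present
steady_state <- function(spec, initial_guess = NULL, tol = 1e-9,
                         t_relax = 500) {
  eff <- resolve_spec(spec)
  y <- if (is.null(initial_guess)) network_state() else
    check_named_nonneg(initial_guess, species_names(), "initial guess")
  if (!is.na(eff$clamp)) y[["PP2Aact"]] <- eff$clamp

  horizon <- t_relax
  for (round in 1:4) {
    traj <- tryCatch(
      suppressWarnings(integrate_model(spec, initial = y,
                                       times = c(0, horizon),
                                       rtol = 1e-10, atol = 1e-12,
                                       check_conservation = FALSE)),
      error = function(e) NULL)
    if (is.null(traj)) {
      # a pathological guess can defeat the stiff integrator; restart the
      # relaxation from the all-dephosphorylated reference state
      y <- network_state()
      if (!is.na(eff$clamp)) y[["PP2Aact"]] <- eff$clamp
      traj <- integrate_model(spec, initial = y, times = c(0, horizon),
                              rtol = 1e-8, atol = 1e-10,
                              check_conservation = FALSE)
    }
    y <- stats::setNames(as.numeric(traj[nrow(traj), species_names()]),
                         species_names())
    y[y < 0 & y > -1e-12] <- 0
    ref <- newton_refine(y, eff)
    if (!is.null(ref) && state_residual(ref, eff) < tol) {
      y <- ref
      break
    }
    if (state_residual(y, eff) < tol) break
    horizon <- horizon * 10
  }
  res <- state_residual(y, eff)
  if (res >= tol)
    stop("steady state did not converge for variant '", eff$label,
         "' (residual ", signif(res, 3), ")", call. = FALSE)
  attr(y, "residual") <- res
  y
}

## Kinase-inhibition protocols ------------------------------------------------

protocol_kinases <- function(protocol) {
  switch(protocol,
         MPS1i       = kinase_inputs(MPS1 = 0, AurB = 1, CDK1 = 1),
         MPS1i_AurBi = kinase_inputs(MPS1 = 0, AurB = 0, CDK1 = 1),
         stop("unknown protocol '", protocol,
              "'; valid protocols: MPS1i, MPS1i_AurBi", call. = FALSE))
}

#' Kinase-inhibition time course from metaphase arrest
#'
#' Computes the variant's arrest steady state at unit kinase activities, then
#' switches MPS1 off (`MPS1i`) or MPS1 and Aurora B off (`MPS1i_AurBi`) and
#' integrates.  This reproduces the experiment of washing an MPS1 (+/- Aurora
#' B) inhibitor onto nocodazole-arrested cells and following phospho-MELT.
#'
#' @param variant A `kp_variant` or variant name.
#' @param protocol `"MPS1i"` or `"MPS1i_AurBi"`.
#' @param times Output grid; default 0..20 model time units, chosen so the
#'   wild-type decay spans the same dynamic range as the experimental window.
#' @param spec Base model (default [default_model()]).
#' @return A `kp_trajectory` with an extra `pmelt_norm` column
#'   (pmelt_tot relative to its arrest value).
#' @export
inhibition_timecourse <- function(variant = "WT", protocol = c("MPS1i", "MPS1i_AurBi"),
                                  times = seq(0, 20, by = 0.5),
                                  spec = default_model()) {
  protocol <- match.arg(protocol)
  spec <- apply_variant(spec, variant)
  arrest <- steady_state(spec)
  run <- spec
  run$kinases <- protocol_kinases(protocol)
  traj <- integrate_model(run, initial = arrest, times = times)
  p0 <- traj$pmelt_tot[1L]
  traj$pmelt_norm <- if (p0 > 0) traj$pmelt_tot / p0 else traj$pmelt_tot * NA
  attr(traj, "protocol") <- protocol
  traj
}

## Dose-response and sensitivity ----------------------------------------------

#' Steady-state dose response to MPS1
#'
#' Steady-state phospho-MELT for each MPS1 activity on the grid, with Aurora B
#' and CDK1 held at protocol values.  Steady states are continued along the
#' grid (each dose seeded with the previous solution) for speed and branch
#' consistency.
#'
#' @param variant A `kp_variant` or name.
#' @param mps1_grid Strictly positive, increasing MPS1 activities; default 30
#'   log-spaced points over `[1e-2, 1e1]`.
#' @param aurb,cdk1 Held kinase activities (the Aurora-B-inhibited wild-type
#'   curve uses `aurb = 0`).
#' @param spec Base model.
#' @return A `kp_doseresponse` data.frame with `MPS1`, `pmelt_tot_ss` and the
#'   arrest species columns.
#' @export
dose_response <- function(variant = "WT",
                          mps1_grid = 10^seq(-2, 1, length.out = 30),
                          aurb = 1, cdk1 = 1, spec = default_model()) {
  if (any(mps1_grid <= 0) || is.unsorted(mps1_grid, strictly = TRUE))
    stop("mps1_grid must be strictly positive and increasing", call. = FALSE)
  spec <- apply_variant(spec, variant)
  eff <- resolve_spec(spec)
  guess <- NULL
  rows <- vector("list", length(mps1_grid))
  for (i in seq_along(mps1_grid)) {
    run <- spec
    run$kinases <- kinase_inputs(MPS1 = mps1_grid[i], AurB = aurb, CDK1 = cdk1)
    ss <- tryCatch(steady_state(run, initial_guess = guess),
                   error = function(e)
                     stop("dose-response failed at MPS1 = ", mps1_grid[i],
                          ": ", conditionMessage(e), call. = FALSE))
    guess <- ss
    rows[[i]] <- c(MPS1 = mps1_grid[i],
                   pmelt_tot_ss = pmelt_total(ss, clamp = eff$clamp), ss)
  }
  dr <- as.data.frame(do.call(rbind, rows))
  attr(dr, "variant") <- eff$label
  attr(dr, "aurb") <- aurb
  class(dr) <- c("kp_doseresponse", "data.frame")
  dr
}

#' Log-log sensitivity of a dose-response curve
#'
#' The slope d log10(pMELTtot) / d log10(MPS1) by central differences on the
#' log-log curve; the conventional measure of responsiveness (slope near 1)
#' versus robustness (slope near 0) of the checkpoint signal.
#'
#' @param curve A `kp_doseresponse`.
#' @return data.frame with `MPS1` (interior grid points) and `slope`.
#' @export
sensitivity <- function(curve) {
  stopifnot(inherits(curve, "kp_doseresponse"))
  x <- curve$MPS1
  y <- curve$pmelt_tot_ss
  if (any(y <= 0))
    stop("sensitivity undefined: non-positive steady-state values", call. = FALSE)
  lx <- log10(x); ly <- log10(y)
  n <- length(x)
  if (n < 3L) stop("need at least 3 doses for central differences", call. = FALSE)
  i <- 2:(n - 1L)
  data.frame(MPS1 = x[i], slope = (ly[i + 1L] - ly[i - 1L]) / (lx[i + 1L] - lx[i - 1L]))
}

## Cross-regulation and pNDC80 readouts ---------------------------------------

#' Arrest levels of active PP1 and PP2A across phosphatase knockouts
#'
#' Kinetochore PP1 and PP2A at the metaphase-arrest steady state for the wild
#' type and the single knockouts, exposing the mutual (cross-)regulation: PP2A
#' loss starves PP1 of its dephosphorylated RVSF dock, while PP1 loss leaves
#' more phospho-BUBR1 to recruit PP2A.
#'
#' @param variants Character vector of variant names.
#' @param spec Base model.
#' @return data.frame with `variant`, `PP1act`, `PP2Aact`, `pmelt_tot`.
#' @export
cross_regulation <- function(variants = c("WT", "dPP1", "dPP2A"),
                             spec = default_model()) {
  rows <- lapply(variants, function(v) {
    sp <- apply_variant(spec, v)
    ss <- steady_state(sp)
    data.frame(variant = v, PP1act = ss[["PP1act"]], PP2Aact = ss[["PP2Aact"]],
               pmelt_tot = pmelt_total(ss, clamp = resolve_spec(sp)$clamp))
  })
  do.call(rbind, rows)
}

#' Steady-state NDC80 phosphorylation during arrest, WT-normalised
#'
#' pNDC80 at the arrest steady state per variant, divided by the wild-type
#' value.  Because pNDC80 feeds back on nothing, its absolute scale depends on
#' the (unconstrained) NDC80 rate pair; the normalised readout does not.
#'
#' @param variants Character vector of variant names (must include `WT`).
#' @param spec Base model.
#' @return data.frame with `variant`, `pNDC80`, `pNDC80_norm`.
#' @export
pndc80_readout <- function(variants = c("WT", "dPP1", "dPP2A"),
                           spec = default_model()) {
  if (!("WT" %in% variants)) variants <- c("WT", variants)
  raw <- vapply(variants, function(v)
    steady_state(apply_variant(spec, v))[["pNDC80"]], numeric(1))
  data.frame(variant = variants, pNDC80 = unname(raw),
             pNDC80_norm = unname(raw) / raw[["WT"]])
}
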