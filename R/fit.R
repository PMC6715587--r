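## Least-squares parameter estimation against normalised pMELT time courses
##
## The fitting surface mirrors the original estimation procedure: normalised
## phospho-MELT decay curves for {WT, dPP1, dPP2A} x {MPS1i, MPS1i_AurBi},
## plus the active-PP2A ratio of the catalytically dead B56 mutant over wild
## type (kinetochore B56 levels are the measurable proxy for PP2Aact).

#' Construct a fitting dataset
#'
#' @param variant Variant name.
#' @param protocol Protocol name (`timecourse` kind) or `NA` (`pp2a_level`).
#' @param times Time grid of the observations (`timecourse` kind).
#' @param values Observed normalised pMELTtot means (timecourse) or the single
#'   observed PP2Aact ratio B56CD/WT (pp2a_level).
#' @param weights Optional per-point weights (default equal).
#' @param kind `"timecourse"` or `"pp2a_level"`.
#' @return An object of class `kp_fit_dataset`.
#' @export
fit_dataset <- function(variant = "WT", protocol = "MPS1i", times = NULL,
                        values, weights = NULL,
                        kind = c("timecourse", "pp2a_level")) {
  kind <- match.arg(kind)
  if (kind == "timecourse") {
    stopifnot(length(times) == length(values), !is.unsorted(times))
    if (any(values < 0) || any(values > 1.5))
      stop("normalised values outside [0, 1.5]", call. = FALSE)
  } else {
    stopifnot(length(values) == 1L)
    times <- 0
  }
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights >= 0))
  structure(list(variant = variant, protocol = protocol, times = times,
                 values = values, weights = weights, kind = kind),
            class = "kp_fit_dataset")
}

#' The default six-condition fitting surface, generated from a model
#'
#' Noiseless normalised time courses for the three genotypes under both
#' inhibition protocols, plus the B56CD/WT PP2Aact ratio.  Used to build
#' synthetic fitting problems and recovery tests.  When `cells_summary` rows
#' (from [summarize_cells()]) are supplied for a condition they replace the
#' noiseless values, with inverse-variance weights if repeat SDs are present.
#'
#' @param spec Generating model.
#' @param times Shared observation grid.
#' @param conditions data.frame with columns `variant`, `protocol`; default
#'   the six named conditions.
#' @param include_pp2a_ratio Append the B56CD PP2Aact constraint?
#' @return List of `kp_fit_dataset`.
#' @export
default_fit_datasets <- function(spec = default_model(),
                                 times = c(0, 2.5, 5, 10, 20),
                                 conditions = expand.grid(
                                   variant = c("WT", "dPP1", "dPP2A"),
                                   protocol = c("MPS1i", "MPS1i_AurBi"),
                                   stringsAsFactors = FALSE),
                                 include_pp2a_ratio = TRUE) {
  ds <- lapply(seq_len(nrow(conditions)), function(i) {
    tr <- inhibition_timecourse(conditions$variant[i], conditions$protocol[i],
                                times = times, spec = spec)
    fit_dataset(conditions$variant[i], conditions$protocol[i],
                times = times, values = pmin(tr$pmelt_norm, 1.5))
  })
  if (include_pp2a_ratio) {
    r <- pp2a_ratio(spec)
    ds <- c(ds, list(fit_dataset("B56CD", NA_character_, values = r,
                                 kind = "pp2a_level")))
  }
  ds
}

pp2a_ratio <- function(spec) {
  wt <- steady_state(apply_variant(spec, "WT"))[["PP2Aact"]]
  cd <- steady_state(apply_variant(spec, "B56CD"))[["PP2Aact"]]
  if (wt <= 0) return(NA_real_)
  cd / wt
}

with_params <- function(spec, params) {
  spec$params <- params
  spec
}

residuals_for <- function(params, datasets, spec, penalty = 1e3) {
  sp <- with_params(spec, params)
  # one arrest steady state per variant per candidate, shared across protocols
  cache <- new.env(parent = emptyenv())
  arrest_for <- function(variant) {
    key <- variant_label(variant)
    if (is.null(cache[[key]]))
      cache[[key]] <- steady_state(apply_variant(sp, variant))
    cache[[key]]
  }
  unlist(lapply(datasets, function(d) {
    # solver warnings on pathological candidates are folded into the penalty
    sim <- tryCatch(suppressWarnings({
      if (d$kind == "timecourse") {
        run <- apply_variant(sp, d$variant)
        arrest <- arrest_for(d$variant)
        clamp <- resolve_spec(run)$clamp
        run$kinases <- protocol_kinases(d$protocol)
        tgrid <- if (d$times[1] > 0) c(0, d$times) else d$times
        tr <- integrate_model(run, initial = arrest, times = tgrid)
        p0 <- pmelt_total(arrest, clamp = clamp)
        tr$pmelt_tot[match(d$times, tr$time)] / p0
      } else {
        wt <- arrest_for("WT")[["PP2Aact"]]
        if (wt <= 0) NA_real_ else arrest_for("B56CD")[["PP2Aact"]] / wt
      }
    }), error = function(e) NULL)
    if (is.null(sim) || any(!is.finite(sim)))
      return(rep(penalty, length(d$values)))
    sqrt(d$weights) * (sim - d$values)
  }), use.names = FALSE)
}

#' Sum-of-squares objective for a candidate parameter set
#'
#' Weighted squared residuals between simulated and observed normalised
#' series, summed over datasets (order-invariant).  A solver failure during a
#' candidate evaluation contributes a large finite penalty per point instead
#' of an exception, so optimisers can continue past pathological candidates.
#'
#' @param params Full [parameter_set()].
#' @param datasets List of [fit_dataset()] objects.
#' @param spec Base model carrying totals/kinases (parameters are replaced).
#' @return Non-negative scalar.
#' @export
#' @examples
#' ds <- default_fit_datasets(times = c(0, 5, 20), include_pp2a_ratio = FALSE)
#' fit_objective(parameter_set(), ds)   # ~0: data generated from these values
fit_objective <- function(params, datasets, spec = default_model()) {
  if (!length(datasets)) return(0)
  sum(residuals_for(params, datasets, spec)^2)
}

#' Fit rate constants by bounded least squares in log-parameter space
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) on log10
#' parameters, which enforces positivity by construction and matches the
#' scale-free character of rate constants.  Multi-start: start 1 is `init`,
#' further starts perturb the free parameters by seeded lognormal factors.
#' Deterministic given `seed` and `init`.
#'
#' @param datasets List of [fit_dataset()].
#' @param init Initial full [parameter_set()].
#' @param free Character vector of parameter names to optimise (default: the
#'   13 fitted constants, excluding the NDC80 pair which no dataset
#'   constrains).
#' @param lower,upper Bounds on the natural scale (applied to free
#'   parameters).
#' @param n_starts Number of starts.
#' @param seed Integer seed for the start perturbations.
#' @param perturb Range of multiplicative start perturbations.
#' @param stop_objective Stop launching new starts once a start reaches this
#'   objective (default `NULL`: run all starts).
#' @param maxiter Per-start iteration cap.
#' @param spec Base model.
#' @return A `kp_fit` list: `params`, `objective`, `n_evaluations`,
#'   `converged`, `seed`, `start_objectives`.
#' @export
fit_parameters <- function(datasets, init = parameter_set(),
                           free = setdiff(parameter_names(),
                                          c("kpNDC80", "kdpNDC80")),
                           lower = init[free] / 100, upper = init[free] * 100,
                           n_starts = 1L, seed = 1L, perturb = c(0.5, 2),
                           stop_objective = NULL, maxiter = 80L,
                           spec = default_model()) {
  stopifnot(all(free %in% parameter_names()))
  init <- check_named_nonneg(init, parameter_names(), "init")
  if (!length(free)) {
    obj <- fit_objective(init, datasets, spec)
    return(structure(list(params = init, objective = obj, n_evaluations = 1L,
                          converged = TRUE, seed = seed,
                          start_objectives = obj), class = "kp_fit"))
  }
  lower <- rep_len(lower, length(free)); upper <- rep_len(upper, length(free))
  if (any(lower <= 0)) stop("lower bounds must be positive", call. = FALSE)

  n_eval <- 0L
  fn <- function(lp) {
    n_eval <<- n_eval + 1L
    p <- init
    p[free] <- 10^lp
    residuals_for(p, datasets, spec)
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1L]] <- log10(init[free])
  if (n_starts > 1L)
    for (s in 2:n_starts)
      starts[[s]] <- log10(pmin(pmax(
        init[free] * stats::runif(length(free), perturb[1L], perturb[2L]),
        lower), upper))

  best <- NULL
  start_obj <- rep(NA_real_, n_starts)
  diags <- character(n_starts)
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = unname(starts[[s]]), fn = fn,
                         lower = log10(lower), upper = log10(upper),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) e)
    if (inherits(res, "error")) {
      diags[s] <- conditionMessage(res)
      next
    }
    obj <- res$deviance
    start_obj[s] <- obj
    if (is.null(best) || obj < best$deviance) best <- res
    if (!is.null(stop_objective) && obj < stop_objective) break
  }
  if (is.null(best))
    stop("all fit starts failed:\n", paste(diags, collapse = "\n"), call. = FALSE)
  params <- init
  params[free] <- 10^best$par
  structure(list(params = params, objective = best$deviance,
                 n_evaluations = n_eval,
                 converged = best$info %in% 1:4, seed = seed,
                 start_objectives = start_obj),
            class = "kp_fit")
}

#' @export
print.kp_fit <- function(x, ...) {
  cat("<kp_fit> objective =", signif(x$objective, 4),
      " evaluations =", x$n_evaluations,
      " converged =", x$converged, "\n")
  invisible(x)
}

#' Objective profile along one parameter
#'
#' Objective as a function of one parameter over a grid; with
#' `optimize_others = TRUE` the remaining free parameters are re-fitted at
#' each grid value (a profile likelihood up to the Gaussian approximation),
#' otherwise they are held fixed (fast mode).  A flat profile flags a
#' non-identifiable ("sloppy") direction.
#'
#' @param name Parameter name.
#' @param grid Positive values of the profiled parameter.
#' @param datasets List of [fit_dataset()].
#' @param init Full parameter set.
#' @param optimize_others Re-fit the other free parameters per grid point?
#' @param free Parameters allowed to move in `optimize_others` mode.
#' @param spec Base model.
#' @param ... Passed to [fit_parameters()].
#' @return data.frame with `value`, `objective` and attribute `optimized`.
#' @export
profile_parameter <- function(name, grid, datasets, init = parameter_set(),
                              optimize_others = FALSE,
                              free = setdiff(parameter_names(),
                                             c(name, "kpNDC80", "kdpNDC80")),
                              spec = default_model(), ...) {
  if (!(name %in% parameter_names()))
    stop("unknown parameter '", name, "'", call. = FALSE)
  stopifnot(all(grid > 0))
  obj <- vapply(grid, function(v) {
    p <- init
    p[name] <- v
    if (optimize_others)
      fit_parameters(datasets, init = p, free = free, spec = spec, ...)$objective
    else fit_objective(p, datasets, spec)
  }, numeric(1))
  out <- data.frame(value = grid, objective = obj)
  attr(out, "optimized") <- optimize_others
  out
}

#' Build fitting datasets from summarised synthetic cells
#'
#' @param summary Output of [summarize_cells()] for one condition.
#' @return A `kp_fit_dataset` (timecourse kind) with inverse-variance weights
#'   where repeat SDs are available.
#' @export
fit_dataset_from_summary <- function(summary) {
  stopifnot(nrow(summary) > 0)
  v <- summary$mean
  w <- if (all(is.finite(summary$sd_repeats)) && all(summary$sd_repeats > 0))
    1 / summary$sd_repeats^2 else rep(1, length(v))
  fit_dataset(summary$variant[1L], summary$protocol[1L],
              times = summary$time, values = pmin(pmax(v, 0), 1.5),
              weights = w)
}

#' Half-decay time of a normalised inhibition time course
#'
#' First time at which the normalised pMELT signal crosses 0.5, by linear
#' interpolation; `NA` if it never does within the horizon.
#'
#' @param traj A trajectory from [inhibition_timecourse()].
#' @return Scalar time (model units).
#' @export
half_decay_time <- function(traj) {
  y <- traj$pmelt_norm
  t <- traj$time
  below <- which(y <= 0.5)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (0.5 - y[i - 1L]) * (t[i] - t[i - 1L]) / (y[i] - y[i - 1L])
}
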