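#' Declarative model variant
#'
#' A variant perturbs the wild-type model by overriding totals and/or rate
#' constants, flagging the PP2A holoenzyme as catalytically dead, or clamping
#' the active PP2A pool at a constant exogenous value.  The wild type is the
#' identity variant.
#'
#' @param label Short name for reporting.
#' @param totals_overrides Named numeric, subset of [total_amounts()] names.
#' @param param_overrides Named numeric, subset of [parameter_names()].
#' @param catalytically_dead_pp2a If `TRUE`, PP2A binds and occupies pools but
#'   contributes nothing to any dephosphorylation rate.
#' @param clamped_PP2Aact `NULL`, or a constant active-PP2A amount removed
#'   from the ODE system and held fixed in every rate law.
#' @return An object of class `kp_variant`.
#' @export
model_variant <- function(label, totals_overrides = numeric(),
                          param_overrides = numeric(),
                          catalytically_dead_pp2a = FALSE,
                          clamped_PP2Aact = NULL) {
  if (length(totals_overrides)) {
    bad <- setdiff(names(totals_overrides), total_names())
    if (length(bad)) stop("unknown total(s) in variant: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(param_overrides)) {
    bad <- setdiff(names(param_overrides), parameter_names())
    if (length(bad)) stop("unknown parameter(s) in variant: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(clamped_PP2Aact))
    stopifnot(is.numeric(clamped_PP2Aact), length(clamped_PP2Aact) == 1L,
              clamped_PP2Aact >= 0)
  structure(list(label = label,
                 totals_overrides = totals_overrides,
                 param_overrides = param_overrides,
                 catalytically_dead_pp2a = isTRUE(catalytically_dead_pp2a),
                 clamped_PP2Aact = clamped_PP2Aact),
            class = "kp_variant")
}

#' Named model variants
#'
#' The in-silico mutants used throughout:
#' \describe{
#'   \item{WT}{identity.}
#'   \item{dPP1}{PP1 knockout, `PP1tot = 0`.}
#'   \item{dPP2A}{PP2A-B56 knockout, `PP2Atot = 0`.}
#'   \item{B56CD}{catalytically dead B56: PP2A is recruited normally but
#'     erases nothing (the pooled phosphatase activity reduces to PP1act).}
#'   \item{BUBR1_PP2A_fusion}{constitutive BUBR1--PP2A coupling: BUBR1
#'     phosphorylation and PP2A binding made quasi-instantaneous and
#'     irreversible (`kpBUBR1 = kpBUBR1_free = kbPP2A = 1e4`,
#'     `kdpBUBR1 = kdPP2A = 0`), removing the negative feedback through
#'     phospho-BUBR1.}
#'   \item{KNL1_PP2A}{PP2A fused directly to KNL1: recruitment decoupled from
#'     both phospho-BUBR1 and phospho-MELT (`kbPP2A = kdPP2A = 0`, active
#'     PP2A clamped at 1, one copy per KNL1 molecule).}
#' }
#'
#' @param name One of `WT`, `dPP1`, `dPP2A`, `B56CD`, `BUBR1_PP2A_fusion`,
#'   `KNL1_PP2A`.
#' @return A `kp_variant`.
#' @export
#' @examples
#' make_variant("dPP2A")$totals_overrides    # PP2Atot = 0
#' make_variant("KNL1_PP2A")$clamped_PP2Aact # 1
make_variant <- function(name) {
  valid <- c("WT", "dPP1", "dPP2A", "B56CD", "BUBR1_PP2A_fusion", "KNL1_PP2A")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown variant '", name, "'; valid variants: ",
         paste(valid, collapse = ", "), call. = FALSE)
  switch(name,
    WT    = model_variant("WT"),
    dPP1  = model_variant("dPP1",  totals_overrides = c(PP1tot = 0)),
    dPP2A = model_variant("dPP2A", totals_overrides = c(PP2Atot = 0)),
    B56CD = model_variant("B56CD", catalytically_dead_pp2a = TRUE),
    BUBR1_PP2A_fusion = model_variant("BUBR1_PP2A_fusion",
      param_overrides = c(kpBUBR1 = 1e4, kpBUBR1_free = 1e4, kbPP2A = 1e4,
                          kdpBUBR1 = 0, kdPP2A = 0)),
    KNL1_PP2A = model_variant("KNL1_PP2A",
      param_overrides = c(kbPP2A = 0, kdPP2A = 0),
      clamped_PP2Aact = 1))
}

#' Apply a variant to a model specification
#'
#' @param spec A `kp_model`.
#' @param variant A `kp_variant` or a name accepted by [make_variant()].
#' @return A `kp_model` carrying the variant.
#' @export
apply_variant <- function(spec, variant) {
  stopifnot(inherits(spec, "kp_model"))
  if (is.character(variant)) variant <- make_variant(variant)
  stopifnot(inherits(variant, "kp_variant"))
  spec$variant <- variant
  spec
}

#' @export
print.kp_variant <- function(x, ...) {
  cat("<kp_variant>", x$label, "\n")
  if (length(x$totals_overrides))
    cat("  totals:", paste(names(x$totals_overrides), x$totals_overrides,
                           sep = "=", collapse = ", "), "\n")
  if (length(x$param_overrides))
    cat("  params:", paste(names(x$param_overrides), x$param_overrides,
                           sep = "=", collapse = ", "), "\n")
  if (x$catalytically_dead_pp2a) cat("  catalytically dead PP2A\n")
  if (!is.null(x$clamped_PP2Aact))
    cat("  PP2Aact clamped at", x$clamped_PP2Aact, "\n")
  invisible(x)
}
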