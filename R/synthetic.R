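## Synthetic per-cell kinetochore-intensity data
##
## Emulates the statistical structure of per-cell quantitative
## immunofluorescence: each condition is sampled as independent cells at each
## time point, nested in experimental repeats, with multiplicative lognormal
## noise (intensity ratios are positive and right-skewed).

#' Noise model for synthetic per-cell intensities
#'
#' @param cell_cv Lognormal coefficient of variation of single-cell values
#'   around the repeat mean (default 0.3, typical of per-cell kinetochore
#'   intensity scatter).
#' @param repeat_sd Standard deviation (log scale) of the per-repeat
#'   multiplicative offset (default 0.1, day-to-day staining variation).
#' @return An object of class `kp_noise`.
#' @export
noise_model <- function(cell_cv = 0.3, repeat_sd = 0.1) {
  stopifnot(cell_cv >= 0, repeat_sd >= 0)
  structure(list(cell_cv = cell_cv, repeat_sd = repeat_sd),
            class = "kp_noise")
}

#' Generate a synthetic per-cell dataset for one condition
#'
#' Simulates the condition's normalised phospho-MELT time course (the truth),
#' then draws `n_cells` cells per time point, allocated round-robin across
#' `n_repeats` repeats.  Each cell value is
#' `truth(t) * lognormal(repeat) * lognormal(cell)`, with both lognormals
#' mean-one so that large-sample averages recover the truth.
#'
#' @param variant Variant name or `kp_variant`.
#' @param protocol `"MPS1i"` or `"MPS1i_AurBi"`.
#' @param times Sampling times within the simulated horizon.
#' @param n_cells Cells per condition per time point (default 30).
#' @param n_repeats Experimental repeats (default 3).
#' @param noise A [noise_model()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param spec Base model.
#' @return data.frame (`kp_cells`): `variant`, `protocol`, `time`,
#'   `repeat_id`, `cell_id`, `value`, plus the truth curve as attribute.
#' @export
generate_dataset <- function(variant = "WT", protocol = "MPS1i",
                             times = c(0, 2.5, 5, 10, 20),
                             n_cells = 30, n_repeats = 3,
                             noise = noise_model(), seed = 1,
                             spec = default_model()) {
  stopifnot(inherits(noise, "kp_noise"), n_cells >= 1, n_repeats >= 1)
  if (any(times < 0))
    stop("times outside the simulated horizon", call. = FALSE)
  horizon <- seq(0, max(times, 1), length.out = 81L)
  traj <- inhibition_timecourse(variant, protocol, times = horizon, spec = spec)
  truth <- stats::approx(traj$time, traj$pmelt_norm, xout = times)$y

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  sd_cell <- sqrt(log(1 + noise$cell_cv^2))
  rep_off <- stats::rlnorm(n_repeats, meanlog = -noise$repeat_sd^2 / 2,
                           sdlog = noise$repeat_sd)
  rep_of_cell <- rep_len(seq_len(n_repeats), n_cells)

  rows <- lapply(seq_along(times), function(i) {
    cell_mult <- stats::rlnorm(n_cells, meanlog = -sd_cell^2 / 2, sdlog = sd_cell)
    data.frame(variant = variant_label(variant), protocol = protocol,
               time = times[i], repeat_id = rep_of_cell,
               cell_id = seq_len(n_cells),
               value = truth[i] * rep_off[rep_of_cell] * cell_mult)
  })
  cells <- do.call(rbind, rows)
  attr(cells, "truth") <- data.frame(time = times, value = truth)
  class(cells) <- c("kp_cells", "data.frame")
  cells
}

variant_label <- function(v) if (inherits(v, "kp_variant")) v$label else v

#' Summarise per-cell data the way the experiments are displayed
#'
#' Per condition and time point: the mean over all cells, and the standard
#' deviation computed over repeat-level means (the display convention of the
#' imaging experiments, where error bars show variation between repeats).
#'
#' @param cells A `kp_cells` data.frame.
#' @return data.frame with `variant`, `protocol`, `time`, `mean`, `sd_repeats`,
#'   `n_cells`, `n_repeats`.  With a single repeat `sd_repeats` is `NA` with a
#'   warning.
#' @export
summarize_cells <- function(cells) {
  if (!nrow(cells)) stop("empty cell table", call. = FALSE)
  key <- interaction(cells$variant, cells$protocol, cells$time, drop = TRUE)
  out <- lapply(split(cells, key), function(d) {
    rm_ <- tapply(d$value, d$repeat_id, mean)
    nr <- length(rm_)
    if (nr < 2L) {
      warning("single repeat: SD over repeat means undefined", call. = FALSE)
      sdr <- NA_real_
    } else sdr <- stats::sd(rm_)
    data.frame(variant = d$variant[1L], protocol = d$protocol[1L],
               time = d$time[1L], mean = mean(d$value), sd_repeats = sdr,
               n_cells = nrow(d), n_repeats = nr)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$variant, out$protocol, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read per-cell tables as TSV
#'
#' @param cells A `kp_cells` data.frame.
#' @param path File path.
#' @return `read_cells_tsv` returns a `kp_cells` data.frame.
#' @export
write_cells_tsv <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_tsv
#' @export
read_cells_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("variant", "protocol", "time", "repeat_id", "cell_id", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cell table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  class(d) <- c("kp_cells", "data.frame")
  d
}
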