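# Cell-death quantification from two-channel event tables: only
# Hoechst-positive (nucleated) events enter the denominator, and events
# positive in both channels are scored dead.

#' Gate configuration
#'
#' Fixed scalar intensity thresholds; "positive" is strict (`>`). The
#' defaults are calibrated on the synthetic generator's channel mixtures
#' (the populations are separated by ~4 lognormal standard deviations, so
#' misclassification is negligible at these cuts).
#'
#' @param hoechst_threshold,yopro_threshold Positive finite intensity
#'   thresholds.
#' @return List of class `gate_config`.
#' @export
gate_config <- function(hoechst_threshold = 300, yopro_threshold = 500) {
  stopifnot(is.finite(hoechst_threshold), hoechst_threshold > 0,
            is.finite(yopro_threshold), yopro_threshold > 0)
  structure(list(hoechst_threshold = hoechst_threshold,
                 yopro_threshold = yopro_threshold),
            class = "gate_config")
}

#' Gate an event table and quantify cell death
#'
#' @param events Tibble with numeric `hoechst` and `yopro` columns (e.g.
#'   from [simulate_cytometry()] or [read_tsv_file()]).
#' @param config A [gate_config()].
#' @param condition Optional condition label (defaults to the table's
#'   `condition` attribute).
#' @return Object of class `death_result`: `condition`, `n_events`,
#'   `n_hoechst_pos`, `n_double_pos`, `percent_dead`
#'   (`100 * n_double_pos / n_hoechst_pos`).
#' @export
gate <- function(events, config = gate_config(), condition = NULL) {
  stopifnot(inherits(config, "gate_config"),
            all(c("hoechst", "yopro") %in% names(events)),
            is.numeric(events$hoechst), is.numeric(events$yopro))
  if (is.null(condition)) condition <- attr(events, "condition") %||% NA_character_
  h_pos <- events$hoechst > config$hoechst_threshold
  y_pos <- events$yopro > config$yopro_threshold
  n_h <- sum(h_pos)
  if (n_h == 0L) {
    stop("undefined percent: no Hoechst-positive events to gate on", call. = FALSE)
  }
  n_double <- sum(h_pos & y_pos)
  structure(list(condition = condition, n_events = nrow(events),
                 n_hoechst_pos = n_h, n_double_pos = n_double,
                 percent_dead = 100 * n_double / n_h),
            class = "death_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.death_result <- function(x, ...) {
  cat(sprintf("<death_result> %s: %.1f%% dead (%d/%d Hoechst-positive of %d events)\n",
              x$condition, x$percent_dead, x$n_double_pos, x$n_hoechst_pos,
              x$n_events))
  invisible(x)
}

#' Compare gated conditions against a baseline
#'
#' Per condition: the gated percent dead, the net increase over the
#' baseline, and the fold ratio to the baseline (the normalisation used for
#' cross-cell-type comparisons of the death phenotype).
#'
#' @param results List of [gate()] results (named or carrying conditions).
#' @param baseline Name of the baseline condition (must be present).
#' @return Tibble `condition`, `percent_dead`, `net_increase`, `ratio`.
#' @export
compare_conditions <- function(results, baseline) {
  conds <- vapply(results, function(r) r$condition, character(1))
  if (!is.null(names(results))) conds <- names(results)
  if (!baseline %in% conds) {
    stop(sprintf("missing baseline condition '%s'", baseline), call. = FALSE)
  }
  conds <- unname(conds)
  pct <- unname(vapply(results, function(r) r$percent_dead, numeric(1)))
  base <- pct[match(baseline, conds)]
  tibble::tibble(condition = conds, percent_dead = pct,
                 net_increase = pct - base, ratio = pct / base)
}

#' Dose-response table
#'
#' @param doses Numeric vector of doses (pmol); duplicates are an error.
#' @param results List of [gate()] results, parallel to `doses`.
#' @return Tibble `dose_pmol`, `percent_dead` sorted by dose, with
#'   attribute `monotone` (`TRUE` when percent dead is non-decreasing in
#'   dose; reported, not enforced).
#' @export
dose_response <- function(doses, results) {
  stopifnot(length(doses) == length(results), length(doses) >= 2L)
  if (anyDuplicated(doses)) stop("duplicate dose", call. = FALSE)
  ord <- order(doses)
  out <- tibble::tibble(
    dose_pmol = doses[ord],
    percent_dead = vapply(results, function(r) r$percent_dead, numeric(1))[ord])
  attr(out, "monotone") <- !is.unsorted(out$percent_dead)
  out
}

#' EVs delivered per recipient cell
#'
#' Dose arithmetic for EV exposure experiments: a yield of 4.8e9 vesicles
#' over 2e5 recipient cells is 24,000 EVs per cell.
#'
#' @param ev_yield Total EV count (positive).
#' @param recipient_cells Number of recipient cells (positive).
#' @param sig_figs Significant figures kept in the reported value
#'   (default 2). The remaining digits are truncated, not rounded up,
#'   matching how order-of-magnitude doses are quoted (550,000 is
#'   reported as ~500,000 at one significant figure).
#' @return List `exact` (the quotient) and `reported` (leading
#'   `sig_figs` significant figures).
#' @export
ev_dose <- function(ev_yield, recipient_cells, sig_figs = 2) {
  stopifnot(ev_yield > 0)
  if (recipient_cells <= 0) stop("zero recipients", call. = FALSE)
  exact <- ev_yield / recipient_cells
  unit <- 10^(floor(log10(exact)) - sig_figs + 1)
  list(exact = exact, reported = floor(exact / unit) * unit)
}
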