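# Synthetic two-channel cytometry events: Hoechst 33342 (nuclear stain,
# viability-independent) and YO-PRO-1 (enters apoptotic/dead cells only).
# Each condition mixes Hoechst-negative debris, Hoechst-positive live
# cells, and Hoechst/YO-PRO double-positive dead cells with a configured
# true dead fraction.

#' Define a cytometry condition
#'
#' @param name Condition label.
#' @param dead_fraction True fraction of dead cells among Hoechst-positive
#'   (nucleated) events, in `[0, 1]`.
#' @param n_events Number of events to simulate (default 1e4).
#' @param debris_fraction Fraction of Hoechst-negative debris events
#'   (default 0.02).
#' @param hoechst_pos,hoechst_neg,yopro_pos,yopro_neg Lognormal
#'   `(meanlog, sdlog)` parameters of the channel intensity populations;
#'   the dead population is shifted upward in the YO-PRO-1 channel.
#' @param seed Default seed for [simulate_cytometry()].
#' @return List of class `cyto_condition`.
#' @export
cyto_condition <- function(name, dead_fraction, n_events = 1e4,
                           debris_fraction = 0.02,
                           hoechst_pos = c(log(1200), 0.35),
                           hoechst_neg = c(log(60), 0.5),
                           yopro_pos = c(log(2500), 0.35),
                           yopro_neg = c(log(90), 0.35),
                           seed = 1L) {
  stopifnot(dead_fraction >= 0, dead_fraction <= 1,
            debris_fraction >= 0, debris_fraction < 1, n_events >= 1)
  if (yopro_pos[1] <= yopro_neg[1]) {
    stop("dead population must be shifted upward in the viability channel",
         call. = FALSE)
  }
  structure(list(name = name, dead_fraction = dead_fraction,
                 n_events = as.integer(n_events),
                 debris_fraction = debris_fraction,
                 hoechst_pos = hoechst_pos, hoechst_neg = hoechst_neg,
                 yopro_pos = yopro_pos, yopro_neg = yopro_neg,
                 seed = as.integer(seed)),
            class = "cyto_condition")
}

#' Simulate a two-channel cytometry event table
#'
#' @param condition A [cyto_condition()].
#' @param seed Integer seed (defaults to the condition's own).
#' @return Tibble `event_id`, `hoechst`, `yopro` plus truth columns
#'   `true_class` (`"debris"`, `"live"`, `"dead"`); attribute `condition`.
#' @export
simulate_cytometry <- function(condition, seed = condition$seed) {
  stopifnot(inherits(condition, "cyto_condition"))
  set.seed(as.integer(seed))
  n <- condition$n_events
  is_debris <- stats::runif(n) < condition$debris_fraction
  is_dead <- !is_debris & stats::runif(n) < condition$dead_fraction

  hoechst <- numeric(n)
  yopro <- numeric(n)
  hoechst[is_debris] <- stats::rlnorm(sum(is_debris),
                                      condition$hoechst_neg[1],
                                      condition$hoechst_neg[2])
  hoechst[!is_debris] <- stats::rlnorm(sum(!is_debris),
                                       condition$hoechst_pos[1],
                                       condition$hoechst_pos[2])
  yopro[is_dead] <- stats::rlnorm(sum(is_dead), condition$yopro_pos[1],
                                  condition$yopro_pos[2])
  yopro[!is_dead] <- stats::rlnorm(sum(!is_dead), condition$yopro_neg[1],
                                   condition$yopro_neg[2])

  out <- tibble::tibble(
    event_id = sprintf("ev_%06d", seq_len(n)),
    hoechst = round(hoechst, 3), yopro = round(yopro, 3),
    true_class = ifelse(is_debris, "debris", ifelse(is_dead, "dead", "live")))
  attr(out, "condition") <- condition$name
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Packaged cytometry conditions
#'
#' Synthetic presets for the cell-death assays. Only the two EV-RNA
#' transfection percentages are anchored at printed values (BJ cells with
#' BJ EV RNA 10.6%, with K562 EV RNA 20.5%); the untreated (5%), mock
#' (6%) and direct co-culture (20%, i.e. fourfold over untreated)
#' baselines, and the K562 non-response presets, are package defaults.
#'
#' @param n_events Events per condition (default 1e4).
#' @return Named list of [cyto_condition()] objects.
#' @export
default_cyto_conditions <- function(n_events = 1e4) {
  specs <- c(untreated_bj = 0.05, mock_bj = 0.06,
             bj_plus_bj_ev_rna = 0.106, bj_plus_k562_ev_rna = 0.205,
             coculture_bj_k562 = 0.20,
             untreated_k562 = 0.04, mock_k562 = 0.045,
             k562_plus_k562_ev_rna = 0.045)
  seeds <- seq_along(specs) + 500L
  out <- mapply(function(nm, f, s) cyto_condition(nm, f, n_events = n_events,
                                                  seed = s),
                names(specs), specs, seeds, SIMPLIFY = FALSE)
  names(out) <- names(specs)
  out
}

#' Packaged dose-response design
#'
#' The six-dose transfection series of the 5' 31-mer with a monotone
#' increasing true dead fraction, alongside a flat nonspecific-RNA control.
#'
#' @param n_events Events per dose (default 1e4).
#' @return Tibble `dose_pmol`, `treatment`, `condition`
#'   (list of [cyto_condition()]).
#' @export
default_dose_design <- function(n_events = 1e4) {
  doses <- c(10, 50, 100, 200, 300, 400)
  rny5 <- c(0.07, 0.10, 0.14, 0.19, 0.23, 0.26)
  ctrl <- rep(0.06, 6)
  tibble::tibble(
    dose_pmol = rep(doses, 2),
    treatment = rep(c("rny5_31mer", "nonspecific"), each = 6),
    condition = c(
      lapply(seq_along(doses), function(i)
        cyto_condition(sprintf("rny5_31mer_%dpmol", doses[i]), rny5[i],
                       n_events = n_events, seed = 600L + i)),
      lapply(seq_along(doses), function(i)
        cyto_condition(sprintf("nonspecific_%dpmol", doses[i]), ctrl[i],
                       n_events = n_events, seed = 620L + i))))
}
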