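# Bloodstream-infection risk after intestinal domination.
#
# Survival data are encoded in counting-process format: per patient,
# half-open intervals (Start, Stop] on the day axis relative to the
# nearest HCT, with a binary time-dependent domination covariate that
# starts at 0 and switches to 1 once (absorbing), and a genus-matched
# infection event flag at the interval end.

#' Build counting-process risk intervals for one genus
#'
#' Restricts follow-up to `window` (days relative to HCT), anchors one
#' observation per transplant (later windows truncated so overlapping days
#' are never double-counted), sets the domination covariate to 1 from the
#' end of the first sampled day whose genus-level relative abundance
#' strictly exceeds `threshold`, and flags genus-matched bloodstream
#' infections as events. Infections of other genera censor follow-up is
#' not applied: only the matching genus ends follow-up (event); all other
#' patients are censored at the window end. Patients whose matching
#' infection precedes entry are excluded; patients without samples in the
#' window contribute covariate-0 follow-up and are listed in the
#' `no_sample_patients` attribute.
#'
#' @param cohort A cohort with counts, taxonomy, samples, hct and
#'   infections tables.
#' @param genus Focal genus (exact string match against taxonomy and
#'   `InfectiousAgent`).
#' @param threshold Domination threshold (strict `>`).
#' @param window Length-2 integer window in days relative to HCT.
#' @return Tibble `PatientID`, `Start`, `Stop`, `Dominated`, `Event`, one
#'   or two rows per patient-window, class `hosp_risk_intervals`.
#' @export
build_counting_process <- function(cohort, genus, threshold = 0.3,
                                   window = c(-15L, 35L)) {
  stopifnot(window[1] < window[2])
  genus_counts <- aggregate_to_level(cohort$counts, cohort$taxonomy, "Genus")
  if (!genus %in% genus_counts$Taxon) {
    abort(paste0("genus not present in cohort taxonomy/counts: ", genus))
  }
  rel <- relative_abundance(genus_counts)
  dom_samples <- rel |>
    filter(.data$Taxon == genus, .data$Fraction > threshold) |>
    inner_join(select(cohort$samples, "SampleID", "PatientID", "Timepoint"),
               by = "SampleID")
  first_dom <- dom_samples |>
    arrange(.data$Timepoint) |>
    distinct(.data$PatientID, .keep_all = TRUE) |>
    select("PatientID", DomTimepoint = "Timepoint")
  sample_pat <- unique(cohort$samples$PatientID)

  inf <- cohort$infections |>
    filter(.data$InfectiousAgent == genus) |>
    arrange(.data$Timepoint) |>
    distinct(.data$PatientID, .keep_all = TRUE) |>
    select("PatientID", InfTimepoint = "Timepoint")

  hct <- cohort$hct |>
    arrange(.data$PatientID, .data$TimepointOfTransplant)

  rows <- list()
  excluded <- character(0)
  no_sample <- character(0)
  for (p in unique(hct$PatientID)) {
    anchors <- hct$TimepointOfTransplant[hct$PatientID == p]
    inf_tp <- inf$InfTimepoint[match(p, inf$PatientID)]
    dom_tp <- first_dom$DomTimepoint[match(p, first_dom$PatientID)]
    if (!p %in% sample_pat) no_sample <- c(no_sample, p)
    prev_exit_abs <- -Inf
    for (h in anchors) {
      entry_abs <- max(h + window[1], prev_exit_abs)
      end_abs <- h + window[2]
      prev_exit_abs <- max(prev_exit_abs, end_abs)
      if (entry_abs >= end_abs) next
      if (!is.na(inf_tp) && inf_tp <= entry_abs) {
        excluded <- c(excluded, p)
        next
      }
      event <- !is.na(inf_tp) && inf_tp <= end_abs
      exit_abs <- if (event) inf_tp else end_abs
      # relative to this window's transplant day
      entry <- entry_abs - h; exit <- exit_abs - h
      dom_rel <- if (!is.na(dom_tp) && dom_tp < exit_abs) dom_tp - h else NA_real_
      if (!is.na(dom_rel) && dom_rel > entry) {
        rows[[length(rows) + 1]] <- tibble(
          PatientID = p,
          Start = c(entry, dom_rel), Stop = c(dom_rel, exit),
          Dominated = c(0L, 1L), Event = c(FALSE, event)
        )
      } else {
        covariate <- as.integer(!is.na(dom_rel))
        rows[[length(rows) + 1]] <- tibble(
          PatientID = p, Start = entry, Stop = exit,
          Dominated = covariate, Event = event
        )
      }
      if (event) break # no follow-up after the event in later windows
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(PatientID = character(0), Start = numeric(0), Stop = numeric(0),
           Dominated = integer(0), Event = logical(0))
  attr(out, "genus") <- genus
  attr(out, "threshold") <- threshold
  attr(out, "window") <- window
  attr(out, "excluded_prior_infection") <- unique(excluded)
  attr(out, "no_sample_patients") <- no_sample
  class(out) <- c("hosp_risk_intervals", class(out))
  out
}

#' Counting-process intervals from a per-day domination indicator
#'
#' Companion to [simulate_bsi()]: converts a patient-day binary domination
#' indicator plus an infection table into counting-process rows. A day `d`
#' is the interval `(d-1, d]` carrying that day's covariate value.
#'
#' @param domination Tibble `PatientID`, `Day`, `Dominated` (0/1 per
#'   patient-day).
#' @param infections Infection tibble with `PatientID`,
#'   `DayRelativeToNearestHCT`.
#' @param genus Genus to match in `InfectiousAgent` (ignored if the column
#'   is absent).
#' @return Tibble `PatientID`, `Start`, `Stop`, `Dominated`, `Event`.
#' @export
counting_process_from_indicator <- function(domination, infections,
                                            genus = NULL) {
  inf <- infections
  if (!is.null(genus) && "InfectiousAgent" %in% names(inf)) {
    inf <- filter(inf, .data$InfectiousAgent == genus)
  }
  inf_day <- inf |>
    arrange(.data$DayRelativeToNearestHCT) |>
    distinct(.data$PatientID, .keep_all = TRUE) |>
    select("PatientID", InfDay = "DayRelativeToNearestHCT")
  rows <- domination |>
    arrange(.data$PatientID, .data$Day) |>
    group_by(.data$PatientID) |>
    group_map(function(df, key) {
      p <- key$PatientID
      infd <- inf_day$InfDay[match(p, inf_day$PatientID)]
      exit <- if (!is.na(infd)) infd else max(df$Day)
      df <- filter(df, .data$Day <= exit)
      if (nrow(df) == 0) return(NULL)
      entry <- min(df$Day) - 1
      d_star <- suppressWarnings(min(df$Day[df$Dominated == 1]))
      event <- !is.na(infd)
      if (is.finite(d_star) && d_star - 1 > entry) {
        tibble(PatientID = p,
               Start = c(entry, d_star - 1), Stop = c(d_star - 1, exit),
               Dominated = c(0L, 1L), Event = c(FALSE, event))
      } else {
        tibble(PatientID = p, Start = entry, Stop = exit,
               Dominated = as.integer(is.finite(d_star)), Event = event)
      }
    }) |>
    bind_rows()
  rows
}

#' Fit the time-dependent-covariate Cox model
#'
#' Maximizes the Cox partial likelihood over the counting-process rows
#' (Efron tie correction by default) and returns the Wald summary for the
#' domination covariate.
#'
#' @param intervals Counting-process tibble (`PatientID`, `Start`, `Stop`,
#'   `Dominated`, `Event`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `hosp_cox_fit`: `beta`, `se`, `hr`, `ci95`,
#'   `p_value`, `n_patients`, `n_events`, `n_dominated`, plus the
#'   underlying `survival::coxph` fit.
#' @export
fit_cox_td <- function(intervals, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (nrow(intervals) == 0) abort("no risk intervals")
  if (!any(intervals$Event)) abort("no events: hazard ratio not estimable")
  if (n_distinct(intervals$Dominated) < 2) {
    abort("domination covariate has no contrast (constant)",
          class = "hosp_cox_no_contrast")
  }
  ev <- intervals$Dominated[intervals$Event]
  if (all(ev == 1) || all(ev == 0)) {
    abort(paste0("monotone partial likelihood: all ", sum(intervals$Event),
                 " events occur in the covariate-", ev[1],
                 " stratum; beta diverges"),
          class = "hosp_cox_monotone")
  }
  dat <- as_tibble(intervals)
  fit <- coxph(Surv(Start, Stop, Event) ~ Dominated, data = dat, ties = ties)
  beta <- unname(coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  structure(list(
    beta = beta, se = se, hr = exp(beta),
    ci95 = exp(beta + c(-1, 1) * 1.96 * se),
    p_value = 2 * pnorm(-abs(beta / se)),
    n_patients = n_distinct(dat$PatientID),
    n_events = sum(dat$Event),
    n_dominated = n_distinct(dat$PatientID[dat$Dominated == 1]),
    ties = ties,
    model = fit
  ), class = "hosp_cox_fit")
}

#' @export
print.hosp_cox_fit <- function(x, ...) {
  cat(sprintf(
    "<hosp_cox_fit> HR = %.2f [%.2f-%.2f 95%% CI], p = %.3g (%d events, %d/%d patients dominated)\n",
    x$hr, x$ci95[1], x$ci95[2], x$p_value, x$n_events, x$n_dominated,
    x$n_patients))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.hosp_cox_fit <- function(x, ...) {
  tibble(term = "Dominated", estimate = x$beta, std.error = x$se,
         hr = x$hr, conf.low = x$ci95[1], conf.high = x$ci95[2],
         p.value = x$p_value)
}

#' @rdname glance
#' @export
glance.hosp_cox_fit <- function(x, ...) {
  tibble(n_patients = x$n_patients, n_events = x$n_events,
         n_dominated = x$n_dominated, ties = x$ties)
}

#' Hazard-ratio sweep over domination thresholds
#'
#' Repeats the counting-process construction and Cox fit for a set of
#' domination thresholds. Per-threshold fit failures are reported in the
#' `note` column and the sweep continues. The repeated fits are not
#' multiplicity-adjusted (a note attribute records this).
#'
#' @param cohort A cohort.
#' @param genus Focal genus.
#' @param thresholds Numeric thresholds (fractions).
#' @param window Day window relative to HCT.
#' @param ties Tie handling for the Cox fits.
#' @return Tibble `genus`, `threshold`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `n_patients`, `n_events`, `n_dominated`, `note`.
#' @export
threshold_sweep <- function(cohort, genus,
                            thresholds = c(0.30, 0.10, 0.01, 0.001),
                            window = c(-15L, 35L),
                            ties = "efron") {
  rows <- purrr::map(thresholds, function(th) {
    res <- tryCatch({
      ints <- build_counting_process(cohort, genus, threshold = th,
                                     window = window)
      fit <- fit_cox_td(ints, ties = ties)
      tibble(genus = genus, threshold = th, hr = fit$hr,
             ci_low = fit$ci95[1], ci_high = fit$ci95[2], p = fit$p_value,
             n_patients = fit$n_patients, n_events = fit$n_events,
             n_dominated = fit$n_dominated, note = NA_character_)
    }, error = function(e) {
      ints <- tryCatch(build_counting_process(cohort, genus, threshold = th,
                                              window = window),
                       error = function(e2) NULL)
      nd <- if (is.null(ints)) NA_integer_ else
        n_distinct(ints$PatientID[ints$Dominated == 1])
      tibble(genus = genus, threshold = th, hr = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
             n_patients = if (is.null(ints)) NA_integer_ else
               n_distinct(ints$PatientID),
             n_events = if (is.null(ints)) NA_integer_ else sum(ints$Event),
             n_dominated = nd, note = conditionMessage(e))
    })
    res
  })
  out <- bind_rows(rows)
  attr(out, "note") <- "per-threshold fits are not multiplicity-adjusted"
  out
}

#' Per-day, per-genus infection counts
#'
#' Counts positive blood cultures per day relative to HCT and per genus,
#' over a day window, completing missing cells with zero.
#'
#' @param infections Infection tibble.
#' @param window Length-2 day window relative to HCT.
#' @return Tibble `Day`, `InfectiousAgent`, `n` covering the full grid.
#' @export
infection_timeline <- function(infections, window = c(-15L, 35L)) {
  agents <- sort(unique(infections$InfectiousAgent))
  if (length(agents) == 0) {
    return(tibble(Day = seq(window[1], window[2]),
                  InfectiousAgent = NA_character_, n = 0L)[0, ])
  }
  infections |>
    filter(.data$DayRelativeToNearestHCT >= window[1],
           .data$DayRelativeToNearestHCT <= window[2]) |>
    count(Day = .data$DayRelativeToNearestHCT, .data$InfectiousAgent) |>
    complete(Day = seq(window[1], window[2]),
             InfectiousAgent = agents, fill = list(n = 0L))
}
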