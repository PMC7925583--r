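# a minimal cohort with hand-placed genus abundances, one patient
mini_bsi_cohort <- function(dom_day = 2L, inf_day = 10L,
                            dom_frac = 0.6, anchor = 100L) {
  samples <- tibble::tibble(
    SampleID = c("m1", "m2", "m3"), PatientID = "p1",
    Timepoint = anchor + c(-10L, dom_day, 20L),
    DayRelativeToNearestHCT = c(-10L, dom_day, 20L))
  counts <- tibble::tibble(
    SampleID = rep(c("m1", "m2", "m3"), each = 2),
    ASV = rep(c("a1", "a4"), 3),
    Count = c(10, 90, round(dom_frac * 100), 100 - round(dom_frac * 100),
              20, 80))
  infections <- if (is.na(inf_day)) {
    tibble::tibble(PatientID = character(0), Timepoint = integer(0),
                   InfectiousAgent = character(0),
                   DayRelativeToNearestHCT = integer(0))
  } else {
    tibble::tibble(PatientID = "p1", Timepoint = anchor + inf_day,
                   InfectiousAgent = "Enterococcus",
                   DayRelativeToNearestHCT = inf_day)
  }
  new_cohort(samples = samples, counts = counts,
             hct = tibble::tibble(PatientID = "p1",
                                  TimepointOfTransplant = anchor,
                                  HCTSource = "cord", Disease = "AML"),
             infections = infections, taxonomy = tiny_taxonomy)
}

test_that("risk intervals split at domination and end at the event", {
  ints <- build_counting_process(mini_bsi_cohort(), "Enterococcus", 0.30)
  expect_equal(ints$Start, c(-15, 2))
  expect_equal(ints$Stop, c(2, 10))
  expect_equal(ints$Dominated, c(0L, 1L))
  expect_equal(ints$Event, c(FALSE, TRUE))
})

test_that("a never-dominated uninfected patient is one censored covariate-0 interval", {
  ints <- build_counting_process(mini_bsi_cohort(dom_frac = 0.1, inf_day = NA),
                                 "Enterococcus", 0.30)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$Start, -15)
  expect_equal(ints$Stop, 35)
  expect_equal(ints$Dominated, 0L)
  expect_false(ints$Event)
})

test_that("patients infected before entry are excluded", {
  ints <- build_counting_process(mini_bsi_cohort(inf_day = -20L),
                                 "Enterococcus", 0.30)
  expect_equal(nrow(ints), 0)
  expect_equal(attr(ints, "excluded_prior_infection"), "p1")
})

test_that("other-genus infections are not events for the focal genus", {
  coh <- mini_bsi_cohort()
  coh$infections$InfectiousAgent <- "Escherichia"
  ints <- build_counting_process(coh, "Enterococcus", 0.30)
  expect_false(any(ints$Event))
  expect_equal(max(ints$Stop), 35)   # censored at window end, not at day 10
})

test_that("interval sets match a brute-force day-by-day state trace", {
  coh <- gen_small$cohort
  ints <- build_counting_process(coh, "Enterococcus", 0.30)
  # brute force per patient (single HCT, window -15..35)
  agg <- aggregate_to_level(coh$counts, coh$taxonomy, "Genus")
  rel <- relative_abundance(agg) |>
    dplyr::filter(Taxon == "Enterococcus") |>
    dplyr::inner_join(dplyr::select(coh$samples, SampleID, PatientID,
                                    DayRelativeToNearestHCT), by = "SampleID")
  for (p in unique(coh$hct$PatientID)) {
    pi <- ints[ints$PatientID == p, ]
    infd <- coh$infections$DayRelativeToNearestHCT[
      coh$infections$PatientID == p &
        coh$infections$InfectiousAgent == "Enterococcus"]
    infd <- if (length(infd)) min(infd) else NA
    if (!is.na(infd) && infd <= -15) { expect_equal(nrow(pi), 0); next }
    exit <- if (!is.na(infd) && infd <= 35) infd else 35
    domd <- rel$DayRelativeToNearestHCT[rel$PatientID == p & rel$Fraction > 0.30]
    domd <- if (length(domd)) min(domd) else NA
    # time conservation and state trace
    expect_equal(sum(pi$Stop - pi$Start), exit - (-15), info = p)
    expect_equal(min(pi$Start), -15, info = p)
    expect_equal(max(pi$Stop), exit, info = p)
    for (d in seq(-14L, exit)) {
      state <- as.integer(!is.na(domd) && d > domd)
      row <- pi[pi$Start < d & d <= pi$Stop, ]
      expect_equal(row$Dominated, state, info = paste(p, d))
    }
    expect_equal(any(pi$Event), !is.na(infd) && infd <= 35 && infd > -15,
                 info = p)
  }
})

test_that("the Cox fit recovers a known hazard ratio of 2", {
  set.seed(101)
  n <- 2000
  z <- rep(0:1, each = n / 2)
  times <- rexp(n, rate = 0.05 * 2^z)
  cens <- pmin(times, 30)
  ints <- tibble::tibble(PatientID = sprintf("q%04d", 1:n),
                         Start = 0, Stop = cens, Dominated = z,
                         Event = times <= 30)
  fit <- fit_cox_td(ints)
  expect_true(fit$ci95[1] <= 2 && 2 <= fit$ci95[2])
  expect_equal(fit$hr, 2, tolerance = 0.15)
  expect_equal(unname(fit$ci95), unname(exp(fit$beta + c(-1, 1) * 1.96 * fit$se)))
})

test_that("degenerate survival inputs are refused with informative errors", {
  ints <- tibble::tibble(PatientID = c("a", "b"), Start = 0, Stop = 10,
                         Dominated = c(0L, 1L), Event = FALSE)
  expect_error(fit_cox_td(ints), "no events")
  ints$Event <- c(TRUE, FALSE)
  expect_error(fit_cox_td(ints), class = "hosp_cox_monotone")
  ints2 <- tibble::tibble(PatientID = c("a", "b"), Start = 0, Stop = 10,
                          Dominated = 0L, Event = c(TRUE, FALSE))
  expect_error(fit_cox_td(ints2), class = "hosp_cox_no_contrast")
})

test_that("a permuted domination covariate gives hazard ratios bracketing 1", {
  set.seed(202)
  hrs <- replicate(12, {
    dom <- make_domination(400, days = 0:40, dom_prob = 0.5)
    inf <- simulate_bsi(dom, beta = 0, baseline_hazard = 0.005)
    ints <- counting_process_from_indicator(dom, inf)
    fit_cox_td(ints)$hr
  })
  expect_lt(min(hrs), 1)
  expect_gt(max(hrs), 1)
  expect_lt(abs(mean(log(hrs))), 0.2)
})

test_that("threshold sweep reports monotone domination counts and survives fit failures", {
  gen <- generate_cohort(sim_config(n_patients = 60, bsi_baseline_hazard = 0.004),
                         seed = 12)
  sw <- threshold_sweep(gen$cohort, "Enterococcus",
                        thresholds = c(0.30, 0.10, 0.01, 0.001))
  expect_equal(sw$threshold, c(0.30, 0.10, 0.01, 0.001))
  nd <- sw$n_dominated
  expect_true(all(diff(nd) >= 0))    # lower threshold dominates at least as many
  # sweep never errors even when a threshold's fit cannot converge
  sw2 <- threshold_sweep(gen$cohort, "Escherichia",
                         thresholds = c(0.999, 0.30))
  expect_equal(nrow(sw2), 2)
})

test_that("infection timelines count events per day and genus over the window", {
  empty <- infection_timeline(gen_small$cohort$infections[0, ])
  expect_equal(nrow(empty), 0)
  inf <- tibble::tibble(PatientID = "p1", Timepoint = 104L,
                        InfectiousAgent = "Escherichia",
                        DayRelativeToNearestHCT = 4L)
  tl <- infection_timeline(inf, window = c(-15L, 35L))
  expect_equal(nrow(tl), 51)
  expect_equal(tl$n[tl$Day == 4], 1L)
  expect_equal(sum(tl$n), 1L)
})
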