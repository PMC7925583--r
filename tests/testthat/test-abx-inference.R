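drug_row <- function(pid, start, stop, factor = "cefepime",
                     category = "cephalosporins", route = "intravenous",
                     anti = TRUE) {
  tibble::tibble(PatientID = pid, StartTimepoint = as.integer(start),
                 StopTimepoint = as.integer(stop), Factor = factor,
                 Category = category, AntiInfective = anti, Route = route,
                 StartDayRelativeToNearestHCT = as.integer(start),
                 StopDayRelativeToNearestHCT = as.integer(stop))
}

test_that("drug selection keeps antibacterials, promotes singletons, drops the rest", {
  drugs <- dplyr::bind_rows(
    drug_row("p1", 0, 2),
    drug_row("p1", 0, 2, "atovaquone", "miscellaneous"),
    drug_row("p2", 1, 3, "metronidazole", "miscellaneous", "oral"),
    drug_row("p2", 1, 3, "aztreonam", "miscellaneous"),
    drug_row("p2", 1, 3, "mystery_drug", "miscellaneous"),
    drug_row("p3", 1, 3, "acyclovir", "antivirals"),
    drug_row("p3", 1, 3, "ursodiol", "gastrointestinal", anti = FALSE)
  )
  g <- apply_drug_grouping(drugs, drug_grouping_spec())
  expect_setequal(g$Group, c("cephalosporins", "metronidazole", "aztreonam"))
  expect_false("atovaquone" %in% g$Factor)
  expect_false("mystery_drug" %in% g$Factor)
  expect_false("acyclovir" %in% g$Factor)
  # every retained exposure maps to exactly one (group, route)
  expect_equal(nrow(g), nrow(dplyr::distinct(g)))
})

test_that("drug frequency counts distinct patients per route", {
  patients <- tibble::tibble(PatientID = c("p1", "p2", "p3", "p4"))
  drugs <- dplyr::bind_rows(
    drug_row("p1", 0, 2, "drugX", "quinolones", "oral"),
    drug_row("p1", 5, 6, "drugX", "quinolones", "oral"),  # second course, same patient
    drug_row("p2", 0, 2, "drugX", "quinolones", "intravenous")
  )
  fr <- drug_frequency(drugs, patients)
  oral <- fr[fr$Route == "oral", ]
  expect_equal(oral$Fraction, 0.25)
  expect_equal(oral$NPatients, 1L)
  expect_error(drug_frequency(drugs, patients[0, ]), "empty patient")

  # synthetic cohort fractions match brute-force set counting
  spec <- drug_grouping_spec()
  fr <- drug_frequency(gen_small$cohort$drugs, gen_small$cohort$hct, spec)
  g <- apply_drug_grouping(gen_small$cohort$drugs, spec)
  n_tot <- dplyr::n_distinct(gen_small$cohort$hct$PatientID)
  for (i in seq_len(nrow(fr))) {
    want <- length(unique(g$PatientID[g$Group == fr$Drug[i] &
                                        g$Route == fr$Route[i]])) / n_tot
    expect_equal(fr$Fraction[i], want)
  }
})

test_that("exposure matrix marks each day in a closed interval exactly once", {
  g <- apply_drug_grouping(drug_row("p1", 3, 5), drug_grouping_spec())
  ex <- build_exposure_matrix(g)
  expect_setequal(ex$Day, 3:5)
  # overlapping courses are OR-ed
  g2 <- apply_drug_grouping(dplyr::bind_rows(drug_row("p1", 3, 5),
                                             drug_row("p1", 5, 7)),
                            drug_grouping_spec())
  ex2 <- build_exposure_matrix(g2)
  expect_setequal(ex2$Day, 3:7)
  expect_equal(nrow(ex2), 5)

  # random interval sets match a brute-force day membership test
  set.seed(23)
  for (rep_i in 1:20) {
    starts <- sample(0:30, 5, replace = TRUE)
    stops <- starts + sample(0:6, 5, replace = TRUE)
    rows <- dplyr::bind_rows(purrr::map2(starts, stops,
                                         ~drug_row("p1", .x, .y)))
    ex <- build_exposure_matrix(apply_drug_grouping(rows, drug_grouping_spec()))
    for (d in 0:40) {
      expect_equal(d %in% ex$Day,
                   any(starts <= d & d <= stops), info = paste(rep_i, d))
    }
  }
})

test_that("pairs are consecutive, gap-limited, and require qPCR at both ends", {
  samples <- tibble::tibble(
    SampleID = c("x1", "x2", "x3"), PatientID = "p1",
    Timepoint = c(0L, 2L, 6L), Consistency = NA_character_,
    Accession = NA_character_, BioProject = NA_character_,
    DayRelativeToNearestHCT = c(0L, 2L, 6L))
  qpcr <- tibble::tibble(SampleID = c("x1", "x2", "x3"), qPCR16S = 1e8)
  p <- make_pairs(samples, qpcr)
  expect_equal(nrow(p), 1)       # (0,2) kept; (2,6) gap 4 dropped
  expect_equal(p$DeltaT, 2L)
  p <- make_pairs(samples, qpcr[-2, ])
  expect_equal(nrow(p), 0)       # qPCR missing at day 2 kills both pairs

  # synthetic cohort: pair set equals brute-force enumeration
  coh <- gen_small$cohort
  got <- make_pairs(coh$samples, coh$qpcr, max_gap_days = 3)
  want <- coh$samples |>
    dplyr::arrange(PatientID, Timepoint) |>
    dplyr::group_by(PatientID) |>
    dplyr::mutate(nid = dplyr::lead(SampleID), nt = dplyr::lead(Timepoint)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(nid), nt - Timepoint <= 3,
                  SampleID %in% coh$qpcr$SampleID, nid %in% coh$qpcr$SampleID)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$SampleID_i, got$SampleID_f),
                  paste(want$SampleID, want$nid))
  expect_true(all(got$DeltaT > 0 & got$DeltaT <= 3))
})

test_that("exposure covariates count days in the half-open window (t_i, t_f]", {
  g <- apply_drug_grouping(drug_row("p1", 3, 5), drug_grouping_spec())
  ex <- build_exposure_matrix(g)
  pairs <- tibble::tibble(PatientID = "p1", SampleID_i = "a", SampleID_f = "b",
                          T_i = 2L, T_f = 5L, DeltaT = 3L)
  pc <- pair_covariates(pairs, ex)
  cc <- attr(pc, "covariate_cols")
  expect_equal(pc[[cc]], 3L)              # days {3,4,5}
  # drug only on the initial sampled day does not contribute
  pairs2 <- tibble::tibble(PatientID = "p1", SampleID_i = "a", SampleID_f = "b",
                           T_i = 5L, T_f = 7L, DeltaT = 2L)
  expect_equal(pair_covariates(pairs2, ex)[[cc]], 0L)
  # full coverage attains the upper bound C = DeltaT
  g3 <- apply_drug_grouping(drug_row("p1", 0, 10), drug_grouping_spec())
  expect_equal(pair_covariates(pairs, build_exposure_matrix(g3))[[cc]], 3L)
})

test_that("covariates are bounded by the pair gap on synthetic cohorts", {
  coh <- gen_small$cohort
  g <- apply_drug_grouping(coh$drugs, drug_grouping_spec())
  pc <- pair_covariates(make_pairs(coh$samples, coh$qpcr),
                        build_exposure_matrix(g))
  for (cc in attr(pc, "covariate_cols")) {
    expect_true(all(pc[[cc]] >= 0 & pc[[cc]] <= pc$DeltaT), info = cc)
  }
})

test_that("taxon ranking follows mean relative abundance over pair samples", {
  counts <- tibble::tibble(
    SampleID = rep(c("x1", "x2"), each = 2),
    ASV = rep(c("big", "small"), 2),
    Count = c(90, 10, 85, 15))
  pairs <- tibble::tibble(PatientID = "p", SampleID_i = "x1",
                          SampleID_f = "x2", T_i = 0L, T_f = 1L, DeltaT = 1L)
  top <- select_taxa(counts, pairs, k = 1)
  expect_equal(top$Taxon, "big")
  expect_warning(sel <- select_taxa(counts, pairs, k = 10), "only 2 taxa")
  expect_equal(nrow(sel), 2)
})

test_that("regression rows use natural log and discard zero endpoints", {
  pairs <- tibble::tibble(PatientID = "p", SampleID_i = c("x1", "x3"),
                          SampleID_f = c("x2", "x4"),
                          T_i = c(0L, 5L), T_f = c(1L, 6L),
                          DeltaT = c(1L, 1L))
  attr(pairs, "covariate_cols") <- character(0)
  ab <- tibble::tibble(SampleID = c("x1", "x2", "x3", "x4"),
                       Taxon = "t1", Count = 1,
                       Fraction = 1, Abundance = c(10, 100, 0, 50))
  prob <- assemble_problem("t1", pairs, ab)
  expect_equal(length(prob$Y), 1)          # zero-abundance endpoint dropped
  expect_equal(prob$Y, log(10))
  expect_equal(unname(prob$D[1, 1]), 1)
  ab0 <- dplyr::mutate(ab, Abundance = 0)
  expect_error(assemble_problem("t1", pairs, ab0),
               class = "hosp_not_estimable")
})

test_that("ridge solution matches OLS at zero and direct minimization elsewhere", {
  set.seed(55)
  for (rep_i in 1:5) {
    D <- matrix(rnorm(40), 10, 4)
    Y <- rnorm(10)
    prob <- list(Y = Y, D = D)
    # lambda = 0 equals ordinary least squares
    expect_lt(max(abs(fit_ridge(prob, 0) - coef(lm(Y ~ D - 1)))), 1e-10)
    # lambda = 1 matches direct numerical minimization of the objective
    obj <- function(x) sum((Y - D %*% x)^2) + 1 * sum(x^2)
    grd <- function(x) -2 * crossprod(D, Y - D %*% x) + 2 * x
    opt <- optim(rep(0, 4), obj, grd, method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 2000))
    expect_lt(max(abs(fit_ridge(prob, 1) - opt$par)), 1e-8)
    # shrinkage limit
    expect_lt(sqrt(sum(fit_ridge(prob, 1e9)^2)), 1e-3)
  }
  # unpenalized-intercept option leaves the first coefficient out of the identity
  D <- cbind(1, matrix(rnorm(30), 10, 3)); Y <- rnorm(10)
  prob <- list(Y = Y, D = D)
  x <- fit_ridge(prob, 5, penalize_intercept = FALSE)
  obj <- function(b) sum((Y - D %*% b)^2) + 5 * sum(b[-1]^2)
  grd <- function(b) -2 * crossprod(D, Y - D %*% b) + 10 * c(0, b[-1])
  opt <- optim(rep(0, 4), obj, grd, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 2000))
  expect_lt(max(abs(x - opt$par)), 1e-8)
})

test_that("ridge coefficient norm shrinks monotonically with lambda", {
  set.seed(66)
  D <- matrix(rnorm(60), 20, 3); Y <- rnorm(20)
  norms <- sapply(10^seq(-3, 3, by = 0.5),
                  function(l) sqrt(sum(fit_ridge(list(Y = Y, D = D), l)^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("cross-validation picks no shrinkage for a noiseless consistent system", {
  set.seed(77)
  D <- cbind(sample(1:3, 40, TRUE), matrix(rbinom(120, 3, 0.3), 40, 3))
  X <- c(0.4, -0.6, 0.3, 0.2)
  prob <- list(Y = as.vector(D %*% X), D = D,
               pairs = tibble::tibble(PatientID = rep("p", 40)))
  cfg <- ridge_config(seed = 3)
  sel <- select_lambda(prob, cfg)
  expect_equal(sel$lambda, cfg$lambda_grid[1])
  # determinism under the config seed
  sel2 <- select_lambda(prob, cfg)
  expect_identical(sel$cv_curve, sel2$cv_curve)
})

test_that("cross-validation shrinks a pure-noise response", {
  set.seed(88)
  D <- cbind(sample(1:3, 60, TRUE), matrix(rbinom(180, 3, 0.4), 60, 3))
  prob <- list(Y = rnorm(60), D = D,
               pairs = tibble::tibble(PatientID = rep("p", 60)))
  sel <- select_lambda(prob, ridge_config(seed = 5))
  cv <- sel$cv_curve
  expect_lt(cv$sse[nrow(cv)], cv$sse[1])   # heavy shrinkage beats none
})

test_that("a cohort without drugs still recovers growth rates", {
  cfg <- sim_config(n_patients = 15, n_drug_groups = 0, decoy_drug_rate = 0,
                    dynamics_noise_sd = 0, qpcr_noise_sd_log10 = 0,
                    read_depth_mean = Inf, qpcr_coverage = 1)
  gen <- generate_cohort(cfg, seed = 9)
  fit <- suppressWarnings(
    infer_susceptibilities(gen$cohort, ridge = ridge_config(lambda_grid = 1e-8),
                           k = 20))
  co <- tidy(fit)
  expect_true(all(co$Term == "growth_rate"))
  expect_equal(co$Estimate, unname(gen$truth$g[co$Taxon]), tolerance = 1e-6)
})
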