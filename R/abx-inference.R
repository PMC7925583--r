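# Inference of per-antibiotic effects on taxon growth rates.
#
# Model: d log N_k / dt = g_k + sum_j eps_{k,j} u_j(t), with u_j binary
# presence of drug group j. Integrated over a consecutive-sample pair p,
#   log N_k(t_f) - log N_k(t_i) = g_k * dt_p + sum_j eps_{k,j} C_{p,j},
# C_{p,j} = exposed days of group j in the half-open window (t_i, t_f].
# Stacking all pairs gives Y_k = D_k X_k, solved per taxon by ridge
# regression with lambda chosen by repeated 3-fold cross-validation.

#' Drug selection and grouping rules
#'
#' Encodes the antibacterial drug-selection policy: keep only drugs in
#' antibacterial classes, drop `atovaquone`, promote `metronidazole` and
#' `aztreonam` out of the miscellaneous class as their own single-drug
#' groups, remove other miscellaneous drugs, and group the rest by drug
#' category, analyzed separately per administration route.
#'
#' @param antibacterial_categories Character vector of categories counted
#'   as antibacterial classes; defaults to the synthetic generator's class
#'   taxonomy.
#' @param exclude_factors Drug names always removed.
#' @param singleton_factors Drug names promoted to their own groups.
#' @param miscellaneous_category Category whose non-promoted members are
#'   removed.
#' @param routes Routes retained.
#' @return A list of class `drug_grouping_spec`.
#' @export
drug_grouping_spec <- function(antibacterial_categories = synthetic_drug_classes,
                               exclude_factors = "atovaquone",
                               singleton_factors = c("metronidazole", "aztreonam"),
                               miscellaneous_category = "miscellaneous",
                               routes = c("oral", "intravenous")) {
  structure(list(
    antibacterial_categories = antibacterial_categories,
    exclude_factors = exclude_factors,
    singleton_factors = singleton_factors,
    miscellaneous_category = miscellaneous_category,
    routes = routes
  ), class = "drug_grouping_spec")
}

#' Apply the drug-grouping rules to an exposure table
#'
#' @param drugs Drug-exposure tibble (`tbldrug.csv` layout).
#' @param spec A [drug_grouping_spec()].
#' @return The retained rows with added `Group` column; every retained
#'   exposure maps to exactly one (Group, Route).
#' @export
apply_drug_grouping <- function(drugs, spec = drug_grouping_spec()) {
  d <- drugs |>
    filter(tolower(.data$Route) %in% spec$routes,
           !tolower(.data$Factor) %in% tolower(spec$exclude_factors))
  singleton <- tolower(d$Factor) %in% tolower(spec$singleton_factors)
  keep <- singleton |
    (d$Category %in% spec$antibacterial_categories &
       d$Category != spec$miscellaneous_category)
  d <- d[keep, , drop = FALSE]
  singleton <- tolower(d$Factor) %in% tolower(spec$singleton_factors)
  d$Group <- ifelse(singleton, tolower(d$Factor), d$Category)
  d$Route <- tolower(d$Route)
  d
}

#' Fraction of patients ever exposed, per drug and route
#'
#' @param drugs Drug-exposure tibble.
#' @param patients Patient table (`tblhctmeta.csv` layout) defining the
#'   denominator (distinct `PatientID`).
#' @param spec Optional [drug_grouping_spec()]; when given, frequencies are
#'   per (Group, Route) after the selection rules, otherwise per
#'   (Factor, Route) over all drugs.
#' @return Tibble `Drug`, `Category`, `Route`, `NPatients`, `Fraction`.
#' @export
drug_frequency <- function(drugs, patients, spec = NULL) {
  n_total <- n_distinct(patients$PatientID)
  if (n_total == 0) abort("empty patient table")
  if (!is.null(spec)) {
    d <- apply_drug_grouping(drugs, spec)
    d$Drug <- d$Group
  } else {
    d <- mutate(drugs, Drug = .data$Factor, Route = tolower(.data$Route))
  }
  d |>
    distinct(.data$Drug, .data$Category, .data$Route, .data$PatientID) |>
    count(.data$Drug, .data$Category, .data$Route, name = "NPatients") |>
    mutate(Fraction = .data$NPatients / n_total) |>
    arrange(.data$Route, desc(.data$Fraction))
}

#' Binary exposure matrix from closed drug intervals
#'
#' Expands closed `[StartTimepoint, StopTimepoint]` courses into per-day
#' presence indicators per (patient, group, route); overlapping courses of
#' the same group are OR-ed, never double-counted.
#'
#' @param drugs_grouped Output of [apply_drug_grouping()] (needs `Group`).
#' @param day_range Optional length-2 integer clamp on the day axis.
#' @return Tibble `PatientID`, `Day`, `Group`, `Route` with one row per
#'   exposed patient-day-group (u = 1 rows only).
#' @export
build_exposure_matrix <- function(drugs_grouped, day_range = NULL) {
  if (nrow(drugs_grouped) == 0) {
    return(tibble(PatientID = character(0), Day = integer(0),
                  Group = character(0), Route = character(0)))
  }
  stopifnot(all(drugs_grouped$StopTimepoint >= drugs_grouped$StartTimepoint))
  out <- drugs_grouped |>
    select("PatientID", "Group", "Route", "StartTimepoint", "StopTimepoint") |>
    mutate(Day = purrr::map2(.data$StartTimepoint, .data$StopTimepoint, seq)) |>
    tidyr::unnest("Day") |>
    distinct(.data$PatientID, Day = as.integer(.data$Day), .data$Group,
             .data$Route)
  if (!is.null(day_range)) {
    out <- filter(out, .data$Day >= day_range[1], .data$Day <= day_range[2])
  }
  out
}

#' Consecutive same-patient sample pairs
#'
#' Pairs adjacent samples in each patient's day-sorted sequence, keeping
#' pairs at most `max_gap_days` apart with a qPCR measurement at both
#' endpoints. Multiple samples on one patient-day keep the first by
#' SampleID sort order (logged via message).
#'
#' @param samples Sample table.
#' @param qpcr qPCR table.
#' @param max_gap_days Maximum allowed day gap (default 3, the minimum
#'   interval that retains the majority of consecutive samples in dense
#'   inpatient series).
#' @return Tibble `PatientID`, `SampleID_i`, `SampleID_f`, `T_i`, `T_f`,
#'   `DeltaT`.
#' @export
make_pairs <- function(samples, qpcr, max_gap_days = 3) {
  s <- samples |>
    arrange(.data$PatientID, .data$Timepoint, .data$SampleID)
  dup <- duplicated(s[c("PatientID", "Timepoint")])
  if (any(dup)) {
    inform(sprintf("make_pairs: %d duplicate patient-day sample(s) dropped (first by SampleID kept)",
                   sum(dup)))
    s <- s[!dup, , drop = FALSE]
  }
  s <- mutate(s, has_qpcr = .data$SampleID %in% qpcr$SampleID)
  pairs <- s |>
    group_by(.data$PatientID) |>
    mutate(SampleID_f = lead(.data$SampleID),
           T_f = lead(.data$Timepoint),
           qpcr_f = lead(.data$has_qpcr)) |>
    ungroup() |>
    filter(!is.na(.data$SampleID_f)) |>
    transmute(.data$PatientID,
              SampleID_i = .data$SampleID, SampleID_f = .data$SampleID_f,
              T_i = .data$Timepoint, T_f = .data$T_f,
              DeltaT = .data$T_f - .data$T_i,
              ok = .data$has_qpcr & .data$qpcr_f)
  pairs |>
    filter(.data$DeltaT > 0, .data$DeltaT <= max_gap_days, .data$ok) |>
    select(-"ok")
}

#' Cumulative exposure covariates for sample pairs
#'
#' For each pair and each (group, route), counts the exposed days in the
#' half-open window `(T_i, T_f]` — day-resolution quadrature of the
#' exposure integral. A drug active only on the pair's initial sampled day
#' does not contribute; always `0 <= C <= DeltaT`.
#'
#' @param pairs Output of [make_pairs()].
#' @param exposure Output of [build_exposure_matrix()].
#' @return `pairs` with one added `C: group/route` column per exposure
#'   covariate (attribute `covariate_cols` lists them).
#' @export
pair_covariates <- function(pairs, exposure) {
  keys <- exposure |> distinct(.data$Group, .data$Route) |>
    arrange(.data$Group, .data$Route)
  cov_cols <- if (nrow(keys)) paste0("C: ", keys$Group, "/", keys$Route) else character(0)
  out <- pairs
  for (i in seq_len(nrow(keys))) {
    ex <- exposure |>
      filter(.data$Group == keys$Group[i], .data$Route == keys$Route[i])
    cnt <- purrr::pmap_int(list(pairs$PatientID, pairs$T_i, pairs$T_f),
      function(p, ti, tf) {
        sum(ex$PatientID == p & ex$Day > ti & ex$Day <= tf)
      })
    out[[cov_cols[i]]] <- cnt
  }
  attr(out, "covariate_cols") <- cov_cols
  attr(out, "covariate_keys") <- keys
  out
}

#' Rank taxa by mean relative abundance over pair samples
#'
#' Ranks ASVs by their mean relative abundance across the samples that
#' participate in retained pairs, and returns the top `k`.
#'
#' @param counts Melted counts.
#' @param pairs Output of [make_pairs()].
#' @param k Number of taxa to return.
#' @param statistic `"mean_abundance"` (default), `"total_counts"` or
#'   `"prevalence"`.
#' @return Tibble `Taxon`, `Statistic`, ranked descending.
#' @export
select_taxa <- function(counts, pairs, k = 20, statistic = "mean_abundance") {
  sample_ids <- unique(c(pairs$SampleID_i, pairs$SampleID_f))
  sub <- filter(counts, .data$SampleID %in% sample_ids)
  taxon_col <- if ("ASV" %in% names(sub)) "ASV" else "Taxon"
  rel <- relative_abundance(sub)
  n_samples <- n_distinct(sub$SampleID)
  stat <- switch(statistic,
    mean_abundance = rel |>
      group_by(Taxon = .data[[taxon_col]]) |>
      summarise(Statistic = sum(.data$Fraction) / n_samples, .groups = "drop"),
    total_counts = sub |>
      group_by(Taxon = .data[[taxon_col]]) |>
      summarise(Statistic = sum(.data$Count), .groups = "drop"),
    prevalence = sub |>
      filter(.data$Count > 0) |>
      group_by(Taxon = .data[[taxon_col]]) |>
      summarise(Statistic = n() / n_samples, .groups = "drop"),
    abort(paste0("unknown statistic: ", statistic))
  )
  stat <- arrange(stat, desc(.data$Statistic), .data$Taxon)
  if (nrow(stat) < k) {
    warn(sprintf("only %d taxa available (k = %d); returning all", nrow(stat), k))
    k <- nrow(stat)
  }
  head(stat, k)
}

#' Assemble the per-taxon regression problem
#'
#' Builds the stacked linear system Y = D X for one taxon: response is the
#' natural-log absolute-abundance change over each pair, design columns are
#' `[DeltaT, C_1, ..., C_Ma]`. Pairs where the taxon's absolute abundance
#' is zero (or absent) at either endpoint are discarded.
#'
#' @param taxon Taxon identifier.
#' @param pairs_cov Output of [pair_covariates()].
#' @param abs_ab Absolute abundances ([absolute_abundance()] output).
#' @return List of class `hosp_regression_problem`: `taxon`, `Y`, `D`
#'   (first column `DeltaT`), `pairs` (retained rows), `covariate_cols`.
#' @export
assemble_problem <- function(taxon, pairs_cov, abs_ab) {
  taxon_col <- attr(abs_ab, "taxon_col") %||%
    (if ("ASV" %in% names(abs_ab)) "ASV" else "Taxon")
  ab <- abs_ab |>
    filter(.data[[taxon_col]] == taxon, .data$Abundance > 0) |>
    select("SampleID", "Abundance")
  cov_cols <- attr(pairs_cov, "covariate_cols") %||% character(0)
  rows <- pairs_cov |>
    inner_join(rename(ab, A_i = "Abundance"), by = c(SampleID_i = "SampleID")) |>
    inner_join(rename(ab, A_f = "Abundance"), by = c(SampleID_f = "SampleID"))
  if (nrow(rows) == 0) {
    abort(paste0("taxon not estimable (no pairs with non-zero endpoints): ", taxon),
          class = "hosp_not_estimable")
  }
  Y <- log(rows$A_f) - log(rows$A_i)
  D <- cbind(DeltaT = rows$DeltaT,
             as.matrix(rows[, cov_cols, drop = FALSE]))
  structure(list(taxon = taxon, Y = Y, D = D, pairs = rows,
                 covariate_cols = cov_cols),
            class = "hosp_regression_problem")
}

#' Ridge regression by closed-form normal equations
#'
#' Solves `argmin ||Y - D X||^2 + lambda ||X||^2` as
#' `(D'D + lambda I)^{-1} D'Y`. The penalty includes the growth-rate
#' intercept (first column) by default; `penalize_intercept = FALSE`
#' excludes it from the identity. At `lambda = 0` with a rank-deficient
#' design the minimum-norm least-squares solution is returned with a
#' warning.
#'
#' @param problem A `hosp_regression_problem` (or list with `Y`, `D`).
#' @param lambda Non-negative penalty.
#' @param penalize_intercept Include the first coefficient in the penalty?
#' @return Named numeric coefficient vector `[g, eps_1, ...]`.
#' @export
fit_ridge <- function(problem, lambda, penalize_intercept = TRUE) {
  D <- problem$D; Y <- problem$Y
  stopifnot(lambda >= 0, nrow(D) == length(Y))
  p <- ncol(D)
  pen <- diag(p)
  if (!penalize_intercept) pen[1, 1] <- 0
  A <- crossprod(D) + lambda * pen
  ok <- TRUE
  x <- tryCatch(solve(A, crossprod(D, Y)), error = function(e) { ok <<- FALSE; NULL })
  if (!ok || any(!is.finite(x))) {
    warn("rank-deficient design at lambda = 0: returning minimum-norm solution")
    sv <- svd(D)
    keep <- sv$d > max(dim(D)) * .Machine$double.eps * sv$d[1]
    x <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], Y)) / sv$d[keep])
  }
  set_names(as.vector(x), colnames(D))
}

#' Cross-validation settings for the ridge fit
#'
#' @param lambda_grid Ascending positive penalties; default 25 points
#'   log-spaced over `[1e-4, 1e4]`.
#' @param folds Number of CV folds (default 3).
#' @param monte_carlo_reps Number of random re-partitions (default 10).
#' @param seed Seed for the partitions.
#' @param penalize_intercept Passed to [fit_ridge()].
#' @param group_by_patient Partition pairs by patient instead of by row
#'   (leakage-averse option; default `FALSE`, matching the row-wise
#'   objective).
#' @return List of class `ridge_config`.
#' @export
ridge_config <- function(lambda_grid = 10^seq(-4, 4, length.out = 25),
                         folds = 3, monte_carlo_reps = 10, seed = 1,
                         penalize_intercept = TRUE,
                         group_by_patient = FALSE) {
  stopifnot(all(diff(lambda_grid) > 0) || length(lambda_grid) == 1,
            folds >= 2, monte_carlo_reps >= 1)
  structure(list(lambda_grid = lambda_grid, folds = folds,
                 monte_carlo_reps = monte_carlo_reps, seed = seed,
                 penalize_intercept = penalize_intercept,
                 group_by_patient = group_by_patient),
            class = "ridge_config")
}

#' Choose the ridge penalty by repeated k-fold cross-validation
#'
#' For each lambda, accumulates the held-out sum of squared errors over
#' `folds x monte_carlo_reps` random partitions; the minimizer is then
#' refit on all rows. Reproducible under the config seed. A single-point
#' grid skips cross-validation.
#'
#' @param problem A `hosp_regression_problem`.
#' @param config A [ridge_config()].
#' @return List: `lambda` (chosen), `coefficients` (refit at `lambda`),
#'   `cv_curve` (tibble `lambda`, `sse`).
#' @export
select_lambda <- function(problem, config = ridge_config()) {
  n <- length(problem$Y)
  grid <- config$lambda_grid
  if (length(grid) == 1) {
    return(list(lambda = grid,
                coefficients = fit_ridge(problem, grid, config$penalize_intercept),
                cv_curve = tibble(lambda = grid, sse = NA_real_)))
  }
  if (n < config$folds) abort("fewer pairs than folds")
  set.seed(config$seed)
  sse <- rep(0, length(grid))
  units <- if (config$group_by_patient) problem$pairs$PatientID else seq_len(n)
  uniq <- unique(units)
  for (rep_i in seq_len(config$monte_carlo_reps)) {
    fold_of_unit <- set_names(sample(rep_len(seq_len(config$folds), length(uniq))),
                              uniq)
    fold <- fold_of_unit[as.character(units)]
    for (f in seq_len(config$folds)) {
      test <- fold == f
      if (!any(test) || all(test)) next
      sub <- list(Y = problem$Y[!test], D = problem$D[!test, , drop = FALSE])
      for (li in seq_along(grid)) {
        x <- fit_ridge(sub, grid[li], config$penalize_intercept)
        resid <- problem$Y[test] - problem$D[test, , drop = FALSE] %*% x
        sse[li] <- sse[li] + sum(resid^2)
      }
    }
  }
  best <- which.min(sse)
  list(lambda = grid[best],
       coefficients = fit_ridge(problem, grid[best], config$penalize_intercept),
       cv_curve = tibble(lambda = grid, sse = sse))
}

#' Infer antibiotic susceptibilities for the most abundant taxa
#'
#' Runs the full chain: drug grouping, binary exposure matrix, consecutive
#' sample pairs (gap <= `max_gap_days`, qPCR at both ends), cumulative
#' exposure covariates, top-`k` taxon selection, and per-taxon
#' cross-validated ridge regression of natural-log absolute-abundance
#' changes on `[DeltaT, C_1..C_Ma]`.
#'
#' By default a single joint design over both administration routes is
#' fit, with one covariate per (drug group, route); `routes = "oral"` or
#' `"intravenous"` restricts the covariates (and hence the fit) to one
#' route, reproducing a fully separate per-route analysis.
#'
#' @param cohort A cohort with counts, qPCR and drug tables.
#' @param grouping A [drug_grouping_spec()].
#' @param ridge A [ridge_config()].
#' @param k Number of most-abundant taxa to analyze.
#' @param max_gap_days Maximum pair gap in days.
#' @param routes `"both"`, `"oral"` or `"intravenous"`.
#' @param taxon_statistic Ranking statistic for [select_taxa()].
#' @return Object of class `abx_fit`: list with `coefficients` (tibble
#'   `Taxon`, `Term`, `Group`, `Route`, `Estimate`), `lambda` per taxon,
#'   `n_pairs`, `n_patients`, `taxa`, `cv_curves`, `settings`.
#' @export
infer_susceptibilities <- function(cohort,
                                   grouping = drug_grouping_spec(),
                                   ridge = ridge_config(),
                                   k = 20,
                                   max_gap_days = 3,
                                   routes = c("both", "oral", "intravenous"),
                                   taxon_statistic = "mean_abundance") {
  routes <- match.arg(routes)
  grouped <- apply_drug_grouping(cohort$drugs, grouping)
  if (routes != "both") grouped <- filter(grouped, .data$Route == routes)
  exposure <- build_exposure_matrix(grouped)
  pairs <- make_pairs(cohort$samples, cohort$qpcr, max_gap_days)
  if (nrow(pairs) == 0) abort("no sample pairs satisfy the filters")
  pairs_cov <- pair_covariates(pairs, exposure)
  taxa <- select_taxa(cohort$counts, pairs, k = k, statistic = taxon_statistic)
  abs_ab <- absolute_abundance(relative_abundance(cohort$counts), cohort$qpcr)

  keys <- attr(pairs_cov, "covariate_keys")
  coefs <- list(); lambdas <- list(); curves <- list()
  for (tx in taxa$Taxon) {
    prob <- tryCatch(assemble_problem(tx, pairs_cov, abs_ab),
                     hosp_not_estimable = function(e) NULL)
    if (is.null(prob)) next
    sel <- select_lambda(prob, ridge)
    x <- sel$coefficients
    coefs[[tx]] <- tibble(
      Taxon = tx,
      Term = c("growth_rate", attr(pairs_cov, "covariate_cols")),
      Group = c(NA_character_, keys$Group),
      Route = c(NA_character_, keys$Route),
      Estimate = as.numeric(x),
      NPairsUsed = nrow(prob$pairs)
    )
    lambdas[[tx]] <- tibble(Taxon = tx, Lambda = sel$lambda)
    curves[[tx]] <- mutate(sel$cv_curve, Taxon = tx, .before = 1)
  }
  if (length(coefs) == 0) abort("no estimable taxa")
  structure(list(
    coefficients = bind_rows(coefs),
    lambda = bind_rows(lambdas),
    cv_curves = bind_rows(curves),
    n_pairs = nrow(pairs),
    n_patients = n_distinct(pairs$PatientID),
    taxa = taxa,
    settings = list(grouping = grouping, ridge = ridge, k = k,
                    max_gap_days = max_gap_days, routes = routes,
                    exposure_window = "(t_i, t_f]")
  ), class = "abx_fit")
}

#' @export
print.abx_fit <- function(x, ...) {
  cat("<abx_fit>\n")
  cat(sprintf("  taxa analyzed : %d\n", n_distinct(x$coefficients$Taxon)))
  cat(sprintf("  sample pairs  : %d from %d patients\n", x$n_pairs, x$n_patients))
  cat(sprintf("  covariates    : %d (route mode: %s)\n",
              n_distinct(x$coefficients$Term) - 1, x$settings$routes))
  invisible(x)
}

#' Tidy an antibiotic-susceptibility fit
#'
#' @param x An `abx_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (taxon, term): growth-rate intercepts
#'   and per-(group, route) susceptibilities, in 1/day.
#' @export
tidy.abx_fit <- function(x, ...) x$coefficients

#' One-row summary of an antibiotic-susceptibility fit
#'
#' @param x An `abx_fit`.
#' @param ... Unused.
#' @export
glance.abx_fit <- function(x, ...) {
  tibble(n_taxa = n_distinct(x$coefficients$Taxon),
         n_pairs = x$n_pairs,
         n_patients = x$n_patients,
         n_covariates = n_distinct(x$coefficients$Term) - 1L,
         median_lambda = median(x$lambda$Lambda))
}

#' Turn a fitted object into a tidy tibble
#'
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
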