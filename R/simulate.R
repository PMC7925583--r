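# Synthetic hospitalome cohorts.
#
# The forward model is the package's log-linear growth model: each taxon's
# log absolute abundance performs a daily random walk with drift
#   log N_k(t) = log N_k(t-1) + g_k + sum_j eps_{k,j} u_j(t) + eta_t,
# eta_t ~ Normal(0, noise_sd^2). The step into day t uses the drug exposure
# state of day t itself, so the change in log N over a sample pair
# (t_i, t_f] equals g * dt + sum_j eps_j * C_j with C_j counting exposed
# days in the half-open window (t_i, t_f] — the same convention the
# inference module uses for its exposure covariates.

# sample() treats a length-1 integer as 1:n; this keeps draws literal
sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

synthetic_drug_classes <- c(
  "penicillins", "cephalosporins", "quinolones", "glycopeptides",
  "carbapenems", "macrolides", "aminoglycosides", "tetracyclines"
)

synthetic_genera <- c(
  "Enterococcus", "Escherichia", "Blautia", "Bacteroides", "Lactobacillus",
  "Streptococcus", "Klebsiella", "Faecalibacterium", "Akkermansia",
  "Ruminococcus", "Clostridium", "Veillonella", "Prevotella", "Roseburia",
  "Dorea", "Parabacteroides"
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a small allo-HCT-like cohort: one transplant per
#' patient at relative day 0, stool sampled every 1--4 days over day -15 to
#' +35, sequencing depth around 5e4 reads, qPCR load with 0.1 log10
#' measurement noise, day-scale growth perturbations from interval-coded
#' antibiotic courses, and genus-matched bloodstream-infection events whose
#' hazard is multiplied by `exp(bsi_beta)` while the focal genus dominates.
#'
#' @param n_patients Number of patients.
#' @param n_taxa Number of ASVs.
#' @param n_drug_groups Number of antibacterial drug groups (each group is
#'   administered by a single fixed route, alternating oral / intravenous).
#' @param day_window Integer length-2: simulated days relative to HCT.
#' @param sampling_interval_days Integer vector of admissible gaps between
#'   consecutive stool samples (sampled uniformly).
#' @param read_depth_mean,read_depth_dispersion Negative-binomial sequencing
#'   depth; `read_depth_mean = Inf` switches to exact (infinite-depth)
#'   observation in which latent abundances are recorded as real-valued
#'   pseudo-counts.
#' @param qpcr_noise_sd_log10 SD of log10 multiplicative noise on total 16S
#'   load; 0 means the qPCR value equals the latent total exactly.
#' @param qpcr_coverage Fraction of samples that receive a qPCR measurement.
#' @param dynamics_noise_sd Daily process noise SD on natural-log abundance
#'   (per sqrt(day)).
#' @param drug_course_rate Mean antibacterial courses per patient (Poisson).
#' @param drug_course_duration_mean Mean course length in days (geometric,
#'   minimum 1).
#' @param decoy_drug_rate Mean non-antibacterial / excluded courses per
#'   patient (atovaquone, antivirals, ...), exercising the drug-selection
#'   rules.
#' @param bsi_beta Log hazard ratio of domination for bloodstream infection.
#' @param bsi_baseline_hazard Baseline daily infection hazard.
#' @param domination_threshold Relative-abundance threshold defining
#'   intestinal domination in the event simulation.
#' @param bsi_genus Genus whose domination drives infection risk (assigned
#'   to the first taxon).
#' @param extinction_floor Latent absolute abundance below which a taxon is
#'   recorded as absent (count 0).
#' @param g_mean,g_sd Distribution of per-taxon intrinsic growth rates
#'   (1/day).
#' @param epsilon_nonzero_prob,epsilon_min,epsilon_max Susceptibilities
#'   eps_{k,j}: with probability `epsilon_nonzero_prob` drawn with random
#'   sign and magnitude Uniform(`epsilon_min`, `epsilon_max`), else 0.
#' @param log10_n0_mean,log10_n0_sd Initial per-taxon log10 absolute
#'   abundance (16S copies per gram).
#' @param multi_hct_prob Probability that a patient has a second transplant.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 50,
                       n_taxa = 10,
                       n_drug_groups = 4,
                       day_window = c(-15L, 35L),
                       sampling_interval_days = 1:4,
                       read_depth_mean = 5e4,
                       read_depth_dispersion = 10,
                       qpcr_noise_sd_log10 = 0.1,
                       qpcr_coverage = 0.85,
                       dynamics_noise_sd = 0.2,
                       drug_course_rate = 2,
                       drug_course_duration_mean = 5,
                       decoy_drug_rate = 1,
                       bsi_beta = log(4),
                       bsi_baseline_hazard = 0.002,
                       domination_threshold = 0.3,
                       bsi_genus = "Enterococcus",
                       extinction_floor = 1,
                       g_mean = 0.1, g_sd = 0.15,
                       epsilon_nonzero_prob = 0.5,
                       epsilon_min = 0.25, epsilon_max = 0.75,
                       log10_n0_mean = 8, log10_n0_sd = 0.6,
                       multi_hct_prob = 0) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_patients >= 1, cfg$n_taxa >= 1, cfg$n_drug_groups >= 0,
    cfg$day_window[1] < cfg$day_window[2],
    cfg$domination_threshold > 0, cfg$domination_threshold < 1,
    cfg$dynamics_noise_sd >= 0, cfg$qpcr_noise_sd_log10 >= 0,
    cfg$drug_course_rate >= 0, cfg$bsi_baseline_hazard >= 0
  )
  structure(cfg, class = "sim_config")
}

#' Simulate latent log-abundance trajectories
#'
#' Daily Euler integration of the log-linear growth model. `exposure` gives
#' the binary drug-group state per day; row `t` of the returned matrix is
#' the state after stepping through exposure day `t`.
#'
#' @param g Numeric vector of intrinsic growth rates, one per taxon (1/day).
#' @param epsilon Numeric taxa-by-groups matrix of susceptibilities (1/day).
#' @param exposure Binary days-by-groups matrix `u_j(t)`.
#' @param log_n0 Numeric vector of initial natural-log abundances.
#' @param noise_sd Daily process noise SD (natural log scale); 0 gives the
#'   exact deterministic update.
#' @return A `(days + 1) x n_taxa` matrix of natural-log abundances; row 1
#'   is the initial state.
#' @export
simulate_dynamics <- function(g, epsilon, exposure, log_n0, noise_sd = 0) {
  epsilon <- as.matrix(epsilon)
  exposure <- as.matrix(exposure)
  k <- length(g)
  stopifnot(nrow(epsilon) == k, length(log_n0) == k,
            ncol(exposure) == ncol(epsilon))
  if (any(!is.finite(g)) || any(!is.finite(epsilon)) || any(!is.finite(log_n0))) {
    abort("non-finite inputs to simulate_dynamics")
  }
  days <- nrow(exposure)
  out <- matrix(NA_real_, nrow = days + 1, ncol = k)
  out[1, ] <- log_n0
  for (t in seq_len(days)) {
    drift <- g + as.vector(epsilon %*% exposure[t, ])
    eta <- if (noise_sd > 0) rnorm(k, 0, noise_sd) else 0
    out[t + 1, ] <- out[t, ] + drift + eta
  }
  out
}

#' Observe one stool sample: multinomial reads and qPCR total load
#'
#' @param abundances Non-negative latent absolute abundances (not all zero).
#' @param depth Total read count; `Inf` records the abundances themselves as
#'   exact real-valued pseudo-counts.
#' @param qpcr_noise_sd_log10 SD of log10 noise on the total load.
#' @return List with `counts` (per-taxon reads) and `qpcr` (measured total
#'   16S copies per gram).
#' @export
observe_sample <- function(abundances, depth, qpcr_noise_sd_log10 = 0) {
  if (any(abundances < 0)) abort("negative abundance")
  if (sum(abundances) <= 0) abort("all-zero abundance vector")
  if (is.infinite(depth)) {
    counts <- abundances
  } else {
    stopifnot(depth > 0)
    counts <- as.vector(rmultinom(1, size = depth, prob = abundances / sum(abundances)))
  }
  noise <- if (qpcr_noise_sd_log10 > 0) 10^rnorm(1, 0, qpcr_noise_sd_log10) else 1
  list(counts = counts, qpcr = sum(abundances) * noise)
}

#' Simulate interval-coded drug courses
#'
#' Emits closed-interval `[StartTimepoint, StopTimepoint]` courses in the
#' deposited drug-table layout. Antibacterial groups are labelled with
#' synthetic drug-class categories, each with a fixed administration route;
#' decoy courses (atovaquone, an antiviral, a non-anti-infective) exercise
#' the drug-selection rules downstream.
#'
#' @param config A [sim_config()].
#' @param patient_ids Character vector of patients.
#' @param hct_timepoint Named integer vector: each patient's transplant
#'   timepoint (courses are placed in the day window around it).
#' @return Tibble in `tbldrug.csv` layout.
#' @export
simulate_drug_courses <- function(config, patient_ids, hct_timepoint) {
  w <- config$day_window
  groups <- synthetic_drug_classes[seq_len(config$n_drug_groups)]
  routes <- rep(c("intravenous", "oral"), length.out = length(groups))
  decoys <- tibble(
    Factor = c("atovaquone", "acyclovir", "metronidazole", "aztreonam", "ursodiol"),
    Category = c("miscellaneous", "antivirals", "miscellaneous",
                 "miscellaneous", "gastrointestinal"),
    AntiInfective = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  rows <- list()
  for (pid in patient_ids) {
    anchor <- hct_timepoint[[pid]]
    n_courses <- rpois(1, config$drug_course_rate)
    if (n_courses > 0 && length(groups) > 0) {
      for (i in seq_len(n_courses)) {
        gi <- sample.int(length(groups), 1)
        start_rel <- sample(seq(w[1], w[2] - 1), 1)
        dur <- 1 + rgeom(1, 1 / config$drug_course_duration_mean)
        stop_rel <- min(w[2], start_rel + dur - 1)
        rows[[length(rows) + 1]] <- tibble(
          PatientID = pid,
          StartTimepoint = anchor + start_rel,
          StopTimepoint = anchor + stop_rel,
          Factor = paste0(groups[gi], "_syn"),
          Category = groups[gi],
          AntiInfective = TRUE,
          Route = routes[gi],
          StartDayRelativeToNearestHCT = as.integer(start_rel),
          StopDayRelativeToNearestHCT = as.integer(stop_rel)
        )
      }
    }
    n_decoy <- rpois(1, config$decoy_drug_rate)
    if (n_decoy > 0) {
      for (i in seq_len(n_decoy)) {
        di <- sample.int(nrow(decoys), 1)
        start_rel <- sample(seq(w[1], w[2] - 1), 1)
        dur <- 1 + rgeom(1, 1 / config$drug_course_duration_mean)
        stop_rel <- min(w[2], start_rel + dur - 1)
        rows[[length(rows) + 1]] <- tibble(
          PatientID = pid,
          StartTimepoint = anchor + start_rel,
          StopTimepoint = anchor + stop_rel,
          Factor = decoys$Factor[di],
          Category = decoys$Category[di],
          AntiInfective = decoys$AntiInfective[di],
          Route = sample(c("oral", "intravenous"), 1),
          StartDayRelativeToNearestHCT = as.integer(start_rel),
          StopDayRelativeToNearestHCT = as.integer(stop_rel)
        )
      }
    }
  }
  if (length(rows) == 0) return(empty_table("drugs"))
  out <- bind_rows(rows)
  out$StartTimepoint <- as.integer(out$StartTimepoint)
  out$StopTimepoint <- as.integer(out$StopTimepoint)
  out
}

#' Simulate genus-matched bloodstream-infection events
#'
#' Discrete-day event draws with hazard
#' `baseline_hazard * exp(beta * indicator)`; only the first event per
#' patient is retained.
#'
#' @param domination Tibble with columns `PatientID`, `Day` (relative to
#'   HCT) and binary `Dominated`, one row per patient-day at risk.
#' @param beta Log hazard ratio of domination.
#' @param baseline_hazard Baseline daily hazard (events/day).
#' @param genus Genus recorded as `InfectiousAgent`.
#' @param hct_timepoint Named integer vector mapping PatientID to transplant
#'   timepoint (to emit absolute `Timepoint`s).
#' @return Tibble in `tblInfectionsCidPapers.csv` layout.
#' @export
simulate_bsi <- function(domination, beta, baseline_hazard,
                         genus = "Enterococcus", hct_timepoint = NULL) {
  hmax <- baseline_hazard * exp(max(0, beta))
  if (hmax > 1) abort("configuration error: daily hazard exceeds 1")
  if (baseline_hazard == 0 || nrow(domination) == 0) return(empty_table("infections"))
  dom <- arrange(domination, .data$PatientID, .data$Day)
  dom <- mutate(dom,
                hazard = baseline_hazard * exp(beta * .data$Dominated),
                hit = rbinom(n(), 1, .data$hazard) == 1)
  events <- dom |>
    filter(.data$hit) |>
    group_by(.data$PatientID) |>
    slice_min(.data$Day, n = 1, with_ties = FALSE) |>
    ungroup()
  if (nrow(events) == 0) return(empty_table("infections"))
  anchor <- if (is.null(hct_timepoint)) {
    set_names(rep(0L, n_distinct(events$PatientID)), unique(events$PatientID))
  } else hct_timepoint
  tibble(
    PatientID = events$PatientID,
    Timepoint = as.integer(anchor[events$PatientID] + events$Day),
    InfectiousAgent = genus,
    DayRelativeToNearestHCT = as.integer(events$Day)
  )
}

# internal: synthetic taxonomy table for n taxa
synthetic_taxonomy <- function(n_taxa, bsi_genus) {
  asv <- sprintf("ASV_%04d", seq_len(n_taxa))
  genera <- c(bsi_genus,
              rep(setdiff(synthetic_genera, bsi_genus),
                  length.out = max(0, n_taxa - 1)))
  genera <- genera[seq_len(n_taxa)]
  pal <- grDevices::hcl.colors(max(n_taxa, 3), "Spectral")
  hex <- toupper(substr(pal[seq_len(n_taxa)], 1, 7))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_taxa), function(i)
    paste(bases[1 + (seq_len(60) * i + i^2) %% 4], collapse = ""), character(1))
  tibble(
    ASV = asv,
    Sequence = seqs,
    Kingdom = "Bacteria",
    Phylum = ifelse(genera %in% c("Escherichia", "Klebsiella"),
                    "Proteobacteria", "Firmicutes"),
    Class = ifelse(genera %in% c("Escherichia", "Klebsiella"),
                   "Gammaproteobacteria", "Clostridia"),
    Order = ifelse(genera %in% c("Escherichia", "Klebsiella"),
                   "Enterobacterales", "Eubacteriales"),
    Family = paste0(genera, "aceae"),
    Genus = genera,
    ConfidenceKingdom = 1, ConfidencePhylum = 1, ConfidenceClass = 1,
    ConfidenceOrder = 1, ConfidenceFamily = 1, ConfidenceGenus = 1,
    HexColor = hex,
    ColorOrder = seq_len(n_taxa)
  )
}

#' Generate a full synthetic hospitalome cohort with ground truth
#'
#' Draws per-taxon growth rates and susceptibilities, simulates drug
#' courses, latent dynamics, stool-sample observation (multinomial reads +
#' noisy qPCR), genus-matched bloodstream infections driven by intestinal
#' domination, plus temperature, neutrophil and vanA tables, and assembles
#' everything into the deposited CSV layout.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list with elements `cohort` (a [new_cohort()]) and `truth`
#'   (list: `g`, `epsilon` (taxa x groups, with group/route in dimnames),
#'   `groups`, `routes`, `bsi_beta`, `latent` per-patient log-abundance
#'   matrices, `domination` per patient-day indicator).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  w <- config$day_window
  days_rel <- seq(w[1], w[2])
  n_days <- length(days_rel) - 1L
  k <- config$n_taxa
  groups <- synthetic_drug_classes[seq_len(config$n_drug_groups)]
  routes <- rep(c("intravenous", "oral"), length.out = length(groups))

  pid <- sprintf("P%03d", seq_len(config$n_patients))
  # deidentified anchor: random per-patient offset, exercising the secret
  # reference-date convention
  anchor <- set_names(sample.int(10000L, config$n_patients, replace = TRUE), pid)

  g <- rnorm(k, config$g_mean, config$g_sd)
  eps <- matrix(0, nrow = k, ncol = length(groups),
                dimnames = list(sprintf("ASV_%04d", seq_len(k)), groups))
  if (length(groups) > 0) {
    nz <- matrix(runif(k * length(groups)) < config$epsilon_nonzero_prob,
                 nrow = k)
    mag <- matrix(runif(k * length(groups), config$epsilon_min, config$epsilon_max),
                  nrow = k)
    sgn <- matrix(sample(c(-1, 1), k * length(groups), replace = TRUE), nrow = k)
    eps[nz] <- (mag * sgn)[nz]
  }
  names(g) <- rownames(eps)

  taxonomy <- synthetic_taxonomy(k, config$bsi_genus)
  bsi_taxon <- 1L

  # HCT table (optionally a second transplant well after the window)
  hct_rows <- tibble(
    PatientID = pid,
    TimepointOfTransplant = as.integer(anchor[pid]),
    HCTSource = sample(c("BM_unmodified", "PBSC_unmodified", "TCD", "cord"),
                       config$n_patients, replace = TRUE),
    Disease = sample(c("AML", "ALL", "MDS", "NHL"), config$n_patients,
                     replace = TRUE)
  )
  if (config$multi_hct_prob > 0) {
    second <- runif(config$n_patients) < config$multi_hct_prob
    if (any(second)) {
      hct_rows <- bind_rows(hct_rows, tibble(
        PatientID = pid[second],
        TimepointOfTransplant = as.integer(anchor[pid[second]] + diff(w) + 60L),
        HCTSource = "PBSC_unmodified",
        Disease = "AML"
      ))
    }
  }

  drugs <- simulate_drug_courses(config, pid, anchor)

  sample_rows <- list(); count_rows <- list(); qpcr_rows <- list()
  temp_rows <- list(); blood_rows <- list(); vana_rows <- list()
  dom_rows <- list(); latent <- list()
  sample_counter <- 0L

  abx <- filter(drugs, .data$Category %in% groups)
  for (p in pid) {
    # exposure matrix for the stepped-into days (days_rel[-1])
    u <- matrix(0, nrow = n_days, ncol = length(groups),
                dimnames = list(NULL, groups))
    dp <- filter(abx, .data$PatientID == p)
    if (nrow(dp) > 0) {
      for (r in seq_len(nrow(dp))) {
        gi <- match(dp$Category[r], groups)
        span <- seq(dp$StartDayRelativeToNearestHCT[r],
                    dp$StopDayRelativeToNearestHCT[r])
        idx <- match(span, days_rel[-1])
        idx <- idx[!is.na(idx)]
        u[idx, gi] <- 1
      }
    }
    log_n0 <- log(10) * rnorm(k, config$log10_n0_mean, config$log10_n0_sd)
    traj <- simulate_dynamics(g, eps, u, log_n0, config$dynamics_noise_sd)
    dimnames(traj) <- list(as.character(days_rel), taxonomy$ASV)
    latent[[p]] <- traj

    # stool sampling days
    sdays <- integer(0)
    d <- days_rel[1] + sample1(config$sampling_interval_days) - 1L
    while (d <= w[2]) {
      if (d >= w[1]) sdays <- c(sdays, d)
      d <- d + sample1(config$sampling_interval_days)
    }
    dom_series <- rep(0L, length(days_rel))
    for (sd in sdays) {
      sample_counter <- sample_counter + 1L
      sid <- sprintf("S%05d", sample_counter)
      ab <- exp(traj[as.character(sd), ])
      ab[ab < config$extinction_floor] <- 0
      if (sum(ab) == 0) next
      depth <- if (is.infinite(config$read_depth_mean)) Inf else {
        max(1L, rnbinom(1, mu = config$read_depth_mean,
                        size = config$read_depth_dispersion))
      }
      obs <- observe_sample(ab, depth, config$qpcr_noise_sd_log10)
      present <- obs$counts > 0
      sample_rows[[sid]] <- tibble(
        SampleID = sid, PatientID = p,
        Timepoint = as.integer(anchor[p] + sd),
        Consistency = sample(c("formed", "semi-formed", "liquid"), 1),
        Accession = NA_character_, BioProject = NA_character_,
        DayRelativeToNearestHCT = as.integer(sd)
      )
      count_rows[[sid]] <- tibble(
        SampleID = sid,
        ASV = taxonomy$ASV[present],
        Count = as.numeric(unname(obs$counts[present]))
      )
      if (runif(1) < config$qpcr_coverage) {
        qpcr_rows[[sid]] <- tibble(SampleID = sid, qPCR16S = obs$qpcr)
      }
      vana_rows[[sid]] <- tibble(SampleID = sid, VanA = runif(1) < 0.2)
      # observed domination state of the focal genus (absorbing)
      # domination observed on day sd elevates the hazard from day sd + 1
      # (covariate switches at the end of the dominated sample's day)
      frac <- obs$counts[bsi_taxon] / sum(obs$counts)
      if (frac > config$domination_threshold) {
        start_idx <- match(sd, days_rel) + 1L
        if (start_idx <= length(dom_series)) {
          dom_series[start_idx:length(dom_series)] <- 1L
        }
      }
    }
    dom_rows[[p]] <- tibble(PatientID = p, Day = days_rel,
                            Dominated = dom_series)

    # vitals: neutropenic nadir after transplant, occasional fevers
    nad <- pmax(0, 2 - 1.9 * exp(-((days_rel - 18) / 10)^2) -
                  1.6 * exp(-pmax(days_rel, 0) / 25) * (days_rel >= 0))
    neut <- pmax(0, nad + rnorm(length(days_rel), 0, 0.15))
    blood_rows[[p]] <- tibble(
      PatientID = p, Day = as.integer(anchor[p] + days_rel),
      BloodCellType = "Neutrophils",
      Value = round(neut, 3), Unit = "K_per_uL",
      DayRelativeToNearestHCT = as.integer(days_rel)
    )
    fever <- runif(length(days_rel)) < 0.12
    temp_rows[[p]] <- tibble(
      PatientID = p, Timepoint = as.integer(anchor[p] + days_rel),
      MaxTemperature = round(98.2 + fever * runif(length(days_rel), 2.4, 4) +
                               rnorm(length(days_rel), 0, 0.4), 1),
      DayRelativeToNearestHCT = as.integer(days_rel)
    )
  }

  domination <- bind_rows(dom_rows)
  infections <- simulate_bsi(domination, config$bsi_beta,
                             config$bsi_baseline_hazard,
                             genus = config$bsi_genus,
                             hct_timepoint = anchor)

  cohort <- new_cohort(
    samples = bind_rows(sample_rows),
    counts = bind_rows(count_rows),
    qpcr = if (length(qpcr_rows)) bind_rows(qpcr_rows) else NULL,
    hct = hct_rows,
    drugs = drugs,
    infections = infections,
    temperature = bind_rows(temp_rows),
    blood = bind_rows(blood_rows),
    vana = bind_rows(vana_rows),
    taxonomy = taxonomy,
    provenance = list(generator = "hospitalome::generate_cohort", seed = seed)
  )
  truth <- list(
    g = g, epsilon = eps, groups = groups,
    routes = set_names(routes, groups),
    bsi_beta = config$bsi_beta,
    domination_threshold = config$domination_threshold,
    bsi_genus = config$bsi_genus,
    latent = latent, domination = domination,
    config = config
  )
  list(cohort = cohort, truth = truth)
}
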