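# Shared fixtures, built once per test run.

# small default-noise cohort used across modules
gen_small <- generate_cohort(sim_config(n_patients = 20), seed = 11)

# tiny hand-built tables for exact-value tests
tiny_counts <- tibble::tibble(
  SampleID = c("s1", "s1", "s2", "s3"),
  ASV = c("a1", "a2", "a1", "a2"),
  Count = c(30, 70, 500, 0)
)

tiny_taxonomy <- tibble::tibble(
  ASV = c("a1", "a2", "a3", "a4"),
  Sequence = c("ACGT", "AGGT", "ATGT", "AAGT"),
  Kingdom = "Bacteria",
  Phylum = c("Firmicutes", "Firmicutes", "Firmicutes", "Proteobacteria"),
  Class = c("Bacilli", "Bacilli", "Bacilli", "Gammaproteobacteria"),
  Order = c("Lactobacillales", "Lactobacillales", "Lactobacillales",
            "Enterobacterales"),
  Family = c("Enterococcaceae", "Enterococcaceae", "Streptococcaceae",
             "Enterobacteriaceae"),
  Genus = c("Enterococcus", "Enterococcus", NA, "Escherichia"),
  ConfidenceKingdom = 1, ConfidencePhylum = 1, ConfidenceClass = 1,
  ConfidenceOrder = 1, ConfidenceFamily = 1, ConfidenceGenus = 1,
  HexColor = c("#00AA00", "#00BB00", "#888888", "#CC0000"),
  ColorOrder = 1:4
)

# quick accessor: truth vs estimate comparison frame for an abx fit
recovery_frame <- function(fit, truth) {
  co <- tidy(fit)
  eh <- co[co$Term != "growth_rate" & co$Group %in% colnames(truth$epsilon), ]
  eh$Truth <- truth$epsilon[cbind(eh$Taxon, eh$Group)]
  gh <- co[co$Term == "growth_rate", ]
  gh$Truth <- unname(truth$g[gh$Taxon])
  list(eps = eh, g = gh,
       decoy = co[co$Term != "growth_rate" &
                    !co$Group %in% colnames(truth$epsilon), ])
}

# per-day domination indicator table for survival simulations
make_domination <- function(n_patients, days = -15:35, dom_prob = 0.4) {
  rows <- lapply(seq_len(n_patients), function(i) {
    d0 <- if (stats::runif(1) < dom_prob) sample(days[-length(days)], 1) else NA
    tibble::tibble(PatientID = sprintf("P%04d", i), Day = days,
                   Dominated = as.integer(!is.na(d0) & days > d0))
  })
  dplyr::bind_rows(rows)
}
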