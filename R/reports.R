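# Descriptive reports: patient timeline, composition map, drug-frequency
# panels. All figures are ggplot/patchwork objects built from tibbles the
# analysis functions already expose; rendering never mutates the cohort.

#' Restrict a cohort to one patient and a day window
#'
#' Slices every table to the given patient and the inclusive day window
#' relative to the nearest HCT. Drug courses are kept when their interval
#' overlaps the window.
#'
#' @param cohort A cohort.
#' @param patient_id Patient identifier.
#' @param window Inclusive length-2 day window relative to HCT.
#' @return A [new_cohort()] restricted to the slice.
#' @export
filter_patient_window <- function(cohort, patient_id, window = c(-5L, 21L)) {
  known <- unique(c(cohort$samples$PatientID, cohort$hct$PatientID,
                    cohort$drugs$PatientID, cohort$temperature$PatientID,
                    cohort$blood$PatientID))
  if (!patient_id %in% known) abort(paste0("unknown patient: ", patient_id))
  in_win <- function(d) !is.na(d) & d >= window[1] & d <= window[2]
  samples <- filter(cohort$samples, .data$PatientID == patient_id,
                    in_win(.data$DayRelativeToNearestHCT))
  if (nrow(samples) == 0) {
    warn(paste0("no stool samples for ", patient_id, " in window [",
                window[1], ", ", window[2], "]"))
  }
  slice <- new_cohort(
    samples = samples,
    counts = filter(cohort$counts, .data$SampleID %in% samples$SampleID),
    qpcr = filter(cohort$qpcr, .data$SampleID %in% samples$SampleID),
    hct = filter(cohort$hct, .data$PatientID == patient_id),
    drugs = filter(cohort$drugs, .data$PatientID == patient_id,
                   .data$StopDayRelativeToNearestHCT >= window[1],
                   .data$StartDayRelativeToNearestHCT <= window[2]),
    infections = filter(cohort$infections, .data$PatientID == patient_id,
                        in_win(.data$DayRelativeToNearestHCT)),
    temperature = filter(cohort$temperature, .data$PatientID == patient_id,
                         in_win(.data$DayRelativeToNearestHCT)),
    blood = filter(cohort$blood, .data$PatientID == patient_id,
                   in_win(.data$DayRelativeToNearestHCT)),
    vana = filter(cohort$vana, .data$SampleID %in% samples$SampleID),
    taxonomy = cohort$taxonomy,
    provenance = list(parent = attr(cohort, "provenance"),
                      patient = patient_id, window = window)
  )
  slice
}

#' Patient timeline figure
#'
#' Four aligned panels over days relative to HCT: daily maximum
#' temperature with fever days highlighted, anti-infective administration
#' bars, neutrophil counts with neutropenic days highlighted, and stacked
#' genus/ASV composition bars colored by the taxonomy's hex colors in
#' color order. Taxa below `min_abundance` mean relative abundance in the
#' window are pooled into an "other" band.
#'
#' @param cohort A cohort (will be sliced).
#' @param patient_id Patient identifier.
#' @param window Inclusive day window relative to HCT.
#' @param fever_threshold_f Fever threshold in degrees Fahrenheit; the
#'   conventional febrile-neutropenia cutoff 100.4 F (38.0 C) by default.
#'   Pass `98.6` to mark anything above 37 C instead.
#' @param neutropenia_threshold Neutropenia cutoff in cells/uL (strict
#'   `<`).
#' @param min_abundance Pooling threshold for minor taxa.
#' @return A patchwork object (panels also available via
#'   `attr(, "panels")`).
#' @export
plot_timeline <- function(cohort, patient_id, window = c(-5L, 21L),
                          fever_threshold_f = 100.4,
                          neutropenia_threshold = 500,
                          min_abundance = 0.01) {
  slice <- filter_patient_window(cohort, patient_id, window)
  panels <- list()

  tp <- slice$temperature
  if (nrow(tp) > 0) {
    tp <- mutate(tp, fever = .data$MaxTemperature > fever_threshold_f)
    panels$temperature <- ggplot(tp, aes(.data$DayRelativeToNearestHCT,
                                         .data$MaxTemperature)) +
      geom_point(aes(color = .data$fever), size = 1.4, show.legend = FALSE) +
      scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
      geom_hline(yintercept = fever_threshold_f, linetype = 3) +
      labs(y = "Max temp (F)", x = NULL) +
      coord_cartesian(xlim = window) + theme_minimal()
  } else inform("timeline: temperature panel omitted (no data)")

  dr <- filter(slice$drugs, .data$AntiInfective %in% c(TRUE, NA))
  if (nrow(dr) > 0) {
    dr <- dr |>
      mutate(start = pmax(.data$StartDayRelativeToNearestHCT, window[1]),
             stop = pmin(.data$StopDayRelativeToNearestHCT, window[2]),
             Drug = paste0(.data$Factor, " (", substr(.data$Route, 1, 2), ")"))
    panels$drugs <- ggplot(dr) +
      geom_segment(aes(x = .data$start - 0.45, xend = .data$stop + 0.45,
                       y = .data$Drug, yend = .data$Drug,
                       color = .data$Category), linewidth = 3) +
      labs(y = NULL, x = NULL, color = "class") +
      coord_cartesian(xlim = window) + theme_minimal() +
      theme(legend.position = "none")
  } else inform("timeline: anti-infective panel omitted (no data)")

  bl <- filter(slice$blood, .data$BloodCellType == "Neutrophils")
  if (nrow(bl) > 0) {
    # counts are deposited in K_per_uL (1000 cells/uL)
    bl <- mutate(bl,
                 cells_per_ul = .data$Value *
                   ifelse(.data$Unit == "M_per_uL", 1e6, 1e3),
                 neutropenic = .data$cells_per_ul < neutropenia_threshold)
    panels$neutrophils <- ggplot(bl, aes(.data$DayRelativeToNearestHCT,
                                         .data$cells_per_ul)) +
      geom_point(aes(color = .data$neutropenic), size = 1.4,
                 show.legend = FALSE) +
      scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
      geom_hline(yintercept = neutropenia_threshold, linetype = 3) +
      scale_y_continuous(trans = "log1p") +
      labs(y = "Neutrophils (/uL)", x = NULL) +
      coord_cartesian(xlim = window) + theme_minimal()
  } else inform("timeline: neutrophil panel omitted (no data)")

  if (nrow(slice$counts) > 0) {
    rel <- relative_abundance(slice$counts) |>
      inner_join(select(slice$samples, "SampleID", "DayRelativeToNearestHCT"),
                 by = "SampleID")
    mean_ab <- rel |>
      group_by(.data$ASV) |>
      summarise(m = sum(.data$Fraction) / n_distinct(rel$SampleID),
                .groups = "drop")
    minor <- mean_ab$ASV[mean_ab$m < min_abundance]
    tax <- slice$taxonomy
    rel <- rel |>
      mutate(TaxLabel = ifelse(.data$ASV %in% minor, "other", .data$ASV)) |>
      left_join(select(tax, "ASV", "HexColor", "ColorOrder"), by = "ASV") |>
      mutate(HexColor = ifelse(.data$TaxLabel == "other", "#BBBBBB",
                               .data$HexColor),
             ColorOrder = ifelse(.data$TaxLabel == "other", 1e9,
                                 .data$ColorOrder))
    ord <- rel |> distinct(.data$TaxLabel, .data$ColorOrder) |>
      arrange(.data$ColorOrder)
    cols <- rel |> distinct(.data$TaxLabel, .data$HexColor)
    rel$TaxLabel <- factor(rel$TaxLabel, levels = ord$TaxLabel)
    panels$composition <- ggplot(rel, aes(.data$DayRelativeToNearestHCT,
                                          .data$Fraction,
                                          fill = .data$TaxLabel)) +
      geom_col(width = 0.85, position = "stack") +
      scale_fill_manual(values = set_names(cols$HexColor, cols$TaxLabel)) +
      labs(y = "Relative abundance", x = "Day relative to HCT",
           fill = NULL) +
      coord_cartesian(xlim = window) + theme_minimal() +
      theme(legend.position = "none")
  } else inform("timeline: composition panel omitted (no samples)")

  if (length(panels) == 0) abort("timeline: no panel data at all")
  fig <- patchwork::wrap_plots(panels, ncol = 1)
  attr(fig, "panels") <- panels
  fig
}

#' Composition map with an optional patient trajectory
#'
#' Scatter of the 2-D embedding colored by each sample's dominant taxon;
#' optionally overlays one patient's time-ordered samples connected by
#' arrows.
#'
#' @param embedding Output of [embed_2d()].
#' @param samples Sample table (needed for the trajectory).
#' @param trajectory_patient Optional PatientID to overlay.
#' @param window Day window (relative to HCT) for the trajectory samples.
#' @return A ggplot object; trajectory segment data in
#'   `attr(, "trajectory")`.
#' @export
plot_embedding_map <- function(embedding, samples = NULL,
                               trajectory_patient = NULL,
                               window = NULL) {
  p <- ggplot(embedding, aes(.data$x, .data$y))
  if ("HexColor" %in% names(embedding) && !all(is.na(embedding$HexColor))) {
    p <- p + geom_point(aes(color = .data$DominantTaxon), size = 1) +
      scale_color_manual(values = embedding |>
                           distinct(.data$DominantTaxon, .data$HexColor) |>
                           (\(d) set_names(d$HexColor, d$DominantTaxon))())
  } else {
    p <- p + geom_point(aes(color = .data$DominantTaxon), size = 1)
  }
  traj <- NULL
  if (!is.null(trajectory_patient)) {
    stopifnot(!is.null(samples))
    s <- filter(samples, .data$PatientID == trajectory_patient)
    if (!is.null(window)) {
      s <- filter(s, .data$DayRelativeToNearestHCT >= window[1],
                  .data$DayRelativeToNearestHCT <= window[2])
    }
    s <- s |>
      inner_join(embedding, by = "SampleID") |>
      arrange(.data$Timepoint)
    if (nrow(s) >= 2) {
      traj <- tibble(
        x = head(s$x, -1), y = head(s$y, -1),
        xend = tail(s$x, -1), yend = tail(s$y, -1),
        SampleID_from = head(s$SampleID, -1),
        SampleID_to = tail(s$SampleID, -1)
      )
      p <- p + geom_segment(data = traj,
                            aes(x = .data$x, y = .data$y,
                                xend = .data$xend, yend = .data$yend),
                            color = "white", linewidth = 0.8,
                            arrow = grid::arrow(length = grid::unit(2, "mm")))
    } else {
      inform("trajectory patient has fewer than 2 embedded samples; points only")
    }
  }
  p <- p + labs(x = "t-SNE 1", y = "t-SNE 2", color = "dominant taxon") +
    theme_minimal()
  attr(p, "trajectory") <- traj
  p
}

#' Drug administration frequency panels
#'
#' Bar chart of the fraction of patients ever exposed to each drug,
#' faceted by administration route and colored by drug category.
#'
#' @param frequencies Output of [drug_frequency()].
#' @return A ggplot object.
#' @export
plot_drug_frequency <- function(frequencies) {
  ggplot(frequencies,
         aes(x = stats::reorder(.data$Drug, .data$Fraction),
             y = .data$Fraction, fill = .data$Category)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~Route) +
    labs(x = NULL, y = "Fraction of patients ever exposed",
         fill = "drug class") +
    theme_minimal()
}

#' Heatmap of inferred antibiotic effects
#'
#' Taxa-by-drug-group tile map of the estimated susceptibilities, faceted
#' by administration route (red = suppression, blue = expansion).
#'
#' @param object An `abx_fit` from [infer_susceptibilities()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.abx_fit <- function(object, ...) {
  df <- filter(object$coefficients, .data$Term != "growth_rate")
  ggplot(df, aes(.data$Group, .data$Taxon, fill = .data$Estimate)) +
    geom_tile() +
    scale_fill_gradient2(low = "#B2182B", mid = "white", high = "#2166AC") +
    facet_wrap(~Route, scales = "free_x") +
    labs(x = NULL, y = NULL, fill = "effect (1/day)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
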