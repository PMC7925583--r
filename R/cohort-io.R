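# Table registry for the hospitalome CSV layout.
#
# Each entry records the deposited file name, the typed columns (readr
# collector per column), which columns are mandatory, and the internal
# short name used to address the table inside a cohort object.

hosp_table_registry <- function() {
  list(
    samples = list(
      file = "tblASVsamples.csv",
      cols = cols(
        SampleID = col_character(),
        PatientID = col_character(),
        Timepoint = col_integer(),
        Consistency = col_character(),
        Accession = col_character(),
        BioProject = col_character(),
        DayRelativeToNearestHCT = col_integer()
      ),
      required = c("SampleID", "PatientID", "Timepoint")
    ),
    counts = list(
      file = "tblcounts_asv_melt.csv",
      cols = cols(
        SampleID = col_character(),
        ASV = col_character(),
        Count = col_double()
      ),
      required = c("SampleID", "ASV", "Count")
    ),
    qpcr = list(
      file = "tblqpcr.csv",
      cols = cols(
        SampleID = col_character(),
        qPCR16S = col_double()
      ),
      required = c("SampleID", "qPCR16S")
    ),
    hct = list(
      file = "tblhctmeta.csv",
      cols = cols(
        PatientID = col_character(),
        TimepointOfTransplant = col_integer(),
        HCTSource = col_character(),
        Disease = col_character()
      ),
      required = c("PatientID", "TimepointOfTransplant")
    ),
    drugs = list(
      file = "tbldrug.csv",
      cols = cols(
        PatientID = col_character(),
        StartTimepoint = col_integer(),
        StopTimepoint = col_integer(),
        Factor = col_character(),
        Category = col_character(),
        AntiInfective = col_logical(),
        Route = col_character(),
        StartDayRelativeToNearestHCT = col_integer(),
        StopDayRelativeToNearestHCT = col_integer()
      ),
      required = c("PatientID", "StartTimepoint", "StopTimepoint", "Factor")
    ),
    infections = list(
      file = "tblInfectionsCidPapers.csv",
      cols = cols(
        PatientID = col_character(),
        Timepoint = col_integer(),
        InfectiousAgent = col_character(),
        DayRelativeToNearestHCT = col_integer()
      ),
      required = c("PatientID", "Timepoint", "InfectiousAgent")
    ),
    temperature = list(
      file = "tbltemperature.csv",
      cols = cols(
        PatientID = col_character(),
        Timepoint = col_integer(),
        MaxTemperature = col_double(),
        DayRelativeToNearestHCT = col_integer()
      ),
      required = c("PatientID", "Timepoint", "MaxTemperature")
    ),
    blood = list(
      file = "tblbc.csv",
      cols = cols(
        PatientID = col_character(),
        Day = col_integer(),
        BloodCellType = col_character(),
        Value = col_double(),
        Unit = col_character(),
        DayRelativeToNearestHCT = col_integer()
      ),
      required = c("PatientID", "Day", "BloodCellType", "Value")
    ),
    vana = list(
      file = "tblVanA.csv",
      cols = cols(
        SampleID = col_character(),
        VanA = col_logical()
      ),
      required = c("SampleID", "VanA")
    ),
    taxonomy = list(
      file = "tblASVtaxonomy_silva_v4v5_filter.csv",
      cols = cols(
        ASV = col_character(),
        Sequence = col_character(),
        Kingdom = col_character(),
        Phylum = col_character(),
        Class = col_character(),
        Order = col_character(),
        Family = col_character(),
        Genus = col_character(),
        ConfidenceKingdom = col_double(),
        ConfidencePhylum = col_double(),
        ConfidenceClass = col_double(),
        ConfidenceOrder = col_double(),
        ConfidenceFamily = col_double(),
        ConfidenceGenus = col_double(),
        HexColor = col_character(),
        ColorOrder = col_integer()
      ),
      required = c("ASV")
    )
  )
}

empty_table <- function(name) {
  spec <- hosp_table_registry()[[name]]
  collectors <- spec$cols$cols
  out <- lapply(collectors, function(cl) {
    switch(class(cl)[1],
      collector_character = character(0),
      collector_integer = integer(0),
      collector_double = double(0),
      collector_logical = logical(0),
      character(0)
    )
  })
  as_tibble(out)
}

#' Construct a hospitalome cohort from individual tables
#'
#' A cohort bundles the (up to) ten deidentified tables of the hospitalome
#' layout: stool samples, melted ASV counts, 16S qPCR load, HCT metadata,
#' drug-exposure intervals, positive blood cultures, daily maximum
#' temperatures, blood cell counts, vanA PCR results and ASV taxonomy. All
#' time coordinates are deidentified integer days; only differences between
#' days are meaningful.
#'
#' @param samples,counts,qpcr,hct,drugs,infections,temperature,blood,vana,taxonomy
#'   Tibbles with the deposited column layout; omitted tables default to
#'   empty typed tables.
#' @param provenance Optional list of provenance metadata (source directory,
#'   load time, validation report).
#' @return An object of class `hosp_cohort`: a named list of tibbles with a
#'   `provenance` attribute.
#' @export
new_cohort <- function(samples = NULL, counts = NULL, qpcr = NULL, hct = NULL,
                       drugs = NULL, infections = NULL, temperature = NULL,
                       blood = NULL, vana = NULL, taxonomy = NULL,
                       provenance = list()) {
  given <- list(
    samples = samples, counts = counts, qpcr = qpcr, hct = hct,
    drugs = drugs, infections = infections, temperature = temperature,
    blood = blood, vana = vana, taxonomy = taxonomy
  )
  registry <- hosp_table_registry()
  tables <- lapply(names(registry), function(nm) {
    tbl <- given[[nm]]
    if (is.null(tbl)) return(empty_table(nm))
    tbl <- as_tibble(tbl)
    proto <- empty_table(nm)
    for (mc in setdiff(names(proto), names(tbl))) {
      tbl[[mc]] <- rep(proto[[mc]][NA_integer_], nrow(tbl))
    }
    # normalize canonical column types (e.g. integer draws into double slots)
    for (cc in names(proto)) {
      if (is.double(proto[[cc]]) && is.integer(tbl[[cc]])) {
        tbl[[cc]] <- as.double(tbl[[cc]])
      } else if (is.integer(proto[[cc]]) && is.double(tbl[[cc]]) &&
                 all(is.na(tbl[[cc]]) | tbl[[cc]] == round(tbl[[cc]]))) {
        tbl[[cc]] <- as.integer(tbl[[cc]])
      }
    }
    # keep canonical column order first, pass through any extras
    tbl[, c(names(proto), setdiff(names(tbl), names(proto))), drop = FALSE]
  })
  names(tables) <- names(registry)
  structure(tables, provenance = provenance, class = "hosp_cohort")
}

#' @export
print.hosp_cohort <- function(x, ...) {
  cat("<hosp_cohort>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  }
  n_pat <- n_distinct(x$samples$PatientID)
  cat(sprintf("  patients with samples: %d\n", n_pat))
  invisible(x)
}

#' Day relative to the nearest HCT
#'
#' Convert a deidentified timepoint into days relative to the nearest
#' transplant day of that patient. Ties between two equidistant transplants
#' are broken toward the earlier transplant (deterministic convention).
#'
#' @param timepoint Integer vector of deidentified days.
#' @param hct_days Integer vector of transplant days for the patient
#'   (non-empty).
#' @return Integer vector: `timepoint` minus the nearest transplant day.
#' @examples
#' day_relative_to_nearest_hct(100, c(95, 200)) # 5
#' day_relative_to_nearest_hct(95, 95)          # 0
#' @export
day_relative_to_nearest_hct <- function(timepoint, hct_days) {
  if (length(hct_days) == 0 || all(is.na(hct_days))) {
    abort("patient has no HCT: `hct_days` is empty", class = "hosp_no_hct")
  }
  hct_days <- sort(unique(as.integer(hct_days[!is.na(hct_days)])))
  vapply(as.integer(timepoint), function(tp) {
    if (is.na(tp)) return(NA_integer_)
    d <- abs(tp - hct_days)
    # which.min returns the first (earlier) HCT on ties
    tp - hct_days[which.min(d)]
  }, integer(1))
}

#' Load a hospitalome cohort from a directory of CSV files
#'
#' Reads whichever of the deposited CSV files are present in `directory`
#' (by their canonical names, searched also in the deposit's `counts/`,
#' `meta_data/`, `samples/` and `taxonomy/` subfolders), parses them with
#' typed columns, and validates the result.
#'
#' @param directory Path containing at least one of the named CSV files.
#' @param strict If `TRUE`, any invariant violation raises an error; if
#'   `FALSE` (default) violations are collected into the validation report
#'   stored in the cohort's provenance.
#' @return A [new_cohort()] object. Tables whose file is absent are empty.
#' @export
load_cohort <- function(directory, strict = FALSE) {
  if (!dir.exists(directory)) abort(paste0("no such directory: ", directory))
  registry <- hosp_table_registry()
  subdirs <- c(".", "counts", "meta_data", "samples", "taxonomy")
  tables <- list()
  for (nm in names(registry)) {
    spec <- registry[[nm]]
    path <- NULL
    for (sd in subdirs) {
      cand <- file.path(directory, sd, spec$file)
      if (file.exists(cand)) { path <- cand; break }
    }
    if (is.null(path)) { tables[[nm]] <- empty_table(nm); next }
    hdr <- names(read_csv(path, n_max = 0, col_types = cols(), progress = FALSE,
                          show_col_types = FALSE))
    missing_req <- setdiff(spec$required, hdr)
    if (length(missing_req) > 0) {
      abort(sprintf("schema error in %s: missing mandatory column(s) %s",
                    spec$file, paste(missing_req, collapse = ", ")),
            class = "hosp_schema_error")
    }
    known <- spec$cols$cols[intersect(names(spec$cols$cols), hdr)]
    # real-valued columns are read as text and converted with R's
    # correctly-rounded strtod, so serialized doubles round-trip exactly
    dbl_cols <- names(known)[vapply(known, function(cl)
      inherits(cl, "collector_double"), logical(1))]
    for (dc in dbl_cols) known[[dc]] <- col_character()
    tbl <- read_csv(path, col_types = do.call(cols, known),
                    progress = FALSE, show_col_types = FALSE)
    prob <- readr::problems(tbl)
    if (nrow(prob) > 0) {
      msg <- sprintf("unparseable value(s) in %s: e.g. row %d, column %s",
                     spec$file, prob$row[1], hdr[prob$col[1]])
      abort(msg, class = "hosp_parse_error")
    }
    for (dc in dbl_cols) {
      raw <- tbl[[dc]]
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & raw != "" & is.na(num))
      if (length(bad) > 0) {
        abort(sprintf("unparseable value(s) in %s: e.g. row %d, column %s",
                      spec$file, bad[1], dc), class = "hosp_parse_error")
      }
      tbl[[dc]] <- num
    }
    tables[[nm]] <- tbl
  }
  cohort <- do.call(new_cohort, c(tables, list(provenance = list(
    source = normalizePath(directory),
    loaded_at = format(Sys.time(), tz = "UTC")
  ))))
  report <- validate_cohort(cohort)
  attr(cohort, "provenance")$validation <- report
  attr(cohort, "provenance")$confidence_scale <-
    detect_confidence_scale(cohort$taxonomy)
  if (strict && nrow(report) > 0) {
    abort(paste0("cohort fails validation in strict mode:\n",
                 paste(utils::capture.output(print(as.data.frame(report))),
                       collapse = "\n")),
          class = "hosp_validation_error")
  }
  cohort
}

# Confidence columns are deposited either on [0,1] or [0,100]; detect which.
detect_confidence_scale <- function(taxonomy) {
  conf_cols <- grep("^Confidence", names(taxonomy), value = TRUE)
  vals <- unlist(lapply(conf_cols, function(cc) taxonomy[[cc]]))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_character_)
  if (max(vals) > 1) "percent" else "fraction"
}

#' Validate a cohort against the table invariants
#'
#' Checks per-table invariants (key uniqueness, non-negative counts, closed
#' drug intervals, plausible temperature range, hex colors, consistency of
#' the day-relative-to-HCT columns) and cross-table referential integrity
#' (counts/qPCR/vanA rows whose sample is absent from the sample table,
#' samples whose patient is unknown elsewhere). Report-only: never errors.
#'
#' @param cohort A [new_cohort()] object.
#' @return A tibble with columns `table`, `rule`, `n`, `detail`; zero rows
#'   means no violations.
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  add <- function(table, rule, n, detail = "") {
    if (n > 0) v[[length(v) + 1]] <<- tibble(table = table, rule = rule,
                                             n = as.integer(n), detail = detail)
  }

  s <- cohort$samples
  add("samples", "duplicate SampleID", sum(duplicated(s$SampleID)))

  cn <- cohort$counts
  add("counts", "negative count", sum(cn$Count < 0, na.rm = TRUE))
  add("counts", "non-integer count",
      sum(abs(cn$Count - round(cn$Count)) > 1e-9, na.rm = TRUE))
  add("counts", "duplicate (SampleID, ASV)",
      sum(duplicated(cn[c("SampleID", "ASV")])))
  if (nrow(s) > 0) {
    orphans <- setdiff(unique(cn$SampleID), s$SampleID)
    add("counts", "SampleID absent from sample table", length(orphans),
        paste(head(orphans, 3), collapse = ", "))
  }
  if (nrow(cohort$taxonomy) > 0 && nrow(cn) > 0) {
    unres <- setdiff(unique(cn$ASV), cohort$taxonomy$ASV)
    add("counts", "ASV absent from taxonomy", length(unres),
        paste(head(unres, 3), collapse = ", "))
  }

  q <- cohort$qpcr
  add("qpcr", "non-positive qPCR16S", sum(q$qPCR16S <= 0, na.rm = TRUE))
  add("qpcr", "duplicate SampleID", sum(duplicated(q$SampleID)))
  if (nrow(s) > 0) {
    orphans <- setdiff(unique(q$SampleID), s$SampleID)
    add("qpcr", "SampleID absent from sample table", length(orphans))
  }

  d <- cohort$drugs
  add("drugs", "StopTimepoint < StartTimepoint",
      sum(d$StopTimepoint < d$StartTimepoint, na.rm = TRUE))

  h <- cohort$hct
  if (nrow(h) > 0) {
    per_pat <- table(h$PatientID)
    add("hct", "more than 3 HCT rows for a patient", sum(per_pat > 3))
    # recompute DayRelativeToNearestHCT for samples of patients with HCT
    if (nrow(s) > 0 && "DayRelativeToNearestHCT" %in% names(s)) {
      hct_by_pat <- split(h$TimepointOfTransplant, h$PatientID)
      chk <- s[!is.na(s$DayRelativeToNearestHCT) & s$PatientID %in% names(hct_by_pat), ]
      if (nrow(chk) > 0) {
        expect <- vapply(seq_len(nrow(chk)), function(i) {
          day_relative_to_nearest_hct(chk$Timepoint[i],
                                      hct_by_pat[[chk$PatientID[i]]])
        }, integer(1))
        # equidistant ties are convention-dependent: flag but count separately
        hct_sorted <- lapply(hct_by_pat, function(x) sort(unique(x)))
        tie <- vapply(seq_len(nrow(chk)), function(i) {
          hd <- hct_sorted[[chk$PatientID[i]]]
          dd <- abs(chk$Timepoint[i] - hd)
          sum(dd == min(dd)) > 1
        }, logical(1))
        add("samples", "DayRelativeToNearestHCT mismatch",
            sum(expect != chk$DayRelativeToNearestHCT & !tie))
        add("samples", "equidistant-HCT tie (earlier HCT convention used)",
            sum(tie & expect != chk$DayRelativeToNearestHCT))
      }
    }
  }

  inf <- cohort$infections
  agents <- c("Enterococcus", "Escherichia", "Klebsiella", "Enterobacter",
              "Pseudomonas", "Stenotrophomonas", "Citrobacter")
  add("infections", "InfectiousAgent outside analyzed genera",
      sum(!inf$InfectiousAgent %in% agents, na.rm = TRUE))

  tp <- cohort$temperature
  add("temperature", "MaxTemperature outside [90, 110] F",
      sum(tp$MaxTemperature < 90 | tp$MaxTemperature > 110, na.rm = TRUE))

  b <- cohort$blood
  add("blood", "negative blood value", sum(b$Value < 0, na.rm = TRUE))
  add("blood", "unknown unit",
      sum(!b$Unit %in% c("K_per_uL", "M_per_uL", NA)))

  tx <- cohort$taxonomy
  add("taxonomy", "duplicate ASV", sum(duplicated(tx$ASV)))
  if (nrow(tx) > 0 && "HexColor" %in% names(tx)) {
    bad <- !is.na(tx$HexColor) & !grepl("^#?[0-9A-Fa-f]{6}$", tx$HexColor)
    add("taxonomy", "malformed HexColor", sum(bad))
  }

  if (length(v) == 0) {
    return(tibble(table = character(0), rule = character(0),
                  n = integer(0), detail = character(0)))
  }
  bind_rows(v)
}

#' Write a cohort back to the deposited CSV layout
#'
#' Writes each non-empty table (and headers-only files for empty ones) under
#' its canonical file name, RFC 4180 CSV, UTF-8, empty cells for missing
#' values. Round-trips: `load_cohort(write_cohort(c, d))` reproduces `c`
#' field for field.
#'
#' @param cohort A [new_cohort()] object.
#' @param directory Output directory, created if needed.
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) abort(paste0("cannot create directory: ", directory))
  registry <- hosp_table_registry()
  for (nm in names(registry)) {
    tbl <- cohort[[nm]]
    # real-valued columns are serialized with a shortest round-trippable
    # decimal form so that load(write(c)) reproduces c bit for bit
    for (cl in names(tbl)) {
      if (is.double(tbl[[cl]]) && !is.integer(tbl[[cl]])) {
        tbl[[cl]] <- format_roundtrip(tbl[[cl]])
      }
    }
    write_csv(tbl, file.path(directory, registry[[nm]]$file),
              na = "", progress = FALSE)
  }
  invisible(directory)
}

format_roundtrip <- function(x) {
  out <- sprintf("%.15g", x)
  bad <- !is.na(x) & as.numeric(out) != x
  if (any(bad)) out[bad] <- sprintf("%.17g", x[bad])
  out[is.na(x)] <- NA_character_
  out
}
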