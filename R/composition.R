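# Composition transforms: counts -> fractions -> qPCR-scaled absolute
# abundances, taxonomic aggregation, intestinal-domination calls, and the
# t-SNE map of all compositions.

taxonomic_ranks <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus")

#' Per-sample relative abundances
#'
#' Divides each taxon's read count by the sample's total read count (its
#' depth). Samples with zero total depth are excluded and listed in the
#' `excluded` attribute.
#'
#' @param counts Tibble with columns `SampleID`, a taxon column (`ASV` or
#'   `Taxon`) and `Count`.
#' @return Tibble `SampleID`, taxon column, `Count`, `Fraction`, with
#'   attributes `taxon_col` and `excluded`.
#' @export
relative_abundance <- function(counts) {
  taxon_col <- if ("ASV" %in% names(counts)) "ASV" else "Taxon"
  if (any(counts$Count < 0, na.rm = TRUE)) abort("negative counts")
  totals <- counts |>
    group_by(.data$SampleID) |>
    summarise(depth = sum(.data$Count), .groups = "drop")
  excluded <- totals$SampleID[totals$depth <= 0]
  out <- counts |>
    inner_join(filter(totals, .data$depth > 0), by = "SampleID") |>
    mutate(Fraction = .data$Count / .data$depth) |>
    select(-"depth")
  attr(out, "taxon_col") <- taxon_col
  attr(out, "excluded") <- excluded
  attr(out, "kind") <- "relative"
  out
}

#' qPCR-scaled absolute abundances
#'
#' Multiplies relative abundances by the sample's total 16S load measured
#' by qPCR (copies per gram of stool). Samples without a qPCR record are
#' excluded and listed in the `excluded_no_qpcr` attribute.
#'
#' @param rel Output of [relative_abundance()].
#' @param qpcr Tibble with `SampleID`, `qPCR16S`.
#' @return `rel` with an added `Abundance` column (`Fraction * qPCR16S`),
#'   restricted to samples with qPCR.
#' @export
absolute_abundance <- function(rel, qpcr) {
  if (!"Fraction" %in% names(rel)) abort("`rel` must contain relative abundances")
  have <- unique(rel$SampleID)
  excluded <- setdiff(have, qpcr$SampleID)
  out <- rel |>
    inner_join(select(qpcr, "SampleID", "qPCR16S"), by = "SampleID") |>
    mutate(Abundance = .data$Fraction * .data$qPCR16S)
  for (a in c("taxon_col", "kind")) attr(out, a) <- attr(rel, a)
  attr(out, "excluded_no_qpcr") <- excluded
  out
}

#' Aggregate ASV counts to a taxonomic rank
#'
#' Sums counts over ASVs sharing the taxon label at `level`. ASVs that are
#' unclassified at that rank are grouped into one bucket per parent lineage
#' (never merged across different parents), labelled
#' `"unclassified <parent>"`.
#'
#' @param counts Melted counts (`SampleID`, `ASV`, `Count`).
#' @param taxonomy Taxonomy table with rank columns `Kingdom` .. `Genus`.
#' @param level One of `"ASV"`, `"Genus"`, `"Family"`, `"Order"`,
#'   `"Class"`, `"Phylum"`, `"Kingdom"` (case-insensitive).
#' @return Tibble `SampleID`, `Taxon`, `Count` (or the input unchanged for
#'   `level = "ASV"`).
#' @export
aggregate_to_level <- function(counts, taxonomy, level) {
  level <- paste0(toupper(substr(level, 1, 1)), tolower(substr(level, 2, nchar(level))))
  if (level == "Asv" || level == "ASV" || tolower(level) == "asv") return(counts)
  if (!level %in% taxonomic_ranks) abort(paste0("unknown rank: ", level))
  ridx <- match(level, taxonomic_ranks)
  parents <- taxonomic_ranks[seq_len(ridx - 1)]
  tx <- taxonomy
  lab <- tx[[level]]
  unclass <- is.na(lab) | lab == "" | grepl("^unclassified", lab, ignore.case = TRUE)
  parent_lineage <- if (length(parents) > 0) {
    apply(as.data.frame(tx[parents]), 1, function(r) {
      r <- r[!is.na(r) & r != ""]
      if (length(r) == 0) "root" else paste(r, collapse = ";")
    })
  } else rep("root", nrow(tx))
  lab[unclass] <- paste0("unclassified ", parent_lineage[unclass])
  map <- tibble(ASV = tx$ASV, Taxon = lab)
  missing_tax <- setdiff(unique(counts$ASV), map$ASV)
  if (length(missing_tax) > 0) {
    warn(paste0(length(missing_tax), " ASV(s) absent from taxonomy grouped as 'unclassified root'"))
    map <- bind_rows(map, tibble(ASV = missing_tax, Taxon = "unclassified root"))
  }
  counts |>
    inner_join(map, by = "ASV") |>
    group_by(.data$SampleID, .data$Taxon) |>
    summarise(Count = sum(.data$Count), .groups = "drop")
}

#' Call intestinal domination per patient
#'
#' Domination is a genus-level relative abundance strictly above
#' `threshold` in a stool sample. Returns each patient's earliest dominated
#' sampling day (relative to nearest HCT), or `NA` if never dominated.
#'
#' @param rel_genus Genus-level relative abundances (from
#'   [relative_abundance()] on [aggregate_to_level()] output).
#' @param samples Sample table (`SampleID`, `PatientID`,
#'   `DayRelativeToNearestHCT`).
#' @param genus Genus name (exact string match).
#' @param threshold Fraction in (0, 1); strict `>` comparison.
#' @return Tibble `PatientID`, `Genus`, `Threshold`, `FirstDominationDay`
#'   (NA if never), one row per patient in `samples`.
#' @export
call_domination <- function(rel_genus, samples, genus, threshold = 0.3) {
  taxa <- unique(rel_genus$Taxon)
  if (!genus %in% taxa) abort(paste0("genus not present in table: ", genus))
  dom_days <- rel_genus |>
    filter(.data$Taxon == genus, .data$Fraction > threshold) |>
    inner_join(select(samples, "SampleID", "PatientID",
                      "DayRelativeToNearestHCT"), by = "SampleID") |>
    arrange(.data$DayRelativeToNearestHCT) |>
    distinct(.data$PatientID, .keep_all = TRUE) |>
    select("PatientID", FirstDominationDay = "DayRelativeToNearestHCT")
  tibble(PatientID = unique(samples$PatientID)) |>
    left_join(dom_days, by = "PatientID") |>
    mutate(Genus = genus, Threshold = threshold, .after = "PatientID")
}

#' Two-dimensional embedding of all compositions
#'
#' Projects per-sample composition vectors to 2-D with t-SNE (an
#' off-the-shelf stochastic neighbor embedding, used as a black box).
#' Deterministic under a fixed seed. If a taxonomy is supplied, each point
#' carries its dominant taxon and that taxon's hex color for plotting.
#'
#' @param rel Relative abundances (long tibble from [relative_abundance()]).
#' @param seed Integer seed.
#' @param taxonomy Optional taxonomy table for dominant-taxon colors.
#' @param perplexity t-SNE perplexity; default adapts to sample count.
#' @return Tibble `SampleID`, `x`, `y`, `DominantTaxon` (+ `HexColor` when
#'   taxonomy given).
#' @export
embed_2d <- function(rel, seed = 1, taxonomy = NULL, perplexity = NULL) {
  taxon_col <- attr(rel, "taxon_col") %||%
    (if ("ASV" %in% names(rel)) "ASV" else "Taxon")
  wide <- rel |>
    select("SampleID", all_of(taxon_col), "Fraction") |>
    pivot_wider(names_from = all_of(taxon_col), values_from = "Fraction",
                values_fill = 0)
  n <- nrow(wide)
  if (n < 3) abort("embedding needs at least 3 samples")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (is.null(perplexity)) perplexity <- max(0.5, min(30, (n - 1) / 3 - 0.01))
  set.seed(seed)
  fit <- Rtsne::Rtsne(m, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = ncol(m) > 50,
                      theta = if (n < 100) 0 else 0.5, verbose = FALSE)
  dom_idx <- max.col(m, ties.method = "first")
  out <- tibble(
    SampleID = wide$SampleID,
    x = fit$Y[, 1], y = fit$Y[, 2],
    DominantTaxon = colnames(m)[dom_idx]
  )
  if (!is.null(taxonomy)) {
    key <- if (taxon_col == "ASV") "ASV" else "Genus"
    cols <- taxonomy |>
      select(all_of(key), "HexColor") |>
      distinct(.data[[key]], .keep_all = TRUE)
    out <- left_join(out, cols, by = set_names(key, "DominantTaxon"))
  }
  out
}

#' Read / write a wide-format counts table
#'
#' The deposited wide tables (`tblcounts_{level}_wide.csv`) are
#' taxa-by-sample matrices. These helpers convert between that layout and
#' the melted layout used throughout the package.
#'
#' @param counts Melted counts (`SampleID`, taxon column, `Count`).
#' @param path CSV path.
#' @return `write_counts_wide()` returns `path` invisibly;
#'   `read_counts_wide()` returns a melted tibble (zero cells dropped).
#' @export
write_counts_wide <- function(counts, path) {
  taxon_col <- if ("ASV" %in% names(counts)) "ASV" else "Taxon"
  wide <- counts |>
    pivot_wider(id_cols = all_of(taxon_col), names_from = "SampleID",
                values_from = "Count", values_fill = 0)
  write_csv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_counts_wide
#' @param taxon_col Name for the taxon column on read.
#' @export
read_counts_wide <- function(path, taxon_col = "Taxon") {
  wide <- read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(wide)[1] <- taxon_col
  wide |>
    pivot_longer(-all_of(taxon_col), names_to = "SampleID",
                 values_to = "Count") |>
    filter(.data$Count != 0) |>
    select("SampleID", all_of(taxon_col), "Count")
}
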