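specimen_required_cols <- c(
  "species", "specimen_id",
  "leaf_length_1", "leaf_length_2", "leaf_length_3",
  "leaf_width_1", "leaf_width_2", "leaf_width_3",
  "flower_count"
)

#' Read a specimen trait table
#'
#' Reads a wide-format CSV of herbarium specimen measurements: one row per
#' voucher specimen with three replicate lamina length and width measurements
#' (mm), one flower count per inflorescence, and optional elevation (m).
#' Validation failures are fatal and name the offending column or rows.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row
#'   naming at least the columns `species`, `specimen_id`,
#'   `leaf_length_1..3`, `leaf_width_1..3`, `flower_count`; `elevation` is
#'   optional.
#' @param strict If `TRUE`, rows with missing leaf replicates are rejected;
#'   by default 1-2 available replicates are accepted with a warning, since
#'   herbarium material is often incomplete.
#'
#' @return A validated specimen tibble.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_specimens(generate_species("sp", 3, c(3, 2), diag(0.02, 2), 1, 0.2,
#'                                  seed = 1), tf)
#' read_specimens(tf)
read_specimens <- function(path, strict = FALSE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_specimens(df, strict = strict)
}

#' Write a specimen trait table
#'
#' Inverse of [read_specimens()]; round-trips losslessly on valid tables.
#'
#' @param specimens A specimen tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  readr::write_csv(specimens, path, progress = FALSE)
  invisible(path)
}

#' Validate a specimen table
#'
#' Checks the column contract and row-level invariants: strictly positive
#' leaf measurements, integer flower counts of at least 1, non-negative
#' elevation. Species names are trimmed of surrounding whitespace; matching
#' elsewhere in the package is exact after trimming.
#'
#' @param specimens A data frame shaped as in [read_specimens()].
#' @param strict Reject rows with missing leaf replicates instead of warning.
#' @return The validated tibble (invisibly coerced to `tibble`).
#' @export
validate_specimens <- function(specimens, strict = FALSE) {
  df <- as_tibble(specimens)
  missing_cols <- setdiff(specimen_required_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Specimen table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  num_cols <- setdiff(specimen_required_cols, c("species", "specimen_id"))
  if ("elevation" %in% names(df)) num_cols <- c(num_cols, "elevation")
  for (col in num_cols) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]]))
      abort(paste0("Column `", col, "` is not numeric",
                   if (length(bad) > 0) paste0(" (first bad row: ", bad[1], ")"), "."))
    }
  }
  df$species <- trimws(df$species)
  df$specimen_id <- trimws(as.character(df$specimen_id))

  leaf_cols <- grep("^leaf_(length|width)_[123]$", names(df), value = TRUE)
  leaf <- as.matrix(df[leaf_cols])
  bad_leaf <- which(apply(leaf, 1L, function(x) any(!is.na(x) & x <= 0)))
  if (length(bad_leaf) > 0) {
    abort(paste0("Leaf measurements must be strictly positive; bad row(s): ",
                 paste(head(bad_leaf, 10), collapse = ", ")))
  }
  fc <- df$flower_count
  bad_fc <- which(is.na(fc) | fc < 1 | fc != round(fc))
  if (length(bad_fc) > 0) {
    abort(paste0("`flower_count` must be an integer >= 1; bad row(s): ",
                 paste(head(bad_fc, 10), collapse = ", ")))
  }
  if ("elevation" %in% names(df) && any(df$elevation < 0, na.rm = TRUE)) {
    abort("`elevation` must be non-negative.")
  }

  n_len <- rowSums(!is.na(df[paste0("leaf_length_", 1:3)]))
  n_wid <- rowSums(!is.na(df[paste0("leaf_width_", 1:3)]))
  incomplete <- which(n_len < 3 | n_wid < 3)
  none <- which(n_len == 0 | n_wid == 0)
  if (length(none) > 0) {
    abort(paste0("Rows with no usable leaf replicate: ",
                 paste(head(none, 10), collapse = ", ")))
  }
  if (length(incomplete) > 0) {
    if (strict) {
      abort(paste0("strict = TRUE: rows with fewer than 3 leaf replicates: ",
                   paste(head(incomplete, 10), collapse = ", ")))
    }
    warn(paste0(length(incomplete), " specimen(s) have fewer than 3 leaf ",
                "replicates; available replicates will be averaged (rows ",
                paste(head(incomplete, 5), collapse = ", "), ")."))
  }
  df
}

#' Aggregate specimens to per-specimen trait means
#'
#' Averages the replicate lamina measurements of each specimen into a single
#' mean length and width, keeping the flower count as is — one count per
#' inflorescence per specimen. This per-specimen-mean table is the unit of
#' all downstream analysis.
#'
#' @param specimens A validated specimen tibble.
#' @return A tibble with columns `species`, `specimen_id`, `leaf_length`,
#'   `leaf_width` (mm, replicate means), `flower_count`, and `elevation` if
#'   present.
#' @export
#' @examples
#' sp <- generate_species("sp", 4, c(3, 2), diag(0.02, 2), 1, 0.2, seed = 1)
#' specimen_means(sp)
specimen_means <- function(specimens) {
  df <- as_tibble(specimens)
  if (nrow(df) == 0) abort("Empty specimen table.")
  out <- tibble(
    species = trimws(df$species),
    specimen_id = as.character(df$specimen_id),
    leaf_length = rowMeans(df[paste0("leaf_length_", 1:3)], na.rm = TRUE),
    leaf_width = rowMeans(df[paste0("leaf_width_", 1:3)], na.rm = TRUE),
    flower_count = df$flower_count
  )
  if ("elevation" %in% names(df)) out$elevation <- df$elevation
  out
}

#' Drop species with too few specimens
#'
#' The tolerance-region method needs a covariance estimate and so a sample
#' size larger than three; species below `min_n` are removed and reported.
#' The excluded set is attached as the `"excluded"` attribute (a tibble of
#' species and n) for logging.
#'
#' @param means A specimen-means tibble from [specimen_means()].
#' @param min_n Minimum specimens per retained species (default 4).
#' @return The filtered tibble, with attribute `"excluded"`.
#' @export
filter_min_n <- function(means, min_n = 4) {
  stopifnot(min_n >= 1)
  counts <- dplyr::count(means, .data$species)
  excluded <- dplyr::filter(counts, .data$n < min_n)
  if (nrow(excluded) > 0) {
    inform(paste0("Excluding ", nrow(excluded), " species with n < ", min_n,
                  ": ", paste(excluded$species, collapse = ", ")))
  }
  out <- dplyr::filter(means, !(.data$species %in% excluded$species))
  attr(out, "excluded") <- excluded
  out
}

#' Per-species descriptive statistics
#'
#' Minimum, mean and maximum of per-specimen mean leaf length and width and
#' of flower number, plus the elevation range, per species — the layout of a
#' standard morphometric descriptive table.
#'
#' @param means A specimen-means tibble.
#' @return A tibble, one row per species, columns `species`, `n`, then
#'   `<trait>_min/_mean/_max` for `leaf_length`, `leaf_width` and
#'   `flower_count`, and `elevation_min`/`elevation_max` when elevation is
#'   present.
#' @export
descriptive_stats <- function(means) {
  if (nrow(means) == 0) abort("Empty specimen-means table.")
  out <- means |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n = dplyr::n(),
      leaf_length_min = min(.data$leaf_length),
      leaf_length_mean = mean(.data$leaf_length),
      leaf_length_max = max(.data$leaf_length),
      leaf_width_min = min(.data$leaf_width),
      leaf_width_mean = mean(.data$leaf_width),
      leaf_width_max = max(.data$leaf_width),
      flower_count_min = min(.data$flower_count),
      flower_count_mean = mean(.data$flower_count),
      flower_count_max = max(.data$flower_count),
      .groups = "drop"
    )
  if ("elevation" %in% names(means)) {
    elev <- means |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(
        elevation_min = suppressWarnings(min(.data$elevation, na.rm = TRUE)),
        elevation_max = suppressWarnings(max(.data$elevation, na.rm = TRUE)),
        .groups = "drop"
      )
    elev$elevation_min[!is.finite(elev$elevation_min)] <- NA_real_
    elev$elevation_max[!is.finite(elev$elevation_max)] <- NA_real_
    out <- dplyr::left_join(out, elev, by = "species")
  }
  out
}
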