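#' Read a tagged-fish track table
#'
#' One CSV carries both per-fish metadata rows and per-day longitude rows.
#' Metadata rows have `release_date` filled (plus `release_lat`,
#' `release_lon`, `release_region`, and the recapture fields); daily rows
#' have `date` and `longitude` filled. Daily rows are returned date-sorted
#' regardless of file order.
#'
#' @param path CSV path.
#' @return A tibble with one row per fish: the metadata columns plus a
#'   `track` list-column of tibbles with columns `date` and `longitude`
#'   (zero-row for fish with no daily estimates; classification then falls
#'   back to the recapture position).
#' @seealso [classify_behaviour()], [write_track_table()]
#' @export
read_track_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("fish_id", "release_date", "release_lat", "release_lon", "release_region",
              "recapture_date", "recapture_lat", "recapture_lon", "date", "longitude")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Track CSV lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  raw$release_date <- as.Date(raw$release_date)
  raw$recapture_date <- as.Date(raw$recapture_date)
  raw$date <- as.Date(raw$date)

  meta <- raw[!is.na(raw$release_date), ]
  daily <- raw[is.na(raw$release_date) & !is.na(raw$date), ]
  if (nrow(meta) == 0) abort("Track CSV contains no metadata rows (release_date filled).")
  if (anyDuplicated(meta$fish_id)) abort("Duplicated fish_id in metadata rows.")
  orphans <- setdiff(daily$fish_id, meta$fish_id)
  if (length(orphans) > 0) {
    abort(sprintf("Daily rows for unknown fish_id(s): %s.", paste(unique(orphans), collapse = ", ")))
  }
  late <- !is.na(meta$recapture_date) & meta$recapture_date < meta$release_date
  if (any(late)) {
    abort(sprintf("Recapture before release for: %s.", paste(meta$fish_id[late], collapse = ", ")))
  }

  daily <- daily[order(daily$fish_id, daily$date), c("fish_id", "date", "longitude")]
  tracks <- split(daily[c("date", "longitude")], factor(daily$fish_id, levels = meta$fish_id))
  fish <- as_tibble(meta[, c("fish_id", "release_date", "release_lat", "release_lon",
                             "release_region", "recapture_date", "recapture_lat", "recapture_lon")])
  fish$track <- lapply(tracks, as_tibble)
  fish
}

#' Write a tagged-fish track table
#'
#' Inverse of [read_track_table()]: writes one CSV holding the metadata rows
#' and the date-ordered daily longitude rows.
#'
#' @param fish A tibble as returned by [read_track_table()] or
#'   [sim_tagged_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(fish, path) {
  meta <- fish[, c("fish_id", "release_date", "release_lat", "release_lon",
                   "release_region", "recapture_date", "recapture_lat", "recapture_lon")]
  meta$date <- as.Date(NA)
  meta$longitude <- NA_real_
  daily <- purrr::map2(fish$fish_id, fish$track, function(id, tr) {
    if (is.null(tr) || nrow(tr) == 0) return(NULL)
    tibble(
      fish_id = id, release_date = as.Date(NA), release_lat = NA_real_,
      release_lon = NA_real_, release_region = NA_character_,
      recapture_date = as.Date(NA), recapture_lat = NA_real_, recapture_lon = NA_real_,
      date = tr$date, longitude = tr$longitude
    )
  }) |> dplyr::bind_rows()
  readr::write_csv(dplyr::bind_rows(meta, daily), path, progress = FALSE)
  invisible(path)
}

#' Read a sample-metadata sidecar CSV
#'
#' Genepop files cannot carry sample metadata; it travels in a sidecar CSV
#' keyed by sample label with columns `sample`, `region`, `stage`, `date`,
#' `lat`, `lon` (WGS84 decimal degrees, east-positive longitude).
#'
#' @param path CSV path.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample", "region", "stage", "date", "lat", "lon")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("Sample metadata lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample)) abort("Duplicated sample labels in metadata.")
  as_tibble(meta)
}
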