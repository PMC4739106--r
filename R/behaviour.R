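#' Validate a daily longitude series
#'
#' Light-based daily longitude estimates carry noise and occasional spurious
#' single-day excursions. A new location is accepted only when three or more
#' consecutive estimates each depart more than `threshold` (one longitudinal
#' degree) from the current valid longitude; the committed value is the run
#' mean, and run members must lie within `threshold` of that mean (mutual
#' coherence). Estimates not part of a committed run are discarded as noise.
#' The series is initialised at the release longitude.
#'
#' @param longitudes Numeric vector of daily longitude estimates
#'   (date-ordered; may be empty).
#' @param release_lon Release longitude, the initial valid location.
#' @param threshold Departure/coherence threshold in degrees (default 1.0).
#' @param min_run Minimum run length to commit (default 3).
#' @return Numeric vector of validated longitudes, beginning with
#'   `release_lon`.
#' @examples
#' validate_longitudes(c(11.0, 11.1, 9.5, 11.05, 11.0), 11.2)  # excursion rejected
#' validate_longitudes(c(9.5, 9.4, 9.6), 11.2)                 # commits ~9.5
#' @export
validate_longitudes <- function(longitudes, release_lon, threshold = 1.0, min_run = 3) {
  valid <- release_lon
  current <- release_lon
  run <- numeric(0)
  commit <- function() {
    if (length(run) >= min_run) {
      m <- mean(run)
      if (all(abs(run - m) <= threshold)) {
        valid <<- c(valid, m)
        current <<- m
        run <<- numeric(0)
        return(TRUE)
      }
    }
    FALSE
  }
  for (x in longitudes) {
    if (is.na(x)) next
    if (abs(x - current) > threshold) {
      if (length(run) > 0 && abs(x - mean(c(run, x))) > threshold) {
        # new estimate breaks run coherence: close the run, start a fresh one
        commit()
        run <- if (abs(x - current) > threshold) x else numeric(0)
      } else {
        run <- c(run, x)
      }
    } else {
      commit()
      run <- numeric(0)
    }
  }
  commit()
  valid
}

#' Days at liberty
#'
#' Calendar-day difference between recapture and release. The study filter
#' requires strictly more than 30 days, so exactly 30 fails it.
#'
#' @param release_date,recapture_date `Date` vectors.
#' @return Integer days.
#' @export
days_at_liberty <- function(release_date, recapture_date) {
  d <- as.integer(as.Date(recapture_date) - as.Date(release_date))
  if (any(!is.na(d) & d < 0)) abort("Recapture before release: chronology error.")
  d
}

#' Classify migratory behaviour of tagged fish
#'
#' Applies the study's classification rules to each tagged fish:
#' * excluded with reason `short_liberty` when days at liberty do not exceed
#'   `min_liberty` (30 days);
#' * excluded with reason `unreconstructable` when both the recapture
#'   position and the track are absent;
#' * a fish recaptured or validly geolocated west of `west_lon` (10 degrees
#'   E) is migrating towards the North Sea (`SkagerrakToNorthSea` or
#'   `KattegatToNorthSea` by release region);
#' * otherwise a fish released in the eastern Skagerrak and recaptured in
#'   the Kattegat box (latitude below `boundary_lat`, longitude at or east
#'   of `boundary_lon`) is `SkagerrakToKattegat`;
#' * otherwise `NonmigratorySkagerrak` / `NonmigratoryKattegat`.
#'
#' The Skagerrak/Kattegat boundary is a single latitude cut at Skagen's
#' parallel (57.75 degrees N) east of 10 degrees E; both numbers are
#' configurable. Fish whose time at liberty does not span a spawning season
#' (no mid-February between release and recapture) are flagged
#' `spans_spawning = FALSE` but retained.
#'
#' @param fish A tibble as from [read_track_table()] or
#'   [sim_tagged_cohort()]: metadata columns plus a `track` list-column.
#' @param west_lon Longitude (degrees E) defining "towards the North Sea"
#'   (default 10).
#' @param boundary_lat,boundary_lon Skagerrak/Kattegat boundary (defaults
#'   57.75 N, 10 E).
#' @param min_liberty Minimum days at liberty, strict inequality (default 30).
#' @param validate_args List of extra arguments for [validate_longitudes()].
#' @return A tibble per fish: `fish_id`, `category`, `reason` (`NA` unless
#'   excluded), `days_at_liberty`, `min_validated_lon`, `spans_spawning`.
#'   Categories: `SkagerrakToNorthSea`, `KattegatToNorthSea`,
#'   `SkagerrakToKattegat`, `NonmigratorySkagerrak`, `NonmigratoryKattegat`,
#'   `Excluded`.
#' @export
classify_behaviour <- function(fish, west_lon = 10, boundary_lat = 57.75,
                               boundary_lon = 10, min_liberty = 30,
                               validate_args = list()) {
  needed <- c("fish_id", "release_date", "release_lon", "release_region",
              "recapture_date", "recapture_lat", "recapture_lon", "track")
  missing_cols <- setdiff(needed, names(fish))
  if (length(missing_cols) > 0) {
    abort(sprintf("`fish` lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  bad_region <- setdiff(unique(fish$release_region), c("ESkagerrak", "Kattegat"))
  if (length(bad_region) > 0) {
    abort(sprintf("Unknown release_region(s): %s.", paste(bad_region, collapse = ", ")))
  }

  rows <- purrr::pmap(fish[needed], function(fish_id, release_date, release_lon,
                                             release_region, recapture_date,
                                             recapture_lat, recapture_lon, track) {
    dal <- days_at_liberty(release_date, recapture_date)
    spawn <- spans_spawning(release_date, recapture_date)
    lons <- if (!is.null(track) && nrow(track) > 0) track$longitude else numeric(0)
    valid <- do.call(validate_longitudes,
                     c(list(lons, release_lon), validate_args))
    min_valid <- min(valid)
    rec <- function(category, reason = NA_character_) {
      tibble(fish_id = fish_id, category = category, reason = reason,
             days_at_liberty = dal, min_validated_lon = min_valid,
             spans_spawning = spawn)
    }
    no_recapture <- is.na(recapture_lon)
    if (no_recapture && length(lons) == 0) {
      return(rec("Excluded", "unreconstructable"))
    }
    if (is.na(dal)) {
      return(rec("Excluded", "unreconstructable"))
    }
    if (dal <= min_liberty) {
      return(rec("Excluded", "short_liberty"))
    }
    towards_ns <- any(valid < west_lon) ||
      (!no_recapture && recapture_lon < west_lon)
    if (towards_ns) {
      return(rec(if (release_region == "ESkagerrak") "SkagerrakToNorthSea" else "KattegatToNorthSea"))
    }
    in_kattegat <- !no_recapture && !is.na(recapture_lat) &&
      recapture_lat < boundary_lat && recapture_lon >= boundary_lon
    if (release_region == "ESkagerrak" && in_kattegat) {
      return(rec("SkagerrakToKattegat"))
    }
    rec(if (release_region == "ESkagerrak") "NonmigratorySkagerrak" else "NonmigratoryKattegat")
  })
  dplyr::bind_rows(rows)
}

# TRUE when any mid-spawning date (Feb 15) lies within [release, recapture].
spans_spawning <- function(release_date, recapture_date) {
  if (is.na(release_date) || is.na(recapture_date)) return(NA)
  years <- seq(as.integer(format(as.Date(release_date), "%Y")),
               as.integer(format(as.Date(recapture_date), "%Y")))
  feb <- as.Date(paste0(years, "-02-15"))
  any(feb >= as.Date(release_date) & feb <= as.Date(recapture_date))
}

#' Plot validated longitude tracks
#'
#' @param fish A tagged-fish tibble with a `track` list-column.
#' @param west_lon Reference line for the towards-North-Sea rule.
#' @return A ggplot: daily longitude per fish over time with the 10 degrees
#'   E rule line.
#' @export
plot_tracks <- function(fish, west_lon = 10) {
  daily <- purrr::map2(fish$fish_id, fish$track, function(id, tr) {
    if (is.null(tr) || nrow(tr) == 0) return(NULL)
    tibble(fish_id = id, date = tr$date, longitude = tr$longitude)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(daily, ggplot2::aes(x = .data$date, y = .data$longitude,
                                      group = .data$fish_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = west_lon, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Longitude (degrees E)",
                  title = "Daily longitude estimates per tagged fish") +
    ggplot2::theme_minimal()
}
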