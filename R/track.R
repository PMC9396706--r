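#' Construct a telemetry track
#'
#' A `cm_track` is a data.frame of time-ordered satellite fixes for a single
#' animal with columns `animal_id`, `time` (POSIXct, UTC), `lon`, `lat`, and
#' optionally `lc_class` (Argos location-quality class) and `true_lon`,
#' `true_lat` (known true positions, available for synthetic tracks).
#'
#' @param animal_id Character scalar or vector identifying the animal.
#' @param time `POSIXct` vector (UTC), strictly increasing.
#' @param lon,lat Observed coordinates in decimal degrees.
#' @param lc_class Optional character vector of Argos classes (e.g. "LC3").
#' @param true_lon,true_lat Optional true coordinates (synthetic tracks).
#' @return A `cm_track` data.frame.
#' @export
cm_track <- function(animal_id, time, lon, lat, lc_class = NULL,
                     true_lon = NULL, true_lat = NULL) {
  n <- length(time)
  stopifnot(inherits(time, "POSIXct"), length(lon) == n, length(lat) == n)
  check_lonlat(lon, lat)
  if (length(animal_id) == 1L) animal_id <- rep(animal_id, n)
  df <- data.frame(animal_id = as.character(animal_id),
                   time = time, lon = lon, lat = lat,
                   stringsAsFactors = FALSE)
  if (!is.null(lc_class)) df$lc_class <- as.character(lc_class)
  if (!is.null(true_lon)) {
    stopifnot(length(true_lon) == n, length(true_lat) == n)
    df$true_lon <- true_lon
    df$true_lat <- true_lat
  }
  validate_cm_track(structure(df, class = c("cm_track", "data.frame")))
}

validate_cm_track <- function(x) {
  if (length(unique(x$animal_id)) > 1L) {
    stop("a cm_track holds fixes for exactly one animal", call. = FALSE)
  }
  dt <- diff(as.numeric(x$time))
  if (any(dt <= 0)) {
    stop("timestamps must be strictly increasing (duplicates or disorder)",
         call. = FALSE)
  }
  x
}

#' @export
print.cm_track <- function(x, ...) {
  cat(sprintf("<cm_track> animal %s: %d fixes, %s to %s\n",
              x$animal_id[1], nrow(x),
              format(min(x$time), "%Y-%m-%d %H:%M"),
              format(max(x$time), "%Y-%m-%d %H:%M")))
  if (!is.null(x$lc_class)) {
    tab <- table(x$lc_class)
    cat("  Argos classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read telemetry tracks from delimited text
#'
#' Reads the package's tracking schema (`animal_id, timestamp, lon, lat,
#' lc_class[, true_lon, true_lat]`, comma-separated, ISO-8601 UTC timestamps)
#' and returns one `cm_track` per animal. Rows are sorted by time within each
#' animal; a duplicated timestamp within an animal is an error reporting the
#' offending line.
#'
#' @param path Path to a CSV file.
#' @return Named list of `cm_track` objects.
#' @export
read_tracking <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(raw))) {
    stop("tracking file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  time <- parse_utc_times(raw$timestamp)
  if (any(is.na(time))) {
    bad <- which(is.na(time))[1]
    stop(sprintf("unparseable timestamp at data line %d: '%s'",
                 bad, raw$timestamp[bad]), call. = FALSE)
  }
  raw$.time <- time
  out <- lapply(split(raw, raw$animal_id), function(d) {
    o <- order(d$.time)
    d <- d[o, ]
    dup <- which(duplicated(as.numeric(d$.time)))
    if (length(dup)) {
      stop(sprintf("duplicated timestamp for animal %s at '%s'",
                   d$animal_id[1], format(d$.time[dup[1]], "%Y-%m-%dT%H:%M:%S")),
           call. = FALSE)
    }
    cm_track(d$animal_id, d$.time, d$lon, d$lat,
             lc_class = if ("lc_class" %in% names(d)) d$lc_class,
             true_lon = if ("true_lon" %in% names(d)) d$true_lon,
             true_lat = if ("true_lat" %in% names(d)) d$true_lat)
  })
  out
}

## ISO-8601 (or date-only) UTC parser that leaves NA where no format matches,
## so callers can report the offending line instead of aborting mid-parse.
parse_utc_times <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], tz = "UTC", format = fmt)
  }
  out
}

#' Write telemetry tracks to delimited text
#'
#' @param tracks A `cm_track` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(tracks, path) {
  if (inherits(tracks, "cm_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    d <- data.frame(animal_id = tr$animal_id,
                    timestamp = format(tr$time, "%Y-%m-%dT%H:%M:%S"),
                    lon = tr$lon, lat = tr$lat,
                    stringsAsFactors = FALSE)
    d$lc_class <- if (!is.null(tr$lc_class)) tr$lc_class else NA
    d$true_lon <- if (!is.null(tr$true_lon)) tr$true_lon else NA
    d$true_lat <- if (!is.null(tr$true_lat)) tr$true_lat else NA
    d
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Thin a track to one fix per calendar day
#'
#' Telemetry duty cycles concentrate fixes in bursts, so days are unequally
#' represented. For occurrence-based niche analysis one fix is drawn uniformly
#' at random per UTC calendar day.
#'
#' @param traj A `cm_track`.
#' @param seed Integer seed for the per-day draw (reproducible thinning).
#' @return A `cm_track` with at most one fix per day.
#' @export
thin_daily <- function(traj, seed = NULL) {
  stopifnot(inherits(traj, "cm_track"))
  day <- format(traj$time, "%Y-%m-%d")
  keep <- with_seed(seed, {
    vapply(split(seq_len(nrow(traj)), day), function(idx) {
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }, integer(1))
  })
  out <- traj[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(traj))
}

#' Label fixes by season from month windows
#'
#' Assigns `"winter"` to fixes in the non-breeding months (default November
#' to February) and `"summer"` to the breeding months (default June to
#' August); other fixes get `NA` (migration or shoulder periods).
#'
#' @param time `POSIXct` vector.
#' @param winter_months,summer_months Integer month numbers.
#' @return Character vector of season labels.
#' @export
season_from_months <- function(time, winter_months = c(11, 12, 1, 2),
                               summer_months = 6:8) {
  m <- as.integer(format(time, "%m"))
  out <- rep(NA_character_, length(m))
  out[m %in% winter_months] <- "winter"
  out[m %in% summer_months] <- "summer"
  out
}
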