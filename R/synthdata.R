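#' Configuration for the synthetic migration simulator
#'
#' Describes a seasonal migrant commuting between a subtropical winter
#' (non-breeding) range and a temperate summer (breeding) range. Within a
#' range the true position follows a Gaussian random walk attracted to the
#' range centre; inside a migration window the bird moves directly toward the
#' other centre at `migration_speed_km_day` until it arrives. Fixes are
#' emitted on an irregular duty-cycle schedule emulating Argos transmitters
#' (bursts of consecutive hourly fixes separated by off periods).
#'
#' @param winter_centre,summer_centre `c(lon, lat)` of the range centres.
#'   Defaults place the winter range on the northern Gulf of Mexico coast and
#'   the summer range in the northern Great Plains, about 1950 km apart.
#' @param spring_window,autumn_window Day-of-year intervals `c(start, end)`
#'   during which directed migration occurs; must lie in `[1, 365]` and not
#'   overlap.
#' @param step_sd_km Within-range random-walk scale (km per day).
#' @param attraction_per_day Fraction of the displacement from the range
#'   centre removed per day by the attraction (mean reversion) term.
#' @param migration_speed_km_day Directed ground speed during migration.
#' @param sampling List of duty-cycle blocks, each a list with elements
#'   `start_day`, `end_day`, `every_h` (hours between burst starts) and
#'   `burst_h` (number of consecutive hourly fixes per burst). The default
#'   emulates six consecutive hourly fixes every 48 h from October to
#'   mid-June and every 10 days from mid-June through September.
#' @param argos_class_probs Named numeric probabilities for classes
#'   LC3/LC2/LC1/LC0; must sum to 1.
#' @param argos_class_sd_km Named numeric isotropic error SD (km) per class.
#' @param year Calendar year used for timestamps.
#' @return A `sim_config` list.
#' @export
sim_config <- function(winter_centre = c(-90.5, 30.5),
                       summer_centre = c(-96.0, 47.5),
                       spring_window = c(110, 125),
                       autumn_window = c(270, 285),
                       step_sd_km = 8,
                       attraction_per_day = 0.5,
                       migration_speed_km_day = 150,
                       sampling = list(
                         list(start_day = 1, end_day = 166, every_h = 48, burst_h = 6),
                         list(start_day = 167, end_day = 273, every_h = 240, burst_h = 6),
                         list(start_day = 274, end_day = 365, every_h = 48, burst_h = 6)
                       ),
                       argos_class_probs = c(LC3 = 0.10, LC2 = 0.20,
                                             LC1 = 0.30, LC0 = 0.40),
                       argos_class_sd_km = c(LC3 = 0.25, LC2 = 0.5,
                                             LC1 = 1.5, LC0 = 5),
                       year = 2000) {
  cfg <- list(winter_centre = winter_centre, summer_centre = summer_centre,
              spring_window = spring_window, autumn_window = autumn_window,
              step_sd_km = step_sd_km, attraction_per_day = attraction_per_day,
              migration_speed_km_day = migration_speed_km_day,
              sampling = sampling,
              argos_class_probs = argos_class_probs,
              argos_class_sd_km = argos_class_sd_km, year = year)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  win <- list(cfg$spring_window, cfg$autumn_window)
  for (w in win) {
    if (length(w)) {
      if (w[1] > w[2] || w[1] < 1 || w[2] > 365) {
        stop("migration windows must be increasing intervals within [1, 365]",
             call. = FALSE)
      }
    }
  }
  if (length(cfg$spring_window) && length(cfg$autumn_window) &&
      cfg$spring_window[2] >= cfg$autumn_window[1]) {
    stop("spring and autumn windows must not overlap", call. = FALSE)
  }
  if (abs(sum(cfg$argos_class_probs) - 1) > 1e-8) {
    stop("argos_class_probs must sum to 1", call. = FALSE)
  }
  if (any(cfg$argos_class_sd_km < 0) || cfg$step_sd_km < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a migratory trajectory
#'
#' Generates the true hourly path for one annual cycle under `config` and
#' emits noise-free fixes on the configured duty-cycle schedule. Observed
#' coordinates equal the true coordinates until [corrupt_with_argos_error()]
#' is applied.
#'
#' @param config A [sim_config()].
#' @param animal_id Identifier stored in the track.
#' @param seed Integer seed; the same seed reproduces the same track exactly.
#' @return A `cm_track` with `true_lon`/`true_lat` columns.
#' @export
simulate_migratory_path <- function(config, animal_id = "bird1", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n_hours <- 365L * 24L
    dt_day <- 1 / 24
    step_sd_h <- config$step_sd_km * sqrt(dt_day)
    v_h <- config$migration_speed_km_day * dt_day
    arrive_km <- 25

    ## work in a plane centred at the winter centre; both centres planar
    sc <- project_to_plane(config$summer_centre[1], config$summer_centre[2],
                           origin = config$winter_centre)
    centres <- list(winter = c(0, 0), summer = c(sc$x_km, sc$y_km))

    pos <- matrix(NA_real_, nrow = n_hours, ncol = 2)
    p <- centres$winter
    state <- "winter"    # winter / spring / summer / autumn
    for (i in seq_len(n_hours)) {
      day <- (i - 1) / 24 + 1
      if (state == "winter" && length(config$spring_window) &&
          day >= config$spring_window[1] && day <= config$spring_window[2]) {
        state <- "spring"
      }
      if (state == "summer" && length(config$autumn_window) &&
          day >= config$autumn_window[1] && day <= config$autumn_window[2]) {
        state <- "autumn"
      }
      if (state == "spring" && day > config$spring_window[2]) state <- "summer"
      if (state == "autumn" && day > config$autumn_window[2]) state <- "winter"

      if (state %in% c("spring", "autumn")) {
        target <- if (state == "spring") centres$summer else centres$winter
        d <- target - p
        dist <- sqrt(sum(d^2))
        if (dist <= arrive_km) {
          state <- if (state == "spring") "summer" else "winter"
        } else {
          p <- p + d / dist * min(v_h, dist) + stats::rnorm(2, 0, step_sd_h)
        }
      }
      if (state %in% c("winter", "summer")) {
        centre <- centres[[state]]
        p <- p + (centre - p) * config$attraction_per_day * dt_day +
          stats::rnorm(2, 0, step_sd_h)
      }
      pos[i, ] <- p
    }

    ## duty-cycle sampling: hour indices of emitted fixes
    hours <- sort(unique(unlist(lapply(config$sampling, function(b) {
      h0 <- (b$start_day - 1) * 24
      h1 <- b$end_day * 24 - 1
      starts <- seq(h0, h1, by = b$every_h)
      idx <- unlist(lapply(starts, function(s) s + seq_len(b$burst_h) - 1))
      idx[idx <= h1]
    }))))
    hours <- hours[hours < n_hours]

    ll <- plane_to_lonlat(pos[hours + 1, 1], pos[hours + 1, 2],
                          origin = config$winter_centre)
    time <- as.POSIXct(sprintf("%d-01-01 00:00:00", config$year), tz = "UTC") +
      hours * 3600
    tr <- cm_track(animal_id, time, ll$lon, ll$lat,
                   true_lon = ll$lon, true_lat = ll$lat)
    attr(tr, "seed") <- seed
    attr(tr, "config") <- config
    tr
  })
}

#' Add Argos-class location error to a track
#'
#' Each fix is assigned a location class drawn from
#' `config$argos_class_probs` and displaced by isotropic Gaussian noise with
#' that class's standard deviation (km). True positions are retained in
#' `true_lon`/`true_lat` for validation.
#'
#' @param traj A `cm_track` with true positions.
#' @param config A [sim_config()] supplying class probabilities and SDs.
#' @param seed Integer seed.
#' @return A `cm_track` with noisy `lon`/`lat` and an `lc_class` column.
#' @export
corrupt_with_argos_error <- function(traj, config, seed = NULL) {
  stopifnot(inherits(traj, "cm_track"))
  if (is.null(traj$true_lon)) stop("track has no true positions", call. = FALSE)
  probs <- config$argos_class_probs
  sds <- config$argos_class_sd_km
  if (!all(names(probs) %in% names(sds))) {
    stop("missing error SD for some Argos class", call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(traj)
    cls <- sample(names(probs), n, replace = TRUE, prob = probs)
    sd_km <- unname(sds[cls])
    dx <- stats::rnorm(n, 0, sd_km)
    dy <- stats::rnorm(n, 0, sd_km)
    # km offsets to degrees at the local latitude
    lat <- traj$true_lat + dy / 111.1949
    lon <- traj$true_lon + dx / (111.1949 * cos(traj$true_lat * pi / 180))
    out <- traj
    out$lon <- lon
    out$lat <- lat
    out$lc_class <- cls
    out
  })
}

#' Simulate an NSD series directly from a sigmoid model
#'
#' Forward-evaluates the single (spring-only) or double (rise-plateau-return)
#' sigmoid model of net squared displacement at the given times, optionally
#' adding Gaussian observation noise. With `noise_sd = 0` the values are the
#' exact model curve.
#'
#' @param params Named list or vector of parameters. Single model:
#'   `delta`, `theta`, `phi`. Double model: `delta`, `theta_s`, `theta_a`,
#'   `phi_s`, `phi_a`.
#' @param times Numeric vector of (fractional) days of year.
#' @param noise_sd SD of additive Gaussian noise (km^2).
#' @param seed Integer seed for the noise.
#' @param animal_id Identifier attached to the series.
#' @return An [nsd_series()].
#' @export
simulate_nsd_series <- function(params, times, noise_sd = 0, seed = NULL,
                                animal_id = "sim") {
  params <- as.list(params)
  kind <- if (!is.null(params$theta_s)) "double" else "single"
  if (kind == "single") {
    if (params$phi <= 0) stop("phi must be positive", call. = FALSE)
    y <- single_sigmoid(times, params$delta, params$theta, params$phi)
  } else {
    if (params$phi_s <= 0 || params$phi_a <= 0) {
      stop("phi_s and phi_a must be positive", call. = FALSE)
    }
    y <- double_sigmoid(times, params$delta, params$theta_s, params$theta_a,
                        params$phi_s, params$phi_a)
  }
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(times), 0, noise_sd))
  }
  nsd_series(times, y, animal_id = animal_id, from_trajectory = FALSE)
}

#' A simple in-memory climate raster
#'
#' A regular lon/lat grid holding the four seasonal climate variables used in
#' the niche analysis: mean monthly minimum temperature (`tmin`, degC), mean
#' monthly maximum temperature (`tmax`, degC), mean monthly precipitation
#' (`precip`, mm) and mean wind speed (`wind`, m/s). Matrices are indexed
#' `[row = latitude band (south to north), col = longitude band]`.
#'
#' @param bbox Numeric `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param cell_size Cell edge in degrees.
#' @param tmin,tmax,precip,wind Matrices of cell values.
#' @param season Season label ("winter" or "summer").
#' @return A `cm_raster` object.
#' @export
cm_raster <- function(bbox, cell_size, tmin, tmax, precip, wind,
                      season = NA_character_) {
  if (any(tmax < tmin)) stop("tmax < tmin in some cell", call. = FALSE)
  if (any(precip < 0)) stop("negative precipitation", call. = FALSE)
  if (any(wind < 0)) stop("negative wind speed", call. = FALSE)
  structure(list(bbox = bbox, cell_size = cell_size, season = season,
                 vars = list(tmin = tmin, tmax = tmax,
                             precip = precip, wind = wind)),
            class = "cm_raster")
}

#' @export
print.cm_raster <- function(x, ...) {
  d <- dim(x$vars$tmin)
  cat(sprintf("<cm_raster> %s season, %d x %d cells of %g deg, bbox [%g, %g] x [%g, %g]\n",
              x$season, d[1], d[2], x$cell_size,
              x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

## cell-centre coordinate vectors of a cm_raster
raster_centres <- function(r) {
  d <- dim(r$vars$tmin)
  list(lon = r$bbox[1] + (seq_len(d[2]) - 0.5) * r$cell_size,
       lat = r$bbox[2] + (seq_len(d[1]) - 0.5) * r$cell_size)
}

#' Default seasonal climate configuration
#'
#' Per-season, per-variable means and SDs of the synthetic Gaussian climate
#' fields. The defaults encode the contrast the niche analysis assumes:
#' temperatures and precipitation strongly separated between the subtropical
#' winter region and the temperate summer region (approximately 7-10 SDs),
#' wind speed essentially identical (winter mean 3.33 m/s, SD 0.4; summer
#' mean 3.26 m/s, SD 0.34). `tmax` is generated as `tmin` plus a non-negative
#' diurnal gap so that `tmin <= tmax` holds cell-wise by construction.
#'
#' @param identical_seasons If `TRUE`, the summer region is drawn from the
#'   winter distributions (a niche-tracking null configuration).
#' @return A list with components `winter` and `summer`, each holding
#'   `centre`, `half_extent_deg`, `n_cells` (grid edge) and a `vars` list of
#'   `c(mean, sd)` pairs for `tmin`, `tgap`, `precip`, `wind`.
#' @export
climate_config <- function(identical_seasons = FALSE) {
  winter <- list(centre = c(-90.5, 30.5), half_extent_deg = 1.5, n_cells = 60,
                 vars = list(tmin = c(4, 1), tgap = c(12, 1),
                             precip = c(120, 8), wind = c(3.33, 0.40)))
  summer <- list(centre = c(-96.0, 47.5), half_extent_deg = 1.5, n_cells = 60,
                 vars = list(tmin = c(14, 1), tgap = c(12, 1),
                             precip = c(60, 8), wind = c(3.26, 0.34)))
  if (identical_seasons) summer$vars <- winter$vars
  list(winter = winter, summer = summer)
}

#' Simulate paired winter/summer climate rasters
#'
#' Draws cell-wise independent Gaussian fields for each region according to a
#' [climate_config()]; precipitation and the diurnal temperature gap are
#' truncated at zero to respect physical invariants.
#'
#' @param config A [climate_config()].
#' @param seed Integer seed.
#' @return Named list with `winter` and `summer` `cm_raster` objects.
#' @export
simulate_climate_fields <- function(config = climate_config(), seed = NULL) {
  with_seed(seed, {
    out <- lapply(c(winter = "winter", summer = "summer"), function(season) {
      cf <- config[[season]]
      for (v in cf$vars) {
        if (v[2] < 0) stop("negative SD in climate config", call. = FALSE)
      }
      n <- cf$n_cells
      bbox <- c(cf$centre[1] - cf$half_extent_deg,
                cf$centre[2] - cf$half_extent_deg,
                cf$centre[1] + cf$half_extent_deg,
                cf$centre[2] + cf$half_extent_deg)
      cell <- 2 * cf$half_extent_deg / n
      tmin <- matrix(stats::rnorm(n * n, cf$vars$tmin[1], cf$vars$tmin[2]), n, n)
      tgap <- matrix(rtnorm0(n * n, cf$vars$tgap[1], cf$vars$tgap[2]), n, n)
      precip <- matrix(rtnorm0(n * n, cf$vars$precip[1], cf$vars$precip[2]), n, n)
      wind <- matrix(rtnorm0(n * n, cf$vars$wind[1], cf$vars$wind[2]), n, n)
      cm_raster(bbox, cell, tmin, tmin + tgap, precip, wind, season = season)
    })
    out
  })
}

#' Write a climate raster variable to delimited text
#'
#' One file per variable per season: a single JSON header line (prefixed
#' `#`) with the bounding box, cell size, season and variable name, followed
#' by the value matrix as tab-separated rows (south to north).
#'
#' @param raster A `cm_raster`.
#' @param var One of `"tmin"`, `"tmax"`, `"precip"`, `"wind"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_grid <- function(raster, var, path) {
  stopifnot(var %in% names(raster$vars))
  hdr <- jsonlite::toJSON(list(bbox = raster$bbox, cell_size = raster$cell_size,
                               season = raster$season, variable = var),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(raster$vars[[var]], con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a climate raster variable written by [write_raster_grid()]
#'
#' @param path Input path.
#' @return A list with `header` (parsed JSON) and `values` (matrix).
#' @export
read_raster_grid <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#")) stop("missing raster header", call. = FALSE)
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  values <- as.matrix(utils::read.table(text = lines[-1], sep = "\t"))
  dimnames(values) <- NULL
  list(header = header, values = values)
}
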