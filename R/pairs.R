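#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km (vectorised,
#' symmetric, zero only for identical points).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.195
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coord <- function(lat, lon) {
    bad <- (!is.na(lat) & (lat < -90 | lat > 90)) |
      (!is.na(lon) & (lon < -180 | lon > 180))
    if (any(bad)) {
      abort("coordinates out of range (lat in [-90,90], lon in [-180,180])",
            class = "melodiverge_input_error")
    }
  }
  check_coord(lat1, lon1); check_coord(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Build the within-song-group pair table
#'
#' One row per unordered pair of melodies sharing a song group: the
#' dependent variable `Y` (melodic distance `1 - PID/100`), and the pair
#' covariates `I` (different island, 0/1), `D` (great-circle distance in km
#' between recording sites), `T` (absolute difference in recording years),
#' `C` (different social context, 0/1) and `S` (different source, 0/1).
#' `I` and `D` are `NA` whenever either melody's recording site is unknown.
#'
#' @param corpus Corpus tibble.
#' @param dmat Optional precomputed distance matrix over (at least) the
#'   corpus song IDs; when `NULL`, supply `params` and within-group
#'   distances are computed directly.
#' @param params [alignment_params()], used when `dmat` is `NULL`.
#' @return A tibble with columns `song_i`, `song_j`, `group`, `Y`, `I`,
#'   `D`, `T`, `C`, `S`.
#' @export
build_pair_table <- function(corpus, dmat = NULL, params = NULL) {
  validate_corpus(corpus)
  if (is.null(dmat) && is.null(params)) {
    abort("supply either a distance matrix or alignment params",
          class = "melodiverge_input_error")
  }
  if (!is.null(dmat)) {
    missing_ids <- setdiff(corpus$song_id, rownames(dmat))
    if (length(missing_ids) > 0L) {
      abort(paste("melodies missing from the distance matrix:",
                  paste(missing_ids, collapse = ", ")),
            class = "melodiverge_input_error")
    }
  }
  pairs <- corpus |>
    dplyr::group_by(.data$group_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(pair = list(t(combn(.data$song_id, 2))), .groups = "drop") |>
    tidyr::unnest(cols = "pair")
  if (nrow(pairs) == 0L) {
    abort("no within-group pairs (all groups have < 2 melodies)",
          class = "melodiverge_input_error")
  }
  tab <- tibble::tibble(group = pairs$group_id,
                        song_i = pairs$pair[, 1], song_j = pairs$pair[, 2])
  m <- corpus[match(tab$song_i, corpus$song_id), ]
  p <- corpus[match(tab$song_j, corpus$song_id), ]
  if (!is.null(dmat)) {
    Y <- dmat[cbind(tab$song_i, tab$song_j)]
  } else {
    Y <- purrr::map2_dbl(m$sequence, p$sequence,
                         ~ melodic_distance(.x, .y, params))
  }
  site_known <- !is.na(m$site_lat) & !is.na(p$site_lat)
  D <- ifelse(site_known,
              haversine_km(m$site_lat, m$site_lon, p$site_lat, p$site_lon),
              NA_real_)
  tibble::tibble(
    song_i = tab$song_i, song_j = tab$song_j, group = tab$group,
    Y = Y,
    I = ifelse(site_known, as.numeric(m$island != p$island), NA_real_),
    D = D,
    T = abs(m$recording_year - p$recording_year),
    C = as.numeric(m$context != p$context),
    S = as.numeric(m$source != p$source)
  )
}

#' Z-score columns of a pair table
#'
#' Each listed column is centred and scaled by the mean and standard
#' deviation of its complete cases (binary indicators included, matching the
#' convention of standardising every variable; set `keep_binary = TRUE` to
#' leave 0/1 columns untouched for sensitivity analyses). The scaling
#' metadata is attached as attribute `"scaling"` so coefficients can be
#' back-transformed.
#'
#' @param table A data frame.
#' @param columns Character vector of numeric columns to standardize.
#' @param keep_binary Leave columns with values in \{0, 1\} unscaled.
#' @return `table` with the columns z-scored and a `"scaling"` attribute
#'   (tibble: column, mean, sd).
#' @export
standardize_columns <- function(table, columns, keep_binary = FALSE) {
  scaling <- purrr::map_dfr(columns, function(cn) {
    x <- table[[cn]]
    if (!is.numeric(x)) {
      abort(sprintf("column '%s' is not numeric", cn),
            class = "melodiverge_input_error")
    }
    if (keep_binary && all(x[!is.na(x)] %in% c(0, 1))) {
      return(tibble::tibble(column = cn, mean = 0, sd = 1))
    }
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("column '%s' has zero variance", cn),
            class = "melodiverge_input_error")
    }
    tibble::tibble(column = cn, mean = mu, sd = s)
  })
  for (k in seq_len(nrow(scaling))) {
    cn <- scaling$column[k]
    table[[cn]] <- (table[[cn]] - scaling$mean[k]) / scaling$sd[k]
  }
  attr(table, "scaling") <- scaling
  table
}
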