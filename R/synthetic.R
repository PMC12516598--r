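#' The four Koizumi five-tone scales
#'
#' Pitch-class content of the four basic scale types of traditional Japanese
#' song under the standard tetrachord formulation, together with the letters
#' they occupy after transposition to a C tonic. The minyo and miyako-bushi
#' scales use chromatic (lowercase) degrees, so their melodies differ from
#' ryukyu/ritsu melodies only by letter case at some positions when mode is
#' included.
#'
#' @return A tibble with columns `name`, `pitch_classes` (list of integer
#'   vectors, tonic 0 always included) and `letters` (list of 5 letters).
#' @export
koizumi_scales <- function() {
  pcs <- list(ryukyu = c(0L, 4L, 5L, 7L, 11L),
              ritsu = c(0L, 2L, 5L, 7L, 9L),
              minyo = c(0L, 3L, 5L, 7L, 10L),
              miyako_bushi = c(0L, 1L, 5L, 7L, 8L))
  tibble::tibble(
    name = names(pcs),
    pitch_classes = unname(pcs),
    letters = lapply(pcs, function(p) MELODY_ALPHABET[p + 1L])
  )
}

scale_letters <- function(scale) {
  sc <- koizumi_scales()
  i <- match(scale, sc$name)
  if (is.na(i)) {
    abort(paste("unknown scale:", scale), class = "melodiverge_input_error")
  }
  sc$letters[[i]]
}

#' Island centroid table for the simulated archipelago
#'
#' Seventeen islands across the four regions with approximate centroid
#' coordinates. These are fixture data for the synthetic-corpus generator
#' (plausible, not authoritative geography).
#'
#' @return A tibble with `island`, `region`, `lat`, `lon`.
#' @export
ryukyu_islands <- function() {
  tibble::tribble(
    ~island, ~region, ~lat, ~lon,
    "Amami Oshima", "Amami", 28.33, 129.43,
    "Kikai", "Amami", 28.32, 129.98,
    "Tokunoshima", "Amami", 27.82, 128.93,
    "Okinoerabu", "Amami", 27.37, 128.57,
    "Yoron", "Amami", 27.04, 128.42,
    "Okinawa Island", "Okinawa", 26.50, 127.97,
    "Kume", "Okinawa", 26.34, 126.77,
    "Iheya", "Okinawa", 27.04, 127.97,
    "Izena", "Okinawa", 26.93, 127.94,
    "Zamami", "Okinawa", 26.23, 127.30,
    "Miyako Island", "Miyako", 24.77, 125.30,
    "Irabu", "Miyako", 24.83, 125.18,
    "Tarama", "Miyako", 24.67, 124.70,
    "Ishigaki", "Yaeyama", 24.40, 124.18,
    "Iriomote", "Yaeyama", 24.33, 123.80,
    "Taketomi", "Yaeyama", 24.33, 124.08,
    "Hateruma", "Yaeyama", 24.06, 123.77
  )
}

#' Draw a random melody on a five-tone scale
#'
#' The first note is the tonic letter `"C"` by convention; the remaining
#' positions are uniform over the scale's five letters. Uses the current RNG
#' stream (seed upstream for reproducibility).
#'
#' @param scale Scale name, see [koizumi_scales()].
#' @param length Melody length, >= 1.
#' @return A coded sequence string.
#' @export
sample_scale_melody <- function(scale, length) {
  if (length < 1) {
    abort("length must be at least 1", class = "melodiverge_input_error")
  }
  letters5 <- scale_letters(scale)
  rest <- if (length > 1) sample(letters5, length - 1, replace = TRUE) else character(0)
  paste(c("C", rest), collapse = "")
}

#' Mutate a coded sequence along transmission edges
#'
#' Applies, for each of `n_edges` transmission steps, an independent
#' per-note Bernoulli substitution (replacement drawn uniformly from the
#' scale's other letters), per-note deletion, and per-note insertion (a
#' scale letter inserted after the note). Deletion is suppressed when the
#' sequence would become empty.
#'
#' @param seq Coded sequence string.
#' @param n_edges Number of transmission edges to apply.
#' @param mu_sub,mu_ins,mu_del Per-note, per-edge event rates.
#' @param scale Scale supplying replacement/insertion letters.
#' @return The mutated coded sequence.
#' @export
mutate_sequence <- function(seq, n_edges, mu_sub, mu_ins, mu_del, scale) {
  validate_coded_sequence(seq)
  if (any(c(mu_sub, mu_ins, mu_del) < 0)) {
    abort("mutation rates must be nonnegative", class = "melodiverge_input_error")
  }
  letters5 <- scale_letters(scale)
  x <- strsplit(seq, "")[[1]]
  for (e in seq_len(n_edges)) {
    L <- length(x)
    # substitutions: jump a uniform 1..4 steps around the scale, so the
    # replacement is uniform over the four letters other than the current one
    hit <- which(runif(L) < mu_sub)
    if (length(hit) > 0L) {
      cur <- match(x[hit], letters5)
      x[hit] <- letters5[1 + (cur - 1 + sample.int(4, length(hit), replace = TRUE)) %% 5]
    }
    # deletions (never empty the sequence)
    del <- runif(length(x)) < mu_del
    if (all(del)) del[sample(length(x), 1)] <- FALSE
    x <- x[!del]
    # insertions: after each surviving note
    ins <- runif(length(x)) < mu_ins
    if (any(ins)) {
      out <- vector("list", length(x))
      for (i in seq_along(x)) {
        out[[i]] <- if (ins[i]) c(x[i], sample(letters5, 1)) else x[i]
      }
      x <- unlist(out)
    }
  }
  paste(x, collapse = "")
}

#' Configuration for the synthetic-corpus generator
#'
#' Defaults encode the study conditions the generator emulates: 38 song
#' groups of at least three melodies each (sizes 3 + Poisson(0.9), matching
#' a 148-song corpus in expectation), ancestral melodies of 30-50 notes on
#' one of the four Koizumi scales, substitution rate 0.03 and indel rates
#' 0.01 per note per transmission edge (3 edges per lineage), island-crossing
#' multiplying a lineage's rates by 2 and a social-context change by 3, a
#' 60/40 SJF/field source mix with recording years 1964-1990 (SJF) and
#' 2015-2019 (field), and a small fraction of melodies with unknown
#' recording sites.
#'
#' @param n_groups Number of song groups.
#' @param group_size_lambda Group size is `3 + rpois(group_size_lambda)`.
#' @param length_range Ancestral melody length range (uniform integer).
#' @param scale_probs Named per-group scale probabilities.
#' @param mu_sub,mu_ins,mu_del Per-note per-edge mutation rates.
#' @param n_edges Transmission edges per descendant lineage.
#' @param m_island,m_context Rate multipliers (>= 1) for lineages that cross
#'   islands / change social context.
#' @param p_island_change,p_context_change Per-descendant probabilities of
#'   island / context change relative to the ancestor.
#' @param p_sjf Probability a melody comes from the published score source.
#' @param p_missing_site Probability a melody's recording site is unknown.
#' @param islands Island table, see [ryukyu_islands()].
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_groups = 38,
                              group_size_lambda = 0.9,
                              length_range = c(30L, 50L),
                              scale_probs = c(ryukyu = 0.4, ritsu = 0.3,
                                              minyo = 0.2, miyako_bushi = 0.1),
                              mu_sub = 0.03, mu_ins = 0.01, mu_del = 0.01,
                              n_edges = 3,
                              m_island = 2, m_context = 3,
                              p_island_change = 0.4, p_context_change = 0.3,
                              p_sjf = 0.6, p_missing_site = 0.03,
                              islands = ryukyu_islands(),
                              seed = 1L) {
  if (any(c(mu_sub, mu_ins, mu_del) < 0)) {
    abort("mutation rates must be nonnegative", class = "melodiverge_input_error")
  }
  if (m_island < 1 || m_context < 1) {
    abort("divergence multipliers must be >= 1", class = "melodiverge_input_error")
  }
  cfg <- list(n_groups = n_groups, group_size_lambda = group_size_lambda,
              length_range = length_range, scale_probs = scale_probs,
              mu_sub = mu_sub, mu_ins = mu_ins, mu_del = mu_del,
              n_edges = n_edges, m_island = m_island, m_context = m_context,
              p_island_change = p_island_change,
              p_context_change = p_context_change,
              p_sjf = p_sjf, p_missing_site = p_missing_site,
              islands = islands, seed = as.integer(seed))
  if (length(unique(cfg$islands$island)) < 2 &&
      (m_island > 1 || p_island_change > 0)) {
    warn("island effects requested but fewer than 2 islands configured",
         class = "melodiverge_config_warning")
  }
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic melodic corpus with ground truth
#'
#' For each song group an ancestral melody is drawn on one of the four
#' scales and descendants evolve along a star of transmission edges. A
#' descendant assigned to a different island than the ancestor has its
#' per-edge mutation rates multiplied by `m_island`; one with a changed
#' social context by `m_context`, so island crossing and context change
#' inflate divergence by construction. Coordinates come from the island
#' centroid table; recording years follow the source (published scores vs
#' field recordings). Fully seeded: identical config gives an identical
#' corpus.
#'
#' @param config A [simulation_config()].
#' @return A list with `corpus` (a corpus tibble as [read_corpus()] returns)
#'   and `truth` (per-group ancestors and scales, per-melody lineage flags
#'   and realized rate multipliers).
#' @export
generate_corpus <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  islands <- config$islands
  region_probs <- c(Amami = 0.3, Okinawa = 0.35, Miyako = 0.15, Yaeyama = 0.2)
  scales <- names(config$scale_probs)

  groups <- vector("list", config$n_groups)
  truth_groups <- vector("list", config$n_groups)
  for (g in seq_len(config$n_groups)) {
    gid <- sprintf("G%02d", g)
    size <- 3L + rpois(1, config$group_size_lambda)
    scale <- sample(scales, 1, prob = config$scale_probs)
    len <- sample(seq(config$length_range[1], config$length_range[2]), 1)
    ancestor <- sample_scale_melody(scale, len)
    region <- sample(names(region_probs), 1, prob = region_probs)
    region_islands <- islands$island[islands$region == region]
    anc_island <- sample(region_islands, 1)
    anc_context <- sample(CONTEXT_LEVELS, 1)

    recs <- vector("list", size)
    lineages <- vector("list", size)
    for (v in seq_len(size)) {
      crossed <- length(region_islands) > 1 &&
        runif(1) < config$p_island_change
      island <- if (crossed) {
        sample(setdiff(region_islands, anc_island), 1)
      } else anc_island
      changed <- runif(1) < config$p_context_change
      context <- if (changed) {
        sample(setdiff(CONTEXT_LEVELS, anc_context), 1)
      } else anc_context
      mult <- (if (crossed) config$m_island else 1) *
        (if (changed) config$m_context else 1)
      seqv <- mutate_sequence(ancestor, config$n_edges,
                              min(1, config$mu_sub * mult),
                              min(1, config$mu_ins * mult),
                              min(1, config$mu_del * mult), scale)
      source <- if (runif(1) < config$p_sjf) "SJF" else "field"
      year <- if (source == "SJF") sample(1964:1990, 1) else sample(2015:2019, 1)
      site_known <- runif(1) >= config$p_missing_site
      isl_row <- islands[islands$island == island, ]
      recs[[v]] <- tibble::tibble(
        song_id = sprintf("%s.%d", gid, v), group_id = gid,
        region = region, island = island,
        site_lat = if (site_known) isl_row$lat else NA_real_,
        site_lon = if (site_known) isl_row$lon else NA_real_,
        recording_year = as.integer(year), context = context,
        source = source, sequence = seqv)
      lineages[[v]] <- tibble::tibble(
        song_id = sprintf("%s.%d", gid, v), group_id = gid,
        island_crossed = crossed, context_changed = changed,
        rate_multiplier = mult, n_edges = config$n_edges)
    }
    groups[[g]] <- dplyr::bind_rows(recs)
    truth_groups[[g]] <- list(
      group_id = gid, scale = scale, ancestor = ancestor,
      ancestor_island = anc_island, ancestor_context = anc_context,
      lineages = dplyr::bind_rows(lineages))
  }
  corpus <- dplyr::bind_rows(groups)
  validate_corpus(corpus)
  truth <- list(
    groups = tibble::tibble(
      group_id = vapply(truth_groups, `[[`, character(1), "group_id"),
      scale = vapply(truth_groups, `[[`, character(1), "scale"),
      ancestor = vapply(truth_groups, `[[`, character(1), "ancestor"),
      ancestor_island = vapply(truth_groups, `[[`, character(1), "ancestor_island"),
      ancestor_context = vapply(truth_groups, `[[`, character(1), "ancestor_context")
    ),
    lineages = dplyr::bind_rows(lapply(truth_groups, `[[`, "lineages")),
    config = config
  )
  list(corpus = corpus, truth = truth)
}

#' Summary counts of a corpus metadata table
#'
#' Group, song and within-group pair counts for the full table and for the
#' published-score (SJF) subset: the song groups holding at least three SJF
#' melodies, the SJF melodies they hold, and the within-group pairs in which
#' both melodies are SJF.
#'
#' @param meta A data frame with at least `song_id`, `group_id`, `source`.
#' @return A one-row tibble of counts.
#' @export
corpus_counts <- function(meta) {
  sizes <- dplyr::count(meta, .data$group_id, name = "n")
  sjf <- meta |>
    dplyr::filter(.data$source == "SJF") |>
    dplyr::count(.data$group_id, name = "n_sjf")
  sjf_rich <- sjf |> dplyr::filter(.data$n_sjf >= 3)
  tibble::tibble(
    n_songs = nrow(meta),
    n_groups = nrow(sizes),
    n_pairs = sum(choose(sizes$n, 2)),
    n_sjf_songs = sum(meta$source == "SJF"),
    n_sjf_groups = nrow(sjf_rich),
    n_sjf_songs_in_sjf_groups = sum(sjf_rich$n_sjf),
    n_sjf_pairs = sum(choose(sjf$n_sjf, 2)),
    n_sjf_pairs_in_sjf_groups = sum(choose(sjf_rich$n_sjf, 2))
  )
}

#' Synthetic stand-in for the published song list
#'
#' A deterministic, clearly synthetic reconstruction of the corpus song
#' list: 148 songs in 38 song groups of at least three melodies (group
#' sizes 29x3, 2x4, 3x5, 1x6, 2x8, 1x16), 88 songs from the published score
#' collection (SJF) and 60 from field recordings, with exactly 13 groups
#' holding at least three SJF songs (44 SJF songs in those groups). Song
#' membership, regions, islands, contexts and years are synthetic fixture
#' assignments; only the count structure mirrors the real corpus summary.
#'
#' @return A tibble with `song_id`, `group_id`, `region`, `island`,
#'   `context`, `source`, `recording_year`.
#' @export
synthetic_song_table <- function() {
  # region prefix, group index within region, group size, SJF count
  spec <- tibble::tribble(
    ~prefix, ~region, ~size, ~sjf,
    # 12 Amami groups
    "A", "Amami", 16L, 4L,
    "A", "Amami", 5L, 4L,
    "A", "Amami", 3L, 3L,
    "A", "Amami", 3L, 3L,
    "A", "Amami", 3L, 2L,
    "A", "Amami", 3L, 2L,
    "A", "Amami", 3L, 2L,
    "A", "Amami", 3L, 2L,
    "A", "Amami", 3L, 1L,
    "A", "Amami", 3L, 1L,
    "A", "Amami", 3L, 2L,
    "A", "Amami", 3L, 2L,
    # 13 Okinawa groups
    "O", "Okinawa", 8L, 4L,
    "O", "Okinawa", 8L, 4L,
    "O", "Okinawa", 6L, 4L,
    "O", "Okinawa", 5L, 3L,
    "O", "Okinawa", 5L, 3L,
    "O", "Okinawa", 4L, 3L,
    "O", "Okinawa", 4L, 3L,
    "O", "Okinawa", 3L, 2L,
    "O", "Okinawa", 3L, 2L,
    "O", "Okinawa", 3L, 2L,
    "O", "Okinawa", 3L, 2L,
    "O", "Okinawa", 3L, 2L,
    "O", "Okinawa", 3L, 2L,
    # 6 Miyako groups
    "M", "Miyako", 3L, 2L,
    "M", "Miyako", 3L, 2L,
    "M", "Miyako", 3L, 2L,
    "M", "Miyako", 3L, 2L,
    "M", "Miyako", 3L, 1L,
    "M", "Miyako", 3L, 1L,
    # 7 Yaeyama groups
    "Y", "Yaeyama", 3L, 3L,
    "Y", "Yaeyama", 3L, 3L,
    "Y", "Yaeyama", 3L, 2L,
    "Y", "Yaeyama", 3L, 2L,
    "Y", "Yaeyama", 3L, 2L,
    "Y", "Yaeyama", 3L, 2L,
    "Y", "Yaeyama", 3L, 0L
  )
  spec <- spec |>
    dplyr::group_by(.data$prefix) |>
    dplyr::mutate(gnum = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(group_id = paste0(.data$prefix, .data$gnum))
  islands <- ryukyu_islands()
  rows <- purrr::pmap_dfr(spec, function(prefix, region, size, sjf, gnum, group_id) {
    region_islands <- islands$island[islands$region == region]
    tibble::tibble(
      song_id = sprintf("%s.%d", group_id, seq_len(size)),
      group_id = group_id,
      region = region,
      island = region_islands[1 + (seq_len(size) - 1) %% length(region_islands)],
      context = CONTEXT_LEVELS[1 + (gnum + seq_len(size)) %% 4],
      source = c(rep("SJF", sjf), rep("field", size - sjf)),
      recording_year = ifelse(seq_len(size) <= sjf,
                              1964L + ((gnum * 7L + seq_len(size)) %% 27L),
                              2015L + (seq_len(size) %% 5L))
    )
  })
  rows
}
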