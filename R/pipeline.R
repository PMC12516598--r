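#' Run configuration for the full analysis pipeline
#'
#' A run either reads a corpus (`sequence_path` + `metadata_path`) or
#' simulates one (`simulate = TRUE` with a [simulation_config()]). Every
#' artifact is produced once per alignment parameter set;
#' `parameter_set = "both"` (the default) writes each with `_set1` / `_set2`
#' suffixes.
#'
#' @param sequence_path,metadata_path Corpus input paths (ignored when
#'   simulating).
#' @param simulate Generate the corpus with [generate_corpus()].
#' @param sim_config [simulation_config()] used when simulating; its seed is
#'   overridden by the stage seed derived from `seed`.
#' @param parameter_set 1, 2 or `"both"`.
#' @param region Optional region filter applied before analysis.
#' @param sjf_only Restrict to published-score (SJF) melodies before the
#'   pair table and models.
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed; per-stage seeds are derived from it by hashing the
#'   stage name, so stages are individually reproducible.
#' @param alpha_random,alpha_fixed Elimination thresholds.
#' @param standardize Fit the selection on z-scored variables (a raw-scale
#'   fit of the selected model is always reported too).
#' @param restrict_ID Restrict selection to at most one of `I` and `D`.
#' @param n_power_sim Simulations for the post-hoc power analysis of the
#'   full model (0 skips it).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sequence_path = NULL, metadata_path = NULL,
                       simulate = is.null(sequence_path),
                       sim_config = simulation_config(),
                       parameter_set = "both", region = NULL,
                       sjf_only = FALSE, out_dir = tempfile("melodiverge_run_"),
                       seed = 1L, alpha_random = 0.1, alpha_fixed = 0.05,
                       standardize = TRUE, restrict_ID = FALSE,
                       n_power_sim = 0L) {
  if (!as.character(parameter_set) %in% c("1", "2", "both")) {
    abort("parameter_set must be 1, 2 or 'both'",
          class = "melodiverge_input_error")
  }
  structure(list(sequence_path = sequence_path, metadata_path = metadata_path,
                 simulate = simulate, sim_config = sim_config,
                 parameter_set = as.character(parameter_set), region = region,
                 sjf_only = sjf_only, out_dir = out_dir, seed = as.integer(seed),
                 alpha_random = alpha_random, alpha_fixed = alpha_fixed,
                 standardize = standardize, restrict_ID = restrict_ID,
                 n_power_sim = as.integer(n_power_sim)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; a `sim_config` mapping is
#' passed on to [simulation_config()].
#'
#' @param path YAML file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim_config)) {
    y$sim_config <- do.call(simulation_config, y$sim_config)
  }
  do.call(run_config, y)
}

# deterministic per-stage seed below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100000L) * 17989L + h %% 17989L
}

#' Run the full melodic-diversification analysis
#'
#' Orchestrates, per alignment parameter set: the distance matrix (CSV +
#' NEXUS), same/different-group PID summary with the Brunner-Munzel test,
#' the delta score, the Neighbor-Net split network (NEXUS + CSV), the
#' within-group pair table, the full linear mixed model and backward
#' elimination (with trace), and an optional post-hoc power analysis for the
#' full model. A `manifest.json` records the configuration, seed, package
#' version and counts. Any stage failure aborts with the stage name;
#' artifacts already written are preserved.
#'
#' @param config A [run_config()].
#' @return A result bundle: list with `corpus`, `counts`, `manifest`, and a
#'   per-parameter-set list of results (`distances`, `pid_summary`, `bm`,
#'   `delta`, `splits`, `pairs`, `full_fit`, `elimination`, `power`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "melodiverge_pipeline_error")
    })
  }

  corpus <- stage("input", {
    if (config$simulate) {
      sc <- config$sim_config
      sc$seed <- stage_seed(config$seed, "simulate")
      gen <- generate_corpus(sc)
      write_corpus(gen$corpus,
                   file.path(config$out_dir, "corpus.fasta"),
                   file.path(config$out_dir, "corpus_metadata.csv"))
      jsonlite::write_json(
        list(groups = gen$truth$groups, lineages = gen$truth$lineages),
        file.path(config$out_dir, "ground_truth.json"),
        dataframe = "columns", digits = NA)
      gen$corpus
    } else {
      read_corpus(config$sequence_path, config$metadata_path)
    }
  })
  if (!is.null(config$region)) {
    corpus <- dplyr::filter(corpus, .data$region %in% config$region)
  }
  if (config$sjf_only) {
    corpus <- dplyr::filter(corpus, .data$source == "SJF")
    corpus <- dplyr::group_by(corpus, .data$group_id) |>
      dplyr::filter(dplyr::n() >= 3) |>
      dplyr::ungroup()
  }
  if (nrow(corpus) < 4L) {
    abort("fewer than 4 melodies after filtering",
          class = "melodiverge_input_error")
  }
  counts <- corpus_counts(corpus)

  sets <- switch(config$parameter_set, "1" = 1, "2" = 2, "both" = c(1, 2))
  results <- list()
  for (set in sets) {
    suffix <- sprintf("_set%d", set)
    params <- alignment_preset(set)
    out <- function(name) file.path(config$out_dir, paste0(name, suffix))

    D <- stage("distances", {
      D <- distance_matrix(corpus, params)
      write_distance_csv(D, paste0(out("distances"), ".csv"))
      write_distance_nexus(D, paste0(out("distances"), ".nex"))
      D
    })
    pidsum <- stage("group-stats", {
      s <- pid_group_summary(corpus, params)
      readr::write_csv(s, paste0(out("pid_summary"), ".csv"))
      s
    })
    bm <- stage("group-stats", {
      pairs <- pid_pairs(corpus, params)
      set.seed(stage_seed(config$seed, paste0("bm", set)))
      bm <- brunner_munzel(pairs$pid[!pairs$same_group],
                           pairs$pid[pairs$same_group])
      readr::write_csv(tidy(bm), paste0(out("bm_test"), ".csv"))
      bm
    })
    delta <- stage("delta", {
      d <- delta_score(D)
      writeLines(format(d$overall_delta, digits = 10),
                 paste0(out("delta"), ".txt"))
      d
    })
    splits <- stage("network", {
      ss <- neighbor_net(D)
      write_splits_nexus(ss, D, paste0(out("splits"), ".nex"))
      readr::write_csv(tidy(ss), paste0(out("splits"), ".csv"))
      ss
    })
    pair_tab <- stage("pairs", {
      pt <- build_pair_table(corpus, dmat = D)
      readr::write_csv(pt, paste0(out("pair_table"), ".csv"), na = "")
      pt
    })
    fits <- stage("lmm", {
      tab <- pair_tab
      # covariates that are constant after filtering (e.g. the source
      # indicator in an SJF-only run) carry no information and are dropped
      terms <- c("I", "D", "T", "C", "S")
      usable <- terms[vapply(terms, function(cn) {
        x <- tab[[cn]][!is.na(tab[[cn]])]
        length(unique(x)) > 1
      }, logical(1))]
      if (config$standardize) {
        tab <- standardize_columns(tab, c("Y", usable))
      }
      full <- fit_lmm(tab, fixed_terms = usable)
      readr::write_csv(tidy(full), paste0(out("full_model"), ".csv"))
      elim <- backward_eliminate(tab, fixed_terms = usable,
                                 alpha_random = config$alpha_random,
                                 alpha_fixed = config$alpha_fixed,
                                 restrict_ID = config$restrict_ID)
      sel <- if (config$restrict_ID) elim[["I"]] else elim
      readr::write_csv(tidy(sel), paste0(out("elimination_trace"), ".csv"))
      readr::write_csv(tidy(sel$fit), paste0(out("selected_model"), ".csv"))
      # raw-scale fit of the selected terms for interpretable coefficients
      raw_sel <- fit_lmm(pair_tab, sel$fit$fixed_terms,
                         random_intercept = sel$random_kept)
      readr::write_csv(tidy(raw_sel), paste0(out("selected_model_raw"), ".csv"))
      list(full = full, elimination = elim, selected_raw = raw_sel)
    })
    pw <- NULL
    if (config$n_power_sim > 0) {
      pw <- stage("power", {
        p <- power_simulation(fits$full, "C", n_sim = config$n_power_sim,
                              seed = stage_seed(config$seed, paste0("power", set)))
        readr::write_csv(tidy(p), paste0(out("power"), ".csv"))
        p
      })
    }
    results[[paste0("set", set)]] <- list(
      distances = D, pid_summary = pidsum, bm = bm, delta = delta,
      splits = splits, pairs = pair_tab, full_fit = fits$full,
      elimination = fits$elimination, selected_raw = fits$selected_raw,
      power = pw)
  }

  manifest <- list(
    package = "melodiverge",
    version = as.character(utils::packageVersion("melodiverge")),
    seed = config$seed,
    parameter_set = config$parameter_set,
    region = config$region, sjf_only = config$sjf_only,
    standardize = config$standardize, restrict_ID = config$restrict_ID,
    counts = as.list(counts)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(corpus = corpus, counts = counts, manifest = manifest,
                 results = results, out_dir = config$out_dir))
}
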