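#' Affine-gap alignment parameters
#'
#' Scoring is match +1, mismatch -1, and a maximal gap run of length k costs
#' `gop + gep * k` (the opening penalty is charged once per run, the
#' extension penalty once per gap symbol). Terminal gaps are penalised (true
#' global alignment). `mode = "ignore"` recodes lowercase (chromatic) letters
#' to uppercase before scoring, so modal variants of a degree count as
#' matches; `mode = "include"` compares letters case-sensitively.
#'
#' Two presets are in common use for tune-family work:
#' set 1 (GOP 12, GEP 6, ignoring mode) is gap-averse and suits separating
#' tune families; set 2 (GOP 0.8, GEP 0.2, including mode) is gap-friendly
#' and suits comparisons within a family.
#'
#' @param gop Gap opening penalty, >= 0.
#' @param gep Gap extension penalty (per gap symbol), >= 0.
#' @param mode `"include"` or `"ignore"`.
#' @return An object of class `"alignment_params"`.
#' @examples
#' alignment_params(12, 6, "ignore")
#' alignment_preset(2)
#' @export
alignment_params <- function(gop, gep, mode = c("include", "ignore")) {
  mode <- match.arg(mode)
  if (!is.numeric(gop) || !is.numeric(gep) || gop < 0 || gep < 0) {
    abort("gap penalties must be nonnegative numbers",
          class = "melodiverge_parameter_error")
  }
  structure(list(gop = gop, gep = gep, mode = mode),
            class = "alignment_params")
}

#' @rdname alignment_params
#' @param set Preset number, 1 or 2.
#' @export
alignment_preset <- function(set = 1) {
  if (identical(as.numeric(set), 1)) {
    alignment_params(12, 6, "ignore")
  } else if (identical(as.numeric(set), 2)) {
    alignment_params(0.8, 0.2, "include")
  } else {
    abort("preset must be 1 or 2", class = "melodiverge_parameter_error")
  }
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf("Alignment parameters: GOP = %g, GEP = %g, %s mode\n",
              x$gop, x$gep,
              if (x$mode == "ignore") "ignoring" else "including"))
  invisible(x)
}

#' Globally align two coded melodies
#'
#' Optimal global alignment under the affine gap model of
#' [alignment_params()], computed by three-state dynamic programming.
#' Ties among co-optimal alignments are broken deterministically: diagonal
#' moves are preferred, then gaps in the shorter input, then gaps in the
#' longer.
#'
#' @param s1,s2 Coded sequences (single strings over the melody alphabet).
#' @param params An [alignment_params()] object.
#' @return An object of class `"melody_alignment"`: list with `aligned1`,
#'   `aligned2` (equal-length gapped strings), `score`, `id_count` (number of
#'   identical aligned columns), `L1`, `L2` (pre-alignment lengths) and
#'   `params`.
#' @examples
#' align_pair("CE", "CDE", alignment_preset(2))
#' @export
align_pair <- function(s1, s2, params) {
  stopifnot(inherits(params, "alignment_params"))
  validate_coded_sequence(c(s1, s2))
  L1 <- nchar(s1); L2 <- nchar(s2)
  if (params$mode == "ignore") {
    s1 <- recode_ignore_mode(s1)
    s2 <- recode_ignore_mode(s2)
  }
  res <- gotoh_align_cpp(s1, s2, params$gop, params$gep, TRUE)
  structure(list(aligned1 = res$aligned1, aligned2 = res$aligned2,
                 score = res$score, id_count = res$id_count,
                 L1 = L1, L2 = L2, params = params),
            class = "melody_alignment")
}

#' @export
print.melody_alignment <- function(x, ...) {
  cat(x$aligned1, "\n", x$aligned2, "\n", sep = "")
  cat(sprintf("score %g, %d identical of L1 = %d, L2 = %d (PID %.2f)\n",
              x$score, x$id_count, x$L1, x$L2, percent_identity(x)))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' PID = 100 * 2 * ID / (L1 + L2): the number of identical aligned notes
#' normalised by the mean of the two pre-alignment sequence lengths, so it is
#' symmetric in the two sequences and lies in \[0, 100\].
#'
#' @param res A `"melody_alignment"` or the integer identity count.
#' @param L1,L2 Pre-alignment sequence lengths (taken from `res` when it is
#'   an alignment object).
#' @return PID as a number in \[0, 100\].
#' @examples
#' percent_identity(2, 2, 3)  # 80
#' @export
percent_identity <- function(res, L1 = NULL, L2 = NULL) {
  if (inherits(res, "melody_alignment")) {
    id <- res$id_count
    L1 <- L1 %||% res$L1
    L2 <- L2 %||% res$L2
  } else {
    id <- res
  }
  if (is.null(L1) || is.null(L2) || L1 <= 0 || L2 <= 0) {
    abort("L1 and L2 must be positive pre-alignment lengths",
          class = "melodiverge_input_error")
  }
  if (id > min(L1, L2)) {
    abort("id_count cannot exceed the shorter sequence length",
          class = "melodiverge_input_error")
  }
  100 * 2 * id / (L1 + L2)
}

#' Melodic distance between two coded sequences
#'
#' `1 - PID/100` under the given alignment parameters; 0 for identical
#' sequences, at most 1, and symmetric.
#'
#' @inheritParams align_pair
#' @return A number in \[0, 1\].
#' @export
melodic_distance <- function(s1, s2, params) {
  res <- align_pair(s1, s2, params)
  1 - percent_identity(res) / 100
}

#' Pairwise melodic distance matrix for a corpus
#'
#' @param corpus Corpus tibble (needs `song_id` and `sequence` columns), or a
#'   named character vector of coded sequences.
#' @param params An [alignment_params()] object.
#' @return A symmetric matrix of `1 - PID/100` values with song IDs as
#'   dimnames.
#' @export
distance_matrix <- function(corpus, params) {
  stopifnot(inherits(params, "alignment_params"))
  if (is.data.frame(corpus)) {
    seqs <- setNames(corpus$sequence, corpus$song_id)
  } else {
    seqs <- corpus
  }
  if (length(seqs) < 2L) {
    abort("need at least 2 melodies", class = "melodiverge_input_error")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("melodies must carry unique labels", class = "melodiverge_input_error")
  }
  validate_coded_sequence(seqs, ids = names(seqs))
  L <- nchar(seqs)
  aligned <- if (params$mode == "ignore") recode_ignore_mode(seqs) else seqs
  id <- gotoh_id_matrix_cpp(unname(aligned), params$gop, params$gep)
  pid <- 200 * id / outer(L, L, `+`)
  D <- 1 - pid / 100
  diag(D) <- 0
  dimnames(D) <- list(names(seqs), names(seqs))
  D
}

#' Export a distance matrix
#'
#' `write_distance_csv()` writes a square CSV with a leading label column;
#' `write_distance_nexus()` writes a SplitsTree4-readable NEXUS file with
#' TAXA and DISTANCES blocks (`triangle=both`, diagonal included).
#'
#' @param D Labelled symmetric distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(D, path) {
  df <- tibble::as_tibble(D, rownames = "song_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
write_distance_nexus <- function(D, path) {
  labs <- nexus_quote(rownames(D))
  lines <- c(
    "#NEXUS", "",
    "BEGIN Taxa;",
    sprintf("DIMENSIONS ntax=%d;", nrow(D)),
    "TAXLABELS",
    sprintf("[%d] %s", seq_len(nrow(D)), labs),
    ";",
    "END; [Taxa]", "",
    "BEGIN Distances;",
    sprintf("DIMENSIONS ntax=%d;", nrow(D)),
    "FORMAT labels=left diagonal triangle=both;",
    "MATRIX",
    vapply(seq_len(nrow(D)), function(i) {
      paste(labs[i], paste(format(D[i, ], digits = 10, trim = TRUE),
                           collapse = " "))
    }, character(1)),
    ";",
    "END; [Distances]"
  )
  writeLines(lines, path)
  invisible(path)
}

nexus_quote <- function(x) {
  needs <- grepl("[[:space:]']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}
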