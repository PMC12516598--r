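#' The 12-letter pitch-class alphabet
#'
#' Melodies are coded over the 12 pitch classes after transposition to a C
#' tonic. The seven diatonic classes get uppercase letters and the five
#' chromatic classes get lowercase letters, so that letter case carries the
#' "mode" of a note (e.g. a minor versus a major third above the tonic).
#' Recoding lowercase to uppercase ("ignoring mode") merges each chromatic
#' class with its diatonic neighbour for alignment purposes.
#'
#' @return A character vector of length 12: the letter for pitch classes
#'   0 through 11 (0 = C).
#' @examples
#' pitch_letters()
#' @export
pitch_letters <- function() {
  c("C", "d", "D", "e", "E", "F", "g", "G", "a", "A", "b", "B")
}

MELODY_ALPHABET <- c("C", "d", "D", "e", "E", "F", "g", "G", "a", "A", "b", "B")
UPPER_LETTERS <- c("C", "D", "E", "F", "G", "A", "B")

# natural-letter pitch classes for note-name parsing
NOTE_PC <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

parse_pitch_class <- function(notes) {
  if (is.numeric(notes)) {
    if (any(notes != as.integer(notes)) || any(notes < 0) || any(notes > 11)) {
      bad <- notes[notes != as.integer(notes) | notes < 0 | notes > 11][1]
      abort(sprintf("unparseable note token: %s (integers must be pitch classes 0-11)", bad),
            class = "melodiverge_input_error")
    }
    return(as.integer(notes))
  }
  m <- regmatches(notes, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)?$", notes))
  pc <- vapply(seq_along(notes), function(i) {
    g <- m[[i]]
    if (length(g) == 0L) {
      abort(sprintf("unparseable note token: '%s'", notes[i]),
            class = "melodiverge_input_error")
    }
    base <- NOTE_PC[[toupper(g[2])]]
    shift <- switch(g[3], "#" = 1L, "b" = -1L, 0L)
    (base + shift) %% 12L
  }, integer(1))
  pc
}

#' Encode a melody as a pitch-class letter sequence
#'
#' Notes are reduced to pitch classes (durations and octaves are ignored),
#' transposed so that the tonic becomes C (pitch class 0), and mapped to the
#' 12-letter alphabet of [pitch_letters()]. Repeated and responsorial
#' passages are assumed to have been removed by the caller.
#'
#' @param notes Ordered notes: either scientific pitch notation (letter,
#'   optional `#`/`b`, optional octave integer, e.g. `"Eb4"`) or bare pitch
#'   class integers 0-11.
#' @param tonic Tonic pitch class, 0-11, or a note name.
#' @return A single string over the 12-letter alphabet, one character per note.
#' @examples
#' encode_melody(c("C4", "E4", "G4"), tonic = 0)
#' encode_melody(c("A4", "B4", "A4", "D5"), tonic = 9)
#' @export
encode_melody <- function(notes, tonic = 0) {
  if (length(notes) == 0L) {
    abort("note list is empty", class = "melodiverge_input_error")
  }
  tonic_pc <- parse_pitch_class(tonic)
  if (length(tonic_pc) != 1L) {
    abort("tonic must be a single pitch class", class = "melodiverge_input_error")
  }
  pc <- (parse_pitch_class(notes) - tonic_pc) %% 12L
  paste(MELODY_ALPHABET[pc + 1L], collapse = "")
}

#' Recode a sequence ignoring mode
#'
#' Replaces every lowercase (chromatic) letter by its uppercase neighbour
#' (d->D, e->E, g->G, a->A, b->B), so that alignment no longer distinguishes
#' e.g. minor from major thirds. Idempotent; length preserving.
#'
#' @param seq Coded sequence(s) as character vector.
#' @return Character vector of the same length with only uppercase letters.
#' @examples
#' recode_ignore_mode("CeFGb")
#' @export
recode_ignore_mode <- function(seq) {
  validate_coded_sequence(seq)
  chartr("degab", "DEGAB", seq)
}

validate_coded_sequence <- function(seq, ids = NULL) {
  if (length(seq) == 0L || any(is.na(seq)) || any(nchar(seq) == 0L)) {
    abort("coded sequences must be nonempty", class = "melodiverge_input_error")
  }
  ok <- !grepl(sprintf("[^%s]", paste(MELODY_ALPHABET, collapse = "")), seq)
  if (!all(ok)) {
    i <- which(!ok)[1]
    chars <- strsplit(seq[i], "")[[1]]
    pos <- which(!chars %in% MELODY_ALPHABET)[1]
    who <- if (!is.null(ids)) ids[i] else sprintf("sequence %d", i)
    abort(sprintf("invalid character '%s' at position %d in %s",
                  chars[pos], pos, who),
          class = "melodiverge_input_error")
  }
  invisible(seq)
}

CONTEXT_LEVELS <- c("child", "ritual", "work", "amusement")
SOURCE_LEVELS <- c("SJF", "field")
REGION_LEVELS <- c("Amami", "Okinawa", "Miyako", "Yaeyama")

CORPUS_COLUMNS <- c("song_id", "group_id", "region", "island", "site_lat",
                    "site_lon", "recording_year", "context", "source",
                    "sequence")

validate_corpus <- function(corpus) {
  missing_cols <- setdiff(CORPUS_COLUMNS, names(corpus))
  if (length(missing_cols) > 0L) {
    abort(paste("corpus is missing columns:", paste(missing_cols, collapse = ", ")),
          class = "melodiverge_input_error")
  }
  if (anyDuplicated(corpus$song_id)) {
    dup <- unique(corpus$song_id[duplicated(corpus$song_id)])
    abort(paste("duplicate song_id:", paste(dup, collapse = ", ")),
          class = "melodiverge_input_error")
  }
  validate_coded_sequence(corpus$sequence, ids = corpus$song_id)
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad) > 0L) {
      abort(sprintf("unknown %s token(s): %s", what, paste(bad, collapse = ", ")),
            class = "melodiverge_input_error")
    }
  }
  check_levels(corpus$context, CONTEXT_LEVELS, "context")
  check_levels(corpus$source, SOURCE_LEVELS, "source")
  check_levels(corpus$region, REGION_LEVELS, "region")
  half <- xor(is.na(corpus$site_lat), is.na(corpus$site_lon))
  if (any(half)) {
    abort(paste("site_lat/site_lon must be both present or both missing for:",
                paste(corpus$song_id[half], collapse = ", ")),
          class = "melodiverge_input_error")
  }
  invisible(corpus)
}

#' Read a melody corpus from FASTA + metadata CSV
#'
#' Sequences are read from a FASTA file whose headers are song IDs; metadata
#' is read from a CSV with one row per song ID and columns `song_id`,
#' `group_id`, `region`, `island`, `site_lat`, `site_lon`, `recording_year`,
#' `context`, `source` (empty latitude/longitude fields encode unknown
#' recording sites). Entries present in only one of the two files are an
#' error naming the offending IDs.
#'
#' @param sequence_path Path to the FASTA file.
#' @param metadata_path Path to the metadata CSV.
#' @return A tibble with one row per melody (columns above plus `sequence`).
#' @export
read_corpus <- function(sequence_path, metadata_path) {
  fa <- seqinr::read.fasta(sequence_path, as.string = TRUE,
                           forceDNAtolower = FALSE, seqonly = FALSE)
  seqs <- tibble::tibble(
    song_id = vapply(fa, function(s) attr(s, "name"), character(1)),
    sequence = vapply(fa, function(s) as.character(s)[1], character(1))
  )
  if (anyDuplicated(seqs$song_id)) {
    dup <- unique(seqs$song_id[duplicated(seqs$song_id)])
    abort(paste("duplicate song_id in FASTA:", paste(dup, collapse = ", ")),
          class = "melodiverge_input_error")
  }
  meta <- readr::read_csv(
    metadata_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      song_id = readr::col_character(),
      group_id = readr::col_character(),
      region = readr::col_character(),
      island = readr::col_character(),
      site_lat = readr::col_double(),
      site_lon = readr::col_double(),
      recording_year = readr::col_integer(),
      context = readr::col_character(),
      source = readr::col_character()
    )
  )
  if (anyDuplicated(meta$song_id)) {
    dup <- unique(meta$song_id[duplicated(meta$song_id)])
    abort(paste("duplicate song_id in metadata:", paste(dup, collapse = ", ")),
          class = "melodiverge_input_error")
  }
  only_fa <- setdiff(seqs$song_id, meta$song_id)
  only_meta <- setdiff(meta$song_id, seqs$song_id)
  if (length(only_fa) || length(only_meta)) {
    abort(paste0(
      "sequence/metadata mismatch.",
      if (length(only_fa)) paste0(" No metadata for: ", paste(only_fa, collapse = ", "), ".") else "",
      if (length(only_meta)) paste0(" No sequence for: ", paste(only_meta, collapse = ", "), ".") else ""
    ), class = "melodiverge_input_error")
  }
  corpus <- dplyr::left_join(meta, seqs, by = "song_id")
  corpus <- dplyr::select(corpus, dplyr::all_of(CORPUS_COLUMNS))
  validate_corpus(corpus)
  corpus
}

#' Write a melody corpus to FASTA + metadata CSV
#'
#' Inverse of [read_corpus()]: `write_corpus()` followed by [read_corpus()]
#' reproduces the corpus exactly.
#'
#' @param corpus Corpus tibble as returned by [read_corpus()] or
#'   [generate_corpus()].
#' @param sequence_path,metadata_path Output paths.
#' @return The input corpus, invisibly.
#' @export
write_corpus <- function(corpus, sequence_path, metadata_path) {
  if (nrow(corpus) == 0L) {
    abort("corpus is empty", class = "melodiverge_input_error")
  }
  validate_corpus(corpus)
  seqinr::write.fasta(as.list(corpus$sequence), names = corpus$song_id,
                      file.out = sequence_path, nbchar = 10000)
  meta <- dplyr::select(corpus, dplyr::all_of(setdiff(CORPUS_COLUMNS, "sequence")))
  readr::write_csv(meta, metadata_path, na = "")
  invisible(corpus)
}
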