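#' Delta score: quartet-based treelikeness of a distance matrix
#'
#' For each quartet of taxa the three pairwise-sum quantities are ordered
#' m1 <= m2 <= m3 and the quartet's delta is (m3 - m2) / (m3 - m1) (taken as
#' 0 when m3 = m1, e.g. for equidistant taxa). The overall delta score is the
#' mean over all `choose(n, 4)` quartets: 0 when the matrix is an additive
#' tree metric, approaching 1 as the signal becomes maximally conflicting.
#'
#' @param D Symmetric, nonnegative distance matrix with >= 4 labelled taxa.
#' @param per_taxon Also compute each taxon's mean delta over the quartets
#'   containing it.
#' @return An object of class `"delta_score"`: `overall_delta`,
#'   `n_quartets`, and optionally `per_taxon` (a tibble).
#' @examples
#' D <- matrix(c(0, 2, 3, 4, 2, 0, 4, 3, 3, 4, 0, 2, 4, 3, 2, 0), 4, 4)
#' dimnames(D) <- list(letters[1:4], letters[1:4])
#' delta_score(D)$overall_delta
#' @export
delta_score <- function(D, per_taxon = FALSE) {
  D <- validate_distance(D, min_n = 4)
  res <- delta_score_cpp(D, per_taxon)
  out <- list(overall_delta = res$overall_delta,
              n_quartets = res$n_quartets)
  if (per_taxon) {
    out$per_taxon <- tibble::tibble(taxon = rownames(D),
                                    delta = as.numeric(res$per_taxon))
  }
  structure(out, class = "delta_score")
}

validate_distance <- function(D, min_n = 3) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < min_n) {
    abort(sprintf("need at least %d taxa", min_n),
          class = "melodiverge_input_error")
  }
  if (ncol(D) != n || !isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    abort("distance matrix must be square and symmetric",
          class = "melodiverge_input_error")
  }
  if (any(D < 0)) {
    abort("distances must be nonnegative", class = "melodiverge_input_error")
  }
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  }
  D
}

#' @export
print.delta_score <- function(x, ...) {
  cat(sprintf("delta score = %.4f over %s quartets\n",
              x$overall_delta, format(x$n_quartets, big.mark = ",")))
  invisible(x)
}

#' @export
tidy.delta_score <- function(x, ...) {
  if (!is.null(x$per_taxon)) return(x$per_taxon)
  tibble::tibble(overall_delta = x$overall_delta, n_quartets = x$n_quartets)
}

#' @export
glance.delta_score <- function(x, ...) {
  tibble::tibble(overall_delta = x$overall_delta, n_quartets = x$n_quartets)
}

#' Neighbor-Net split network from a distance matrix
#'
#' Runs the Neighbor-Net agglomeration (neighbour-joining generalised to
#' clusters with 3-node path reduction) to obtain a circular ordering of the
#' taxa, then estimates nonnegative weights for the circular splits by
#' constrained least squares against the distances. Splits with estimated
#' weight at or below `weight_threshold` are dropped. For exactly 3 taxa the
#' closed-form decomposition is used: the three trivial splits with weights
#' `(d_ab + d_ac - d_bc)/2` and rotations.
#'
#' @param D Symmetric labelled distance matrix, >= 3 taxa.
#' @param weight_threshold Drop splits with weight <= this (default 0, i.e.
#'   keep every positively weighted split).
#' @return An object of class `"split_system"`: `labels` (taxa, input
#'   order), `circular_order` (labels permuted to the Neighbor-Net cycle),
#'   `splits` (list of integer vectors indexing `labels`; each split is
#'   stored as the side not containing the first label) and `weights`.
#' @export
neighbor_net <- function(D, weight_threshold = 0) {
  D <- validate_distance(D, min_n = 3)
  labels <- rownames(D)
  n <- nrow(D)
  if (n == 3L) {
    w <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
           (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
           (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    ss <- new_split_system(labels, labels,
                           splits = list(1L, 2L, 3L), weights = w)
    return(filter_splits(ss, weight_threshold))
  }
  nn <- phangorn::neighborNet(stats::as.dist(D))
  spl <- nn$splits
  spl_labels <- attr(spl, "labels")
  cycle <- attr(spl, "cycle")
  weights <- attr(spl, "weights")
  # map phangorn's label indexing back onto the input label order
  remap <- match(spl_labels, labels)
  splits <- lapply(spl, function(s) sort(remap[s]))
  ss <- new_split_system(labels, spl_labels[cycle], splits, weights)
  filter_splits(ss, weight_threshold)
}

new_split_system <- function(labels, circular_order, splits, weights) {
  n <- length(labels)
  splits <- lapply(splits, function(s) {
    s <- sort(as.integer(s))
    if (1L %in% s) s <- sort(setdiff(seq_len(n), s))  # canonical side
    s
  })
  keep <- lengths(splits) > 0L & lengths(splits) < n
  ss <- structure(list(labels = labels, circular_order = circular_order,
                       splits = splits[keep], weights = as.numeric(weights)[keep]),
                  class = "split_system")
  validate_split_system(ss)
  ss
}

validate_split_system <- function(ss) {
  pos <- match(ss$labels, ss$circular_order)
  if (anyNA(pos) || length(ss$circular_order) != length(ss$labels)) {
    abort("circular order must be a permutation of the labels",
          class = "melodiverge_input_error")
  }
  if (length(ss$splits) != length(ss$weights)) {
    abort("splits and weights differ in length", class = "melodiverge_input_error")
  }
  n <- length(ss$labels)
  ok <- vapply(ss$splits, function(s) {
    p <- sort(pos[s])
    # contiguous on the circle: the side or its complement is an interval
    contiguous <- function(q) length(q) == 0L || all(diff(q) == 1L)
    contiguous(p) || contiguous(sort(setdiff(seq_len(n), p)))
  }, logical(1))
  if (!all(ok)) {
    abort("every split must be contiguous in the circular order",
          class = "melodiverge_input_error")
  }
  invisible(ss)
}

filter_splits <- function(ss, threshold) {
  keep <- ss$weights > threshold
  ss$splits <- ss$splits[keep]
  ss$weights <- ss$weights[keep]
  ss
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("Split system on %d taxa: %d splits (total weight %.4f)\n",
              length(x$labels), length(x$splits), sum(x$weights)))
  cat("circular order:", paste(x$circular_order, collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.split_system <- function(x, ...) {
  tibble::tibble(
    split = seq_along(x$splits),
    weight = x$weights,
    size = lengths(x$splits),
    taxa = vapply(x$splits, function(s) paste(x$labels[s], collapse = ","),
                  character(1))
  )
}

#' @export
glance.split_system <- function(x, ...) {
  tibble::tibble(n_taxa = length(x$labels), n_splits = length(x$splits),
                 total_weight = sum(x$weights),
                 n_nontrivial = sum(lengths(x$splits) > 1 &
                                      lengths(x$splits) < length(x$labels) - 1))
}

#' @export
autoplot.split_system <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(kind = ifelse(.data$size == 1 |
                                  .data$size == length(object$labels) - 1,
                                "trivial", "nontrivial")) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(factor(.data$split), -.data$weight),
                                 y = .data$weight, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "split (by decreasing weight)", y = "weight",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Distances induced by a split system
#'
#' Sum of split weights separating each pair; useful for residual checks
#' against the input distance matrix.
#'
#' @param ss A `"split_system"`.
#' @return A symmetric matrix over `ss$labels`.
#' @export
split_distances <- function(ss) {
  n <- length(ss$labels)
  D <- matrix(0, n, n, dimnames = list(ss$labels, ss$labels))
  for (k in seq_along(ss$splits)) {
    side <- logical(n)
    side[ss$splits[[k]]] <- TRUE
    sep <- outer(side, side, xor)
    D <- D + ss$weights[k] * sep
  }
  D
}

#' Write a split system as a SplitsTree4-compatible NEXUS file
#'
#' Emits TAXA, DISTANCES and SPLITS blocks in the `st_splits` dialect that
#' SplitsTree4 opens directly, so networks can be rendered and inspected
#' there. Taxon labels containing whitespace are quoted.
#'
#' @param ss A `"split_system"` with at least one split.
#' @param D The distance matrix the system was estimated from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splits_nexus <- function(ss, D, path) {
  if (length(ss$splits) == 0L) {
    abort("split system has no splits", class = "melodiverge_input_error")
  }
  stopifnot(identical(rownames(D), ss$labels))
  n <- length(ss$labels)
  labs <- nexus_quote(ss$labels)
  cycle_idx <- match(ss$circular_order, ss$labels)
  split_lines <- vapply(seq_along(ss$splits), function(k) {
    s <- ss$splits[[k]]
    sprintf("[%d, size=%d]\t%.10g\t%s,", k, length(s),
            ss$weights[k], paste(s, collapse = " "))
  }, character(1))
  lines <- c(
    "#NEXUS", "",
    "BEGIN Taxa;",
    sprintf("DIMENSIONS ntax=%d;", n),
    "TAXLABELS",
    sprintf("[%d] %s", seq_len(n), labs),
    ";",
    "END; [Taxa]", "",
    "BEGIN Distances;",
    sprintf("DIMENSIONS ntax=%d;", n),
    "FORMAT labels=left diagonal triangle=both;",
    "MATRIX",
    vapply(seq_len(n), function(i) {
      paste(labs[i], paste(format(D[i, ], digits = 10, trim = TRUE),
                           collapse = " "))
    }, character(1)),
    ";",
    "END; [Distances]", "",
    "BEGIN Splits;",
    sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, length(ss$splits)),
    "FORMAT labels=no weights=yes confidences=no intervals=no;",
    "PROPERTIES fit=-1.0 cyclic;",
    paste("CYCLE", paste(cycle_idx, collapse = " "), ";"),
    "MATRIX",
    split_lines,
    ";",
    "END; [Splits]"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a NEXUS split system written by [write_splits_nexus()]
#'
#' Internal-dialect parser used for round-trip checks; it understands the
#' exact TAXA/SPLITS layout this package writes.
#'
#' @param path NEXUS file path.
#' @return A `"split_system"`.
#' @export
read_splits_nexus <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#NEXUS")) {
    abort("not a NEXUS file", class = "melodiverge_input_error")
  }
  unquote <- function(x) {
    q <- startsWith(x, "'")
    x[q] <- gsub("''", "'", substr(x[q], 2, nchar(x[q]) - 1))
    x
  }
  tax_start <- grep("^TAXLABELS", lines)[1]
  tax_end <- which(lines == ";" & seq_along(lines) > tax_start)[1]
  labels <- unquote(sub("^\\[\\d+\\] ", "", lines[(tax_start + 1):(tax_end - 1)]))
  cyc_line <- grep("^CYCLE", lines, value = TRUE)[1]
  cycle <- as.integer(strsplit(trimws(gsub("CYCLE|;", "", cyc_line)), "\\s+")[[1]])
  sp_begin <- grep("^BEGIN Splits;", lines)
  mat_start <- which(lines == "MATRIX" & seq_along(lines) > sp_begin)[1]
  mat_end <- which(lines == ";" & seq_along(lines) > mat_start)[1]
  entries <- lines[(mat_start + 1):(mat_end - 1)]
  parts <- stringr::str_match(entries,
    "^\\[\\d+, size=\\d+\\]\\t([-0-9.eE+]+)\\t([0-9 ]+),$")
  weights <- as.numeric(parts[, 2])
  splits <- lapply(strsplit(parts[, 3], " "), as.integer)
  new_split_system(labels, labels[cycle], splits, weights)
}
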