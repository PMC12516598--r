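#' Brunner-Munzel rank test
#'
#' Nonparametric two-sample test of the relative effect
#' p = P(X < Y) + 0.5 P(X = Y) against p = 1/2, without assuming equal
#' variances. The asymptotic method studentises the midrank estimator and
#' refers it to a t distribution with Welch-Satterthwaite degrees of freedom;
#' the permutation method computes the same statistic under relabelings of
#' the pooled sample (full enumeration when `choose(n1 + n2, n1)` does not
#' exceed `exact_limit`, otherwise Monte Carlo with `n_perm` draws from the
#' current RNG stream).
#'
#' When both within-sample rank variances vanish (complete separation or all
#' values tied) the studentised statistic is undefined: the relative effect
#' is still reported, a `melodiverge_degenerate_variance` warning is raised,
#' and the asymptotic p-value is `NA` — use `method = "permutation"`.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm Monte Carlo permutation count.
#' @param exact_limit Enumerate all relabelings when their number is at most
#'   this.
#' @return An object of class `"bm_test"`: `relative_effect`, `statistic`,
#'   `df`, `p_value`, `method`, sample sizes and a `degenerate` flag.
#' @examples
#' brunner_munzel(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
brunner_munzel <- function(x, y, method = c("asymptotic", "permutation"),
                           n_perm = 10000, exact_limit = 20000) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    abort("each sample needs at least 2 observations",
          class = "melodiverge_input_error")
  }
  obs <- bm_statistic(x, y)
  out <- structure(
    list(relative_effect = obs$p_hat, statistic = obs$statistic,
         df = obs$df, p_value = NA_real_, method = method,
         n_x = length(x), n_y = length(y), degenerate = obs$degenerate),
    class = "bm_test")

  if (method == "asymptotic") {
    if (obs$degenerate) {
      warn(paste("Brunner-Munzel variance estimate is zero (complete",
                 "separation or all ties); asymptotic p-value undefined,",
                 "use method = \"permutation\""),
           class = "melodiverge_degenerate_variance")
    } else {
      out$p_value <- 2 * pt(-abs(obs$statistic), df = obs$df)
    }
    return(out)
  }

  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  obs_abs <- bm_abs_statistic(obs)
  n_comb <- choose(n, n1)
  if (n_comb <= exact_limit) {
    idx <- combn(n, n1)
    stats <- apply(idx, 2, function(ii) {
      bm_abs_statistic(bm_statistic(pooled[ii], pooled[-ii]))
    })
    out$p_value <- mean(stats >= obs_abs - 1e-12)
    out$n_perm <- ncol(idx)
    out$exact <- TRUE
  } else {
    stats <- vapply(seq_len(n_perm), function(b) {
      ii <- sample.int(n, n1)
      bm_abs_statistic(bm_statistic(pooled[ii], pooled[-ii]))
    }, numeric(1))
    out$p_value <- (1 + sum(stats >= obs_abs - 1e-12)) / (1 + n_perm)
    out$n_perm <- n_perm
    out$exact <- FALSE
  }
  out
}

# Midrank-based studentised statistic (Brunner & Munzel 2000).
bm_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  r1 <- rank(x); r2 <- rank(y)
  m1 <- mean(r[seq_len(n1)]); m2 <- mean(r[n1 + seq_len(n2)])
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r[seq_len(n1)] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r[n1 + seq_len(n2)] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  vs <- n1 * v1 + n2 * v2
  degenerate <- vs <= 0
  if (degenerate) {
    stat <- if (m2 == m1) 0 else sign(m2 - m1) * Inf
    df <- NA_real_
  } else {
    stat <- n1 * n2 * (m2 - m1) / n / sqrt(vs)
    df <- vs^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  }
  list(p_hat = p_hat, statistic = stat, df = df, degenerate = degenerate)
}

bm_abs_statistic <- function(s) {
  if (is.infinite(s$statistic)) Inf else abs(s$statistic)
}

#' @export
print.bm_test <- function(x, ...) {
  cat("Brunner-Munzel test (", x$method, ")\n", sep = "")
  cat(sprintf("relative effect p = %.4f, statistic = %.4f%s, p-value = %s\n",
              x$relative_effect, x$statistic,
              if (!is.na(x$df)) sprintf(", df = %.2f", x$df) else "",
              format.pval(x$p_value)))
  if (isTRUE(x$degenerate)) cat("note: degenerate variance estimate\n")
  invisible(x)
}

#' @export
tidy.bm_test <- function(x, ...) {
  tibble::tibble(relative_effect = x$relative_effect,
                 statistic = x$statistic, df = x$df, p.value = x$p_value,
                 method = x$method)
}

#' @export
glance.bm_test <- function(x, ...) {
  tibble::tibble(n_x = x$n_x, n_y = x$n_y, degenerate = x$degenerate,
                 method = x$method)
}

#' All pairwise PID values of a corpus, classified by song group
#'
#' Computes PID for every unordered pair of melodies and flags whether the
#' two belong to the same song group. This is the long table behind the
#' same-group / different-group comparison; summarise it with
#' [pid_group_summary()] or test it with [brunner_munzel()].
#'
#' @param corpus Corpus tibble.
#' @param params An [alignment_params()] object.
#' @return A tibble with columns `song_i`, `song_j`, `group_i`, `group_j`,
#'   `same_group`, `pid`.
#' @export
pid_pairs <- function(corpus, params) {
  if (nrow(corpus) < 2L) {
    abort("need at least 2 melodies", class = "melodiverge_input_error")
  }
  D <- distance_matrix(corpus, params)
  pid <- 100 * (1 - D)
  idx <- which(upper.tri(pid), arr.ind = TRUE)
  grp <- setNames(corpus$group_id, corpus$song_id)
  ids <- rownames(pid)
  tibble::tibble(
    song_i = ids[idx[, 1]],
    song_j = ids[idx[, 2]],
    group_i = unname(grp[ids[idx[, 1]]]),
    group_j = unname(grp[ids[idx[, 2]]]),
    same_group = grp[ids[idx[, 1]]] == grp[ids[idx[, 2]]],
    pid = pid[idx]
  )
}

#' Median and IQR of PID for same-group and different-group pairs
#'
#' Quantiles use R's default linear-interpolation convention
#' (`stats::quantile`, type 7), so the summary is bit-reproducible.
#'
#' @param corpus Corpus tibble (>= 2 melodies, >= 2 groups).
#' @param params An [alignment_params()] object.
#' @return A tibble with one row per class (`same`, `different`):
#'   `n_pairs`, `median`, `q1`, `q3`.
#' @export
pid_group_summary <- function(corpus, params) {
  pairs <- pid_pairs(corpus, params)
  if (length(unique(corpus$group_id)) < 2L) {
    abort("need at least 2 song groups", class = "melodiverge_input_error")
  }
  pairs |>
    dplyr::mutate(class = ifelse(.data$same_group, "same", "different")) |>
    dplyr::group_by(class = factor(.data$class, levels = c("same", "different"))) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      median = median(.data$pid),
      q1 = unname(quantile(.data$pid, 0.25)),
      q3 = unname(quantile(.data$pid, 0.75)),
      .groups = "drop"
    )
}

#' Boxplot-style view of same- versus different-group PID
#'
#' @param pairs Output of [pid_pairs()].
#' @return A ggplot object.
#' @export
plot_pid_distributions <- function(pairs) {
  pairs |>
    dplyr::mutate(class = ifelse(.data$same_group, "same group", "different group")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$class, y = .data$pid)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "percent identity (PID)") +
    ggplot2::theme_minimal()
}
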