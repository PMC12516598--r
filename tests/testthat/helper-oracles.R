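# Independent oracles and fixture builders used across the suite.

melody_alphabet <- pitch_letters()

random_melody <- function(len, letters = c("C", "D", "E", "F", "G")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# --- brute-force global alignment ------------------------------------------
# Enumerates every monotone alignment (move 1 = diagonal, 2 = gap in s2,
# 3 = gap in s1; no gap-gap columns) and scores it directly from its columns,
# so the affine gap accounting is independent of any dynamic program.
# Move sets depend only on the two lengths and are cached.

.move_cache <- new.env(parent = emptyenv())

enumerate_moves <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.move_cache[[key]])) return(.move_cache[[key]])
  res <- list()
  rec <- function(i, j, acc) {
    if (i == n && j == m) {
      res[[length(res) + 1L]] <<- acc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, c(acc, 1L))
    if (i < n) rec(i + 1L, j, c(acc, 2L))
    if (j < m) rec(i, j + 1L, c(acc, 3L))
  }
  rec(0L, 0L, integer(0))
  .move_cache[[key]] <- res
  res
}

# gap run of length k costs gop + gep * k when convention = "open_plus_ext",
# or gop + gep * (k - 1) under the alternative accounting
score_moves <- function(moves, x, y, gop, gep, convention = "open_plus_ext") {
  i <- 0L; j <- 0L
  sub <- 0
  for (mv in moves) {
    if (mv == 1L) {
      i <- i + 1L; j <- j + 1L
      sub <- sub + if (x[i] == y[j]) 1 else -1
    } else if (mv == 2L) i <- i + 1L else j <- j + 1L
  }
  r <- rle(moves)
  runs <- r$lengths[r$values != 1L]
  gap_cost <- if (convention == "open_plus_ext") {
    sum(gop + gep * runs)
  } else {
    sum(gop + gep * pmax(runs - 1, 0))
  }
  sub - gap_cost
}

brute_force_score <- function(s1, s2, gop, gep, convention = "open_plus_ext") {
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]
  moves <- enumerate_moves(length(x), length(y))
  max(vapply(moves, score_moves, numeric(1), x = x, y = y,
             gop = gop, gep = gep, convention = convention))
}

# score an explicit gapped alignment under the package's gap convention
score_gapped <- function(a1, a2, gop, gep) {
  c1 <- strsplit(a1, "")[[1]]; c2 <- strsplit(a2, "")[[1]]
  both <- c1 != "-" & c2 != "-"
  sub <- sum(ifelse(c1[both] == c2[both], 1, -1))
  gap_cost <- function(cc) {
    r <- rle(cc == "-")
    sum(gop + gep * r$lengths[r$values])
  }
  sub - gap_cost(c1) - gap_cost(c2)
}

count_gap_runs <- function(a1, a2) {
  runs <- function(cc) {
    r <- rle(strsplit(cc, "")[[1]] == "-")
    sum(r$values)
  }
  runs(a1) + runs(a2)
}

# --- quartet-iterating delta oracle ----------------------------------------

delta_oracle <- function(D) {
  n <- nrow(D)
  qs <- combn(n, 4)
  ds <- apply(qs, 2, function(q) {
    s <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
                D[q[1], q[3]] + D[q[2], q[4]],
                D[q[1], q[4]] + D[q[2], q[3]]))
    if (s[3] - s[1] <= 0) 0 else (s[3] - s[2]) / (s[3] - s[1])
  })
  mean(ds)
}

# --- additive tree metrics and their true splits ---------------------------

random_tree_metric <- function(n, min_edge = 0.1, max_edge = 2) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(nrow(tr$edge), min_edge, max_edge)
  D <- ape::cophenetic.phylo(tr)
  D <- D[tr$tip.label, tr$tip.label]
  list(tree = tr, D = D)
}

# splits of an unrooted tree as canonical label-set keys -> edge weights
tree_split_weights <- function(tr) {
  n <- length(tr$tip.label)
  po <- ape::reorder.phylo(tr, "postorder")
  desc <- vector("list", max(po$edge))
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character(0); weights <- numeric(0)
  for (e in seq_len(nrow(po$edge))) {
    side <- sort(desc[[po$edge[e, 2]]])
    keys <- c(keys, split_key(tr$tip.label, side))
    weights <- c(weights, po$edge.length[e])
  }
  setNames(weights, keys)
}

# canonical key: the side not containing the alphabetically first label
split_key <- function(labels, side_idx) {
  n <- length(labels)
  side <- sort(side_idx)
  first <- order(labels)[1]
  if (first %in% side) side <- sort(setdiff(seq_len(n), side))
  paste(sort(labels[side]), collapse = "|")
}

split_system_keys <- function(ss, min_weight = 0) {
  keep <- ss$weights > min_weight
  setNames(ss$weights[keep],
           vapply(ss$splits[keep], split_key, character(1), labels = ss$labels))
}

# --- small corpus fixtures --------------------------------------------------

toy_corpus <- function() {
  tibble::tibble(
    song_id = c("A1.1", "A1.2", "A1.3", "B1.1", "B1.2", "B1.3"),
    group_id = rep(c("A1", "B1"), each = 3),
    region = rep(c("Amami", "Okinawa"), each = 3),
    island = rep(c("Amami Oshima", "Okinawa Island"), each = 3),
    site_lat = c(28.33, 28.32, NA, 26.50, 26.34, 26.50),
    site_lon = c(129.43, 129.98, NA, 127.97, 126.77, 127.97),
    recording_year = c(1968L, 2016L, 1980L, 1970L, 1985L, 2019L),
    context = c("work", "work", "ritual", "child", "child", "amusement"),
    source = c("SJF", "field", "SJF", "SJF", "SJF", "field"),
    sequence = c("CEGEC", "CEGC", "CEGEG", "CDFGA", "CDFFGA", "CDFGAD")
  )
}

# pair table simulated straight from the mixed model, for LMM-only checks
simulate_pair_table <- function(n_groups = 30, pairs_per_group = 10,
                                beta = c(`(Intercept)` = 0.15, I = 0.05,
                                         D = 0, T = 0, C = 0.15, S = 0),
                                tau = 0.05, sigma = 0.05,
                                p_na_site = 0) {
  n <- n_groups * pairs_per_group
  g <- rep(sprintf("G%02d", seq_len(n_groups)), each = pairs_per_group)
  I <- rbinom(n, 1, 0.5)
  D <- I * runif(n, 20, 300) + (1 - I) * runif(n, 0, 10)
  TT <- sample(0:50, n, replace = TRUE)
  C <- rbinom(n, 1, 0.4)
  S <- rbinom(n, 1, 0.45)
  r <- rnorm(n_groups, 0, tau)[match(g, unique(g))]
  Y <- beta[["(Intercept)"]] + beta[["I"]] * I + beta[["D"]] * D +
    beta[["T"]] * TT + beta[["C"]] * C + beta[["S"]] * S +
    r + rnorm(n, 0, sigma)
  out <- tibble::tibble(
    song_i = sprintf("s%d.1", seq_len(n)), song_j = sprintf("s%d.2", seq_len(n)),
    group = g, Y = Y, I = as.numeric(I), D = D, T = as.numeric(TT),
    C = as.numeric(C), S = as.numeric(S))
  if (p_na_site > 0) {
    na <- runif(n) < p_na_site
    out$I[na] <- NA; out$D[na] <- NA
  }
  out
}
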