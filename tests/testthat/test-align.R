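test_that("preset parameter sets carry the published penalty values", {
  p1 <- alignment_preset(1)
  expect_equal(c(p1$gop, p1$gep), c(12, 6))
  expect_equal(p1$mode, "ignore")
  p2 <- alignment_preset(2)
  expect_equal(c(p2$gop, p2$gep), c(0.8, 0.2))
  expect_equal(p2$mode, "include")
  expect_error(alignment_params(-1, 2), class = "melodiverge_parameter_error")
})

test_that("worked alignment examples come out as enumerated by hand", {
  r <- align_pair("CDE", "CDE", alignment_preset(2))
  expect_equal(r$aligned1, "CDE")
  expect_equal(r$score, 3)
  expect_equal(r$id_count, 3)

  r <- align_pair("CE", "CDE", alignment_preset(2))
  expect_equal(r$aligned1, "C-E")
  expect_equal(r$aligned2, "CDE")
  expect_equal(r$score, 1.0)   # 1 + 1 - (0.8 + 0.2)
  expect_equal(r$id_count, 2)

  # under set 1 a gap costs >= 18, so the mismatch alignment wins
  r <- align_pair("CDE", "CFE", alignment_preset(1))
  expect_equal(r$aligned1, "CDE")
  expect_equal(r$aligned2, "CFE")
  expect_equal(r$score, 1)
  expect_equal(r$id_count, 2)

  expect_error(align_pair("", "CDE", alignment_preset(1)),
               class = "melodiverge_input_error")
})

test_that("dynamic program matches the exhaustive alignment oracle", {
  set.seed(21)
  param_grid <- list(c(12, 6), c(0.8, 0.2), c(2, 0.5), c(0, 0))
  for (rep in 1:30) {
    s1 <- random_melody(sample(1:6, 1))
    s2 <- random_melody(sample(1:6, 1))
    for (p in param_grid) {
      params <- alignment_params(p[1], p[2], "include")
      r <- align_pair(s1, s2, params)
      expect_equal(r$score, brute_force_score(s1, s2, p[1], p[2]),
                   tolerance = 1e-12,
                   info = sprintf("%s vs %s, gop %g gep %g", s1, s2, p[1], p[2]))
      # the returned alignment is valid and scores what it claims
      expect_equal(gsub("-", "", r$aligned1), s1)
      expect_equal(gsub("-", "", r$aligned2), s2)
      cols <- cbind(strsplit(r$aligned1, "")[[1]], strsplit(r$aligned2, "")[[1]])
      expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
      expect_equal(score_gapped(r$aligned1, r$aligned2, p[1], p[2]), r$score,
                   tolerance = 1e-12)
      expect_equal(sum(cols[, 1] == cols[, 2]), r$id_count)
    }
  }
})

test_that("alignment score and identity count are symmetric in the inputs", {
  set.seed(22)
  for (rep in 1:20) {
    s1 <- random_melody(sample(2:12, 1), melody_alphabet)
    s2 <- random_melody(sample(2:12, 1), melody_alphabet)
    for (set in 1:2) {
      a <- align_pair(s1, s2, alignment_preset(set))
      b <- align_pair(s2, s1, alignment_preset(set))
      expect_equal(a$score, b$score)
      expect_equal(a$id_count, b$id_count)
    }
  }
})

test_that("raising the opening penalty never creates more gap runs", {
  set.seed(23)
  for (rep in 1:15) {
    s1 <- random_melody(sample(4:10, 1))
    s2 <- random_melody(sample(4:10, 1))
    runs <- vapply(c(0.5, 1, 2, 4, 8, 16), function(gop) {
      r <- align_pair(s1, s2, alignment_params(gop, 0.2, "include"))
      count_gap_runs(r$aligned1, r$aligned2)
    }, numeric(1))
    expect_true(all(diff(runs) <= 0))
  }
})

test_that("percent identity uses the mean-length denominator", {
  expect_equal(percent_identity(3, 3, 3), 100)
  expect_equal(percent_identity(2, 2, 3), 80)
  expect_equal(percent_identity(0, 7, 3), 0)
  expect_equal(percent_identity(2, 2, 3), percent_identity(2, 3, 2))
  expect_error(percent_identity(2, 0, 3), class = "melodiverge_input_error")
  expect_error(percent_identity(5, 4, 6), class = "melodiverge_input_error")
})

test_that("self-comparison gives PID 100 and distance 0", {
  set.seed(24)
  for (rep in 1:10) {
    s <- random_melody(sample(1:20, 1), melody_alphabet)
    for (set in 1:2) {
      expect_equal(percent_identity(align_pair(s, s, alignment_preset(set))), 100)
      expect_equal(melodic_distance(s, s, alignment_preset(set)), 0)
    }
  }
})

test_that("melodic distance is symmetric and bounded", {
  set.seed(25)
  p2 <- alignment_preset(2)
  expect_equal(melodic_distance("CE", "CDE", p2), 0.2)
  for (rep in 1:10) {
    s1 <- random_melody(sample(1:15, 1), melody_alphabet)
    s2 <- random_melody(sample(1:15, 1), melody_alphabet)
    d <- melodic_distance(s1, s2, p2)
    expect_equal(d, melodic_distance(s2, s1, p2))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("distance matrix agrees with independent per-pair calls", {
  corpus <- toy_corpus()[1:3, ]
  for (set in 1:2) {
    params <- alignment_preset(set)
    D <- distance_matrix(corpus, params)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 3))
    for (i in 1:2) for (j in (i + 1):3) {
      expect_equal(D[i, j],
                   melodic_distance(corpus$sequence[i], corpus$sequence[j], params))
    }
  }
  two <- setNames(c("CEG", "CEG"), c("a", "b"))
  expect_equal(unname(distance_matrix(two, alignment_preset(1))),
               matrix(0, 2, 2))
  expect_error(distance_matrix(setNames(c("CEG", "CEG"), c("a", "a")),
                               alignment_preset(1)),
               class = "melodiverge_input_error")
})

test_that("the two parameter sets disagree exactly when mode matters", {
  seqs <- setNames(c("CEGEC", "CeGeC", "CDADC"), c("x", "y", "z"))
  D1 <- distance_matrix(seqs, alignment_preset(1))
  D2 <- distance_matrix(seqs, alignment_preset(2))
  expect_equal(D1["x", "y"], 0)      # e == E when mode is ignored
  expect_gt(D2["x", "y"], 0)         # but not when it is included
  expect_false(isTRUE(all.equal(D1, D2)))
})

test_that("distance matrix exports round through CSV and NEXUS text", {
  D <- distance_matrix(toy_corpus(), alignment_preset(2))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(D, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$song_id, rownames(D))
  expect_equal(as.matrix(back[, -1]), unname(D) + 0,
               ignore_attr = TRUE, tolerance = 1e-9)
  nex <- withr::local_tempfile(fileext = ".nex")
  write_distance_nexus(D, nex)
  lines <- readLines(nex)
  expect_equal(lines[1], "#NEXUS")
  expect_true(any(grepl("BEGIN Distances;", lines)))
})
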