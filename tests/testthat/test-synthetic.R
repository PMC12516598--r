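test_that("the four scales have the expected pitch-class content and letters", {
  sc <- koizumi_scales()
  expect_setequal(sc$name, c("ryukyu", "ritsu", "minyo", "miyako_bushi"))
  get <- function(nm, col) sc[[col]][[match(nm, sc$name)]]
  expect_equal(get("ryukyu", "pitch_classes"), c(0L, 4L, 5L, 7L, 11L))
  expect_equal(get("ryukyu", "letters"), c("C", "E", "F", "G", "B"))
  expect_equal(get("ritsu", "letters"), c("C", "D", "F", "G", "A"))
  expect_equal(get("minyo", "letters"), c("C", "e", "F", "G", "b"))
  expect_equal(get("miyako_bushi", "letters"), c("C", "d", "F", "G", "a"))
  expect_true(all(vapply(sc$pitch_classes, function(p) 0L %in% p, logical(1))))
})

test_that("scale melodies start on the tonic and stay within the scale", {
  set.seed(71)
  s <- replicate(200, sample_scale_melody("ryukyu", 8))
  expect_true(all(substr(s, 1, 1) == "C"))
  chars <- unique(strsplit(paste(s, collapse = ""), "")[[1]])
  expect_true(all(chars %in% c("C", "E", "F", "G", "B")))
  set.seed(72)
  a <- sample_scale_melody("minyo", 12)
  set.seed(72)
  b <- sample_scale_melody("minyo", 12)
  expect_identical(a, b)
  expect_error(sample_scale_melody("ryukyu", 0), class = "melodiverge_input_error")
})

test_that("non-tonic positions are uniform over the five scale letters", {
  set.seed(73)
  draws <- replicate(2000, sample_scale_melody("ritsu", 6))
  tail_chars <- unlist(strsplit(substr(draws, 2, 6), ""))
  counts <- table(factor(tail_chars, levels = c("C", "D", "F", "G", "A")))
  n <- length(tail_chars)
  # each letter within 3 binomial sd of n/5
  expect_true(all(abs(counts - n / 5) < 3 * sqrt(n * 0.2 * 0.8)))
})

test_that("mutation respects rates, scale closure and never empties a melody", {
  set.seed(74)
  s <- sample_scale_melody("ryukyu", 50)
  expect_identical(mutate_sequence(s, 3, 0, 0, 0, "ryukyu"), s)
  # substitutions only: length preserved, changes ~ Binomial(50, 0.1)
  changes <- replicate(400, {
    m <- mutate_sequence(s, 1, 0.1, 0, 0, "ryukyu")
    expect_equal(nchar(m), 50)
    sum(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  })
  expect_lt(abs(mean(changes) - 5), 4 * sqrt(50 * 0.1 * 0.9) / sqrt(400))
  # extreme deletion pressure still leaves at least one note
  m <- mutate_sequence("CEG", 10, 0, 0, 1, "ryukyu")
  expect_gte(nchar(m), 1)
  # mutated letters stay within the scale
  m2 <- mutate_sequence(s, 5, 0.5, 0.3, 0.1, "ryukyu")
  expect_true(all(strsplit(m2, "")[[1]] %in% c("C", "E", "F", "G", "B")))
})

test_that("corpus generation is exactly reproducible from the seed", {
  cfg <- simulation_config(n_groups = 8, seed = 75)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$truth$groups, b$truth$groups)
  d <- generate_corpus(simulation_config(n_groups = 8, seed = 76))
  expect_false(identical(a$corpus$sequence, d$corpus$sequence))
})

test_that("generated corpora satisfy the metadata contract", {
  gen <- generate_corpus(simulation_config(n_groups = 12, seed = 77))
  corpus <- gen$corpus
  expect_true(all(table(corpus$group_id) >= 3))
  expect_false(anyDuplicated(corpus$song_id) > 0)
  expect_true(all(xor(is.na(corpus$site_lat), is.na(corpus$site_lon)) == FALSE))
  isl <- ryukyu_islands()
  expect_true(all(corpus$island %in% isl$island))
  # island coordinates come from the centroid table
  known <- !is.na(corpus$site_lat)
  expect_equal(corpus$site_lat[known],
               isl$lat[match(corpus$island[known], isl$island)])
  sjf <- corpus$source == "SJF"
  expect_true(all(corpus$recording_year[sjf] %in% 1964:1990))
  expect_true(all(corpus$recording_year[!sjf] %in% 2015:2019))
  expect_identical(sort(unique(gen$truth$lineages$song_id)),
                   sort(corpus$song_id))
})

test_that("zero mutation rates give identical melodies within each group", {
  cfg <- simulation_config(n_groups = 5, mu_sub = 0, mu_ins = 0, mu_del = 0,
                           seed = 78)
  gen <- generate_corpus(cfg)
  pt <- build_pair_table(gen$corpus, params = alignment_preset(1))
  expect_true(all(pt$Y == 0))
  pt2 <- build_pair_table(gen$corpus, params = alignment_preset(2))
  expect_true(all(pt2$Y == 0))
})

test_that("island crossing inflates divergence at the default calibration", {
  set.seed(79)
  diffs <- vapply(1:10, function(i) {
    gen <- generate_corpus(simulation_config(n_groups = 20, seed = 7900 + i))
    pt <- build_pair_table(gen$corpus, params = alignment_preset(2))
    mean(pt$Y[pt$I == 1], na.rm = TRUE) - mean(pt$Y[pt$I == 0], na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(diffs), 0.02)
})

test_that("groups on different scales are more distant than groups sharing one", {
  gen <- generate_corpus(simulation_config(n_groups = 16, seed = 80))
  D <- distance_matrix(gen$corpus, alignment_preset(2))
  scale_of <- gen$truth$groups$scale[match(gen$corpus$group_id,
                                           gen$truth$groups$group_id)]
  same_scale <- outer(scale_of, scale_of, `==`)
  same_group <- outer(gen$corpus$group_id, gen$corpus$group_id, `==`)
  off <- upper.tri(D) & !same_group
  expect_gt(mean(D[off & !same_scale]), mean(D[off & same_scale]))
})

test_that("the synthetic song list realizes the published corpus structure", {
  tab <- synthetic_song_table()
  expect_false(anyDuplicated(tab$song_id) > 0)
  sizes <- table(tab$group_id)
  expect_true(all(sizes >= 3))
  expect_equal(sort(as.integer(table(factor(sizes, levels = c(3, 4, 5, 6, 8, 16))))),
               sort(c(29L, 2L, 3L, 1L, 2L, 1L)))
  expect_true(all(tab$context %in% c("child", "ritual", "work", "amusement")))
  expect_true(all(tab$source %in% c("SJF", "field")))
  isl <- ryukyu_islands()
  expect_equal(tab$region, isl$region[match(tab$island, isl$island)])
  # group id is a prefix of the song id, by convention
  expect_true(all(startsWith(tab$song_id, tab$group_id)))
})
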