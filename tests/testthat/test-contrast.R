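make_feature_rows <- function(n_talkers, pair = "p01", seed = 1) {
  with_seed_local(seed, {
    data.frame(
      talker_id = rep(sprintf("T%02d", seq_len(n_talkers)), each = 2),
      word_id = rep(c("wa", "wb"), n_talkers),
      pair_id = pair,
      f1_c0 = rnorm(2 * n_talkers, 8), f1_c1 = rnorm(2 * n_talkers),
      f1_c2 = rnorm(2 * n_talkers), f2_c0 = rnorm(2 * n_talkers, 12),
      f2_c1 = rnorm(2 * n_talkers), f2_c2 = rnorm(2 * n_talkers),
      duration = runif(2 * n_talkers, 0.1, 0.4)
    )
  })
}

test_that("z-scoring gives each dimension mean 0 and unit SD in the pair frame", {
  v <- make_feature_rows(10)
  z <- zscore_features(v)
  for (d in ownvoice:::feature_dims()) {
    expect_lt(abs(mean(z[[d]])), 1e-12)
    expect_equal(sd(z[[d]]), 1, tolerance = 1e-12)
  }
  # affine rescaling of a raw dimension changes nothing
  v2 <- v
  v2$duration <- 3.7 * v2$duration - 0.4
  expect_equal(zscore_features(v2)$duration, z$duration, tolerance = 1e-9)
  # zero-variance dimensions map to zero, not NaN
  v3 <- v
  v3$f1_c2 <- 5
  expect_true(all(zscore_features(v3)$f1_c2 == 0))
  expect_error(zscore_features(v[v$talker_id == "T01", ]), "at least 2 talkers")
})

test_that("a single varying value yields +/- constant z-scores", {
  v <- make_feature_rows(2)
  for (d in ownvoice:::feature_dims()) v[[d]] <- 1
  v$duration <- c(0.1, 0.1, 0.1, 0.3)    # only T02's second word differs
  z <- zscore_features(v)
  expect_equal(mean(z$duration), 0, tolerance = 1e-12)
  expect_equal(sort(unique(round(z$duration, 9))), round(c(-0.5, 1.5), 9))
})

test_that("pair_distance is the plain 7-D Euclidean distance", {
  expect_equal(pair_distance(rep(0, 7), rep(0, 7)), 0)
  a <- rep(0, 7); b <- rep(0, 7); b[3] <- 1
  expect_equal(pair_distance(a, b), 1)
  expect_equal(pair_distance(c(1, 0, 0, 0, 0, 0, 0.5),
                             c(0, -1, 0, 0, 0, 0, 0)), 1.5)
  expect_error(pair_distance(rep(0, 7), rep(0, 6)), "dimension mismatch")
})

test_that("group assignment follows the largest-remainder rule", {
  # brute-force oracle: most even partition with earlier groups taking extras
  balanced_sizes <- function(n, k) {
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    sizes
  }
  for (n in c(25, 33, 29, 12)) {
    sc <- data.frame(pair_id = "p01",
                     talker_id = sprintf("T%02d", seq_len(n)),
                     distance = rev(seq_len(n)) / n, rank = seq_len(n))
    asg <- suppressWarnings(assign_groups(sc))
    expect_equal(as.integer(table(factor(asg$group, levels = LETTERS[1:5]))),
                 balanced_sizes(n, 5))
    # ordering: max distance in A, min in E, medians non-increasing
    expect_equal(asg$group[which.max(asg$distance)], "A")
    expect_equal(asg$group[which.min(asg$distance)], "E")
    med <- tapply(asg$distance, asg$group, median)
    expect_true(all(diff(med[LETTERS[1:5]]) <= 0))
  }
  expect_equal(as.integer(table(suppressWarnings(assign_groups(
    data.frame(pair_id = "p", talker_id = sprintf("T%02d", 1:33),
               distance = runif(33), rank = 1:33)))$group)),
    c(7L, 7L, 7L, 6L, 6L))
  sc25 <- data.frame(pair_id = "p", talker_id = sprintf("T%02d", 1:25),
                     distance = 25:1, rank = 1:25)
  asg25 <- assign_groups(sc25)
  expect_equal(asg25$group[asg25$rank <= 5], rep("A", 5))
  expect_equal(asg25$group[asg25$rank >= 21], rep("E", 5))
  expect_error(assign_groups(sc25, n_groups = 1), "k|n_groups")
  expect_warning(assign_groups(sc25[1:8, ]), "outside the intended bounds")
})

test_that("manual override table replaces computed groups", {
  sc <- data.frame(pair_id = "p", talker_id = sprintf("T%02d", 1:25),
                   distance = 25:1, rank = 1:25)
  asg <- assign_groups(sc, override = data.frame(talker_id = "T01", group = "E"))
  expect_equal(asg$group[asg$talker_id == "T01"], "E")
})

test_that("contrast scores are permutation-invariant and rank correctly", {
  co <- tiny_cohort(n_talkers = 8, n_pairs = 2)
  toks <- synthesize_production_set(co, jitter = 0.02, seed = 3)
  ft <- feature_table(toks)
  sc <- contrast_scores(ft, co$roster)
  expect_equal(nrow(sc), 8L * 2L)
  expect_true(all(sc$distance >= 0))
  for (p in unique(sc$pair_id)) {
    expect_setequal(sc$rank[sc$pair_id == p], seq_len(8))
  }
  ft_shuffled <- ft[with_seed_local(4, sample(nrow(ft))), ]
  sc2 <- contrast_scores(ft_shuffled, co$roster)
  ord <- order(sc$pair_id, sc$talker_id)
  ord2 <- order(sc2$pair_id, sc2$talker_id)
  expect_equal(sc[ord, ]$distance, sc2[ord2, ]$distance, tolerance = 1e-12)
  expect_equal(sc[ord, ]$rank, sc2[ord2, ]$rank)
})

test_that("talkers missing a pair member are excluded from that pair", {
  co <- tiny_cohort(n_talkers = 6, n_pairs = 1)
  toks <- synthesize_production_set(co, jitter = 0.01, seed = 5)
  ft <- feature_table(toks)
  ft <- ft[!(ft$talker_id == "T01" & ft$word_id == "gai1"), ]
  sc <- contrast_scores(ft, co$roster)
  expect_false("T01" %in% sc$talker_id)
  expect_setequal(sc$rank, seq_len(5))
})

test_that("generating separation delta drives computed distance", {
  co <- make_cohort(33, 2, seed = 21)
  toks <- synthesize_production_set(co, jitter = 0.02, seed = 22)
  ft <- feature_table(toks)
  sc <- contrast_scores(ft, co$roster)
  m <- merge(sc, co$delta)
  # monotonicity is a within-pair property: 33 talkers ranked per pair
  rho <- vapply(split(m, m$pair_id),
                function(d) cor(d$delta, d$distance, method = "spearman"),
                numeric(1))
  expect_true(all(rho >= 0.9))
})
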