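test_that("distance score reproduces hand-computed nearest-neighbour averages", {
  zero <- descriptor_set(matrix(0, 1, 128))
  entry <- descriptor_set(rbind(c(1, rep(0, 127)), c(3, rep(0, 127))))
  expect_equal(distance_score(zero, entry), 1.0)

  # two probe descriptors with NN squared distances 1 and 9 average to 5
  probe <- descriptor_set(rbind(rep(0, 128), c(6, rep(0, 127))))
  expect_equal(distance_score(probe, entry), 5.0)

  set.seed(9)
  s <- random_set(17)
  expect_equal(distance_score(s, s), 0)
  expect_error(distance_score(descriptor_set(matrix(numeric(0), 0, 128)), s),
               "non-empty")
})

test_that("accelerated scoring equals the brute-force double loop", {
  set.seed(10)
  for (i in 1:40) {
    P <- random_descriptors(sample(1:30, 1))
    E <- random_descriptors(sample(1:30, 1))
    ref <- brute_nn_score(P, E)
    fast <- distance_score(descriptor_set(P), descriptor_set(E))
    loop <- distance_score(descriptor_set(P), descriptor_set(E), method = "loop")
    expect_equal(fast, ref, tolerance = 1e-9)
    expect_equal(loop, ref, tolerance = 1e-12)
  }
})

test_that("gender filter keeps exact label matches and falls back when unknown", {
  recs <- list(make_record("A", "F", random_set(2)),
               make_record("B", "M", random_set(2)),
               make_record("C", "F", random_set(2)))
  expect_equal(vapply(apply_gender_filter(recs, "F"), `[[`, "", "subject_id"),
               c("A", "C"))
  expect_length(apply_gender_filter(recs[2], "F"), 0L)
  expect_length(apply_gender_filter(recs, NA), 3L)
})

test_that("ranking sorts ascending, breaks ties lexicographically and truncates", {
  base <- rep(0, 128)
  mk <- function(v) descriptor_set(matrix(c(v, rep(0, 127)), 1, 128))
  probe <- mk(0)
  # B and A tie at squared distance 4; C is at 25
  recs <- list(make_record("B", "F", mk(2)), make_record("A", "F", mk(2)),
               make_record("C", "F", mk(5)))
  cfg <- pipeline_config(use_gender_filter = FALSE)
  r <- rank_matches(probe, recs, cfg)
  expect_equal(r$subject_id, c("A", "B", "C"))
  expect_equal(r$score, c(4, 4, 25))
  expect_equal(r$rank, 1:3)

  expect_equal(nrow(rank_matches(probe, recs[3], cfg)), 1L)

  set.seed(12)
  vals <- sample(1:60, 15)
  recs15 <- lapply(seq_along(vals), function(i) {
    make_record(sprintf("G%02d", i), "F", mk(vals[i]))
  })
  r15 <- rank_matches(probe, recs15, cfg)
  expect_equal(nrow(r15), 10L)
  expect_equal(r15$score, sort(vals^2)[1:10])  # the 10 smallest of all 15
})

test_that("self-identification puts the probe's own composite at rank 1 score 0", {
  set.seed(13)
  recs <- lapply(1:8, function(i) make_record(paste0("S", i), "F", random_set(10)))
  probe <- recs[[5]]$composite
  r <- rank_matches(probe, recs, pipeline_config(use_gender_filter = FALSE))
  expect_equal(r$subject_id[1], "S5")
  expect_equal(r$score[1], 0)
})

test_that("ranks are invariant under monotone transforms of the score", {
  set.seed(14)
  probe <- random_set(6)
  recs <- lapply(1:9, function(i) make_record(paste0("S", i), "F", random_set(8)))
  sq <- vapply(recs, function(r) distance_score(probe, r$composite), numeric(1))
  expect_equal(order(sqrt(sq)), order(sq))  # plain vs squared Euclidean
  expect_equal(order(log1p(sq)), order(sq))
})

test_that("outcomes follow the top-1 / top-10 / no-match designation", {
  ranked <- data.frame(subject_id = sprintf("S%02d", 1:10), score = 1:10,
                       rank = 1:10)
  expect_equal(classify_outcome(ranked, "S01"),
               list(outcome = "top1", rank = 1L))
  expect_equal(classify_outcome(ranked, "S05"),
               list(outcome = "top10", rank = 5L))
  expect_equal(classify_outcome(ranked, "S99"),
               list(outcome = "none", rank = NA_integer_))
})

test_that("filtering by the correct label never demotes the true match", {
  set.seed(15)
  for (i in 1:20) {
    recs <- lapply(1:12, function(j) {
      make_record(sprintf("S%02d", j), sample(c("F", "M"), 1), random_set(6))
    })
    true <- sample(12, 1)
    recs[[true]]$gender <- "F"
    probe <- descriptor_set(abs(recs[[true]]$composite$descriptors +
                                  matrix(stats::rnorm(6 * 128, 0, 5), 6, 128)))
    cfg_on <- pipeline_config(use_gender_filter = TRUE, top_k = 12)
    cfg_off <- pipeline_config(use_gender_filter = FALSE, top_k = 12)
    rank_on <- match(recs[[true]]$subject_id,
                     rank_matches(probe, recs, cfg_on, "F")$subject_id)
    rank_off <- match(recs[[true]]$subject_id,
                      rank_matches(probe, recs, cfg_off, "F")$subject_id)
    expect_lte(rank_on, rank_off)
  }
})
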