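test_that("split assigns train/test per subject with disjoint roles", {
  m <- data.frame(image_path = sprintf("i%d.png", 1:8),
                  subject_id = rep(c("A", "B"), each = 4),
                  gender = "F", side = "left", capture_index = rep(1:4, 2))
  sp <- split_spec(m)
  expect_equal(as.vector(table(sp$role)), c(4L, 4L))
  for (sid in c("A", "B")) {
    mine <- sp[sp$subject_id == sid, ]
    expect_setequal(mine$role, c("train", "test"))
    expect_equal(sum(mine$role == "train"), 2L)
  }
  sp1 <- split_spec(m, n_train = 1)
  expect_equal(sum(sp1$role == "train"), 2L)

  m$side <- rep(c("left", "left", "right", "right"), 2)
  sps <- split_spec(m, by_side = TRUE)
  a <- sps[sps$subject_id == "A", ]
  expect_equal(a$role[a$image_path %in% c("i1.png", "i3.png")], c("train", "train"))
})

test_that("evaluation counts ranks into cumulative rank-k rates", {
  # scripted outcomes: true ranks 12 (out of list), 1, 3, 1, 1, ...
  enroll <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120)
  probe <- enroll + 1
  probe[1] <- 230  # own record (10) ends up farthest of all twelve
  probe[3] <- 44   # two competitors (40, 50) closer than own 30
  co <- scripted_cohort(enroll, probe)
  res <- evaluate_cohort(co$manifest, config = stub_config(), image_dir = co$dir)
  ranks <- res$per_probe$rank[order(res$per_probe$true_id)]
  expect_equal(ranks[1:4], c(NA, 1L, 3L, 1L))
  expect_equal(res$n_probes, 12L)
  expect_equal(res$rate_at_k[1], 10 / 12)
  expect_equal(res$rate_at_k[3], 11 / 12)
  expect_equal(res$rate_at_k[10], 11 / 12)
  expect_true(all(diff(res$rate_at_k) >= 0))

  # probing with exact copies of the enrollment images is perfect
  res2 <- evaluate_cohort(scripted_cohort(enroll, enroll)$manifest,
                          config = stub_config(),
                          image_dir = scripted_cohort(enroll, enroll)$dir)
  expect_equal(res2$rate_at_k[1], 1.0)
})

test_that("derived four-probe example: ranks {1,1,3,12} give 0.5 and 0.75", {
  hits <- function(ranks, k) mean(!is.na(ranks) & ranks <= k)
  ranks <- c(1L, 1L, 3L, NA)  # rank 12 falls outside the top-10 list
  expect_equal(hits(ranks, 1), 0.5)
  expect_equal(hits(ranks, 10), 0.75)
})

test_that("rates are invariant to gallery enrollment order", {
  enroll <- c(15, 30, 45, 60, 75, 90)
  probe <- enroll + c(2, -3, 4, 1, -2, 3)
  co <- scripted_cohort(enroll, probe)
  res <- evaluate_cohort(co$manifest, config = stub_config(), image_dir = co$dir)
  perm <- co$manifest[rev(seq_len(nrow(co$manifest))), ]
  res_perm <- evaluate_cohort(perm, config = stub_config(), image_dir = co$dir)
  expect_equal(res_perm$rate_at_k, res$rate_at_k)
})

test_that("adding a distractor subject never raises any rate", {
  enroll <- c(10, 30, 50, 70, 90)
  probe <- enroll + c(4, -4, 6, -5, 4)
  base <- scripted_cohort(enroll, probe)
  res <- evaluate_cohort(base$manifest, config = stub_config(), image_dir = base$dir)
  # distractor lands near subject 3's probe value
  more <- scripted_cohort(c(enroll, 57), c(probe, 57))
  res2 <- evaluate_cohort(more$manifest, config = stub_config(), image_dir = more$dir)
  keep <- res2$per_probe$true_id != "P06"
  hits2 <- vapply(1:10, function(k) {
    mean(!is.na(res2$per_probe$rank[keep]) & res2$per_probe$rank[keep] <= k)
  }, numeric(1))
  expect_true(all(hits2 <= res$rate_at_k))
})

test_that("strategy presets encode the published technique grids", {
  t5 <- strategy_presets("table5")
  expect_length(t5, 6L)
  expect_false(t5$one$use_crop)
  expect_false(t5$one$use_hist_eq)
  expect_true(t5$two$use_hist_eq)   # HE without crop: the order-sensitivity probe
  expect_false(t5$two$use_crop)
  expect_true(all(unlist(t5$six[c("use_crop", "use_resize", "use_hist_eq",
                                  "use_concatenation", "use_gender_filter")])))
  t6 <- strategy_presets("table6")
  expect_length(t6, 5L)
  expect_true(all(vapply(t6, `[[`, logical(1), "use_crop")))
  expect_true(all(unlist(t6$all_techniques[c("use_hist_eq", "use_concatenation",
                                             "use_gender_filter")])))
})

test_that("identical strategies produce identical results and CSV output rounds to 2 dp", {
  enroll <- c(12, 34, 56, 78)
  co <- scripted_cohort(enroll, enroll + 2)
  two <- run_ablation(co$manifest, strategies = list(a = stub_config(), b = stub_config()),
                      image_dir = co$dir)
  expect_equal(two$results$a$rate_at_k, two$results$b$rate_at_k)
  csv <- tempfile(fileext = ".csv")
  pp <- tempfile(fileext = ".csv")
  write_evaluation_csv(two$results, csv, pp)
  tab <- read.csv(csv)
  expect_equal(names(tab)[1:3], c("strategy", "width", "n_probes"))
  expect_true(all(tab$rank1 == round(tab$rank1, 2)))
  expect_equal(nrow(read.csv(pp)), 2L * two$results$a$n_probes)
})

test_that("resize sweep is consistent with plain evaluation", {
  co <- mini_cohort()
  sw <- resize_sweep(co$manifest, co$rois, widths = c(100L, 100L),
                     image_dir = co$dir)
  expect_equal(nrow(sw$summary), 2L)
  expect_equal(sw$summary$rank1[1], sw$summary$rank1[2])  # duplicate widths agree
  single <- evaluate_cohort(co$manifest, co$rois,
                            config = pipeline_config(use_hist_eq = FALSE,
                                                     use_concatenation = FALSE,
                                                     use_gender_filter = FALSE,
                                                     target_width = 100L),
                            image_dir = co$dir)
  expect_equal(sw$summary$rank1[1], single$rate_at_k[1])
})
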