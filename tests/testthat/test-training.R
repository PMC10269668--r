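test_that("slide_windows produces the documented arithmetic progression", {
  s <- random_dna(2500, 1)
  w <- slide_windows(s, 1000, 500)
  expect_equal(w$start, c(0, 500, 1000, 1500))
  expect_equal(w$end, c(1000, 1500, 2000, 2500))
  expect_equal(nchar(w$seq), rep(1000L, 4))
  expect_equal(w$seq[2], substr(s, 501, 1500))
  expect_equal(nrow(slide_windows(random_dna(800, 2), 1000, 500)), 0)
  w1 <- slide_windows(random_dna(1000, 3), 1000, 500)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(0, 1000))
  # non-overlapping windows reconstruct the covered prefix
  s2 <- random_dna(1050, 4)
  w2 <- slide_windows(s2, 200, 0)
  expect_equal(paste(w2$seq, collapse = ""), substr(s2, 1, 1000))
})

test_that("default window grid pairs sizes with their overlaps", {
  sp <- default_window_specs()
  expect_equal(sp$window,
               c(500000, 200000, 100000, 50000, 20000, 10000, 5000, 2000,
                 1000, 500))
  expect_equal(sp$overlap,
               c(50000, 20000, 10000, 5000, 2000, 1000, 500, 200, 100, 50))
  expect_true(all(sp$overlap < sp$window))
  expect_equal(nrow(default_window_specs(max_window = 10000)), 5)
})

test_that("training-set construction samples, caps, and filters chromosomes", {
  reps <- tibble::tibble(
    id = c("chr_small", "plas"),
    seq = c(random_dna(10000, 1), random_dna(10000, 2)),
    label = c("chromosome", "plasmid"))
  spec <- tibble::tibble(window = 500L, overlap = 50L)
  # short chromosome contributes nothing under the default 500-kb filter
  ts <- build_training_set(reps, spec, sample_frac = 1, seed = 1)
  expect_true(all(ts$label == "plasmid"))
  # with the filter lowered both contribute; each replicon has
  # floor((10000-500)/450)+1 = 22 windows
  ts2 <- build_training_set(reps, spec, sample_frac = 1,
                            chrom_min_len = 1000L, seed = 1)
  expect_equal(nrow(ts2), 44)
  # 80% draw: floor(0.8 * 44) = 35
  ts3 <- build_training_set(reps, spec, sample_frac = 0.8,
                            chrom_min_len = 1000L, seed = 1)
  expect_equal(nrow(ts3), 35)
  # cap truncates the draw
  ts4 <- build_training_set(reps, spec, sample_frac = 0.8, cap = 10L,
                            chrom_min_len = 1000L, seed = 1)
  expect_equal(nrow(ts4), 10)
  # without replacement, reproducible under seed
  expect_equal(anyDuplicated(ts3$window_id), 0)
  expect_identical(ts3, build_training_set(reps, spec, sample_frac = 0.8,
                                           chrom_min_len = 1000L, seed = 1))
})

test_that("a linearly separable toy trains to perfect holdout accuracy", {
  set.seed(2)
  feats <- dplyr::bind_rows(
    purrr::map(1:150, ~ make_feature_row(paste0("c", .x), "chromosome",
                                         r_k18 = 1, rp = 1)),
    purrr::map(1:150, ~ make_feature_row(paste0("p", .x), "plasmid",
                                         p_k25 = 1)))
  m <- train_plasmid_model(feats, ntrees = 100, seed = 1)
  expect_equal(m$holdout_metrics$accuracy, 1)
  expect_equal(m$holdout_metrics$auc, 1)
  # deterministic under a fixed seed
  m2 <- train_plasmid_model(feats, ntrees = 100, seed = 1)
  expect_identical(unclass(m$holdout_confusion), unclass(m2$holdout_confusion))
  expect_identical(predict(m, feats), predict(m2, feats))
  # importance: the separating feature ranks first, sums to one
  imp <- feature_importance(m)
  expect_equal(nrow(imp), 26)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(imp$feature[1] %in% c("r_k18", "p_k25", "rp"))
  expect_error(train_plasmid_model(feats[1:150, ], seed = 1), "2 classes")
})

test_that("repeated training returns one metrics row per repetition", {
  feats <- dplyr::bind_rows(
    purrr::map(1:60, ~ make_feature_row(paste0("c", .x), "chromosome",
                                        r_k18 = 1)),
    purrr::map(1:60, ~ make_feature_row(paste0("p", .x), "plasmid",
                                        p_k25 = 1)))
  reps <- repeated_training(feats, ntrees = 50, repetitions = 3, seed = 9)
  expect_equal(nrow(reps), 3)
  expect_equal(reps$repetition, 1:3)
  one <- train_plasmid_model(feats, ntrees = 50, seed = 9)
  expect_equal(reps$accuracy[1], one$holdout_metrics$accuracy)
  # stability on the separable fixture
  expect_lt(diff(range(reps$accuracy)), 0.05)
})

test_that("models round-trip through their serialized container", {
  m <- tiny_model()
  path <- withr::local_tempfile()
  write_plasmid_model(m, path)
  m2 <- read_plasmid_model(path)
  expect_identical(m2$feature_order, feature_order())
  g <- tiny_genome()
  f <- extract_features(
    tibble::tibble(id = "w", seq = substr(g$replicons$seq[2], 1, 1000)),
    tiny_dbs(), g$markers)
  expect_identical(predict(m, f), predict(m2, f))
  bad <- m
  bad$format_version <- "other/0"
  saveRDS(bad, path)
  expect_error(read_plasmid_model(path), "format")
})

test_that("tidy and glance expose importance and holdout summaries", {
  m <- tiny_model()
  td <- tidy(m)
  expect_named(td, c("feature", "importance"))
  gl <- glance(m)
  expect_equal(gl$ntrees, 200L)
  expect_true(all(c("accuracy", "sensitivity", "specificity", "auc")
                  %in% names(gl)))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
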