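# Segmentation, 2-D expansion, standardization, and split planning.

test_that("non-overlapping 178-point windows give 23 segments per 4096-point file", {
  rec <- toy_recording(4096)
  cfg <- segmentation_config(preset = "ucistyle")
  segs <- segment_recording(rec, cfg, 0L)
  expect_length(segs, 23)
  expect_equal(segs[[1]]$origin$start, 0)
  expect_equal(segs[[1]]$origin$end, 178)
  expect_equal(segs[[23]]$origin$end, 23 * 178)
  expect_identical(segs[[2]]$values, rec$samples[179:356])
})

test_that("a window equal to the recording yields one segment; shorter recordings error", {
  rec <- toy_recording(4096)
  cfg <- segmentation_config(window_pts = 4096)
  segs <- segment_recording(rec, cfg, 1L)
  expect_length(segs, 1)
  expect_identical(segs[[1]]$values, rec$samples)
  expect_error(segment_recording(toy_recording(100), cfg, 0L), "shorter")
})

test_that("segment counts match a brute-force window enumerator", {
  set.seed(7)
  for (trial in 1:50) {
    len <- sample(50:400, 1)
    window <- sample(10:45, 1)
    overlap <- sample(c(0, 0.25, 0.5, 0.9), 1)
    cfg <- segmentation_config(window_pts = window, overlap_frac = overlap)
    stride <- max(1L, as.integer(round(window * (1 - overlap))))
    rec <- eeg_recording(seq_len(len), set_label = "A", source_id = "x")
    got <- length(segment_recording(rec, cfg, 0L))
    expect_equal(got, oracle_segment_count(len, window, stride),
                 info = sprintf("len=%d window=%d overlap=%g", len, window, overlap))
  }
})

test_that("factorize_length matches the enumeration oracle and the canonical values", {
  expect_equal(as.integer(factorize_length(342)), c(19, 18))
  expect_equal(attr(factorize_length(342), "padded_len"), 342)
  expect_equal(as.integer(factorize_length(4)), c(2, 2))
  expect_equal(as.integer(factorize_length(178)), c(15, 12))
  expect_equal(attr(factorize_length(178), "padded_len"), 180)
  for (L in 2:300) {
    o <- oracle_factorize(L)
    got <- factorize_length(L)
    expect_equal(as.integer(got), o[1:2], info = paste("L =", L))
    expect_equal(attr(got, "padded_len"), o[3], info = paste("L =", L))
    expect_lte(got[1] / got[2], 2)
  }
})

test_that("expand_dims fills row-major with trailing zeros and inverts exactly", {
  expect_equal(expand_dims(c(1, 2, 3, 4), 2, 2),
               matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  seg <- seq_len(342)
  m <- expand_dims(seg, 19, 18)
  expect_equal(m[1, ], as.numeric(1:18))
  seg178 <- rnorm(178)
  m2 <- expand_dims(seg178, 15, 12)
  expect_equal(as.vector(t(m2))[179:180], c(0, 0))
  expect_equal(flatten_matrix(m2, 178), seg178)
  expect_error(expand_dims(seq_len(10), 3, 3), "cannot hold")

  set.seed(3)
  for (trial in 1:20) {
    L <- sample(5:120, 1)
    hw <- factorize_length(L)
    v <- rnorm(L)
    expect_equal(flatten_matrix(expand_dims(v, hw[1], hw[2]), L), v)
  }
})

test_that("batched expansion agrees with per-segment expand_dims", {
  set.seed(4)
  V <- matrix(rnorm(5 * 11), 5, 11)
  hw <- factorize_length(11)
  X <- capseeg:::expand_segment_set(V, hw[1], hw[2])
  for (i in 1:5)
    expect_equal(matrix(X[i, , ], hw[1], hw[2]), expand_dims(V[i, ], hw[1], hw[2]))
})

test_that("standardization uses training statistics only", {
  V <- rbind(c(0, 0), c(2, 2), c(10, 10))
  out <- standardize(V, train_idx = 1:2)
  expect_equal(out$mean, 1)
  expect_equal(out$sd, 1)
  expect_equal(out$values[1:2, ], rbind(c(-1, -1), c(1, 1)))
  expect_equal(out$values[3, ], c(9, 9))  # test row scaled by train stats
  expect_equal(mean(out$values[1:2, ]), 0)
  expect_error(standardize(rbind(c(1, 1), c(1, 1))), "zero variance")
  # reuse of stored statistics reproduces the transform
  out2 <- standardize(V, stats = list(mean = out$mean, sd = out$sd))
  expect_equal(out2$values, out$values)
})

test_that("make_splits is a stratified leak-free 7:3 partition with 3 folds", {
  y <- rep(0:1, c(40, 20))
  plan <- make_splits(y, seed = 5)
  expect_s3_class(plan, "split_plan")
  expect_length(intersect(plan$train_idx, plan$test_idx), 0)
  expect_equal(sort(c(plan$train_idx, plan$test_idx)), 1:60)
  expect_lte(abs(length(plan$train_idx) - 0.7 * 60), 1)
  # folds partition the training indices
  vals <- lapply(plan$folds, `[[`, "val")
  expect_equal(sort(unlist(vals)), sort(plan$train_idx))
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_equal(sort(c(f$train, f$val)), sort(plan$train_idx))
  }
  # stratification: each part's class-1 share within one segment of global
  for (part in c(list(plan$train_idx, plan$test_idx), vals)) {
    expect_lte(abs(sum(y[part] == 1) - length(part) / 3), 1.0001)
  }
  expect_identical(make_splits(y, seed = 5), plan)     # determinism
  expect_false(identical(make_splits(y, seed = 6)$train_idx, plan$train_idx))
  expect_error(make_splits(rep(0:1, 3), seed = 1), "at least 10")
  expect_error(make_splits(rep(c(0, 1), c(57, 3)), seed = 1), "folds")
})

test_that("every fold's validation part contains every class even at n = 10", {
  y <- rep(0:1, each = 5)
  plan <- make_splits(y, seed = 9)
  for (f in plan$folds) expect_setequal(unique(y[f$val]), 0:1)
})

test_that("segment CSV round-trips values and labels", {
  sets <- tiny_surrogate(1, sets = c("A", "E"))
  case <- dataset_case("A_vs_E", c(A = 0L, E = 1L), 2L)
  segset <- segment_case(build_case(sets, case),
                         segmentation_config(preset = "ucistyle"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_segment_csv(segset, f)
  back <- read_segment_csv(f)
  expect_equal(back$values, segset$values)
  expect_equal(back$class_idx, segset$class_idx)
  expect_equal(ncol(back$values), 178)
})
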