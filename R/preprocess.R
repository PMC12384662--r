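# Sliding-window segmentation, dimensionality expansion of 1-D segments into
# small 2-D matrices, training-statistics standardization, and the 7:3 split
# with three-fold cross-validation plans.

#' Segmentation configuration
#'
#' A fixed sliding window of `window_s` seconds with fractional overlap
#' `overlap_frac` (0 means non-overlapping windows). Two named presets pin
#' the window to a point count rather than a duration: `"table1"` uses
#' 342-point segments, which expand to a 19 x 18 matrix, and `"ucistyle"`
#' uses 178-point segments (the one-row-per-segment CSV layout), zero-padded
#' to 180 and expanded to 15 x 12. The default (`"auto"`) derives the point
#' count from `round(window_s * fs)`.
#'
#' @param window_s window length in seconds (default 1.0).
#' @param overlap_frac overlap as a fraction of the window, in [0, 1).
#' @param fs sampling rate in Hz.
#' @param preset one of "auto", "table1", "ucistyle".
#' @param window_pts optional explicit point count, overriding `window_s`.
#' @return an object of class `segmentation_config` with fields `window_pts`
#'   (the raw window), and `h`, `w`, `padded_len` (the 2-D expansion, via
#'   [factorize_length()]).
#' @export
segmentation_config <- function(window_s = 1.0, overlap_frac = 0,
                                fs = BONN_FS,
                                preset = c("auto", "table1", "ucistyle"),
                                window_pts = NULL) {
  preset <- match.arg(preset)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stopf("overlap_frac must lie in [0, 1), got %s", overlap_frac)
  if (!is.finite(fs) || fs <= 0) stopf("fs must be > 0")
  if (is.null(window_pts)) {
    window_pts <- switch(preset,
      table1   = 342L,
      ucistyle = 178L,
      auto     = as.integer(round(window_s * fs)))
  }
  window_pts <- as.integer(window_pts)
  if (window_pts < 2L) stopf("window must span at least 2 points")
  hw <- factorize_length(window_pts)
  structure(list(window_s = window_pts / fs, overlap_frac = overlap_frac,
                 fs = fs, preset = preset, window_pts = window_pts,
                 h = unname(hw[1L]), w = unname(hw[2L]),
                 padded_len = unname(hw[1L] * hw[2L])),
            class = "segmentation_config")
}

#' @export
print.segmentation_config <- function(x, ...) {
  cat(sprintf(
    "<segmentation_config> %s: %d pts (%.3f s @ %.2f Hz), overlap %.0f%%, grid %dx%d (pad %d)\n",
    x$preset, x$window_pts, x$window_s, x$fs, 100 * x$overlap_frac,
    x$h, x$w, x$padded_len - x$window_pts))
  invisible(x)
}

#' Find the near-square 2-D grid for a segment length
#'
#' Returns the factor pair `(h, w)` with `h >= w` of the smallest integer
#' `L' >= L` whose most-square factorization satisfies the aspect bound
#' `h / w <= 2`; the segment is zero-padded by `L' - L` when `L'` exceeds
#' `L`. This realizes the expansion of a 342-point window into a 19 x 18
#' grid (no padding) and of a 178-point window into 15 x 12 (padding 2),
#' deterministically for any length.
#'
#' @param L segment length in points (>= 2).
#' @return integer vector `c(h, w)` with attribute `padded_len = h * w`.
#' @export
factorize_length <- function(L) {
  L <- as.integer(L)
  if (L < 2L) stopf("segment length must be >= 2, got %d", L)
  for (Lp in L:(2L * L)) {
    w <- max(which(Lp %% seq_len(as.integer(floor(sqrt(Lp)))) == 0L))
    h <- Lp %/% w
    if (h <= 2L * w)
      return(structure(c(h = h, w = w), padded_len = Lp))
  }
  stopf("no admissible factorization for length %d", L) # unreachable: 2k x k
}

#' Cut one recording into fixed-length labelled segments
#'
#' Windows are taken at stride `window_pts * (1 - overlap_frac)` (rounded,
#' minimum 1 point); the trailing remainder shorter than one window is
#' discarded. Origins are recorded as 0-based half-open intervals into the
#' source samples.
#'
#' @param rec an [eeg_recording].
#' @param cfg a [segmentation_config].
#' @param class_idx 0-based class index attached to every segment.
#' @return list of segments; each has `values`, `class_idx`,
#'   `origin = c(source_id, start, end)`.
#' @export
segment_recording <- function(rec, cfg, class_idx = NA_integer_) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "segmentation_config"))
  n <- length(rec$samples)
  m <- cfg$window_pts
  if (n < m)
    stopf("recording %s has %d samples, shorter than one %d-point window",
          rec$source_id, n, m)
  stride <- max(1L, as.integer(round(m * (1 - cfg$overlap_frac))))
  starts <- seq.int(0L, n - m, by = stride)
  lapply(starts, function(s) {
    list(values = rec$samples[(s + 1L):(s + m)],
         class_idx = as.integer(class_idx),
         origin = list(source_id = rec$source_id, start = s, end = s + m))
  })
}

#' Segment a whole labelled case into a segment set
#'
#' Applies [segment_recording()] to every recording of a case (as returned
#' by [build_case()]) and stacks the results into a dense segment set: a
#' numeric matrix `values` (one row per segment), an integer label vector,
#' and an origin table.
#'
#' @param recordings list of labelled recordings (with `$class_idx`).
#' @param cfg a [segmentation_config].
#' @return an object of class `segment_set` with fields `values`
#'   (n x window_pts matrix), `class_idx`, `origin` (data.frame), `cfg`.
#' @export
segment_case <- function(recordings, cfg) {
  segs <- unlist(lapply(recordings, function(r) {
    if (is.null(r$class_idx)) stopf("recording %s has no class label", r$source_id)
    segment_recording(r, cfg, r$class_idx)
  }), recursive = FALSE)
  values <- do.call(rbind, lapply(segs, `[[`, "values"))
  origin <- data.frame(
    source_id = vapply(segs, function(s) s$origin$source_id, character(1)),
    start = vapply(segs, function(s) s$origin$start, numeric(1)),
    end = vapply(segs, function(s) s$origin$end, numeric(1)))
  structure(list(values = values,
                 class_idx = vapply(segs, `[[`, integer(1), "class_idx"),
                 origin = origin, cfg = cfg),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d points, classes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d (n=%d)", as.integer(names(table(x$class_idx))),
                            as.integer(table(x$class_idx))), collapse = ", ")))
  invisible(x)
}

#' Expand a 1-D segment into its 2-D matrix
#'
#' Row-major fill: the first `w` values form row 1, the next `w` row 2, and
#' so on; positions beyond the segment length are zero. The operation is
#' invertible on the unpadded prefix (see [flatten_matrix()]).
#'
#' @param values numeric segment vector.
#' @param h,w grid dimensions with `h * w >= length(values)`.
#' @return an `h x w` matrix.
#' @export
expand_dims <- function(values, h, w) {
  L <- length(values)
  if (h * w < L)
    stopf("grid %dx%d = %d cannot hold a %d-point segment", h, w, h * w, L)
  matrix(c(values, numeric(h * w - L)), nrow = h, ncol = w, byrow = TRUE)
}

#' Flatten a segment matrix back to the 1-D segment
#'
#' Inverse of [expand_dims()]: row-major read-out, trailing pad removed when
#' the original length is given.
#'
#' @param grid matrix from [expand_dims()].
#' @param orig_len original (unpadded) segment length; default keeps all.
#' @return numeric vector.
#' @export
flatten_matrix <- function(grid, orig_len = length(grid)) {
  as.vector(t(grid))[seq_len(orig_len)]
}

# Stack a segment-set value matrix into a (n, h, w) array of expanded
# matrices, zero-padding each row-major. Vectorized: row-major fill of all
# segments at once.
expand_segment_set <- function(values, h, w) {
  n <- nrow(values)
  L <- ncol(values)
  padded <- cbind(values, matrix(0, n, h * w - L))
  # padded[i, ] row-major into (h, w): arrange as (n, w, h) then swap
  aperm(array(as.vector(padded), dim = c(n, w, h)), c(1L, 3L, 2L))
}

#' Standardize segments with training-set statistics
#'
#' Z-scores every segment value with the pooled mean and (population)
#' standard deviation of the training segments only; the test portion reuses
#' the training statistics, so no information leaks across the split.
#'
#' @param values n x L segment matrix.
#' @param train_idx row indices (1-based) of the training segments.
#' @param stats optional precomputed `list(mean, sd)` to apply (e.g. at test
#'   time); when given, `train_idx` is ignored.
#' @return `list(values, mean, sd)` with the transformed matrix.
#' @export
standardize <- function(values, train_idx = seq_len(nrow(values)), stats = NULL) {
  if (is.null(stats)) {
    if (length(train_idx) == 0L) stopf("no training segments to standardize from")
    x <- values[train_idx, , drop = FALSE]
    mu <- mean(x)
    sd_ <- sqrt(mean((x - mu)^2))
    if (sd_ <= 0) stopf("training segments have zero variance")
    stats <- list(mean = mu, sd = sd_)
  }
  list(values = (values - stats$mean) / stats$sd,
       mean = stats$mean, sd = stats$sd)
}

#' Shuffle, split 7:3, and plan three-fold cross-validation
#'
#' Segments are shuffled with the given seed, partitioned into training and
#' testing portions at `1 - test_frac : test_frac` (default 7:3), and the
#' training portion is divided into `n_folds` validation folds. Everything
#' is stratified by class: each class's share of every part is within one
#' segment of its global share. The validation folds partition the training
#' indices exactly.
#'
#' @param class_idx integer vector of 0-based class labels, one per segment.
#' @param seed RNG seed for the shuffle.
#' @param test_frac held-out fraction (default 0.3).
#' @param n_folds number of cross-validation folds over the training portion.
#' @return an object of class `split_plan`: `train_idx`, `test_idx`, `folds`
#'   (list of `list(train, val)`), `seed`.
#' @export
make_splits <- function(class_idx, seed, test_frac = 0.3, n_folds = 3L) {
  n <- length(class_idx)
  if (n < 10L) stopf("need at least 10 segments to split, got %d", n)
  classes <- sort(unique(class_idx))
  set.seed(derive_seed(seed, "split"))
  perm_by_class <- lapply(classes, function(k) sample(which(class_idx == k)))

  # largest-remainder allocation keeps the overall train count at
  # round((1 - test_frac) * n) while every class stays within one segment
  # of its own 7:3 cut
  n_c <- vapply(perm_by_class, length, integer(1))
  tgt <- (1 - test_frac) * n_c
  n_train_c <- floor(tgt)
  short <- round((1 - test_frac) * n) - sum(n_train_c)
  if (short > 0) {
    bump <- order(tgt - n_train_c, decreasing = TRUE)[seq_len(short)]
    n_train_c[bump] <- n_train_c[bump] + 1L
  }

  train_idx <- integer(0); test_idx <- integer(0)
  folds <- replicate(n_folds, integer(0), simplify = FALSE)
  for (j in seq_along(classes)) {
    p <- perm_by_class[[j]]
    tr <- p[seq_len(n_train_c[j])]
    if (length(tr) < n_folds)
      stopf("class %d has only %d training segments (< %d folds)",
            classes[j], length(tr), n_folds)
    train_idx <- c(train_idx, tr)
    test_idx <- c(test_idx, p[-seq_len(n_train_c[j])])
    fold_of <- rep(seq_len(n_folds), length.out = length(tr))
    for (f in seq_len(n_folds)) folds[[f]] <- c(folds[[f]], tr[fold_of == f])
  }
  plan <- list(
    train_idx = train_idx, test_idx = test_idx,
    folds = lapply(folds, function(v) list(train = setdiff(train_idx, v),
                                           val = v)),
    seed = seed, test_frac = test_frac)
  class(plan) <- "split_plan"
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / test %d, %d folds, seed %d\n",
              length(x$train_idx), length(x$test_idx), length(x$folds), x$seed))
  invisible(x)
}

#' Write a segment set as CSV (one row per segment, trailing class column)
#'
#' @param segset a `segment_set`.
#' @param path output path.
#' @param header write a header row (`x1..xL, class`)?
#' @return `path`, invisibly.
#' @export
write_segment_csv <- function(segset, path, header = TRUE) {
  df <- as.data.frame(segset$values)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$class <- segset$class_idx
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' Read a segment CSV back into a segment set
#'
#' Expects the layout written by [write_segment_csv()]: numeric columns then
#' one trailing integer class column.
#'
#' @param path CSV path.
#' @param header does the file carry a header row?
#' @param fs sampling rate used to reconstruct the window duration.
#' @return a `segment_set` (origins are synthesized from row numbers).
#' @export
read_segment_csv <- function(path, header = TRUE, fs = BONN_FS) {
  df <- utils::read.csv(path, header = header)
  if (ncol(df) < 2L) stopf("%s: need at least one value column plus a class column", path)
  values <- as.matrix(df[, -ncol(df), drop = FALSE])
  storage.mode(values) <- "double"
  cls <- as.integer(df[[ncol(df)]])
  cfg <- segmentation_config(fs = fs, window_pts = ncol(values))
  structure(list(values = unname(values), class_idx = cls,
                 origin = data.frame(source_id = sprintf("csv:%d", seq_len(nrow(values))),
                                     start = 0, end = ncol(values)),
                 cfg = cfg),
            class = "segment_set")
}
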