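# Stream segmentation, dataset assembly, cross-validation folds and
# per-channel standardization.
#
# Conventions: channel order is ax, ay, az, gx, gy, gz everywhere;
# annotation epochs are half-open [start, end) in 0-based sample indices; a
# window must lie entirely inside exactly one single-label epoch.

CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

#' A collection of labeled windows from one domain
#'
#' @param windows List of [imu_window] objects.
#' @param class_names Ordered label set; defaults to sorted unique labels.
#' @param splits Optional fold/split assignment from [make_folds()].
#' @return A `domain_dataset`.
#' @export
domain_dataset <- function(windows, class_names = NULL, splits = NULL) {
  if (!length(windows)) stop("dataset has no windows", call. = FALSE)
  labels <- vapply(windows, `[[`, "", "label")
  if (is.null(class_names)) class_names <- sort(unique(labels))
  if (!all(labels %in% class_names))
    stop("window labels outside class_names", call. = FALSE)
  structure(list(windows = windows, class_names = class_names,
                 splits = splits), class = "domain_dataset")
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset> %d windows, %d classes (%s)%s\n",
              length(x$windows), length(x$class_names),
              paste(x$class_names, collapse = ", "),
              if (is.null(x$splits)) "" else ", folds assigned"))
  invisible(x)
}

#' @export
length.domain_dataset <- function(x) length(x$windows)

dataset_labels <- function(ds) {
  match(vapply(ds$windows, `[[`, "", "label"), ds$class_names)
}

# Stack windows into the engine's activation layout: (T*B) x 6 matrix with
# time fastest, plus integer labels.
dataset_tensor <- function(ds, idx = seq_along(ds$windows)) {
  T <- ncol(ds$windows[[1]]$x)
  B <- length(idx)
  X <- matrix(0, T * B, 6)
  for (j in seq_along(idx))
    X[(j - 1) * T + seq_len(T), ] <- t(ds$windows[[idx[j]]]$x)
  attr(X, "dims") <- c(T = T, B = B)
  list(X = X, y = dataset_labels(ds)[idx], T = T, B = B)
}

#' An annotated multichannel sensor stream
#'
#' @param samples Numeric matrix, one row per sample, columns ax..gz.
#' @param fs_hz Sampling rate in Hz.
#' @param annotations Data frame with columns `start`, `end` (half-open,
#'   0-based sample indices) and `label`.
#' @param subject_id,domain_tag Metadata strings.
#' @return An `annotated_stream`.
#' @export
annotated_stream <- function(samples, fs_hz, annotations,
                             subject_id = "unknown", domain_tag = "unknown") {
  samples <- as.matrix(samples)
  if (ncol(samples) != 6) stop("samples must have 6 channels", call. = FALSE)
  if (anyNA(samples)) stop("samples contain NA/NaN", call. = FALSE)
  ann <- annotations[order(annotations$start), , drop = FALSE]
  n <- nrow(samples)
  for (i in seq_len(nrow(ann))) {
    if (ann$start[i] < 0 || ann$end[i] > n || ann$end[i] <= ann$start[i])
      stop(sprintf("epoch %d ([%d,%d), '%s') out of range for %d samples",
                   i, ann$start[i], ann$end[i], ann$label[i], n),
           call. = FALSE)
    if (i > 1 && ann$start[i] < ann$end[i - 1])
      stop(sprintf("epoch %d overlaps epoch %d", i, i - 1), call. = FALSE)
  }
  structure(list(samples = samples, fs_hz = fs_hz, annotations = ann,
                 subject_id = subject_id, domain_tag = domain_tag),
            class = "annotated_stream")
}

#' Segment an annotated stream into fixed-length windows
#'
#' Within each retained epoch, windows of `window_s` seconds start every
#' `round(fs * window_s * (1 - overlap_frac))` samples from the epoch start;
#' only windows fully inside the epoch are emitted, so no window ever
#' crosses an annotation boundary. Epochs shorter than `min_epoch_s` are
#' dropped. Epochs at least `min_epoch_s` but shorter than one full window
#' yield zero windows (no padding is invented).
#'
#' @param stream An [annotated_stream()].
#' @param window_s Window length (s), default 2.
#' @param overlap_frac Fractional overlap in `[0, 1)`, default 0.5.
#' @param min_epoch_s Minimum epoch duration kept (s), default 1.
#' @return List of [imu_window] objects.
#' @export
segment_stream <- function(stream, window_s = 2, overlap_frac = 0.5,
                           min_epoch_s = 1) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
  T <- round(stream$fs_hz * window_s)
  stride <- round(stream$fs_hz * window_s * (1 - overlap_frac))
  if (stride < 1) stop("stride below one sample; decrease overlap_frac",
                       call. = FALSE)
  min_len <- round(stream$fs_hz * min_epoch_s)
  out <- list()
  for (i in seq_len(nrow(stream$annotations))) {
    a <- stream$annotations[i, ]
    L <- a$end - a$start
    if (L < min_len || L < T) next
    starts <- seq(0, L - T, by = stride)
    for (s in starts) {
      seg <- stream$samples[(a$start + s + 1):(a$start + s + T), , drop = FALSE]
      out[[length(out) + 1]] <- imu_window(t(seg), a$label,
                                           domain = stream$domain_tag,
                                           subject = stream$subject_id)
    }
  }
  out
}

#' Read a long-format CSV stream
#'
#' Expects columns `timestamp, ax, ay, az, gx, gy, gz, label` (renameable
#' through `column_map`). Contiguous runs of one label become annotation
#' epochs; empty or `"unlabeled"` labels break epochs and contribute no
#' data.
#'
#' @param path CSV file path.
#' @param fs_hz Sampling rate of the recording.
#' @param column_map Optional named character vector mapping the expected
#'   names (`timestamp`, `ax`, ..., `label`) to the file's column names.
#' @param subject_id,domain_tag Metadata strings.
#' @return An [annotated_stream()].
#' @export
read_csv_stream <- function(path, fs_hz = 100, column_map = NULL,
                            subject_id = "unknown", domain_tag = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("timestamp", CHANNELS, "label")
  names_map <- stats::setNames(want, want)
  if (!is.null(column_map)) names_map[names(column_map)] <- column_map
  missing <- setdiff(names_map, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  ts <- df[[names_map[["timestamp"]]]]
  if (any(diff(ts) <= 0))
    stop("non-monotone timestamps at row(s): ",
         paste(utils::head(which(diff(ts) <= 0) + 1, 5), collapse = ", "),
         call. = FALSE)
  X <- as.matrix(df[, names_map[CHANNELS]])
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite sensor values at row(s): ",
         paste(unique(utils::head(bad[, 1], 5)), collapse = ", "),
         " (column ", CHANNELS[bad[1, 2]], ")", call. = FALSE)
  colnames(X) <- CHANNELS
  lab <- as.character(df[[names_map[["label"]]]])
  lab[is.na(lab) | lab == "" | tolower(lab) == "unlabeled"] <- ""
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != ""
  ann <- data.frame(start = starts[keep], end = ends[keep],
                    label = r$values[keep], stringsAsFactors = FALSE)
  annotated_stream(X, fs_hz, ann, subject_id, domain_tag)
}

#' Assign stratified cross-validation folds and train/val/test splits
#'
#' Windows are assigned to `n_folds` folds stratified by class so the folds'
#' test sets partition the dataset. Within each fold, the non-test windows
#' are split 3:1 into train and validation (i.e. test = 20%, then val = 25%
#' of the remainder), again stratified by class; all assignments are seeded
#' and reproducible.
#'
#' @param dataset A [domain_dataset()].
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param group_by_subject If `TRUE`, whole subjects are kept in one fold
#'   (off by default: the reference protocol splits windows, not subjects).
#' @return The dataset with a `splits` element: `fold` (test-fold index,
#'   0-based, per window) and `role`, an `n x n_folds` character matrix of
#'   `"train"/"val"/"test"`.
#' @export
make_folds <- function(dataset, n_folds = 5, seed = 1,
                       group_by_subject = FALSE) {
  y <- dataset_labels(dataset)
  n <- length(y)
  counts <- table(factor(y, levels = seq_along(dataset$class_names)))
  if (any(counts < n_folds))
    stop("class '", dataset$class_names[which.min(counts)],
         "' has fewer windows than folds", call. = FALSE)
  fold <- integer(n)
  with_seed(child_seed(seed, "folds"), {
    if (group_by_subject) {
      subj <- vapply(dataset$windows, `[[`, "", "subject")
      us <- sample(unique(subj))
      sf <- rep_len(0:(n_folds - 1), length(us))
      fold <- sf[match(subj, us)]
    } else {
      for (c in seq_along(dataset$class_names)) {
        idx <- sample(which(y == c))
        fold[idx] <- rep_len(0:(n_folds - 1), length(idx))
      }
    }
  })
  role <- matrix("", n, n_folds)
  for (f in 0:(n_folds - 1)) {
    role[fold == f, f + 1] <- "test"
    rest <- which(fold != f)
    with_seed(child_seed(seed, "trainval", f), {
      for (c in seq_along(dataset$class_names)) {
        idx <- sample(intersect(rest, which(y == c)))
        nv <- round(length(idx) / 4)  # train:val = 3:1
        role[idx[seq_len(nv)], f + 1] <- "val"
        role[setdiff(idx, idx[seq_len(nv)]), f + 1] <- "train"
      }
    })
  }
  dataset$splits <- list(fold = fold, role = role, n_folds = n_folds,
                         seed = seed)
  dataset
}

#' Indices of the train/val/test windows for one fold
#'
#' @param dataset A [domain_dataset()] with folds assigned.
#' @param fold Fold index, 0-based.
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
split_indices <- function(dataset, fold = 0) {
  if (is.null(dataset$splits)) stop("run make_folds() first", call. = FALSE)
  role <- dataset$splits$role[, fold + 1]
  list(train = which(role == "train"), val = which(role == "val"),
       test = which(role == "test"))
}

#' Fit a per-channel standardizer on training windows
#'
#' Computes per-channel mean and standard deviation over all training
#' windows and time points. Channels with zero variance get sd clamped to 1
#' with a warning. The fitted parameters are applied unchanged to
#' validation, test, and target-domain data, so a domain shift in the target
#' survives standardization.
#'
#' @param train_windows List of [imu_window] objects (source-train only).
#' @return A `standardizer` with `mean` and `sd` 6-vectors.
#' @export
fit_standardizer <- function(train_windows) {
  M <- do.call(cbind, lapply(train_windows, `[[`, "x"))
  mu <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("zero-variance channel(s): sd clamped to 1")
    sdv[sdv == 0] <- 1
  }
  structure(list(mean = mu, sd = sdv), class = "standardizer")
}

#' Apply a fitted standardizer to windows
#'
#' @param windows List of [imu_window] objects.
#' @param scaler A `standardizer` from [fit_standardizer()].
#' @return The windows, z-scored per channel.
#' @export
standardize_windows <- function(windows, scaler) {
  lapply(windows, function(w) {
    w$x <- (w$x - scaler$mean) / scaler$sd
    w
  })
}

#' Export fold assignments as a data frame
#'
#' @param dataset A [domain_dataset()] with folds assigned.
#' @return Data frame with `window_id`, `fold`, and one `split_fold<k>`
#'   column per fold.
#' @export
fold_table <- function(dataset) {
  if (is.null(dataset$splits)) stop("run make_folds() first", call. = FALSE)
  out <- data.frame(window_id = seq_along(dataset$windows) - 1L,
                    fold = dataset$splits$fold)
  for (f in seq_len(dataset$splits$n_folds))
    out[[paste0("split_fold", f - 1)]] <- dataset$splits$role[, f]
  out
}

#' Write a domain dataset as a long-format CSV
#'
#' One row per time sample with columns `window_id, domain, label, t, ax,
#' ..., gz`; readable by [read_windows_csv()].
#' @param dataset A [domain_dataset()].
#' @param path Output file.
#' @param fs_hz Sampling rate used for the time column.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(dataset, path, fs_hz = 100) {
  rows <- lapply(seq_along(dataset$windows), function(i) {
    w <- dataset$windows[[i]]
    T <- ncol(w$x)
    df <- as.data.frame(t(w$x))
    names(df) <- CHANNELS
    cbind(data.frame(window_id = i - 1L, domain = w$domain, label = w$label,
                     t = (seq_len(T) - 1) / fs_hz), df)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format window CSV written by [write_windows_csv()]
#'
#' @param path CSV file.
#' @return A [domain_dataset()].
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_id", "domain", "label", CHANNELS)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  ids <- unique(df$window_id)
  windows <- lapply(ids, function(id) {
    d <- df[df$window_id == id, ]
    x <- t(as.matrix(d[, CHANNELS]))
    dimnames(x) <- NULL
    imu_window(x, d$label[1], d$domain[1])
  })
  domain_dataset(windows)
}
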