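#' Sliding-window specifications
#'
#' The standard window/overlap grid used to build training sets spanning
#' contig lengths from 500 kb down to 500 bp: windows of 500 kb, 200 kb,
#' 100 kb, 50 kb, 20 kb, 10 kb, 5 kb, 2 kb, 1 kb and 500 bp with overlaps
#' of 50 kb, 20 kb, 10 kb, 5 kb, 2 kb, 1 kb, 500 bp, 200 bp, 100 bp and
#' 50 bp, respectively.
#'
#' @param max_window Drop strata with windows larger than this (useful for
#'   small genomes; default keeps all ten).
#' @return Tibble with columns `window`, `overlap`.
#' @export
default_window_specs <- function(max_window = Inf) {
  specs <- tibble::tibble(
    window = c(500000L, 200000L, 100000L, 50000L, 20000L,
               10000L, 5000L, 2000L, 1000L, 500L),
    overlap = c(50000L, 20000L, 10000L, 5000L, 2000L,
                1000L, 500L, 200L, 100L, 50L)
  )
  specs[specs$window <= max_window, ]
}

#' Slide a sequence into fixed-size overlapping windows
#'
#' Window starts form the arithmetic progression 0, step, 2*step, ... with
#' `step = window - overlap`; only full windows with `end <= |seq|` are
#' kept (a trailing fragment shorter than the window is dropped, so every
#' example in a stratum has exactly the stratum's length). Coordinates are
#' 0-based half-open.
#'
#' @param seq A single DNA string.
#' @param window,overlap Window and overlap lengths in bp
#'   (`0 <= overlap < window`).
#' @return Tibble with columns `start`, `end`, `seq`.
#' @export
slide_windows <- function(seq, window, overlap) {
  stopifnot(length(seq) == 1, overlap >= 0, overlap < window)
  L <- nchar(seq)
  step <- window - overlap
  if (L < window)
    return(tibble::tibble(start = integer(0), end = integer(0),
                          seq = character(0)))
  starts <- seq.int(0L, L - window, by = step)
  tibble::tibble(
    start = as.integer(starts),
    end = as.integer(starts + window),
    seq = substring(seq, starts + 1L, starts + window)
  )
}

#' Build a sliding-window training set from labelled replicons
#'
#' Chromosomal replicons shorter than `chrom_min_len` (default 500 kb) are
#' excluded to avoid plasmid contamination of the chromosome class. Every
#' remaining replicon is slid at each window specification; within each
#' window-size stratum, `floor(sample_frac * N)` windows are drawn
#' uniformly without replacement and the draw is truncated to `cap`
#' (defaults: 80% and 100,000).
#'
#' @param replicons Tibble with columns `id`, `seq`, `label`
#'   (`"chromosome"` or `"plasmid"`).
#' @param specs Window specification tibble (`window`, `overlap`).
#' @param sample_frac Fraction of windows sampled per stratum, in (0, 1].
#' @param cap Per-stratum ceiling on sampled windows.
#' @param chrom_min_len Minimum chromosome replicon length in bp.
#' @param seed Integer seed controlling the draw.
#' @return Tibble with columns `window_id`, `source_id`, `label`,
#'   `window_size`, `start`, `end`, `seq`.
#' @export
build_training_set <- function(replicons, specs = default_window_specs(),
                               sample_frac = 0.8, cap = 100000L,
                               chrom_min_len = 500000L, seed = 1L) {
  stopifnot(all(c("id", "seq", "label") %in% names(replicons)),
            all(replicons$label %in% c("chromosome", "plasmid")),
            sample_frac > 0, sample_frac <= 1, cap >= 1)
  keep <- replicons$label == "plasmid" |
    nchar(replicons$seq) >= chrom_min_len
  replicons <- replicons[keep, ]
  out <- list()
  for (i in seq_len(nrow(specs))) {
    w <- specs$window[i]
    o <- specs$overlap[i]
    stratum <- dplyr::bind_rows(purrr::map2(
      replicons$id, seq_len(nrow(replicons)),
      function(id, j) {
        win <- slide_windows(replicons$seq[j], w, o)
        if (nrow(win) == 0) return(NULL)
        win$source_id <- id
        win$label <- replicons$label[j]
        win
      }))
    n <- nrow(stratum)
    if (n == 0) {
      warning(sprintf("window size %d bp: no windows; stratum skipped", w))
      next
    }
    n_take <- min(floor(sample_frac * n), cap)
    idx <- local({
      set.seed(seed + i)
      sample.int(n, n_take)
    })
    stratum <- stratum[sort(idx), ]
    stratum$window_size <- w
    out[[length(out) + 1L]] <- stratum
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    return(tibble::tibble(window_id = character(0), source_id = character(0),
                          label = character(0), window_size = integer(0),
                          start = integer(0), end = integer(0),
                          seq = character(0)))
  res$window_id <- sprintf("%s:%d-%d", res$source_id, res$start, res$end)
  res[, c("window_id", "source_id", "label", "window_size", "start", "end",
          "seq")]
}

MODEL_FORMAT <- "plasmidr_model/1"

#' Train the plasmid/chromosome random forest
#'
#' Fits a probability random forest (impurity importance, single thread for
#' determinism) on a seeded 2/3 split of the feature table and evaluates on
#' the remaining 1/3 holdout. Class labels: plasmid is the positive class.
#'
#' @param features Feature table with a `label` column
#'   (`"chromosome"`/`"plasmid"`) and the 26 feature columns.
#' @param ntrees Number of trees (default 500).
#' @param seed Integer seed for the split and the forest.
#' @param train_frac Fraction of rows used for fitting (default 2/3).
#' @return A `plasmid_model`: the fitted forest plus `feature_order`,
#'   `format_version`, `training_summary` (per-class counts),
#'   `holdout_confusion` and `holdout_metrics`.
#' @export
train_plasmid_model <- function(features, ntrees = 500L, seed = 1L,
                                train_frac = 2 / 3) {
  stopifnot("label" %in% names(features),
            all(feature_order() %in% names(features)))
  labs <- features$label
  if (length(unique(labs)) < 2) stop("training data must contain 2 classes")
  x <- as.data.frame(features[, feature_order()])
  if (anyNA(x)) stop("missing values in feature table")
  n <- nrow(x)
  idx <- local({
    set.seed(seed)
    sample.int(n, floor(train_frac * n))
  })
  dat <- cbind(x, .label = factor(labs, levels = c("chromosome", "plasmid")))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = dat[idx, ],
    num.trees = ntrees, probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1
  )
  model <- structure(
    list(forest = fit, ntrees = as.integer(ntrees), seed = as.integer(seed),
         feature_order = feature_order(), format_version = MODEL_FORMAT,
         feature_version = FEATURE_VERSION,
         training_summary = table(labs[idx])),
    class = "plasmid_model"
  )
  hold <- setdiff(seq_len(n), idx)
  if (length(hold) > 0 && length(unique(labs[hold])) == 2) {
    p <- predict(model, features[hold, ])
    cm <- confusion_matrix(labs[hold],
                           ifelse(p >= 0.5, "plasmid", "chromosome"))
    model$holdout_confusion <- cm
    met <- compute_metrics(cm)
    met$auc <- auc_score(p, labs[hold])
    model$holdout_metrics <- met
  }
  model
}

#' @export
print.plasmid_model <- function(x, ...) {
  cat(sprintf("<plasmid_model> %d trees, seed %d, %s\n", x$ntrees, x$seed,
              x$format_version))
  cat("training counts:",
      paste(names(x$training_summary), as.integer(x$training_summary),
            collapse = ", "), "\n")
  if (!is.null(x$holdout_metrics))
    cat(sprintf("holdout: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
                x$holdout_metrics$accuracy, x$holdout_metrics$sensitivity,
                x$holdout_metrics$specificity, x$holdout_metrics$auc))
  invisible(x)
}

#' Predict plasmid probabilities from a fitted model
#'
#' @param object A `plasmid_model`.
#' @param features Feature table containing the 26 feature columns.
#' @param ... Unused.
#' @return Numeric vector of plasmid probabilities in \[0, 1\].
#' @export
predict.plasmid_model <- function(object, features, ...) {
  stopifnot(identical(object$feature_order, feature_order()))
  x <- as.data.frame(features[, object$feature_order])
  pr <- predict(object$forest, data = x, num.threads = 1)$predictions
  unname(pr[, "plasmid"])
}

#' Repeated model construction
#'
#' Re-runs the seeded 2/3--1/3 resampling and fit `repetitions` times
#' (default 100) with independent derived seeds and collects the holdout
#' metrics of each repetition, for dispersion/stability reporting.
#'
#' @inheritParams train_plasmid_model
#' @param repetitions Number of repetitions.
#' @return Tibble of holdout metrics, one row per repetition (column
#'   `repetition` first).
#' @export
repeated_training <- function(features, ntrees = 500L, repetitions = 100L,
                              seed = 1L) {
  stopifnot(repetitions >= 1)
  dplyr::bind_rows(lapply(seq_len(repetitions), function(r) {
    m <- train_plasmid_model(features, ntrees = ntrees, seed = seed + r - 1L)
    dplyr::bind_cols(tibble::tibble(repetition = r), m$holdout_metrics)
  }))
}

#' Impurity-based feature importance
#'
#' Normalised Gini-impurity importance of the 26 features, sorted
#' descending; importances sum to 1.
#'
#' @param model A fitted `plasmid_model`.
#' @return Tibble with columns `feature`, `importance`.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "plasmid_model") || is.null(model$forest))
    stop("need a fitted plasmid_model")
  imp <- ranger::importance(model$forest)
  imp <- imp / sum(imp)
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
tidy.plasmid_model <- function(x, ...) feature_importance(x)

#' @export
glance.plasmid_model <- function(x, ...) {
  out <- tibble::tibble(
    ntrees = x$ntrees, seed = x$seed,
    n_chromosome = as.integer(x$training_summary[["chromosome"]]),
    n_plasmid = as.integer(x$training_summary[["plasmid"]])
  )
  if (!is.null(x$holdout_metrics))
    out <- dplyr::bind_cols(out, x$holdout_metrics[
      , c("accuracy", "sensitivity", "specificity", "f1", "auc")])
  out
}

#' Save / load a fitted model
#'
#' Models are stored as a versioned serialized container embedding the
#' feature order and training summary; the loader rejects unknown format
#' versions.
#'
#' @param model A `plasmid_model`.
#' @param path File path.
#' @return `path` invisibly (write); `plasmid_model` (read).
#' @export
write_plasmid_model <- function(model, path) {
  stopifnot(inherits(model, "plasmid_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_plasmid_model
#' @export
read_plasmid_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "plasmid_model") ||
      !identical(m$format_version, MODEL_FORMAT))
    stop("unknown model format version")
  m
}

#' Plot feature importances
#'
#' @param object A `plasmid_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plasmid_model <- function(object, ...) {
  imp <- feature_importance(object)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "normalised impurity importance", y = NULL) +
    ggplot2::theme_minimal()
}
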