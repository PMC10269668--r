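#' Confusion matrix with plasmid as the positive class
#'
#' @param truth,predicted Character vectors of `"chromosome"`/`"plasmid"`
#'   labels (records with other predicted labels, e.g. `"filtered"`, are
#'   dropped with a message).
#' @param positive Positive-class label (default `"plasmid"`).
#' @return A `confusion_matrix` (named list `tp`, `tn`, `fp`, `fn`).
#' @export
confusion_matrix <- function(truth, predicted, positive = "plasmid") {
  stopifnot(length(truth) == length(predicted))
  keep <- predicted %in% c("chromosome", "plasmid")
  if (!all(keep)) {
    message(sum(!keep), " records with non-binary predicted label dropped")
    truth <- truth[keep]
    predicted <- predicted[keep]
  }
  pos_t <- truth == positive
  pos_p <- predicted == positive
  structure(list(
    tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
    fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d tn=%d fp=%d fn=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' The ten confusion-matrix metrics
#'
#' Computes, with plasmid as positive: sensitivity (plasmid accuracy)
#' tp/(tp+fn), specificity (chromosome accuracy) tn/(tn+fp), accuracy
#' (tp+tn)/total, precision tp/(tp+fp), FNR fn/(tp+fn), FPR fp/(tn+fp),
#' FOR fn/(fn+tn), FDR fp/(fp+tp), NPV tn/(fn+tn) and F1
#' 2(sens*prec)/(sens+prec). A metric whose denominator is zero is
#' reported as `NA` (undefined), never coerced to 0 or 1. `prevalence`
#' ((tp+fn)/total) is always reported alongside, since precision, F1 and
#' accuracy depend on class balance.
#'
#' @param cm A `confusion_matrix`, or a list/tibble with `tp`, `tn`, `fp`,
#'   `fn`.
#' @return One-row tibble with columns `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `precision`, `fnr`, `fpr`,
#'   `for_`, `fdr`, `npv`, `f1`, `prevalence`.
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  div <- function(a, b) if (b > 0) a / b else NA_real_
  total <- tp + tn + fp + fn
  sens <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * (sens * prec) / (sens + prec) else NA_real_
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = sens,
    specificity = div(tn, tn + fp),
    accuracy = div(tp + tn, total),
    precision = prec,
    fnr = div(fn, tp + fn),
    fpr = div(fp, tn + fp),
    for_ = div(fn, fn + tn),
    fdr = div(fp, fp + tp),
    npv = div(tn, fn + tn),
    f1 = f1,
    prevalence = div(tp + fn, total)
  )
}

#' Area under the ROC curve (rank-sum estimator)
#'
#' The Mann-Whitney estimate: the probability that a randomly chosen
#' plasmid receives a higher score than a randomly chosen chromosome, with
#' ties counted 0.5.
#'
#' @param probabilities Numeric scores (higher = more plasmid-like).
#' @param truth Character vector of true labels.
#' @param positive Positive-class label.
#' @return AUC in \[0, 1\]; `NA` if either class is absent.
#' @export
auc_score <- function(probabilities, truth, positive = "plasmid") {
  stopifnot(length(probabilities) == length(truth))
  pos <- truth == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(probabilities)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Balanced down-sampling of predictions
#'
#' Down-samples the majority class uniformly without replacement to the
#' minority-class count, optionally within strata (e.g. per window
#' length), so class-balance-sensitive metrics (precision, accuracy, FDR,
#' F1) are comparable across lengths.
#'
#' @param records Tibble with a `truth` column
#'   (`"chromosome"`/`"plasmid"`).
#' @param seed Integer seed.
#' @param strata Optional name of a column defining strata (e.g.
#'   `"length"`); `NULL` balances globally.
#' @return Subset of `records` with equal class counts (per stratum).
#' @export
balanced_downsample <- function(records, seed = 1L, strata = NULL) {
  stopifnot("truth" %in% names(records))
  balance_one <- function(df, s) {
    n_pos <- sum(df$truth == "plasmid")
    n_neg <- sum(df$truth == "chromosome")
    if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
    minority <- min(n_pos, n_neg)
    majority_label <- if (n_pos > n_neg) "plasmid" else "chromosome"
    maj_idx <- which(df$truth == majority_label)
    keep_maj <- local({
      set.seed(s)
      sample(maj_idx, minority)
    })
    df[sort(c(which(df$truth != majority_label), keep_maj)), ]
  }
  if (is.null(strata)) return(balance_one(records, seed))
  stopifnot(strata %in% names(records))
  groups <- split(seq_len(nrow(records)), records[[strata]])
  out <- lapply(seq_along(groups), function(i)
    balance_one(records[groups[[i]], ], seed + i))
  dplyr::bind_rows(out)
}

#' Truth-label contigs by shared-k-mer bias against their source genome
#'
#' Emulates the benchmark truth-labelling of simulated assemblies: a
#' contig sharing less than `discard_threshold` (default 95%) of its
#' k-mers with the whole reference genome (chromosomes and plasmids
#' jointly) is considered mis-assembled and discarded; every other contig
#' is labelled `"chromosome"` or `"plasmid"` by the larger of its shared
#' fractions against the chromosome set and the plasmid set, with an exact
#' tie discarded as ambiguous.
#'
#' @param contigs Sequence tibble (`id`, `seq`).
#' @param ref_chromosomes,ref_plasmids Reference sequence tibbles.
#' @param k K-mer length for the comparison (default 21).
#' @param discard_threshold Minimum shared fraction with the reference
#'   union.
#' @return Tibble: `id`, `label` (`"chromosome"`, `"plasmid"` or
#'   `"discarded"`), `frac_union`, `frac_chromosome`, `frac_plasmid`,
#'   `reason` (`NA`, `"misassembled"` or `"ambiguous"`).
#' @export
label_contigs_by_kmer_bias <- function(contigs, ref_chromosomes,
                                       ref_plasmids, k = 21L,
                                       discard_threshold = 0.95) {
  stopifnot(nrow(ref_chromosomes) > 0, nrow(ref_plasmids) > 0)
  db_c <- build_kmer_db(ref_chromosomes, k, 1, "chromosome")
  db_p <- build_kmer_db(ref_plasmids, k, 1, "plasmid")
  db_u <- new_kmer_db(k = db_c$k, kmers = sort(union(db_c$kmers, db_p$kmers)),
                      sketch_fraction = 1, label = "union", hash_seed = 42L,
                      source_count = db_c$source_count + db_p$source_count)
  fu <- query_kmer_db(contigs, db_u)$shared_fraction
  fc <- query_kmer_db(contigs, db_c)$shared_fraction
  fp <- query_kmer_db(contigs, db_p)$shared_fraction
  label <- ifelse(fu < discard_threshold, "discarded",
                  ifelse(fc > fp, "chromosome",
                         ifelse(fp > fc, "plasmid", "discarded")))
  reason <- ifelse(fu < discard_threshold, "misassembled",
                   ifelse(fc == fp, "ambiguous", NA_character_))
  reason[label != "discarded"] <- NA_character_
  tibble::tibble(id = contigs$id, label = label, frac_union = fu,
                 frac_chromosome = fc, frac_plasmid = fp, reason = reason)
}

#' Length-stratified metric report
#'
#' One metrics row per minimum-length filter, each computed over the
#' records whose length passes that filter (a 0 threshold reproduces the
#' unfiltered report).
#'
#' @param records Tibble with columns `truth`, `predicted`, `length`.
#' @param bins Numeric vector of minimum-length thresholds in bp
#'   (default `c(0, 500, 1000, 2000)`).
#' @return Tibble: `min_length`, `n`, then the metric columns of
#'   [compute_metrics()].
#' @export
length_stratified_report <- function(records,
                                     bins = c(0, 500, 1000, 2000)) {
  stopifnot(all(c("truth", "predicted", "length") %in% names(records)))
  dplyr::bind_rows(lapply(bins, function(b) {
    sel <- records[records$length >= b, ]
    met <- if (nrow(sel) == 0)
      compute_metrics(list(tp = 0L, tn = 0L, fp = 0L, fn = 0L))
    else compute_metrics(confusion_matrix(sel$truth, sel$predicted))
    dplyr::bind_cols(tibble::tibble(min_length = b, n = nrow(sel)), met)
  }))
}

#' Plot a length-stratified report
#'
#' Line plot of selected metrics against the minimum contig length.
#'
#' @param report Output of [length_stratified_report()].
#' @param metrics Metric columns to draw.
#' @return A ggplot.
#' @export
plot_length_metrics <- function(report,
                                metrics = c("sensitivity", "specificity",
                                            "accuracy", "f1")) {
  long <- tidyr::pivot_longer(report[, c("min_length", metrics)],
                              -"min_length", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$min_length, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "minimum contig length (bp)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
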