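# independent oracle: the ten confusion-matrix formulas, written directly
oracle_metrics <- function(tp, tn, fp, fn) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe(tp, tp + fn); prec <- safe(tp, tp + fp)
  list(
    sensitivity = sens,
    specificity = safe(tn, tn + fp),
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    precision = prec,
    fnr = safe(fn, tp + fn),
    fpr = safe(fp, tn + fp),
    for_ = safe(fn, fn + tn),
    fdr = safe(fp, fp + tp),
    npv = safe(tn, fn + tn),
    f1 = if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
      2 * (sens * prec) / (sens + prec) else NA_real_
  )
}
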