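test_that("compute_metrics reproduces the ten formulas by hand", {
  m <- compute_metrics(list(tp = 9, tn = 8, fp = 2, fn = 1))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$f1, 2 * (0.9 * 9 / 11) / (0.9 + 9 / 11))
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$prevalence, 0.5)
  perfect <- compute_metrics(list(tp = 5, tn = 7, fp = 0, fn = 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$fnr + perfect$fpr + perfect$fdr + perfect$for_, 0)
  # inverting labels swaps sensitivity and specificity
  inv <- compute_metrics(list(tp = 8, tn = 9, fp = 1, fn = 2))
  expect_equal(inv$sensitivity, m$specificity)
  expect_equal(inv$specificity, m$sensitivity)
})

test_that("zero-denominator metrics are undefined, not coerced", {
  all0 <- compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0))
  expect_true(all(is.na(unlist(all0[, 5:15]))))
  no_pos <- compute_metrics(list(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$precision))
  expect_equal(no_pos$specificity, 1)
  expect_equal(no_pos$prevalence, 0)
})

test_that("metrics match an independent oracle on random matrices", {
  set.seed(13)
  for (i in 1:100) {
    cm <- as.list(setNames(sample(0:40, 4, TRUE), c("tp", "tn", "fp", "fn")))
    got <- compute_metrics(cm)
    want <- oracle_metrics(cm$tp, cm$tn, cm$fp, cm$fn)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]])
    # complementary-pair identities
    if (cm$tp + cm$fn > 0) expect_equal(got$sensitivity + got$fnr, 1,
                                        tolerance = 1e-12)
    if (cm$tn + cm$fp > 0) expect_equal(got$specificity + got$fpr, 1,
                                        tolerance = 1e-12)
    if (cm$tp + cm$fp > 0) expect_equal(got$precision + got$fdr, 1,
                                        tolerance = 1e-12)
    if (cm$tn + cm$fn > 0) expect_equal(got$npv + got$for_, 1,
                                        tolerance = 1e-12)
  }
})

test_that("auc_score equals the all-pairs exceedance probability", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.1),
                         c("plasmid", "plasmid", "chromosome", "chromosome")),
               1)
  expect_equal(auc_score(rep(0.5, 6), rep(c("plasmid", "chromosome"), 3)),
               0.5)
  expect_equal(auc_score(c(0.9, 0.8, 0.85, 0.1),
                         c("plasmid", "plasmid", "chromosome", "chromosome")),
               0.75)
  expect_true(is.na(auc_score(c(0.1, 0.9), c("plasmid", "plasmid"))))
  # brute force over all pairs, with ties at 0.5
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    truth <- sample(c("plasmid", "chromosome"), n, TRUE,
                    prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    p <- round(runif(n), 1)  # coarse grid to force ties
    pos <- p[truth == "plasmid"]; neg <- p[truth != "plasmid"]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(auc_score(p, truth), brute)
  }
})

test_that("balanced down-sampling equalizes class counts", {
  rec <- tibble::tibble(
    truth = c(rep("chromosome", 1000), rep("plasmid", 100)),
    length = rep(c(500, 1000), 550))
  b <- balanced_downsample(rec, seed = 1)
  expect_equal(sum(b$truth == "plasmid"), 100)
  expect_equal(sum(b$truth == "chromosome"), 100)
  expect_identical(b, balanced_downsample(rec, seed = 1))
  # already balanced input unchanged
  eq <- tibble::tibble(truth = rep(c("plasmid", "chromosome"), 10))
  expect_identical(balanced_downsample(eq, seed = 2), eq)
  # per-stratum balancing
  bs <- balanced_downsample(rec, seed = 3, strata = "length")
  counts <- dplyr::count(bs, .data$length, .data$truth)
  expect_true(all(tapply(counts$n, counts$length,
                         function(x) length(unique(x)) == 1)))
  expect_error(balanced_downsample(
    tibble::tibble(truth = rep("plasmid", 5)), 1), "both classes")
})

test_that("k-mer bias labelling keeps verbatim contigs and discards chimeras", {
  g <- tiny_genome()
  chrom <- g$replicons[g$replicons$label == "chromosome", c("id", "seq")]
  plas <- g$replicons[g$replicons$label == "plasmid", c("id", "seq")]
  pseq <- plas$seq[1]
  cseq <- chrom$seq[1]
  contigs <- tibble::tibble(
    id = c("from_plasmid", "from_chrom", "mutated", "chimera"),
    seq = c(substr(pseq, 1001, 3000),
            substr(cseq, 5001, 7000),
            # heavy mutation destroys >5% of 21-mers
            local({
              s <- substr(cseq, 1, 2000)
              set.seed(5)
              pos <- sample(50:1950, 40)
              for (p in pos) substr(s, p, p) <- c(A = "C", C = "A", G = "T",
                                                  T = "G")[substr(s, p, p)]
              s
            }),
            paste0(substr(cseq, 10001, 11000), substr(pseq, 4001, 5000))))
  lab <- label_contigs_by_kmer_bias(contigs, chrom, plas)
  expect_equal(lab$label[1], "plasmid")
  expect_equal(lab$label[2], "chromosome")
  expect_equal(lab$label[3], "discarded")
  expect_equal(lab$reason[3], "misassembled")
  expect_lt(lab$frac_union[3], 0.95)
  # 50/50 chimera: equal shared fractions -> ambiguous tie
  expect_equal(lab$label[4], "discarded")
  expect_equal(lab$reason[4], "ambiguous")
  expect_equal(lab$frac_chromosome[4], lab$frac_plasmid[4])
})

test_that("length-stratified reports filter records exactly", {
  set.seed(23)
  rec <- tibble::tibble(
    truth = sample(c("plasmid", "chromosome"), 200, TRUE),
    length = sample(c(300, 700, 1500, 3000), 200, TRUE))
  rec$predicted <- ifelse(runif(200) < 0.9, rec$truth,
                          ifelse(rec$truth == "plasmid", "chromosome",
                                 "plasmid"))
  rep_ <- length_stratified_report(rec)
  expect_equal(rep_$min_length, c(0, 500, 1000, 2000))
  expect_equal(rep_$n, vapply(c(0, 500, 1000, 2000),
                              function(b) sum(rec$length >= b), numeric(1)))
  expect_true(all(diff(rep_$n) <= 0))
  # the 0 bin equals the unstratified report
  un <- compute_metrics(confusion_matrix(rec$truth, rec$predicted))
  expect_equal(rep_$accuracy[1], un$accuracy)
  expect_equal(rep_$f1[1], un$f1)
  # exact recomputation for the 1-kb bin
  sel <- rec[rec$length >= 1000, ]
  expect_equal(rep_$sensitivity[3],
               compute_metrics(confusion_matrix(sel$truth,
                                                sel$predicted))$sensitivity)
  p <- plot_length_metrics(rep_)
  expect_s3_class(p, "ggplot")
})

test_that("non-binary predicted labels are excluded from the matrix", {
  expect_message(cm <- confusion_matrix(
    c("plasmid", "plasmid", "chromosome"),
    c("plasmid", "filtered", "chromosome")), "dropped")
  expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, 2)
})
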