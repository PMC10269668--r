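# Shared fixtures, built once per test run. The tiny genome keeps unit
# tests fast; the full-size default genome is only used in the acceptance
# file.

.fixtures <- new.env(parent = emptyenv())

random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tiny_spec <- function() {
  synth_genome_spec(seed = 42L, chromosome_length = 40000L,
                    n_plasmids = 2L,
                    plasmid_length_range = c(8000L, 12000L))
}

tiny_genome <- function() {
  if (is.null(.fixtures$g)) .fixtures$g <- generate_genome(tiny_spec())
  .fixtures$g
}

tiny_dbs <- function() {
  if (is.null(.fixtures$dbs)) {
    g <- tiny_genome()
    .fixtures$dbs <- build_reference_dbs(
      g$replicons[g$replicons$label == "chromosome", c("id", "seq")],
      g$replicons[g$replicons$label == "plasmid", c("id", "seq")])
  }
  .fixtures$dbs
}

# a kmer_db built directly from a set of k-mer strings (unsketched)
db_from_kmers <- function(kmers, k, label = "manual") {
  plasmidr:::new_kmer_db(
    k = as.integer(k),
    kmers = sort(plasmidr:::cpp_encode_kmers(kmers, as.integer(k), TRUE)),
    sketch_fraction = 1, label = label, hash_seed = 42L,
    source_count = 0L)
}

# one feature row with every feature 0 except overrides; label optional
make_feature_row <- function(id = "s", label = NULL, ...) {
  vals <- setNames(as.list(rep(0, length(feature_order()))), feature_order())
  over <- list(...)
  vals[names(over)] <- over
  row <- tibble::as_tibble(c(list(id = id, length = 1000L), vals))
  if (!is.null(label)) row$label <- label
  row
}

# hit tibble row(s) for constructing marker summaries
make_hits <- function(category, evalue, score = 100, rds = NA_real_,
                      query_id = "s1", orf_id = NA_character_) {
  n <- if (length(evalue) == 0) 0L else
    max(length(evalue), length(rds), length(score))
  tibble::tibble(
    query_id = query_id, category = category,
    marker_id = sprintf("m%d", seq_len(n)),
    orf_id = rep_len(orf_id, n),
    score = rep_len(score, n), evalue = rep_len(evalue, n),
    rds = rep_len(rds, n))
}

# tiny trained model over the tiny fixture (built on demand)
tiny_model <- function() {
  if (is.null(.fixtures$model)) {
    g <- tiny_genome()
    ts <- build_training_set(
      g$replicons, default_window_specs(max_window = 2000),
      sample_frac = 0.8, cap = 150L, chrom_min_len = 1000L, seed = 5L)
    feats <- extract_features(
      dplyr::rename(ts, id = window_id)[, c("id", "seq", "label")],
      tiny_dbs(), g$markers)
    .fixtures$model <- train_plasmid_model(feats, ntrees = 200, seed = 3)
  }
  .fixtures$model
}
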