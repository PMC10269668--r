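#' Canonical feature order
#'
#' The 26 features, in the fixed order used for training and prediction:
#' four shared-k-mer fractions (`r_k18`, `rmp_k18`, `p_k25`, `pmr_k25`),
#' the chromosome/plasmid bias ratio `rp`, max score / max `-log10(E)` /
#' presence for conjugation, mobilization, AMR and replication genes, the
#' three RDS summaries, oriT and rRNA motif features, and `maxEvalue`, the
#' maximum of all E-value-derived features except `rRNAMaxEvalue`.
#'
#' @return Character vector of length 26.
#' @export
feature_order <- function() {
  c("r_k18", "rmp_k18", "p_k25", "pmr_k25", "rp",
    "ConjMaxScore", "ConjMaxEvalue", "MobiMaxScore", "MobiMaxEvalue",
    "AMRMaxScore", "AMRMaxEvalue", "RepMaxScore", "RepMaxEvalue",
    "hasConjugation", "hasMobilization", "hasAMR", "hasReplication",
    "RDSAvgScore", "RDSMaxScore", "rdsBias",
    "OritMaxEvalue", "hasOriT",
    "rRNAMaxScore", "rRNAMaxEvalue", "hasrRNA",
    "maxEvalue")
}

FEATURE_VERSION <- "plasmidr_features/26.1"

#' Chromosome/plasmid k-mer bias ratio
#'
#' `rp = r / (r + p)` where `r` and `p` are the shared-k-mer fractions
#' against the chromosome (k = 18) and plasmid (k = 25) databases. Higher
#' values indicate chromosome-like sequences. The degenerate case
#' `r + p = 0` returns the neutral value 0.5.
#'
#' @param r,p Nonnegative shared fractions.
#' @return Value in \[0, 1\].
#' @export
rp_ratio <- function(r, p) {
  if (any(r < 0) || any(p < 0)) stop("rp_ratio inputs must be >= 0")
  ifelse(r + p > 0, r / (r + p), 0.5)
}

#' Assemble the 26-feature vector for one sequence
#'
#' Combines shared-k-mer fractions against the four reference databases
#' with genomic-marker summaries into the fixed-order feature vector.
#'
#' @param id,seq Sequence identifier and DNA string.
#' @param kmer_dbs Named list with `kmer_db` elements `r_k18`, `p_k25`,
#'   `rmp_k18`, `pmr_k25`.
#' @param hits Marker hit tibble for this sequence (as from
#'   [search_markers()]); hits for other `query_id`s are ignored.
#' @return One-row tibble: `id`, `length`, then the 26 features in
#'   [feature_order()].
#' @export
assemble_features <- function(id, seq, kmer_dbs, hits = empty_hits()) {
  needed <- c("r_k18", "p_k25", "rmp_k18", "pmr_k25")
  if (!all(needed %in% names(kmer_dbs)))
    stop("kmer_dbs must contain r_k18, p_k25, rmp_k18, pmr_k25")
  one <- tibble::tibble(id = id, seq = seq)
  kf <- vapply(needed, function(nm)
    query_kmer_db(one, kmer_dbs[[nm]])$shared_fraction, numeric(1))
  h <- hits[hits$query_id == id, , drop = FALSE]
  conj <- category_features(h, "conjugation")
  mobi <- category_features(h, "mobilization")
  amr <- category_features(h, "amr")
  rep_ <- category_features(h, "replication")
  orit <- category_features(h, "orit")
  rrna <- category_features(h, "rrna")
  rds <- rds_features(h[h$category == "mps", , drop = FALSE])
  max_e <- max(conj$max_neg_log_e, mobi$max_neg_log_e, amr$max_neg_log_e,
               rep_$max_neg_log_e, orit$max_neg_log_e)
  tibble::tibble(
    id = id, length = nchar(seq),
    r_k18 = kf[["r_k18"]], rmp_k18 = kf[["rmp_k18"]],
    p_k25 = kf[["p_k25"]], pmr_k25 = kf[["pmr_k25"]],
    rp = rp_ratio(kf[["r_k18"]], kf[["p_k25"]]),
    ConjMaxScore = conj$max_score, ConjMaxEvalue = conj$max_neg_log_e,
    MobiMaxScore = mobi$max_score, MobiMaxEvalue = mobi$max_neg_log_e,
    AMRMaxScore = amr$max_score, AMRMaxEvalue = amr$max_neg_log_e,
    RepMaxScore = rep_$max_score, RepMaxEvalue = rep_$max_neg_log_e,
    hasConjugation = conj$present, hasMobilization = mobi$present,
    hasAMR = amr$present, hasReplication = rep_$present,
    RDSAvgScore = rds$avg_score, RDSMaxScore = rds$max_score,
    rdsBias = rds$bias,
    OritMaxEvalue = orit$max_neg_log_e, hasOriT = orit$present,
    rRNAMaxScore = rrna$max_score, rRNAMaxEvalue = rrna$max_neg_log_e,
    hasrRNA = rrna$present,
    maxEvalue = max_e
  )
}

#' Extract feature vectors for a set of sequences
#'
#' Runs the marker search and k-mer queries for every sequence and stacks
#' the per-sequence feature vectors into one table.
#'
#' @param seqs Sequence tibble (`id`, `seq`), optionally with extra columns
#'   (e.g. `label`) that are carried through.
#' @param kmer_dbs Named list of the four reference `kmer_db`s.
#' @param markers Marker database tibble (NULL for no marker features).
#' @param backend Search backend.
#' @param min_aa Minimum ORF length in codons.
#' @return Feature table: `id`, `length`, carried columns, then the 26
#'   features.
#' @export
extract_features <- function(seqs, kmer_dbs, markers = NULL,
                             backend = naive_backend(), min_aa = 30L) {
  hits <- if (is.null(markers) || nrow(markers) == 0) empty_hits() else
    search_markers(seqs, markers, backend = backend, min_aa = min_aa)
  feats <- dplyr::bind_rows(purrr::map2(
    seqs$id, seqs$seq,
    function(id, s) assemble_features(id, s, kmer_dbs,
                                      hits[hits$query_id == id, ])))
  extra <- setdiff(names(seqs), c("seq", names(feats)))
  if (length(extra) > 0)
    feats <- dplyr::left_join(feats, seqs[, c("id", extra)], by = "id") |>
      dplyr::relocate(dplyr::all_of(extra), .after = "length")
  feats
}

#' Write / read a feature table
#'
#' TSV with a mandatory header row: `id`, `length`, optional carried
#' columns, then the 26 features in canonical order. Values round-trip
#' bit-identically (full-precision formatting).
#'
#' @param features Feature table.
#' @param path File path.
#' @return `path` invisibly (write); feature tibble (read).
#' @export
write_feature_table <- function(features, path) {
  stopifnot(all(feature_order() %in% names(features)))
  num <- vapply(features, function(x) is.double(x), logical(1))
  out <- features
  out[num] <- lapply(features[num], function(x) sprintf("%.17g", x))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # parse numerics with base R strtod (correctly rounded) for bit-exact
  # round-trips
  tb <- readr::read_tsv(path,
                        col_types = readr::cols(.default =
                                                  readr::col_character()))
  num_cols <- setdiff(names(tb), c("id", "label"))
  tb[num_cols] <- lapply(tb[num_cols], as.numeric)
  stopifnot(all(feature_order() %in% names(tb)))
  int_cols <- intersect(c("length", "hasConjugation", "hasMobilization",
                          "hasAMR", "hasReplication", "rdsBias", "hasOriT",
                          "hasrRNA"), names(tb))
  tb[int_cols] <- lapply(tb[int_cols], as.integer)
  tb
}
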