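#' Classify contigs as plasmid or chromosome
#'
#' End-to-end prediction for a set of contigs. Sequences longer than
#' `length_cutoff` (default 500 kb) are labelled chromosome directly
#' without feature extraction (`bypass = TRUE`): sequences that long
#' essentially never originate from plasmids and skipping them saves most
#' of the run time. Sequences shorter than `min_length` (default 500 bp,
#' configurable down to 1) are reported as `"filtered"` rather than
#' silently dropped, so downstream record counts reconcile. Every other
#' sequence gets the 26-feature vector and a forest vote; it is labelled
#' plasmid when its plasmid probability is `>= prob_threshold` (default
#' 0.5), or strictly `>` when `strict = TRUE`.
#'
#' @param contigs Sequence tibble (`id`, `seq`) as from [read_fasta()].
#' @param model A fitted `plasmid_model`.
#' @param kmer_dbs Named list of the four reference `kmer_db`s.
#' @param markers Marker database tibble (NULL to skip marker features).
#' @param length_cutoff Chromosome bypass length in bp.
#' @param min_length Minimum predictable length in bp.
#' @param prob_threshold Plasmid probability cutoff.
#' @param strict Break exact-threshold ties toward chromosome.
#' @param backend Marker search backend.
#' @param features_out Optional path; when set, the feature table of the
#'   predicted contigs is written there as TSV.
#' @return Tibble with one row per input contig, in input order: `id`,
#'   `length`, `label` (`"chromosome"`, `"plasmid"` or `"filtered"`),
#'   `plasmid_probability` (`NA` when bypassed or filtered), `bypass`,
#'   `flag` (`"no_informative_kmers"` for e.g. all-N sequences, else
#'   `NA`).
#' @export
classify_contigs <- function(contigs, model, kmer_dbs, markers = NULL,
                             length_cutoff = 500000L, min_length = 500L,
                             prob_threshold = 0.5, strict = FALSE,
                             backend = naive_backend(),
                             features_out = NULL) {
  stopifnot(inherits(model, "plasmid_model"), min_length >= 1)
  if (nrow(contigs) == 0) {
    warning("empty input; no predictions")
    return(tibble::tibble(id = character(0), length = integer(0),
                          label = character(0),
                          plasmid_probability = numeric(0),
                          bypass = logical(0), flag = character(0)))
  }
  if (anyDuplicated(contigs$id)) stop("duplicate contig ids")
  len <- nchar(contigs$seq)
  out <- tibble::tibble(
    id = contigs$id, length = len, label = NA_character_,
    plasmid_probability = NA_real_,
    bypass = len > length_cutoff, flag = NA_character_
  )
  out$label[out$bypass] <- "chromosome"
  filtered <- !out$bypass & len < min_length
  out$label[filtered] <- "filtered"
  todo <- which(is.na(out$label))
  if (length(todo) > 0) {
    feats <- extract_features(contigs[todo, c("id", "seq")], kmer_dbs,
                              markers, backend = backend)
    if (!is.null(features_out)) write_feature_table(feats, features_out)
    p <- predict(model, feats)
    out$plasmid_probability[todo] <- p
    is_plasmid <- if (strict) p > prob_threshold else p >= prob_threshold
    out$label[todo] <- ifelse(is_plasmid, "plasmid", "chromosome")
    no_inf <- feats$r_k18 == 0 & feats$p_k25 == 0 &
      grepl("^N*$", contigs$seq[todo])
    out$flag[todo][no_inf] <- "no_informative_kmers"
  }
  out
}
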