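#' Marker categories
#'
#' The seven marker categories used for genomic-marker features. The
#' gene-based categories (conjugation, mobilization, replication, amr, mps)
#' are searched as proteins against predicted ORFs; orit and rrna are
#' nucleotide motifs searched directly against the sequence.
#' @export
marker_categories <- function() {
  c("conjugation", "mobilization", "replication", "amr", "mps",
    "orit", "rrna")
}

PROTEIN_CATEGORIES <- c("conjugation", "mobilization", "replication",
                        "amr", "mps")
NUCLEOTIDE_CATEGORIES <- c("orit", "rrna")

#' Find open reading frames
#'
#' Naive ORF scan on both strands: all maximal ATG-to-stop ORFs of at least
#' `min_aa` codons, translated with the standard genetic code. ORFs without
#' an in-frame stop codon are not reported. Coordinates are on the forward
#' strand, 0-based half-open, and include the stop codon.
#'
#' @param seq A single DNA string.
#' @param min_aa Minimum ORF length in codons (default 30, excluding the
#'   stop).
#' @return Tibble with columns `protein`, `start`, `end`, `strand`.
#' @examples
#' find_orfs("ATGAAATAA", min_aa = 2)  # one ORF, protein "MK"
#' @export
find_orfs <- function(seq, min_aa = 30L) {
  stopifnot(length(seq) == 1, min_aa >= 1)
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      n_codon <- (L - frame) %/% 3
      if (n_codon < min_aa + 1) next
      sub <- substr(s, frame + 1, frame + n_codon * 3)
      prot <- cpp_translate(sub)
      m <- gregexpr("M[^*]*\\*", prot)[[1]]
      if (m[1] == -1) next
      starts_aa <- as.integer(m)
      lens <- attr(m, "match.length")
      keep <- (lens - 1L) >= min_aa
      if (!any(keep)) next
      starts_aa <- starts_aa[keep]
      lens <- lens[keep]
      # nt coords on strand s, 0-based half-open, stop codon included
      s0 <- frame + 3L * (starts_aa - 1L)
      e0 <- frame + 3L * (starts_aa - 1L + lens)
      if (strand == "-") {
        tmp <- L - e0
        e0 <- L - s0
        s0 <- tmp
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        protein = substr(rep(prot, length(starts_aa)), starts_aa,
                         starts_aa + lens - 2L),
        start = s0, end = e0, strand = strand
      )
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(protein = character(0), start = integer(0),
                          end = integer(0), strand = character(0)))
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end, .data$strand)
}

#' Negative log10 of an E-value
#'
#' `-log10(e)`, floored at 0 (E >= 1 maps to 0) and capped at 300 (E = 0,
#' i.e. underflow, maps to 300). This is the scale on which the marker
#' presence threshold of 50 (E <= 1e-50) is applied.
#'
#' @param e Numeric vector of E-values, all >= 0.
#' @return Numeric vector in \[0, 300\].
#' @export
neg_log_evalue <- function(e) {
  if (any(e < 0)) stop("E-value must be >= 0")
  ifelse(e == 0, 300, pmin(300, pmax(0, -log10(e))))
}

empty_hits <- function() {
  tibble::tibble(query_id = character(0), category = character(0),
                 marker_id = character(0), orf_id = character(0),
                 score = numeric(0), evalue = numeric(0), rds = numeric(0))
}

#' Built-in naive search backend
#'
#' A deterministic, dependency-free search backend: protein markers are
#' scored against predicted ORFs and nucleotide markers against both
#' strands of the sequence by best ungapped local alignment (match +5,
#' mismatch -4); a raw score S is converted to a pseudo E-value
#' `e = m * n * 2^(-S)` with m, n the query/target lengths. This is a
#' documented pseudo-statistic, adequate for planted-cassette fixtures but
#' not equivalent to HMMER/DIAMOND/BLAST statistics. Alternative backends
#' (e.g. adapters shelling out to external aligners) can be supplied as
#' objects with a `search_backend` subclass and a [backend_search()] method
#' returning the same hit schema.
#'
#' @param match,mismatch Alignment scores.
#' @param evalue_max Hits with pseudo E-value above this are dropped
#'   (default 1e-3).
#' @return A backend object.
#' @export
naive_backend <- function(match = 5, mismatch = -4, evalue_max = 1e-3) {
  structure(list(name = "naive", match = match, mismatch = mismatch,
                 evalue_max = evalue_max,
                 capabilities = marker_categories()),
            class = c("naive_backend", "search_backend"))
}

#' Run a search backend on one sequence
#'
#' Generic implemented by each backend; returns the unified hit schema
#' (`query_id`, `category`, `marker_id`, `orf_id`, `score`, `evalue`,
#' `rds`).
#'
#' @param backend A `search_backend` object.
#' @param id,seq Query identifier and DNA string.
#' @param markers Marker database tibble (see [read_marker_db()]).
#' @param min_aa Minimum ORF length for gene-based categories.
#' @return Hit tibble.
#' @export
backend_search <- function(backend, id, seq, markers, min_aa = 30L) {
  UseMethod("backend_search")
}

#' @export
backend_search.naive_backend <- function(backend, id, seq, markers,
                                         min_aa = 30L) {
  hits <- list()
  prot_markers <- markers[markers$category %in% PROTEIN_CATEGORIES, ]
  if (nrow(prot_markers) > 0) {
    orfs <- find_orfs(seq, min_aa = min_aa)
    if (nrow(orfs) > 0) {
      orf_enc <- lapply(orfs$protein, utf8ToInt)
      orf_ids <- sprintf("%s|%d-%d(%s)", id, orfs$start, orfs$end,
                         orfs$strand)
      mk_enc <- lapply(prot_markers$seq, utf8ToInt)
      for (i in seq_along(orf_enc)) {
        for (j in seq_len(nrow(prot_markers))) {
          s <- cpp_ungapped_local(orf_enc[[i]], mk_enc[[j]],
                                  backend$match, backend$mismatch)
          e <- length(orf_enc[[i]]) * length(mk_enc[[j]]) * 2^(-s)
          if (e <= backend$evalue_max) {
            hits[[length(hits) + 1L]] <- tibble::tibble(
              query_id = id, category = prot_markers$category[j],
              marker_id = prot_markers$marker_id[j], orf_id = orf_ids[i],
              score = s, evalue = e, rds = prot_markers$rds[j])
          }
        }
      }
    }
  }
  nuc_markers <- markers[markers$category %in% NUCLEOTIDE_CATEGORIES, ]
  if (nrow(nuc_markers) > 0) {
    q_fwd <- utf8ToInt(toupper(seq))
    q_rev <- utf8ToInt(revcomp(seq))
    for (j in seq_len(nrow(nuc_markers))) {
      mk <- utf8ToInt(toupper(nuc_markers$seq[j]))
      s <- max(cpp_ungapped_local(q_fwd, mk, backend$match, backend$mismatch),
               cpp_ungapped_local(q_rev, mk, backend$match, backend$mismatch))
      e <- length(q_fwd) * length(mk) * 2^(-s)
      if (e <= backend$evalue_max) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          query_id = id, category = nuc_markers$category[j],
          marker_id = nuc_markers$marker_id[j], orf_id = NA_character_,
          score = s, evalue = e, rds = NA_real_)
      }
    }
  }
  if (length(hits) == 0) empty_hits() else dplyr::bind_rows(hits)
}

#' Search marker databases for hits on input sequences
#'
#' Runs the backend once per sequence over all marker categories present in
#' `markers`; a category with no database records simply yields no hits.
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param markers Marker database tibble with columns `marker_id`,
#'   `category`, `rds`, `seq`.
#' @param backend Search backend (default [naive_backend()]).
#' @param min_aa Minimum ORF length in codons for protein categories.
#' @return Hit tibble (`query_id`, `category`, `marker_id`, `orf_id`,
#'   `score`, `evalue`, `rds`).
#' @export
search_markers <- function(seqs, markers, backend = naive_backend(),
                           min_aa = 30L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (is.null(markers) || nrow(markers) == 0) {
    warning("empty marker database; no hits")
    return(empty_hits())
  }
  dplyr::bind_rows(purrr::map2(seqs$id, seqs$seq, function(id, s)
    backend_search(backend, id, s, markers, min_aa = min_aa)))
}

#' Per-category marker summary features
#'
#' For one sequence and one category: the maximum alignment score, the
#' maximum `-log10(E)` over hits, and the presence flag, which is 1 exactly
#' when the maximum `-log10(E)` is at least 50 (E <= 1e-50). With no hits
#' all three are 0.
#'
#' @param hits Hit tibble (any mixture; filtered internally).
#' @param category One of [marker_categories()].
#' @param query_id Optional query filter.
#' @return One-row tibble: `max_score`, `max_neg_log_e`, `present`.
#' @export
category_features <- function(hits, category, query_id = NULL) {
  h <- hits[hits$category == category, ]
  if (!is.null(query_id)) h <- h[h$query_id == query_id, ]
  if (nrow(h) == 0)
    return(tibble::tibble(max_score = 0, max_neg_log_e = 0, present = 0L))
  mnle <- max(neg_log_evalue(h$evalue))
  tibble::tibble(max_score = max(h$score), max_neg_log_e = mnle,
                 present = as.integer(mnle >= 50))
}

#' Replicon-distribution-score features
#'
#' Summarises marker-protein (MPS) hits into RDSAvgScore, RDSMaxScore and
#' rdsBias. When an `orf_id` column is present, hits are first reduced to
#' the best hit per gene (lowest E-value; ties by higher score, then
#' marker id) so one gene contributes one RDS value. rdsBias is 1 if the
#' average RDS is >= 5, -1 if it is <= -10, and 0 otherwise. With no hits
#' all three are 0.
#'
#' @param mps_hits Hit tibble of category `mps`; every hit must carry an
#'   `rds` value.
#' @return One-row tibble: `avg_score`, `max_score`, `bias`.
#' @export
rds_features <- function(mps_hits) {
  if (nrow(mps_hits) == 0)
    return(tibble::tibble(avg_score = 0, max_score = 0, bias = 0L))
  if (!"rds" %in% names(mps_hits) || anyNA(mps_hits$rds))
    stop("every MPS hit must carry an rds value")
  h <- mps_hits
  if ("orf_id" %in% names(h) && !anyNA(h$orf_id)) {
    h <- h |>
      dplyr::group_by(.data$orf_id) |>
      dplyr::arrange(.data$evalue, dplyr::desc(.data$score),
                     .data$marker_id, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
  }
  avg <- mean(h$rds)
  bias <- if (avg >= 5) 1L else if (avg <= -10) -1L else 0L
  tibble::tibble(avg_score = avg, max_score = max(h$rds), bias = bias)
}

#' Write / read a marker database
#'
#' Marker databases are TSV files with columns `marker_id`, `category`,
#' `rds` (NA except for MPS entries) and `seq` (amino-acid sequence for
#' gene categories, nucleotide for orit/rrna).
#'
#' @param markers Marker tibble.
#' @param path File path.
#' @return `path` invisibly (write); marker tibble (read).
#' @export
write_marker_db <- function(markers, path) {
  stopifnot(all(c("marker_id", "category", "rds", "seq") %in% names(markers)))
  readr::write_tsv(markers[, c("marker_id", "category", "rds", "seq")], path)
  invisible(path)
}

#' @rdname write_marker_db
#' @export
read_marker_db <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), category = readr::col_character(),
    rds = readr::col_double(), seq = readr::col_character()))
}
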