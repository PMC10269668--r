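#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement, so counting is strand-invariant. Vectorised over
#' `kmer`; all elements must have the same length.
#'
#' @param kmer Character vector of ACGT strings (lowercase accepted).
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer("CGT")  # "ACG"
#' @export
canonical_kmer <- function(kmer) {
  kmer <- toupper(kmer)
  if (length(kmer) == 0) return(character(0))
  if (any(nchar(kmer) < 1)) stop("k-mer length must be >= 1")
  if (any(grepl("[^ACGT]", kmer))) stop("ambiguous k-mer")
  out <- character(length(kmer))
  for (k in unique(nchar(kmer))) {
    i <- nchar(kmer) == k
    out[i] <- cpp_decode_kmers(cpp_encode_kmers(kmer[i], as.integer(k), TRUE),
                               as.integer(k))
  }
  out
}

#' Extract the set of canonical k-mers of a sequence
#'
#' Windows containing any non-ACGT character are skipped; lowercase
#' (soft-masked) bases are uppercased first. A sequence shorter than `k`
#' yields an empty set.
#'
#' @param seq A single DNA string.
#' @param k K-mer length (1--26).
#' @return Character vector of distinct canonical k-mers, sorted.
#' @examples
#' extract_kmers("ACGTAC", 3)  # "ACG" "GTA"
#' @export
extract_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1, k >= 1)
  cpp_decode_kmers(cpp_kmer_set(seq, as.integer(k), 1.0, 42L), as.integer(k))
}

#' Build a canonical k-mer database
#'
#' Unions the canonical k-mer sets of all input sequences, then applies the
#' min-hash sketch criterion: a k-mer is retained iff
#' `H(kmer) < sketch_fraction * 2^64` for a fixed 64-bit hash `H`
#' (splitmix64, seed `hash_seed`), so databases are deterministic across
#' runs and platforms and `sketch_fraction = 1` keeps everything.
#'
#' @param seqs Sequence tibble (`id`, `seq`) or a character vector of DNA
#'   strings.
#' @param k K-mer length; the reference configuration uses 18 for
#'   chromosome-side and 25 for plasmid-side databases.
#' @param sketch_fraction Fraction `f` of the hash space retained, in (0, 1].
#'   Chromosome databases are sketched at 0.1 by default in the reference
#'   configuration; plasmid databases are unsketched.
#' @param label Free-text label (e.g. `"chromosome"`, `"plasmid"`,
#'   `"chromosome_minus_plasmid"`, `"plasmid_minus_chromosome"`).
#' @param hash_seed Fixed hash seed (default 42).
#' @return A `kmer_db` object.
#' @export
build_kmer_db <- function(seqs, k, sketch_fraction = 1, label = "",
                          hash_seed = 42L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  seqs <- as.character(seqs)
  stopifnot(k >= 1, sketch_fraction > 0, sketch_fraction <= 1)
  if (length(seqs) == 0) warning("empty input sequence list; empty database")
  kmers <- cpp_kmer_set(seqs, as.integer(k), sketch_fraction,
                        as.integer(hash_seed))
  new_kmer_db(k = as.integer(k), kmers = kmers,
              sketch_fraction = sketch_fraction, label = label,
              hash_seed = as.integer(hash_seed),
              source_count = length(seqs))
}

new_kmer_db <- function(k, kmers, sketch_fraction, label, hash_seed,
                        source_count) {
  structure(
    list(k = k, kmers = kmers, sketch_fraction = sketch_fraction,
         label = label, hash_seed = hash_seed, source_count = source_count),
    class = "kmer_db"
  )
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf(
    "<kmer_db> k=%d  n_kmers=%s  sketch_fraction=%g  label=\"%s\"  sources=%d\n",
    x$k, format(length(x$kmers), big.mark = ","), x$sketch_fraction,
    x$label, x$source_count))
  invisible(x)
}

#' Set-subtract one k-mer database from another
#'
#' Returns the k-mers of `a` not present in `b`. Both databases must share
#' the same `k` (the plasmid-minus-chromosome database is built at k = 25 on
#' both sides, chromosome-minus-plasmid at k = 18 on both sides). The result
#' keeps `a`'s sketch fraction and hash seed.
#'
#' @param a,b `kmer_db` objects with equal `k`.
#' @param label Label for the result.
#' @return A `kmer_db`.
#' @export
subtract_kmer_db <- function(a, b, label = paste0(a$label, "_minus_", b$label)) {
  stopifnot(inherits(a, "kmer_db"), inherits(b, "kmer_db"))
  if (a$k != b$k) stop("k mismatch")
  new_kmer_db(k = a$k, kmers = setdiff(a$kmers, b$kmers),
              sketch_fraction = a$sketch_fraction, label = label,
              hash_seed = a$hash_seed, source_count = a$source_count)
}

#' Shared-k-mer fraction of sequences against a database
#'
#' Query k-mers are extracted at the database's `k`, canonicalised, then
#' filtered by the database's own sketch criterion (same hash, same
#' fraction) before counting, so a query drawn verbatim from a database's
#' source scores 1.0 regardless of sketching. The shared fraction is
#' query-relative: `n_shared / n_query_kmers` (0 when the query has no
#' informative k-mers).
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param db A `kmer_db`.
#' @return Tibble with one row per query: `id`, `n_query_kmers`, `n_shared`,
#'   `shared_fraction`, `no_informative_kmers`.
#' @export
query_kmer_db <- function(seqs, db) {
  stopifnot(inherits(db, "kmer_db"), all(c("id", "seq") %in% names(seqs)))
  res <- purrr::map2(seqs$id, seqs$seq, function(id, s) {
    cnt <- cpp_shared_count(s, db$k, db$sketch_fraction, db$hash_seed,
                            db$kmers)
    nq <- cnt$n_query_kmers
    tibble::tibble(
      id = id,
      n_query_kmers = nq,
      n_shared = cnt$n_shared,
      shared_fraction = if (nq > 0) cnt$n_shared / nq else 0,
      no_informative_kmers = nq == 0
    )
  })
  dplyr::bind_rows(res)
}

#' Build the four reference k-mer databases
#'
#' Convenience wrapper producing the standard database set used for feature
#' extraction: `r_k18` (chromosome, sketched), `p_k25` (plasmid,
#' unsketched), `rmp_k18` (chromosome minus plasmid, both sides at k = 18)
#' and `pmr_k25` (plasmid minus chromosome, both sides at k = 25). The
#' subtrahend of each difference is built unsketched so subtraction removes
#' every overlapping k-mer; the minuend keeps its own sketch fraction.
#'
#' @param chromosomes,plasmids Sequence tibbles (`id`, `seq`).
#' @param k_chrom,k_plasmid K-mer lengths (defaults 18 and 25).
#' @param chrom_sketch Sketch fraction for chromosome-side databases
#'   (default 0.1).
#' @param hash_seed Fixed hash seed.
#' @return Named list of four `kmer_db` objects:
#'   `r_k18`, `p_k25`, `rmp_k18`, `pmr_k25`.
#' @export
build_reference_dbs <- function(chromosomes, plasmids, k_chrom = 18L,
                                k_plasmid = 25L, chrom_sketch = 0.1,
                                hash_seed = 42L) {
  r <- build_kmer_db(chromosomes, k_chrom, chrom_sketch, "chromosome",
                     hash_seed)
  p <- build_kmer_db(plasmids, k_plasmid, 1, "plasmid", hash_seed)
  p18 <- build_kmer_db(plasmids, k_chrom, 1, "plasmid", hash_seed)
  r25 <- build_kmer_db(chromosomes, k_plasmid, 1, "chromosome", hash_seed)
  list(
    r_k18 = r,
    p_k25 = p,
    rmp_k18 = subtract_kmer_db(r, p18, "chromosome_minus_plasmid"),
    pmr_k25 = subtract_kmer_db(p, r25, "plasmid_minus_chromosome")
  )
}

KMER_DB_FORMAT <- "plasmidr_kmer_db/1"

#' Write a k-mer database to a plain-text file
#'
#' Header lines (prefixed `#`) carry the format version, `k`, sketch
#' fraction, hash seed, label and counts; the body lists one canonical
#' k-mer per line. Databases round-trip bit-exactly.
#'
#' @param db A `kmer_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_db <- function(db, path) {
  stopifnot(inherits(db, "kmer_db"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#format\t", KMER_DB_FORMAT),
    paste0("#k\t", db$k),
    paste0("#sketch_fraction\t", format(db$sketch_fraction, digits = 17)),
    paste0("#hash_seed\t", db$hash_seed),
    paste0("#label\t", db$label),
    paste0("#source_count\t", db$source_count),
    paste0("#n_kmers\t", length(db$kmers))
  ), con)
  if (length(db$kmers) > 0)
    writeLines(cpp_decode_kmers(db$kmers, db$k), con)
  invisible(path)
}

#' Read a k-mer database written by [write_kmer_db()]
#'
#' @param path Path to a database file.
#' @return A `kmer_db`.
#' @export
read_kmer_db <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- lines[hdr_idx]
  kv <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  if (is.na(vals["format"]) || vals[["format"]] != KMER_DB_FORMAT)
    stop("unknown k-mer database format version")
  k <- as.integer(vals[["k"]])
  body <- lines[-hdr_idx]
  body <- body[nzchar(body)]
  n_expected <- as.integer(vals[["n_kmers"]])
  if (length(body) != n_expected) stop("truncated k-mer database")
  kmers <- if (n_expected > 0) sort(cpp_encode_kmers(body, k, TRUE)) else numeric(0)
  new_kmer_db(
    k = k, kmers = kmers,
    sketch_fraction = as.numeric(vals[["sketch_fraction"]]),
    label = vals[["label"]], hash_seed = as.integer(vals[["hash_seed"]]),
    source_count = as.integer(vals[["source_count"]])
  )
}
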