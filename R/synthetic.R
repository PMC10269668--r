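#' Specification for a synthetic genome set
#'
#' Describes the deterministic synthetic study system: one chromosome and
#' several plasmids drawn from two compositionally distinct order-2 Markov
#' chains (by default GC 0.42 vs 0.58, a stand-in for the taxonomic
#' composition signal of real replicons), with planted marker cassettes --
#' conjugation, mobilization, replication, AMR and positive-RDS
#' marker-protein genes plus an oriT motif on plasmids; rRNA motifs and
#' negative-RDS marker-protein genes on the chromosome. The chromosome
#' default length (600 kb) clears the 500-kb chromosome training filter;
#' plasmid lengths (20--80 kb) span typical large conjugative plasmids.
#'
#' @param seed Integer seed; every sequence, cassette position and toy
#'   marker is a pure function of it.
#' @param chromosome_length Chromosome length in bp.
#' @param n_plasmids Number of plasmids.
#' @param plasmid_length_range Min/max plasmid length in bp.
#' @param chromosome_gc,plasmid_gc GC targets of the two composition
#'   classes.
#' @param marker_plan Named list of planted-cassette counts:
#'   `plasmid` (per plasmid) and `chromosome` (total), each a named
#'   integer vector over categories.
#' @return A `synth_genome_spec`.
#' @export
synth_genome_spec <- function(seed = 1L,
                              chromosome_length = 600000L,
                              n_plasmids = 6L,
                              plasmid_length_range = c(20000L, 80000L),
                              chromosome_gc = 0.42,
                              plasmid_gc = 0.58,
                              marker_plan = list(
                                plasmid = c(conjugation = 1L,
                                            mobilization = 1L,
                                            replication = 1L, amr = 1L,
                                            orit = 1L, mps = 2L),
                                chromosome = c(rrna = 3L, mps = 10L))) {
  stopifnot(chromosome_length > 0, n_plasmids >= 0,
            all(plasmid_length_range > 0),
            plasmid_length_range[1] <= plasmid_length_range[2],
            chromosome_gc > 0, chromosome_gc < 1,
            plasmid_gc > 0, plasmid_gc < 1)
  structure(list(seed = as.integer(seed),
                 chromosome_length = as.integer(chromosome_length),
                 n_plasmids = as.integer(n_plasmids),
                 plasmid_length_range = as.integer(plasmid_length_range),
                 chromosome_gc = chromosome_gc, plasmid_gc = plasmid_gc,
                 marker_plan = marker_plan),
            class = "synth_genome_spec")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

# one fixed codon per amino acid, for deterministic reverse translation
CODON1 <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
            G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
            M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
            S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1, replace = TRUE), collapse = ""))
}

reverse_translate <- function(protein) {
  paste0(paste(CODON1[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

# order-2 transition matrix around a GC target with a deterministic
# row-wise jitter so the chain is genuinely order-2
markov_transitions <- function(gc, jitter_seed) {
  base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  set.seed(jitter_seed)
  jit <- matrix(runif(64, -0.35, 0.35), nrow = 16)
  tr <- matrix(rep(base, each = 16), nrow = 16) * exp(jit)
  tr / rowSums(tr)
}

#' Generate a toy marker database
#'
#' Deterministic toy markers for the built-in search backend: two protein
#' markers per gene category (conjugation, mobilization, replication,
#' AMR), three plasmid-enriched (positive RDS) and three
#' chromosome-enriched (negative RDS) marker-protein entries, a 60-bp oriT
#' motif and two 120-bp rRNA motifs.
#'
#' @param seed Integer seed.
#' @param protein_len Marker protein length in amino acids.
#' @return Marker database tibble (`marker_id`, `category`, `rds`,
#'   `seq`).
#' @export
toy_marker_db <- function(seed = 1L, protein_len = 80L) {
  set.seed(seed + 7777L)
  rows <- list()
  for (cat in c("conjugation", "mobilization", "replication", "amr")) {
    for (i in 1:2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker_id = sprintf("%s_%d", cat, i), category = cat,
        rds = NA_real_, seq = random_protein(protein_len))
  }
  for (i in 1:3)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      marker_id = sprintf("mps_plasmid_%d", i), category = "mps",
      rds = c(6, 8, 10)[i], seq = random_protein(protein_len))
  for (i in 1:3)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      marker_id = sprintf("mps_chromosome_%d", i), category = "mps",
      rds = c(-12, -13, -15)[i], seq = random_protein(protein_len))
  rows[[length(rows) + 1L]] <- tibble::tibble(
    marker_id = "orit_1", category = "orit", rds = NA_real_,
    seq = paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = ""))
  for (i in 1:2)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      marker_id = sprintf("rrna_%d", i), category = "rrna", rds = NA_real_,
      seq = paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                  collapse = ""))
  dplyr::bind_rows(rows)
}

# plant cassettes into seq at random non-overlapping positions; returns
# list(seq, cassettes tibble)
plant_cassettes <- function(seq, replicon_id, cassettes_dna) {
  L <- nchar(seq)
  total <- sum(nchar(cassettes_dna))
  if (total > L)
    stop("replicon of ", L, " bp too short for planted cassettes (",
         total, " bp)")
  placed <- list()
  used <- matrix(numeric(0), ncol = 2)
  for (i in seq_along(cassettes_dna)) {
    clen <- nchar(cassettes_dna[i])
    for (try in 1:200) {
      start <- sample.int(L - clen + 1L, 1L) - 1L  # 0-based
      ok <- nrow(used) == 0 ||
        all(start + clen <= used[, 1] | start >= used[, 2])
      if (ok) break
      if (try == 200) stop("could not place cassette without overlap")
    }
    used <- rbind(used, c(start, start + clen))
    substr(seq, start + 1L, start + clen) <- cassettes_dna[i]
    placed[[i]] <- tibble::tibble(
      replicon = replicon_id, marker_id = names(cassettes_dna)[i],
      start = start, end = start + clen)
  }
  list(seq = seq, cassettes = dplyr::bind_rows(placed))
}

#' Generate a deterministic synthetic genome set
#'
#' Draws the chromosome and plasmids from their class compositions and
#' plants the marker cassettes (exact copies of the toy markers, reverse
#' translated for proteins) according to the marker plan in `spec`. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [synth_genome_spec()].
#' @return A `synth_genome` list: `replicons` (tibble `id`, `seq`,
#'   `label`), `manifest` (tibble `id`, `label`, `length`), `cassettes`
#'   (tibble `replicon`, `marker_id`, `category`, `start`, `end`) and
#'   `markers` (the toy marker database).
#' @export
generate_genome <- function(spec = synth_genome_spec()) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  markers <- toy_marker_db(spec$seed)
  marker_dna <- setNames(
    ifelse(markers$category %in% PROTEIN_CATEGORIES,
           vapply(markers$seq, reverse_translate, ""),
           markers$seq),
    markers$marker_id)
  tr_chrom <- markov_transitions(spec$chromosome_gc, spec$seed + 11L)
  tr_plasmid <- markov_transitions(spec$plasmid_gc, spec$seed + 22L)

  pick <- function(class) {
    # cassette DNA for the planted copies of one replicon
    plan <- spec$marker_plan[[class]]
    ids <- character(0)
    for (cat in names(plan)) {
      pool <- markers$marker_id[markers$category == cat]
      if (cat == "mps")
        pool <- grep(paste0("mps_", class), pool, value = TRUE)
      if (length(pool) == 0 || plan[[cat]] < 1) next
      ids <- c(ids, rep(pool, length.out = plan[[cat]]))
    }
    marker_dna[ids]
  }

  set.seed(spec$seed)
  chrom_seq <- cpp_markov_seq(spec$chromosome_length, tr_chrom)
  chrom <- plant_cassettes(chrom_seq, "chromosome_1",
                           pick("chromosome"))
  replicons <- tibble::tibble(id = "chromosome_1", seq = chrom$seq,
                              label = "chromosome")
  cassettes <- chrom$cassettes
  if (spec$n_plasmids > 0) {
    for (i in seq_len(spec$n_plasmids)) {
      plen <- sample(spec$plasmid_length_range[1]:
                       spec$plasmid_length_range[2], 1L)
      pseq <- cpp_markov_seq(plen, tr_plasmid)
      pid <- sprintf("plasmid_%d", i)
      pl <- plant_cassettes(pseq, pid, pick("plasmid"))
      replicons <- dplyr::bind_rows(
        replicons, tibble::tibble(id = pid, seq = pl$seq, label = "plasmid"))
      cassettes <- dplyr::bind_rows(cassettes, pl$cassettes)
    }
  }
  cassettes <- dplyr::left_join(
    cassettes, markers[, c("marker_id", "category")], by = "marker_id")
  structure(list(
    replicons = replicons,
    manifest = tibble::tibble(id = replicons$id, label = replicons$label,
                              length = nchar(replicons$seq)),
    cassettes = cassettes[, c("replicon", "marker_id", "category", "start",
                              "end")],
    markers = markers
  ), class = "synth_genome")
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("<synth_genome> %d replicons (%s bp), %d planted cassettes\n",
              nrow(x$replicons),
              format(sum(x$manifest$length), big.mark = ","),
              nrow(x$cassettes)))
  invisible(x)
}

#' Fragment replicons into assembly-like contigs
#'
#' Draws random subsequences emulating a fragmented short-read assembly:
#' source replicons are chosen proportional to length, contig lengths from
#' a log-normal distribution (default median 2 kb) clipped to
#' `[min_len, replicon length]`, positions uniform. Each contig's true
#' source is recorded.
#'
#' @param replicons Tibble (`id`, `seq`, `label`).
#' @param n_fragments Number of contigs to draw (0 gives an empty
#'   result).
#' @param meanlog,sdlog Log-normal length parameters (defaults give a
#'   2-kb median).
#' @param min_len Minimum contig length in bp.
#' @param seed Integer seed.
#' @return Tibble: `id`, `seq`, `source_id`, `source_label`, `start`,
#'   `end`.
#' @export
fragment_assembly <- function(replicons, n_fragments,
                              meanlog = log(2000), sdlog = 0.7,
                              min_len = 200L, seed = 1L) {
  stopifnot(n_fragments >= 0)
  empty <- tibble::tibble(id = character(0), seq = character(0),
                          source_id = character(0),
                          source_label = character(0),
                          start = integer(0), end = integer(0))
  if (n_fragments == 0 || nrow(replicons) == 0) return(empty)
  set.seed(seed)
  lens <- nchar(replicons$seq)
  src <- sample.int(nrow(replicons), n_fragments, replace = TRUE,
                    prob = lens)
  flen <- pmax(min_len, round(stats::rlnorm(n_fragments, meanlog, sdlog)))
  flen <- pmin(flen, lens[src])
  start <- vapply(seq_len(n_fragments), function(i)
    sample.int(lens[src[i]] - flen[i] + 1L, 1L) - 1L, integer(1))
  tibble::tibble(
    id = sprintf("contig_%d", seq_len(n_fragments)),
    seq = substring(replicons$seq[src], start + 1L, start + flen),
    source_id = replicons$id[src],
    source_label = replicons$label[src],
    start = as.integer(start), end = as.integer(start + flen)
  )
}

#' Write a synthetic genome set to a directory
#'
#' Writes `chromosome.fa`, `plasmids.fa`, `markers.tsv`, `manifest.tsv`
#' and `cassettes.tsv`.
#'
#' @param genome A `synth_genome`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "synth_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chrom <- genome$replicons[genome$replicons$label == "chromosome", ]
  plas <- genome$replicons[genome$replicons$label == "plasmid", ]
  write_fasta(chrom, file.path(dir, "chromosome.fa"))
  write_fasta(plas, file.path(dir, "plasmids.fa"))
  write_marker_db(genome$markers, file.path(dir, "markers.tsv"))
  readr::write_tsv(genome$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(genome$cassettes, file.path(dir, "cassettes.tsv"))
  invisible(dir)
}
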