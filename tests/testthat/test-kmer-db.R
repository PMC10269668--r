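test_that("canonical_kmer picks the lexicographic min of the strand pair", {
  expect_equal(canonical_kmer("ACGT"), "ACGT")  # revcomp palindrome
  expect_equal(canonical_kmer("CGT"), "ACG")
  expect_equal(canonical_kmer("TAC"), "GTA")
  expect_equal(canonical_kmer("acg"), "ACG")
  # idempotent
  set.seed(1)
  kms <- replicate(25, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                             collapse = ""))
  expect_equal(canonical_kmer(canonical_kmer(kms)), canonical_kmer(kms))
  expect_error(canonical_kmer("ACNT"), "ambiguous")
})

test_that("extract_kmers enumerates canonical windows, skipping ambiguity", {
  expect_setequal(extract_kmers("ACGTAC", 3), c("ACG", "GTA"))
  expect_length(extract_kmers("ACNGT", 3), 0)
  expect_length(extract_kmers("AC", 3), 0)
  # lowercase soft-masking is uppercased, not skipped
  expect_setequal(extract_kmers("acgtac", 3), c("ACG", "GTA"))
  # brute-force oracle on random sequences
  for (seed in 1:5) {
    s <- random_dna(200, seed)
    oracle <- unique(canonical_kmer(substring(s, 1:(200 - 6), 7:200)))
    expect_setequal(extract_kmers(s, 7), oracle)
  }
})

test_that("min-hash sketching is a binomial thinning and is nested in f", {
  s <- random_dna(10000, seed = 11)
  full <- build_kmer_db(s, 18, 1, "full")
  n_full <- length(full$kmers)
  sk <- build_kmer_db(s, 18, 0.1, "sketched")
  sd_bin <- sqrt(n_full * 0.1 * 0.9)
  expect_lt(abs(length(sk$kmers) - 0.1 * n_full), 3 * sd_bin)
  # sketch(f1) is a subset of sketch(f2) for f1 <= f2
  fs <- c(0.05, 0.1, 0.3, 1)
  dbs <- lapply(fs, function(f) build_kmer_db(s, 18, f, "x"))
  for (i in 1:3)
    expect_true(all(dbs[[i]]$kmers %in% dbs[[i + 1]]$kmers))
  # deterministic across runs
  expect_identical(build_kmer_db(s, 18, 0.1, "a")$kmers, sk$kmers)
})

test_that("databases round-trip through the on-disk format bit-exactly", {
  s <- random_dna(5000, seed = 3)
  db <- build_kmer_db(tibble::tibble(id = "x", seq = s), 25, 0.1,
                      "plasmid")
  path <- withr::local_tempfile()
  write_kmer_db(db, path)
  db2 <- read_kmer_db(path)
  expect_identical(db2$kmers, db$kmers)
  expect_identical(db2$k, db$k)
  expect_identical(db2$sketch_fraction, db$sketch_fraction)
  expect_identical(db2$label, db$label)
  expect_identical(db2$source_count, db$source_count)
  # unknown version rejected
  lines <- readLines(path)
  lines[1] <- "#format\tsomething_else/9"
  writeLines(lines, path)
  expect_error(read_kmer_db(path), "format")
})

test_that("subtract matches naive set algebra and checks k", {
  a <- db_from_kmers(c("AAA", "ACA", "AGA"), 3)
  b <- db_from_kmers("ACA", 3)
  expect_setequal(cpp_decode_kmers(subtract_kmer_db(a, b)$kmers, 3),
                  c("AAA", "AGA"))
  expect_length(subtract_kmer_db(a, a)$kmers, 0)
  expect_error(subtract_kmer_db(a, db_from_kmers("ACAA", 4)), "k mismatch")
  # random 1000-k-mer sets against the R set-algebra oracle
  set.seed(7)
  for (rep in 1:5) {
    ka <- sample(0:(4^9 - 1), 1000)
    kb <- sample(0:(4^9 - 1), 1000)
    A <- plasmidr:::new_kmer_db(9L, sort(as.numeric(ka)), 1, "a", 42L, 0L)
    B <- plasmidr:::new_kmer_db(9L, sort(as.numeric(kb)), 1, "b", 42L, 0L)
    d <- subtract_kmer_db(A, B)
    expect_setequal(d$kmers, setdiff(A$kmers, B$kmers))
    expect_length(intersect(d$kmers, B$kmers), 0)
    expect_equal(length(d$kmers) + length(intersect(A$kmers, B$kmers)),
                 length(A$kmers))
  }
})

test_that("shared_fraction is query-relative and sketch-consistent", {
  s <- random_dna(4000, seed = 21)
  one <- tibble::tibble(id = "q", seq = s)
  # verbatim self-query scores 1.0 even against a sketched database
  db <- build_kmer_db(one, 18, 0.1, "src")
  expect_equal(query_kmer_db(one, db)$shared_fraction, 1.0)
  # compositionally disjoint query scores 0
  at_only <- tibble::tibble(id = "at", seq = strrep("AT", 500))
  cg_db <- build_kmer_db(strrep("CG", 2000), 18, 1, "cg")
  expect_equal(query_kmer_db(at_only, cg_db)$shared_fraction, 0)
  # hand-checkable example: query {ACG, GTA} vs db {ACG}
  r <- query_kmer_db(tibble::tibble(id = "q", seq = "ACGTAC"),
                     db_from_kmers("ACG", 3))
  expect_equal(r$n_query_kmers, 2)
  expect_equal(r$n_shared, 1)
  expect_equal(r$shared_fraction, 0.5)
  # no informative k-mers
  nn <- query_kmer_db(tibble::tibble(id = "n", seq = "NNNNNNNN"), db)
  expect_equal(nn$shared_fraction, 0)
  expect_true(nn$no_informative_kmers)
})

test_that("k-mer queries are invariant to reverse complement", {
  db <- tiny_dbs()$r_k18
  for (seed in 1:10) {
    s <- random_dna(800, seed + 100)
    f <- query_kmer_db(tibble::tibble(id = "q", seq = s), db)
    r <- query_kmer_db(tibble::tibble(id = "q", seq = plasmidr:::revcomp(s)),
                       db)
    expect_identical(f, r)
  }
})

test_that("shared fractions stay within [0, 1]", {
  db <- tiny_dbs()$p_k25
  fr <- query_kmer_db(tibble::tibble(
    id = c("a", "b", "c"),
    seq = c(random_dna(300, 1), substr(tiny_genome()$replicons$seq[2], 1, 500),
            "NNNN")), db)$shared_fraction
  expect_true(all(fr >= 0 & fr <= 1))
})
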