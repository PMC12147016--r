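test_that("generation is a deterministic function of the spec seed", {
  spec <- synthetic_spec(n_transcripts = 20, seed = 99)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_cds_fasta(d1, f1); write_cds_fasta(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- generate_dataset(synthetic_spec(n_transcripts = 20, seed = 100))
  expect_false(identical(d1$transcripts[[1]]$sequence,
                         d3$transcripts[[1]]$sequence))
})

test_that("generation does not disturb the session RNG stream", {
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(runif(1))
  invisible(generate_dataset(synthetic_spec(n_transcripts = 3, seed = 5)))
  expect_equal(runif(2), before[2:3])
})

test_that("scanned stretches equal the injected ground truth", {
  for (seed in c(1, 2, 3)) {
    spec <- synthetic_spec(n_transcripts = 40, stretch_rate = 3, seed = seed)
    ds <- generate_dataset(spec)
    found <- scan_stretches(ds)
    truth <- ds$truth
    expect_equal(nrow(found), nrow(truth))
    key <- c("transcript_id", "start", "length", "ga", "n_caa", "n_cag",
             "purity")
    f <- found[order(found$transcript_id, found$start), key]
    t <- truth[order(truth$transcript_id, truth$start), key]
    rownames(f) <- NULL; rownames(t) <- NULL
    expect_equal(f, t)
  }
})

test_that("a zero stretch rate yields transcripts without any Q codons", {
  ds <- generate_dataset(synthetic_spec(n_transcripts = 10, stretch_rate = 0,
                                        seed = 4))
  expect_equal(nrow(ds$truth), 0)
  expect_equal(nrow(scan_stretches(ds)), 0)
})

test_that("stretches and transcripts are valid frame-0 CDS over ACGT", {
  ds <- generate_dataset(synthetic_spec(n_transcripts = 15, seed = 6))
  for (tx in ds$transcripts) {
    expect_equal(nchar(tx$sequence) %% 3, 0)
    expect_false(grepl("[^ACGT]", tx$sequence))
    # internal codons contain no stop; the appended terminal codon is one
    expect_false(any(tx$codons %in% c("TAA", "TAG", "TGA")))
    last <- substr(tx$sequence, nchar(tx$sequence) - 2, nchar(tx$sequence))
    expect_true(last %in% c("TAA", "TAG", "TGA"))
  }
})

test_that("infeasible stretch lengths are rejected", {
  spec <- synthetic_spec(transcript_length_codons = c(20, 30),
                         stretch_length_dist = setNames(1, 50))
  expect_error(generate_dataset(spec), "infeasible")
})

test_that("length-dependent usage is recovered per class", {
  p_by_len <- setNames(c(0.5, 0.56, 0.62, 0.68, 0.74, 0.8, 0.7),
                       c(as.character(1:6), ">6"))
  set.seed(71)
  st <- simulate_stretches(20000, synthetic_spec(p_cag_by_length = p_by_len))
  u <- usage_profile(st)
  for (cl in c("1", "2", "3", "4")) {   # classes with plenty of codons
    row <- u[u$class == cl, ]
    n <- row$n_caa + row$n_cag
    p0 <- p_by_len[[cl]]
    expect_lt(abs(row$cag_fraction - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("background Q codons keep scan output internally consistent", {
  ds <- generate_dataset(synthetic_spec(n_transcripts = 30, bg_q_rate = 0.02,
                                        seed = 8))
  st <- scan_stretches(ds)
  expect_gt(nrow(st), nrow(ds$truth))   # chance runs appear in the filler
  # maximality still holds for every scanned stretch
  expect_false(any(st$up_1 %in% c("CAA", "CAG")))
  expect_false(any(st$down_1 %in% c("CAA", "CAG")))
})

test_that("simulate_stretches honours lengths and composition labels", {
  set.seed(72)
  st <- simulate_stretches(100, synthetic_spec(), lengths = c(4L, 7L))
  expect_setequal(unique(st$length), c(4L, 7L))
  expect_equal(nchar(st$ga), st$length)
  expect_equal(st$n_caa + st$n_cag, st$length)
  lab <- ifelse(st$n_caa == 0, "pure_CAG",
                ifelse(st$n_cag == 0, "pure_CAA", "mixed"))
  expect_equal(st$purity, lab)
})

test_that("the recovery suite passes on a biased spec and flags neutrality", {
  rep_biased <- recovery_suite(synthetic_spec(
    n_transcripts = 150, stretch_rate = 4, caa_cterm_bias = 3,
    flank_similarity_bias = 0.7, seed = 9))
  expect_true(rep_biased$detection$pass)
  expect_true(rep_biased$usage$pass)
  expect_true(rep_biased$position$pass)
  expect_true(rep_biased$flank$pass)

  rep_neutral <- recovery_suite(synthetic_spec(n_transcripts = 60, seed = 10))
  expect_true(rep_neutral$detection$pass)
  expect_true(is.na(rep_neutral$position$pass))  # no bias to confirm
  expect_true(is.na(rep_neutral$flank$pass))
})
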