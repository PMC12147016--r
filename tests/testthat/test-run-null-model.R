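test_that("max-run PMF satisfies its boundary identities and normalisation", {
  for (L in c(1, 2, 5, 9)) {
    for (p in c(0, 0.25, 0.5, 0.75, 1)) {
      pm <- max_run_pmf(L, p)
      expect_equal(sum(pm$pmf), 1, tolerance = 1e-12)
      expect_equal(unname(pm$pmf[as.character(L)]), p^L)
      expect_equal(unname(pm$pmf[as.character(0)]), (1 - p)^L)
    }
  }
  pm <- max_run_pmf(5, 1)
  expect_equal(unname(pm$pmf[as.character(5)]), 1)
  expect_equal(sum(pm$pmf[1:5]), 0)
  expect_error(max_run_pmf(80, 0.5), "cap")
})

test_that("the DP equals exhaustive enumeration on small stretches", {
  for (L in c(1, 3, 8)) {
    for (p in c(0.1, 0.3, 0.75)) {
      expect_equal(unname(max_run_pmf(L, p)$pmf), oracle_max_run_pmf(L, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("random stretches are i.i.d. draws reproducible under a seed", {
  expect_equal(polyqscan:::with_rng_seed(5, generate_random_stretch(4, 1)),
               "GGGG")
  expect_equal(polyqscan:::with_rng_seed(5, generate_random_stretch(6, 0)),
               "AAAAAA")
  s1 <- polyqscan:::with_rng_seed(99, generate_random_stretch(10, 0.6, n = 5))
  s2 <- polyqscan:::with_rng_seed(99, generate_random_stretch(10, 0.6, n = 5))
  expect_identical(s1, s2)

  # empirical max-run histogram agrees with the exact PMF
  set.seed(123)
  draws <- generate_random_stretch(5, 0.75, n = 20000)
  emp <- tabulate(max_identical_run(draws, "CAG") + 1, nbins = 6) / 20000
  pm <- max_run_pmf(5, 0.75)$pmf
  se <- sqrt(pm * (1 - pm) / 20000)
  expect_true(all(abs(emp - pm) < 4 * se + 1e-9))
})

test_that("random cohorts are length-matched with class-specific usage", {
  set.seed(14)
  st <- simulate_stretches(300, synthetic_spec())
  u <- usage_profile(st)
  rnd <- random_cohort(st, u)
  expect_equal(nchar(rnd), st$length)            # exact length matching

  # degenerate all-CAG usage gives all-CAG randoms
  st_g <- simulate_stretches(50, synthetic_spec(p_cag_by_length = 1))
  rnd_g <- random_cohort(st_g, usage_profile(st_g))
  expect_true(all(grepl("^G+$", rnd_g)))

  # a length class absent from usage falls back to bg with a warning
  st2 <- st[st$length <= 2, ]
  u2 <- usage_profile(st2)
  st2$length[1] <- 5L
  st2$ga[1] <- "GGGGA"
  expect_warning(rnd2 <- random_cohort(st2, u2), "bg")
  expect_equal(nchar(rnd2[1]), 5L)
})

test_that("cohort max-run distribution matches the PMF mixture over lengths", {
  set.seed(15)
  st <- simulate_stretches(4000, synthetic_spec(p_cag_by_length = 0.7),
                           lengths = rep(c(4L, 6L), 2000))
  u <- usage_profile(st)
  rnd <- random_cohort(st, u)
  mr <- max_identical_run(rnd, "CAG")
  # mixture: half the cohort at L=4, half at L=6, at the class usage values
  p4 <- u$cag_fraction[u$class == "4"]
  p6 <- u$cag_fraction[u$class == "6"]
  mix <- c(max_run_pmf(4, p4)$pmf, numeric(2)) / 2 + max_run_pmf(6, p6)$pmf / 2
  emp <- tabulate(mr + 1, nbins = 7) / 4000
  se <- sqrt(mix * (1 - mix) / 4000)
  expect_true(all(abs(emp - mix) < 4 * se + 1e-9))
})

test_that("observed-vs-random comparisons detect construction and identity", {
  set.seed(16)
  st <- simulate_stretches(200, synthetic_spec(), lengths = 4 + rpois(200, 2))
  # identical cohorts: every bin comparison has p = 1
  cmp <- compare_observed_random(st, st$ga)
  expect_true(all(cmp$p_value[!is.na(cmp$p_value)] == 1))
  expect_equal(cmp$median_observed, cmp$median_random)

  # forced CAA interruptions every 2 codons vs random at high CAG usage
  lens <- rep(8L, 300)
  interrupted <- vapply(lens, function(L)
    paste(rep(c("G", "G", "A"), length.out = L), collapse = ""), character(1))
  st_int <- data.frame(transcript_id = "t", species_code = "syn",
                       start = 0L, length = lens, ga = interrupted,
                       n_caa = vapply(strsplit(interrupted, ""),
                                      function(x) sum(x == "A"), integer(1)),
                       n_cag = NA, purity = "mixed",
                       stringsAsFactors = FALSE)
  st_int$n_cag <- st_int$length - st_int$n_caa
  rnd <- random_cohort(st_int, usage_profile(st_int))
  cmp2 <- compare_observed_random(st_int, rnd)
  row <- cmp2[cmp2$codon == "CAG" & cmp2$length_bin == "len8plus", ]
  expect_lt(row$median_observed, row$median_random)
  expect_lt(row$p_value, 0.001)

  # empty bins are marked missing
  expect_true(any(is.na(cmp2$p_value[cmp2$length_bin == "len4to5"])))
})
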