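flank_fixture <- function(ga, up_1 = NA_character_, down_1 = NA_character_,
                          species = "syn") {
  n_caa <- sum(strsplit(ga, "")[[1]] == "A")
  df <- data.frame(transcript_id = "t", species_code = species,
                   start = 0L, length = nchar(ga), ga = ga,
                   n_caa = n_caa, n_cag = nchar(ga) - n_caa,
                   purity = if (n_caa == 0) "pure_CAG"
                            else if (n_caa == nchar(ga)) "pure_CAA"
                            else "mixed",
                   stringsAsFactors = FALSE)
  for (col in paste0("up_", 5:1)) df[[col]] <- NA_character_
  for (col in paste0("down_", 1:5)) df[[col]] <- NA_character_
  df$up_1 <- up_1; df$down_1 <- down_1
  df
}

test_that("hamming counts mismatched positions and validates input", {
  expect_equal(hamming("CAG", "CAG"), 0L)
  expect_equal(hamming("CAG", "CAT"), 1L)
  expect_equal(hamming("CAG", "GTC"), 3L)
  expect_equal(hamming("cag", "CAT"), 1L)        # case-insensitive
  expect_equal(hamming("CAN", "CAG"), 1L)        # ambiguity mismatches
  expect_equal(hamming("CAN", "CAN"), 0L)        # ... except itself
  expect_error(hamming("CAGT", "CAG"), "length-3")
  expect_equal(hamming(c("CAG", "CAA"), "CAA"), c(1L, 0L))  # vectorised
})

test_that("hamming is a metric on the full 64x64 codon table", {
  codons <- polyqscan:::ALL_CODONS
  D <- outer(seq_along(codons), seq_along(codons),
             function(i, j) hamming(codons[i], codons[j]))
  expect_true(all(diag(D) == 0))
  expect_true(all(D[upper.tri(D)] > 0))          # identity of indiscernibles
  expect_equal(D, t(D))                           # symmetry
  for (j in seq_along(codons)) {                  # triangle inequality
    expect_true(all(D <= outer(D[, j], D[j, ], `+`)))
  }
  # every glutamine codon has a sense non-Q neighbour at distance exactly 1
  non_q <- polyqscan:::NON_Q_SENSE_CODONS
  expect_equal(min(hamming(rep("CAG", length(non_q)), non_q)), 1L)
  expect_equal(min(hamming(rep("CAA", length(non_q)), non_q)), 1L)
})

test_that("flank records use the adjacent stretch codon and skip missing flanks", {
  st <- flank_fixture("GG", down_1 = "CCA")
  rec <- flank_distances(st)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$side, "plus1")
  expect_equal(rec$distance, 2L)                 # CAG vs CCA: A->C, G->A
  expect_equal(rec$purity, "pure_CAG")

  # mixed stretch: the codon adjacent to the flank is the reference
  st2 <- flank_fixture("GA", up_1 = "GAG", down_1 = "GAG")
  rec2 <- flank_distances(st2)
  expect_equal(rec2$distance[rec2$side == "minus1"], 1L)  # CAG vs GAG
  expect_equal(rec2$distance[rec2$side == "plus1"], 2L)   # CAA vs GAG

  # mean-over-stretch reference mode
  rec3 <- flank_distances(st2, reference = "mean")
  expect_equal(rec3$distance[rec3$side == "plus1"], 1.5)  # mean(1, 2)

  # length filter and missing flanks
  expect_equal(nrow(flank_distances(flank_fixture("G", down_1 = "CCA"))), 0)
  expect_equal(nrow(flank_distances(flank_fixture("GG"))), 0)
})

test_that("purity and side comparisons are laid out as in the figures", {
  rec <- rbind(
    data.frame(species_code = "syn", transcript_id = "t",
               purity = "pure_CAG", side = "plus1",
               distance = rep(1, 20), stretch_length = 2),
    data.frame(species_code = "syn", transcript_id = "t",
               purity = "pure_CAA", side = "plus1",
               distance = rep(3, 20), stretch_length = 2),
    data.frame(species_code = "syn", transcript_id = "t",
               purity = "mixed", side = "plus1",
               distance = rep(2, 20), stretch_length = 2))
  cmp <- compare_flank_distances(rec, group_by = "purity")
  expect_equal(cmp$group_a, c("pure_CAA", "mixed", "mixed"))
  expect_equal(cmp$group_b, c("pure_CAG", "pure_CAG", "pure_CAA"))
  row1 <- cmp[1, ]
  expect_lt(row1$mean_b, row1$mean_a)            # pure CAG closer to flank
  expect_equal(row1$u_statistic, 0)              # complete separation
  expect_lt(row1$p_value, 0.001)
  expect_true(all(!is.na(cmp$p_adj_bh)))

  # identical groups: p = 1 by symmetry
  rec_same <- rec
  rec_same$distance <- rep(2, nrow(rec_same))
  cmp_same <- compare_flank_distances(rec_same, group_by = "purity")
  expect_true(all(cmp_same$p_value == 1))

  # side layout (pure CAG only)
  rec2 <- rbind(rec[rec$purity == "pure_CAG", ],
                transform(rec[rec$purity == "pure_CAG", ], side = "minus1",
                          distance = 3))
  cmp2 <- compare_flank_distances(rec2, group_by = "side")
  expect_equal(nrow(cmp2), 1)
  expect_equal(cmp2$group_a, "minus1")
  expect_lt(cmp2$mean_b, cmp2$mean_a)

  # a group with no records is marked missing
  cmp3 <- compare_flank_distances(rec[rec$purity != "pure_CAA", ],
                                  group_by = "purity")
  expect_true(is.na(cmp3$p_value[cmp3$group_a == "pure_CAA"]))
})

test_that("a +1 similarity bias for pure-CAG stretches is detected", {
  set.seed(21)
  st <- simulate_stretches(3000, synthetic_spec(p_cag_by_length = 0.5,
                                                flank_similarity_bias = 0.6),
                           lengths = 2 + rpois(3000, 1))
  cmp <- compare_flank_distances(flank_distances(st), group_by = "purity")
  row <- cmp[cmp$group_a == "pure_CAA" & cmp$group_b == "pure_CAG", ]
  expect_lt(row$mean_b, row$mean_a)
  expect_lt(row$p_value, 0.001)
})
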