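#' Hamming distance between two codons
#'
#' Number of mismatched nucleotide positions between two 3-mers
#' (case-insensitive). Ambiguity letters match only themselves, so e.g.
#' \code{hamming("CAN", "CAN")} is 0 but \code{hamming("CAN", "CAG")} is 1.
#'
#' @param codon_a,codon_b length-3 strings (vectorised; recycled).
#' @return integer vector of distances in 0..3.
#' @examples
#' hamming("CAG", "CAT")  # 1
#' hamming("CAG", "GTC")  # 3
#' @export
hamming <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (any(nchar(codon_a) != 3L) || any(nchar(codon_b) != 3L))
    stop("hamming is defined on length-3 codons")
  n <- max(length(codon_a), length(codon_b))
  codon_a <- rep_len(codon_a, n); codon_b <- rep_len(codon_b, n)
  a <- matrix(unlist(strsplit(codon_a, "")), nrow = 3L)
  b <- matrix(unlist(strsplit(codon_b, "")), nrow = 3L)
  as.integer(colSums(a != b))
}

#' Nucleotide similarity between stretches and their -1/+1 flanking codons
#'
#' For every stretch of length >= \code{min_length} with a present flank on a
#' side, emits the Hamming distance between the flank codon and the stretch
#' codon adjacent to that flank (the last stretch codon for side +1, the
#' first for side -1) -- the codon whose point mutation would generate the
#' flank. For mixed stretches the choice of reference codon is genuinely
#' ambiguous; \code{reference = "mean"} instead reports, per side, the mean
#' distance from the flank to all stretch codons.
#'
#' Flank codons of a maximal stretch are never CAA/CAG, so distances to
#' present flanks are always in 1..3.
#'
#' @param stretches a stretch table from \code{\link{scan_stretches}}.
#' @param min_length minimum stretch length (default 2, as the analysis
#'   targets runs rather than isolated glutamines).
#' @param reference "adjacent" (default) or "mean"; see Details.
#' @return a data.frame with columns species_code, transcript_id, purity,
#'   side ("minus1"/"plus1"), distance, stretch_length.
#' @export
flank_distances <- function(stretches, min_length = 2L,
                            reference = c("adjacent", "mean")) {
  reference <- match.arg(reference)
  st <- stretches[stretches$length >= min_length, , drop = FALSE]
  rows <- list()
  for (side in c("minus1", "plus1")) {
    flank <- if (side == "minus1") st$up_1 else st$down_1
    ok <- !is.na(flank)
    if (!any(ok)) next
    sub <- st[ok, , drop = FALSE]
    if (reference == "adjacent") {
      term <- if (side == "minus1") substr(sub$ga, 1, 1)
              else substr(sub$ga, sub$length, sub$length)
      ref_codon <- ifelse(term == "G", "CAG", "CAA")
      d <- hamming(ref_codon, flank[ok])
    } else {
      d <- mapply(function(ga, fl) {
        ch <- strsplit(ga, "")[[1]]
        mean(hamming(ifelse(ch == "G", "CAG", "CAA"), fl))
      }, sub$ga, flank[ok], USE.NAMES = FALSE)
    }
    rows[[side]] <- data.frame(
      species_code = sub$species_code,
      transcript_id = sub$transcript_id,
      purity = sub$purity,
      side = side,
      distance = d,
      stretch_length = sub$length,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(species_code = character(0),
                      transcript_id = character(0), purity = character(0),
                      side = character(0), distance = numeric(0),
                      stretch_length = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(match(out$side, c("minus1", "plus1"))), , drop = FALSE]
}

#' Rank-sum comparisons of flanking-codon distances
#'
#' Two comparison layouts:
#' \itemize{
#'   \item \code{group_by = "purity"}: within the +1 side, pairwise tests
#'     pure_CAA vs pure_CAG, mixed vs pure_CAG, mixed vs pure_CAA (the
#'     purity-class contrast).
#'   \item \code{group_by = "side"}: within pure_CAG stretches, -1 vs +1
#'     distances (the upstream/downstream contrast).
#' }
#' A Benjamini-Hochberg adjusted p-value column is emitted alongside the raw
#' per-comparison p-values.
#'
#' @param records output of \code{\link{flank_distances}}.
#' @param group_by "purity" or "side".
#' @param side which side to use when grouping by purity (default "plus1").
#' @param purity which purity class when grouping by side (default
#'   "pure_CAG").
#' @return a data.frame with one row per comparison: group_a, group_b, the
#'   \code{\link{mann_whitney_u}} summary columns, and p_adj_bh. Comparisons
#'   with an empty group have NA statistics.
#' @export
compare_flank_distances <- function(records, group_by = c("purity", "side"),
                                    side = "plus1", purity = "pure_CAG") {
  group_by <- match.arg(group_by)
  if (group_by == "purity") {
    rec <- records[records$side == side, , drop = FALSE]
    pairs <- list(c("pure_CAA", "pure_CAG"),
                  c("mixed", "pure_CAG"),
                  c("mixed", "pure_CAA"))
    groups <- split(rec$distance, rec$purity)
  } else {
    rec <- records[records$purity == purity, , drop = FALSE]
    pairs <- list(c("minus1", "plus1"))
    groups <- split(rec$distance, rec$side)
  }
  res <- lapply(pairs, function(p) {
    ga <- groups[[p[1]]]; gb <- groups[[p[2]]]
    rt <- if (length(ga) >= 1 && length(gb) >= 1) mann_whitney_u(ga, gb)
          else NULL
    cbind(data.frame(group_a = p[1], group_b = p[2],
                     stringsAsFactors = FALSE),
          rank_test_row(rt))
  })
  out <- do.call(rbind, res)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
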