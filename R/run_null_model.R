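#' Exact distribution of the longest CAG run under independent codon choice
#'
#' Inside a glutamine stretch of L codons where each codon is independently
#' CAG with probability \code{p_cag} (else CAA), computes the exact
#' probability mass function of the length of the longest run of consecutive
#' CAG codons, by dynamic programming over (current trailing run, maximum run
#' so far). This is the chance model against which observed maximum runs are
#' judged: boundary identities pmf(L) = p^L (no CAA at all) and
#' pmf(0) = (1-p)^L hold exactly.
#'
#' Swapping the roles of the codons (longest CAA run) is
#' \code{max_run_pmf(L, 1 - p_cag)}.
#'
#' @param L stretch length in codons (>= 1).
#' @param p_cag per-codon CAG probability in [0, 1].
#' @param max_L guard for the DP size (default 64); longer stretches should
#'   use Monte-Carlo via \code{\link{generate_random_stretch}}.
#' @return an object of class \code{"max_run_pmf"}: list with \code{L},
#'   \code{p_cag} and \code{pmf}, a numeric vector of length L+1 whose k+1-th
#'   element is P(longest CAG run = k), k = 0..L.
#' @examples
#' pm <- max_run_pmf(5, 0.75)
#' round(100 * pm$pmf[c(4, 5, 6)], 2)  # 23.73 15.82 23.73 (k = 3, 4, 5)
#' @export
max_run_pmf <- function(L, p_cag, max_L = 64L) {
  stopifnot(L >= 1, p_cag >= 0, p_cag <= 1)
  if (L > max_L)
    stop("L exceeds the exact-DP cap (", max_L,
         "); use generate_random_stretch() for a Monte-Carlo null")
  p <- p_cag; q <- 1 - p_cag
  # state[r + 1, m + 1] = P(current trailing CAG run = r, max run so far = m)
  state <- matrix(0, nrow = L + 1, ncol = L + 1)
  state[1, 1] <- q   # first codon CAA
  state[2, 2] <- p   # first codon CAG
  if (L > 1) {
    for (i in 2:L) {
      nxt <- matrix(0, nrow = L + 1, ncol = L + 1)
      for (m in 0:(i - 1)) {
        for (r in 0:m) {
          pr <- state[r + 1, m + 1]
          if (pr == 0) next
          nxt[1, m + 1] <- nxt[1, m + 1] + pr * q
          m2 <- max(m, r + 1)
          nxt[r + 2, m2 + 1] <- nxt[r + 2, m2 + 1] + pr * p
        }
      }
      state <- nxt
    }
  }
  pmf <- colSums(state)
  names(pmf) <- 0:L
  structure(list(L = L, p_cag = p_cag, pmf = pmf), class = "max_run_pmf")
}

#' @export
print.max_run_pmf <- function(x, ...) {
  cat(sprintf("Longest-CAG-run PMF, L = %d, P(CAG) = %g:\n", x$L, x$p_cag))
  print(round(x$pmf, 6))
  invisible(x)
}

#' Draw random glutamine stretches under the i.i.d. codon model
#'
#' L independent codons, CAG with probability \code{p_cag} else CAA, encoded
#' as a G/A composition string (the same encoding the stretch table uses).
#'
#' @param L stretch length (codons).
#' @param p_cag per-codon CAG probability.
#' @param n number of stretches to draw.
#' @return character vector of n composition strings of length L.
#' @export
generate_random_stretch <- function(L, p_cag, n = 1L) {
  stopifnot(L >= 1)
  draws <- matrix(ifelse(runif(n * L) < p_cag, "G", "A"), nrow = n)
  apply(draws, 1, paste, collapse = "")
}

#' Length-matched random cohort for observed stretches
#'
#' Implements the null-cohort construction used throughout: one random
#' stretch per observed stretch, of identical length, with the per-codon CAG
#' probability taken from the length-specific usage class containing that
#' length (exact classes up to the pooling threshold, the pooled ">6"-style
#' class above it). A usage class with no codons falls back to the background
#' ("bg") usage with a warning.
#'
#' @param stretches a stretch table from \code{\link{scan_stretches}}.
#' @param usage a \code{\link{usage_profile}} computed from the same species'
#'   stretches.
#' @param exact_length_usage if TRUE, lengths above the pooling threshold use
#'   their exact-length usage where available instead of the pooled class.
#' @return character vector of composition strings, parallel to
#'   \code{stretches}.
#' @export
random_cohort <- function(stretches, usage, exact_length_usage = FALSE) {
  stopifnot(inherits(usage, "usage_profile"))
  pool <- attr(usage, "pool_threshold")
  frac <- setNames(usage$cag_fraction, usage$class)
  cls <- usage_class(stretches$length, pool)
  if (exact_length_usage) {
    # exact-length usage where computable, pooled class otherwise
    exact <- vapply(stretches$length, function(l) {
      sel <- stretches$length == l
      tot <- sum(stretches$n_caa[sel]) + sum(stretches$n_cag[sel])
      if (tot > 0) sum(stretches$n_cag[sel]) / tot else NA_real_
    }, numeric(1))
    p <- ifelse(is.na(exact), frac[cls], exact)
  } else {
    p <- frac[cls]
  }
  if (anyNA(p)) {
    warning("usage class missing for some lengths; falling back to bg usage")
    p[is.na(p)] <- frac[["bg"]]
  }
  vapply(seq_len(nrow(stretches)), function(i) {
    generate_random_stretch(stretches$length[i], p[[i]])
  }, character(1))
}

RUN_BINS <- c("len4to5", "len6to7", "len8plus")

run_length_bin <- function(length) {
  ifelse(length >= 8, "len8plus", ifelse(length >= 6, "len6to7",
         ifelse(length >= 4, "len4to5", NA_character_)))
}

#' Observed vs random maximum identical-codon runs
#'
#' Per codon (CAA, CAG) and stretch-length bin (4-5, 6-7, >= 8 codons),
#' compares the observed distribution of maximum identical-codon runs with
#' the one from a length-matched random cohort, by Mann-Whitney U test, with
#' group medians. Stretches shorter than 4 codons are not binned.
#'
#' @param stretches a stretch table from \code{\link{scan_stretches}}.
#' @param randoms character vector of composition strings, one per observed
#'   stretch (e.g. from \code{\link{random_cohort}}).
#' @return a data.frame with one row per codon x bin: codon, length_bin, n,
#'   median_observed, median_random, the \code{\link{mann_whitney_u}} summary
#'   columns and p_adj_bh; empty bins have NA statistics.
#' @export
compare_observed_random <- function(stretches, randoms) {
  stopifnot(nrow(stretches) == length(randoms))
  stopifnot(all(stretches$length == nchar(randoms)))
  bin <- run_length_bin(stretches$length)
  res <- list()
  for (codon in c("CAA", "CAG")) {
    obs_all <- max_identical_run(stretches$ga, codon)
    rnd_all <- max_identical_run(randoms, codon)
    for (b in RUN_BINS) {
      sel <- !is.na(bin) & bin == b
      rt <- if (sum(sel) >= 1)
        mann_whitney_u(obs_all[sel], rnd_all[sel]) else NULL
      res[[paste(codon, b)]] <- cbind(
        data.frame(codon = codon, length_bin = b, n = sum(sel),
                   median_observed = if (sum(sel)) median(obs_all[sel]) else NA_real_,
                   median_random = if (sum(sel)) median(rnd_all[sel]) else NA_real_,
                   stringsAsFactors = FALSE),
        rank_test_row(rt))
    }
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
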