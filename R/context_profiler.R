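CONTEXT_POSITIONS <- c(paste0("-", 5:1), paste0("+", 1:5))
AA_LETTERS <- c(sort(unique(setdiff(Biostrings::GENETIC_CODE, "*"))), "X")
LENGTH_BINS_CONTEXT <- c("len4to7", "len8plus")

#' Translate a codon under the standard genetic code
#'
#' Standard code (table 1); any codon containing a non-ACGT letter translates
#' to "X"; stop codons to "*".
#'
#' @param codon character vector of 3-mers.
#' @return character vector of amino-acid letters ("X" for ambiguous, "*" for
#'   stop).
#' @examples
#' translate_codon(c("CAT", "CCN", "TAA"))  # "H" "X" "*"
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa[is.na(aa) & !is.na(codon)] <- "X"
  aa
}

#' Amino-acid context around polyQ stretches
#'
#' Tallies the translated flanking codons at positions -5..-1 and +1..+5, per
#' purity class and stretch-length bin (4-7 codons vs >= 8 codons; shorter
#' stretches are excluded). Missing flanks (transcript boundary) contribute
#' nothing, so per-position totals can be below n_stretches.
#'
#' @param stretches a stretch table from \code{\link{scan_stretches}}.
#' @return a list of \code{"context_table"} objects (one per purity x bin
#'   with at least one stretch), each holding \code{species_code},
#'   \code{purity}, \code{length_bin}, \code{n_stretches} and \code{counts}
#'   (amino-acid x position matrix).
#' @export
context_table <- function(stretches) {
  st <- stretches[stretches$length >= 4, , drop = FALSE]
  if (nrow(st) == 0) return(list())
  st$length_bin <- ifelse(st$length >= 8, "len8plus", "len4to7")
  flank_cols <- c(FLANK_COLS_UP, FLANK_COLS_DOWN)
  groups <- split(st, list(st$purity, st$length_bin), drop = TRUE)
  out <- lapply(groups, function(g) {
    counts <- matrix(0L, nrow = length(AA_LETTERS),
                     ncol = length(CONTEXT_POSITIONS),
                     dimnames = list(AA_LETTERS, CONTEXT_POSITIONS))
    for (j in seq_along(flank_cols)) {
      codons <- g[[flank_cols[j]]]
      aa <- translate_codon(codons[!is.na(codons)])
      aa <- aa[aa != "*"]  # only reachable when stop stripping is off
      if (length(aa) > 0) {
        tab <- table(factor(aa, levels = AA_LETTERS))
        counts[, j] <- counts[, j] + as.integer(tab)
      }
    }
    structure(list(species_code = unique(g$species_code),
                   purity = unique(g$purity),
                   length_bin = unique(g$length_bin),
                   n_stretches = nrow(g),
                   counts = counts),
              class = "context_table")
  })
  names(out) <- NULL
  out
}

#' @export
print.context_table <- function(x, ...) {
  cat(sprintf("<context_table> %s %s %s (%d stretches)\n",
              x$species_code, x$purity, x$length_bin, x$n_stretches))
  top <- vapply(CONTEXT_POSITIONS, function(p) {
    t <- top_non_q(x, p)
    if (is.na(t$aa)) "-" else t$aa
  }, character(1))
  cat("top non-Q aa: ", paste(sprintf("%s:%s", CONTEXT_POSITIONS, top),
                              collapse = " "), "\n")
  invisible(x)
}

#' Most frequent non-glutamine amino acid at a context position
#'
#' Returns the amino acid (excluding Q and X) with the highest count at the
#' given position; NA when no non-Q amino acid occurs there. Ties are broken
#' alphabetically and flagged. Glutamine dominates most context positions, so
#' leaving it out exposes the rest of the compositional signal; with a
#' proteome background from \code{\link{proteome_aa_usage}} the
#' proteome-normalised enrichment ratio is reported alongside.
#'
#' @param table a \code{"context_table"}.
#' @param position one of "-5".."-1", "+1".."+5" (also accepts integers -5..5).
#' @param background optional named proportion vector from
#'   \code{\link{proteome_aa_usage}}; when supplied the returned list gains
#'   \code{enrichment} = position frequency / proteome frequency of the top
#'   amino acid.
#' @return list with \code{aa} (letter or NA), \code{count}, \code{freq},
#'   \code{tie} (logical), and optionally \code{enrichment}.
#' @export
top_non_q <- function(table, position, background = NULL) {
  if (is.numeric(position))
    position <- sprintf("%+d", position)
  if (!position %in% CONTEXT_POSITIONS)
    stop("position must be one of ", paste(CONTEXT_POSITIONS, collapse = " "))
  cnt <- table$counts[, position]
  cnt <- cnt[!names(cnt) %in% c("Q", "X")]
  if (sum(cnt) == 0 || max(cnt) == 0)
    return(list(aa = NA_character_, count = 0L, freq = NA_real_, tie = FALSE))
  winners <- names(cnt)[cnt == max(cnt)]
  aa <- sort(winners)[1]
  out <- list(aa = aa, count = unname(max(cnt)),
              freq = unname(max(cnt) / sum(table$counts[, position])),
              tie = length(winners) > 1)
  if (!is.null(background)) {
    pos_freq <- unname(cnt[aa] / sum(cnt))
    out$enrichment <- if (!is.na(background[aa]) && background[aa] > 0)
      pos_freq / unname(background[aa]) else NA_real_
  }
  out
}

#' Proteome-wide amino-acid usage
#'
#' Amino-acid frequencies over all translated sense codons of all transcripts
#' (stop codons excluded; ambiguous codons count as "X"). Used as the
#' background for context enrichment ratios.
#'
#' @param transcripts a \code{cds_set} or list of transcript records.
#' @return named numeric vector of proportions (sums to 1), empty input gives
#'   an all-zero vector.
#' @export
proteome_aa_usage <- function(transcripts) {
  if (inherits(transcripts, "cds_set")) transcripts <- transcripts$transcripts
  codons <- unlist(lapply(transcripts, `[[`, "codons"))
  zero <- setNames(numeric(length(AA_LETTERS)), AA_LETTERS)
  if (length(codons) == 0) return(zero)
  aa <- translate_codon(codons)
  aa <- aa[aa != "*"]
  if (length(aa) == 0) return(zero)
  tab <- table(factor(aa, levels = AA_LETTERS))
  prop <- as.numeric(tab) / sum(tab)
  setNames(prop, AA_LETTERS)
}
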