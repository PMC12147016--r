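QUAD_PATTERNS <- sort(apply(expand.grid(rep(list(c("A", "G")), 4)), 1, paste,
                            collapse = ""))

#' Sliding four-codon patterns of a stretch
#'
#' All L-3 sliding windows of four codons, written over G = CAG, A = CAA
#' (empty for stretches shorter than four codons). E.g. the composition
#' GGGGGAG decomposes into GGGG, GGGG, GGGA, GGAG.
#'
#' @param ga one composition string over G/A.
#' @return character vector of 4-letter patterns (possibly empty).
#' @examples
#' quadruplets("GGGGGAG")
#' @export
quadruplets <- function(ga) {
  stopifnot(length(ga) == 1)
  L <- nchar(ga)
  if (L < 4) return(character(0))
  substring(ga, 1:(L - 3), 4:L)
}

#' Four-codon pattern proportions by stretch-length bin
#'
#' Pools quadruplet windows from qualifying stretches per length bin (4-7 vs
#' >= 8 codons) and normalises to proportions over the 16 patterns in
#' \{A,G\}^4. By default all stretches contribute (so the pure-stretch
#' patterns GGGG/AAAA are included in the denominator); restricting to mixed
#' stretches is available, in which case GGGG/AAAA can still occur as windows
#' within mixed stretches but never as whole stretches.
#'
#' @param stretches a stretch table from \code{\link{scan_stretches}}.
#' @param restrict_to_mixed only use mixed CAG/CAA stretches (default FALSE).
#' @return a data.frame of class \code{"quadruplet_profile"} with one row per
#'   length_bin x pattern: species_code, length_bin, pattern, n, proportion
#'   (NA when the bin has no windows), plus n_windows per bin.
#' @export
quadruplet_profile <- function(stretches, restrict_to_mixed = FALSE) {
  st <- stretches[stretches$length >= 4, , drop = FALSE]
  if (restrict_to_mixed) st <- st[st$purity == "mixed", , drop = FALSE]
  sp <- if (nrow(stretches) > 0) unique(stretches$species_code)[1] else NA_character_
  bins <- ifelse(st$length >= 8, "len8plus", "len4to7")
  out <- lapply(LENGTH_BINS_CONTEXT, function(b) {
    ga <- st$ga[bins == b]
    wins <- unlist(lapply(ga, quadruplets))
    n_windows <- length(wins)
    counts <- table(factor(wins, levels = QUAD_PATTERNS))
    data.frame(species_code = sp,
               length_bin = b,
               pattern = QUAD_PATTERNS,
               n = as.integer(counts),
               proportion = if (n_windows > 0) as.numeric(counts) / n_windows
                            else NA_real_,
               n_windows = n_windows,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("quadruplet_profile", "data.frame")
  out
}
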