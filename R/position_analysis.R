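#' Relative positions of CAA and CAG codons within stretches
#'
#' For every stretch of length L >= \code{min_length}, the codon at
#' within-stretch index i (0-based) has relative position i/(L-1): 0 is the
#' N-terminal end of the stretch, 1 the C-terminal end, intermediate codons
#' evenly spaced. Positions are pooled across stretches into one sample per
#' codon identity. Per-stretch mean aggregation is available as an
#' alternative summary.
#'
#' @param stretches a stretch table from \code{\link{scan_stretches}}.
#' @param min_length minimum stretch length to contribute (default 4; shorter
#'   stretches carry little positional information). Must be >= 2 so that
#'   relative position is defined.
#' @param per_stretch_means if TRUE, each stretch contributes its mean CAA
#'   position and mean CAG position (where present) instead of every codon.
#' @return a list of class \code{"relpos_sample"} with numeric vectors
#'   \code{caa} and \code{cag}, plus \code{species_code} and
#'   \code{min_length}.
#' @examples
#' st <- data.frame(ga = "GGAA", length = 4, species_code = "syn")
#' relative_positions(st)  # CAG at 0, 1/3; CAA at 2/3, 1
#' @export
relative_positions <- function(stretches, min_length = 4L,
                               per_stretch_means = FALSE) {
  stopifnot(min_length >= 2)
  sel <- stretches$length >= min_length
  ga <- stretches$ga[sel]
  acc_a <- vector("list", length(ga)); acc_g <- acc_a
  for (k in seq_along(ga)) {
    ch <- strsplit(ga[[k]], "")[[1]]
    L <- length(ch)
    pos <- (seq_len(L) - 1) / (L - 1)
    pa <- pos[ch == "A"]; pg <- pos[ch == "G"]
    if (per_stretch_means) {
      acc_a[[k]] <- if (length(pa) > 0) mean(pa) else numeric(0)
      acc_g[[k]] <- if (length(pg) > 0) mean(pg) else numeric(0)
    } else {
      acc_a[[k]] <- pa; acc_g[[k]] <- pg
    }
  }
  caa <- unlist(acc_a); cag <- unlist(acc_g)
  if (is.null(caa)) caa <- numeric(0)
  if (is.null(cag)) cag <- numeric(0)
  structure(list(caa = caa, cag = cag,
                 species_code = unique(stretches$species_code),
                 min_length = min_length,
                 per_stretch_means = per_stretch_means),
            class = "relpos_sample")
}

#' Compare CAA and CAG positional distributions
#'
#' Mann-Whitney U comparison of the two relative-position samples, with both
#' sample means for directionality (mean CAA position > mean CAG position
#' indicates CAA codons sit C-terminally of CAG codons).
#'
#' @param x a \code{relpos_sample} from \code{\link{relative_positions}}, or
#'   a numeric vector (CAA positions) when \code{y} is given.
#' @param y CAG positions when \code{x} is a bare numeric vector.
#' @return a \code{\link{mann_whitney_u}} result, or NULL with a warning when
#'   either sample is empty.
#' @export
compare_positions <- function(x, y = NULL) {
  if (inherits(x, "relpos_sample")) {
    a <- x$caa; b <- x$cag
  } else {
    a <- x; b <- y
  }
  if (length(a) == 0 || length(b) == 0) {
    warning("empty position sample; no comparison performed")
    return(NULL)
  }
  mann_whitney_u(a, b)
}
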