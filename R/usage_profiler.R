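USAGE_CLASSES <- c("1", "2", "3", "4", "5", "6", ">6", "bg")

#' Background and length-specific glutamine codon usage
#'
#' Aggregates CAA/CAG codon counts over a species' stretches into length
#' classes 1-6 (exact stretch length), ">6" (length >= 7, pooled because long
#' stretches are rare), and "bg" (all stretches together, the species'
#' background glutamine codon usage). Fractions are reported with their raw
#' counts so denominators never need re-deriving.
#'
#' @param stretches a stretch table from \code{\link{scan_stretches}}; all
#'   rows must share one species_code.
#' @param pool_threshold stretch lengths strictly greater than this are pooled
#'   into the ">6"-style class (default 6, giving classes 1-6 and ">6").
#' @return an object of class \code{"usage_profile"}: a data.frame with
#'   columns class, n_caa, n_cag, n_stretches, cag_fraction (NA for empty
#'   classes).
#' @examples
#' st <- data.frame(length = c(1, 2), n_caa = c(0, 1), n_cag = c(1, 1),
#'                  species_code = "syn")
#' usage_profile(st)
#' @export
usage_profile <- function(stretches, pool_threshold = 6L) {
  stopifnot(is.data.frame(stretches), pool_threshold >= 1)
  sp <- unique(stretches$species_code)
  if (length(sp) > 1)
    stop("usage_profile expects a single species; got: ",
         paste(sp, collapse = ", "))
  classes <- c(as.character(seq_len(pool_threshold)),
               paste0(">", pool_threshold), "bg")
  out <- data.frame(class = classes,
                    n_caa = 0L, n_cag = 0L, n_stretches = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(stretches) > 0) {
    cls <- usage_class(stretches$length, pool_threshold)
    for (i in seq_along(classes[-length(classes)])) {
      sel <- cls == classes[i]
      out$n_caa[i] <- sum(stretches$n_caa[sel])
      out$n_cag[i] <- sum(stretches$n_cag[sel])
      out$n_stretches[i] <- sum(sel)
    }
    k <- length(classes)
    out$n_caa[k] <- sum(stretches$n_caa)
    out$n_cag[k] <- sum(stretches$n_cag)
    out$n_stretches[k] <- nrow(stretches)
  }
  denom <- out$n_caa + out$n_cag
  out$cag_fraction <- ifelse(denom > 0, out$n_cag / denom, NA_real_)
  attr(out, "species_code") <- if (length(sp) == 1) sp else NA_character_
  attr(out, "pool_threshold") <- pool_threshold
  class(out) <- c("usage_profile", "data.frame")
  out
}

usage_class <- function(length, pool_threshold = 6L) {
  ifelse(length > pool_threshold, paste0(">", pool_threshold),
         as.character(length))
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("Glutamine codon usage (%s), classes by stretch length:\n",
              attr(x, "species_code")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
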