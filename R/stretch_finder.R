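FLANK_COLS_UP <- paste0("up_", 5:1)
FLANK_COLS_DOWN <- paste0("down_", 1:5)

#' Find maximal glutamine-codon runs in one transcript
#'
#' A polyQ stretch is a maximal run of consecutive CAA/CAG codons; runs of
#' length one are included. Each stretch is annotated with its 0-based start
#' codon index, length, codon composition (encoded as a string over
#' \code{G} = CAG, \code{A} = CAA), purity class, and the five codons on
#' either side (positions -5..-1 upstream, +1..+5 downstream), NA where the
#' transcript ends first. Codons containing ambiguity letters are never
#' glutamine codons and therefore terminate runs.
#'
#' @param transcript a transcript record as produced by
#'   \code{\link{read_cds_fasta}} (list with \code{codons},
#'   \code{transcript_id}, \code{species_code}).
#' @return a data.frame with one row per stretch, ordered by start index.
#'   Columns: transcript_id, species_code, start, length, ga, n_caa, n_cag,
#'   purity (pure_CAG / pure_CAA / mixed), up_5..up_1, down_1..down_5.
#' @examples
#' tx <- list(transcript_id = "t", species_code = "syn",
#'            codons = c("ATG", "CAG", "CAG", "CAA", "TGG"))
#' find_stretches(tx)
#' @export
find_stretches <- function(transcript) {
  codons <- transcript$codons
  stopifnot(length(codons) > 0)
  is_q <- codons %in% Q_CODONS
  r <- rle(is_q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qi <- which(r$values)
  n <- length(qi)
  out <- empty_stretch_table()
  if (n == 0) return(out)

  start <- starts[qi]          # 1-based
  len <- r$lengths[qi]
  ga_all <- ifelse(codons == "CAG", "G", "A")
  ga <- vapply(seq_len(n), function(k) {
    paste(ga_all[start[k]:(start[k] + len[k] - 1L)], collapse = "")
  }, character(1))
  n_cag <- vapply(seq_len(n), function(k) {
    sum(codons[start[k]:(start[k] + len[k] - 1L)] == "CAG")
  }, integer(1))
  n_caa <- len - n_cag

  flank <- function(offsets, anchor) {
    # anchor: vector of 1-based codon indices just outside the stretch side
    sapply(offsets, function(d) {
      idx <- anchor + d
      val <- rep(NA_character_, n)
      ok <- idx >= 1L & idx <= length(codons)
      val[ok] <- codons[idx[ok]]
      val
    })
  }
  up <- matrix(flank(-(4:0), start - 1L), nrow = n)      # positions -5..-1
  down <- matrix(flank(0:4, start + len), nrow = n)      # positions +1..+5

  out <- data.frame(
    transcript_id = rep(transcript$transcript_id, n),
    species_code = rep(transcript$species_code, n),
    start = start - 1L,
    length = len,
    ga = ga,
    n_caa = n_caa,
    n_cag = n_cag,
    purity = ifelse(n_caa == 0L, "pure_CAG",
                    ifelse(n_cag == 0L, "pure_CAA", "mixed")),
    stringsAsFactors = FALSE
  )
  up <- as.data.frame(up, stringsAsFactors = FALSE)
  names(up) <- FLANK_COLS_UP
  down <- as.data.frame(down, stringsAsFactors = FALSE)
  names(down) <- FLANK_COLS_DOWN
  cbind(out, up, down)
}

empty_stretch_table <- function() {
  cols <- c("transcript_id", "species_code", "start", "length", "ga",
            "n_caa", "n_cag", "purity", FLANK_COLS_UP, FLANK_COLS_DOWN)
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out$start <- integer(0); out$length <- integer(0)
  out$n_caa <- integer(0); out$n_cag <- integer(0)
  out
}

#' Scan a whole dataset for polyQ stretches
#'
#' Applies \code{\link{find_stretches}} to every transcript and binds the
#' results into one stretch table.
#'
#' @param x a \code{cds_set} from \code{\link{read_cds_fasta}} or
#'   \code{\link{generate_dataset}}, or a bare list of transcript records.
#' @return a stretch table (data.frame), possibly with zero rows.
#' @export
scan_stretches <- function(x) {
  if (inherits(x, "cds_set")) x <- x$transcripts
  tabs <- lapply(x, find_stretches)
  tabs <- tabs[vapply(tabs, nrow, integer(1)) > 0]
  if (length(tabs) == 0) return(empty_stretch_table())
  do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}

#' Longest run of one codon within a stretch
#'
#' Length of the longest contiguous run of the given codon inside a stretch's
#' codon sequence; 0 if the codon does not occur.
#'
#' @param ga stretch composition string over \code{G}/\code{A}
#'   (or a vector of them).
#' @param codon "CAG" or "CAA".
#' @return integer vector of maximal run lengths.
#' @examples
#' max_identical_run("GGGAG", "CAG")  # 3
#' max_identical_run("GG", "CAA")     # 0
#' @export
max_identical_run <- function(ga, codon = c("CAG", "CAA")) {
  codon <- match.arg(codon)
  letter <- if (codon == "CAG") "G" else "A"
  vapply(strsplit(ga, ""), function(ch) {
    r <- rle(ch == letter)
    hits <- r$lengths[r$values]
    if (length(hits) == 0) 0L else max(hits)
  }, integer(1))
}
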