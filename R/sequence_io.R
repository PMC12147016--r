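#' Read a coding-sequence FASTA file into framed transcripts
#'
#' Reads a (possibly gzipped) multi-FASTA of coding sequences, frames every
#' record into codons from position 0 (Ensembl CDS convention: the sequence is
#' assumed to start in frame; no ORF search is performed) and strips a
#' terminal stop codon when present. The first whitespace-delimited token of
#' each header is taken as the transcript identifier.
#'
#' Records shorter than 3 nt are dropped and counted in the manifest.
#' Trailing 1-2 nt that do not complete a codon are dropped and flagged.
#' Ambiguity letters (N etc.) are kept in codons; such codons can never be
#' glutamine codons and translate to "X".
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param species_code short species label (conventionally 3 letters) attached
#'   to every transcript.
#' @param strip_stop strip a terminal TAA/TAG/TGA codon before analysis
#'   (default TRUE), so that a C-terminal polyQ's +1 flank is reported as
#'   missing rather than as a stop codon. Stop stripping is counted in the
#'   manifest so the alternative can be audited.
#' @return a list of class \code{"cds_set"} with elements
#'   \code{transcripts} (list of transcript records, each with
#'   \code{transcript_id}, \code{species_code}, \code{sequence},
#'   \code{codons}, \code{n_trailing_nt}, \code{stop_stripped}) and
#'   \code{manifest} (species_code, source path, record counts and a
#'   reason-keyed drop table).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 demo", "ATGCAGCAATAA"), fa)
#' cds <- read_cds_fasta(fa, "hsa")
#' cds$transcripts[[1]]$codons  # ATG CAG CAA; the stop is stripped
#' @export
read_cds_fasta <- function(path, species_code, strip_stop = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  stopifnot(is.character(species_code), nzchar(species_code))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    warning("empty FASTA: ", path)
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  raw <- toupper(as.character(seqs))

  drop_reasons <- c(too_short = 0L)
  n_stop_stripped <- 0L
  n_trailing <- 0L
  transcripts <- vector("list", length(raw))
  keep <- logical(length(raw))
  for (i in seq_along(raw)) {
    s <- raw[[i]]
    if (nchar(s) < 3) {
      drop_reasons["too_short"] <- drop_reasons["too_short"] + 1L
      next
    }
    tx <- frame_transcript(ids[[i]], species_code, s, strip_stop = strip_stop)
    n_stop_stripped <- n_stop_stripped + tx$stop_stripped
    n_trailing <- n_trailing + (tx$n_trailing_nt > 0L)
    transcripts[[i]] <- tx
    keep[i] <- TRUE
  }
  transcripts <- transcripts[keep]

  manifest <- list(
    species_code = species_code,
    source_path = path,
    n_transcripts = length(transcripts),
    n_dropped = sum(drop_reasons),
    drop_reasons = as.list(drop_reasons),
    n_stop_stripped = n_stop_stripped,
    n_with_trailing_nt = n_trailing
  )
  structure(list(transcripts = transcripts, manifest = manifest),
            class = "cds_set")
}

# Frame one sequence into codons; used by both the reader and the generator.
frame_transcript <- function(transcript_id, species_code, sequence,
                             strip_stop = TRUE) {
  n <- nchar(sequence)
  n_codons <- n %/% 3L
  n_trailing <- n - 3L * n_codons
  codons <- substring(sequence, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  stop_stripped <- FALSE
  if (strip_stop && n_codons > 0 && codons[n_codons] %in% STOP_CODONS) {
    codons <- codons[-n_codons]
    stop_stripped <- TRUE
  }
  list(transcript_id = transcript_id,
       species_code = species_code,
       sequence = sequence,
       codons = codons,
       n_trailing_nt = n_trailing,
       stop_stripped = stop_stripped)
}

#' @export
print.cds_set <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cds_set> %s: %d transcripts (%d dropped; %d stop codons stripped)\n",
              m$species_code, m$n_transcripts, m$n_dropped, m$n_stop_stripped))
  invisible(x)
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts a \code{cds_set} or a bare list of transcript records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path) {
  if (inherits(transcripts, "cds_set")) transcripts <- transcripts$transcripts
  seqs <- vapply(transcripts, `[[`, character(1), "sequence")
  names(seqs) <- vapply(transcripts, `[[`, character(1), "transcript_id")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write a result table as TSV with "-" for missing values
#'
#' All tabular outputs of the package go through this writer: tab-separated,
#' header line, missing values written as "-".
#'
#' @param rows a data.frame.
#' @param path output path.
#' @param schema optional character vector giving the column order; all named
#'   columns must exist.
#' @return the path, invisibly.
#' @export
write_qtable <- function(rows, path, schema = NULL) {
  stopifnot(is.data.frame(rows))
  if (!is.null(schema)) {
    missing_cols <- setdiff(schema, names(rows))
    if (length(missing_cols) > 0)
      stop("rows do not conform to schema; missing: ",
           paste(missing_cols, collapse = ", "))
    rows <- rows[, schema, drop = FALSE]
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, na = "-",
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{write_qtable}
#'
#' "-" cells are restored to NA; column types are re-inferred.
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
read_qtable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "-",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA)
}
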