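# Independent oracles and tiny fixture builders shared across tests.

# Minimal transcript record.
make_tx <- function(codons, id = "tx1", species = "syn") {
  list(transcript_id = id, species_code = species,
       sequence = paste(codons, collapse = ""), codons = codons,
       n_trailing_nt = 0L, stop_stripped = FALSE)
}

# Brute-force PMF of the longest run of 1s over all 2^L weighted sequences.
oracle_max_run_pmf <- function(L, p) {
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), L)))
  mr <- apply(grid, 1, function(x) {
    r <- rle(as.integer(x))
    m <- r$lengths[r$values == 1L]
    if (length(m)) max(m) else 0L
  })
  k <- rowSums(grid)
  w <- p^k * (1 - p)^(L - k)
  vapply(0:L, function(v) sum(w[mr == v]), numeric(1))
}

# Longest run of `letter` in a string, written independently of the package
# (character scan, no rle).
oracle_max_run <- function(s, letter) {
  best <- 0L; cur <- 0L
  for (ch in strsplit(s, "")[[1]]) {
    cur <- if (ch == letter) cur + 1L else 0L
    if (cur > best) best <- cur
  }
  best
}

# Exact two-sided Mann-Whitney p-value by full enumeration of the
# choose(n_a + n_b, n_a) equally likely rank splits (assumes no ties).
oracle_mwu_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(na + nb, na)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- if (u_obs > na * nb / 2) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(p, 1)
}

# Write a FASTA file from named sequences; returns the path.
write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(mapply(function(nm, s) c(paste0(">", nm), s),
                         names(seqs), seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}
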