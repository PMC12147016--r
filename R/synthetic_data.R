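# Sense codons one nucleotide away from CAG (CAA and stops excluded): the
# codons a single point mutation of CAG can reach without losing sense.
CAG_NEIGHBOURS <- c("AAG", "GAG", "CCG", "CGG", "CTG", "CAC", "CAT")

#' Specification of a synthetic species dataset
#'
#' Describes a synthetic transcriptome with the statistical structure the
#' analysis stages assume: heavy-tailed stretch lengths, length-class CAG
#' usage, an optional C-terminal CAA placement bias, an optional
#' similarity bias of the +1 flank of pure-CAG stretches, and optional
#' amino-acid emission distributions for context positions. Filler codons are
#' drawn from the 59 non-glutamine sense codons so the injected stretches are
#' exactly the maximal CAA/CAG runs and ground truth is exact (an optional
#' background Q-codon rate relaxes this to exercise maximality handling).
#'
#' Defaults describe a neutral, mammal-like dataset: truncated-geometric
#' stretch lengths with ratio 0.5 (87.5\% of stretches of length 1-3, under
#' 1\% of length >= 8), constant P(CAG) = 0.75 across length classes, no
#' placement or flank bias, transcripts of 100-400 codons with on average two
#' stretches each.
#'
#' @param species_code dataset label (default "syn").
#' @param n_transcripts number of transcripts.
#' @param transcript_length_codons integer c(min, max); lengths drawn
#'   uniformly.
#' @param stretch_rate expected stretches per transcript (Poisson).
#' @param stretch_length_dist named numeric vector of probabilities over
#'   stretch lengths (names = lengths), or NULL for the default
#'   truncated-geometric(0.5) on 1..30.
#' @param p_cag_by_length single probability, or named vector over the usage
#'   classes "1".."6", ">6".
#' @param caa_cterm_bias >= 0; CAA positions inside a stretch are drawn with
#'   weights exp(bias * relpos), so 0 is uniform placement and larger values
#'   push CAA codons C-terminally.
#' @param flank_similarity_bias probability in [0,1] that the +1 flank of a
#'   pure-CAG stretch is drawn from the sense codons at Hamming distance 1
#'   from CAG rather than uniformly from all non-Q sense codons.
#' @param context_emissions optional list keyed by context position ("-5"..
#'   "-1", "+1".."+5"), each a list with elements \code{len4to7} and/or
#'   \code{len8plus}: named amino-acid probability vectors from which the
#'   flank codon at that position is drawn (uniformly among the sense codons
#'   of the emitted amino acid, glutamine excluded).
#' @param bg_q_rate probability that a filler codon is replaced by a random
#'   glutamine codon (default 0, keeping ground truth exact).
#' @param include_stop append a random stop codon to every transcript.
#' @param seed integer seed; generation is a deterministic function of the
#'   spec including the seed.
#' @return a validated list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(species_code = "syn",
                           n_transcripts = 200L,
                           transcript_length_codons = c(100L, 400L),
                           stretch_rate = 2,
                           stretch_length_dist = NULL,
                           p_cag_by_length = 0.75,
                           caa_cterm_bias = 0,
                           flank_similarity_bias = 0,
                           context_emissions = NULL,
                           bg_q_rate = 0,
                           include_stop = TRUE,
                           seed = 1L) {
  if (is.null(stretch_length_dist)) {
    w <- 0.5^(1:30)
    stretch_length_dist <- setNames(w / sum(w), 1:30)
  }
  stopifnot(n_transcripts >= 1,
            length(transcript_length_codons) == 2,
            transcript_length_codons[1] >= 1,
            transcript_length_codons[2] >= transcript_length_codons[1],
            stretch_rate >= 0,
            all(stretch_length_dist >= 0), sum(stretch_length_dist) > 0,
            !is.null(names(stretch_length_dist)),
            caa_cterm_bias >= 0,
            flank_similarity_bias >= 0, flank_similarity_bias <= 1,
            bg_q_rate >= 0, bg_q_rate <= 1)
  classes <- c(as.character(1:6), ">6")
  if (length(p_cag_by_length) == 1 && is.null(names(p_cag_by_length))) {
    p_cag_by_length <- setNames(rep(p_cag_by_length, length(classes)), classes)
  }
  stopifnot(all(classes %in% names(p_cag_by_length)),
            all(p_cag_by_length >= 0), all(p_cag_by_length <= 1))
  if (!is.null(context_emissions)) {
    stopifnot(all(names(context_emissions) %in% CONTEXT_POSITIONS))
    for (em in context_emissions) {
      stopifnot(all(names(em) %in% LENGTH_BINS_CONTEXT))
      for (d in em) {
        stopifnot(!is.null(names(d)), all(d >= 0), sum(d) > 0,
                  !"Q" %in% names(d))
      }
    }
  }
  structure(list(species_code = species_code,
                 n_transcripts = as.integer(n_transcripts),
                 transcript_length_codons = as.integer(transcript_length_codons),
                 stretch_rate = stretch_rate,
                 stretch_length_dist = stretch_length_dist,
                 p_cag_by_length = p_cag_by_length,
                 caa_cterm_bias = caa_cterm_bias,
                 flank_similarity_bias = flank_similarity_bias,
                 context_emissions = context_emissions,
                 bg_q_rate = bg_q_rate,
                 include_stop = include_stop,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Draw one stretch composition: n_caa ~ Binomial(L, 1-p), CAA positions
# weighted by exp(bias * relpos). bias = 0 reduces to i.i.d. codons.
r_stretch_ga <- function(L, p_cag, bias = 0) {
  n_caa <- rbinom(1, L, 1 - p_cag)
  ch <- rep("G", L)
  if (n_caa > 0) {
    if (n_caa == L) {
      ch[] <- "A"
    } else {
      relpos <- if (L == 1) 0 else (seq_len(L) - 1) / (L - 1)
      idx <- sample(L, n_caa, prob = exp(bias * relpos))
      ch[idx] <- "A"
    }
  }
  paste(ch, collapse = "")
}

draw_stretch_lengths <- function(n, dist) {
  if (n == 0) return(integer(0))
  lens <- as.integer(names(dist))
  sample(lens, n, replace = TRUE, prob = dist)
}

# Codons (non-Q sense) whose translation is a given amino acid.
codons_for_aa <- function(aa) {
  hits <- NON_Q_SENSE_CODONS[translate_codon(NON_Q_SENSE_CODONS) == aa]
  if (length(hits) == 0) stop("no non-glutamine sense codon encodes: ", aa)
  hits
}

#' Generate a synthetic transcriptome with known ground truth
#'
#' Builds in-frame coding transcripts containing injected glutamine-codon
#' stretches according to a \code{\link{synthetic_spec}}, together with the
#' exact ground-truth stretch table. With the default \code{bg_q_rate = 0}
#' the injected stretches are provably the only maximal CAA/CAG runs, so
#' \code{\link{scan_stretches}} output can be compared to the truth exactly.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return an object of classes \code{"synthetic_cds_set"} and
#'   \code{"cds_set"}: \code{transcripts}, \code{manifest}, the generating
#'   \code{spec}, and \code{truth} (a stretch table of the injected
#'   stretches: transcript_id, species_code, start, length, ga, n_caa,
#'   n_cag, purity).
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_transcripts = 5, seed = 42))
#' nrow(ds$truth)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  max_len_drawn <- max(as.integer(names(spec$stretch_length_dist))[
    spec$stretch_length_dist > 0])
  if (max_len_drawn > spec$transcript_length_codons[1])
    stop("infeasible spec: a stretch of length ", max_len_drawn,
         " cannot fit in a transcript of ", spec$transcript_length_codons[1],
         " codons")
  with_rng_seed(spec$seed, {
    transcripts <- vector("list", spec$n_transcripts)
    truth <- vector("list", spec$n_transcripts)
    for (t in seq_len(spec$n_transcripts)) {
      gt <- generate_transcript(spec, sprintf("%s_tx%04d", spec$species_code, t))
      transcripts[[t]] <- gt$transcript
      truth[[t]] <- gt$truth
    }
    truth <- truth[!vapply(truth, is.null, logical(1))]
    truth <- if (length(truth) == 0) {
      empty_stretch_table()[, c("transcript_id", "species_code", "start",
                                "length", "ga", "n_caa", "n_cag", "purity")]
    } else {
      do.call(rbind, c(truth, list(make.row.names = FALSE)))
    }
    structure(list(transcripts = transcripts,
                   manifest = list(species_code = spec$species_code,
                                   source_path = "<synthetic>",
                                   n_transcripts = spec$n_transcripts,
                                   n_dropped = 0L,
                                   drop_reasons = list(),
                                   n_stop_stripped = NA_integer_,
                                   n_with_trailing_nt = 0L),
                   spec = spec,
                   truth = truth),
              class = c("synthetic_cds_set", "cds_set"))
  })
}

generate_transcript <- function(spec, transcript_id) {
  rng <- spec$transcript_length_codons
  L_t <- sample(rng[1]:rng[2], 1)
  n_st <- rpois(1, spec$stretch_rate)
  lens <- draw_stretch_lengths(n_st, spec$stretch_length_dist)
  # drop stretches that no longer fit (needs one separator codon in between)
  while (length(lens) > 0 && sum(lens) + length(lens) - 1 > L_t)
    lens <- lens[-length(lens)]
  n_st <- length(lens)

  codons <- sample(NON_Q_SENSE_CODONS, L_t, replace = TRUE)
  if (spec$bg_q_rate > 0) {
    hit <- runif(L_t) < spec$bg_q_rate
    codons[hit] <- sample(Q_CODONS, sum(hit), replace = TRUE)
  }
  truth <- NULL
  is_stretch <- logical(L_t)
  if (n_st > 0) {
    free <- L_t - sum(lens) - (n_st - 1L)
    gaps <- as.vector(stats::rmultinom(1, free, rep(1, n_st + 1L)))
    starts <- integer(n_st)
    pos <- 0L
    for (k in seq_len(n_st)) {
      pos <- pos + gaps[k] + (if (k > 1) 1L else 0L)
      starts[k] <- pos           # 0-based
      pos <- pos + lens[k]
    }
    ga <- character(n_st)
    for (k in seq_len(n_st)) {
      p <- spec$p_cag_by_length[[usage_class(lens[k])]]
      ga[k] <- r_stretch_ga(lens[k], p, spec$caa_cterm_bias)
      ch <- strsplit(ga[k], "")[[1]]
      idx <- starts[k] + seq_len(lens[k])
      codons[idx] <- ifelse(ch == "G", "CAG", "CAA")
      is_stretch[idx] <- TRUE
    }
    # flank rewrites: never inside a stretch, never outside the transcript
    rewrite <- function(idx1, value) {
      if (idx1 >= 1 && idx1 <= L_t && !is_stretch[idx1])
        codons[idx1] <<- value
    }
    n_caa <- vapply(strsplit(ga, ""), function(ch) sum(ch == "A"), integer(1))
    if (spec$flank_similarity_bias > 0) {
      for (k in seq_len(n_st)) {
        if (n_caa[k] == 0 && runif(1) < spec$flank_similarity_bias)
          rewrite(starts[k] + lens[k] + 1L, sample(CAG_NEIGHBOURS, 1))
      }
    }
    if (!is.null(spec$context_emissions)) {
      for (k in seq_len(n_st)) {
        if (lens[k] < 4) next
        bin <- if (lens[k] >= 8) "len8plus" else "len4to7"
        for (posname in names(spec$context_emissions)) {
          d <- spec$context_emissions[[posname]][[bin]]
          if (is.null(d)) next
          off <- as.integer(posname)
          idx1 <- if (off < 0) starts[k] + 1L + off
                  else starts[k] + lens[k] + off
          aa <- sample(names(d), 1, prob = d)
          rewrite(idx1, sample(codons_for_aa(aa), 1))
        }
      }
    }
    truth <- data.frame(transcript_id = transcript_id,
                        species_code = spec$species_code,
                        start = starts, length = lens, ga = ga,
                        n_caa = n_caa, n_cag = lens - n_caa,
                        purity = ifelse(n_caa == 0L, "pure_CAG",
                                        ifelse(n_caa == lens, "pure_CAA",
                                               "mixed")),
                        stringsAsFactors = FALSE)
  }
  seq <- paste(codons, collapse = "")
  stop_stripped <- FALSE
  if (spec$include_stop) {
    seq <- paste0(seq, sample(STOP_CODONS, 1))
    stop_stripped <- TRUE
  }
  list(transcript = list(transcript_id = transcript_id,
                         species_code = spec$species_code,
                         sequence = seq,
                         codons = codons,
                         n_trailing_nt = 0L,
                         stop_stripped = stop_stripped),
       truth = truth)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards, so generation is reproducible without disturbing the
# session stream.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Directly simulate a stretch table (no transcripts)
#'
#' Stretch-level shortcut around \code{\link{generate_dataset}} for
#' calibration and power studies: draws n stretches with the same composition
#' model (lengths, length-class CAG usage, C-terminal CAA bias) and fills the
#' -1/+1 flanks from the flank model (uniform non-Q sense codons, with the
#' +1 flank of pure-CAG stretches optionally biased towards the Hamming-1
#' neighbours of CAG). Outer flank columns (-5..-2, +2..+5) are uniform
#' filler. Uses the current RNG stream unless \code{seed} is given.
#'
#' @param n number of stretches.
#' @param spec a \code{\link{synthetic_spec}} providing the composition and
#'   flank model (its transcript-level fields are ignored).
#' @param lengths optional integer vector (length n or recycled) of stretch
#'   lengths overriding the spec's length distribution.
#' @param seed optional seed (NULL = current RNG stream).
#' @return a stretch table like \code{\link{scan_stretches}}'s.
#' @export
simulate_stretches <- function(n, spec = synthetic_spec(), lengths = NULL,
                               seed = NULL) {
  stopifnot(n >= 1)
  with_rng_seed(seed, {
    lens <- if (is.null(lengths)) draw_stretch_lengths(n, spec$stretch_length_dist)
            else rep_len(as.integer(lengths), n)
    ga <- vapply(lens, function(L) {
      r_stretch_ga(L, spec$p_cag_by_length[[usage_class(L)]],
                   spec$caa_cterm_bias)
    }, character(1))
    n_caa <- vapply(strsplit(ga, ""), function(ch) sum(ch == "A"), integer(1))
    flanks <- matrix(sample(NON_Q_SENSE_CODONS, 10 * n, replace = TRUE),
                     nrow = n)
    colnames(flanks) <- c(FLANK_COLS_UP, FLANK_COLS_DOWN)
    if (spec$flank_similarity_bias > 0) {
      pure_g <- n_caa == 0L
      hit <- pure_g & runif(n) < spec$flank_similarity_bias
      if (any(hit))
        flanks[hit, "down_1"] <- sample(CAG_NEIGHBOURS, sum(hit),
                                        replace = TRUE)
    }
    cbind(data.frame(transcript_id = sprintf("sim_%06d", seq_len(n)),
                     species_code = spec$species_code,
                     start = 0L, length = lens, ga = ga,
                     n_caa = n_caa, n_cag = lens - n_caa,
                     purity = ifelse(n_caa == 0L, "pure_CAG",
                                     ifelse(n_caa == lens, "pure_CAA",
                                            "mixed")),
                     stringsAsFactors = FALSE),
          as.data.frame(flanks, stringsAsFactors = FALSE))
  })
}

#' Run the full pipeline on a synthetic dataset and check recovery
#'
#' Generates a dataset from the spec, runs every analysis stage, and checks
#' that the known generating structure is recovered: (i) detected stretches
#' equal the injected ground truth exactly (when \code{bg_q_rate = 0});
#' (ii) per-class CAG usage lies within 3 binomial standard errors of the
#' generating value (classes with >= 30 codons); (iii) a positive
#' \code{caa_cterm_bias} is detected as a significant C-terminal CAA shift;
#' (iv) a positive \code{flank_similarity_bias} is detected as a
#' significantly lower +1 distance for pure-CAG stretches; for a neutral
#' spec the stage p-values are reported (single-replicate calibration is not
#' asserted; see \code{\link{calibrate_type1}}).
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param alpha significance level used by the bias checks.
#' @return list of class \code{"recovery_report"}: per-check list with
#'   \code{pass} (logical or NA when not applicable) and details.
#' @export
recovery_suite <- function(spec, alpha = 0.001) {
  ds <- generate_dataset(spec)
  found <- scan_stretches(ds)
  truth <- ds$truth
  key_cols <- c("transcript_id", "start", "length", "ga")
  f_keys <- found[order(found$transcript_id, found$start), key_cols]
  t_keys <- truth[order(truth$transcript_id, truth$start), key_cols]
  rownames(f_keys) <- NULL; rownames(t_keys) <- NULL
  detection <- list(
    pass = if (spec$bg_q_rate == 0) isTRUE(all.equal(f_keys, t_keys)) else NA,
    n_found = nrow(found), n_truth = nrow(truth))

  usage <- usage_profile(found)
  cls <- usage$class[usage$class != "bg"]
  usage_checks <- vapply(cls, function(cl) {
    row <- usage[usage$class == cl, ]
    n <- row$n_caa + row$n_cag
    if (n < 30) return(NA)
    p0 <- spec$p_cag_by_length[[cl]]
    se <- sqrt(p0 * (1 - p0) / n)
    abs(row$cag_fraction - p0) <= 3 * se + 1e-12
  }, logical(1))
  usage_check <- list(pass = all(usage_checks[!is.na(usage_checks)]),
                      per_class = usage_checks)

  pos <- relative_positions(found)
  pos_test <- compare_positions(pos)
  position_check <- list(
    pass = if (spec$caa_cterm_bias > 0 && !is.null(pos_test))
      pos_test$p_value < alpha && pos_test$mean_a > pos_test$mean_b else NA,
    test = pos_test)

  fd <- flank_distances(found)
  fl_cmp <- compare_flank_distances(fd, group_by = "purity")
  fl_row <- fl_cmp[fl_cmp$group_a == "pure_CAA" & fl_cmp$group_b == "pure_CAG", ]
  flank_check <- list(
    pass = if (spec$flank_similarity_bias > 0 && nrow(fl_row) == 1 &&
               !is.na(fl_row$p_value))
      fl_row$p_value < alpha && fl_row$mean_b < fl_row$mean_a else NA,
    comparison = fl_cmp)

  rnd <- random_cohort(found, usage)
  run_cmp <- compare_observed_random(found, rnd)

  structure(list(detection = detection,
                 usage = usage_check,
                 position = position_check,
                 flank = flank_check,
                 run_comparisons = run_cmp),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  fmt <- function(p) if (is.na(p)) "n/a" else if (isTRUE(p)) "ok" else "FAIL"
  cat("Synthetic recovery report\n")
  cat("  detection exact match: ", fmt(x$detection$pass),
      sprintf(" (%d found / %d injected)\n",
              x$detection$n_found, x$detection$n_truth))
  cat("  usage recovery:        ", fmt(x$usage$pass), "\n")
  cat("  CAA position bias:     ", fmt(x$position$pass), "\n")
  cat("  flank similarity bias: ", fmt(x$flank$pass), "\n")
  invisible(x)
}

#' Type-I error calibration of a comparison stage under a neutral model
#'
#' Repeatedly generates neutral data (no positional, flank or run structure)
#' and records the rejection rate of one comparison stage at level
#' \code{alpha}. "positions" compares CAA vs CAG relative positions,
#' "flanks" compares pure-CAA vs pure-CAG +1 distances, "runs" compares
#' observed vs length-matched random maximum CAG runs with both cohorts
#' drawn i.i.d. at the known class usage, which isolates the calibration of
#' the comparison itself. (The pipeline's cohort instead plugs in the usage
#' estimated from the observed stretches; that coupling makes the pipeline
#' comparison mildly conservative, never anti-conservative.)
#'
#' @param stage one of "positions", "flanks", "runs".
#' @param n_reps number of replicate datasets.
#' @param n_stretches stretches per replicate.
#' @param p_cag neutral per-codon CAG probability.
#' @param alpha nominal level.
#' @param seed optional seed.
#' @return list with \code{rate}, \code{n_tests}, \code{alpha}.
#' @export
calibrate_type1 <- function(stage = c("positions", "flanks", "runs"),
                            n_reps = 2000L, n_stretches = 150L,
                            p_cag = 0.75, alpha = 0.05, seed = NULL) {
  stage <- match.arg(stage)
  spec <- synthetic_spec(p_cag_by_length = p_cag)
  with_rng_seed(seed, {
    pvals <- numeric(0)
    for (r in seq_len(n_reps)) {
      p <- switch(stage,
        positions = {
          st <- simulate_stretches(n_stretches, spec,
                                   lengths = 3 + rpois(n_stretches, 2) + 1)
          rt <- suppressWarnings(compare_positions(relative_positions(st)))
          if (is.null(rt)) NA_real_ else rt$p_value
        },
        flanks = {
          sp2 <- synthetic_spec(p_cag_by_length = 0.5)
          st <- simulate_stretches(n_stretches, sp2,
                                   lengths = 1 + rpois(n_stretches, 1) + 1)
          fd <- flank_distances(st)
          cmp <- compare_flank_distances(fd, group_by = "purity")
          cmp$p_value[cmp$group_a == "pure_CAA" & cmp$group_b == "pure_CAG"]
        },
        runs = {
          st <- simulate_stretches(n_stretches, spec, lengths = 5L)
          rnd <- generate_random_stretch(5L, p_cag, n = n_stretches)
          cmp <- compare_observed_random(st, rnd)
          cmp$p_value[cmp$codon == "CAG" & cmp$length_bin == "len4to5"]
        })
      pvals <- c(pvals, p)
    }
    pvals <- pvals[!is.na(pvals)]
    list(rate = mean(pvals < alpha), n_tests = length(pvals), alpha = alpha)
  })
}
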