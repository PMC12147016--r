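#' Run every analysis stage for one species dataset
#'
#' scan -> usage -> positions -> flanks -> context -> runs -> patterns, on an
#' already-loaded dataset. Randomness (the length-matched random cohort) is
#' drawn from the current RNG stream, or from \code{seed} when given.
#'
#' @param cds a \code{cds_set} (from \code{\link{read_cds_fasta}} or
#'   \code{\link{generate_dataset}}).
#' @param seed optional integer seed for the random cohort.
#' @param position_min_length,flank_min_length stage length thresholds
#'   (defaults 4 and 2).
#' @param flank_reference see \code{\link{flank_distances}}.
#' @param mixed_only_patterns restrict quadruplet windows to mixed stretches.
#' @param pool_threshold usage pooling threshold (default 6).
#' @return a list of class \code{"polyq_species_result"} with elements
#'   stretches, usage, positions (sample + test), flanks (records + purity
#'   and side comparisons), context (tables + proteome background), runs
#'   (random cohort + comparisons), patterns, manifest.
#' @export
polyq_species_analysis <- function(cds, seed = NULL,
                                   position_min_length = 4L,
                                   flank_min_length = 2L,
                                   flank_reference = "adjacent",
                                   mixed_only_patterns = FALSE,
                                   pool_threshold = 6L) {
  stretches <- scan_stretches(cds)
  usage <- usage_profile(stretches, pool_threshold = pool_threshold)
  pos <- relative_positions(stretches, min_length = position_min_length)
  pos_test <- suppressWarnings(compare_positions(pos))
  fl <- flank_distances(stretches, min_length = flank_min_length,
                        reference = flank_reference)
  fl_purity <- compare_flank_distances(fl, group_by = "purity")
  fl_side <- compare_flank_distances(fl, group_by = "side")
  ctx <- context_table(stretches)
  bg_aa <- proteome_aa_usage(cds)
  runs <- with_rng_seed(seed, {
    if (nrow(stretches) > 0 && any(!is.na(usage$cag_fraction))) {
      rnd <- suppressWarnings(random_cohort(stretches, usage))
      list(randoms = rnd,
           comparisons = compare_observed_random(stretches, rnd))
    } else list(randoms = character(0), comparisons = NULL)
  })
  patterns <- quadruplet_profile(stretches,
                                 restrict_to_mixed = mixed_only_patterns)
  structure(list(species_code = cds$manifest$species_code,
                 stretches = stretches,
                 usage = usage,
                 positions = list(sample = pos, test = pos_test),
                 flanks = list(records = fl, by_purity = fl_purity,
                               by_side = fl_side),
                 context = list(tables = ctx, proteome_aa = bg_aa),
                 runs = runs,
                 patterns = patterns,
                 manifest = cds$manifest),
            class = "polyq_species_result")
}

#' @export
print.polyq_species_result <- function(x, ...) {
  cat(sprintf("<polyq_species_result> %s: %d stretches in %d transcripts\n",
              x$species_code, nrow(x$stretches), x$manifest$n_transcripts))
  bg <- x$usage[x$usage$class == "bg", ]
  cat(sprintf("  bg CAG fraction: %.3f (%d CAG / %d CAA)\n",
              bg$cag_fraction, bg$n_cag, bg$n_caa))
  if (!is.null(x$positions$test))
    cat(sprintf("  CAA vs CAG position: mean %.3f vs %.3f, p = %.3g (%s)\n",
                x$positions$test$mean_a, x$positions$test$mean_b,
                x$positions$test$p_value, x$positions$test$significance))
  invisible(x)
}

#' Run the full multi-species polyQ pipeline
#'
#' Loads (or accepts preloaded) datasets, runs
#' \code{\link{polyq_species_analysis}} per species, and consolidates results
#' across species. Each species draws its randomness from its own substream
#' derived from the top-level seed, so adding or removing one dataset leaves
#' the others' outputs unchanged. When \code{output_dir} is given, all
#' result tables are written as TSV ("-" for missing) plus a machine-readable
#' run log.
#'
#' @param datasets a named list: names are species codes, values are FASTA
#'   paths or \code{cds_set} objects.
#' @param output_dir optional directory for TSV outputs.
#' @param seed top-level integer seed (default 1).
#' @param ... stage thresholds passed to
#'   \code{\link{polyq_species_analysis}}.
#' @param strip_stop passed to \code{\link{read_cds_fasta}} for path inputs.
#' @return an object of class \code{"polyq_run"}: per-species results
#'   (\code{species}), consolidated data.frames (\code{consolidated}:
#'   stretches, usage, positions, flank comparisons, run comparisons,
#'   patterns), failed dataset names, and the run log.
#' @export
run_polyq_pipeline <- function(datasets, output_dir = NULL, seed = 1L,
                               strip_stop = TRUE, ...) {
  stopifnot(is.list(datasets), !is.null(names(datasets)),
            all(nzchar(names(datasets))))
  results <- list()
  failed <- character(0)
  codes <- names(datasets)
  for (i in seq_along(datasets)) {
    code <- codes[i]
    res <- tryCatch({
      cds <- datasets[[i]]
      if (is.character(cds))
        cds <- read_cds_fasta(cds, code, strip_stop = strip_stop)
      # per-species substream: independent of the other datasets
      polyq_species_analysis(cds, seed = (seed + 7919L * i) %% .Machine$integer.max,
                             ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("dataset ", code, " failed: ", conditionMessage(res))
      failed <- c(failed, code)
    } else results[[code]] <- res
  }
  if (length(results) == 0) stop("all datasets failed")

  consolidated <- list(
    stretches = do.call(rbind, c(lapply(results, `[[`, "stretches"),
                                 list(make.row.names = FALSE))),
    usage = do.call(rbind, c(lapply(results, function(r) {
      u <- as.data.frame(r$usage)
      cbind(species_code = r$species_code, u)
    }), list(make.row.names = FALSE))),
    positions = do.call(rbind, c(lapply(results, function(r) {
      cbind(data.frame(species_code = r$species_code),
            rank_test_row(r$positions$test))
    }), list(make.row.names = FALSE))),
    flank_comparisons = do.call(rbind, c(lapply(results, function(r) {
      cbind(species_code = r$species_code,
            rbind(cbind(layout = "purity", r$flanks$by_purity),
                  cbind(layout = "side", r$flanks$by_side)))
    }), list(make.row.names = FALSE))),
    run_comparisons = do.call(rbind, c(lapply(results, function(r) {
      if (is.null(r$runs$comparisons)) return(NULL)
      cbind(species_code = r$species_code, r$runs$comparisons)
    }), list(make.row.names = FALSE))),
    patterns = do.call(rbind, c(lapply(results, function(r)
      as.data.frame(r$patterns)), list(make.row.names = FALSE)))
  )
  log <- list(seed = seed,
              package_version = as.character(utils::packageVersion("polyqscan")),
              r_version = R.version.string,
              species = names(results),
              failed = failed,
              strip_stop = strip_stop,
              thresholds = list(...))
  run <- structure(list(species = results, consolidated = consolidated,
                        failed = failed, log = log),
                   class = "polyq_run")
  if (!is.null(output_dir)) write_polyq_run(run, output_dir)
  run
}

#' Write all tables of a pipeline run to a directory
#'
#' @param run a \code{polyq_run}.
#' @param output_dir directory (created if needed).
#' @return output_dir, invisibly.
#' @export
write_polyq_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(run$consolidated)) {
    tab <- run$consolidated[[nm]]
    if (!is.null(tab))
      write_qtable(tab, file.path(output_dir, paste0(nm, ".tsv")))
  }
  # context: long format across species/purity/bin
  ctx_rows <- list()
  for (r in run$species) {
    for (tb in r$context$tables) {
      cnt <- tb$counts
      df <- data.frame(species_code = tb$species_code,
                       purity = tb$purity, length_bin = tb$length_bin,
                       position = rep(colnames(cnt), each = nrow(cnt)),
                       aa = rep(rownames(cnt), times = ncol(cnt)),
                       count = as.vector(cnt),
                       n_stretches = tb$n_stretches,
                       stringsAsFactors = FALSE)
      ctx_rows[[length(ctx_rows) + 1L]] <- df[df$count > 0, , drop = FALSE]
    }
  }
  if (length(ctx_rows) > 0)
    write_qtable(do.call(rbind, c(ctx_rows, list(make.row.names = FALSE))),
                 file.path(output_dir, "context.tsv"))
  log_lines <- c(
    sprintf("seed\t%d", run$log$seed),
    sprintf("package_version\t%s", run$log$package_version),
    sprintf("r_version\t%s", run$log$r_version),
    sprintf("species\t%s", paste(run$log$species, collapse = ",")),
    sprintf("failed\t%s", paste(run$log$failed, collapse = ",")),
    sprintf("strip_stop\t%s", run$log$strip_stop),
    vapply(names(run$log$thresholds), function(k)
      sprintf("%s\t%s", k, paste(run$log$thresholds[[k]], collapse = ",")),
      character(1))
  )
  writeLines(log_lines, file.path(output_dir, "run_log.tsv"))
  invisible(output_dir)
}

#' @export
print.polyq_run <- function(x, ...) {
  cat(sprintf("<polyq_run> %d species (%s)%s\n",
              length(x$species), paste(names(x$species), collapse = ", "),
              if (length(x$failed)) paste0("; failed: ",
                                           paste(x$failed, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
summary.polyq_run <- function(object, ...) {
  u <- object$consolidated$usage
  bg <- u[u$class == "bg", c("species_code", "n_caa", "n_cag", "cag_fraction")]
  pos <- object$consolidated$positions
  out <- merge(bg, pos[, c("species_code", "mean_a", "mean_b", "p_value",
                           "significance")],
               by = "species_code", all.x = TRUE)
  names(out)[names(out) == "mean_a"] <- "mean_pos_caa"
  names(out)[names(out) == "mean_b"] <- "mean_pos_cag"
  out
}
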