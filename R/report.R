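#' Integrate divergence, RAD and pool evidence into a consensus MSY call
#'
#' The divergence MSY is `[changepoint, chrom_end)`. The RAD interval runs
#' from the lower edge of the upper `rad_quantile` mass of male-only hit
#' positions to the chromosome end. The consensus is their intersection
#' (conservative: the two marker sets of a real analysis can delimit
#' different proximal borders); `mode = "union"` is available. The pool scan
#' and repeat summaries do not move the consensus but are flagged
#' supporting, neutral or conflicting.
#'
#' @param boundary a [detect_boundary()] call
#' @param rad_hits data frame from [map_tags()] on the male-only tags (may
#'   have zero rows)
#' @param pool_windows data frame from [window_sex_snp_scan()] (or NULL)
#' @param repeat_summaries list of two `region_repeat_summary` objects
#'   (PAR, MSY) or NULL
#' @param chrom_length Y chromosome length
#' @param rad_quantile mass of hit positions the RAD interval must contain
#' @param mode `"intersection"` (default) or `"union"` of the divergence and
#'   RAD intervals
#' @param config optional [scenario_config()] echoed into the report
#' @return an object of class `msy_report`
#' @export
integrate_evidence <- function(boundary, rad_hits, pool_windows = NULL,
                               repeat_summaries = NULL, chrom_length,
                               rad_quantile = 0.9,
                               mode = c("intersection", "union"),
                               config = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(boundary, "boundary_call"))
  div_int <- c(boundary$changepoint_bp, chrom_length)
  flags <- c(divergence = if (isTRUE(boundary$no_transition)) "neutral"
             else "supporting")

  if (!is.null(rad_hits) && nrow(rad_hits) > 0) {
    lower <- unname(quantile(rad_hits$t_pos, probs = 1 - rad_quantile,
                             type = 1))
    rad_int <- c(as.numeric(lower), chrom_length)
  } else {
    rad_int <- NULL
  }

  if (is.null(rad_int)) {
    consensus <- div_int
    flags["rad"] <- "neutral"
  } else {
    if (mode == "intersection") {
      consensus <- c(max(div_int[1], rad_int[1]),
                     min(div_int[2], rad_int[2]))
    } else {
      consensus <- c(min(div_int[1], rad_int[1]),
                     max(div_int[2], rad_int[2]))
    }
    if (consensus[1] >= consensus[2]) {
      consensus <- div_int
      flags["rad"] <- "conflicting"
    } else {
      jac <- interval_jaccard(div_int, rad_int)
      flags["rad"] <- if (jac >= 0.5) "supporting" else "conflicting"
    }
  }

  pool_int <- NULL
  if (!is.null(pool_windows) && nrow(pool_windows)) {
    usable <- pool_windows[!pool_windows$low_coverage, , drop = FALSE]
    if (nrow(usable) && sum(usable$n_sex_snps) > 0) {
      thr <- 2 * mean(usable$n_sex_snps)
      hot <- usable[usable$n_sex_snps > thr, , drop = FALSE]
      if (nrow(hot)) {
        pool_int <- c(min(hot$t_start), max(hot$t_end))
        ov <- max(0, min(pool_int[2], consensus[2]) -
                       max(pool_int[1], consensus[1]))
        flags["pool"] <- if (ov > 0) "supporting" else "conflicting"
      } else flags["pool"] <- "neutral"
    } else flags["pool"] <- "neutral"
  } else flags["pool"] <- "neutral"

  if (!is.null(repeat_summaries)) {
    fr <- vapply(repeat_summaries, `[[`, numeric(1), "repeat_fraction")
    lab <- vapply(repeat_summaries, `[[`, character(1), "label")
    msy_fr <- fr[match("MSY", lab)]; par_fr <- fr[match("PAR", lab)]
    flags["repeats"] <- if (!is.na(msy_fr) && !is.na(par_fr)) {
      if (msy_fr > par_fr) "supporting" else "neutral"
    } else "neutral"
  } else flags["repeats"] <- "neutral"

  structure(list(
    divergence_interval = div_int, rad_interval = rad_int,
    pool_interval = pool_int, consensus_interval = consensus,
    flags = flags, boundary = boundary,
    n_rad_hits = if (is.null(rad_hits)) 0L else nrow(rad_hits),
    chrom_length = chrom_length, mode = mode,
    rad_quantile = rad_quantile,
    config = config, version = pkg_version(), seed = config$seed %||% NA),
    class = "msy_report")
}

interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni <= 0) return(0)
  inter / uni
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version <- function() {
  as.character(utils::packageVersion("msyscan"))
}

#' @export
print.msy_report <- function(x, ...) {
  fmt_int <- function(i) if (is.null(i)) "none"
    else sprintf("[%s, %s)", format(round(i[1]), big.mark = ","),
                 format(round(i[2]), big.mark = ","))
  cat("MSY consensus report\n")
  cat(sprintf("  divergence MSY:  %s (%s)\n", fmt_int(x$divergence_interval),
              x$flags["divergence"]))
  cat(sprintf("  RAD interval:    %s (%s, %d hits)\n",
              fmt_int(x$rad_interval), x$flags["rad"], x$n_rad_hits))
  cat(sprintf("  pool hotspots:   %s (%s)\n", fmt_int(x$pool_interval),
              x$flags["pool"]))
  cat(sprintf("  repeats:         %s\n", x$flags["repeats"]))
  cat(sprintf("  consensus (%s): %s  (%.2f Mb)\n", x$mode,
              fmt_int(x$consensus_interval),
              diff(x$consensus_interval) / 1e6))
  invisible(x)
}

#' Run the full pipeline on a synthetic scenario
#'
#' Simulates every input, runs alignment and windowed divergence with
#' boundary detection, the RAD male-only marker route, the pooled sex-SNP
#' scan and the repeat contrast, and integrates them into a consensus MSY
#' report. When `outdir` is given, stage outputs are written as plain-text
#' files (FASTA, BED, TSV, JSON), each TSV/BED carrying a header comment
#' with package version, configuration hash and seed.
#'
#' @param config a [scenario_config()]
#' @param outdir optional output directory (created if missing)
#' @param window_bp divergence window size; defaults to the 10 kb-equivalent
#'   under the config scale
#' @param pool_window_bp pool scan window; defaults to 50 kb-equivalent
#' @param k seed k-mer size for the aligner
#' @return an `msy_report`; stage results are attached as the `stages`
#'   attribute
#' @export
run_pipeline <- function(config, outdir = NULL,
                         window_bp = max(1000, round(10000 * config$scale)),
                         pool_window_bp = max(5000,
                                              round(50000 * config$scale)),
                         k = 15) {
  t0 <- Sys.time()
  msg <- function(...) message(sprintf(...))
  xy <- simulate_xy_pair(config)
  y_len <- xy$truth$chrom_length_y
  msg("simulate: X %d bp, Y %d bp, %d SNPs, %d indels",
      xy$truth$chrom_length_x, y_len, nrow(xy$truth$snps),
      nrow(xy$truth$indels))

  chains <- align_xy(xy$x_sequence, xy$y_sequence, k = k)
  windows <- window_divergence(chains, y_len, window_bp = window_bp)
  boundary <- detect_boundary(windows)
  msg("divergence: %d chains, %d windows, changepoint %d bp (fold %.2f)",
      length(chains), nrow(windows), boundary$changepoint_bp, boundary$fold)

  rad <- simulate_rad_individuals(config, xy)
  mo_ids <- call_male_only_tags(rad$catalog,
                                min_males = ceiling(config$n_males / 2))
  mo_tags <- rad$catalog$tags[rad$catalog$tags$tag_id %in% mo_ids, ]
  hits <- map_tags(mo_tags, xy$y_sequence)
  co <- scenario_coords(config)
  distal16 <- c(round(0.84 * y_len), y_len)
  enr <- region_enrichment(hits, distal16, y_len)
  msg("rad: %d male-only tags, %d mapped, %.1f%% in distal 16%%",
      length(mo_ids), nrow(hits),
      100 * (enr$fraction_in_region %||% NA))

  pool <- simulate_pool_counts(config, xy)
  calls <- call_sex_specific_snps(pool$table)
  pool_windows <- window_sex_snp_scan(calls, pool$table, y_len,
                                      window_bp = pool_window_bp)
  msg("pool: %d sex-specific sites, %d windows",
      nrow(calls$sites), nrow(pool_windows))

  reps <- simulate_repeats(config, xy)
  rs_par <- region_repeat_summary(reps, xy$truth$par_interval, "PAR")
  rs_msy <- region_repeat_summary(reps, xy$truth$msy_interval, "MSY")
  ages <- age_contrast(rs_par, rs_msy)
  msg("repeats: PAR %.3f / MSY %.3f fraction, age contrast p = %.3g",
      rs_par$repeat_fraction, rs_msy$repeat_fraction, ages$p_value)

  report <- integrate_evidence(boundary, hits, pool_windows,
                               list(rs_par, rs_msy), y_len, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- output_header(config)
    write_fasta(c(X = xy$x_sequence, Y = xy$y_sequence),
                file.path(outdir, "xy.fasta"))
    write_bed(data.frame(chrom = "Y",
                         start = c(xy$truth$par_interval[1],
                                   xy$truth$msy_interval[1]),
                         end = c(xy$truth$par_interval[2],
                                 xy$truth$msy_interval[2]),
                         name = c("PAR_truth", "MSY_truth")),
              file.path(outdir, "truth.bed"), header = hdr)
    write_tsv(windows, file.path(outdir, "divergence_windows.tsv"),
              header = hdr)
    write_bed(data.frame(chrom = "Y", start = boundary$msy_interval[1],
                         end = boundary$msy_interval[2], name = "MSY_call"),
              file.path(outdir, "msy_call.bed"), header = hdr)
    write_paf(chains, file.path(outdir, "alignment.paf"),
              q_len = xy$truth$chrom_length_x, t_len = y_len)
    write_tsv(pool_windows, file.path(outdir, "pool_windows.tsv"),
              header = hdr)
    write_sync(pool$table, file.path(outdir, "pool_counts.sync"),
               header = hdr)
    if (nrow(hits))
      write_bed(data.frame(chrom = "Y", start = hits$t_pos,
                           end = hits$t_pos + config$tag_len_bp,
                           name = hits$tag_id),
                file.path(outdir, "male_only_hits.bed"), header = hdr)
    write_tsv(reps, file.path(outdir, "repeats.tsv"), header = hdr)
    jsonlite::write_json(report_to_list(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  msg("pipeline finished in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  attr(report, "stages") <- list(xy = xy, windows = windows,
                                 boundary = boundary, rad_hits = hits,
                                 rad_enrichment = enr,
                                 pool_windows = pool_windows,
                                 repeats = reps, ages = ages)
  report
}

report_to_list <- function(report) {
  cfg_echo <- if (!is.null(report$config)) {
    c(unclass(report$config),
      list(config_hash = digest_config(report$config)))
  }
  list(version = report$version,
       seed = report$seed,
       config = cfg_echo,
       chrom_length = report$chrom_length,
       divergence_interval = report$divergence_interval,
       rad_interval = report$rad_interval,
       pool_interval = report$pool_interval,
       consensus_interval = report$consensus_interval,
       consensus_mode = report$mode,
       flags = as.list(report$flags),
       boundary = list(changepoint_bp = report$boundary$changepoint_bp,
                       mean_before = report$boundary$mean_before,
                       mean_after = report$boundary$mean_after,
                       fold = report$boundary$fold,
                       no_transition = report$boundary$no_transition),
       n_rad_hits = report$n_rad_hits)
}
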