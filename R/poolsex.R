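#' Call sex-specific SNPs from pooled allele counts
#'
#' A site is male-specific when some allele has a male-pool frequency within
#' `[0.5 - het_band, 0.5 + het_band]` (heterozygous in every XY male) and a
#' female-pool frequency at most `max_other`; female-specific is defined
#' symmetrically. Sites below `min_depth` in either pool are skipped and
#' counted in the QC summary.
#'
#' @param table data frame with columns `chrom`, `pos` (1-based), `ref` and
#'   allele counts `A_m`, `C_m`, `G_m`, `T_m`, `A_f`, `C_f`, `G_f`, `T_f`
#' @param min_depth minimum pool depth per site
#' @param het_band half-width of the heterozygous frequency band
#' @param max_other maximum allele frequency tolerated in the other pool
#' @return list with `sites` (data frame: the qualifying rows plus `class`
#'   = `"male_specific"`/`"female_specific"`, `allele`, `freq_m`, `freq_f`)
#'   and `qc` (list: `n_sites`, `n_skipped_depth`, thresholds)
#' @export
call_sex_specific_snps <- function(table, min_depth = 10, het_band = 0.10,
                                   max_other = 0.05) {
  al <- c("A", "C", "G", "T")
  m_mat <- as.matrix(table[, paste0(al, "_m")])
  f_mat <- as.matrix(table[, paste0(al, "_f")])
  dm <- rowSums(m_mat); df <- rowSums(f_mat)
  ok <- dm >= min_depth & df >= min_depth
  fm <- m_mat / pmax(dm, 1L)
  ff <- f_mat / pmax(df, 1L)
  in_band <- function(x) x >= 0.5 - het_band & x <= 0.5 + het_band
  male_al <- in_band(fm) & ff <= max_other
  female_al <- in_band(ff) & fm <= max_other
  male_idx <- apply(male_al & ok, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  female_idx <- apply(female_al & ok, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  is_m <- !is.na(male_idx)
  is_f <- !is.na(female_idx) & !is_m
  rows <- which(is_m | is_f)
  if (length(rows)) {
    allele_i <- ifelse(is_m[rows], male_idx[rows], female_idx[rows])
    sites <- data.frame(
      table[rows, c("chrom", "pos", "ref")],
      class = ifelse(is_m[rows], "male_specific", "female_specific"),
      allele = al[allele_i],
      freq_m = fm[cbind(rows, allele_i)],
      freq_f = ff[cbind(rows, allele_i)],
      depth_m = dm[rows], depth_f = df[rows],
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), class = character(0),
                        allele = character(0), freq_m = numeric(0),
                        freq_f = numeric(0), depth_m = numeric(0),
                        depth_f = numeric(0), stringsAsFactors = FALSE)
  }
  list(sites = sites,
       qc = list(n_sites = nrow(table), n_skipped_depth = sum(!ok),
                 min_depth = min_depth, het_band = het_band,
                 max_other = max_other))
}

#' Windowed sex-specific SNP scan
#'
#' Tiles the chromosome into windows (default 50 kb) and reports, per
#' window, the number of called sex-specific SNPs, the mean pool coverages
#' over all sites in the window, their ratio, and a low-coverage flag: a
#' window whose mean coverage falls below `min_cov_depth` in either pool
#' cannot distinguish "no sex-linked SNPs" from "no mapping" and must not be
#' read as evidence of absence.
#'
#' @param calls result of [call_sex_specific_snps()] (or its `sites` frame)
#' @param table the full pool count table (for coverage means)
#' @param chrom_length chromosome length (bp)
#' @param window_bp,step_bp window size and step (default 50 kb tiles)
#' @param min_cov_depth mean-coverage floor for a confident window
#' @param class which calls to count (default male-specific)
#' @return data frame with `t_start`, `t_end` (0-based half-open),
#'   `n_sex_snps`, `n_sites`, `cov_m`, `cov_f`, `ratio`, `low_coverage`
#' @export
window_sex_snp_scan <- function(calls, table, chrom_length,
                                window_bp = 50000, step_bp = window_bp,
                                min_cov_depth = 5,
                                class = "male_specific") {
  sites <- if (is.data.frame(calls)) calls else calls$sites
  sites <- sites[sites$class %in% class, , drop = FALSE]
  al <- c("A", "C", "G", "T")
  dm <- rowSums(as.matrix(table[, paste0(al, "_m")]))
  df <- rowSums(as.matrix(table[, paste0(al, "_f")]))
  starts <- seq.int(0L, max(chrom_length - 1L, 0L), by = step_bp)
  ends <- pmin(starts + window_bp, chrom_length)
  res <- data.frame(t_start = starts, t_end = ends)
  pos0_sites <- sites$pos - 1L
  pos0_all <- table$pos - 1L
  res$n_sex_snps <- vapply(seq_along(starts), function(i)
    sum(pos0_sites >= starts[i] & pos0_sites < ends[i]), integer(1))
  res$n_sites <- vapply(seq_along(starts), function(i)
    sum(pos0_all >= starts[i] & pos0_all < ends[i]), integer(1))
  res$cov_m <- vapply(seq_along(starts), function(i) {
    sel <- pos0_all >= starts[i] & pos0_all < ends[i]
    if (any(sel)) mean(dm[sel]) else NA_real_
  }, numeric(1))
  res$cov_f <- vapply(seq_along(starts), function(i) {
    sel <- pos0_all >= starts[i] & pos0_all < ends[i]
    if (any(sel)) mean(df[sel]) else NA_real_
  }, numeric(1))
  res$ratio <- ifelse(!is.na(res$cov_f) & res$cov_f > 0,
                      res$cov_m / res$cov_f, NA_real_)
  res$low_coverage <- is.na(res$cov_m) | is.na(res$cov_f) |
    res$cov_m < min_cov_depth | res$cov_f < min_cov_depth
  res
}

#' Read a sync-like pooled count table
#'
#' Tab-separated `chrom pos ref male_counts female_counts` with counts as
#' `A:C:G:T:N:del` strings (1-based positions, lines starting with `#`
#' ignored).
#'
#' @param file path
#' @return data frame as consumed by [call_sex_specific_snps()]
#' @export
read_sync <- function(file) {
  raw <- read.delim(file, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 5) stop("sync table needs 5 columns")
  names(raw)[1:5] <- c("chrom", "pos", "ref", "male", "female")
  parse_counts <- function(s, suffix) {
    parts <- do.call(rbind, strsplit(s, ":", fixed = TRUE))
    out <- data.frame(apply(parts[, 1:4, drop = FALSE], 2, as.integer))
    names(out) <- paste0(c("A", "C", "G", "T"), suffix)
    out
  }
  cbind(raw[, c("chrom", "pos", "ref")],
        parse_counts(raw$male, "_m"), parse_counts(raw$female, "_f"))
}

#' Write a sync-like pooled count table
#' @param table data frame as returned by [simulate_pool_counts()]
#' @param file path
#' @param header optional comment lines (written with a leading `#`)
#' @export
write_sync <- function(table, file, header = NULL) {
  al <- c("A", "C", "G", "T")
  fmt <- function(suffix) {
    m <- as.matrix(table[, paste0(al, suffix)])
    paste(m[, 1], m[, 2], m[, 3], m[, 4], 0L, 0L, sep = ":")
  }
  lines <- paste(table$chrom, table$pos, table$ref,
                 fmt("_m"), fmt("_f"), sep = "\t")
  if (!is.null(header)) lines <- c(paste0("#", header), lines)
  writeLines(lines, file)
}

#' Simulate pooled male/female allele counts
#'
#' The female pool draws from X/X, the male pool from X/Y so that a planted
#' MSY difference segregates at expected frequency 0.5 among male reads and
#' 0 among female reads. Planted PAR differences are emitted as ordinary
#' population polymorphisms (one random allele frequency shared by both
#' pools): in a recombining region a variant cannot be sex-linked.
#' Depths are Poisson(`pool_depth`); a terminal interval of the chromosome
#' (`pool_mask_terminal_bp`, scaled) receives no reads at all, emulating
#' mapping failure where X and Y have diverged too far. Monomorphic
#' background sites are added for coverage estimation. Positions are
#' 1-based on the Y frame.
#'
#' @param config a [scenario_config()]
#' @param xy an [simulate_xy_pair()] result
#' @return list with `table` (count data frame) and `truth`
#'   (`msy_site_pos`: 1-based positions of the truly sex-linked sites)
#' @export
simulate_pool_counts <- function(config, xy) {
  validate_scenario_config(config)
  if (config$pool_depth <= 0) stop("pool_depth must be positive")
  set.seed(component_seed(config, "pool"))
  co <- scenario_coords(config)
  truth <- xy$truth
  y_len <- truth$chrom_length_y
  al <- c("A", "C", "G", "T")
  snps <- truth$snps
  n_bg <- config$n_pool_background
  bg_pos <- sort(sample.int(y_len, min(n_bg, y_len)) - 1L)
  bg_pos <- setdiff(bg_pos, snps$y_pos)
  y_chars <- strsplit(xy$y_sequence, "")[[1]]

  pos0 <- c(snps$y_pos, bg_pos)
  ref <- c(snps$ref, y_chars[bg_pos + 1L])        # ref = X allele
  alt <- c(snps$alt, rep(NA_character_, length(bg_pos)))
  region <- c(snps$region, rep("background", length(bg_pos)))
  ord <- order(pos0)
  pos0 <- pos0[ord]; ref <- ref[ord]; alt <- alt[ord]; region <- region[ord]

  n <- length(pos0)
  masked <- pos0 >= y_len - co$pool_mask_terminal
  depth_m <- rpois(n, config$pool_depth)
  depth_f <- rpois(n, config$pool_depth)
  depth_m[masked] <- 0L; depth_f[masked] <- 0L

  m_mat <- matrix(0L, n, 4, dimnames = list(NULL, al))
  f_mat <- matrix(0L, n, 4, dimnames = list(NULL, al))
  ref_i <- match(ref, al)
  alt_i <- match(alt, al)
  is_msy <- region == "MSY" & !is.na(alt_i)
  is_par <- region == "PAR" & !is.na(alt_i)
  # MSY: male pool X/Y -> alt at 0.5; female pool X/X -> ref only
  alt_m <- integer(n); alt_f <- integer(n)
  alt_m[is_msy] <- rbinom(sum(is_msy), depth_m[is_msy], 0.5)
  # PAR: shared polymorphism at one random frequency in both pools
  f_shared <- runif(n)
  alt_m[is_par] <- rbinom(sum(is_par), depth_m[is_par], f_shared[is_par])
  alt_f[is_par] <- rbinom(sum(is_par), depth_f[is_par], f_shared[is_par])
  ref_m <- depth_m - alt_m
  ref_f <- depth_f - alt_f
  m_mat[cbind(seq_len(n), ref_i)] <- ref_m
  f_mat[cbind(seq_len(n), ref_i)] <- ref_f
  has_alt <- !is.na(alt_i)
  m_mat[cbind(which(has_alt), alt_i[has_alt])] <-
    m_mat[cbind(which(has_alt), alt_i[has_alt])] + alt_m[has_alt]
  f_mat[cbind(which(has_alt), alt_i[has_alt])] <-
    f_mat[cbind(which(has_alt), alt_i[has_alt])] + alt_f[has_alt]

  table <- data.frame(chrom = "Y", pos = pos0 + 1L, ref = ref,
                      stringsAsFactors = FALSE)
  table[paste0(al, "_m")] <- as.data.frame(m_mat)
  table[paste0(al, "_f")] <- as.data.frame(f_mat)
  list(table = table,
       truth = list(msy_site_pos = table$pos[is_msy],
                    masked_interval = c(y_len - co$pool_mask_terminal, y_len)))
}
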