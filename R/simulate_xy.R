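#' Simulate an X/Y chromosome pair with a planted PAR/MSY structure
#'
#' Generates a random X chromosome and derives the Y from it by applying
#' region-specific substitution and indel processes: a low-divergence proximal
#' segment (the pseudoautosomal region, PAR) and a sharply elevated distal
#' segment (the male-specific region, MSY). Telomere-like `(TTAGGG)n` repeats
#' occupy both termini (of both sequences, as on a real chromosome) and are
#' never edited. Every planted edit is recorded once in the truth set, with
#' exact coordinates on both the X and the Y frame.
#'
#' Substitutions always change the base. Indel events are equiprobably
#' insertions or deletions with geometrically distributed lengths
#' (mean `indel_mean_len`); events that would overlap an earlier event are
#' skipped so that truth records are unambiguous. All coordinates are 0-based
#' half-open.
#'
#' @param config a [scenario_config()]
#' @return an object of class `xy_simulation`: list with `x_sequence`,
#'   `y_sequence` (character scalars), `truth` (see Details) and `config`.
#'   `truth` contains `par_interval` and `msy_interval` (0-based half-open, Y
#'   frame), `boundary_y`, `snps` (data frame: `x_pos`, `y_pos`, `ref`,
#'   `alt`, `region`), `indels` (data frame: `type`, `x_pos`, `y_pos`,
#'   `length`, `region`) and `chrom_length_y`.
#' @examples
#' cfg <- scenario_config(scale = 0.002, seed = 42)
#' sim <- simulate_xy_pair(cfg)
#' nchar(sim$y_sequence)
#' sim$truth$msy_interval
#' @export
simulate_xy_pair <- function(config) {
  validate_scenario_config(config)
  co <- scenario_coords(config)
  L <- co$chrom_length
  tel <- min(co$telomere, L %/% 4)
  bound <- co$boundary
  set.seed(component_seed(config, "xy"))

  bases <- c("A", "C", "G", "T")
  x <- sample(bases, L, replace = TRUE)
  telomere <- strsplit(strrep("TTAGGG", ceiling(tel / 6)), "")[[1]][seq_len(tel)]
  if (tel > 0) {
    x[seq_len(tel)] <- telomere
    x[(L - tel + 1):L] <- telomere
  }

  eligible <- rep(FALSE, L)
  if (L - tel >= tel + 1) eligible[(tel + 1):(L - tel)] <- TRUE
  is_par <- seq_len(L) <= bound          # 0-based pos < boundary
  sub_rate <- ifelse(is_par, config$sub_rate_par, config$sub_rate_msy)
  ind_rate <- ifelse(is_par, config$indel_rate_par, config$indel_rate_msy)

  # indel events, left to right, skipping overlaps with a previous deletion
  ev_pos <- which(runif(L) < ind_rate & eligible)
  n_ev <- length(ev_pos)
  ev_len <- rgeom(n_ev, prob = 1 / config$indel_mean_len) + 1L
  ev_ins <- runif(n_ev) < 0.5
  deleted <- rep(FALSE, L)
  ins_pos <- integer(0); ins_len <- integer(0); ins_seq <- character(0)
  del_pos <- integer(0); del_len <- integer(0)
  last_end <- 0L
  for (e in seq_len(n_ev)) {
    p <- ev_pos[e]
    if (p <= last_end) next
    if (ev_ins[e]) {
      ins_pos <- c(ins_pos, p); ins_len <- c(ins_len, ev_len[e])
      last_end <- p
    } else {
      l <- min(ev_len[e], L - tel - p + 1L)
      if (l <= 0) next
      deleted[p:(p + l - 1L)] <- TRUE
      del_pos <- c(del_pos, p); del_len <- c(del_len, l)
      last_end <- p + l - 1L
    }
  }
  if (length(ins_pos))
    ins_seq <- vapply(ins_len, function(l)
      paste(sample(bases, l, replace = TRUE), collapse = ""), character(1))

  # substitutions on surviving template bases
  sub_pos <- which(runif(L) < sub_rate & eligible & !deleted)
  y_base <- x
  if (length(sub_pos)) {
    shift <- sample(1:3, length(sub_pos), replace = TRUE)
    old_i <- match(x[sub_pos], bases)
    y_base[sub_pos] <- bases[((old_i - 1L + shift) %% 4L) + 1L]
  }

  # coordinate map: Y 0-based coordinate of each kept X base
  kept <- !deleted
  cumkept <- cumsum(kept)
  insadd <- integer(L)
  if (length(ins_pos)) insadd[ins_pos] <- ins_len
  cumins <- cumsum(insadd)
  y0 <- cumkept - 1L + cumins            # valid where kept

  # assemble Y
  y_core <- paste(y_base[kept], collapse = "")
  if (length(ins_pos)) {
    # split y_core at the offsets where insertions land
    off <- cumkept[ins_pos] - kept[ins_pos]  # kept bases strictly before pos
    # multiple insertions cannot share a position (overlap rule)
    ord <- order(off)
    off <- off[ord]; seqs <- ins_seq[ord]
    starts <- c(1L, off + 1L)
    ends <- c(off, nchar(y_core))
    parts <- substring(y_core, starts, ends)
    y_core <- paste(c(rbind(parts, c(seqs, ""))), collapse = "")
  }
  y_len <- nchar(y_core)
  stopifnot(y_len == sum(kept) + sum(ins_len))

  # boundary on the Y frame: first kept X base at or beyond the boundary
  bkeep <- which(kept & seq_len(L) > bound)
  boundary_y <- if (length(bkeep)) y0[bkeep[1]] else y_len

  region_of <- function(pos1) ifelse(pos1 <= bound, "PAR", "MSY")
  snps <- data.frame(
    x_pos = sub_pos - 1L, y_pos = y0[sub_pos],
    ref = x[sub_pos], alt = y_base[sub_pos],
    region = region_of(sub_pos), stringsAsFactors = FALSE)
  indels <- rbind(
    if (length(ins_pos)) data.frame(
      type = "insertion", x_pos = ins_pos - 1L,
      y_pos = cumkept[ins_pos] - kept[ins_pos] + cumins[ins_pos] - ins_len[ins_pos],
      length = ins_len, region = region_of(ins_pos), stringsAsFactors = FALSE),
    if (length(del_pos)) data.frame(
      type = "deletion", x_pos = del_pos - 1L,
      y_pos = cumkept[del_pos] + cumins[del_pos],
      length = del_len, region = region_of(del_pos), stringsAsFactors = FALSE))
  if (is.null(indels))
    indels <- data.frame(type = character(0), x_pos = integer(0),
                         y_pos = integer(0), length = integer(0),
                         region = character(0), stringsAsFactors = FALSE)
  indels <- indels[order(indels$x_pos), , drop = FALSE]
  rownames(indels) <- NULL

  truth <- list(
    par_interval = c(0L, as.integer(boundary_y)),
    msy_interval = c(as.integer(boundary_y), as.integer(y_len)),
    boundary_y = as.integer(boundary_y),
    snps = snps, indels = indels,
    chrom_length_y = as.integer(y_len),
    chrom_length_x = L,
    telomere_bp = tel)
  structure(list(x_sequence = paste(x, collapse = ""),
                 y_sequence = y_core,
                 truth = truth, config = config),
            class = "xy_simulation")
}

#' @export
print.xy_simulation <- function(x, ...) {
  t <- x$truth
  cat("Synthetic X/Y pair\n")
  cat(sprintf("  X: %s bp, Y: %s bp\n",
              format(t$chrom_length_x, big.mark = ","),
              format(t$chrom_length_y, big.mark = ",")))
  cat(sprintf("  PAR [0, %s), MSY [%s, %s) on Y\n",
              format(t$boundary_y, big.mark = ","),
              format(t$boundary_y, big.mark = ","),
              format(t$chrom_length_y, big.mark = ",")))
  cat(sprintf("  planted edits: %d SNPs, %d indels\n",
              nrow(t$snps), nrow(t$indels)))
  invisible(x)
}
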