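#' Seed exact-match anchors between an X and a Y chromosome
#'
#' Reports all maximal runs of k-mer co-matches that are unique in both
#' sequences, on the forward and (optionally) the reverse-complement strand
#' of the query. The Y sequence is the alignment target, the X the query, so
#' every downstream coordinate is a Y coordinate. Anchors are 0-based and
#' returned ordered by `(t_start, q_start)`.
#'
#' @param x_sequence query (X) sequence, character scalar
#' @param y_sequence target (Y) sequence, character scalar
#' @param k seed k-mer size (>= 11, default 15)
#' @param both_strands also search the reverse complement of the query
#' @return data frame with `t_start`, `q_start`, `length`, `strand`
#'   (`q_start` is always on the forward frame of the query); attribute
#'   `q_len`/`t_len` carry the sequence lengths
#' @export
seed_anchors <- function(x_sequence, y_sequence, k = 15, both_strands = TRUE) {
  if (!nzchar(x_sequence) || !nzchar(y_sequence))
    stop("sequences must be non-empty")
  if (k < 11) stop("k must be >= 11")
  fwd <- .anchors_cpp(y_sequence, x_sequence, as.integer(k))
  fwd$strand <- rep("+", nrow(fwd))
  out <- fwd
  q_len <- nchar(x_sequence)
  if (both_strands) {
    rcq <- revcomp(x_sequence)
    rev <- .anchors_cpp(y_sequence, rcq, as.integer(k))
    if (nrow(rev)) {
      rev$q_start <- q_len - (rev$q_start + rev$length)
      rev$strand <- "-"
      out <- rbind(fwd, rev)
    }
  }
  out <- out[order(out$t_start, out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "t_len") <- nchar(y_sequence)
  attr(out, "q_len") <- q_len
  out
}

#' Chain anchors into co-linear alignment chains
#'
#' Dynamic-programming chaining: maximises anchored bases minus an affine
#' cost `gap_open + gap_extend * |dt - dq|` on the coordinate offset between
#' consecutive anchors, with anchors strictly increasing on both sequences
#' within a chain. Chains are extracted greedily by descending score. A
#' bounded predecessor lookback keeps the scan near-linear; for anchor sets
#' smaller than the lookback the optimum is exact.
#'
#' @param anchors data frame from [seed_anchors()]
#' @param gap_open,gap_extend affine chaining gap cost
#' @param lookback predecessor window of the DP scan
#' @param min_score minimum chain score to report
#' @param q_len query length (needed for minus-strand chains; taken from the
#'   `anchors` attribute when present)
#' @return list of `alignment_chain` objects (fields `anchors`, `score`,
#'   `strand`), ordered by descending score
#' @export
chain_anchors <- function(anchors, gap_open = 2, gap_extend = 1,
                          lookback = 64, min_score = 30,
                          q_len = attr(anchors, "q_len")) {
  chains <- list()
  if (!nrow(anchors)) return(chains)
  if (is.null(anchors$strand)) anchors$strand <- rep("+", nrow(anchors))
  for (str in unique(anchors$strand)) {
    a <- anchors[anchors$strand == str, , drop = FALSE]
    # minus strand: chain on the reverse-complement frame of the query,
    # where co-linearity is increasing again
    qs <- if (str == "-") q_len - (a$q_start + a$length) else a$q_start
    ord <- order(a$t_start, qs)
    a <- a[ord, , drop = FALSE]; qs <- qs[ord]
    res <- .chain_cpp(as.integer(a$t_start), as.integer(qs),
                      as.integer(a$length), gap_open, gap_extend,
                      as.integer(lookback), min_score)
    ids <- res$chain_id
    for (ci in seq_along(res$score)) {
      sel <- which(ids == ci)
      if (!length(sel)) next
      ca <- a[sel, , drop = FALSE]
      ca <- ca[order(ca$t_start), , drop = FALSE]
      rownames(ca) <- NULL
      chains[[length(chains) + 1L]] <- structure(
        list(anchors = ca, score = res$score[ci], strand = str,
             q_len = q_len, filled = FALSE),
        class = "alignment_chain")
    }
  }
  chains[order(vapply(chains, `[[`, numeric(1), "score"),
               decreasing = TRUE)]
}

#' Fill inter-anchor gaps of a chain to a base-level alignment
#'
#' Aligns each unanchored region between consecutive anchors (and the chain
#' ends, up to `max_gap`) with a banded affine-gap global alignment and
#' classifies every column as match, mismatch, `t_gap` (gap in the target:
#' the column consumes a query base only) or `q_gap` (gap in the query).
#' A length-L gap costs `gap_open + gap_extend * L`. Regions larger than
#' `max_gap` on either sequence are left unaligned and flagged.
#'
#' @param chain an `alignment_chain` from [chain_anchors()]
#' @param x_sequence,y_sequence the query (X) and target (Y) sequences
#' @param max_gap largest inter-anchor region to realign (bp)
#' @param match,mismatch,gap_open,gap_extend alignment scores (costs as
#'   positive numbers for the gap parameters)
#' @param band_margin extra band width around the coordinate offset
#' @param align_ends also align the regions before the first and after the
#'   last anchor (out to the sequence ends)
#' @return the chain with `ops`/`lens` run-length encoded column classes
#'   (1 match, 2 mismatch, 3 t_gap, 4 q_gap), `t_start`/`t_end`,
#'   `q_start`/`q_end`, and an `unaligned` data frame
#' @export
fill_chain_gaps <- function(chain, x_sequence, y_sequence, max_gap = 20000,
                            match = 1, mismatch = -1, gap_open = 2,
                            gap_extend = 1, band_margin = 128,
                            align_ends = TRUE) {
  stopifnot(inherits(chain, "alignment_chain"))
  a <- chain$anchors
  q_seq <- x_sequence
  q_starts <- a$q_start
  if (chain$strand == "-") {
    q_seq <- revcomp(x_sequence)
    q_starts <- chain$q_len - (a$q_start + a$length)
    ord <- order(a$t_start)
    a <- a[ord, , drop = FALSE]; q_starts <- q_starts[ord]
  }
  filled <- .fill_chain_cpp(y_sequence, q_seq,
                            as.integer(a$t_start), as.integer(q_starts),
                            as.integer(a$length), as.integer(max_gap),
                            as.integer(match), as.integer(mismatch),
                            as.integer(gap_open), as.integer(gap_extend),
                            as.integer(band_margin), align_ends)
  chain$ops <- filled$ops
  chain$lens <- filled$lens
  chain$t_start <- filled$t_start
  chain$t_end <- filled$t_end
  chain$q_start <- filled$q_start
  chain$q_end <- filled$q_end
  chain$unaligned <- filled$unaligned
  chain$filled <- TRUE
  chain
}

#' @export
print.alignment_chain <- function(x, ...) {
  cat(sprintf("alignment_chain: %d anchors, strand %s, score %.0f\n",
              nrow(x$anchors), x$strand, x$score))
  if (isTRUE(x$filled)) {
    tot <- column_counts(x)
    cat(sprintf("  filled: target [%d, %d), %d columns (%d match, %d mismatch, %d t_gap, %d q_gap)\n",
                x$t_start, x$t_end, sum(tot), tot["match"], tot["mismatch"],
                tot["t_gap"], tot["q_gap"]))
  }
  invisible(x)
}

#' Column class totals of a filled chain
#' @param chain a filled `alignment_chain`
#' @return named integer vector (match, mismatch, t_gap, q_gap)
#' @export
column_counts <- function(chain) {
  stopifnot(isTRUE(chain$filled))
  out <- integer(4)
  for (i in 1:4) out[i] <- sum(chain$lens[chain$ops == i])
  setNames(out, names(.op_codes))
}

#' Net chains to a single-coverage tiling of the target
#'
#' Accepts chains greedily by descending score; each chain keeps only the
#' part of its target span that does not overlap previously kept spans
#' (the overlapping remainder is trimmed at column resolution). The result
#' covers every target base at most once, retaining the orthologous
#' alignment at each locus.
#'
#' @param chains list of filled `alignment_chain` objects
#' @return list of (possibly trimmed) chains, by descending score
#' @export
net_chains <- function(chains) {
  if (!length(chains)) return(chains)
  stopifnot(all(vapply(chains, function(c) isTRUE(c$filled), logical(1))))
  ord <- order(vapply(chains, `[[`, numeric(1), "score"), decreasing = TRUE)
  chains <- chains[ord]
  kept <- IRanges::IRanges()
  out <- list()
  for (ch in chains) {
    span <- IRanges::IRanges(start = ch$t_start + 1L, end = ch$t_end)
    if (ch$t_end <= ch$t_start) next
    ov <- IRanges::intersect(span, kept)
    if (length(ov)) {
      ch <- trim_chain(ch, ov)
      if (is.null(ch)) { next }
    }
    if (ch$t_end > ch$t_start) {
      kept <- IRanges::reduce(c(kept, IRanges::IRanges(ch$t_start + 1L,
                                                       ch$t_end)))
      out[[length(out) + 1L]] <- ch
    }
  }
  out
}

# Drop columns whose target coordinate falls into `excl` (1-based IRanges);
# t_gap columns follow their left flank. Keeps the largest remaining block.
trim_chain <- function(chain, excl) {
  ops <- chain$ops; lens <- chain$lens
  n <- length(ops)
  new_ops <- integer(0); new_lens <- integer(0)
  t <- chain$t_start
  q <- chain$q_start
  first_t <- NA_integer_; last_t <- chain$t_start
  first_q <- NA_integer_; last_q <- chain$q_start
  excl_mask_start <- IRanges::start(excl) - 1L   # back to 0-based
  excl_mask_end <- IRanges::end(excl)            # half-open end
  in_excl <- function(pos) {
    any(pos >= excl_mask_start & pos < excl_mask_end)
  }
  push <- function(op, l) {
    if (l <= 0) return()
    m <- length(new_ops)
    if (m && new_ops[m] == op) new_lens[m] <<- new_lens[m] + l
    else { new_ops[m + 1L] <<- op; new_lens[m + 1L] <<- l }
  }
  for (r in seq_len(n)) {
    op <- ops[r]; l <- lens[r]
    if (op == .op_codes["t_gap"]) {
      if (!in_excl(max(t - 1L, 0L))) push(op, l)
      q <- q + l
      next
    }
    # target-consuming run: split at exclusion boundaries
    pos <- t
    rem <- l
    while (rem > 0L) {
      # length of the homogeneous (excluded or not) stretch from pos
      excl_now <- in_excl(pos)
      nxt <- rem
      for (b in seq_along(excl_mask_start)) {
        s <- excl_mask_start[b]; e <- excl_mask_end[b]
        if (excl_now && pos >= s && pos < e) nxt <- min(nxt, e - pos)
        if (!excl_now && s > pos) nxt <- min(nxt, s - pos)
      }
      if (!excl_now) {
        if (is.na(first_t)) { first_t <- pos; first_q <- q }
        push(op, nxt)
        last_t <- pos + nxt
        last_q <- q + if (op != .op_codes["q_gap"]) nxt else 0L
      }
      pos <- pos + nxt
      if (op != .op_codes["q_gap"]) q <- q + nxt
      rem <- rem - nxt
    }
    t <- pos
  }
  if (!length(new_ops) || is.na(first_t)) return(NULL)
  chain$ops <- new_ops; chain$lens <- new_lens
  chain$t_start <- first_t; chain$t_end <- last_t
  chain$q_start <- if (is.na(first_q)) chain$q_start else first_q
  chain$q_end <- last_q
  chain
}

#' Windowed SNP + indel divergence along the target
#'
#' Tiles the target (Y) chromosome into windows and computes, per window, the
#' number of aligned columns, mismatch (SNP) columns and gap (indel) columns,
#' and the divergence percentage
#' `100 * (n_snp + n_indel_cols) / max(aligned_cols, 1)`. Columns are
#' assigned to windows by the target coordinate of their left flank; `t_gap`
#' columns (which consume no target base) attach to the left flanking
#' position. Windows where the aligned target fraction falls below `min_cov`
#' are flagged low-confidence.
#'
#' @param chains list of netted, filled `alignment_chain` objects
#' @param chrom_length target chromosome length (bp)
#' @param window_bp window size (default 10 kb)
#' @param step_bp window step (default `window_bp`: non-overlapping tiles)
#' @param min_cov minimum covered fraction for a confident window
#' @param indel_mode count indel `"columns"` (gap bases; default) or
#'   `"events"` (maximal gap runs) in the numerator
#' @return data frame with `t_chrom`, `t_start`, `t_end`, `aligned_cols`,
#'   `n_snp`, `n_indel_cols`, `divergence_pct`, `covered_fraction`,
#'   `low_confidence`
#' @export
window_divergence <- function(chains, chrom_length, window_bp = 10000,
                              step_bp = window_bp, min_cov = 0.25,
                              indel_mode = c("columns", "events")) {
  indel_mode <- match.arg(indel_mode)
  if (inherits(chains, "alignment_chain")) chains <- list(chains)
  cm <- integer(chrom_length); cx <- integer(chrom_length)
  ct <- integer(chrom_length); cq <- integer(chrom_length)
  ev <- integer(chrom_length)
  for (ch in chains) {
    stopifnot(isTRUE(ch$filled))
    pc <- .per_base_counts_cpp(ch$ops, ch$lens, ch$t_start, chrom_length)
    cm <- cm + pc$match; cx <- cx + pc$mismatch
    ct <- ct + pc$t_gap; cq <- cq + pc$q_gap
    if (indel_mode == "events")
      ev <- ev + .indel_events_cpp(ch$ops, ch$lens, ch$t_start, chrom_length)
  }
  starts <- seq.int(0L, max(chrom_length - 1L, 0L), by = step_bp)
  ends <- pmin(starts + window_bp, chrom_length)
  csum <- function(v) { s <- c(0, cumsum(as.numeric(v))); s[ends + 1] - s[starts + 1] }
  wm <- csum(cm); wx <- csum(cx); wt <- csum(ct); wq <- csum(cq)
  aligned <- wm + wx + wt + wq
  n_indel <- if (indel_mode == "columns") wt + wq else csum(ev)
  covered <- (wm + wx + wq) / (ends - starts)
  div <- 100 * (wx + n_indel) / pmax(aligned, 1)
  data.frame(t_chrom = "Y", t_start = starts, t_end = ends,
             aligned_cols = aligned, n_snp = wx, n_indel_cols = n_indel,
             divergence_pct = div, covered_fraction = covered,
             low_confidence = covered < min_cov,
             stringsAsFactors = FALSE)
}

#' Detect the PAR/MSY boundary in a window divergence series
#'
#' Exhaustive single-changepoint scan: the split position (on a window edge)
#' minimising the total within-segment squared error of `divergence_pct` over
#' all admissible splits. The fold change `mean_after / mean_before` is
#' reported; when it falls below `fold_threshold` the call is flagged
#' `no_transition` (degenerate/uniform series). Ties in the squared error are
#' broken to the rightmost edge. Low-confidence windows are excluded unless
#' `use_low_conf` is set.
#'
#' @param windows data frame from [window_divergence()]
#' @param min_windows_per_side minimum windows required on each side
#' @param fold_threshold fold change below which no transition is called
#' @param use_low_conf include low-confidence windows in the scan
#' @return an object of class `boundary_call`: `changepoint_bp`,
#'   `mean_before`, `mean_after`, `fold`, `msy_interval` (0-based half-open),
#'   `no_transition`, `n_windows`
#' @export
detect_boundary <- function(windows, min_windows_per_side = 5,
                            fold_threshold = 1.5, use_low_conf = FALSE) {
  w <- windows
  if (!use_low_conf) w <- w[!w$low_confidence, , drop = FALSE]
  w <- w[order(w$t_start), , drop = FALSE]
  n <- nrow(w)
  if (n < 2 * min_windows_per_side)
    stop("need at least ", 2 * min_windows_per_side,
         " usable windows, got ", n)
  d <- w$divergence_pct
  cs <- cumsum(d); cs2 <- cumsum(d^2)
  tot <- cs[n]; tot2 <- cs2[n]
  ks <- seq.int(min_windows_per_side, n - min_windows_per_side)
  sse <- (cs2[ks] - cs[ks]^2 / ks) +
    ((tot2 - cs2[ks]) - (tot - cs[ks])^2 / (n - ks))
  # rightmost minimiser
  best <- ks[max(which(sse <= min(sse) + 1e-12))]
  mean_before <- cs[best] / best
  mean_after <- (tot - cs[best]) / (n - best)
  fold <- if (mean_before > 0) mean_after / mean_before else Inf
  changepoint <- w$t_start[best + 1L]
  chrom_end <- max(windows$t_end)
  structure(list(changepoint_bp = changepoint,
                 mean_before = mean_before, mean_after = mean_after,
                 fold = fold,
                 msy_interval = c(changepoint, chrom_end),
                 no_transition = is.finite(fold) && fold < fold_threshold,
                 n_windows = n),
            class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat("PAR/MSY boundary call\n")
  cat(sprintf("  changepoint: %s bp\n",
              format(x$changepoint_bp, big.mark = ",")))
  cat(sprintf("  mean divergence: %.3f%% proximal, %.3f%% distal (fold %.2f)\n",
              x$mean_before, x$mean_after, x$fold))
  cat(sprintf("  MSY: [%s, %s)\n",
              format(x$msy_interval[1], big.mark = ","),
              format(x$msy_interval[2], big.mark = ",")))
  if (isTRUE(x$no_transition))
    cat("  flag: no transition (fold below threshold)\n")
  invisible(x)
}

#' Align an X/Y pair end to end
#'
#' Convenience wrapper running [seed_anchors()], [chain_anchors()],
#' [fill_chain_gaps()] and [net_chains()] with shared parameters.
#'
#' @inheritParams seed_anchors
#' @inheritParams fill_chain_gaps
#' @param chain_gap_open,chain_gap_extend chaining gap cost
#' @param min_score minimum chain score
#' @return list of netted, filled `alignment_chain` objects
#' @export
align_xy <- function(x_sequence, y_sequence, k = 15, both_strands = TRUE,
                     chain_gap_open = 2, chain_gap_extend = 1,
                     min_score = 30, max_gap = 20000, match = 1,
                     mismatch = -1, gap_open = 2, gap_extend = 1,
                     band_margin = 128) {
  anchors <- seed_anchors(x_sequence, y_sequence, k = k,
                          both_strands = both_strands)
  if (!nrow(anchors)) return(list())
  chains <- chain_anchors(anchors, gap_open = chain_gap_open,
                          gap_extend = chain_gap_extend,
                          min_score = min_score)
  chains <- lapply(chains, fill_chain_gaps, x_sequence = x_sequence,
                   y_sequence = y_sequence, max_gap = max_gap, match = match,
                   mismatch = mismatch, gap_open = gap_open,
                   gap_extend = gap_extend, band_margin = band_margin)
  net_chains(chains)
}
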