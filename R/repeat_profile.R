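#' Kimura two-parameter distance
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` for transition proportion
#' `P` and transversion proportion `Q` (element versus consensus). Used as a
#' repeat age proxy: younger insertions have diverged less from their family
#' consensus and carry smaller K.
#'
#' @param P transition proportion(s)
#' @param Q transversion proportion(s)
#' @return numeric distance(s)
#' @examples
#' kimura2p(0.1, 0.05)
#' @export
kimura2p <- function(P, Q) {
  n <- max(length(P), length(Q))
  P <- rep_len(P, n); Q <- rep_len(Q, n)
  if (any(P < 0) || any(Q < 0)) stop("P and Q must be non-negative")
  bad1 <- 1 - 2 * P - Q <= 0
  if (any(bad1))
    stop("K2P domain violation: 1 - 2P - Q <= 0 (P = ",
         P[which(bad1)[1]], ", Q = ", Q[which(bad1)[1]], ")")
  bad2 <- 1 - 2 * Q <= 0
  if (any(bad2))
    stop("K2P domain violation: 1 - 2Q <= 0 (Q = ", Q[which(bad2)[1]], ")")
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

#' Repeat base fraction of a region
#'
#' Overlapping repeat intervals are merged before coverage is computed;
#' the fraction is merged covered bases inside the region divided by the
#' region length.
#'
#' @param intervals data frame with `start`, `end` (0-based half-open)
#' @param region length-2 numeric, 0-based half-open
#' @return fraction in `[0, 1]`
#' @export
region_repeat_fraction <- function(intervals, region) {
  if (!nrow(intervals)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start + 1L,
                                         intervals$end))
  reg <- IRanges::IRanges(region[1] + 1L, region[2])
  sum(IRanges::width(IRanges::intersect(ir, reg))) /
    (region[2] - region[1])
}

#' Region repeat summary
#'
#' Repeat fraction plus the Kimura distances of the elements whose midpoint
#' falls inside the region.
#'
#' @param intervals data frame with `start`, `end`, `family`, `P`, `Q`
#' @param region length-2 numeric, 0-based half-open
#' @param label region label
#' @return an object of class `region_repeat_summary`: list with `label`,
#'   `repeat_fraction`, `n_elements`, `kimura`
#' @export
region_repeat_summary <- function(intervals, region, label) {
  mid <- (intervals$start + intervals$end) / 2
  sel <- mid >= region[1] & mid < region[2]
  kim <- if (any(sel)) kimura2p(intervals$P[sel], intervals$Q[sel])
         else numeric(0)
  structure(list(label = label,
                 repeat_fraction = region_repeat_fraction(intervals, region),
                 n_elements = sum(sel), kimura = kim),
            class = "region_repeat_summary")
}

#' @export
print.region_repeat_summary <- function(x, ...) {
  cat(sprintf("%s: repeat fraction %.3f, %d elements, median Kimura %s\n",
              x$label, x$repeat_fraction, x$n_elements,
              if (x$n_elements) sprintf("%.4f", median(x$kimura)) else "NA"))
  invisible(x)
}

#' Repeat age contrast between two regions
#'
#' Two-sided rank-based location test (Wilcoxon rank-sum) of the Kimura
#' distances of two regions, with medians and their difference. Samples
#' smaller than 5 per side are flagged underpowered.
#'
#' @param par_summary,msy_summary `region_repeat_summary` objects (or plain
#'   numeric Kimura vectors)
#' @return list with `statistic`, `p_value`, `median_par`, `median_msy`,
#'   `median_difference` (MSY minus PAR; negative means MSY younger),
#'   `underpowered`
#' @export
age_contrast <- function(par_summary, msy_summary) {
  kp <- if (inherits(par_summary, "region_repeat_summary"))
    par_summary$kimura else as.numeric(par_summary)
  km <- if (inherits(msy_summary, "region_repeat_summary"))
    msy_summary$kimura else as.numeric(msy_summary)
  under <- length(kp) < 5 || length(km) < 5
  if (!length(kp) || !length(km))
    return(list(statistic = NA_real_, p_value = NA_real_,
                median_par = if (length(kp)) median(kp) else NA_real_,
                median_msy = if (length(km)) median(km) else NA_real_,
                median_difference = NA_real_, underpowered = under))
  wt <- suppressWarnings(wilcox.test(km, kp, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_par = median(kp), median_msy = median(km),
       median_difference = median(km) - median(kp),
       underpowered = under)
}

#' Compute P and Q from paired element/consensus sequences
#'
#' Helper for inputs that carry sequences instead of count columns:
#' proportions of transition and transversion columns over the ungapped
#' aligned columns of each pair.
#'
#' @param element,consensus equal-length aligned sequences (gaps `-` are
#'   skipped)
#' @return list with `P`, `Q`, `n_columns`
#' @export
pq_from_alignment <- function(element, consensus) {
  a <- strsplit(toupper(element), "")[[1]]
  b <- strsplit(toupper(consensus), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(list(P = NA_real_, Q = NA_real_, n_columns = 0L))
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  list(P = mean(transition), Q = mean(diff & !transition),
       n_columns = length(a))
}

#' Simulate repeat annotations with region-specific density and age
#'
#' Walks each region (PAR, MSY) alternating exponential gaps and
#' lognormally distributed element lengths so that the merged repeat base
#' fraction matches the configured density. Each element receives a target
#' Kimura distance drawn from its region's (truncated normal) age
#' distribution -- younger in the MSY -- which is converted to transition/
#' transversion proportions under a two-parameter substitution process with
#' a transition/transversion rate ratio of 2.
#'
#' @param config a [scenario_config()]
#' @param xy an [simulate_xy_pair()] result (supplies the region intervals)
#' @return data frame with `chrom`, `start`, `end`, `family`, `region`,
#'   `P`, `Q`
#' @export
simulate_repeats <- function(config, xy) {
  validate_scenario_config(config)
  set.seed(component_seed(config, "repeats"))
  truth <- xy$truth
  families <- c("hAT", "Tc1-Mariner", "Gypsy", "LINE-R2", "Helitron")

  sample_region <- function(region, density, k_mean, label) {
    if (density <= 0) return(NULL)
    lo <- region[1]; hi <- region[2]
    len_mean <- exp(config$repeat_len_meanlog +
                    config$repeat_len_sdlog^2 / 2)
    gap_mean <- len_mean * (1 - density) / density
    starts <- integer(0); ends <- integer(0)
    pos <- lo + rexp(1, 1 / max(gap_mean, 1))
    while (pos < hi) {
      l <- min(max(round(rlnorm(1, config$repeat_len_meanlog,
                                config$repeat_len_sdlog)), 50), 5000)
      if (pos + l > hi) break
      starts <- c(starts, round(pos)); ends <- c(ends, round(pos) + l)
      pos <- pos + l + rexp(1, 1 / max(gap_mean, 1))
    }
    n <- length(starts)
    if (!n) return(NULL)
    k <- rnorm(n, k_mean, config$kimura_sd)
    k <- pmin(pmax(k, 0.01), 0.45)
    # K = (alpha + 2 beta) t with alpha/beta = 2: beta t = K/4, alpha t = K/2
    bt <- k / 4; at <- k / 2
    Q <- 0.5 * (1 - exp(-4 * bt))
    P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
    data.frame(chrom = "Y", start = starts, end = ends,
               family = sample(families, n, replace = TRUE),
               region = label, P = P, Q = Q, stringsAsFactors = FALSE)
  }
  out <- rbind(
    sample_region(truth$par_interval, config$repeat_density_par,
                  config$kimura_mean_par, "PAR"),
    sample_region(truth$msy_interval, config$repeat_density_msy,
                  config$kimura_mean_msy, "MSY"))
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      region = character(0), P = numeric(0), Q = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
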