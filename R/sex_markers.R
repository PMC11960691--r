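#' Construct a RAD tag catalog from per-individual reads
#'
#' Collapses identical reads within each individual, then merges tags across
#' individuals by single-linkage clustering at up to `max_mismatch`
#' substitutions between equal-length sequences (reads of unequal length are
#' never merged). The cluster representative is its most abundant sequence;
#' the depth matrix records per-individual read counts per catalog tag.
#'
#' @param per_individual_reads named list of character vectors (reads per
#'   individual)
#' @param sex character vector (`"M"`/`"F"`), one per individual
#' @param max_mismatch single-linkage merge radius (substitutions)
#' @return a `tag_catalog`: list with `tags` (data frame `tag_id`,
#'   `sequence`), `depth` (integer matrix tags x individuals) and `sex`
#' @export
build_tag_catalog <- function(per_individual_reads, sex, max_mismatch = 2) {
  stopifnot(length(per_individual_reads) == length(sex))
  inds <- names(per_individual_reads)
  if (is.null(inds)) inds <- paste0("ind", seq_along(per_individual_reads))
  counts <- lapply(per_individual_reads, function(r) {
    if (!length(r)) return(integer(0))
    table(toupper(r))
  })
  seqs <- unique(unlist(lapply(counts, names), use.names = FALSE))
  if (!length(seqs)) stop("no reads supplied")
  comp <- .hamming_cluster_cpp(seqs, as.integer(max_mismatch))
  depth <- matrix(0L, nrow = max(comp), ncol = length(inds),
                  dimnames = list(NULL, inds))
  abundance <- numeric(max(comp))
  rep_seq <- character(max(comp))
  total_per_seq <- setNames(numeric(length(seqs)), seqs)
  for (i in seq_along(counts)) {
    ci <- counts[[i]]
    if (!length(ci)) next
    idx <- comp[match(names(ci), seqs)]
    depth[, i] <- depth[, i] +
      as.integer(tapply(as.integer(ci), factor(idx, levels = seq_len(max(comp))),
                        sum, default = 0L))
    total_per_seq[names(ci)] <- total_per_seq[names(ci)] + as.integer(ci)
  }
  for (cl in seq_len(max(comp))) {
    members <- seqs[comp == cl]
    rep_seq[cl] <- members[which.max(total_per_seq[members])]
    abundance[cl] <- sum(total_per_seq[members])
  }
  tag_catalog(tags = data.frame(tag_id = sprintf("tag%05d", seq_len(max(comp))),
                                sequence = rep_seq, stringsAsFactors = FALSE),
              depth = depth, sex = sex)
}

#' Assemble a tag catalog from a precomputed depth matrix
#'
#' @param tags data frame with `tag_id` and `sequence` (plus any extra
#'   columns, kept as-is)
#' @param depth integer matrix tags x individuals
#' @param sex per-individual sex labels (`"M"`/`"F"`)
#' @return a `tag_catalog`
#' @export
tag_catalog <- function(tags, depth, sex) {
  stopifnot(nrow(tags) == nrow(depth), ncol(depth) == length(sex),
            all(depth >= 0))
  sex <- toupper(substr(sex, 1, 1))
  if (!all(sex %in% c("M", "F"))) stop("sex labels must be M or F")
  structure(list(tags = tags, depth = depth, sex = sex),
            class = "tag_catalog")
}

#' @export
print.tag_catalog <- function(x, ...) {
  cat(sprintf("tag_catalog: %d tags x %d individuals (%d M / %d F)\n",
              nrow(x$tags), ncol(x$depth), sum(x$sex == "M"),
              sum(x$sex == "F")))
  invisible(x)
}

#' Tile distribution of tag presence by sex
#'
#' The contingency cube of the tile plot: `counts[f+1, m+1]` is the number of
#' catalog tags present (depth >= `min_depth`) in exactly `f` females and `m`
#' males. All cells sum to the catalog size.
#'
#' @param catalog a `tag_catalog`
#' @param min_depth presence threshold
#' @return integer matrix with rownames `0..F` (females) and colnames
#'   `0..M` (males)
#' @export
tile_distribution <- function(catalog, min_depth = 1) {
  pres <- catalog$depth >= min_depth
  nf <- sum(catalog$sex == "F"); nm <- sum(catalog$sex == "M")
  f_cnt <- rowSums(pres[, catalog$sex == "F", drop = FALSE])
  m_cnt <- rowSums(pres[, catalog$sex == "M", drop = FALSE])
  out <- matrix(0L, nrow = nf + 1L, ncol = nm + 1L,
                dimnames = list(0:nf, 0:nm))
  tab <- table(factor(f_cnt, levels = 0:nf), factor(m_cnt, levels = 0:nm))
  out[] <- as.integer(tab)
  out
}

#' Call male-only tags
#'
#' Tags present (depth >= `min_depth`) in at least `min_males` males and at
#' most `max_females` females.
#'
#' @inheritParams tile_distribution
#' @param min_males minimum male presence count
#' @param max_females maximum tolerated female presence count (default 0)
#' @return character vector of `tag_id`s
#' @export
call_male_only_tags <- function(catalog, min_males, max_females = 0,
                                min_depth = 1) {
  pres <- catalog$depth >= min_depth
  f_cnt <- rowSums(pres[, catalog$sex == "F", drop = FALSE])
  m_cnt <- rowSums(pres[, catalog$sex == "M", drop = FALSE])
  catalog$tags$tag_id[m_cnt >= min_males & f_cnt <= max_females]
}

#' Karlin-Altschul E-value of an ungapped score
#'
#' `E = K * m * n * exp(-lambda * S)` with ungapped nucleotide constants
#' (defaults `lambda = 1.28`, `K = 0.46` for match +1 / mismatch -2).
#'
#' @param score ungapped alignment score(s)
#' @param m,n query and search-space lengths
#' @param lambda,K Karlin-Altschul parameters
#' @return numeric E-value(s)
#' @export
karlin_evalue <- function(score, m, n, lambda = 1.28, K = 0.46) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

#' Map tags to a genome by ungapped seed-and-extend
#'
#' Finds, per tag, the best-scoring ungapped local hit on either strand of
#' the target (exact k-mer seeds, maximum-scoring diagonal segment,
#' match +1 / mismatch -2 by default), converts the score to a
#' Karlin-Altschul E-value and discards hits above `evalue_max`. Score ties
#' are broken to the smallest target coordinate.
#'
#' @param tags character vector of tag sequences (names are tag ids) or the
#'   `tags` data frame of a `tag_catalog`
#' @param y_sequence target sequence
#' @param evalue_max E-value cutoff (default 1e-40, the classic `e-40`)
#' @param k seed size
#' @param match,mismatch ungapped scores
#' @param lambda,K Karlin-Altschul parameters
#' @param max_seeds_per_tag candidate diagonal cap per tag
#' @return data frame with `tag_id`, `t_pos` (0-based best-hit left
#'   coordinate), `strand`, `score`, `evalue`
#' @export
map_tags <- function(tags, y_sequence, evalue_max = 1e-40, k = 15,
                     match = 1, mismatch = -2, lambda = 1.28, K = 0.46,
                     max_seeds_per_tag = 512) {
  if (is.data.frame(tags)) {
    ids <- tags$tag_id
    seqs <- tags$sequence
  } else {
    seqs <- unname(tags)
    ids <- names(tags)
    if (is.null(ids)) ids <- paste0("tag", seq_along(seqs))
  }
  if (!length(seqs))
    return(data.frame(tag_id = character(0), t_pos = integer(0),
                      strand = character(0), score = integer(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  hits <- .map_tags_cpp(toupper(seqs), y_sequence, as.integer(k),
                        as.integer(match), as.integer(mismatch),
                        as.integer(max_seeds_per_tag))
  ev <- karlin_evalue(hits$score, nchar(seqs[hits$tag_index]),
                      nchar(y_sequence), lambda, K)
  keep <- ev <= evalue_max
  data.frame(tag_id = ids[hits$tag_index[keep]],
             t_pos = hits$t_pos[keep], strand = hits$strand[keep],
             score = hits$score[keep], evalue = ev[keep],
             stringsAsFactors = FALSE)
}

#' Positional enrichment of tag hits in a region
#'
#' Fraction of best hits falling inside a region, with a one-sided exact
#' binomial test against the null that hits land uniformly
#' (`p0 = region_length / chrom_length`).
#'
#' @param hits data frame from [map_tags()] (uses `t_pos`)
#' @param region_interval length-2 numeric, 0-based half-open
#' @param chrom_length chromosome length (bp)
#' @return list with `n_hits`, `n_in_region`, `fraction_in_region`, `p0`,
#'   `binomial_p`
#' @export
region_enrichment <- function(hits, region_interval, chrom_length) {
  n <- nrow(hits)
  p0 <- (region_interval[2] - region_interval[1]) / chrom_length
  if (n == 0)
    return(list(n_hits = 0L, n_in_region = 0L, fraction_in_region = NA_real_,
                p0 = p0, binomial_p = NA_real_))
  inside <- sum(hits$t_pos >= region_interval[1] &
                hits$t_pos < region_interval[2])
  pval <- binom.test(inside, n, p = p0, alternative = "greater")$p.value
  list(n_hits = n, n_in_region = inside, fraction_in_region = inside / n,
       p0 = p0, binomial_p = pval)
}

#' Simulate RAD tag depths across male and female individuals
#'
#' Samples tag loci on the simulated Y: shared loci anywhere along the
#' chromosome and truly male-limited loci placed so that a configured
#' fraction (default 70%) lies distal of the distal enrichment cutoff
#' (24 Mb-equivalent) and the remainder within the 20-23.5 Mb-equivalent
#' range. Male-limited loci have nonzero depth only in males; every
#' individual/locus combination is subject to dropout; depths are Poisson.
#'
#' @param config a [scenario_config()]
#' @param xy an [simulate_xy_pair()] result (tag sequences are cut from its
#'   Y sequence)
#' @return list with `catalog` (a `tag_catalog`; the `tags` data frame
#'   carries the true `y_pos`), and `truth` (list: `male_only_tag_ids`,
#'   `positions`)
#' @export
simulate_rad_individuals <- function(config, xy) {
  validate_scenario_config(config)
  if (config$n_males < 1 || config$n_females < 1)
    stop("need at least one individual per sex")
  if (config$n_tag_loci < 1) stop("n_tag_loci must be positive")
  set.seed(component_seed(config, "rad"))
  co <- scenario_coords(config)
  y <- xy$y_sequence
  y_len <- nchar(y)
  tl <- config$tag_len_bp
  n_mo <- config$n_male_only_loci
  n_sh <- config$n_tag_loci - n_mo
  stopifnot(n_sh >= 0)
  tel <- xy$truth$telomere_bp

  distal <- runif(n_mo) < config$male_only_fraction_distal
  lo_d <- co$rad_distal_cutoff
  hi_d <- y_len - tl - tel
  lo_p <- co$rad_proximal_range[1]
  hi_p <- min(co$rad_proximal_range[2], y_len - tl)
  pos_mo <- integer(n_mo)
  pos_mo[distal] <- as.integer(floor(runif(sum(distal), lo_d, hi_d)))
  pos_mo[!distal] <- as.integer(floor(runif(sum(!distal), lo_p, hi_p)))
  pos_sh <- as.integer(floor(runif(n_sh, tel, y_len - tl - tel)))
  pos <- c(pos_mo, pos_sh)
  male_only <- c(rep(TRUE, n_mo), rep(FALSE, n_sh))
  seqs <- substring(y, pos + 1L, pos + tl)

  n_ind <- config$n_males + config$n_females
  sex <- c(rep("M", config$n_males), rep("F", config$n_females))
  inds <- paste0(ifelse(sex == "M", "male", "female"),
                 c(seq_len(config$n_males), seq_len(config$n_females)))
  n_tag <- length(pos)
  depth <- matrix(rpois(n_tag * n_ind, config$tag_depth),
                  nrow = n_tag, ncol = n_ind, dimnames = list(NULL, inds))
  drop <- matrix(runif(n_tag * n_ind) < config$tag_dropout,
                 nrow = n_tag, ncol = n_ind)
  depth[drop] <- 0L
  depth[male_only, sex == "F"] <- 0L

  ids <- sprintf("tag%05d", seq_len(n_tag))
  tags <- data.frame(tag_id = ids, sequence = seqs, y_pos = pos,
                     male_only = male_only, stringsAsFactors = FALSE)
  list(catalog = tag_catalog(tags, depth, sex),
       truth = list(male_only_tag_ids = ids[male_only],
                    positions = setNames(pos, ids)))
}
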