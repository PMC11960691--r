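#' Build hap-mer sets from two parents' k-mer collections
#'
#' Hap-mers are the canonical k-mers private to one parent: the set
#' differences A\\B and B\\A. Reads are later assigned to the parent whose
#' hap-mers they carry more of. Canonical means the lexicographic minimum of
#' a k-mer and its reverse complement; k-mers containing ambiguous bases are
#' dropped (no k-mer spans an N).
#'
#' @param parentA,parentB character vectors: either DNA sequences (k-mers are
#'   counted internally) or pre-computed k-mer strings of length `k`
#' @param k odd k-mer size in `[15, 31]` (default 21, the community standard
#'   for trio binning)
#' @param labels length-2 character vector of parent labels
#' @return list of two `hapmer_set` objects (`parentA` private, `parentB`
#'   private)
#' @examples
#' hs <- build_hapmer_sets("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTT", k = 15)
#' lengths(lapply(hs, `[[`, "kmers"))
#' @export
build_hapmer_sets <- function(parentA, parentB, k = 21,
                              labels = c("parentA", "parentB")) {
  if (k %% 2 == 0) stop("k must be odd")
  if (k < 15 || k > 31) stop("k must lie in [15, 31]")
  if (!length(parentA) || !length(parentB))
    stop("both parents need at least one sequence")
  ka <- .canon_kmers_cpp(toupper(parentA), as.integer(k))
  kb <- .canon_kmers_cpp(toupper(parentB), as.integer(k))
  new_set <- function(label, kmers)
    structure(list(parent_label = label, k = as.integer(k), kmers = kmers),
              class = "hapmer_set")
  list(new_set(labels[1], setdiff(ka, kb)),
       new_set(labels[2], setdiff(kb, ka)))
}

#' @export
print.hapmer_set <- function(x, ...) {
  cat(sprintf("hapmer_set '%s': %d canonical %d-mers\n",
              x$parent_label, length(x$kmers), x$k))
  invisible(x)
}

#' Classify a read by parental hap-mer content
#'
#' Counts canonical k-mer hits against each parent's hap-mer set; the larger
#' count wins. A tie (including 0-0) is `unclassified`; reads shorter than
#' `min_len` are `too_short` and not counted.
#'
#' @param read_sequence character scalar
#' @param hapA,hapB `hapmer_set` objects with equal `k`
#' @param min_len minimum read length to attempt classification (>= k);
#'   default 1000 bp
#' @return data frame with `label` (one of `parentA`/`parentB` labels,
#'   `"unclassified"`, `"too_short"`), `countA`, `countB`
#' @export
classify_read <- function(read_sequence, hapA, hapB, min_len = 1000) {
  res <- bin_readset(read_sequence, hapA, hapB, min_len)
  res$assignments[, c("label", "countA", "countB")]
}

#' Bin a read set by parental origin
#'
#' Applies [classify_read()] logic to every read and partitions them into
#' four bins: the two parents, `unclassified` and `too_short`. Every read
#' lands in exactly one bin and base totals are conserved.
#'
#' @param reads character vector of read sequences (names are read ids; when
#'   unnamed, `read1..readN` are used)
#' @inheritParams classify_read
#' @return list with `assignments` (data frame: `read_id`, `label`, `countA`,
#'   `countB`, `length`), `bins` (named list of read-id vectors) and
#'   `summary` (data frame: `bin`, `n_reads`, `n_bases`)
#' @export
bin_readset <- function(reads, hapA, hapB, min_len = 1000) {
  stopifnot(inherits(hapA, "hapmer_set"), inherits(hapB, "hapmer_set"))
  if (hapA$k != hapB$k) stop("hap-mer sets disagree on k")
  k <- hapA$k
  if (min_len < k) stop("min_len must be >= k")
  labA <- hapA$parent_label; labB <- hapB$parent_label
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  bins_order <- c(labA, labB, "unclassified", "too_short")
  if (!length(reads)) {
    empty <- data.frame(read_id = character(0), label = character(0),
                        countA = integer(0), countB = integer(0),
                        length = integer(0), stringsAsFactors = FALSE)
    return(list(assignments = empty,
                bins = setNames(rep(list(character(0)), 4), bins_order),
                summary = data.frame(bin = bins_order, n_reads = 0L,
                                     n_bases = 0L, stringsAsFactors = FALSE)))
  }
  hits <- .count_hapmer_hits_cpp(toupper(reads), hapA$kmers, hapB$kmers,
                                 as.integer(k))
  too_short <- hits$length < min_len
  countA <- ifelse(too_short, 0L, hits$countA)
  countB <- ifelse(too_short, 0L, hits$countB)
  label <- ifelse(too_short, "too_short",
           ifelse(countA > countB, labA,
           ifelse(countB > countA, labB, "unclassified")))
  assignments <- data.frame(read_id = ids, label = label,
                            countA = countA, countB = countB,
                            length = hits$length, stringsAsFactors = FALSE)
  bins <- lapply(setNames(bins_order, bins_order),
                 function(b) ids[label == b])
  summary <- data.frame(
    bin = bins_order,
    n_reads = vapply(bins_order, function(b) sum(label == b), integer(1)),
    n_bases = vapply(bins_order,
                     function(b) sum(hits$length[label == b]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(assignments = assignments, bins = bins, summary = summary)
}

#' Simulate a trio read set with known parental origin
#'
#' Generates two divergent parental haplotypes (substitution divergence
#' `trio_divergence`), samples child reads from each with lognormal lengths
#' and applies a per-base substitution error, keeping the true origin label
#' of every read.
#'
#' @param config a [scenario_config()]
#' @return list with `reads` (named character vector), `truth_labels`
#'   (character vector, `"parentA"`/`"parentB"`), `parentA`, `parentB`
#'   (haplotype sequences)
#' @export
simulate_trio_reads <- function(config) {
  validate_scenario_config(config)
  set.seed(component_seed(config, "trio"))
  bases <- c("A", "C", "G", "T")
  L <- config$trio_hap_bp
  pa <- sample(bases, L, replace = TRUE)
  pb <- pa
  mut <- which(runif(L) < config$trio_divergence)
  if (length(mut)) {
    shift <- sample(1:3, length(mut), replace = TRUE)
    pb[mut] <- bases[((match(pa[mut], bases) - 1L + shift) %% 4L) + 1L]
  }
  haps <- list(parentA = pa, parentB = pb)
  n <- config$trio_n_reads
  origin <- sample(c("parentA", "parentB"), n, replace = TRUE)
  len <- pmin(pmax(round(rlnorm(n, config$trio_read_meanlog,
                                config$trio_read_sdlog)), 100L), L)
  start <- vapply(len, function(l) sample.int(L - l + 1L, 1L), integer(1))
  reads <- character(n)
  for (i in seq_len(n)) {
    r <- haps[[origin[i]]][start[i]:(start[i] + len[i] - 1L)]
    err <- which(runif(len[i]) < config$trio_error)
    if (length(err)) {
      shift <- sample(1:3, length(err), replace = TRUE)
      r[err] <- bases[((match(r[err], bases) - 1L + shift) %% 4L) + 1L]
    }
    reads[i] <- paste(r, collapse = "")
  }
  names(reads) <- sprintf("read%04d", seq_len(n))
  list(reads = reads, truth_labels = origin,
       parentA = paste(pa, collapse = ""), parentB = paste(pb, collapse = ""))
}
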