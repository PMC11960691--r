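#' Construct a gene model
#'
#' Exons are kept 0-based half-open internally (GFF3 I/O converts to 1-based
#' inclusive), sorted and non-overlapping.
#'
#' @param model_id identifier
#' @param source evidence class, `"homology"` or `"abinitio"`
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param exons data frame with `start`, `end` (0-based half-open)
#' @return an object of class `gene_model`
#' @export
gene_model <- function(model_id, source = c("homology", "abinitio"),
                       chrom, strand, exons) {
  source <- match.arg(source)
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) stop("empty exon in ", model_id)
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("overlapping exons in ", model_id)
  structure(list(model_id = model_id, source = source, chrom = chrom,
                 strand = strand, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s, %s%s): %d exon(s), [%d, %d)\n",
              x$model_id, x$source, x$chrom, x$strand, nrow(x$exons),
              min(x$exons$start), max(x$exons$end)))
  invisible(x)
}

# introns as a data frame of 0-based half-open intervals
model_introns <- function(model) {
  e <- model$exons
  n <- nrow(e)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = e$end[-n], end = e$start[-1])
}

# canonical signature for equality tests
model_signature <- function(model) {
  paste(model$chrom, model$strand,
        paste(model$exons$start, model$exons$end, sep = "-", collapse = ","))
}

#' Transcript support of a gene model
#'
#' Per-exon covered-base fraction against transcript coverage intervals and
#' per-intron junction match flags against an observed junction list. The
#' scalar score is `0.5 * mean(exon fractions) + 0.5 * fraction of matched
#' junctions`; single-exon models use the exon term alone.
#'
#' @param model a [gene_model()]
#' @param cover data frame of transcript coverage intervals (`chrom`,
#'   `start`, `end`; 0-based half-open)
#' @param junctions data frame of observed introns (`chrom`, `intron_start`,
#'   `intron_end`, `strand`)
#' @return list with `exon_fraction` (numeric vector), `junction_match`
#'   (logical vector) and `score`
#' @export
compute_support <- function(model, cover, junctions) {
  cov <- cover[cover$chrom == model$chrom, , drop = FALSE]
  cov_ir <- IRanges::reduce(IRanges::IRanges(cov$start + 1L, cov$end))
  ex_ir <- IRanges::IRanges(model$exons$start + 1L, model$exons$end)
  ov <- IRanges::intersect(ex_ir, cov_ir)
  hits <- IRanges::findOverlaps(ex_ir, ov)
  covered <- numeric(length(ex_ir))
  if (length(hits)) {
    w <- IRanges::width(IRanges::pintersect(
      ex_ir[S4Vectors::queryHits(hits)], ov[S4Vectors::subjectHits(hits)]))
    covered <- as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
                                           levels = seq_along(ex_ir)),
                                 sum, default = 0))
    covered[is.na(covered)] <- 0
  }
  exon_fraction <- covered / IRanges::width(ex_ir)
  intr <- model_introns(model)
  if (nrow(intr)) {
    jx <- junctions[junctions$chrom == model$chrom &
                    junctions$strand == model$strand, , drop = FALSE]
    key <- paste(jx$intron_start, jx$intron_end)
    junction_match <- paste(intr$start, intr$end) %in% key
    score <- 0.5 * mean(exon_fraction) + 0.5 * mean(junction_match)
  } else {
    junction_match <- logical(0)
    score <- mean(exon_fraction)
  }
  list(exon_fraction = exon_fraction, junction_match = junction_match,
       score = score)
}

#' Cluster gene models by same-strand exonic overlap
#'
#' Connected components of the graph whose edges join models sharing at
#' least one exonic base on the same chromosome and strand.
#'
#' @param models list of [gene_model()] objects
#' @return integer vector of cluster ids, one per model
#' @export
cluster_models <- function(models) {
  n <- length(models)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  exon_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- models[[i]]$exons
    data.frame(i = i, chrom = models[[i]]$chrom,
               strand = models[[i]]$strand, start = e$start, end = e$end,
               stringsAsFactors = FALSE)
  }))
  for (grp in split(exon_df, paste(exon_df$chrom, exon_df$strand))) {
    ir <- IRanges::IRanges(grp$start + 1L, grp$end)
    ov <- IRanges::findOverlaps(ir, ir)
    qi <- grp$i[S4Vectors::queryHits(ov)]
    si <- grp$i[S4Vectors::subjectHits(ov)]
    for (e in which(qi != si)) {
      ra <- find(qi[e]); rb <- find(si[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Select the representative model of a cluster
#'
#' Highest support score wins; ties are broken by longer total exonic (CDS)
#' length, then by smaller start coordinate.
#'
#' @param cluster list of [gene_model()] objects in one cluster
#' @param scores numeric support scores, one per model
#' @return list with `kept` (the model), `kept_index`, `eliminated` (list)
#' @export
select_representative <- function(cluster, scores) {
  stopifnot(length(cluster) == length(scores))
  len <- vapply(cluster, function(m) sum(m$exons$end - m$exons$start),
                numeric(1))
  start <- vapply(cluster, function(m) min(m$exons$start), numeric(1))
  ord <- order(-scores, -len, start)
  best <- ord[1]
  list(kept = cluster[[best]], kept_index = best,
       eliminated = cluster[-best])
}

#' Rescue poorly supported terminal exons from eliminated models
#'
#' When a terminal (first or last) exon of the kept model has transcript
#' coverage below `tau`, eliminated models of the same cluster are screened
#' for a replacement: a donor qualifies when it shares every internal
#' junction of the kept model apart from the terminal exon's own bounding
#' junction, its bounding junction meets the kept structure at the same
#' inner boundary, and its terminal exon has strictly greater coverage. The
#' best such donor's terminal exon (and bounding junction) replaces the kept
#' one; at most one replacement per end. A replacement that would create
#' overlapping exons is rejected.
#'
#' @param kept the kept [gene_model()]
#' @param eliminated list of eliminated models from the same cluster
#' @param cover,junctions transcript evidence (see [compute_support()])
#' @param tau coverage threshold below which a terminal exon is "poorly
#'   supported" (default 0.5)
#' @return list with `model` (possibly modified), `rescued_left`,
#'   `rescued_right`, `log` (character)
#' @export
rescue_terminal_exons <- function(kept, eliminated, cover, junctions,
                                  tau = 0.5) {
  log <- character(0)
  if (nrow(kept$exons) < 2 || !length(eliminated))
    return(list(model = kept, rescued_left = FALSE, rescued_right = FALSE,
                log = log))
  eliminated <- Filter(function(m) m$strand == kept$strand &&
                         m$chrom == kept$chrom && nrow(m$exons) >= 2,
                       eliminated)
  prof_kept <- compute_support(kept, cover, junctions)
  kept_introns <- model_introns(kept)
  n_ex <- nrow(kept$exons)
  rescued <- c(left = FALSE, right = FALSE)

  try_side <- function(side) {
    term_i <- if (side == "left") 1L else n_ex
    bound_i <- if (side == "left") 1L else n_ex - 1L
    if (prof_kept$exon_fraction[term_i] >= tau) return(NULL)
    internal <- kept_introns[-bound_i, , drop = FALSE]
    inner_pos <- if (side == "left") kept_introns$end[bound_i]
                 else kept_introns$start[bound_i]
    best <- NULL; best_cov <- prof_kept$exon_fraction[term_i]
    for (don in eliminated) {
      din <- model_introns(don)
      key <- paste(din$start, din$end)
      if (!all(paste(internal$start, internal$end) %in% key)) next
      don_bound_i <- if (side == "left") 1L else nrow(din)
      don_inner <- if (side == "left") din$end[don_bound_i]
                   else din$start[don_bound_i]
      if (don_inner != inner_pos) next
      don_term_i <- if (side == "left") 1L else nrow(don$exons)
      don_cov <- compute_support(don, cover, junctions)$exon_fraction[don_term_i]
      if (don_cov > best_cov) {
        best <- don$exons[don_term_i, , drop = FALSE]
        best_cov <- don_cov
      }
    }
    best
  }

  for (side in c("left", "right")) {
    repl <- try_side(side)
    if (is.null(repl)) next
    new_exons <- kept$exons
    idx <- if (side == "left") 1L else n_ex
    new_exons[idx, ] <- repl
    ok <- tryCatch({
      gene_model(kept$model_id, kept$source, kept$chrom, kept$strand,
                 new_exons); TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      log <- c(log, sprintf("%s: %s-end replacement rejected (overlap)",
                            kept$model_id, side))
      next
    }
    kept <- gene_model(kept$model_id, kept$source, kept$chrom, kept$strand,
                       new_exons)
    rescued[[side]] <- TRUE
    log <- c(log, sprintf("%s: %s terminal exon replaced", kept$model_id,
                          side))
  }
  list(model = kept, rescued_left = rescued[["left"]],
       rescued_right = rescued[["right"]], log = log)
}

#' Recruit fully supported ab initio models
#'
#' An ab initio model is recruited iff it overlaps no homology model
#' (same-strand exonic overlap) and is fully supported: every exon covered at
#' fraction 1.0 and every junction matched.
#'
#' @param abinitio list of ab initio [gene_model()] objects
#' @param homology list of homology models (the clusters to avoid)
#' @param cover,junctions transcript evidence
#' @return list of recruited models
#' @export
recruit_abinitio <- function(abinitio, homology, cover, junctions) {
  if (!length(abinitio)) return(list())
  keep <- vapply(abinitio, function(m) {
    both <- c(homology, list(m))
    cl <- cluster_models(both)
    if (length(homology) && any(cl[seq_along(homology)] == cl[length(both)]))
      return(FALSE)
    p <- compute_support(m, cover, junctions)
    all(p$exon_fraction >= 1 - 1e-9) && all(p$junction_match)
  }, logical(1))
  abinitio[keep]
}

#' Merge gene evidence into a final annotation
#'
#' The full synthesis: cluster overlapping homology models, keep the best
#' transcript-supported model per cluster (ties to longer CDS, then smaller
#' start), rescue poorly supported terminal exons from the eliminated
#' models, and recruit ab initio models that are fully supported and
#' overlap no homology cluster.
#'
#' @param homology,abinitio lists of [gene_model()] objects
#' @param cover,junctions transcript evidence (see [compute_support()])
#' @param tau terminal-exon rescue threshold
#' @return an object of class `merged_annotation`: list with `models`
#'   (final list), `provenance` (character vector: `selected`,
#'   `terminal-rescued`, `recruited`), `clusters` (integer vector over the
#'   homology input), `log`
#' @export
merge_gene_evidence <- function(homology, abinitio = list(), cover,
                                junctions, tau = 0.5) {
  clusters <- cluster_models(homology)
  models <- list(); provenance <- character(0); log <- character(0)
  for (cl in sort(unique(clusters))) {
    members <- homology[clusters == cl]
    scores <- vapply(members, function(m)
      compute_support(m, cover, junctions)$score, numeric(1))
    sel <- select_representative(members, scores)
    res <- rescue_terminal_exons(sel$kept, sel$eliminated, cover, junctions,
                                 tau = tau)
    models[[length(models) + 1L]] <- res$model
    provenance <- c(provenance,
                    if (res$rescued_left || res$rescued_right)
                      "terminal-rescued" else "selected")
    log <- c(log, res$log)
  }
  rec <- recruit_abinitio(abinitio, homology, cover, junctions)
  models <- c(models, rec)
  provenance <- c(provenance, rep("recruited", length(rec)))
  structure(list(models = models, provenance = provenance,
                 clusters = clusters, log = log),
            class = "merged_annotation")
}

#' @export
print.merged_annotation <- function(x, ...) {
  cat(sprintf("merged_annotation: %d models (%d selected, %d rescued, %d recruited)\n",
              length(x$models), sum(x$provenance == "selected"),
              sum(x$provenance == "terminal-rescued"),
              sum(x$provenance == "recruited")))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits a `gene -> mRNA -> exon` hierarchy, 1-based inclusive coordinates,
#' evidence class in the source column and optional provenance in a `note`
#' attribute.
#'
#' @param models list of [gene_model()] objects
#' @param file path
#' @param provenance optional character vector parallel to `models`
#' @export
write_gff3_models <- function(models, file, provenance = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(models)) {
    m <- models[[i]]
    g0 <- min(m$exons$start) + 1L; g1 <- max(m$exons$end)
    note <- if (!is.null(provenance))
      paste0(";note=", provenance[i]) else ""
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                       m$chrom, m$source, g0, g1, m$strand, m$model_id,
                       note), con)
    writeLines(sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       m$chrom, m$source, g0, g1, m$strand, m$model_id,
                       m$model_id), con)
    for (e in seq_len(nrow(m$exons)))
      writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                         m$chrom, m$source, m$exons$start[e] + 1L,
                         m$exons$end[e], m$strand, m$model_id, e,
                         m$model_id), con)
  }
}

#' Read gene models from GFF3
#'
#' Parses the `gene -> mRNA -> exon` subset written by [write_gff3_models()]
#' (one mRNA per gene); the source column becomes the evidence class.
#'
#' @param file path
#' @return list of [gene_model()] objects; provenance notes, when present,
#'   are attached as the `provenance` attribute
#' @export
read_gff3_models <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    ifelse(lengths(regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"),
                                             attrs))) > 0,
           sub(paste0("^;?", key, "="), "", m), NA_character_)
  }
  type <- f[, 3]
  genes <- f[type == "gene", , drop = FALSE]
  exons <- f[type == "exon", , drop = FALSE]
  gene_ids <- vapply(genes[, 9], function(a)
    sub("^.*ID=([^;]*).*$", "\\1", a), character(1), USE.NAMES = FALSE)
  notes <- vapply(genes[, 9], function(a) {
    if (grepl("note=", a)) sub("^.*note=([^;]*).*$", "\\1", a)
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
  exon_parent <- sub("\\.t1$", "",
                     vapply(exons[, 9], function(a)
                       sub("^.*Parent=([^;]*).*$", "\\1", a), character(1),
                       USE.NAMES = FALSE))
  models <- lapply(seq_along(gene_ids), function(i) {
    id <- gene_ids[i]
    sel <- exon_parent == id
    gene_model(id,
               source = if (genes[i, 2] %in% c("homology", "abinitio"))
                 genes[i, 2] else "homology",
               chrom = genes[i, 1], strand = genes[i, 7],
               exons = data.frame(
                 start = as.integer(exons[sel, 4]) - 1L,
                 end = as.integer(exons[sel, 5])))
  })
  attr(models, "provenance") <- notes
  models
}
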