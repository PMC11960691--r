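#' Simulate gene models with evidence classes and transcript support
#'
#' Plants a set of true multi-exon gene models along the chromosome and
#' derives from them the three evidence inputs of the annotation synthesis:
#'
#' * homology models: one truth-equal model per gene, plus (for a configured
#'   fraction of genes) a best-scoring model whose terminal exon is extended
#'   into unsupported sequence and a lower-scoring donor model carrying the
#'   correct terminal exon -- the constellation that exercises terminal-exon
#'   rescue while keeping the planted truth exactly recoverable;
#' * ab initio models: truth-equal and fully supported for genes lacking
#'   homology evidence, plus unsupported intergenic decoys and fully
#'   supported duplicates overlapping homology clusters (which must not be
#'   recruited);
#' * transcript evidence: coverage intervals equal to the true exons and the
#'   true junction list.
#'
#' With `gene_corrupt_frac = 0` every homology gene is represented by its
#' truth model only.
#'
#' @param config a [scenario_config()]
#' @return list with `homology`, `abinitio` (lists of [gene_model()]),
#'   `cover`, `junctions` (data frames), `truth` (list of true models) and
#'   `chrom_length`
#' @export
simulate_gene_evidence <- function(config) {
  validate_scenario_config(config)
  set.seed(component_seed(config, "genes"))
  co <- scenario_coords(config)
  L <- co$chrom_length
  n <- config$n_genes
  chrom <- "Y"

  # non-overlapping gene loci with generous intergenic gaps
  truth <- list(); pos <- 5000
  for (g in seq_len(n)) {
    n_ex <- sample(3:8, 1)
    ex_len <- sample(80:300, n_ex, replace = TRUE)
    in_len <- sample(100:2000, n_ex - 1, replace = TRUE)
    starts <- pos + cumsum(c(0, ex_len[-n_ex] + in_len))
    exons <- data.frame(start = starts, end = starts + ex_len)
    truth[[g]] <- gene_model(sprintf("gene%03d", g), "homology", chrom,
                             sample(c("+", "-"), 1), exons)
    pos <- max(exons$end) + sample(3000:8000, 1)
    if (pos > L - 30000) { truth <- truth[seq_len(g)]; break }
  }
  n <- length(truth)

  cover <- do.call(rbind, lapply(truth, function(m)
    data.frame(chrom = chrom, start = m$exons$start, end = m$exons$end,
               stringsAsFactors = FALSE)))
  junctions <- do.call(rbind, lapply(truth, function(m) {
    intr <- model_introns(m)
    if (!nrow(intr)) return(NULL)
    data.frame(chrom = chrom, intron_start = intr$start,
               intron_end = intr$end, strand = m$strand,
               count = sample(5:50, nrow(intr), replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  ab_only <- runif(n) < config$gene_abinitio_frac
  corrupt <- !ab_only & runif(n) < config$gene_corrupt_frac &
    vapply(truth, function(m) nrow(m$exons) >= 3, logical(1))

  extend_exon <- function(m, which_end, factor) {
    e <- m$exons
    i <- if (which_end == "right") nrow(e) else 1L
    len <- e$end[i] - e$start[i]
    if (which_end == "right") e$end[i] <- e$end[i] + factor * len
    else e$start[i] <- max(0, e$start[i] - factor * len)
    e
  }

  homology <- list(); abinitio <- list()
  for (g in seq_len(n)) {
    m <- truth[[g]]
    if (ab_only[g]) {
      abinitio[[length(abinitio) + 1L]] <-
        gene_model(paste0(m$model_id, ".ab"), "abinitio", chrom, m$strand,
                   m$exons)
    } else if (corrupt[g]) {
      # winner: correct structure, last exon extended (coverage ~ 1/3)
      homology[[length(homology) + 1L]] <-
        gene_model(paste0(m$model_id, ".h1"), "homology", chrom, m$strand,
                   extend_exon(m, "right", 2))
      # donor: correct last exon, first exon extended further (loses)
      homology[[length(homology) + 1L]] <-
        gene_model(paste0(m$model_id, ".h2"), "homology", chrom, m$strand,
                   extend_exon(m, "left", 4))
    } else {
      homology[[length(homology) + 1L]] <-
        gene_model(paste0(m$model_id, ".h1"), "homology", chrom, m$strand,
                   m$exons)
      if (runif(1) < 0.5)   # an eliminated worse duplicate
        homology[[length(homology) + 1L]] <-
          gene_model(paste0(m$model_id, ".h2"), "homology", chrom,
                     m$strand, extend_exon(m, "right", 3))
      if (runif(1) < 0.3)   # fully supported duplicate: overlaps -> ignored
        abinitio[[length(abinitio) + 1L]] <-
          gene_model(paste0(m$model_id, ".abdup"), "abinitio", chrom,
                     m$strand, m$exons)
    }
  }
  # unsupported intergenic decoys
  for (d in seq_len(5)) {
    s <- L - 25000 + d * 4000
    abinitio[[length(abinitio) + 1L]] <-
      gene_model(sprintf("decoy%02d", d), "abinitio", chrom, "+",
                 data.frame(start = c(s, s + 500), end = c(s + 200, s + 700)))
  }
  list(homology = homology, abinitio = abinitio, cover = cover,
       junctions = junctions, truth = truth, chrom_length = L)
}
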