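#' Export filled alignment chains to PAF
#'
#' One PAF record per chain, with the base-level alignment in a `cg:Z:` tag
#' using extended CIGAR operations (`=`, `X`, `I`, `D`): `I` columns exist in
#' the query only (a gap in the target), `D` columns in the target only. All
#' coordinates follow PAF's native 0-based half-open convention; query
#' coordinates of minus-strand chains are on the forward frame of the query.
#'
#' @param chains list of filled `alignment_chain` objects
#' @param file output path
#' @param q_name,t_name sequence names
#' @param q_len,t_len sequence lengths (bp)
#' @export
write_paf <- function(chains, file, q_name = "X", t_name = "Y",
                      q_len, t_len) {
  ops_chr <- c("=", "X", "I", "D")
  lines <- vapply(chains, function(ch) {
    stopifnot(isTRUE(ch$filled))
    cig <- paste0(ch$lens, ops_chr[ch$ops], collapse = "")
    nmatch <- sum(ch$lens[ch$ops == 1L])
    alen <- sum(ch$lens)
    if (ch$strand == "-") {
      qs <- ch$q_len - ch$q_end
      qe <- ch$q_len - ch$q_start
    } else {
      qs <- ch$q_start; qe <- ch$q_end
    }
    paste(q_name, q_len, qs, qe, ch$strand, t_name, t_len,
          ch$t_start, ch$t_end, nmatch, alen, 255,
          paste0("cg:Z:", cig), sep = "\t")
  }, character(1))
  writeLines(lines, file)
}

#' Import PAF records as filled alignment chains
#'
#' Reads PAF with `cg:Z:` extended-CIGAR tags (as written by [write_paf()] or
#' by an external aligner run with `--eqx`) and reconstructs the run-length
#' encoded column classes, so that [window_divergence()] on the result
#' reproduces the original records exactly.
#'
#' @param file PAF path
#' @return list of filled `alignment_chain` objects
#' @export
read_paf <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", f, value = TRUE)[1])
    if (is.na(cg)) stop("PAF record without cg:Z: tag")
    toks <- regmatches(cg, gregexpr("[0-9]+[=XIDM]", cg))[[1]]
    if (!length(toks) || sum(nchar(toks)) != nchar(cg))
      stop("unparseable cigar: ", cg)
    op_chr <- substring(toks, nchar(toks))
    if (any(op_chr == "M"))
      stop("cg tag uses ambiguous 'M' operations; an extended (=/X) cigar ",
           "is required to recover column classes")
    lens <- as.integer(substring(toks, 1, nchar(toks) - 1L))
    ops <- match(op_chr, c("=", "X", "I", "D"))
    strand <- f[5]
    q_len <- as.integer(f[2])
    qs <- as.integer(f[3]); qe <- as.integer(f[4])
    if (strand == "-") { q0 <- q_len - qe; q1 <- q_len - qs }
    else { q0 <- qs; q1 <- qe }
    structure(list(
      anchors = data.frame(t_start = as.integer(f[8]), q_start = qs,
                           length = 0L, strand = strand,
                           stringsAsFactors = FALSE),
      score = as.numeric(f[10]), strand = strand, q_len = q_len,
      filled = TRUE, ops = ops, lens = lens,
      t_start = as.integer(f[8]), t_end = as.integer(f[9]),
      q_start = q0, q_end = q1,
      unaligned = data.frame(t_start = integer(0), t_end = integer(0),
                             q_start = integer(0), q_end = integer(0))),
      class = "alignment_chain")
  })
}
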