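# shared fixture builders; everything is generated in code under fixed seeds

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# substitutions + occasional short indels, returning the mutated sequence
mutate_seq <- function(x, sub = 0.02, indel = 0.001, max_len = 5) {
  b <- c("A", "C", "G", "T")
  v <- strsplit(x, "")[[1]]
  n <- length(v)
  sp <- which(runif(n) < sub)
  if (length(sp))
    v[sp] <- b[((match(v[sp], b) - 1 + sample(1:3, length(sp), TRUE)) %% 4) + 1]
  out <- character(0)
  i <- 1
  while (i <= n) {
    r <- runif(1)
    if (r < indel / 2) { i <- i + sample(seq_len(max_len), 1); next }
    if (r < indel) out <- c(out, sample(b, sample(seq_len(max_len), 1), TRUE))
    out <- c(out, v[i])
    i <- i + 1
  }
  paste(out, collapse = "")
}

# hand-made filled chain from explicit column runs
make_filled_chain <- function(ops, lens, t_start = 0L, q_start = 0L,
                              strand = "+", q_len = 10000L) {
  tcons <- ops %in% c(1L, 2L, 4L)
  qcons <- ops %in% c(1L, 2L, 3L)
  structure(list(anchors = data.frame(t_start = t_start, q_start = q_start,
                                      length = 0L, strand = strand),
                 score = sum(lens[ops == 1L]), strand = strand,
                 q_len = q_len, filled = TRUE,
                 ops = as.integer(ops), lens = as.integer(lens),
                 t_start = as.integer(t_start),
                 t_end = as.integer(t_start + sum(lens[tcons])),
                 q_start = as.integer(q_start),
                 q_end = as.integer(q_start + sum(lens[qcons])),
                 unaligned = data.frame(t_start = integer(0),
                                        t_end = integer(0),
                                        q_start = integer(0),
                                        q_end = integer(0))),
            class = "alignment_chain")
}

# bare-hands divergence of two sequences via Biostrings full-matrix global
# alignment with the package's scoring scheme
oracle_divergence <- function(x, y) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y),
    substitutionMatrix = mat, gapOpening = 2, gapExtension = 1,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  mismatch <- sum(p != "-" & s != "-" & p != s)
  gapc <- sum(p == "-" | s == "-")
  100 * (mismatch + gapc) / length(p)
}

# exhaustive best chain score over all anchor subsets (oracle for chaining)
brute_force_chain_score <- function(anchors, gap_open = 2, gap_extend = 1) {
  n <- nrow(anchors)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(sel)) next
    a <- anchors[sel, , drop = FALSE]
    a <- a[order(a$t_start, a$q_start), , drop = FALSE]
    ok <- TRUE
    sc <- a$length[1]
    if (nrow(a) > 1) {
      for (i in 2:nrow(a)) {
        dt <- a$t_start[i] - (a$t_start[i - 1] + a$length[i - 1])
        dq <- a$q_start[i] - (a$q_start[i - 1] + a$length[i - 1])
        if (dt < 0 || dq < 0) { ok <- FALSE; break }
        g <- abs(dt - dq)
        sc <- sc + a$length[i] - if (g == 0) 0 else gap_open + gap_extend * g
      }
    }
    if (ok) best <- max(best, sc)
  }
  best
}

sig_of_models <- function(models)
  sort(vapply(models, msyscan:::model_signature, character(1)))
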