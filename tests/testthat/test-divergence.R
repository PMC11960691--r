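test_that("identical sequences seed one merged anchor covering everything", {
  set.seed(70)   # fixture free of duplicated 15-mers (uniqueness requirement)
  s <- random_seq(10000)
  a <- seed_anchors(s, s, k = 15)
  plus <- a[a$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$t_start, 0)
  expect_equal(plus$q_start, 0)
  expect_equal(plus$length, 10000)
})

test_that("reverse-complementing the query flips anchors to the minus strand", {
  set.seed(73)
  x <- random_seq(3000)
  y <- mutate_seq(x, sub = 0.01, indel = 0)
  fwd <- seed_anchors(x, y, k = 15)
  rev <- seed_anchors(msyscan:::revcomp(x), y, k = 15)
  f <- fwd[fwd$strand == "+", c("t_start", "q_start", "length")]
  r <- rev[rev$strand == "-", c("t_start", "q_start", "length")]
  # minus-strand q_start is on the forward frame of the query as given,
  # so the original coordinate is recovered by flipping
  r$q_start <- nchar(x) - (r$q_start + r$length)
  rownames(f) <- rownames(r) <- NULL
  expect_equal(f, r)
})

test_that("planted unique 25-mers are recovered as anchors at their positions", {
  set.seed(79)
  probes <- replicate(3, random_seq(25))
  t_pos <- c(500, 2100, 3800)
  q_pos <- c(300, 1500, 3100)
  # low-complexity backgrounds share no 15-mer with the probes
  bg_t <- paste(rep("ACACACAC", 600), collapse = "")
  bg_q <- paste(rep("TGTGTGTG", 500), collapse = "")
  y <- bg_t; x <- bg_q
  for (i in 1:3) {
    substr(y, t_pos[i] + 1, t_pos[i] + 25) <- probes[i]
    substr(x, q_pos[i] + 1, q_pos[i] + 25) <- probes[i]
  }
  a <- seed_anchors(x, y, k = 15)
  a <- a[a$strand == "+", ]
  expect_equal(nrow(a), 3)
  expect_equal(a$t_start, t_pos)
  expect_equal(a$q_start, q_pos)
})

test_that("co-linear anchors chain together; off-diagonal anchors are excluded", {
  a <- data.frame(t_start = c(0, 30), q_start = c(0, 30),
                  length = c(20, 20), strand = "+")
  ch <- chain_anchors(a, min_score = 1)
  expect_equal(nrow(ch[[1]]$anchors), 2)
  b <- data.frame(t_start = c(0, 30, 25), q_start = c(0, 30, 100),
                  length = c(20, 20, 20), strand = "+")
  ch2 <- chain_anchors(b, min_score = 1)
  best <- ch2[[1]]
  expect_equal(best$score, brute_force_chain_score(b))
  expect_equal(sort(best$anchors$t_start), c(0, 30))
})

test_that("chain score equals the exhaustive-subset optimum for small sets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:12, 1)
    a <- data.frame(t_start = sort(sample(0:400, n)),
                    q_start = sort(sample(0:400, n)) +
                      sample(-30:30, n, replace = TRUE),
                    length = sample(10:25, n, replace = TRUE),
                    strand = "+")
    ch <- chain_anchors(a, min_score = 1)
    expect_equal(max(vapply(ch, `[[`, numeric(1), "score")),
                 brute_force_chain_score(a),
                 info = paste("seed", seed))
  }
})

test_that("gap filling reproduces hand-computed alignments", {
  flank_l <- random_seq(30); flank_r <- random_seq(30)
  run_fill <- function(gx, gy) {
    x <- paste0(flank_l, gx, flank_r)
    y <- paste0(flank_l, gy, flank_r)
    ch <- structure(list(
      anchors = data.frame(
        t_start = c(0L, 30L + nchar(gy)), q_start = c(0L, 30L + nchar(gx)),
        length = c(30L, 30L), strand = "+"),
      score = 60, strand = "+", q_len = nchar(x), filled = FALSE),
      class = "alignment_chain")
    fill_chain_gaps(ch, x, y)
  }
  # identical gap: 4 extra match columns
  f1 <- run_fill("ACGT", "ACGT")
  expect_equal(unname(column_counts(f1)),
               c(64L, 0L, 0L, 0L))
  # hand DP: ACGT vs AGGT -> 3 matches + 1 mismatch (score 2 beats gaps)
  f2 <- run_fill("ACGT", "AGGT")
  expect_equal(unname(column_counts(f2)), c(63L, 1L, 0L, 0L))
  # query ACGT vs target AC: two columns consume query only (gap in target)
  f3 <- run_fill("ACGT", "AC")
  cc <- column_counts(f3)
  expect_equal(unname(cc[c("mismatch", "t_gap", "q_gap")]), c(0L, 2L, 0L))
  expect_equal(unname(cc["match"]), 62L)
})

test_that("column conservation holds per chain and over windows", {
  set.seed(83)
  x <- random_seq(4000)
  y <- mutate_seq(x, sub = 0.03, indel = 0.002)
  chains <- align_xy(x, y)
  expect_equal(length(chains), 1)
  cc <- column_counts(chains[[1]])
  expect_equal(sum(chains[[1]]$lens), sum(cc))
  w <- window_divergence(chains, nchar(y), window_bp = 500)
  expect_equal(sum(w$aligned_cols), sum(cc))
  expect_equal(sum(w$n_snp), unname(cc["mismatch"]))
  expect_equal(sum(w$n_indel_cols), unname(cc["t_gap"] + cc["q_gap"]))
})

test_that("netting keeps disjoint chains and trims overlaps by score", {
  c1 <- make_filled_chain(ops = c(1), lens = c(1000), t_start = 0)
  c1$score <- 500
  c2 <- make_filled_chain(ops = c(1), lens = c(1000), t_start = 2000)
  c2$score <- 400
  out <- net_chains(list(c1, c2))
  expect_length(out, 2)
  # a lower-scoring chain overlapping by 200 bp is trimmed exactly there
  c3 <- make_filled_chain(ops = c(1), lens = c(1000), t_start = 800)
  c3$score <- 300
  out2 <- net_chains(list(c1, c3))
  expect_length(out2, 2)
  trimmed <- out2[[which(vapply(out2, `[[`, numeric(1), "score") == 300)]]
  expect_equal(trimmed$t_start, 1000L)
  expect_equal(trimmed$t_end, 1800L)
  expect_equal(sum(trimmed$lens), 800L)
  # single chain is returned unchanged
  out3 <- net_chains(list(c1))
  expect_identical(out3[[1]]$ops, c1$ops)
})

test_that("window divergence matches hand counts and flags poor coverage", {
  # one 100-column window: 94 match, 4 mismatch, 2 gap -> exactly 6%
  ch <- make_filled_chain(ops = c(1, 2, 1, 3, 1), lens = c(50, 4, 24, 2, 20),
                          t_start = 0)
  w <- window_divergence(ch, chrom_length = 100, window_bp = 100)
  expect_equal(w$aligned_cols, 100)
  expect_equal(w$n_snp, 4)
  expect_equal(w$n_indel_cols, 2)
  expect_identical(w$divergence_pct, 6)
  # a perfectly identical alignment has all-zero windows
  ch0 <- make_filled_chain(ops = 1, lens = 5000)
  w0 <- window_divergence(ch0, 5000, window_bp = 1000)
  expect_true(all(w0$divergence_pct == 0))
  # windows under 25% aligned-target coverage are flagged low-confidence
  ch1 <- make_filled_chain(ops = 1, lens = 300, t_start = 0)
  w1 <- window_divergence(ch1, 2000, window_bp = 1000)
  expect_false(w1$low_confidence[1])   # covered 0.30
  expect_true(w1$low_confidence[2])    # covered 0
})

test_that("indel event mode counts gap runs instead of gap columns", {
  ch <- make_filled_chain(ops = c(1, 4, 1, 4, 1), lens = c(20, 5, 20, 3, 20))
  wc <- window_divergence(ch, 100, window_bp = 100, indel_mode = "columns")
  we <- window_divergence(ch, 100, window_bp = 100, indel_mode = "events")
  expect_equal(wc$n_indel_cols, 8)
  expect_equal(we$n_indel_cols, 2)
})

test_that("boundary detection finds the step and flags flat series", {
  w <- data.frame(t_chrom = "Y", t_start = (0:6) * 100,
                  t_end = (1:7) * 100, aligned_cols = 100,
                  n_snp = 0, n_indel_cols = 0,
                  divergence_pct = c(1, 1, 1, 1, 6, 6, 6),
                  covered_fraction = 1, low_confidence = FALSE)
  b <- detect_boundary(w, min_windows_per_side = 1)
  expect_equal(b$changepoint_bp, 400)
  expect_equal(b$mean_before, 1)
  expect_equal(b$mean_after, 6)
  expect_false(b$no_transition)
  # constant series: fold 1, rightmost tie, flagged
  w$divergence_pct <- rep(2, 7)
  b0 <- detect_boundary(w, min_windows_per_side = 1)
  expect_true(b0$no_transition)
  expect_equal(b0$fold, 1)
  expect_equal(b0$changepoint_bp, 600)
  # too few windows errors
  expect_error(detect_boundary(w[1:6, ], min_windows_per_side = 5),
               "windows")
})

test_that("seed-chain-fill divergence matches the full-matrix oracle", {
  for (seed in 1:10) {
    set.seed(900 + seed)
    n <- sample(500:2000, 1)
    x <- random_seq(n)
    y <- mutate_seq(x, sub = runif(1, 0.005, 0.04),
                    indel = runif(1, 0, 0.003))
    chains <- align_xy(x, y)
    w <- window_divergence(chains, nchar(y), window_bp = nchar(y))
    expect_lt(abs(w$divergence_pct[1] - oracle_divergence(x, y)), 0.1,
              label = paste("pair", seed))
  }
})

test_that("PAF round trip reproduces the window records exactly", {
  set.seed(89)
  x <- random_seq(6000)
  y <- mutate_seq(x, sub = 0.02, indel = 0.001)
  chains <- align_xy(x, y)
  w1 <- window_divergence(chains, nchar(y), window_bp = 1000)
  paf <- tempfile(fileext = ".paf")
  write_paf(chains, paf, q_len = nchar(x), t_len = nchar(y))
  back <- read_paf(paf)
  w2 <- window_divergence(back, nchar(y), window_bp = 1000)
  expect_equal(w1, w2)
  unlink(paf)
})
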