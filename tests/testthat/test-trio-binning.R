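test_that("hap-mer sets are the private canonical k-mers of each parent", {
  set.seed(41)
  shared <- random_seq(500)
  privA <- random_seq(130)
  privB <- random_seq(110)
  hs <- build_hapmer_sets(paste0(shared, privA), paste0(shared, privB),
                          k = 15)
  # identical parents give empty sets
  hs0 <- build_hapmer_sets(shared, shared, k = 15)
  expect_length(hs0[[1]]$kmers, 0)
  expect_length(hs0[[2]]$kmers, 0)
  # private sets are disjoint and non-empty
  expect_gt(length(hs[[1]]$kmers), 0)
  expect_gt(length(hs[[2]]$kmers), 0)
  expect_length(intersect(hs[[1]]$kmers, hs[[2]]$kmers), 0)
})

test_that("private k-mer counts follow set arithmetic on a built fixture", {
  set.seed(43)
  # two parents that differ by a single embedded block: the builder must
  # report exactly the k-mers overlapping the block, computed independently
  k <- 15
  left <- random_seq(200); right <- random_seq(200)
  blockA <- random_seq(40); blockB <- random_seq(40)
  pA <- paste0(left, blockA, right)
  pB <- paste0(left, blockB, right)
  all_canon <- function(s) {
    v <- substring(s, seq_len(nchar(s) - k + 1), seq_len(nchar(s) - k + 1) + k - 1)
    rc <- vapply(v, msyscan:::revcomp, character(1), USE.NAMES = FALSE)
    unique(pmin(v, rc))
  }
  expA <- setdiff(all_canon(pA), all_canon(pB))
  expB <- setdiff(all_canon(pB), all_canon(pA))
  hs <- build_hapmer_sets(pA, pB, k = k)
  expect_setequal(hs[[1]]$kmers, expA)
  expect_setequal(hs[[2]]$kmers, expB)
})

test_that("k must be odd and in range; mismatched k is rejected", {
  expect_error(build_hapmer_sets("ACGT", "ACGT", k = 16), "odd")
  expect_error(build_hapmer_sets("ACGT", "ACGT", k = 13), "15")
  set.seed(47)
  h1 <- build_hapmer_sets(random_seq(100), random_seq(100), k = 15)
  h2 <- build_hapmer_sets(random_seq(100), random_seq(100), k = 17)
  expect_error(bin_readset("ACGT", h1[[1]], h2[[2]]), "disagree")
})

test_that("majority rule, tie rule and length gate behave as specified", {
  set.seed(53)
  pA <- random_seq(3000); pB <- mutate_seq(pA, sub = 0.05, indel = 0)
  hs <- build_hapmer_sets(pA, pB, k = 21)
  readA <- substr(pA, 1001, 2500)
  res <- classify_read(readA, hs[[1]], hs[[2]], min_len = 1000)
  expect_equal(res$label, "parentA")
  expect_gt(res$countA, res$countB)
  # a read from neither parent: 0-0 tie is unclassified
  res0 <- classify_read(random_seq(1500), hs[[1]], hs[[2]], min_len = 1000)
  expect_equal(res0$label, "unclassified")
  # too-short reads are gated with zeroed counts
  short <- classify_read(substr(pA, 1, 400), hs[[1]], hs[[2]], min_len = 1000)
  expect_equal(short$label, "too_short")
  expect_equal(short$countA + short$countB, 0)
})

test_that("binning partitions reads, conserves bases and is label-symmetric", {
  cfg <- scenario_config(trio_hap_bp = 20000, trio_n_reads = 120, seed = 3)
  trio <- simulate_trio_reads(cfg)
  hs <- build_hapmer_sets(trio$parentA, trio$parentB, k = 21)
  bins <- bin_readset(trio$reads, hs[[1]], hs[[2]], min_len = 1000)
  expect_equal(sum(bins$summary$n_reads), length(trio$reads))
  expect_equal(sum(bins$summary$n_bases), sum(nchar(trio$reads)))
  expect_equal(sort(unlist(bins$bins, use.names = FALSE)),
               sort(names(trio$reads)))
  # swapping parents swaps the two parent bins exactly
  swapped <- bin_readset(trio$reads, hs[[2]], hs[[1]], min_len = 1000)
  expect_identical(bins$bins$parentA, swapped$bins$parentA)
  expect_identical(bins$bins$parentB, swapped$bins$parentB)
  expect_identical(bins$bins$unclassified, swapped$bins$unclassified)
})

test_that("adding parentA-unique k-mers never moves reads toward parentB", {
  set.seed(59)
  pA <- random_seq(5000); pB <- mutate_seq(pA, sub = 0.03, indel = 0)
  hs <- build_hapmer_sets(pA, pB, k = 21)
  reads <- vapply(1:20, function(i) {
    s <- sample(4000, 1); substr(if (i %% 2) pA else pB, s, s + 900)
  }, character(1))
  names(reads) <- paste0("r", 1:20)
  base <- bin_readset(reads, hs[[1]], hs[[2]], min_len = 500)
  extra <- hs[[1]]
  extra$kmers <- union(extra$kmers,
                       build_hapmer_sets(random_seq(300), pB,
                                         k = 21)[[1]]$kmers)
  more <- bin_readset(reads, extra, hs[[2]], min_len = 500)
  moved_to_B <- base$assignments$label == "parentA" &
    more$assignments$label == "parentB"
  expect_false(any(moved_to_B))
  expect_true(all(more$assignments$countA >= base$assignments$countA))
})

test_that("empty input yields four empty bins", {
  set.seed(61)
  hs <- build_hapmer_sets(random_seq(100), random_seq(100), k = 15)
  bins <- bin_readset(character(0), hs[[1]], hs[[2]])
  expect_equal(sum(bins$summary$n_reads), 0)
  expect_length(unlist(bins$bins), 0)
})

test_that("simulated trio binning misassigns at most 1% of reads", {
  cfg <- scenario_config(seed = 2)   # divergence 2%, error 1%, 1000 reads
  trio <- simulate_trio_reads(cfg)
  hs <- build_hapmer_sets(trio$parentA, trio$parentB, k = 21)
  bins <- bin_readset(trio$reads, hs[[1]], hs[[2]], min_len = 1000)
  lab <- bins$assignments$label
  decided <- lab %in% c("parentA", "parentB")
  mis <- mean(lab[decided] != trio$truth_labels[decided])
  expect_lte(mis, 0.01)
  expect_gt(mean(decided), 0.9)
})
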