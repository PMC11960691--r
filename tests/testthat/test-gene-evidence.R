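mk <- function(id, exons, strand = "+", source = "homology", chrom = "Y")
  gene_model(id, source, chrom, strand,
             data.frame(start = exons[, 1], end = exons[, 2]))

test_that("support score combines exon coverage and junction matches", {
  m <- mk("g1", rbind(c(100, 200), c(300, 400)))
  cover_full <- data.frame(chrom = "Y", start = c(100, 300),
                           end = c(200, 400))
  jx <- data.frame(chrom = "Y", intron_start = 200, intron_end = 300,
                   strand = "+")
  s_full <- compute_support(m, cover_full, jx)
  expect_equal(s_full$score, 1.0)
  # 2 x 100 bp exons with 150 bp covered and the junction matched: 0.875
  cover_part <- data.frame(chrom = "Y", start = c(100, 300),
                           end = c(200, 350))
  s_part <- compute_support(m, cover_part, jx)
  expect_equal(s_part$exon_fraction, c(1.0, 0.5))
  expect_equal(s_part$score, 0.5 * 0.75 + 0.5 * 1.0)
  # no transcript data at all: score 0
  none <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  s0 <- compute_support(m, none, jx[0, ])
  expect_equal(s0$score, 0)
  # single-exon model uses the exon term only
  s1 <- compute_support(mk("g2", rbind(c(500, 600))), cover_full, jx)
  expect_equal(s1$score, 0)
})

test_that("clustering joins same-strand exonic overlap transitively", {
  a <- mk("a", rbind(c(0, 100)))
  b <- mk("b", rbind(c(99, 200)))          # shares 1 bp with a
  c_ <- mk("c", rbind(c(150, 300)))        # overlaps b, not a
  d <- mk("d", rbind(c(0, 100)), strand = "-")
  cl <- cluster_models(list(a, b, c_, d))
  expect_equal(cl[1], cl[2])
  expect_equal(cl[2], cl[3])               # transitive closure
  expect_false(cl[4] == cl[1])             # strand rule
  # intron-only overlap does not join
  e <- mk("e", rbind(c(0, 50), c(500, 600)))
  f <- mk("f", rbind(c(100, 200)))         # inside e's intron
  expect_false(cluster_models(list(e, f))[1] ==
               cluster_models(list(e, f))[2])
})

test_that("representative selection uses score, CDS length, then start", {
  m1 <- mk("m1", rbind(c(0, 900)))
  m2 <- mk("m2", rbind(c(0, 600)))
  sel <- select_representative(list(m1, m2), c(0.9, 0.4))
  expect_equal(sel$kept$model_id, "m1")
  sel_tie <- select_representative(list(m2, m1), c(0.8, 0.8))
  expect_equal(sel_tie$kept$model_id, "m1")  # longer CDS wins the tie
  singleton <- select_representative(list(m2), 0.5)
  expect_equal(singleton$kept$model_id, "m2")
  expect_length(singleton$eliminated, 0)
})

test_that("terminal-exon rescue fires exactly under its conditions", {
  truth_ex <- rbind(c(100, 200), c(300, 400), c(500, 600))
  cover <- data.frame(chrom = "Y", start = truth_ex[, 1],
                      end = truth_ex[, 2])
  jx <- data.frame(chrom = "Y", intron_start = c(200, 400),
                   intron_end = c(300, 500), strand = "+")
  kept <- mk("kept", rbind(c(100, 200), c(300, 400), c(500, 900)))
  donor <- mk("donor", truth_ex)
  res <- rescue_terminal_exons(kept, list(donor), cover, jx)
  expect_true(res$rescued_right)
  expect_false(res$rescued_left)
  expect_equal(res$model$exons$end[3], 600)
  # a well-supported terminal exon (>= tau) is left alone
  ok <- mk("ok", truth_ex)
  res2 <- rescue_terminal_exons(ok, list(donor), cover, jx)
  expect_false(res2$rescued_left || res2$rescued_right)
  # a donor with an incompatible internal junction is ignored
  bad_donor <- mk("bad", rbind(c(100, 200), c(310, 400), c(500, 600)))
  res3 <- rescue_terminal_exons(kept, list(bad_donor), cover, jx)
  expect_false(res3$rescued_right)
})

test_that("ab initio recruitment is strict and overlap-aware", {
  hom <- list(mk("h1", rbind(c(1000, 1200), c(1400, 1600))))
  cover <- data.frame(chrom = "Y",
                      start = c(1000, 1400, 5000, 5400, 7000, 7400),
                      end = c(1200, 1600, 5200, 5600, 7200, 7590))
  jx <- data.frame(chrom = "Y", intron_start = c(1200, 5200, 7200),
                   intron_end = c(1400, 5400, 7400), strand = "+")
  free_full <- mk("a1", rbind(c(5000, 5200), c(5400, 5600)),
                  source = "abinitio")
  almost <- mk("a2", rbind(c(7000, 7200), c(7400, 7600)),
               source = "abinitio")    # last exon covered 190/200
  overlapping <- mk("a3", rbind(c(1000, 1200), c(1400, 1600)),
                    source = "abinitio")
  rec <- recruit_abinitio(list(free_full, almost, overlapping), hom,
                          cover, jx)
  expect_equal(vapply(rec, `[[`, character(1), "model_id"), "a1")
})

test_that("the merge is idempotent and conserves counts", {
  cfg <- scenario_config(seed = 37)
  ge <- simulate_gene_evidence(cfg)
  mg <- merge_gene_evidence(ge$homology, ge$abinitio, ge$cover, ge$junctions)
  n_clusters <- length(unique(mg$clusters))
  expect_equal(sum(mg$provenance != "recruited"), n_clusters)
  expect_equal(length(mg$models),
               n_clusters + sum(mg$provenance == "recruited"))
  again <- merge_gene_evidence(mg$models[mg$provenance != "recruited"],
                               list(), ge$cover, ge$junctions)
  expect_identical(sig_of_models(again$models),
                   sig_of_models(mg$models[mg$provenance != "recruited"]))
})

test_that("planted truth is recovered exactly across seeds", {
  for (seed in 1:5) {
    cfg <- scenario_config(seed = seed)
    ge <- simulate_gene_evidence(cfg)
    mg <- merge_gene_evidence(ge$homology, ge$abinitio, ge$cover,
                              ge$junctions)
    expect_identical(sig_of_models(mg$models), sig_of_models(ge$truth),
                     info = paste("seed", seed))
  }
  # with no corruption the homology set already contains truth only
  cfg0 <- scenario_config(gene_corrupt_frac = 0, seed = 41)
  ge0 <- simulate_gene_evidence(cfg0)
  mg0 <- merge_gene_evidence(ge0$homology, ge0$abinitio, ge0$cover,
                             ge0$junctions)
  expect_identical(sig_of_models(mg0$models), sig_of_models(ge0$truth))
})

test_that("GFF3 round trip preserves models and provenance", {
  cfg <- scenario_config(seed = 43)
  ge <- simulate_gene_evidence(cfg)
  mg <- merge_gene_evidence(ge$homology, ge$abinitio, ge$cover, ge$junctions)
  f <- tempfile(fileext = ".gff3")
  write_gff3_models(mg$models, f, provenance = mg$provenance)
  back <- read_gff3_models(f)
  expect_identical(sig_of_models(back), sig_of_models(mg$models))
  expect_identical(sort(unique(attr(back, "provenance"))),
                   sort(unique(mg$provenance)))
  unlink(f)
})
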