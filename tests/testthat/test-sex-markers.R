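test_that("catalog collapses identical reads and merges near-identical tags", {
  t1 <- strrep("ACGT", 20)
  t2 <- t1; substr(t2, 5, 5) <- "T"          # 1 mismatch: merged
  t3 <- t1
  substr(t3, 1, 1) <- "T"; substr(t3, 2, 2) <- "G"; substr(t3, 3, 3) <- "T"
  # t3 differs from t1 at 3 sites (and from t2 at 4): separate tag
  reads <- list(ind1 = c(t1, t1, t1), ind2 = c(t2, t2), ind3 = c(t3))
  cat <- build_tag_catalog(reads, sex = c("M", "M", "F"), max_mismatch = 2)
  expect_equal(nrow(cat$tags), 2)
  merged_row <- which(cat$tags$sequence == t1)
  expect_equal(unname(cat$depth[merged_row, ]), c(3L, 2L, 0L))
  # empty individual contributes a zero column and changes nothing else
  cat2 <- build_tag_catalog(c(reads, list(ind4 = character(0))),
                            sex = c("M", "M", "F", "F"))
  expect_equal(nrow(cat2$tags), 2)
  expect_true(all(cat2$depth[, "ind4"] == 0))
  # unequal-length reads are never merged
  cat3 <- build_tag_catalog(list(a = c(t1, substr(t1, 1, 60))),
                            sex = "M")
  expect_equal(nrow(cat3$tags), 2)
})

test_that("tile distribution is an exact presence contingency cube", {
  depth <- rbind(c(2, 5, 1, 0, 0),    # 3 males, 0 females
                 c(3, 3, 3, 4, 4),    # everywhere
                 c(0, 0, 0, 2, 0))    # 1 female
  cat <- tag_catalog(data.frame(tag_id = paste0("t", 1:3),
                                sequence = c("AAAA", "CCCC", "GGGG")),
                     depth, sex = c("M", "M", "M", "F", "F"))
  tt <- tile_distribution(cat)
  expect_equal(sum(tt), 3)
  expect_equal(tt["0", "3"], 1L)
  expect_equal(tt["2", "3"], 1L)
  expect_equal(tt["1", "0"], 1L)
  # random fixture: cells always sum to the tag count
  set.seed(101)
  d2 <- matrix(rpois(200, 1), nrow = 20)
  cat2 <- tag_catalog(data.frame(tag_id = paste0("t", 1:20),
                                 sequence = replicate(20, random_seq(30))),
                      d2, sex = rep(c("M", "F"), each = 5))
  expect_equal(sum(tile_distribution(cat2)), 20)
  # presence shrinks as min_depth rises
  expect_lte(sum(tile_distribution(cat2, min_depth = 2)[, -1]),
             sum(tile_distribution(cat2, min_depth = 1)[, -1]))
})

test_that("male-only calling applies both thresholds and is monotone", {
  set.seed(103)
  depth <- matrix(rpois(30 * 50, 10), nrow = 30)
  sex <- rep(c("M", "F"), each = 25)
  depth[1, sex == "F"] <- 0                     # male-only everywhere
  depth[2, sex == "F"] <- 0; depth[2, sex == "M"][1:5] <- 0  # 20/25 males
  depth[3, sex == "F"] <- 0
  depth[3, which(sex == "F")[1]] <- 7           # one female: excluded
  cat <- tag_catalog(data.frame(tag_id = paste0("t", 1:30),
                                sequence = replicate(30, random_seq(40))),
                     depth, sex = sex)
  called <- call_male_only_tags(cat, min_males = 10)
  expect_true(all(c("t1", "t2") %in% called))
  expect_false("t3" %in% called)
  # monotone shrink in min_males
  sizes <- vapply(c(5, 10, 20, 25), function(m)
    length(call_male_only_tags(cat, min_males = m)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # allowing one female readmits t3
  expect_true("t3" %in% call_male_only_tags(cat, min_males = 10,
                                            max_females = 1))
})

test_that("E-value follows the Karlin-Altschul form and is monotone in score", {
  expect_equal(karlin_evalue(0, 10, 10), 46)
  e <- karlin_evalue(c(20, 40, 95), 95, 28.5e6)
  expect_true(all(diff(e) < 0))
  # a perfect 95 bp tag on a chromosome-sized target clears e-40
  expect_lt(karlin_evalue(95, 95, 28.5e6), 1e-40)
  # a short perfect hit does not
  expect_gt(karlin_evalue(20, 20, 28.5e6), 1e-40)
})

test_that("tag mapping finds planted positions and honours the cutoff", {
  set.seed(107)
  y <- random_seq(50000)
  pos <- c(1000, 20000, 44000)
  tags <- setNames(substring(y, pos + 1, pos + 95),
                   paste0("tag", seq_along(pos)))
  hits <- map_tags(tags, y)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$t_pos, pos)
  expect_true(all(hits$evalue < 1e-40))
  # reverse-complemented tag maps to the same locus on the minus strand
  rc_hit <- map_tags(c(rc = msyscan:::revcomp(tags[2])), y)
  expect_equal(rc_hit$t_pos, pos[2])
  expect_equal(rc_hit$strand, "-")
  # absent tag: no hit under the cutoff
  expect_equal(nrow(map_tags(c(x = random_seq(95)), y)), 0)
})

test_that("region enrichment reproduces the exact binomial tail", {
  hits <- data.frame(tag_id = paste0("t", 1:10),
                     t_pos = c(rep(900, 7), 10, 20, 30))
  enr <- region_enrichment(hits, c(840, 1000), 1000)
  expect_equal(enr$fraction_in_region, 0.7)
  expect_equal(enr$p0, 0.16)
  expect_equal(enr$binomial_p,
               sum(dbinom(7:10, 10, 0.16)), tolerance = 1e-12)
  # all hits outside: fraction 0, p = 1
  enr0 <- region_enrichment(data.frame(t_pos = c(10, 20)), c(500, 600), 1000)
  expect_equal(enr0$fraction_in_region, 0)
  expect_equal(enr0$binomial_p, 1)
})

test_that("simulated male-only markers are recovered with high recall", {
  recalls <- c(); false_rates <- c()
  for (seed in 1:3) {
    cfg <- scenario_config(scale = 0.05, seed = seed)
    xy <- simulate_xy_pair(cfg)
    rad <- simulate_rad_individuals(cfg, xy)
    called <- call_male_only_tags(rad$catalog,
                                  min_males = ceiling(cfg$n_males / 2))
    truth <- rad$truth$male_only_tag_ids
    recalls <- c(recalls, mean(truth %in% called))
    shared_n <- cfg$n_tag_loci - cfg$n_male_only_loci
    false_rates <- c(false_rates, sum(!(called %in% truth)) / shared_n)
  }
  expect_true(all(recalls >= 0.9))
  expect_true(all(false_rates <= 0.01))
})

test_that("dropout-free male-limited loci are seen in all males, no females", {
  cfg <- scenario_config(scale = 0.05, tag_dropout = 0, seed = 11)
  xy <- simulate_xy_pair(cfg)
  rad <- simulate_rad_individuals(cfg, xy)
  mo <- rad$catalog$tags$male_only
  pres <- rad$catalog$depth > 0
  males <- rad$catalog$sex == "M"
  expect_true(all(pres[mo, males]))
  expect_false(any(pres[mo, !males]))
  # a shared-only scenario yields zero male-only calls
  cfg0 <- scenario_config(scale = 0.05, n_male_only_loci = 0,
                          n_tag_loci = 300, seed = 12)
  rad0 <- simulate_rad_individuals(cfg0, simulate_xy_pair(cfg0))
  expect_length(call_male_only_tags(rad0$catalog, min_males = 13), 0)
})
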