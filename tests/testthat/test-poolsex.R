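make_site <- function(pos, m, f, ref = "A") {
  row <- data.frame(chrom = "Y", pos = pos, ref = ref,
                    A_m = 0L, C_m = 0L, G_m = 0L, T_m = 0L,
                    A_f = 0L, C_f = 0L, G_f = 0L, T_f = 0L,
                    stringsAsFactors = FALSE)
  for (al in names(m)) row[[paste0(al, "_m")]] <- m[[al]]
  for (al in names(f)) row[[paste0(al, "_f")]] <- f[[al]]
  row
}

test_that("sex-specific SNP calling follows the frequency-band rule", {
  tab <- rbind(
    make_site(100, list(A = 15, G = 15), list(A = 30)),        # male-specific G
    make_site(200, list(A = 30), list(A = 30)),                # monomorphic
    make_site(300, list(A = 16, G = 14), list(A = 29, G = 1)), # band + tolerance
    make_site(400, list(A = 30), list(A = 16, T = 14)),        # female-specific
    make_site(500, list(A = 5, G = 4), list(A = 30)))          # below depth
  res <- call_sex_specific_snps(tab)
  s <- res$sites
  expect_equal(s$pos[s$class == "male_specific"], c(100, 300))
  expect_equal(s$allele[s$pos == 100], "G")
  expect_equal(s$freq_m[s$pos == 100], 0.5)
  expect_equal(s$freq_f[s$pos == 100], 0)
  expect_equal(s$pos[s$class == "female_specific"], 400)
  expect_equal(res$qc$n_skipped_depth, 1)
  # site 300: male G at 14/30 = 0.467 inside the 0.4-0.6 band,
  # female 1/30 = 0.033 <= 0.05
  expect_true(300 %in% s$pos)
})

test_that("swapping pool labels swaps male- and female-specific calls", {
  set.seed(113)
  cfg <- scenario_config(scale = 0.02, seed = 7)
  xy <- simulate_xy_pair(cfg)
  pool <- simulate_pool_counts(cfg, xy)
  tab <- pool$table
  swapped <- tab
  for (al in c("A", "C", "G", "T")) {
    swapped[[paste0(al, "_m")]] <- tab[[paste0(al, "_f")]]
    swapped[[paste0(al, "_f")]] <- tab[[paste0(al, "_m")]]
  }
  r1 <- call_sex_specific_snps(tab)
  r2 <- call_sex_specific_snps(swapped)
  m1 <- r1$sites[r1$sites$class == "male_specific", "pos"]
  f2 <- r2$sites[r2$sites$class == "female_specific", "pos"]
  expect_identical(m1, f2)
  f1 <- r1$sites[r1$sites$class == "female_specific", "pos"]
  m2 <- r2$sites[r2$sites$class == "male_specific", "pos"]
  expect_identical(f1, m2)
})

test_that("window counts conserve called sites and place them correctly", {
  sites <- data.frame(chrom = "Y", pos = c(101, 102, 103, 104, 105),
                      ref = "A", class = "male_specific", allele = "G",
                      freq_m = 0.5, freq_f = 0, depth_m = 30, depth_f = 30)
  tab <- make_site(1, list(A = 30), list(A = 30))
  for (p in c(101:105, 60001)) tab <- rbind(tab, make_site(p, list(A = 30),
                                                           list(A = 30)))
  w <- window_sex_snp_scan(sites, tab, chrom_length = 100000,
                           window_bp = 50000)
  expect_equal(nrow(w), 2)
  expect_equal(w$n_sex_snps, c(5, 0))
  expect_equal(sum(w$n_sex_snps), nrow(sites))
  # zero called sites: all windows zero
  w0 <- window_sex_snp_scan(sites[0, ], tab, 100000, window_bp = 50000)
  expect_true(all(w0$n_sex_snps == 0))
})

test_that("planted MSY sites are recovered and PAR stays quiet", {
  cfg <- scenario_config(scale = 0.05, seed = 19)
  xy <- simulate_xy_pair(cfg)
  pool <- simulate_pool_counts(cfg, xy)
  res <- call_sex_specific_snps(pool$table)
  called <- res$sites$pos[res$sites$class == "male_specific"]
  truth <- pool$truth$msy_site_pos
  # per-site detection has finite power (binomial band at Poisson depth);
  # the bulk of planted sites must be recovered and few calls be spurious
  expect_gt(mean(truth %in% called), 0.5)
  expect_lt(mean(!(called %in% truth)), 0.02)
  w <- window_sex_snp_scan(res, pool$table, xy$truth$chrom_length_y,
                           window_bp = 2500)
  b <- xy$truth$boundary_y
  msy_w <- w$t_start >= b & !w$low_coverage
  par_w <- w$t_end <= b & !w$low_coverage
  wt <- wilcox.test(w$n_sex_snps[msy_w], w$n_sex_snps[par_w],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("the masked terminal region is flagged low coverage, not zero-SNP", {
  cfg <- scenario_config(scale = 0.05, seed = 23)
  xy <- simulate_xy_pair(cfg)
  pool <- simulate_pool_counts(cfg, xy)
  res <- call_sex_specific_snps(pool$table)
  w <- window_sex_snp_scan(res, pool$table, xy$truth$chrom_length_y,
                           window_bp = 2500)
  mask <- pool$truth$masked_interval
  masked_w <- w$t_start >= mask[1]
  expect_true(all(w$low_coverage[masked_w]))
  expect_true(all(w$n_sex_snps[masked_w] == 0))
})

test_that("sync round trip preserves the count table", {
  cfg <- scenario_config(scale = 0.01, seed = 29)
  xy <- simulate_xy_pair(cfg)
  pool <- simulate_pool_counts(cfg, xy)
  f <- tempfile(fileext = ".sync")
  write_sync(pool$table, f, header = "test")
  back <- read_sync(f)
  expect_equal(back, pool$table, ignore_attr = TRUE)
  unlink(f)
})
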