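#' Scenario configuration for the synthetic sex-chromosome generator
#'
#' Bundles every tunable of the synthetic data generator. The defaults encode
#' the "reference scenario": a 28.5 Mb Y chromosome whose proximal 23.5 Mb
#' recombine with the X (pseudoautosomal region, PAR; ~1% windowed X-Y
#' difference) and whose distal ~5 Mb form the male-specific region (MSY;
#' ~6% difference, SNPs plus indels), with telomere-like termini, male-limited
#' RAD loci concentrated distally, XY/XX pool allele counts, repeat
#' enrichment and a younger MSY repeat age distribution.
#'
#' `scale` multiplies genome-coordinate quantities (chromosome length,
#' boundary, telomere length, RAD placement cutoffs, pool mapping mask) so the
#' scenario can be shrunk without changing any per-base rate or the expected
#' divergence percentages. Instrument-scale lengths (indel mean length, tag
#' length, read lengths, repeat element lengths, trio haplotype length) are
#' deliberately not scaled.
#'
#' @param chrom_length_bp chromosome length in bp (before scaling)
#' @param boundary_bp PAR/MSY transition in bp on Y coordinates (before scaling)
#' @param sub_rate_par,sub_rate_msy per-base substitution probability
#' @param indel_rate_par,indel_rate_msy per-base indel-event probability
#' @param indel_mean_len mean indel length in bases (geometric)
#' @param telomere_bp length of the telomere-like (TTAGGG)n terminus (scaled)
#' @param n_males,n_females individuals per sex for the RAD design
#' @param n_tag_loci total RAD tag loci (shared plus male-limited)
#' @param n_male_only_loci truly male-limited tag loci
#' @param male_only_fraction_distal fraction of male-limited loci placed
#'   distal of `rad_distal_cutoff_bp`; the remainder fall in
#'   `rad_proximal_range_bp`
#' @param rad_distal_cutoff_bp distal placement cutoff in bp (scaled)
#' @param rad_proximal_range_bp length-2 bp range for the proximal
#'   male-limited loci (scaled)
#' @param tag_len_bp RAD tag length in bases
#' @param tag_depth mean per-individual tag depth (Poisson)
#' @param tag_dropout per-individual, per-locus dropout probability
#' @param pool_depth mean pooled-sequencing depth per site (Poisson)
#' @param pool_mask_terminal_bp terminal interval with no pool mapping
#'   (emulates alignment failure at the diverged chromosome end; scaled)
#' @param n_pool_background monomorphic background sites in the pool table
#' @param repeat_density_par,repeat_density_msy target repeat base fraction
#' @param repeat_len_meanlog,repeat_len_sdlog lognormal repeat element length
#' @param kimura_mean_par,kimura_mean_msy,kimura_sd location/spread of the
#'   Kimura-distance (age proxy) distributions per region
#' @param trio_hap_bp parental haplotype length for the trio-read simulator
#' @param trio_divergence per-base substitution divergence between parents
#' @param trio_error per-base read error rate
#' @param trio_n_reads number of child reads
#' @param trio_read_meanlog,trio_read_sdlog lognormal read length parameters
#' @param n_genes true gene models for the annotation simulator
#' @param gene_corrupt_frac fraction of homology genes whose best model
#'   carries a corrupted (extended, poorly supported) terminal exon
#' @param gene_abinitio_frac fraction of genes with ab initio evidence only
#' @param scale positive rational applied to genome-coordinate quantities
#' @param seed integer seed; every generator derives its own substream
#' @return an object of class `scenario_config`
#' @examples
#' cfg <- scenario_config(scale = 0.01, seed = 1)
#' cfg
#' @export
scenario_config <- function(chrom_length_bp = 28500000,
                            boundary_bp = 23500000,
                            sub_rate_par = 0.008,
                            sub_rate_msy = 0.048,
                            indel_rate_par = 0.0005,
                            indel_rate_msy = 0.003,
                            indel_mean_len = 4,
                            telomere_bp = 3000,
                            n_males = 25,
                            n_females = 25,
                            n_tag_loci = 2000,
                            n_male_only_loci = 200,
                            male_only_fraction_distal = 0.70,
                            rad_distal_cutoff_bp = 24000000,
                            rad_proximal_range_bp = c(20000000, 23500000),
                            tag_len_bp = 95,
                            tag_depth = 20,
                            tag_dropout = 0.1,
                            pool_depth = 50,
                            pool_mask_terminal_bp = 300000,
                            n_pool_background = 5000,
                            repeat_density_par = 0.35,
                            repeat_density_msy = 0.55,
                            repeat_len_meanlog = log(400),
                            repeat_len_sdlog = 0.5,
                            kimura_mean_par = 0.20,
                            kimura_mean_msy = 0.15,
                            kimura_sd = 0.06,
                            trio_hap_bp = 150000,
                            trio_divergence = 0.02,
                            trio_error = 0.01,
                            trio_n_reads = 1000,
                            trio_read_meanlog = log(3000),
                            trio_read_sdlog = 0.4,
                            n_genes = 30,
                            gene_corrupt_frac = 0.3,
                            gene_abinitio_frac = 0.2,
                            scale = 0.1,
                            seed = 1) {
  cfg <- list(
    chrom_length_bp = chrom_length_bp, boundary_bp = boundary_bp,
    sub_rate_par = sub_rate_par, sub_rate_msy = sub_rate_msy,
    indel_rate_par = indel_rate_par, indel_rate_msy = indel_rate_msy,
    indel_mean_len = indel_mean_len, telomere_bp = telomere_bp,
    n_males = n_males, n_females = n_females,
    n_tag_loci = n_tag_loci, n_male_only_loci = n_male_only_loci,
    male_only_fraction_distal = male_only_fraction_distal,
    rad_distal_cutoff_bp = rad_distal_cutoff_bp,
    rad_proximal_range_bp = rad_proximal_range_bp,
    tag_len_bp = tag_len_bp, tag_depth = tag_depth, tag_dropout = tag_dropout,
    pool_depth = pool_depth, pool_mask_terminal_bp = pool_mask_terminal_bp,
    n_pool_background = n_pool_background,
    repeat_density_par = repeat_density_par,
    repeat_density_msy = repeat_density_msy,
    repeat_len_meanlog = repeat_len_meanlog,
    repeat_len_sdlog = repeat_len_sdlog,
    kimura_mean_par = kimura_mean_par, kimura_mean_msy = kimura_mean_msy,
    kimura_sd = kimura_sd,
    trio_hap_bp = trio_hap_bp, trio_divergence = trio_divergence,
    trio_error = trio_error, trio_n_reads = trio_n_reads,
    trio_read_meanlog = trio_read_meanlog, trio_read_sdlog = trio_read_sdlog,
    n_genes = n_genes, gene_corrupt_frac = gene_corrupt_frac,
    gene_abinitio_frac = gene_abinitio_frac,
    scale = scale, seed = as.integer(seed))
  validate_scenario_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$chrom_length_bp > 0, cfg$scale > 0)
  if (!(cfg$boundary_bp > 0 && cfg$boundary_bp < cfg$chrom_length_bp))
    stop("boundary_bp must satisfy 0 < boundary_bp < chrom_length_bp")
  rates <- c(cfg$sub_rate_par, cfg$sub_rate_msy,
             cfg$indel_rate_par, cfg$indel_rate_msy,
             cfg$tag_dropout, cfg$male_only_fraction_distal)
  if (any(rates < 0) || any(rates[1:4] >= 1))
    stop("rates must lie in [0, 1)")
  for (reg in c("par", "msy")) {
    exp_div <- cfg[[paste0("sub_rate_", reg)]] +
      cfg[[paste0("indel_rate_", reg)]] * cfg$indel_mean_len
    if (exp_div > 0.5)
      stop("expected divergence in the ", toupper(reg), " exceeds 50%; ",
           "alignment would not be identifiable")
  }
  invisible(cfg)
}

#' Scaled genome coordinates of a scenario
#'
#' Applies `scale` to the genome-coordinate quantities of a config and rounds
#' to integer bp.
#' @param cfg a [scenario_config()]
#' @return list with `chrom_length`, `boundary`, `telomere`,
#'   `rad_distal_cutoff`, `rad_proximal_range`, `pool_mask_terminal`
#' @export
scenario_coords <- function(cfg) {
  sc <- function(x) as.integer(round(x * cfg$scale))
  list(chrom_length = sc(cfg$chrom_length_bp),
       boundary = sc(cfg$boundary_bp),
       telomere = sc(cfg$telomere_bp),
       rad_distal_cutoff = sc(cfg$rad_distal_cutoff_bp),
       rad_proximal_range = sc(cfg$rad_proximal_range_bp),
       pool_mask_terminal = sc(cfg$pool_mask_terminal_bp))
}

# Derived per-component seed so the generator stages are independently
# reproducible; kept below 2^31 - 1.
component_seed <- function(cfg, component) {
  offsets <- c(xy = 101L, rad = 211L, pool = 307L, trio = 401L,
               genes = 503L, repeats = 601L)
  off <- offsets[[component]]
  as.integer((as.double(cfg$seed) * 7919 + off) %% 2147483647)
}

#' @export
print.scenario_config <- function(x, ...) {
  co <- scenario_coords(x)
  cat("Synthetic sex-chromosome scenario\n")
  cat(sprintf("  chromosome: %s bp (scale %.3g -> %s bp)\n",
              format(x$chrom_length_bp, big.mark = ","), x$scale,
              format(co$chrom_length, big.mark = ",")))
  cat(sprintf("  PAR/MSY boundary: %s bp (scaled %s)\n",
              format(x$boundary_bp, big.mark = ","),
              format(co$boundary, big.mark = ",")))
  cat(sprintf("  substitution rates: PAR %.4g, MSY %.4g\n",
              x$sub_rate_par, x$sub_rate_msy))
  cat(sprintf("  indel rates: PAR %.4g, MSY %.4g (mean length %g)\n",
              x$indel_rate_par, x$indel_rate_msy, x$indel_mean_len))
  cat(sprintf("  RAD: %d males / %d females, %d loci (%d male-limited, %.0f%% distal)\n",
              x$n_males, x$n_females, x$n_tag_loci, x$n_male_only_loci,
              100 * x$male_only_fraction_distal))
  cat(sprintf("  pools: depth %g, terminal mask %s bp\n", x$pool_depth,
              format(co$pool_mask_terminal, big.mark = ",")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
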