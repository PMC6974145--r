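# Synthetic two-SNP splicing study generator: haplotype frequencies at a
# target LD, Hardy-Weinberg genotype sampling, logit-linear genotype ->
# exon-inclusion phenotypes, and Poisson feature counts matching the
# structure the multi-level analysis assumes. SNP1 is the causal variant
# (the rs2304256 analog); SNP2 associates only through LD, giving the
# conditional analysis a ground truth.

#' Solve two-locus haplotype frequencies for a target LD
#'
#' Given minor-allele frequencies at two loci and a target r-squared, finds
#' the four haplotype frequencies with `D = sign * sqrt(r2 * p1 q1 p2 q2)`,
#' `f_AB = p1 p2 + D` and the remaining cells fixed by the margins
#' (upper-case = minor allele). Errors when the target exceeds the
#' attainable maximum for those frequencies.
#'
#' @param maf1,maf2 Minor-allele frequencies in (0, 0.5].
#' @param r2 Target squared correlation between allele indicators, in
#'   \[0, 1\].
#' @param sign Sign of D: `"+"` couples the two minor alleles.
#' @return An object of class `haplotype_freqs`: list with `f_ab`, `f_aB`,
#'   `f_Ab`, `f_AB`, plus `maf1`, `maf2`, `D`, `r2`.
#' @export
solve_haplotypes <- function(maf1, maf2, r2, sign = c("+", "-")) {
  sign <- match.arg(sign)
  if (maf1 <= 0 || maf1 > 0.5 || maf2 <= 0 || maf2 > 0.5) {
    abort("minor-allele frequencies must be in (0, 0.5]")
  }
  if (r2 < 0 || r2 > 1) abort("r2 must be in [0, 1]")
  p1 <- maf1; q1 <- 1 - maf1
  p2 <- maf2; q2 <- 1 - maf2
  s <- if (sign == "+") 1 else -1
  d_max <- if (s > 0) min(p1 * q2, q1 * p2) else min(p1 * p2, q1 * q2)
  r2_max <- d_max^2 / (p1 * q1 * p2 * q2)
  D <- s * sqrt(r2 * p1 * q1 * p2 * q2)
  if (abs(D) > d_max + 1e-12) {
    abort(sprintf(
      "r2 = %.4g is not attainable for MAFs %.3g/%.3g with sign %s (max r2 = %.4g)",
      r2, maf1, maf2, sign, r2_max))
  }
  structure(
    list(f_ab = q1 * q2 + D, f_aB = q1 * p2 - D,
         f_Ab = p1 * q2 - D, f_AB = p1 * p2 + D,
         maf1 = maf1, maf2 = maf2, D = D, r2 = r2),
    class = "haplotype_freqs"
  )
}

#' Recompute LD summaries from haplotype frequencies
#'
#' Inverts [solve_haplotypes()]: recovers the marginal minor-allele
#' frequencies, D and r-squared implied by four haplotype frequencies.
#'
#' @param freqs A `haplotype_freqs` object (or list with the four `f_*`).
#' @return A tibble with `p1`, `p2`, `D`, `r2`.
#' @export
ld_stats <- function(freqs) {
  p1 <- freqs$f_Ab + freqs$f_AB
  p2 <- freqs$f_aB + freqs$f_AB
  D <- freqs$f_AB - p1 * p2
  tibble(p1 = p1, p2 = p2, D = D,
         r2 = D^2 / (p1 * (1 - p1) * p2 * (1 - p2)))
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat(sprintf("<haplotype_freqs> MAFs %.3g/%.3g, D = %.4g, r2 = %.3g\n",
              x$maf1, x$maf2, x$D, x$r2))
  print(round(unlist(x[c("f_ab", "f_aB", "f_Ab", "f_AB")]), 4))
  invisible(x)
}

#' Sample diploid genotypes at two linked SNPs
#'
#' Each individual receives two haplotypes drawn independently from the
#' four-haplotype distribution (random mating / Hardy-Weinberg); the dosage
#' at each SNP is its minor-allele count.
#'
#' @param n Number of individuals.
#' @param freqs A `haplotype_freqs` object from [solve_haplotypes()].
#' @param seed Optional integer; when given, the RNG state is set locally
#'   and restored, making the draw reproducible.
#' @return A tibble with `sample_id`, `dosage1`, `dosage2`.
#' @export
sample_genotypes <- function(n, freqs, seed = NULL) {
  if (n < 1) abort("n must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  probs <- unlist(freqs[c("f_ab", "f_aB", "f_Ab", "f_AB")])
  # haplotype codes: 1 = ab, 2 = aB, 3 = Ab, 4 = AB
  h1 <- sample.int(4L, n, replace = TRUE, prob = probs)
  h2 <- sample.int(4L, n, replace = TRUE, prob = probs)
  carries_A <- c(0L, 0L, 1L, 1L)
  carries_B <- c(0L, 1L, 0L, 1L)
  tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    dosage1 = carries_A[h1] + carries_A[h2],
    dosage2 = carries_B[h1] + carries_B[h2]
  )
}

#' Simulation configuration for the synthetic splicing study
#'
#' Defaults define the study conditions used throughout the package's
#' calibration and recovery analyses: 200 individuals, European-like MAFs
#' 0.26/0.17 with r2 = 0.5 between the two SNPs, a baseline inclusion of
#' about 0.85 (logit 1.73), a +1 logit shift per causal minor allele, 100
#' expected junction-informative reads per sample, and two equally sized
#' populations whose baseline inclusion differs by 0.3 logits.
#'
#' @param n Individuals.
#' @param maf1,maf2 Minor-allele frequencies of the causal SNP (SNP1) and
#'   the LD proxy (SNP2).
#' @param r2 Target LD between the SNPs.
#' @param ld_sign Sign of D (see [solve_haplotypes()]).
#' @param alpha Baseline logit of the exon-inclusion fraction (PSI).
#' @param beta_g Logit-PSI shift per minor-allele copy at SNP1.
#' @param sigma SD of the per-individual logit-PSI noise.
#' @param depth Expected junction-informative reads per sample.
#' @param gamma_intron Intron-signal coefficient: intron read rate is
#'   `depth * gamma_intron * (1 - PSI) + intron_baseline`.
#' @param intron_baseline Baseline intron read rate.
#' @param gene_depth Expected gene-body reads per sample (independent of
#'   genotype: inclusion redistributes isoforms without changing total gene
#'   output).
#' @param pop_shift Numeric vector of per-population logit-PSI offsets; its
#'   length sets the number of populations (equal mixture).
#' @param overdispersion Gamma-Poisson overdispersion; 0 (default) gives
#'   pure Poisson counts.
#' @param seed Integer seed driving all randomness of a simulation run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 200L, maf1 = 0.26, maf2 = 0.17, r2 = 0.5,
                       ld_sign = "+", alpha = qlogis(0.85), beta_g = 1,
                       sigma = 0.3, depth = 100, gamma_intron = 0.5,
                       intron_baseline = 1, gene_depth = 1000,
                       pop_shift = c(0, 0.3), overdispersion = 0,
                       seed = NULL) {
  cfg <- list(n = as.integer(n), maf1 = maf1, maf2 = maf2, r2 = r2,
              ld_sign = ld_sign, alpha = alpha, beta_g = beta_g,
              sigma = sigma, depth = depth, gamma_intron = gamma_intron,
              intron_baseline = intron_baseline, gene_depth = gene_depth,
              pop_shift = pop_shift, overdispersion = overdispersion,
              seed = seed)
  stopifnot(cfg$depth > 0, cfg$n >= 1, cfg$sigma >= 0,
            cfg$overdispersion >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Genotype-dependent exon-inclusion fractions
#'
#' `logit(PSI_i) = alpha + beta_g * dosage1_i + pop_shift[pop_i] + e_i` with
#' `e_i ~ Normal(0, sigma)`; the returned PSI is strictly inside (0, 1).
#'
#' @param dosage1 Causal-SNP dosage vector (0/1/2).
#' @param config A [sim_config()].
#' @param pop Integer population index per sample (into
#'   `config$pop_shift`); defaults to population 1 for everyone.
#' @param seed Optional local seed.
#' @return Numeric PSI vector in (0, 1).
#' @export
simulate_psi <- function(dosage1, config = sim_config(),
                         pop = rep(1L, length(dosage1)), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  eta <- config$alpha + config$beta_g * dosage1 +
    config$pop_shift[pop] + rnorm(length(dosage1), 0, config$sigma)
  pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
}

rcount <- function(n, lambda, overdispersion = 0) {
  if (overdispersion > 0) {
    stats::rnbinom(n, mu = lambda, size = 1 / overdispersion)
  } else {
    rpois(n, lambda)
  }
}

#' Simulate feature-level read counts from per-sample PSI
#'
#' Junctions: `c78, c89 ~ Poisson(depth * PSI)`, `c79 ~ Poisson(depth *
#' (1 - PSI))`. Introns 7 and 9: `Poisson(depth * gamma_intron * (1 - PSI) +
#' intron_baseline)`. Exonic parts: Poisson proportional to part length
#' (per kilobase of `depth`), with the cassette part additionally scaled by
#' PSI. Gene body: `Poisson(gene_depth)`, independent of PSI. The library
#' size is the total of all counted reads per sample.
#'
#' @param psi Per-sample inclusion fractions in (0, 1).
#' @param config A [sim_config()].
#' @param seed Optional local seed.
#' @param sample_ids Optional ids (default `S0001`, ...).
#' @return A tibble with one row per sample: `sample_id`, junction counts
#'   (`c78`, `c89`, `c79`), intron counts (`intron7`, `intron9`), exonic
#'   part counts (`part_exon7`, `part_exon8`, `part_exon9`), `gene` and
#'   `library_size`.
#' @export
simulate_counts <- function(psi, config = sim_config(), seed = NULL,
                            sample_ids = sprintf("S%04d", seq_along(psi))) {
  if (any(psi <= 0 | psi >= 1)) abort("psi must be strictly inside (0, 1)")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(psi)
  d <- config$depth
  od <- config$overdispersion
  part_len <- c(exon7 = 430, exon8 = 198, exon9 = 320)
  out <- tibble(
    sample_id = sample_ids,
    c78 = rcount(n, d * psi, od),
    c89 = rcount(n, d * psi, od),
    c79 = rcount(n, d * (1 - psi), od),
    intron7 = rcount(n, d * config$gamma_intron * (1 - psi) +
                       config$intron_baseline, od),
    intron9 = rcount(n, d * config$gamma_intron * (1 - psi) +
                       config$intron_baseline, od),
    part_exon7 = rcount(n, d * part_len[["exon7"]] / 1000, od),
    part_exon8 = rcount(n, d * part_len[["exon8"]] / 1000 * psi, od),
    part_exon9 = rcount(n, d * part_len[["exon9"]] / 1000, od),
    gene = rcount(n, config$gene_depth, od)
  )
  count_cols <- setdiff(names(out), "sample_id")
  out$library_size <- rowSums(out[count_cols])
  out
}

# per-sample skipping-isoform proportion via the junction-class EM
em_skip_proportion <- function(c78, c89, c79) {
  nj <- c(full = 2L, skip = 1L)
  map_dbl(seq_along(c78), function(i) {
    cls <- tibble(count = c(c78[i] + c89[i], c79[i]),
                  isoforms = list("full", "skip"))
    if (sum(cls$count) == 0) return(NA_real_)
    fit <- quantify_transcripts_em(cls, nj)
    fit$theta[["skip"]]
  })
}

#' Simulate a complete synthetic splicing study
#'
#' End-to-end generator: solves the haplotype frequencies, samples diploid
#' genotypes at the causal SNP and its LD proxy, assigns samples to equally
#' sized populations, draws genotype-dependent PSI and Poisson feature
#' counts, and assembles the normalized multi-level phenotype table
#' (RPKM for gene/exon/intron features, RPM for junctions and splice
#' sites, EM-derived skipping-isoform proportion at transcript level).
#' Splice-site activities flanking the cassette equal the corresponding
#' inclusion-junction counts (sum over the single junction using each
#' site).
#'
#' @param config A [sim_config()]; `config$seed` (or `seed`) drives all
#'   randomness.
#' @param seed Optional override of `config$seed`.
#' @return An object of class `splice_sim`: list with `config`, `freqs`,
#'   `genotypes` (`sample_id`, `dosage1`, `dosage2`), `covariates`
#'   (`sample_id`, `pop`), `counts`, `phenotypes` (long: `level`,
#'   `feature_id`, `sample_id`, `value`), `truth` (`sample_id`, `psi`,
#'   dosages, `pop`) and `gene` (the fixture [tyk2_like_gene()]).
#' @export
simulate_splicing_study <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  freqs <- solve_haplotypes(config$maf1, config$maf2, config$r2,
                            config$ld_sign)
  geno <- sample_genotypes(config$n, freqs)
  n_pop <- length(config$pop_shift)
  pop <- sample(rep_len(seq_len(n_pop), config$n))
  psi <- simulate_psi(geno$dosage1, config, pop = pop)
  counts <- simulate_counts(psi, config, sample_ids = geno$sample_id)
  lib <- counts$library_size
  intron_len <- c(intron7 = 2200, intron9 = 1500)
  part_len <- c(part_exon7 = 430, part_exon8 = 198, part_exon9 = 320)
  pseudo_len <- sum(part_len)
  phen <- bind_rows(
    tibble(level = "gene", feature_id = "gene",
           sample_id = counts$sample_id,
           value = rpkm(counts$gene, lib, pseudo_len)),
    tibble(level = "transcript", feature_id = "skip_transcript",
           sample_id = counts$sample_id,
           value = em_skip_proportion(counts$c78, counts$c89, counts$c79)),
    list_rbind(map(names(part_len), \(p) tibble(
      level = "exon", feature_id = p, sample_id = counts$sample_id,
      value = rpkm(counts[[p]], lib, part_len[[p]])))),
    tibble(level = "junction", feature_id = "e7-e8",
           sample_id = counts$sample_id, value = rpm(counts$c78, lib)),
    tibble(level = "junction", feature_id = "e8-e9",
           sample_id = counts$sample_id, value = rpm(counts$c89, lib)),
    tibble(level = "junction", feature_id = "e7-e9",
           sample_id = counts$sample_id, value = rpm(counts$c79, lib)),
    tibble(level = "splice_site", feature_id = "exon8_acceptor",
           sample_id = counts$sample_id, value = rpm(counts$c78, lib)),
    tibble(level = "splice_site", feature_id = "exon8_donor",
           sample_id = counts$sample_id, value = rpm(counts$c89, lib)),
    list_rbind(map(names(intron_len), \(p) tibble(
      level = "intron", feature_id = p, sample_id = counts$sample_id,
      value = rpkm(counts[[p]], lib, intron_len[[p]]))))
  )
  structure(
    list(config = config, freqs = freqs, genotypes = geno,
         covariates = tibble(sample_id = geno$sample_id,
                             pop = factor(sprintf("pop%d", pop))),
         counts = counts, phenotypes = phen,
         truth = tibble(sample_id = geno$sample_id, psi = psi,
                        dosage1 = geno$dosage1, dosage2 = geno$dosage2,
                        pop = pop),
         gene = tyk2_like_gene()),
    class = "splice_sim"
  )
}

#' @export
print.splice_sim <- function(x, ...) {
  cat(sprintf(
    "<splice_sim> n = %d, MAFs %.2g/%.2g at r2 = %.2g, beta_g = %.2g, depth = %g\n",
    x$config$n, x$config$maf1, x$config$maf2, x$config$r2, x$config$beta_g,
    x$config$depth))
  cat(sprintf("  %d phenotype features across %d levels; mean truth PSI %.3f\n",
              length(unique(x$phenotypes$feature_id)),
              length(unique(x$phenotypes$level)), mean(x$truth$psi)))
  invisible(x)
}

#' Emit spliced read blocks for simulated junction counts
#'
#' Optional block-list read emitter used to exercise the read-level
#' counters: for each junction observation, emits a two-block spliced read
#' with flanking overhangs drawn uniformly from `overhang_range`.
#'
#' @param junctions Tibble with `start`, `end` (intron interval) and
#'   `count` per junction.
#' @param overhang_range Integer range the flanking block lengths are drawn
#'   from.
#' @param seed Optional local seed.
#' @return A read-block tibble (`read_id`, `start`, `end`) suitable for
#'   [extract_junction_counts()].
#' @export
simulate_junction_reads <- function(junctions, overhang_range = c(6L, 30L),
                                    seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  total <- sum(junctions$count)
  if (total == 0) {
    return(tibble(read_id = character(0), start = numeric(0),
                  end = numeric(0)))
  }
  idx <- rep(seq_len(nrow(junctions)), junctions$count)
  o1 <- sample(seq(overhang_range[1], overhang_range[2]), total,
               replace = TRUE)
  o2 <- sample(seq(overhang_range[1], overhang_range[2]), total,
               replace = TRUE)
  s <- junctions$start[idx]
  e <- junctions$end[idx]
  tibble(
    read_id = rep(sprintf("r%06d", seq_len(total)), 2L),
    start = c(s - o1, e),
    end = c(s, e + o2)
  ) |>
    arrange(.data$read_id, .data$start)
}
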