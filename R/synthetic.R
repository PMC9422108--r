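#' Configuration for the synthetic mosaic-haplotype benchmark
#'
#' The generator mirrors the haplotype-copying model itself: panel columns
#' are drawn from a chosen allele-frequency spectrum, query haplotypes are
#' mosaics of panel rows with distance-dependent switch probability, and
#' emitted alleles flip with a per-allele copy error. Because the generator
#' and the inference engine share their assumptions, parameter-matched
#' recovery runs are a clean end-to-end oracle; what the generator does
#' *not* emulate (coalescent genealogy, population structure, genotyping
#' artifacts) is documented in the package vignette.
#'
#' @param n_hap Panel haplotypes `N` (must be even; pairs form samples).
#'   Default 200.
#' @param n_sites Variant count `V`. Default 2000.
#' @param bp_spacing Physical spacing between adjacent sites (bp).
#'   Default 1000.
#' @param rate_cm_mb Constant recombination rate of the synthetic map in
#'   cM/Mb. Default 1 (with the defaults above, a 2 Mb / 2 cM region).
#' @param freq_range Allele-frequency spectrum: panel column frequencies
#'   are drawn uniformly from this range. Default `c(0.02, 0.5)`, a
#'   spectrum dominated by common variants so that common-variant accuracy
#'   is estimated from many sites.
#' @param n_founders Optional block-copy structure: when smaller than
#'   `n_hap`, only this many founder haplotypes are drawn and the remaining
#'   rows are recombined copies of founders, creating panel LD. Default
#'   `n_hap` (independent columns).
#' @param n_e Effective population size of the mosaic switch model (also
#'   the matched inference value). Default 50: with distances entering in
#'   cM, this gives a per-cM switch rate of about `4 n_e / n_hap = 1`,
#'   i.e. mosaic segments of roughly 1 cM.
#' @param eps_sim Per-allele copy error of the generator. Default `1e-4`.
#' @param typed_every Every `typed_every`-th site is typed (array mask);
#'   the rest are untyped imputation targets. Default 10.
#' @param n_query Number of diploid query individuals (2 haplotypes each).
#'   Default 10.
#' @param chrom Chromosome label. Default `"chrS"`.
#' @param seed Mandatory integer seed; every stochastic operation derives
#'   from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_hap = 200L, n_sites = 2000L, bp_spacing = 1000L,
                       rate_cm_mb = 1, freq_range = c(0.02, 0.5),
                       n_founders = n_hap, n_e = 50, eps_sim = 1e-4,
                       typed_every = 10L, n_query = 10L, chrom = "chrS",
                       seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible simulation", call. = FALSE)
  stopifnot(n_hap >= 2L, n_hap %% 2L == 0L, n_sites >= 2L, bp_spacing >= 1L,
            rate_cm_mb > 0, length(freq_range) == 2L,
            all(freq_range >= 0 & freq_range <= 1),
            n_founders >= 1L, n_founders <= n_hap,
            n_e > 0, eps_sim >= 0, eps_sim < 1,
            typed_every >= 2L, n_query >= 1L)
  structure(list(n_hap = as.integer(n_hap), n_sites = as.integer(n_sites),
                 bp_spacing = as.integer(bp_spacing),
                 rate_cm_mb = rate_cm_mb, freq_range = freq_range,
                 n_founders = as.integer(n_founders), n_e = n_e,
                 eps_sim = eps_sim, typed_every = as.integer(typed_every),
                 n_query = as.integer(n_query), chrom = chrom,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a reference panel and its genetic map
#'
#' Draws per-column allele frequencies from the configured spectrum and
#' fills an `N x V` haplotype matrix with independent Bernoulli alleles
#' (or, with `n_founders < n_hap`, recombined copies of a founder set,
#' which induces panel LD). Also writes a constant-rate genetic map table
#' matching the site grid.
#'
#' @param cfg A [sim_config()].
#' @return List with `panel` (a `ref_panel`, whose `sites` carry `cm`) and
#'   `gmap` (a `genetic_map`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  V <- cfg$n_sites; N <- cfg$n_hap
  pos <- seq(1L, by = cfg$bp_spacing, length.out = V)
  cm <- (pos - pos[1]) * cfg$rate_cm_mb / 1e6
  freq <- runif(V, cfg$freq_range[1], cfg$freq_range[2])
  if (cfg$n_founders < N) {
    founders <- matrix(rbinom(cfg$n_founders * V, 1L, rep(freq,
                       each = cfg$n_founders)), cfg$n_founders, V)
    H <- founders[sample.int(cfg$n_founders, N, replace = TRUE), ,
                  drop = FALSE]
    # one uniform crossover per copied row keeps block structure simple
    for (r in seq_len(N)) {
      cut <- sample.int(V - 1L, 1L)
      other <- sample.int(cfg$n_founders, 1L)
      H[r, (cut + 1L):V] <- founders[other, (cut + 1L):V]
    }
  } else {
    H <- matrix(rbinom(N * V, 1L, rep(freq, each = N)), N, V)
  }
  storage.mode(H) <- "integer"
  alleles <- make_alleles(V)
  sites <- data.frame(chrom = cfg$chrom, pos = pos,
                      id = paste0("snv", seq_len(V)),
                      ref = alleles$ref, alt = alleles$alt,
                      cm = cm, stringsAsFactors = FALSE)
  panel <- structure(list(H = H, sites = sites,
                          samples = sprintf("REF%04d", seq_len(N / 2L)),
                          dropped = 0L),
                     class = "ref_panel")
  gmap <- structure(list(chrom = cfg$chrom, pos = as.numeric(pos), cm = cm),
                    class = "genetic_map")
  list(panel = panel, gmap = gmap)
}

make_alleles <- function(V) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[1L + (seq_len(V) %% 4L)]
  alt <- bases[1L + ((seq_len(V) + 1L) %% 4L)]
  list(ref = ref, alt = alt)
}

#' Simulate mosaic query haplotypes from a panel
#'
#' Each query haplotype starts on a uniformly drawn panel row; between
#' consecutive sites it switches, with probability
#' `(N - 1) * p_R(delta_cM)`, to a uniformly drawn *different* row — the
#' exact transition kernel of the copying HMM — and the copied allele is
#' flipped with probability `eps_sim`. The typed-site mask is then applied
#' to produce the observable query.
#'
#' @param sim A [simulate_panel()] result.
#' @param cfg The same [sim_config()].
#' @return List with `query` (a `query_haps` with `NA` at untyped sites),
#'   `truth` (full `2M x V` allele matrix before masking), `truth_geno`
#'   (`M x V` genotype matrix, rownames = sample names), and `paths`
#'   (`2M x V` true mosaic row indices).
#' @export
simulate_query <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- sim$panel
  set.seed(cfg$seed + 1L)
  N <- nrow(panel$H); V <- ncol(panel$H)
  n_hapq <- 2L * cfg$n_query
  p_r <- recomb_prob(diff(panel$sites$cm), N, cfg$n_e)
  p_switch <- pmin((N - 1) * p_r, 1)
  truth <- matrix(NA_integer_, n_hapq, V)
  paths <- matrix(NA_integer_, n_hapq, V)
  for (r in seq_len(n_hapq)) {
    s <- sample.int(N, 1L)
    paths[r, 1L] <- s
    if (V > 1L) for (j in 2:V) {
      if (runif(1) < p_switch[j - 1L]) {
        s_new <- sample.int(N - 1L, 1L)
        s <- if (s_new >= s) s_new + 1L else s_new  # uniform over others
      }
      paths[r, j] <- s
    }
    a <- panel$H[cbind(paths[r, ], seq_len(V))]
    flip <- runif(V) < cfg$eps_sim
    truth[r, ] <- ifelse(flip, 1L - a, a)
  }
  typed <- (seq_len(V) %% cfg$typed_every) == 1L
  A <- truth
  A[, !typed] <- NA_integer_
  samples <- sprintf("QRY%04d", seq_len(cfg$n_query))
  truth_geno <- truth[seq(1L, n_hapq, 2L), , drop = FALSE] +
    truth[seq(2L, n_hapq, 2L), , drop = FALSE]
  rownames(truth_geno) <- samples
  query <- structure(list(A = A, samples = samples,
                          untyped = which(!typed), typed = typed),
                     class = "query_haps")
  list(query = query, truth = truth, truth_geno = truth_geno, paths = paths)
}

#' Build a ready-to-run synthetic benchmark
#'
#' Bundles a simulated panel, masked mosaic queries and the matching truth
#' tables into one job.
#'
#' @param cfg A [sim_config()]; the default configuration is the package's
#'   standard benchmark (200 haplotypes, 2000 sites over 2 cM, every 10th
#'   site typed, matched `n_e`, copy error `1e-4`).
#' @return List with `panel`, `gmap`, `query`, `truth`, `truth_geno`,
#'   `paths` and `cfg`.
#' @export
make_benchmark <- function(cfg = sim_config(seed = 1L)) {
  sim <- simulate_panel(cfg)
  q <- simulate_query(sim, cfg)
  c(sim, q, list(cfg = cfg))
}

#' Write a simulated benchmark to VCF/map files
#'
#' Writes the panel VCF, the (masked) query VCF, an IMPUTE2-format genetic
#' map, the truth genotypes and the typed-position list so the full
#' file-based workflow can be exercised end to end.
#'
#' @param bench A [make_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel_vcf <- file.path(dir, "panel.vcf")
  query_vcf <- file.path(dir, "query.vcf")
  map_file <- file.path(dir, "genetic_map.txt")
  truth_file <- file.path(dir, "truth_genotypes.tsv")
  typed_file <- file.path(dir, "typed_positions.txt")
  write_hap_vcf(bench$panel$H, bench$panel$sites, bench$panel$samples,
                panel_vcf)
  sites <- bench$panel$sites
  typed_idx <- which(bench$query$typed)
  write_hap_vcf(bench$query$A[, typed_idx, drop = FALSE],
                sites[typed_idx, , drop = FALSE],
                bench$query$samples, query_vcf)
  rate <- c(diff(bench$gmap$cm) / diff(bench$gmap$pos) * 1e6, 0)
  writeLines(c("position COMBINED_rate(cM/Mb) Genetic_Map(cM)",
               sprintf("%d %.6f %.8f", as.integer(bench$gmap$pos), rate,
                       bench$gmap$cm)), map_file)
  tg <- data.frame(sample = rep(rownames(bench$truth_geno),
                                times = ncol(bench$truth_geno)),
                   site = rep(seq_len(ncol(bench$truth_geno)),
                              each = nrow(bench$truth_geno)),
                   pos = rep(sites$pos, each = nrow(bench$truth_geno)),
                   geno = as.vector(bench$truth_geno))
  write.table(tg, truth_file, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%d", sites$chrom[typed_idx],
                     sites$pos[typed_idx]), typed_file)
  c(panel = panel_vcf, query = query_vcf, map = map_file,
    truth = truth_file, typed = typed_file)
}

# Minimal phased-VCF writer for simulated haplotype matrices
# (H: 2M x V, 0/1).
write_hap_vcf <- function(H, sites, samples, path) {
  V <- ncol(H)
  stopifnot(nrow(sites) == V, nrow(H) == 2L * length(samples))
  gt <- matrix(paste0(H[seq(1L, nrow(H), 2L), , drop = FALSE], "|",
                      H[seq(2L, nrow(H), 2L), , drop = FALSE]),
               nrow = length(samples))
  header <- c("##fileformat=VCFv4.2",
              "##source=vicimpute-simulator",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(V), function(j)
    paste(c(sites$chrom[j], sites$pos[j], sites$id[j], sites$ref[j],
            sites$alt[j], ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
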