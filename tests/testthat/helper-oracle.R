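# Shared fixtures and independent oracles for the HMM engines.

# Random window instance: V x N panel slice, observed alleles, per-step
# recombination probabilities bounded by 1/N.
rand_instance <- function(N, V, eps = NULL, rho_max = NULL) {
  if (is.null(eps)) eps <- 10^runif(1, -4, -1)
  if (is.null(rho_max)) rho_max <- 1 / N
  H <- matrix(rbinom(V * N, 1L, 0.5), V, N)
  # guarantee at least one polymorphic column so instances are non-trivial
  if (V >= 1L && N >= 2L) H[1, 1:2] <- c(0L, 1L)
  list(H = H, g = rbinom(V, 1L, 0.5),
       rho = c(NA_real_, runif(V - 1, 0, rho_max)), eps = eps)
}

# Exhaustive enumeration over all N^V state paths. Path probability
# includes the uniform 1/N start; J[j, a] = sum of full-path probabilities
# of paths with state a at step j (so F(j,a) B(j,a) = J[j,a] / N given the
# uniform terminal boundary of the backward variables).
enum_oracle <- function(H, g, rho, eps) {
  V <- nrow(H); N <- ncol(H)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), V)))
  lp <- (1 / N) * ifelse(H[1, paths[, 1]] == g[1], 1 - eps, eps)
  if (V > 1) for (j in 2:V) {
    pnr <- 1 - (N - 1) * rho[j]
    lp <- lp * ifelse(paths[, j] == paths[, j - 1], pnr, rho[j]) *
      ifelse(H[j, paths[, j]] == g[j], 1 - eps, eps)
  }
  J <- matrix(NA_real_, V, N)
  for (j in seq_len(V))
    J[j, ] <- rowsum(lp, paths[, j])[, 1]
  best <- which.max(lp)
  list(paths = paths, lp = lp, J = J, total = sum(lp),
       max_p = lp[best], max_path = paths[best, ])
}

# Allele scores at a virtual untyped target anchored at typed member k,
# from the enumeration: restricted path sums by the panel allele of the
# state occupied at k (divided by N for the terminal boundary).
enum_allele_scores <- function(oracle, k, target_alleles) {
  sel <- target_alleles[oracle$paths[, k]]
  c(sum(oracle$lp[sel == 0L]), sum(oracle$lp[sel == 1L])) / length(target_alleles)
}

# Probability of one explicit state path under the model (uniform start).
path_prob <- function(H, g, rho, eps, path) {
  V <- nrow(H); N <- ncol(H)
  p <- (1 / N) * ifelse(H[1, path[1]] == g[1], 1 - eps, eps)
  if (V > 1) for (j in 2:V) {
    pnr <- 1 - (N - 1) * rho[j]
    p <- p * (if (path[j] == path[j - 1]) pnr else rho[j]) *
      ifelse(H[j, path[j]] == g[j], 1 - eps, eps)
  }
  p
}

rel_err <- function(a, b) {
  d <- abs(a - b)
  ifelse(d == 0, 0, d / pmax(abs(a), abs(b)))
}

# Annotated site table on a uniform cM grid; every `typed_every`-th site
# typed. Positions are 1-based, spacing 1 kb.
grid_sites <- function(n, cm_step = 0.01, typed_every = 2L, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq(1L, by = 1000L, length.out = n),
             id = paste0("s", seq_len(n)),
             ref = rep(c("A", "C"), length.out = n),
             alt = rep(c("G", "T"), length.out = n),
             cm = (seq_len(n) - 1L) * cm_step,
             typed = (seq_len(n) %% typed_every) == 1L,
             stringsAsFactors = FALSE)
}

# Plain-text phased VCF writer for hand-built fixtures.
write_test_vcf <- function(path, chrom, pos, ref, alt, gt_matrix, samples,
                           id = NULL) {
  if (is.null(id)) id <- paste0("v", seq_along(pos))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(j)
    paste(c(chrom, pos[j], id[j], ref[j], alt[j], ".", "PASS", ".", "GT",
            gt_matrix[j, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

# Small matched-parameter mosaic benchmark for integration tests.
small_benchmark <- function(seed = 5L, n_hap = 30L, n_sites = 300L,
                            n_query = 3L, ...) {
  cfg <- sim_config(n_hap = n_hap, n_sites = n_sites, n_query = n_query,
                    seed = seed, ...)
  list(bench = make_benchmark(cfg), cfg = cfg)
}

truth_for_calls <- function(calls, bench) {
  bench$truth_geno[cbind(match(calls$sample, rownames(bench$truth_geno)),
                         calls$site)]
}
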