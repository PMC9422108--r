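test_that("allele normalization and genotype combination follow the model", {
  expect_equal(unname(normalize_alleles(c(0.2, 0.6))), c(0.25, 0.75))
  expect_warning(p <- normalize_alleles(c(0, 0)), "both allele scores")
  expect_equal(unname(p), c(0.5, 0.5))
  expect_equal(unname(normalize_alleles(c(3.7, 0))), c(1, 0))
  expect_error(normalize_alleles(c(-1, 2)), "negative")

  expect_equal(genotype_probs(c(0, 1), c(0, 1)), c(0, 0, 1))
  expect_equal(genotype_probs(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  expect_equal(genotype_probs(c(0.9, 0.1), c(0.2, 0.8)), c(0.18, 0.74, 0.08))
  # sums to one by construction for arbitrary inputs
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    expect_equal(sum(genotype_probs(c(a, 1 - a), c(b, 1 - b))), 1)
  }
})

test_that("forward-backward allele scores match restricted path enumeration", {
  set.seed(37)
  for (i in 1:10) {
    N <- sample(2:4, 1); V <- sample(3:5, 1)
    inst <- rand_instance(N, V)
    par <- hmm_params(eps_allele = inst$eps)
    or <- enum_oracle(inst$H, inst$g, inst$rho, inst$eps)
    fw <- ls_forward(inst$H, inst$g, inst$rho, par)
    bw <- ls_backward(inst$H, inst$g, inst$rho, par)
    target_alleles <- rbinom(N, 1L, 0.5)
    for (k in seq_len(V)) {
      w <- list(flank = c(left = k, right = NA))
      sc <- fb_allele_probs(fw, bw, w, target_alleles)
      ref <- enum_allele_scores(or, k, target_alleles)
      if (sum(ref) > 0) {
        expect_equal(unname(normalize_alleles(sc)),
                     ref / sum(ref), tolerance = 1e-9)
      }
    }
  }
})

test_that("degenerate and symmetric target columns give the expected posteriors", {
  H <- matrix(rbinom(4 * 6, 1L, 0.5), 4, 6)
  g <- rbinom(4, 1L, 0.5)
  rho <- c(NA, rep(0.05, 3))
  fw <- ls_forward(H, g, rho)
  bw <- ls_backward(H, g, rho)
  w <- list(flank = c(left = 2L, right = 3L))

  # monomorphic target column: all mass on the observed allele
  sc <- fb_allele_probs(fw, bw, w, rep(0L, 6))
  expect_equal(unname(normalize_alleles(sc)), c(1, 0))

  # uninformative window (all rows identical) and a half/half target
  # column: symmetry forces 0.5/0.5
  H2 <- matrix(0L, 4, 6)
  fw2 <- ls_forward(H2, rep(0L, 4), rho)
  bw2 <- ls_backward(H2, rep(0L, 4), rho)
  sc2 <- fb_allele_probs(fw2, bw2, w, c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_equal(unname(normalize_alleles(sc2)), c(0.5, 0.5))
})

test_that("Viterbi allele calls copy the path at the nearest typed variant", {
  set.seed(41)
  sites <- grid_sites(21L, cm_step = 0.01, typed_every = 2L)
  N <- 8
  H <- matrix(rbinom(21 * N, 1L, 0.5), N, 21)
  target <- 10L  # untyped (even index)
  w <- build_window(target, sites, locality_config(lw = 0.2, lc2t = 0.05))
  rho <- window_rho(w, sites, N, 100)
  Hwin <- t(H[, w$members])
  g <- H[3, w$members]  # copy row 3 verbatim
  vt <- ls_viterbi(Hwin, g, rho, hmm_params(n_e = 100))
  va <- viterbi_allele(vt, w, sites, H[, target])
  expect_true(all(vt$path == 3L))
  expect_equal(va$allele, H[3, target])
  expect_equal(sum(va$probs), 1)

  # monomorphic target column gives that allele with score 1
  va1 <- viterbi_allele(vt, w, sites, rep(1L, N))
  expect_equal(va1$allele, 1L)
  expect_equal(unname(va1$probs), c(0, 1))
})

test_that("imputation records satisfy their probability contracts", {
  s <- small_benchmark(seed = 5L, freq_range = c(0.2, 0.5))
  b <- s$bench
  imp <- impute_genotypes(b$query, b$panel,
                          config = locality_config(lw = 0.3, lc2t = 0.05),
                          params = hmm_params(n_e = s$cfg$n_e),
                          method = "both")
  calls <- imp$calls
  expect_true(all(abs(calls$gp0 + calls$gp1 + calls$gp2 - 1) < 1e-9))
  expect_true(all(abs(calls$dosage - (calls$gp1 + 2 * calls$gp2)) < 1e-12))
  expect_true(all(calls$dosage >= 0 & calls$dosage <= 2))
  expect_setequal(unique(calls$method), c("FB", "VIT"))
  # one record per (sample, untyped target, method)
  ok_targets <- imp$targets$site[imp$targets$status == "ok"]
  expect_equal(nrow(calls),
               2L * length(ok_targets) * length(b$query$samples))
  # deterministic output order: site-major, then sample
  expect_true(!is.unsorted(calls$site))

  # FB and Viterbi agree on confident calls
  fb <- calls[calls$method == "FB", ]
  vit <- calls[calls$method == "VIT", ]
  conf <- pmax(fb$gp0, fb$gp1, fb$gp2) > 0.99
  expect_gt(mean(fb$hard[conf] == vit$hard[conf]), 0.99)
})

test_that("perfect panel copies are recovered exactly by both methods", {
  s <- small_benchmark(seed = 3L, eps_sim = 0, n_e = 1e-9,
                       freq_range = c(0.4, 0.5), typed_every = 5L)
  b <- s$bench
  # panel rows must be distinguishable over the typed sites for the copied
  # row (and hence the target allele) to be identifiable
  key <- apply(b$panel$H[, b$query$typed], 1, paste0, collapse = "")
  stopifnot(!anyDuplicated(key))
  imp <- impute_genotypes(b$query, b$panel,
                          config = locality_config(lw = 4, lc2t = 1.9),
                          params = hmm_params(n_e = 50), method = "both")
  calls <- imp$calls
  known <- truth_for_calls(calls, b)
  for (m in c("FB", "VIT")) {
    sel <- calls$method == m
    expect_equal(mean(calls$hard[sel] == known[sel]), 1)
  }
})

test_that("isolated targets are skipped and logged, not fatal", {
  s <- small_benchmark(seed = 9L, n_sites = 100L, n_query = 1L)
  b <- s$bench
  # shrink the window so the first untyped site (left edge) still works
  # but a site stripped of nearby typed sites fails
  sites <- b$panel$sites
  query <- b$query
  # strip typed status around one untyped target by masking typed sites
  far <- query$typed
  far[2:60] <- FALSE    # strips typed sites 11..51, isolating mid targets
  query$A[, !far & query$typed] <- NA_integer_
  query$untyped <- which(!far)
  query$typed <- far
  imp <- impute_genotypes(query, b$panel,
                          config = locality_config(lw = 0.05, lc2t = 0.02),
                          params = hmm_params(n_e = s$cfg$n_e))
  expect_true(any(grepl("isolated target", imp$targets$status)))
  expect_true(any(imp$targets$status == "ok"))
  skipped <- imp$targets$site[imp$targets$status != "ok"]
  expect_false(any(imp$calls$site %in% skipped))
})

test_that("imputation is invariant to swapping parental copy labels", {
  s <- small_benchmark(seed = 13L, n_query = 2L)
  b <- s$bench
  cfg <- locality_config(lw = 0.5, lc2t = 0.2)
  par <- hmm_params(n_e = s$cfg$n_e)
  imp1 <- impute_genotypes(b$query, b$panel, config = cfg, params = par)
  qswap <- b$query
  swap <- as.vector(rbind(seq(2, nrow(qswap$A), 2), seq(1, nrow(qswap$A), 2)))
  qswap$A <- qswap$A[swap, , drop = FALSE]
  imp2 <- impute_genotypes(qswap, b$panel, config = cfg, params = par)
  expect_equal(imp2$calls$gp0, imp1$calls$gp0, tolerance = 1e-12)
  expect_equal(imp2$calls$gp1, imp1$calls$gp1, tolerance = 1e-12)
  expect_equal(imp2$calls$gp2, imp1$calls$gp2, tolerance = 1e-12)
  expect_equal(imp2$calls$phap0, imp1$calls$phap1, tolerance = 1e-12)
})
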