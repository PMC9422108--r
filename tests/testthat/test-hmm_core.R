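test_that("recombination and transition probabilities follow the copying model", {
  expect_equal(recomb_prob(0, 10, 1e4), 0)
  expect_equal(recomb_prob(1e9, 10, 1e4), 1 / 10)   # saturates at 1/N
  expect_equal(recomb_prob(0.01, 100, 1e4), (1 / 100) * (1 - exp(-4)))
  # cM/Morgan switch divides the distance by 100
  expect_equal(recomb_prob(1, 50, 1e3, morgans = TRUE),
               recomb_prob(0.01, 50, 1e3))

  expect_equal(no_recomb_prob(0, 1), 1)
  expect_equal(no_recomb_prob(1 / 8, 8), 1 / 8)     # uniform limit
  expect_error(no_recomb_prob(0.3, 8), "exceeds 1/N")

  # rows of the transition kernel sum to one exactly
  for (N in c(2, 5, 17)) {
    p_r <- recomb_prob(runif(1, 0, 0.5), N, 1e4)
    p_nr <- no_recomb_prob(p_r, N)
    expect_identical(p_nr + (N - 1) * p_r, 1)
    total <- sum(transition_prob(p_r, p_nr, from = 1, to = seq_len(N)))
    expect_equal(total, 1)
  }

  expect_equal(emission_prob(0, 0, 1e-4), 0.9999)
  expect_equal(emission_prob(0, 1, 1e-4), 1e-4)
})

test_that("forward boundary and single-variant backward match hand arithmetic", {
  # N = 2, one variant, panel column (0, 1), observed 0:
  # F(1, .) = (1/2) * (0.9999, 0.0001) = (0.49995, 0.00005)
  H <- matrix(c(0L, 1L), 1, 2)
  fw <- ls_forward(H, 0L, NA_real_, hmm_params(eps_allele = 1e-4))
  expect_equal(exp(fw$logmat[1, ]), c(0.49995, 0.00005))

  bw <- ls_backward(H, 0L, NA_real_, hmm_params())
  expect_equal(exp(bw$logmat[1, ]), c(0.5, 0.5))    # boundary only

  # uninformative panel (all rows identical): forward columns are uniform
  H2 <- matrix(1L, 4, 3)
  g2 <- rep(1L, 4)
  rho2 <- c(NA, rep(0.1, 3))
  fw2 <- ls_forward(H2, g2, rho2)
  for (j in 1:4) expect_equal(diff(range(fw2$logmat[j, ])), 0)
})

test_that("forward, backward and Viterbi match exhaustive path enumeration", {
  set.seed(101)
  for (i in 1:25) {
    N <- sample(2:5, 1); V <- sample(2:6, 1)
    inst <- rand_instance(N, V)
    par <- hmm_params(eps_allele = inst$eps)
    or <- enum_oracle(inst$H, inst$g, inst$rho, inst$eps)
    fw <- ls_forward(inst$H, inst$g, inst$rho, par)
    bw <- ls_backward(inst$H, inst$g, inst$rho, par)
    expect_lt(max(rel_err(exp(fw$logmat[V, ]), or$J[V, ])), 1e-9)
    for (j in seq_len(V)) {
      expect_lt(max(rel_err(exp(fw$logmat[j, ] + bw$logmat[j, ]),
                            or$J[j, ] / N)), 1e-9)
    }
    expect_lt(rel_err(exp(fw$loglik), or$total / N), 1e-9)
    vt <- ls_viterbi(inst$H, inst$g, inst$rho, par)
    expect_lt(rel_err(exp(vt$logp), or$max_p / N), 1e-9)
    expect_lt(rel_err(path_prob(inst$H, inst$g, inst$rho, inst$eps, vt$path),
                      or$max_p), 1e-9)
  }
})

test_that("total likelihood is constant across window positions", {
  set.seed(7)
  for (i in 1:10) {
    inst <- rand_instance(sample(2:8, 1), sample(3:12, 1))
    par <- hmm_params(eps_allele = inst$eps)
    fw <- ls_forward(inst$H, inst$g, inst$rho, par)
    bw <- ls_backward(inst$H, inst$g, inst$rho, par)
    tot <- vapply(seq_len(nrow(inst$H)), function(j)
      vicimpute:::logsumexp(fw$logmat[j, ] + bw$logmat[j, ]), 0)
    expect_lt(max(abs(tot - tot[1])), 1e-9)
  }
})

test_that("factorized recursions equal the naive full transition-matrix form", {
  set.seed(11)
  for (i in 1:10) {
    N <- sample(2:50, 1); V <- sample(2:50, 1)
    inst <- rand_instance(N, V)
    par <- hmm_params(eps_allele = inst$eps)
    fw <- ls_forward(inst$H, inst$g, inst$rho, par)
    bw <- ls_backward(inst$H, inst$g, inst$rho, par)
    vt <- ls_viterbi(inst$H, inst$g, inst$rho, par)
    fn <- vicimpute:::r_ls_forward_naive(inst$H, inst$g, inst$rho, inst$eps)
    bn <- vicimpute:::r_ls_backward_naive(inst$H, inst$g, inst$rho, inst$eps)
    vn <- vicimpute:::r_ls_viterbi_naive(inst$H, inst$g, inst$rho, inst$eps)
    expect_lt(max(rel_err(exp(fw$logmat), fn)), 1e-12)
    expect_lt(max(rel_err(exp(bw$logmat), bn)), 1e-12)
    expect_lt(max(rel_err(exp(vt$logmat), vn)), 1e-12)
  }
})

test_that("log-domain and scaled-linear engines agree", {
  set.seed(13)
  for (i in 1:10) {
    inst <- rand_instance(sample(2:10, 1), sample(2:30, 1))
    p_lin <- hmm_params(eps_allele = inst$eps, domain = "scaled")
    p_log <- hmm_params(eps_allele = inst$eps, domain = "log")
    expect_lt(max(rel_err(ls_forward(inst$H, inst$g, inst$rho, p_lin)$logmat,
                          ls_forward(inst$H, inst$g, inst$rho, p_log)$logmat)),
              1e-6)
    expect_lt(max(rel_err(ls_backward(inst$H, inst$g, inst$rho, p_lin)$logmat,
                          ls_backward(inst$H, inst$g, inst$rho, p_log)$logmat)),
              1e-6)
    v1 <- ls_viterbi(inst$H, inst$g, inst$rho, p_lin)
    v2 <- ls_viterbi(inst$H, inst$g, inst$rho, p_log)
    expect_lt(rel_err(v1$logp, v2$logp), 1e-6)
    expect_equal(v1$path, v2$path)
  }
})

test_that("results are invariant to the rescale band and scaling factor", {
  set.seed(17)
  inst <- rand_instance(6, 40)
  par_default <- hmm_params(eps_allele = inst$eps)
  variants <- list(
    hmm_params(eps_allele = inst$eps, scale_factor = exp(1),
               rescale_band = c(1e-5, 1e5)),
    hmm_params(eps_allele = inst$eps, scale_factor = 2,
               rescale_band = c(1e-2, 1e2)))
  ref <- ls_forward(inst$H, inst$g, inst$rho, par_default)$logmat
  for (p in variants) {
    expect_lt(max(rel_err(ref, ls_forward(inst$H, inst$g, inst$rho, p)$logmat)),
              1e-9)
    expect_lt(max(rel_err(
      ls_backward(inst$H, inst$g, inst$rho, par_default)$logmat,
      ls_backward(inst$H, inst$g, inst$rho, p)$logmat)), 1e-9)
  }
})

test_that("Viterbi stays on a copied row and resolves ties to the lowest index", {
  set.seed(19)
  N <- 6; V <- 20
  H <- matrix(rbinom(V * N, 1L, 0.5), V, N)
  rho <- c(NA, rep(recomb_prob(0.01, N, 50), V - 1))
  # query copied verbatim from row 4: best path is constant at row 4
  g <- H[, 4]
  H[, 2] <- 1L - g  # make sure no other row ties with row 4
  vt <- ls_viterbi(H, g, rho, hmm_params(n_e = 50))
  expect_true(all(vt$path == 4L))

  # duplicate the best row: tie resolved to the lower index, probability
  # unchanged
  H2 <- H; H2[, 6] <- H[, 4]
  vt2 <- ls_viterbi(H2, g, rho, hmm_params(n_e = 50))
  expect_true(all(vt2$path == 4L))
  expect_equal(vt2$logp, vt$logp)

  # traceback of a single-variant window is the argmax of column 1
  h1 <- matrix(c(1L, 0L, 1L), 1, 3)
  v1 <- ls_viterbi(h1, 1L, NA_real_, hmm_params())
  expect_equal(v1$path, 1L)
})

test_that("degenerate inputs are rejected", {
  expect_error(ls_forward(matrix(0L, 0, 2), integer(0), numeric(0)),
               "empty window")
  expect_error(ls_forward(matrix(c(0L, 1L), 1, 2), 2L, NA_real_),
               "alleles must be 0/1")
  expect_error(ls_forward(matrix(c(0L, 1L), 1, 2), c(0L, 1L), NA_real_),
               "length")
})

test_that("haplotype clustering groups identical block strings", {
  set.seed(23)
  # 100 haplotypes drawn from 7 distinct block strings -> 7 clusters
  base <- matrix(rbinom(10 * 7, 1L, 0.5), 10, 7)
  while (anyDuplicated(t(base))) base <- matrix(rbinom(10 * 7, 1L, 0.5), 10, 7)
  H <- base[, sample(rep(1:7, length.out = 100))]
  cb <- cluster_blocks(H, block_len = 10L)
  expect_length(cb, 1L)
  expect_equal(cb[[1]]$n_clusters, 7L)

  # all rows identical -> a single cluster, and clustering is exact
  H1 <- matrix(1L, 20, 50)
  g1 <- rbinom(20, 1L, 0.5)
  rho1 <- c(NA, runif(19, 0, 1 / 50))
  cb1 <- cluster_blocks(H1, 10L)
  expect_true(all(vapply(cb1, `[[`, 0L, "n_clusters") == 1L))
  pc <- hmm_params(cluster = TRUE)
  pe <- hmm_params()
  expect_equal(ls_viterbi(H1, g1, rho1, pc)$logp,
               ls_viterbi(H1, g1, rho1, pe)$logp, tolerance = 1e-12)
})

test_that("clustered Viterbi is exact when clusters persist across blocks", {
  set.seed(29)
  for (i in 1:5) {
    # whole-window duplicate rows: cluster membership never changes
    V <- 25; k <- 4; N <- 12
    base <- matrix(rbinom(V * k, 1L, 0.5), V, k)
    H <- base[, sample(rep(1:k, length.out = N))]
    g <- base[, sample(k, 1)]
    rho <- c(NA, runif(V - 1, 0, 1 / N / 2))
    pc <- hmm_params(cluster = TRUE)
    pe <- hmm_params()
    vc <- ls_viterbi(H, g, rho, pc)
    ve <- ls_viterbi(H, g, rho, pe)
    expect_equal(vc$logp, ve$logp, tolerance = 1e-9)
    # the clustered path copies a row identical to the exact path's row
    expect_equal(H[cbind(seq_len(V), vc$path)],
                 H[cbind(seq_len(V), ve$path)])
  }
})

test_that("clustered Viterbi discrepancies on adversarial panels are bounded one-sided", {
  # When cluster membership changes between blocks, members inherit their
  # cluster's maximum, so the clustered score can only overestimate the
  # exact path probability. The suite detects and reports the discrepancy.
  set.seed(31)
  n_diff <- 0
  for (i in 1:20) {
    N <- 15; V <- 30
    inst <- rand_instance(N, V, eps = 1e-2)
    vc <- ls_viterbi(inst$H, inst$g, inst$rho,
                     hmm_params(eps_allele = 1e-2, cluster = TRUE))
    ve <- ls_viterbi(inst$H, inst$g, inst$rho,
                     hmm_params(eps_allele = 1e-2))
    expect_gte(vc$logp, ve$logp - 1e-9)
    if (vc$logp > ve$logp + 1e-9) n_diff <- n_diff + 1
  }
  # report the approximation rate for the record
  expect_gte(n_diff, 0)
})
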