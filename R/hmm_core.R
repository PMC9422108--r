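#' Li-Stephens HMM parameters
#'
#' Bundles the model parameters of the haplotype-copying HMM and the
#' numerical settings of its dynamic-programming engines.
#'
#' @param n_e Effective population size scaling the recombination
#'   probability. Default `1e4`, the exploration default used together with
#'   the default locality parameters.
#' @param eps_allele Allele (emission) error probability. Default `1e-4`.
#' @param domain Computation domain: `"scaled"` (linear values with periodic
#'   rescaling, the default and fast path) or `"log"` (all values held as
#'   logarithms).
#' @param scale_factor Multiplicative rescale step for the scaled-linear
#'   domain; default `exp(0.2)`. Results are invariant to this choice.
#' @param rescale_band Two magnitudes `(lower, upper)`; a DP column is
#'   rescaled by an integer power of `scale_factor` whenever its maximum
#'   leaves this band. Default `c(1e-30, 1e30)`.
#' @param morgans If `TRUE`, genetic distances are divided by 100 (cM to
#'   Morgans) inside the recombination-probability formula. Default `FALSE`:
#'   distances enter in centimorgans, matching the model as parameterized
#'   here; `n_e` must be interpreted accordingly.
#' @param cluster If `TRUE`, Viterbi uses haplotype block clustering
#'   (see [cluster_blocks()]), an approximation that can be much faster on
#'   large panels. Default `FALSE` (exact).
#' @param block_len Block length (typed variants) for clustering; default 10.
#'
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(n_e = 1e4, eps_allele = 1e-4,
                       domain = c("scaled", "log"),
                       scale_factor = exp(0.2),
                       rescale_band = c(1e-30, 1e30),
                       morgans = FALSE, cluster = FALSE, block_len = 10L) {
  domain <- match.arg(domain)
  stopifnot(n_e > 0, eps_allele > 0, eps_allele < 0.5, scale_factor > 1,
            length(rescale_band) == 2L, rescale_band[1] < rescale_band[2],
            block_len >= 1L)
  structure(list(n_e = n_e, eps_allele = eps_allele, domain = domain,
                 scale_factor = scale_factor, rescale_band = rescale_band,
                 morgans = morgans, cluster = isTRUE(cluster),
                 block_len = as.integer(block_len)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Li-Stephens HMM parameters\n",
      "  N_e = ", format(x$n_e), ", eps_allele = ", format(x$eps_allele),
      ", domain = ", x$domain,
      if (x$cluster) paste0(", clustered (block ", x$block_len, ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' Recombination probability between adjacent variants
#'
#' Per-state switch probability of the haplotype-copying chain between two
#' consecutive variants separated by genetic distance `delta_r`:
#' `(1/N) * (1 - exp(-4 * N_e * delta_r / N))`.
#'
#' @param delta_r Genetic distance between the variants (centimorgans,
#'   non-negative). Divided by 100 first when `morgans = TRUE`.
#' @param n_hap Number of reference haplotypes (states) `N`.
#' @param n_e Effective population size.
#' @param morgans Convert `delta_r` from cM to Morgans before use.
#' @return Probability of switching to any one *particular* other haplotype;
#'   the total switch probability is `(N - 1)` times this value.
#' @export
recomb_prob <- function(delta_r, n_hap, n_e, morgans = FALSE) {
  stopifnot(all(delta_r >= 0), n_hap >= 1, n_e > 0)
  if (morgans) delta_r <- delta_r / 100
  (1 / n_hap) * (1 - exp(-4 * n_e * delta_r / n_hap))
}

#' Probability of no recombination between adjacent variants
#'
#' Self-transition probability `1 - (N - 1) * p_r`, the complement of all
#' `N - 1` possible switches.
#'
#' @param p_r Per-state recombination probability from [recomb_prob()].
#' @param n_hap Number of reference haplotypes `N`.
#' @export
no_recomb_prob <- function(p_r, n_hap) {
  stopifnot(all(p_r >= 0))
  if (any(p_r > 1 / n_hap + 1e-12))
    stop("recombination probability exceeds 1/N; self-transition would be negative",
         call. = FALSE)
  1 - (n_hap - 1) * p_r
}

#' Transition probability between haplotype states
#'
#' Two-valued transition kernel: the self-transition probability when the
#' copied haplotype is unchanged, the recombination probability otherwise.
#'
#' @param p_r,p_nr Per-step recombination / no-recombination probabilities.
#' @param from,to State indices (any equal-length vectors).
#' @export
transition_prob <- function(p_r, p_nr, from, to) {
  ifelse(from == to, p_nr, p_r)
}

#' Emission probability of an observed allele from a haplotype state
#'
#' `1 - eps` when the panel haplotype carries the observed allele, `eps`
#' otherwise.
#'
#' @param g Observed allele(s) in `{0,1}`.
#' @param hap_allele Panel allele(s) in `{0,1}`.
#' @param eps Allele error probability.
#' @export
emission_prob <- function(g, hap_allele, eps) {
  ifelse(hap_allele == g, 1 - eps, eps)
}

# Validate and unpack the (H, g, rho) window inputs shared by the engines.
# H: V x N 0/1 matrix (rows = typed variants in window order, cols = states);
# g: length-V observed alleles; rho: length-V per-step recombination
# probabilities (rho[1] is unused, the start is uniform).
check_engine_input <- function(H, g, rho) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  V <- nrow(H); N <- ncol(H)
  if (V < 1L) stop("empty window", call. = FALSE)
  if (N < 1L) stop("empty panel", call. = FALSE)
  g <- as.integer(g)
  if (length(g) != V) stop("observed allele sequence length != window length",
                           call. = FALSE)
  if (anyNA(g) || !all(g %in% c(0L, 1L)))
    stop("observed alleles must be 0/1 (typed variants only)", call. = FALSE)
  rho <- as.numeric(rho)
  if (length(rho) != V) stop("rho must have one entry per window variant",
                             call. = FALSE)
  list(H = H, g = g, rho = rho, V = V, N = N)
}

#' Forward variables of the windowed Li-Stephens HMM
#'
#' Computes the forward dynamic-programming matrix over a window of typed
#' variants: `F(1, a) = (1/N) e_1(g_1, a)` and
#' `F(j, a) = e_j(g_j, a) * (p_nr(j) F(j-1, a) + p_r(j) sum_b F(j-1, b))`,
#' the factorized O(N)-per-step form of the full transition sum, which is
#' exact because the transition kernel takes only two values.
#'
#' @param H Window panel matrix, `V x N` of 0/1 alleles (rows = typed
#'   variants in genetic order, columns = reference haplotypes/states).
#' @param g Observed query alleles over the window (length `V`, 0/1).
#' @param rho Per-step recombination probabilities (length `V`; `rho[1]`
#'   unused).
#' @param params [hmm_params()].
#' @return List with `logmat` (`V x N` matrix of log forward variables) and
#'   `loglik` (log total window likelihood, including the uniform terminal
#'   boundary `1/N`).
#' @export
ls_forward <- function(H, g, rho, params = hmm_params()) {
  x <- check_engine_input(H, g, rho)
  logmat <- if (params$domain == "scaled") {
    cpp_ls_forward(x$H, x$g, x$rho, params$eps_allele,
                   log(params$scale_factor),
                   params$rescale_band[1], params$rescale_band[2])
  } else {
    r_ls_forward_log(x$H, x$g, x$rho, params$eps_allele)
  }
  list(logmat = logmat,
       loglik = logsumexp(logmat[x$V, ]) - log(x$N))
}

#' Backward variables of the windowed Li-Stephens HMM
#'
#' Mirror of [ls_forward()]: `B(V, a) = 1/N` (uniform terminal boundary) and
#' `B(j, a) = p_nr(j+1) e_{j+1}(a) B(j+1, a) +
#'            p_r(j+1) sum_b e_{j+1}(b) B(j+1, b)`.
#'
#' @inheritParams ls_forward
#' @return List with `logmat` (`V x N` log backward variables).
#' @export
ls_backward <- function(H, g, rho, params = hmm_params()) {
  x <- check_engine_input(H, g, rho)
  logmat <- if (params$domain == "scaled") {
    cpp_ls_backward(x$H, x$g, x$rho, params$eps_allele,
                    log(params$scale_factor),
                    params$rescale_band[1], params$rescale_band[2])
  } else {
    r_ls_backward_log(x$H, x$g, x$rho, params$eps_allele)
  }
  list(logmat = logmat)
}

#' Viterbi recursion and traceback over a window
#'
#' Maximum-probability mosaic path through the reference haplotypes:
#' `V(j, a) = e_j(g_j, a) * max(p_nr(j) V(j-1, a), p_r(j) max_b V(j-1, b))`
#' with uniform start boundary. Ties are broken deterministically: the
#' self-transition is preferred over a recombination on exact ties, and the
#' lowest state index wins among equal maxima.
#'
#' @inheritParams ls_forward
#' @return List with `logmat` (`V x N` log Viterbi variables), `path`
#'   (length-`V` integer state sequence, 1-based haplotype indices) and
#'   `logp` (log probability of the best path, including the uniform
#'   terminal boundary `1/N` so it is comparable to [ls_forward()]'s
#'   `loglik`).
#' @export
ls_viterbi <- function(H, g, rho, params = hmm_params()) {
  x <- check_engine_input(H, g, rho)
  if (params$cluster) {
    return(r_ls_viterbi_clustered(x$H, x$g, x$rho, params))
  }
  if (params$domain == "scaled") {
    res <- cpp_ls_viterbi(x$H, x$g, x$rho, params$eps_allele,
                          log(params$scale_factor),
                          params$rescale_band[1], params$rescale_band[2])
    list(logmat = res$logmat, path = as.integer(res$path),
         logp = res$logp - log(x$N))
  } else {
    r_ls_viterbi_log(x$H, x$g, x$rho, params$eps_allele)
  }
}

# ---- pure-R log-domain engines -------------------------------------------
# These hold every value as a logarithm; slower than the scaled-linear C++
# path but immune to under/overflow by construction. They double as an
# independent numerical route for the scaled engines.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

r_ls_forward_log <- function(H, g, rho, eps) {
  V <- nrow(H); N <- ncol(H)
  logmat <- matrix(NA_real_, V, N)
  le <- function(j) log(ifelse(H[j, ] == g[j], 1 - eps, eps))
  logmat[1, ] <- -log(N) + le(1)
  if (V > 1L) for (j in 2:V) {
    pr <- rho[j]; pnr <- 1 - (N - 1) * pr
    S <- logsumexp(logmat[j - 1, ])
    # sum over b of tau(b -> a) F(b) = (pnr - pr) F(a) + pr S
    a1 <- log(pnr - pr) + logmat[j - 1, ]
    a2 <- log(pr) + S
    m <- pmax(a1, a2)
    logmat[j, ] <- le(j) + m + log1p(exp(pmin(a1, a2) - m))
  }
  logmat
}

r_ls_backward_log <- function(H, g, rho, eps) {
  V <- nrow(H); N <- ncol(H)
  logmat <- matrix(NA_real_, V, N)
  logmat[V, ] <- -log(N)
  if (V > 1L) for (j in (V - 1):1) {
    pr <- rho[j + 1]; pnr <- 1 - (N - 1) * pr
    w <- log(ifelse(H[j + 1, ] == g[j + 1], 1 - eps, eps)) + logmat[j + 1, ]
    S <- logsumexp(w)
    a1 <- log(pnr - pr) + w
    a2 <- log(pr) + S
    m <- pmax(a1, a2)
    logmat[j, ] <- m + log1p(exp(pmin(a1, a2) - m))
  }
  logmat
}

r_ls_viterbi_log <- function(H, g, rho, eps) {
  V <- nrow(H); N <- ncol(H)
  logmat <- matrix(NA_real_, V, N)
  bp <- matrix(NA_integer_, V, N)
  le <- function(j) log(ifelse(H[j, ] == g[j], 1 - eps, eps))
  logmat[1, ] <- -log(N) + le(1)
  if (V > 1L) for (j in 2:V) {
    pr <- rho[j]; pnr <- 1 - (N - 1) * pr
    best_prev <- which.max(logmat[j - 1, ])  # lowest index on ties
    stay <- log(pnr) + logmat[j - 1, ]
    jump <- log(pr) + logmat[j - 1, best_prev]
    take_stay <- stay >= jump                 # self preferred on exact ties
    logmat[j, ] <- le(j) + ifelse(take_stay, stay, jump)
    bp[j, ] <- ifelse(take_stay, seq_len(N), best_prev)
  }
  path <- integer(V)
  path[V] <- which.max(logmat[V, ])
  if (V > 1L) for (j in V:2) path[j - 1] <- bp[j, path[j]]
  list(logmat = logmat, path = path,
       logp = max(logmat[V, ]) - log(N))
}

# Naive O(N^2)-per-step reference recursions over the full transition
# matrix. Used as an internal cross-check of the factorized engines.
r_ls_forward_naive <- function(H, g, rho, eps) {
  V <- nrow(H); N <- ncol(H)
  Fm <- matrix(NA_real_, V, N)
  Fm[1, ] <- (1 / N) * ifelse(H[1, ] == g[1], 1 - eps, eps)
  if (V > 1L) for (j in 2:V) {
    pr <- rho[j]; pnr <- 1 - (N - 1) * pr
    Tm <- matrix(pr, N, N); diag(Tm) <- pnr      # Tm[b, a] = tau(b -> a)
    Fm[j, ] <- ifelse(H[j, ] == g[j], 1 - eps, eps) *
      as.numeric(crossprod(Tm, Fm[j - 1, ]))
  }
  Fm
}

r_ls_backward_naive <- function(H, g, rho, eps) {
  V <- nrow(H); N <- ncol(H)
  Bm <- matrix(NA_real_, V, N)
  Bm[V, ] <- 1 / N
  if (V > 1L) for (j in (V - 1):1) {
    pr <- rho[j + 1]; pnr <- 1 - (N - 1) * pr
    Tm <- matrix(pr, N, N); diag(Tm) <- pnr
    e <- ifelse(H[j + 1, ] == g[j + 1], 1 - eps, eps)
    Bm[j, ] <- as.numeric(Tm %*% (e * Bm[j + 1, ]))
  }
  Bm
}

r_ls_viterbi_naive <- function(H, g, rho, eps) {
  V <- nrow(H); N <- ncol(H)
  Vm <- matrix(NA_real_, V, N)
  Vm[1, ] <- (1 / N) * ifelse(H[1, ] == g[1], 1 - eps, eps)
  if (V > 1L) for (j in 2:V) {
    pr <- rho[j]; pnr <- 1 - (N - 1) * pr
    e <- ifelse(H[j, ] == g[j], 1 - eps, eps)
    for (a in seq_len(N)) {
      tr <- rep(pr, N); tr[a] <- pnr
      Vm[j, a] <- e[a] * max(tr * Vm[j - 1, ])
    }
  }
  Vm
}

# ---- haplotype block clustering ------------------------------------------

#' Cluster reference haplotypes in blocks of typed variants
#'
#' Within each consecutive block of `block_len` typed variants, haplotypes
#' that carry the identical allele string are grouped into one cluster; the
#' DP recursion can then run over clusters instead of haplotypes. Over short
#' stretches the number of distinct local haplotypes grows much more slowly
#' than the panel size, so this shrinks the effective state space.
#'
#' @param H Window panel matrix (`V x N`, 0/1).
#' @param block_len Number of typed variants per block (default 10).
#' @return Object of class `cluster_blocks`: list of blocks, each with
#'   `rows` (variant rows of the block), `id` (length-`N` cluster index per
#'   haplotype) and `n_clusters`.
#' @export
cluster_blocks <- function(H, block_len = 10L) {
  H <- as.matrix(H)
  V <- nrow(H)
  starts <- seq(1L, V, by = as.integer(block_len))
  blocks <- lapply(starts, function(s) {
    rows <- s:min(s + block_len - 1L, V)
    key <- apply(H[rows, , drop = FALSE], 2, paste0, collapse = "")
    id <- match(key, unique(key))
    list(rows = rows, id = id, n_clusters = max(id))
  })
  structure(blocks, class = "cluster_blocks")
}

# Viterbi over haplotype clusters. At block entry each cluster takes the max
# of its members' values; within the block the recursion runs at cluster
# level (clusters share their allele string exactly, so emissions are
# cluster-wide); at block exit every member inherits its cluster's value.
# The inheritance step makes this an approximation whenever cluster
# membership changes between adjacent blocks.
r_ls_viterbi_clustered <- function(H, g, rho, params) {
  V <- nrow(H); N <- ncol(H)
  eps <- params$eps_allele
  blocks <- cluster_blocks(H, params$block_len)
  logv <- rep(-log(N), N)          # virtual start values per haplotype
  logmat <- matrix(NA_real_, V, N)
  state_of <- integer(V)           # representative haplotype per step
  first <- TRUE
  for (bl in blocks) {
    id <- bl$id
    nc <- bl$n_clusters
    rep_hap <- match(seq_len(nc), id)  # lowest-index member per cluster
    cl <- vapply(seq_len(nc), function(c) max(logv[id == c]), 0)
    for (j in bl$rows) {
      e <- log(ifelse(H[j, rep_hap] == g[j], 1 - eps, eps))
      if (first) {
        cl <- cl + e
        first <- FALSE
      } else {
        pr <- rho[j]; pnr <- 1 - (N - 1) * pr
        best <- max(cl)
        stay <- log(pnr) + cl
        jump <- log(pr) + best
        cl <- e + pmax(stay, jump)
      }
      logmat[j, ] <- cl[id]
      state_of[j] <- rep_hap[which.max(cl)]
    }
    logv <- cl[id]                 # members inherit their cluster's value
  }
  list(logmat = logmat, path = state_of, logp = max(logv) - log(N))
}
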