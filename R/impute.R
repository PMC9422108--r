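#' Allele scores at an untyped target from forward-backward variables
#'
#' Marginalizes the posterior of the copied haplotype at the typed variant
#' `k` flanking the target on the left (the anchor of the window posterior:
#' the product `F(k, a) B(k, a)` accounts for every typed variant in the
#' window), restricted to states whose panel haplotype carries allele `t`
#' at the target. When the target precedes all window members, `k = 1` is
#' used, which folds the uniform start boundary into the missing forward
#' factor; when it follows all members, `k` is the last member and the
#' uniform terminal boundary of the backward variables plays the same role.
#'
#' @param forward,backward Results of [ls_forward()] / [ls_backward()] on
#'   the window.
#' @param window The [build_window()] result.
#' @param target_alleles Panel alleles at the target site (length-`N` 0/1
#'   vector, one per haplotype/state).
#' @return Named numeric vector `c("0" = s0, "1" = s1)` of unnormalized
#'   allele scores on an arbitrary common scale (only their ratio is
#'   meaningful); pass to [normalize_alleles()].
#' @export
fb_allele_probs <- function(forward, backward, window, target_alleles) {
  k <- window$flank[["left"]]
  if (is.na(k)) k <- 1L
  lw <- forward$logmat[k, ] + backward$logmat[k, ]
  ls0 <- if (any(target_alleles == 0L))
    logsumexp(lw[target_alleles == 0L]) else -Inf
  ls1 <- if (any(target_alleles == 1L))
    logsumexp(lw[target_alleles == 1L]) else -Inf
  m <- max(ls0, ls1)
  if (!is.finite(m)) m <- 0
  c("0" = exp(ls0 - m), "1" = exp(ls1 - m))
}

#' Normalize a pair of allele scores to probabilities
#'
#' `P'(t) = s_t / (s_0 + s_1)`. If both scores are zero the result falls
#' back to the uninformative `(0.5, 0.5)` with a warning.
#'
#' @param scores Non-negative numeric pair (allele 0 score, allele 1 score).
#' @return Named numeric pair summing to 1.
#' @export
normalize_alleles <- function(scores) {
  if (any(scores < 0)) stop("negative allele score", call. = FALSE)
  tot <- sum(scores)
  if (tot == 0) {
    warning("both allele scores are zero; falling back to (0.5, 0.5)")
    return(c("0" = 0.5, "1" = 0.5))
  }
  setNames(as.numeric(scores) / tot, c("0", "1"))
}

#' Combine per-haplotype allele probabilities into genotype probabilities
#'
#' For normalized allele probabilities `p` (haplotype 0) and `q`
#' (haplotype 1): `P(G=0) = p0 q0`, `P(G=1) = p0 q1 + p1 q0`,
#' `P(G=2) = p1 q1`; the three sum to 1 by construction.
#'
#' @param p_h0,p_h1 Normalized allele-probability pairs from
#'   [normalize_alleles()] for the two parental copies.
#' @return Numeric triple `(P(G=0), P(G=1), P(G=2))`.
#' @export
genotype_probs <- function(p_h0, p_h1) {
  c(p_h0[[1]] * p_h1[[1]],
    p_h0[[1]] * p_h1[[2]] + p_h0[[2]] * p_h1[[1]],
    p_h0[[2]] * p_h1[[2]])
}

#' Allele call at an untyped target from a Viterbi path
#'
#' Reads the allele carried at the target by the haplotype that the
#' maximum-likelihood mosaic path copies at the typed window member nearest
#' to the target in genetic distance (ties resolved to the left member).
#' A confidence score is attached by normalizing, over the two alleles, the
#' maximum Viterbi variable among states consistent with each allele at the
#' target — a reporting convention, since the Viterbi path itself carries
#' no per-site probability.
#'
#' @param vit [ls_viterbi()] result for the window.
#' @param window The [build_window()] result.
#' @param sites Annotated site table.
#' @param target_alleles Panel alleles at the target (length `N`).
#' @return List with `allele` (0/1 hard call) and `probs` (named score
#'   pair summing to 1).
#' @export
viterbi_allele <- function(vit, window, sites, target_alleles) {
  d <- abs(sites$cm[window$members] - sites$cm[window$target])
  k <- which.min(d)  # first minimum = left member on ties
  allele <- target_alleles[vit$path[k]]
  lv <- vit$logmat[k, ]
  s0 <- if (any(target_alleles == 0L)) max(lv[target_alleles == 0L]) else -Inf
  s1 <- if (any(target_alleles == 1L)) max(lv[target_alleles == 1L]) else -Inf
  m <- max(s0, s1)
  probs <- normalize_alleles(c(exp(s0 - m), exp(s1 - m)))
  list(allele = allele, probs = probs)
}

#' Impute untyped variants with the vicinity-based Li-Stephens HMM
#'
#' For every untyped site and every query haplotype, builds the local
#' window of typed variants, runs the forward-backward and/or Viterbi
#' recursions against the reference panel over that window, converts the
#' result to allele probabilities, and combines the two parental copies of
#' each individual into genotype probabilities, dosages and hard calls.
#' Per-target failures (e.g. isolated targets with no typed variant in
#' reach) are logged and skipped without aborting the run.
#'
#' @param query A `query_haps` object ([read_query()] or
#'   [simulate_query()]).
#' @param panel A `ref_panel` ([read_panel()] or [simulate_panel()]).
#' @param gmap A `genetic_map` for the panel's chromosome, or `NULL` if
#'   `panel$sites` already carries a `cm` column.
#' @param config A [locality_config()].
#' @param params An [hmm_params()].
#' @param method `"fb"` (forward-backward posteriors, default),
#'   `"viterbi"`, or `"both"`.
#' @return An object of class `vicinity_imputation` with components
#'   `calls` (data.frame: one row per sample, untyped site and method, with
#'   per-haplotype alternate-allele probabilities `phap0`/`phap1`, hard
#'   haplotype alleles `hap0`/`hap1`, genotype probabilities
#'   `gp0`/`gp1`/`gp2`, `dosage`, hard genotype `hard`), `targets`
#'   (per-target log: window size, genetic span, status), plus the inputs'
#'   metadata. Supports `print()`, `summary()` and `as.data.frame()`.
#' @export
impute_genotypes <- function(query, panel, gmap = NULL,
                             config = locality_config(),
                             params = hmm_params(),
                             method = c("fb", "viterbi", "both")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "ref_panel"), inherits(query, "query_haps"))
  if (ncol(query$A) != ncol(panel$H))
    stop("query and panel site lists are not aligned", call. = FALSE)
  sites <- panel$sites
  sites$typed <- query$typed
  if (!is.null(gmap)) {
    sites <- annotate_sites(sites, gmap)
  } else if (is.null(sites$cm)) {
    stop("no genetic map: supply `gmap` or a panel with a `cm` site column",
         call. = FALSE)
  }
  config <- replace_ne(config, params)
  N <- nrow(panel$H)
  n_hap_rows <- nrow(query$A)
  M <- n_hap_rows / 2L
  do_fb <- method %in% c("fb", "both")
  do_vit <- method %in% c("viterbi", "both")

  n_t <- length(query$untyped)
  n_methods <- do_fb + do_vit
  cap <- n_t * M * n_methods
  acc <- list(sample = character(cap), site = integer(cap),
              method = character(cap), hap0 = integer(cap),
              hap1 = integer(cap), phap0 = numeric(cap),
              phap1 = numeric(cap), gp0 = numeric(cap), gp1 = numeric(cap),
              gp2 = numeric(cap))
  nrec <- 0L
  log_ntag <- integer(n_t); log_span <- rep(NA_real_, n_t)
  log_status <- character(n_t)
  ti <- 0L
  for (j in query$untyped) {
    ti <- ti + 1L
    w <- tryCatch({
      w <- build_window(j, sites, config)
      subsample_tags(w, config$ntag_max, sites)
    }, error = function(e) conditionMessage(e))
    if (is.character(w)) {
      log_status[ti] <- paste("skipped:", w)
      next
    }
    rho <- window_rho(w, sites, N, config$n_e, params$morgans)
    Hwin <- t(panel$H[, w$members, drop = FALSE])
    col_t <- panel$H[, j]
    # per-haplotype alternate-allele posteriors for each method
    fb_p1 <- vit_p1 <- numeric(n_hap_rows)
    vit_call <- integer(n_hap_rows)
    for (r in seq_len(n_hap_rows)) {
      g <- query$A[r, w$members]
      if (do_fb) {
        fw <- ls_forward(Hwin, g, rho, params)
        bw <- ls_backward(Hwin, g, rho, params)
        fb_p1[r] <- normalize_alleles(fb_allele_probs(fw, bw, w, col_t))[[2]]
      }
      if (do_vit) {
        vt <- ls_viterbi(Hwin, g, rho, params)
        va <- viterbi_allele(vt, w, sites, col_t)
        vit_p1[r] <- va$probs[[2]]
        vit_call[r] <- va$allele
      }
    }
    for (i in seq_len(M)) {
      r0 <- 2L * i - 1L; r1 <- 2L * i
      if (do_fb) {
        nrec <- nrec + 1L
        acc$sample[nrec] <- query$samples[i]
        acc$site[nrec] <- j; acc$method[nrec] <- "FB"
        acc$hap0[nrec] <- as.integer(fb_p1[r0] > 0.5)
        acc$hap1[nrec] <- as.integer(fb_p1[r1] > 0.5)
        acc$phap0[nrec] <- fb_p1[r0]; acc$phap1[nrec] <- fb_p1[r1]
        acc$gp0[nrec] <- (1 - fb_p1[r0]) * (1 - fb_p1[r1])
        acc$gp1[nrec] <- (1 - fb_p1[r0]) * fb_p1[r1] +
          fb_p1[r0] * (1 - fb_p1[r1])
        acc$gp2[nrec] <- fb_p1[r0] * fb_p1[r1]
      }
      if (do_vit) {
        nrec <- nrec + 1L
        acc$sample[nrec] <- query$samples[i]
        acc$site[nrec] <- j; acc$method[nrec] <- "VIT"
        acc$hap0[nrec] <- vit_call[r0]; acc$hap1[nrec] <- vit_call[r1]
        acc$phap0[nrec] <- vit_p1[r0]; acc$phap1[nrec] <- vit_p1[r1]
        acc$gp0[nrec] <- (1 - vit_p1[r0]) * (1 - vit_p1[r1])
        acc$gp1[nrec] <- (1 - vit_p1[r0]) * vit_p1[r1] +
          vit_p1[r0] * (1 - vit_p1[r1])
        acc$gp2[nrec] <- vit_p1[r0] * vit_p1[r1]
      }
    }
    log_ntag[ti] <- length(w$members)
    log_span[ti] <- w$span
    log_status[ti] <- "ok"
  }
  calls <- if (nrec > 0L) {
    idx <- seq_len(nrec)
    s <- lapply(acc, `[`, idx)
    gpm <- cbind(s$gp0, s$gp1, s$gp2)
    data.frame(sample = s$sample, chrom = sites$chrom[s$site],
               pos = sites$pos[s$site],
               id = ifelse(is.na(sites$id[s$site]), ".", sites$id[s$site]),
               ref = sites$ref[s$site], alt = sites$alt[s$site],
               site = s$site, method = s$method,
               hap0 = s$hap0, hap1 = s$hap1,
               phap0 = s$phap0, phap1 = s$phap1,
               gp0 = s$gp0, gp1 = s$gp1, gp2 = s$gp2,
               dosage = s$gp1 + 2 * s$gp2,
               # FB: argmax of the genotype posterior; Viterbi: the path
               # alleles themselves are the call
               hard = ifelse(s$method == "VIT", s$hap0 + s$hap1,
                             max.col(gpm, ties.method = "first") - 1L),
               stringsAsFactors = FALSE)
  } else empty_calls()
  logs <- data.frame(site = query$untyped, pos = sites$pos[query$untyped],
                     n_tag = log_ntag, span = log_span,
                     status = log_status, stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 targets = logs,
                 sites = sites, method = method,
                 config = config, params = params,
                 n_hap = N, samples = query$samples),
            class = "vicinity_imputation")
}

# The locality config carries N_e for user convenience on the CLI; the HMM
# parameter object is authoritative when the two disagree.
replace_ne <- function(config, params) {
  config$n_e <- params$n_e
  config
}

empty_calls <- function() {
  data.frame(sample = character(), chrom = character(), pos = integer(),
             id = character(), ref = character(), alt = character(),
             site = integer(), method = character(), hap0 = integer(),
             hap1 = integer(), phap0 = numeric(), phap1 = numeric(),
             gp0 = numeric(), gp1 = numeric(), gp2 = numeric(),
             dosage = numeric(), hard = integer(), stringsAsFactors = FALSE)
}

#' @export
print.vicinity_imputation <- function(x, ...) {
  ok <- sum(x$targets$status == "ok")
  cat("Vicinity-based HMM imputation (", toupper(x$method), ")\n",
      "  ", length(x$samples), " samples, ", ok, " imputed targets",
      if (any(x$targets$status != "ok"))
        paste0(" (", sum(x$targets$status != "ok"), " skipped)") else "",
      ", panel of ", x$n_hap, " haplotypes\n",
      "  lw = ", x$config$lw, " cM, N_e = ", format(x$params$n_e),
      ", eps = ", format(x$params$eps_allele), "\n", sep = "")
  invisible(x)
}

#' @export
summary.vicinity_imputation <- function(object, ...) {
  calls <- object$calls
  by_m <- split(calls, calls$method)
  out <- lapply(by_m, function(d) {
    maxgp <- pmax(d$gp0, d$gp1, d$gp2)
    c(records = nrow(d),
      mean_max_gp = mean(maxgp),
      frac_confident = mean(maxgp > 0.99),
      mean_dosage = mean(d$dosage))
  })
  res <- list(method = object$method, per_method = out,
              targets = table(object$targets$status),
              mean_n_tag = mean(object$targets$n_tag[
                object$targets$status == "ok"]))
  class(res) <- "summary.vicinity_imputation"
  res
}

#' @export
print.summary.vicinity_imputation <- function(x, ...) {
  cat("Imputation summary (method: ", toupper(x$method), ")\n", sep = "")
  for (m in names(x$per_method)) {
    v <- x$per_method[[m]]
    cat(sprintf("  %s: %d records, mean max GP %.4f, %.1f%% with GP > 0.99\n",
                m, v[["records"]], v[["mean_max_gp"]],
                100 * v[["frac_confident"]]))
  }
  cat("  mean typed variants per window:",
      format(x$mean_n_tag, digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.vicinity_imputation <- function(x, ...) x$calls
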