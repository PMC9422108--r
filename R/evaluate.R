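#' Non-reference genotype concordance at one variant
#'
#' Among individuals whose known genotype is non-reference (> 0), the
#' fraction whose imputed hard call matches the known genotype exactly.
#' Returns `NA` when no individual carries a non-reference genotype.
#'
#' @param known Integer vector of true genotypes in `{0,1,2}`.
#' @param imputed Integer vector of imputed hard calls, aligned to `known`.
#' @return Concordance in `[0,1]`, or `NA` (denominator zero).
#' @export
non_ref_concordance <- function(known, imputed) {
  if (length(known) != length(imputed))
    stop("known and imputed genotype vectors differ in length", call. = FALSE)
  nr <- known > 0
  if (!any(nr)) return(NA_real_)
  mean(imputed[nr] == known[nr])
}

#' Genotype concordance at one variant
#'
#' Fraction of all individuals whose imputed hard call equals the known
#' genotype.
#'
#' @inheritParams non_ref_concordance
#' @export
genotype_concordance <- function(known, imputed) {
  if (length(known) != length(imputed))
    stop("known and imputed genotype vectors differ in length", call. = FALSE)
  mean(imputed == known)
}

#' Precision-recall curve for non-reference genotype calls
#'
#' Pools all (individual, variant) calls, ranks them by the probability of
#' the called genotype, and sweeps a descending threshold. At each
#' threshold, a positive prediction is a non-reference hard call with
#' called-genotype probability at or above the threshold; precision is the
#' fraction of those that match the known genotype exactly, and recall is
#' the number of correct non-reference calls over the number of known
#' non-reference genotypes.
#'
#' @param known Integer vector of true genotypes in `{0,1,2}`.
#' @param called Integer vector of hard calls.
#' @param prob Probability assigned to each hard call (e.g. its GP entry).
#' @return data.frame with columns `threshold`, `precision`, `recall`,
#'   one row per distinct probability value, sorted by descending
#'   threshold.
#' @export
pr_curve <- function(known, called, prob) {
  stopifnot(length(known) == length(called), length(called) == length(prob))
  n_pos <- sum(known > 0)
  thr <- sort(unique(prob), decreasing = TRUE)
  nonref <- called > 0
  correct <- nonref & (called == known)
  prec <- rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    sel <- prob >= thr[i] & nonref
    prec[i] <- if (any(sel)) mean(called[sel] == known[sel]) else NA_real_
    rec[i] <- if (n_pos > 0) sum(correct & prob >= thr[i]) / n_pos else NA_real_
  }
  data.frame(threshold = thr, precision = prec, recall = rec)
}

#' Minor allele frequencies of panel sites
#'
#' @param panel A `ref_panel`.
#' @return Numeric vector of per-site MAF computed from the panel's
#'   haplotype allele counts.
#' @export
panel_maf <- function(panel) {
  p <- colMeans(panel$H)
  pmin(p, 1 - p)
}

#' Stratify sites by minor allele frequency
#'
#' Assigns each MAF to one of four strata: very rare `[0, 0.005]`, rare
#' `(0.005, 0.01]`, uncommon `(0.01, 0.05]`, common `(0.05, 0.5]`; a value
#' on a boundary is assigned to the higher-MAF stratum (so MAF = 0.05 is
#' common). The coarse common/uncommon split at 0.05 is available via
#' `coarse = TRUE`.
#'
#' @param maf Numeric vector of minor allele frequencies.
#' @param coarse If `TRUE`, return only `"common"` (MAF >= 0.05) vs
#'   `"uncommon"`.
#' @return Factor of stratum labels.
#' @export
maf_stratify <- function(maf, coarse = FALSE) {
  stopifnot(all(maf >= 0 & maf <= 0.5 + 1e-12))
  if (coarse) {
    return(factor(ifelse(maf >= 0.05, "common", "uncommon"),
                  levels = c("uncommon", "common")))
  }
  # right = FALSE puts boundary values into the higher-MAF stratum
  cut(maf, breaks = c(-Inf, 0.005, 0.01, 0.05, Inf),
      labels = c("very_rare", "rare", "uncommon", "common"), right = FALSE)
}

#' MAF-stratified concordance report
#'
#' Joins imputed hard calls against known genotypes and reports, per
#' variant: panel MAF, MAF stratum, genotype concordance and non-reference
#' concordance. Precision-recall points (pooled over variants) are
#' attached per stratum.
#'
#' @param calls Imputation calls (`vicinity_imputation` object or its
#'   `calls` data.frame) for a single method.
#' @param truth Matrix of known genotypes (`individuals x sites`, values
#'   0/1/2) with columns indexed like the panel sites, or a data.frame with
#'   `sample`, `site`, `geno`.
#' @param panel The `ref_panel` used for imputation (MAF source).
#' @param method Which method's calls to evaluate if several are present.
#' @return List of class `concordance_report`: `per_variant` data.frame,
#'   `per_stratum` summary, and `pr` (per-stratum PR curves).
#' @export
concordance_report <- function(calls, truth, panel, method = "FB") {
  if (inherits(calls, "vicinity_imputation")) calls <- calls$calls
  calls <- calls[calls$method == method, , drop = FALSE]
  if (!nrow(calls)) stop("no calls for method ", method, call. = FALSE)
  if (is.matrix(truth)) {
    samples <- rownames(truth)
    if (is.null(samples)) stop("truth matrix needs sample rownames",
                               call. = FALSE)
    ij <- cbind(match(calls$sample, samples), calls$site)
    if (anyNA(ij[, 1])) stop("sample mismatch between calls and truth",
                             call. = FALSE)
    calls$known <- truth[ij]
  } else {
    key <- paste(truth$sample, truth$site)
    hit <- match(paste(calls$sample, calls$site), key)
    if (anyNA(hit)) stop("sample/site mismatch between calls and truth",
                         call. = FALSE)
    calls$known <- truth$geno[hit]
  }
  maf <- panel_maf(panel)
  per_variant <- do.call(rbind, lapply(split(calls, calls$site), function(d) {
    s <- d$site[1]
    data.frame(site = s, pos = d$pos[1], maf = maf[s],
               stratum = as.character(maf_stratify(maf[s])),
               concordance = genotype_concordance(d$known, d$hard),
               nr_concordance = non_ref_concordance(d$known, d$hard),
               stringsAsFactors = FALSE)
  }))
  per_variant <- per_variant[order(per_variant$site), , drop = FALSE]
  rownames(per_variant) <- NULL
  calls$stratum <- as.character(maf_stratify(maf[calls$site]))
  calls$called_prob <- ifelse(calls$hard == 0L, calls$gp0,
                              ifelse(calls$hard == 1L, calls$gp1, calls$gp2))
  per_stratum <- do.call(rbind, lapply(split(per_variant,
                                             per_variant$stratum), function(d)
    data.frame(stratum = d$stratum[1], n_variants = nrow(d),
               mean_concordance = mean(d$concordance),
               mean_nr_concordance = mean(d$nr_concordance, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(per_stratum) <- NULL
  pr <- lapply(split(calls, calls$stratum), function(d)
    pr_curve(d$known, d$hard, d$called_prob))
  structure(list(per_variant = per_variant, per_stratum = per_stratum,
                 pr = pr, method = method),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance report (", x$method, "), ",
      nrow(x$per_variant), " variants\n", sep = "")
  print(x$per_stratum, row.names = FALSE)
  invisible(x)
}

#' Write a concordance report to tab-delimited files
#'
#' @param report A [concordance_report()].
#' @param prefix Output path prefix; writes `<prefix>.variants.tsv`,
#'   `<prefix>.strata.tsv` and `<prefix>.pr.tsv`.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, prefix) {
  p1 <- paste0(prefix, ".variants.tsv")
  p2 <- paste0(prefix, ".strata.tsv")
  p3 <- paste0(prefix, ".pr.tsv")
  write.table(report$per_variant, p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$per_stratum, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pr <- do.call(rbind, lapply(names(report$pr), function(s)
    cbind(stratum = s, report$pr[[s]])))
  write.table(pr, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
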