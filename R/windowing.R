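#' Locality configuration for vicinity-based imputation
#'
#' Parameters that define the local window of typed variants used to impute
#' each untyped target.
#'
#' @param lw Total window length in centimorgans; the window spans `lw/2` on
#'   each side of its center. Default 0.3 cM.
#' @param lc2t Maximum target-to-center genetic distance in cM; the window
#'   center may be offset from the target by at most this much. Default
#'   0.05 cM.
#' @param ntag_max Maximum number of typed variants per window; windows with
#'   more are subsampled by uniform striding (see [subsample_tags()]).
#'   Default 10000, i.e. effectively all typed variants for sub-cM windows.
#' @param n_e Effective population size used in the transition
#'   probabilities. Default `1e4`.
#' @param offset Signed genetic offset (cM) of the window center from the
#'   target; must satisfy `|offset| <= lc2t`. Default 0 (target centered).
#' @param profile Optional preset: `"validation"` sets
#'   `(lw, n_e, lc2t, ntag_max) = (0.5, 1e3, 0.02, 1000)`, a tighter tuple
#'   suited to held-out validation; any explicitly supplied argument still
#'   wins over the preset.
#'
#' @return An object of class `locality_config`.
#' @export
locality_config <- function(lw = 0.3, lc2t = 0.05, ntag_max = 10000L,
                            n_e = 1e4, offset = 0, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, "validation")
    if (missing(lw)) lw <- 0.5
    if (missing(n_e)) n_e <- 1e3
    if (missing(lc2t)) lc2t <- 0.02
    if (missing(ntag_max)) ntag_max <- 1000L
  }
  stopifnot(lw > 0, lc2t >= 0, lc2t < lw / 2, ntag_max >= 2L, n_e > 0,
            abs(offset) <= lc2t + 1e-12)
  structure(list(lw = lw, lc2t = lc2t, ntag_max = as.integer(ntag_max),
                 n_e = n_e, offset = offset),
            class = "locality_config")
}

#' @export
print.locality_config <- function(x, ...) {
  cat("Locality config: lw = ", x$lw, " cM, lc2t = ", x$lc2t,
      " cM (offset ", x$offset, "), ntag_max = ", x$ntag_max,
      ", N_e = ", format(x$n_e), "\n", sep = "")
  invisible(x)
}

#' Build the local window of typed variants for one untyped target
#'
#' Selects the typed variants whose genetic position lies within
#' `[c - lw/2, c + lw/2]`, where the center `c` is the target's genetic
#' position plus the configured offset. Windows that run past the first or
#' last typed variant on the chromosome are returned as-is with truncation
#' flags.
#'
#' @param target Index (into `sites`) of the untyped target variant.
#' @param sites Annotated site table (data.frame with `pos`, `cm`, `typed`).
#' @param cfg A [locality_config()].
#' @return Object of class `impute_window`: list with `target`, `members`
#'   (site indices of the window's typed variants, in order), `flank`
#'   (indices within `members` of the typed variants immediately left/right
#'   of the target, `NA` when absent), `span` (genetic span in cM),
#'   `truncated` (named logical, left/right), `rho` (per-step recombination
#'   probabilities, filled by the caller's engine via [window_rho()]).
#' @export
build_window <- function(target, sites, cfg = locality_config()) {
  stopifnot(is.data.frame(sites), all(c("pos", "cm", "typed") %in% names(sites)))
  if (isTRUE(sites$typed[target]))
    stop("target site ", target, " is typed, not an imputation target",
         call. = FALSE)
  typed_idx <- which(sites$typed)
  if (!length(typed_idx)) stop("no typed sites", call. = FALSE)
  ctr <- sites$cm[target] + cfg$offset
  lo <- ctr - cfg$lw / 2
  hi <- ctr + cfg$lw / 2
  cm_t <- sites$cm[typed_idx]
  # 1e-9 cM slack so boundary members are kept under fp rounding
  inside <- cm_t >= lo - 1e-9 & cm_t <= hi + 1e-9
  members <- typed_idx[inside]
  if (!length(members))
    stop("isolated target: no typed variant within ", cfg$lw,
         " cM window of site ", target, call. = FALSE)
  left <- which(sites$pos[members] < sites$pos[target])
  flank <- c(left = if (length(left)) max(left) else NA_integer_,
             right = if (length(left) < length(members))
               length(left) + 1L else NA_integer_)
  structure(list(
    target = target,
    members = members,
    flank = flank,
    span = diff(range(sites$cm[members])),
    truncated = c(left = lo < min(cm_t), right = hi > max(cm_t))
  ), class = "impute_window")
}

#' Subsample a window's typed variants to a maximum count
#'
#' When a window holds more than `ntag_max` typed variants, every
#' `ceiling(n/ntag_max)`-th member is kept by uniform striding starting at
#' the first member. The two typed variants flanking the target are always
#' retained (they anchor the posterior at the target), so the final count
#' can exceed `ntag_max` by at most two.
#'
#' @param window An [build_window()] result.
#' @param ntag_max Maximum typed variants to keep.
#' @param sites The site table the window was built from (needed to restore
#'   the flank bookkeeping).
#' @return The window, possibly with fewer members.
#' @export
subsample_tags <- function(window, ntag_max, sites) {
  n <- length(window$members)
  if (n <= ntag_max) return(window)
  stride <- ceiling(n / ntag_max)
  keep <- seq(1L, n, by = stride)
  keep <- sort(unique(c(keep, window$flank[!is.na(window$flank)])))
  members <- window$members[keep]
  left <- which(sites$pos[members] < sites$pos[window$target])
  window$members <- members
  window$flank <- c(left = if (length(left)) max(left) else NA_integer_,
                    right = if (length(left) < length(members))
                      length(left) + 1L else NA_integer_)
  window$span <- diff(range(sites$cm[members]))
  window
}

#' Per-step recombination probabilities for a window
#'
#' @param window An [build_window()] result.
#' @param sites Annotated site table.
#' @param n_hap Panel haplotype count `N`.
#' @param n_e Effective population size.
#' @param morgans Passed to [recomb_prob()].
#' @return Numeric vector, one entry per window member; the first entry is
#'   `NA` (the chain starts uniform, no incoming transition).
#' @export
window_rho <- function(window, sites, n_hap, n_e, morgans = FALSE) {
  cm <- sites$cm[window$members]
  c(NA_real_, recomb_prob(diff(cm), n_hap, n_e, morgans))
}

#' @export
print.impute_window <- function(x, ...) {
  cat("Imputation window: target site ", x$target, ", ",
      length(x$members), " typed members, span ",
      format(x$span, digits = 4), " cM",
      if (any(x$truncated)) paste0(" [truncated ",
        paste(names(x$truncated)[x$truncated], collapse = "+"), "]") else "",
      "\n", sep = "")
  invisible(x)
}
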