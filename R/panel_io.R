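#' Read a phased reference haplotype panel from VCF
#'
#' Loads a VCF of fully phased, non-missing genotypes and converts it to a
#' haplotype matrix: each sample contributes two rows (the left and right
#' allele of its `GT` field, in that order), each retained record one
#' column. Multi-allelic records and indels are dropped with a message;
#' only biallelic SNVs enter the panel.
#'
#' @param path Path to the panel VCF (plain text or bgzip).
#' @return An object of class `ref_panel`: list with `H` (`N x V` 0/1
#'   integer matrix of haplotypes), `sites` (data.frame `chrom`, `pos`,
#'   `id`, `ref`, `alt`), `samples`, and `dropped` (count of filtered
#'   records). Haplotype row `2i - 1` is sample `i`'s left allele, row `2i`
#'   its right allele.
#' @export
read_panel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- is_biallelic_snv(fix$REF, fix$ALT)
  dropped <- sum(!keep)
  if (dropped) message("read_panel: dropped ", dropped,
                       " multi-allelic/indel record(s)")
  if (!any(keep)) stop("no biallelic SNVs in panel '", path, "'",
                       call. = FALSE)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  bad <- which(is.na(gt) | !grepl("^[01]\\|[01]$", gt), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("panel genotype not phased/complete at ", fix$CHROM[bad[1, 1]], ":",
         fix$POS[bad[1, 1]], " sample ", colnames(gt)[bad[1, 2]],
         " (GT '", gt[bad[1, 1], bad[1, 2]], "')", call. = FALSE)
  }
  H <- gt_to_haps(gt)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  structure(list(H = H, sites = sites, samples = colnames(gt),
                 dropped = dropped),
            class = "ref_panel")
}

is_biallelic_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

# V x M matrix of "a|b" strings -> (2M) x V 0/1 haplotype matrix,
# rows ordered sample-major (left allele then right allele).
gt_to_haps <- function(gt) {
  left <- substr(gt, 1L, 1L)
  right <- substr(gt, 3L, 3L)
  V <- nrow(gt); M <- ncol(gt)
  H <- matrix(NA_integer_, nrow = 2L * M, ncol = V)
  H[seq(1L, 2L * M, by = 2L), ] <- t(matrix(as.integer(left), V, M))
  H[seq(2L, 2L * M, by = 2L), ] <- t(matrix(as.integer(right), V, M))
  H
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("Reference panel: ", nrow(x$H), " haplotypes (",
      length(x$samples), " samples) x ", ncol(x$H), " biallelic SNVs on ",
      paste(unique(x$sites$chrom), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Read phased query genotypes and align them to a panel
#'
#' Reads the query VCF, aligns its records to the panel's site list by
#' `(chromosome, position, ref, alt)` — query records absent from the panel
#' (including allele-swapped records) are dropped with a warning — and
#' marks panel sites with no typed query record as untyped. An optional
#' typed-position list (array positions) forces every site outside the list
#' to untyped as well.
#'
#' @param path Path to the query VCF; genotypes at typed sites must be
#'   phased (`a|b`).
#' @param panel A `ref_panel` from [read_panel()].
#' @param typed_positions Optional integer vector of base-pair positions
#'   (or a data.frame with a `pos` column) defining the array's typed
#'   positions.
#' @return Object of class `query_haps`: list with `A` (`2M x V` allele
#'   matrix aligned to the panel's site columns, `NA` at untyped sites),
#'   `samples`, `untyped` (panel site indices being imputed), `typed`
#'   (logical per panel site).
#' @export
read_query <- function(path, panel, typed_positions = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  key_q <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT)
  key_p <- paste(panel$sites$chrom, panel$sites$pos,
                 panel$sites$ref, panel$sites$alt)
  hit <- match(key_q, key_p)
  if (any(is.na(hit)))
    warning("read_query: dropped ", sum(is.na(hit)),
            " query record(s) not matching the panel by (chrom,pos,ref,alt)")
  if (!any(!is.na(hit))) stop("zero overlapping typed sites between query '",
                              path, "' and panel", call. = FALSE)
  gt <- gt[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  V <- nrow(panel$sites)
  M <- ncol(gt)
  A <- matrix(NA_integer_, nrow = 2L * M, ncol = V)
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  site_missing <- apply(miss, 1, all)
  site_present <- apply(miss, 1, any)
  mixed <- which(site_present & !site_missing)
  if (length(mixed))
    stop("query site at ", fix$POS[mixed[1]],
         " is missing for some but not all individuals; sites must be ",
         "typed for everyone or untyped for everyone", call. = FALSE)
  ok <- !site_missing
  if (any(ok)) {
    sub <- gt[ok, , drop = FALSE]
    badm <- !grepl("^[01]\\|[01]$", sub)
    dim(badm) <- dim(sub)
    bad <- which(badm, arr.ind = TRUE)
    if (nrow(bad))
      stop("query genotype not phased at typed site ",
           fix$POS[which(ok)[bad[1, 1]]], " (GT '",
           sub[bad[1, 1], bad[1, 2]], "')", call. = FALSE)
    A[, hit[ok]] <- gt_to_haps(sub)
  }
  typed <- logical(V)
  typed[hit[ok]] <- TRUE
  if (!is.null(typed_positions)) {
    if (is.data.frame(typed_positions)) typed_positions <- typed_positions$pos
    mask <- panel$sites$pos %in% as.integer(typed_positions)
    A[, typed & !mask] <- NA_integer_
    typed <- typed & mask
  }
  if (!any(typed)) stop("zero typed sites after applying typed-position list",
                        call. = FALSE)
  structure(list(A = A, samples = colnames(gt),
                 untyped = which(!typed), typed = typed),
            class = "query_haps")
}

#' @export
print.query_haps <- function(x, ...) {
  cat("Query haplotypes: ", length(x$samples), " samples, ",
      sum(x$typed), " typed + ", length(x$untyped),
      " untyped sites\n", sep = "")
  invisible(x)
}

#' Read a plain-text typed-position list
#'
#' One `chromosome position` pair per whitespace-delimited line (a bare
#' position column is also accepted).
#'
#' @param path File path.
#' @return Integer vector of positions.
#' @export
read_typed_positions <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  as.integer(tab[[ncol(tab)]])
}

#' Write imputed genotypes to VCF
#'
#' Emits one record per untyped site with FORMAT fields `GT` (phased hard
#' call: per-haplotype argmax alleles), `GP` (the three genotype
#' probabilities, 3 decimals) and `DS` (dosage, 3 decimals), and INFO tag
#' `IMP=FB` or `IMP=VIT` naming the inference method.
#'
#' @param imp A `vicinity_imputation` result or its `calls` data.frame.
#' @param path Output path.
#' @param method Which method's records to write when both are present:
#'   `"FB"` (default) or `"VIT"`.
#' @return `path`, invisibly.
#' @export
write_imputed_vcf <- function(imp, path, method = c("FB", "VIT")) {
  method <- match.arg(method)
  calls <- if (inherits(imp, "vicinity_imputation")) imp$calls else imp
  calls <- calls[calls$method == method, , drop = FALSE]
  samples <- unique(calls$sample)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vicimpute",
    "##INFO=<ID=IMP,Number=1,Type=String,Description=\"Imputation method\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Imputed phased genotype\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype probabilities for 0/0, 0/1, 1/1\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- header
  if (nrow(calls)) {
    ord <- order(calls$pos, match(calls$sample, samples))
    calls <- calls[ord, , drop = FALSE]
    per_site <- split(calls, calls$pos)
    body <- vapply(per_site, function(d) {
      d <- d[match(samples, d$sample), , drop = FALSE]
      fmt <- sprintf("%d|%d:%s,%s,%s:%s",
                     d$hap0, d$hap1,
                     formatC(d$gp0, digits = 3, format = "f"),
                     formatC(d$gp1, digits = 3, format = "f"),
                     formatC(d$gp2, digits = 3, format = "f"),
                     formatC(d$dosage, digits = 3, format = "f"))
      id <- d$id[1]
      if (is.na(id) || !nzchar(id)) id <- "."
      paste(c(d$chrom[1], d$pos[1], id, d$ref[1], d$alt[1], ".", "PASS",
              paste0("IMP=", if (method == "FB") "FB" else "VIT"),
              "GT:GP:DS", fmt), collapse = "\t")
    }, character(1))
    lines <- c(lines, body[order(as.integer(names(per_site)))])
  }
  writeLines(lines, path)
  invisible(path)
}
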