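#' Read a genetic map in IMPUTE2 three-column format
#'
#' Parses a whitespace-delimited genetic map with columns
#' `position`, `COMBINED_rate(cM/Mb)` and `Genetic_Map(cM)`. Only the
#' physical position and the cumulative genetic distance are used; the
#' recombination-rate column is parsed and then ignored, since the
#' cumulative column is authoritative for interpolation.
#'
#' @param path Path to the map file.
#' @param chrom Chromosome label to attach to the table. The IMPUTE2 format
#'   carries no chromosome column, so the label is supplied by the caller
#'   (one map file per chromosome).
#' @param header Logical; `TRUE` (default) skips one header line.
#'
#' @return An object of class `genetic_map`: a list with elements
#'   `chrom`, `pos` (base pairs, 1-based, strictly increasing) and
#'   `cm` (cumulative centimorgans, non-decreasing).
#'
#' @examples
#' f <- tempfile()
#' writeLines(c("position rate cM", "100 1.0 1.0", "200 1.0 2.0"), f)
#' gm <- read_impute2_map(f, chrom = "chr20")
#' interpolate_cm(150, gm)  # 1.5
#' @export
read_impute2_map <- function(path, chrom = "chr1", header = TRUE) {
  raw <- tryCatch(
    read.table(path, header = FALSE, skip = if (header) 1L else 0L,
               colClasses = "numeric", col.names = c("pos", "rate", "cm")),
    error = function(e) stop("failed to parse genetic map '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L) stop("no map entries in '", path, "'", call. = FALSE)
  bad <- which(diff(raw$pos) <= 0)
  if (length(bad)) {
    stop("genetic map positions not strictly increasing at line ",
         bad[1] + 1L + as.integer(header), " of '", path, "'", call. = FALSE)
  }
  bad <- which(diff(raw$cm) < 0)
  if (length(bad)) {
    stop("cumulative cM decreases at line ",
         bad[1] + 1L + as.integer(header), " of '", path, "'", call. = FALSE)
  }
  structure(list(chrom = chrom, pos = raw$pos, cm = raw$cm),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map (", x$chrom, "): ", length(x$pos), " markers, ",
      format(x$pos[1], big.mark = ","), "-",
      format(x$pos[length(x$pos)], big.mark = ","), " bp, ",
      format(x$cm[length(x$cm)] - x$cm[1], digits = 4), " cM\n", sep = "")
  invisible(x)
}

#' Interpolate cumulative genetic position (cM) at physical positions
#'
#' Linear interpolation of cumulative genetic distance between the two map
#' markers flanking each query position. Positions outside the map range are
#' clamped to the terminal marker's cumulative cM, so flanking regions carry
#' zero recombination probability rather than extrapolated distances.
#'
#' @param pos Numeric vector of base-pair positions (1-based).
#' @param gmap A `genetic_map` from [read_impute2_map()].
#' @return Numeric vector of cumulative genetic positions in centimorgans.
#' @export
interpolate_cm <- function(pos, gmap) {
  stopifnot(inherits(gmap, "genetic_map"), length(gmap$pos) >= 1L)
  # rule = 2 clamps to the terminal marker values on both sides
  stats::approx(gmap$pos, gmap$cm, xout = pos, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' Annotate variant sites with interpolated genetic positions
#'
#' @param sites A site table (data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `typed`), sorted by position, single chromosome.
#' @param gmap A `genetic_map` for the same chromosome.
#' @return `sites` with a `cm` column of non-decreasing genetic positions.
#' @export
annotate_sites <- function(sites, gmap) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  if (nrow(sites) == 0L) stop("no sites to annotate", call. = FALSE)
  chr <- unique(sites$chrom)
  if (length(chr) != 1L)
    stop("sites span multiple chromosomes: ", paste(chr, collapse = ", "),
         call. = FALSE)
  if (!identical(as.character(chr), as.character(gmap$chrom)))
    stop("chromosome mismatch: sites on '", chr, "' but map is for '",
         gmap$chrom, "'", call. = FALSE)
  if (is.unsorted(sites$pos, strictly = TRUE))
    stop("site positions must be strictly increasing", call. = FALSE)
  sites$cm <- interpolate_cm(sites$pos, gmap)
  stopifnot(!is.unsorted(sites$cm))
  sites
}
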