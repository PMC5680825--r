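#' Marker map constructor
#'
#' An ordered table of biallelic SNP markers. Positions are 1-based
#' (VCF convention). Markers must be sorted by position within each
#' chromosome and chromosome blocks must be contiguous.
#'
#' @param marker Character vector of marker identifiers.
#' @param chrom Character vector of chromosome labels.
#' @param pos Integer vector of 1-based base-pair positions.
#' @param a1,a2 Allele symbols (reference-like and alternate-like).
#' @return A `data.frame` of class `marker_map`.
#' @export
marker_map <- function(marker, chrom, pos, a1 = "A", a2 = "B") {
  map <- data.frame(marker = as.character(marker),
                    chrom = as.character(chrom),
                    pos = as.integer(pos),
                    a1 = rep_len(as.character(a1), length(marker)),
                    a2 = rep_len(as.character(a2), length(marker)),
                    stringsAsFactors = FALSE)
  validate_marker_map(map)
}

validate_marker_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker", "chrom", "pos") %in% names(map)))
  if (any(is.na(map$pos)) || any(map$pos < 1L))
    stop("marker positions must be integers >= 1 (1-based)")
  # chromosome blocks contiguous, positions non-decreasing within each
  r <- rle(map$chrom)
  if (anyDuplicated(r$values))
    stop("chromosome blocks are not contiguous in the marker map")
  for (cc in split(map$pos, factor(map$chrom, levels = r$values))) {
    if (is.unsorted(cc))
      stop("marker positions are not sorted within a chromosome")
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Phased haplotype panel
#'
#' The substrate of the scan: for each animal two phased haplotype
#' sequences of allele indices (0 = first allele, 1 = second allele,
#' `NA` = missing) over an ordered marker map.
#'
#' @param hap1,hap2 Integer matrices (animals x markers) of allele
#'   indices in \{0, 1, NA\}. Row order defines the animal order.
#' @param map A [marker_map()] with one row per matrix column.
#' @param ids Character vector of unique animal identifiers; defaults
#'   to `rownames(hap1)`.
#' @return An object of class `haplotype_panel` with elements `hap1`,
#'   `hap2`, `map` and `ids`.
#' @export
haplotype_panel <- function(hap1, hap2, map, ids = rownames(hap1)) {
  hap1 <- as.matrix(hap1); storage.mode(hap1) <- "integer"
  hap2 <- as.matrix(hap2); storage.mode(hap2) <- "integer"
  if (is.null(ids)) ids <- sprintf("A%02d", seq_len(nrow(hap1)))
  ids <- as.character(ids)
  map <- validate_marker_map(map)
  if (!all(dim(hap1) == dim(hap2)))
    stop("hap1 and hap2 must have identical dimensions")
  if (ncol(hap1) != nrow(map))
    stop("haplotype length (", ncol(hap1), ") does not match marker count (",
         nrow(map), ")")
  if (length(ids) != nrow(hap1))
    stop("number of ids does not match number of animals")
  if (anyDuplicated(ids))
    stop("duplicate animal identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- c(hap1, hap2)
  bad <- bad[!is.na(bad)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("allele indices must be 0, 1 or NA")
  rownames(hap1) <- rownames(hap2) <- ids
  structure(list(hap1 = hap1, hap2 = hap2, map = map, ids = ids),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Phased haplotype panel:", length(x$ids), "animals x",
      nrow(x$map), "markers on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$hap1) | is.na(x$hap2))
  cat(sprintf("  missing genotype fraction: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) c(length(x$ids), nrow(x$map))

#' Subset a haplotype panel
#'
#' @param x A `haplotype_panel`.
#' @param i Animal index (integer, logical or identifier).
#' @param j Marker index (integer or logical).
#' @param ... Unused.
#' @return A `haplotype_panel` restricted to the selected animals and
#'   markers.
#' @export
`[.haplotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ids)
  if (missing(j)) j <- seq_len(nrow(x$map))
  if (is.character(i)) i <- match(i, x$ids)
  map <- x$map[j, , drop = FALSE]
  rownames(map) <- NULL
  haplotype_panel(x$hap1[i, j, drop = FALSE],
                  x$hap2[i, j, drop = FALSE],
                  map,
                  ids = x$ids[i])
}

#' Genotype dosage matrix of a panel
#'
#' Collapses the two phased haplotypes into allele-2 dosages 0/1/2;
#' a genotype is missing when either allele is missing.
#'
#' @param panel A `haplotype_panel`.
#' @return Integer matrix (animals x markers) with values 0, 1, 2 or
#'   `NA`, with animal ids as row names.
#' @export
genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  g <- panel$hap1 + panel$hap2
  rownames(g) <- panel$ids
  colnames(g) <- panel$map$marker
  g
}
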