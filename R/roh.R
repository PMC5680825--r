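#' Runs of homozygosity
#'
#' Detects, per animal and chromosome, every maximal stretch of
#' markers containing at most `max_het` heterozygous calls (and at
#' most `max_missing` missing calls), then keeps stretches with at
#' least `min_markers` markers and a base-pair span of at least
#' `min_length`. Missing calls never count as heterozygous and do
#' not break a stretch. Maximality is with respect to the
#' heterozygote/missing constraints: extending a reported segment by
#' one marker on either side would violate one of them (or run off
#' the chromosome). Overlapping maximal stretches are each reported
#' (a stretch wholly contained in another is not).
#'
#' @param geno Genotype dosage matrix (animals x markers, 0/1/2/NA)
#'   with animal ids as row names, e.g. from [genotypes()].
#' @param map A [marker_map()] describing the columns of `geno`.
#' @param min_markers Minimum number of markers covering a segment.
#' @param max_het Maximum heterozygous calls inside a segment.
#' @param min_length Minimum base-pair span (`end - start`).
#' @param max_missing Maximum missing calls inside a segment
#'   (unlimited by default).
#' @return A data frame with columns `animal`, `chrom`, `start`,
#'   `end`, `n_markers`, `n_het`, `n_missing`.
#' @export
roh_segments <- function(geno, map, min_markers = 20L, max_het = 1L,
                         min_length = 1e6, max_missing = Inf) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == nrow(map))
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  out <- vector("list", 0)
  chroms <- unique(map$chrom)
  for (cc in chroms) {
    jj <- which(map$chrom == cc)
    pos <- map$pos[jj]
    L <- length(jj)
    for (i in seq_len(nrow(geno))) {
      g <- geno[i, jj]
      het <- !is.na(g) & g == 1L
      mis <- is.na(g)
      segs <- maximal_runs(het, mis, max_het, max_missing)
      if (is.null(segs)) next
      nmk <- segs[, 2] - segs[, 1] + 1L
      span <- pos[segs[, 2]] - pos[segs[, 1]]
      keep <- nmk >= min_markers & span >= min_length
      if (!any(keep)) next
      segs <- segs[keep, , drop = FALSE]
      nh <- vapply(seq_len(nrow(segs)), function(s)
        sum(het[segs[s, 1]:segs[s, 2]]), 0L)
      nm <- vapply(seq_len(nrow(segs)), function(s)
        sum(mis[segs[s, 1]:segs[s, 2]]), 0L)
      out[[length(out) + 1L]] <-
        data.frame(animal = ids[i], chrom = cc,
                   start = pos[segs[, 1]], end = pos[segs[, 2]],
                   n_markers = nmk[keep], n_het = nh, n_missing = nm,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(animal = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_markers = integer(0), n_het = integer(0),
                      n_missing = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Two-pointer enumeration of maximal index runs with at most max_het
# hets and max_missing missing calls. Returns a 2-column matrix of
# (start, end) marker indices, or NULL.
maximal_runs <- function(het, mis, max_het, max_missing) {
  L <- length(het)
  if (L == 0L) return(NULL)
  res <- vector("list", 0)
  r <- 0L; nh <- 0L; nm <- 0L
  prev_r <- 0L
  for (l in seq_len(L)) {
    if (r < l) { r <- l - 1L; nh <- 0L; nm <- 0L }
    while (r < L &&
           nh + het[r + 1L] <= max_het &&
           nm + mis[r + 1L] <= max_missing) {
      r <- r + 1L
      nh <- nh + het[r]
      nm <- nm + mis[r]
    }
    if (r >= l && r > prev_r) {   # not contained in the previous run
      res[[length(res) + 1L]] <- c(l, r)
      prev_r <- r
    }
    nh <- nh - het[l]
    nm <- nm - mis[l]
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}
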