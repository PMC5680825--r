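#' Extract significant scan records
#'
#' @param x A `lethal_scan` object or scan record data frame.
#' @return Data frame of records classified `MH` or `DH`.
#' @export
significant_records <- function(x) {
  recs <- if (inherits(x, "lethal_scan")) x$records else as.data.frame(x)
  recs[recs$classification %in% c("MH", "DH"), , drop = FALSE]
}

#' Collapse overlapping significant windows into loci
#'
#' Significant windows on a chromosome are grouped into loci by
#' transitive base-pair overlap (windows are half-open, so abutting
#' windows do not overlap). Within each locus the record with the
#' lowest p-value is selected; ties are broken by smaller window
#' size, then leftmost start. Selected records are labelled
#' `<population><rank>` with ranks assigned after sorting by
#' chromosome and start.
#'
#' @param x A `lethal_scan` object or a data frame of significant
#'   scan records.
#' @param population Label prefix for haplotype names; taken from the
#'   scan object when available.
#' @return Data frame of one selected record per locus, with columns
#'   `hap`, `locus_start`, `locus_end` (the locus span) prepended to
#'   the scan record columns.
#' @export
collapse_loci <- function(x, population = NULL) {
  if (inherits(x, "lethal_scan")) {
    if (is.null(population)) population <- x$population
    recs <- significant_records(x)
  } else {
    recs <- as.data.frame(x)
  }
  if (is.null(population)) population <- "POP"
  if (nrow(recs) == 0L) {
    out <- cbind(data.frame(hap = character(0), locus_start = numeric(0),
                            locus_end = numeric(0)), recs)
    return(out)
  }
  sel <- vector("list", 0)
  for (cc in unique(recs$chrom)) {
    r <- recs[recs$chrom == cc, , drop = FALSE]
    r <- r[order(r$start, r$end), , drop = FALSE]
    hi <- cummax(r$end)
    # new locus where the window starts at/after the running max end
    locus <- cumsum(c(TRUE, r$start[-1] >= hi[-nrow(r)]))
    for (g in split(seq_len(nrow(r)), locus)) {
      blk <- r[g, , drop = FALSE]
      best <- order(blk$p_value, blk$size, blk$start)[1]
      pick <- blk[best, , drop = FALSE]
      pick <- cbind(data.frame(hap = NA_character_,
                               locus_start = min(blk$start),
                               locus_end = max(blk$end)),
                    pick)
      sel[[length(sel) + 1L]] <- pick
    }
  }
  out <- do.call(rbind, sel)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$hap <- paste0(population, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Loci shared between populations
#'
#' Finds maximal genomic regions where significant loci from at least
#' two populations overlap.
#'
#' @param loci_list Named list (one element per population) of locus
#'   or record data frames with columns `chrom`, `start`, `end`
#'   (half-open).
#' @return Data frame with columns `chrom`, `start`, `end`,
#'   `n_populations`, `populations` (comma-separated labels of every
#'   population whose loci intersect the region).
#' @export
shared_loci <- function(loci_list) {
  stopifnot(is.list(loci_list), length(loci_list) >= 2L)
  labs <- names(loci_list)
  if (is.null(labs)) labs <- paste0("pop", seq_along(loci_list))
  iv <- do.call(rbind, lapply(seq_along(loci_list), function(i) {
    d <- as.data.frame(loci_list[[i]])
    if (nrow(d) == 0L) return(NULL)
    data.frame(chrom = as.character(d$chrom), start = d$start, end = d$end,
               pop = labs[i], stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_populations = integer(0),
                      populations = character(0))
  if (is.null(iv) || nrow(iv) == 0L) return(empty)
  out <- vector("list", 0)
  for (cc in unique(iv$chrom)) {
    r <- iv[iv$chrom == cc, , drop = FALSE]
    bp <- sort(unique(c(r$start, r$end)))
    if (length(bp) < 2L) next
    seg_start <- bp[-length(bp)]
    seg_end <- bp[-1]
    npop <- vapply(seq_along(seg_start), function(s) {
      cov <- r$start < seg_end[s] & r$end > seg_start[s]
      length(unique(r$pop[cov]))
    }, 0L)
    keep <- npop >= 2L
    if (!any(keep)) next
    # merge adjacent kept segments into maximal regions
    ks <- which(keep)
    grp <- cumsum(c(TRUE, diff(ks) > 1L |
                      seg_start[ks[-1]] != seg_end[ks[-length(ks)]]))
    for (g in split(ks, grp)) {
      a <- seg_start[g[1]]; b <- seg_end[g[length(g)]]
      cov <- r$start < b & r$end > a
      out[[length(out) + 1L]] <-
        data.frame(chrom = cc, start = a, end = b,
                   n_populations = length(unique(r$pop[cov])),
                   populations = paste(sort(unique(r$pop[cov])), collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
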