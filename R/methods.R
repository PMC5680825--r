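#' @export
print.lethal_scan <- function(x, ...) {
  cat("Missing-homozygosity haplotype scan (", x$population, ")\n", sep = "")
  cat("  panel      :", x$n_animals, "animals,", x$n_markers, "markers,",
      x$n_trios, "genotyped trios\n")
  cat("  windows    :", x$n_windows, "| haplotypes tested:",
      sum(x$records$testable), "of", nrow(x$records), "\n")
  tab <- table(x$records$classification)
  cat("  MH:", if ("MH" %in% names(tab)) tab[["MH"]] else 0L,
      " DH:", if ("DH" %in% names(tab)) tab[["DH"]] else 0L, "\n")
  invisible(x)
}

#' Summarise a missing-homozygosity scan
#'
#' Collapses overlapping significant windows into loci (lowest
#' p-value per locus) and reports classification counts.
#'
#' @param object A `lethal_scan` fit.
#' @param ... Unused.
#' @return An object of class `summary.lethal_scan` with elements
#'   `loci` (the collapsed locus table), `classification` (table)
#'   and the scan metadata.
#' @export
summary.lethal_scan <- function(object, ...) {
  loci <- collapse_loci(object)
  structure(list(loci = loci,
                 classification = table(object$records$classification),
                 population = object$population,
                 n_records = nrow(object$records),
                 n_trios = object$n_trios),
            class = "summary.lethal_scan")
}

#' @export
print.summary.lethal_scan <- function(x, ...) {
  cat("Scan summary (", x$population, "): ", x$n_records,
      " haplotype records, ", x$n_trios, " trios\n", sep = "")
  print(x$classification)
  if (nrow(x$loci)) {
    cat("\nSelected loci (lowest p per overlap group):\n")
    cols <- c("hap", "chrom", "start", "end", "freq", "expected", "observed",
              "p_value", "cxc_matings", "progeny", "classification")
    print(x$loci[, cols], row.names = FALSE, digits = 3)
  } else {
    cat("\nNo significant loci.\n")
  }
  invisible(x)
}

#' @export
as.data.frame.lethal_scan <- function(x, ...) x$records

#' Manhattan-style plot of a scan
#'
#' Plots `-log10(p)` of every testable haplotype against window
#' midpoint, one panel colour per chromosome, with the MH and DH
#' significance thresholds as horizontal lines.
#'
#' @param x A `lethal_scan` fit.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.lethal_scan <- function(x, ...) {
  r <- x$records[x$records$testable & !is.na(x$records$p_value), , drop = FALSE]
  if (!nrow(r)) {
    warning("no testable haplotypes to plot")
    return(invisible(x))
  }
  chroms <- unique(r$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc) max(r$end[r$chrom == cc]), 0)))
  names(offs) <- c(chroms, "end")
  xpos <- (r$start + r$end) / 2 + offs[r$chrom]
  y <- -log10(r$p_value)
  graphics::plot(xpos, y, pch = 20, cex = 0.6,
                 col = match(r$chrom, chroms) %% 2 + 1,
                 xlab = "genomic position", ylab = "-log10 p", ...)
  graphics::abline(h = -log10(x$params$mh_alpha), lty = 2)
  graphics::abline(h = -log10(x$params$dh_alpha), lty = 3)
  invisible(x)
}
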