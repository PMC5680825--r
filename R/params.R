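#' Scan parameters
#'
#' Collects the tunable parameters of the missing-homozygosity scan:
#' the sliding-window size grid, the slide step as a fraction of the
#' window size, the minimum haplotype frequency retained for testing,
#' and the two significance thresholds used to classify haplotypes as
#' MH (missing homozygosity, zero observed homozygotes) or DH
#' (deficit of homozygotes, some observed but significantly fewer
#' than expected).
#'
#' @param window_sizes Numeric vector of window lengths in base pairs.
#'   The default doubling grid 0.5, 1, 2 and 4 Mb covers the
#'   haplotype-length range at which recessive lethals are typically
#'   tagged on medium-density SNP panels.
#' @param step_factor Slide step as a fraction of the window size;
#'   0.5 makes consecutive same-size windows overlap by half.
#' @param min_freq Minimum haplotype frequency (proportion of
#'   chromosomes); haplotypes are retained when their frequency is
#'   strictly greater than this value.
#' @param mh_alpha Significance threshold for haplotypes with zero
#'   observed homozygotes (MH).
#' @param dh_alpha Significance threshold for haplotypes with a
#'   deficit, but not absence, of homozygotes (DH).
#' @param null_p Optional fixed null success probability for the
#'   binomial test. The default `NULL` derives the null per haplotype
#'   as E/n from the trio transmission products, which equals 0.25
#'   when every carrier parent is heterozygous.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(window_sizes = c(0.5e6, 1e6, 2e6, 4e6),
                        step_factor = 0.5,
                        min_freq = 0.005,
                        mh_alpha = 5e-3,
                        dh_alpha = 5e-6,
                        null_p = NULL) {
  stopifnot(is.numeric(window_sizes), all(window_sizes > 0),
            is.numeric(step_factor), length(step_factor) == 1L,
            step_factor > 0, step_factor <= 1,
            min_freq >= 0, min_freq < 1,
            mh_alpha > 0, mh_alpha < 1,
            dh_alpha > 0, dh_alpha < 1)
  if (!is.null(null_p))
    stopifnot(null_p > 0, null_p < 1)
  structure(list(window_sizes = sort(unique(as.numeric(window_sizes))),
                 step_factor = step_factor,
                 min_freq = min_freq,
                 mh_alpha = mh_alpha,
                 dh_alpha = dh_alpha,
                 null_p = null_p),
            class = "scan_params")
}

#' Quality-control parameters
#'
#' Marker and animal filter thresholds applied before scanning. All
#' thresholds are strict inequalities: a marker is kept when its MAF
#' is greater than `maf_min` and its call rate greater than
#' `marker_callrate_min`; an animal is discarded when its missing
#' fraction is greater than `animal_max_missing`.
#'
#' @param maf_min Minimum minor allele frequency (exclusive).
#' @param marker_callrate_min Minimum marker call rate (exclusive).
#' @param animal_max_missing Maximum per-animal missing-genotype
#'   fraction (exclusive upper bound on discarding).
#' @param autosomes Optional character vector of chromosome labels to
#'   retain; `NULL` keeps all chromosomes.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(maf_min = 0.01,
                      marker_callrate_min = 0.85,
                      animal_max_missing = 0.30,
                      autosomes = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            marker_callrate_min >= 0, marker_callrate_min <= 1,
            animal_max_missing >= 0, animal_max_missing <= 1)
  structure(list(maf_min = maf_min,
                 marker_callrate_min = marker_callrate_min,
                 animal_max_missing = animal_max_missing,
                 autosomes = if (is.null(autosomes)) NULL else as.character(autosomes)),
            class = "qc_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat("Haplotype scan parameters\n")
  cat("  window sizes:", paste(format(x$window_sizes / 1e6, trim = TRUE), collapse = ", "), "Mb\n")
  cat("  step factor :", x$step_factor, "\n")
  cat("  min freq    : >", x$min_freq, "\n")
  cat("  MH alpha    :", format(x$mh_alpha), " DH alpha:", format(x$dh_alpha), "\n")
  invisible(x)
}

#' @export
print.qc_params <- function(x, ...) {
  cat("QC parameters: MAF >", x$maf_min,
      "| call rate >", x$marker_callrate_min,
      "| animal missing <=", x$animal_max_missing, "\n")
  if (!is.null(x$autosomes))
    cat("  chromosomes kept:", paste(x$autosomes, collapse = ","), "\n")
  invisible(x)
}
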