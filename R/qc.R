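#' Filter markers by chromosome, position, call rate and MAF
#'
#' Applies the marker-level pre-processing filters in a fixed order:
#' (1) chromosome filter (keep only `params$autosomes`, when given);
#' (2) duplicate positions — when several markers share a
#' (chromosome, position), only the first by input order is kept;
#' (3) call rate strictly greater than the threshold;
#' (4) minor allele frequency strictly greater than the threshold,
#' computed on the non-missing calls of the marker itself.
#' The filter is idempotent.
#'
#' @param panel A [haplotype_panel()].
#' @param params A [qc_params()] object.
#' @return A list with `panel` (filtered) and `removed`, a data frame
#'   of dropped markers with the first reason that triggered removal
#'   (`non_autosomal`, `duplicate_position`, `low_call_rate`,
#'   `low_maf`).
#' @export
filter_markers <- function(panel, params = qc_params()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  map <- panel$map
  m <- nrow(map)
  reason <- rep(NA_character_, m)
  if (!is.null(params$autosomes))
    reason[!(map$chrom %in% params$autosomes)] <- "non_autosomal"
  dup <- duplicated(paste(map$chrom, map$pos)) & is.na(reason)
  reason[dup] <- "duplicate_position"
  g <- genotypes(panel)
  cand <- is.na(reason)
  callrate <- colMeans(!is.na(g))
  reason[cand & !(callrate > params$marker_callrate_min)] <- "low_call_rate"
  cand <- is.na(reason)
  p <- colMeans(g, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  reason[cand & !(maf > params$maf_min)] <- "low_maf"
  keep <- is.na(reason)
  removed <- data.frame(marker = map$marker[!keep],
                        chrom = map$chrom[!keep], pos = map$pos[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (!any(keep))
    warning("all markers removed by QC")
  list(panel = panel[, keep], removed = removed)
}

#' Filter animals by missing-genotype fraction
#'
#' Discards animals whose fraction of missing genotypes (over the
#' current, marker-filtered panel) is strictly greater than
#' `params$animal_max_missing`. Run after [filter_markers()]: marker
#' removal changes per-animal missingness.
#'
#' @param panel A [haplotype_panel()].
#' @param params A [qc_params()] object.
#' @return A list with `panel` (filtered) and `removed`, a data frame
#'   of dropped animals with their missing fraction.
#' @export
filter_animals <- function(panel, params = qc_params()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  g <- genotypes(panel)
  missfrac <- rowMeans(is.na(g))
  drop <- missfrac > params$animal_max_missing
  removed <- data.frame(animal = panel$ids[drop],
                        missing_fraction = unname(missfrac[drop]),
                        reason = rep("high_missingness", sum(drop)),
                        stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  list(panel = panel[!drop, ], removed = removed)
}

#' Per-animal inbreeding coefficient F
#'
#' F from observed versus expected homozygous genotype counts:
#' over an animal's non-missing markers, the expected homozygote
#' count under Hardy-Weinberg is `E = sum(1 - 2 p (1 - p))` with `p`
#' the marker allele frequency, and `F = (O - E) / (L - E)` where `O`
#' is the observed homozygote count and `L` the number of non-missing
#' markers. F is undefined (`NA`) when `L <= E`, e.g. when all
#' markers are monomorphic.
#'
#' @param geno Genotype dosage matrix (animals x markers, 0/1/2/NA),
#'   e.g. from [genotypes()].
#' @param allele_freqs Optional per-marker allele-2 frequency; by
#'   default computed from `geno` itself.
#' @return A data frame with columns `animal`, `observed_hom`,
#'   `expected_hom`, `n_markers`, `F`.
#' @export
f_coefficient <- function(geno, allele_freqs = NULL) {
  geno <- as.matrix(geno)
  if (is.null(allele_freqs))
    allele_freqs <- colMeans(geno, na.rm = TRUE) / 2
  stopifnot(length(allele_freqs) == ncol(geno))
  p <- as.numeric(allele_freqs)
  hom_term <- 1 - 2 * p * (1 - p)
  nm <- !is.na(geno)
  L <- rowSums(nm)
  obs <- rowSums(geno != 1L & nm, na.rm = TRUE)
  expd <- nm %*% hom_term
  f <- ifelse(L > expd, (obs - expd) / (L - expd), NA_real_)
  data.frame(animal = if (is.null(rownames(geno))) as.character(seq_len(nrow(geno)))
                      else rownames(geno),
             observed_hom = obs, expected_hom = as.numeric(expd),
             n_markers = L, F = as.numeric(f),
             stringsAsFactors = FALSE, row.names = NULL)
}
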