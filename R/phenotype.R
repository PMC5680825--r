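#' Classify matings by parental carrier state
#'
#' Each litter is assigned a mating class from the diplotype copy
#' numbers of its parents for the haplotype under test: `CxC` when
#' both parents carry at least one copy, `CxNC` when exactly one
#' parent carries a copy and the other carries none, `NCxNC` when
#' both carry none, and `unknown` when either parent is ungenotyped
#' or has undetermined phase in the window.
#'
#' @param litters Litter data frame ([read_litters()]).
#' @param copies Named integer vector of diplotype copy numbers
#'   (e.g. from [diplotype_copies()]); animals absent from the vector
#'   are treated as ungenotyped.
#' @return The litter data frame with an added `class` column.
#' @export
classify_matings <- function(litters, copies) {
  cs <- unname(copies[match(litters$boar, names(copies))])
  cd <- unname(copies[match(litters$sow, names(copies))])
  cls <- rep("unknown", nrow(litters))
  known <- !is.na(cs) & !is.na(cd)
  cls[known & cs >= 1L & cd >= 1L] <- "CxC"
  cls[known & ((cs >= 1L) + (cd >= 1L) == 1L)] <- "CxNC"
  cls[known & cs == 0L & cd == 0L] <- "NCxNC"
  litters$class <- cls
  litters
}

#' Welch two-sample t-test
#'
#' Two-sided Welch t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom) via [stats::t.test()]. Degenerate inputs
#' (fewer than two observations per group, or zero variance in both
#' groups) yield `NA` results with `defined = FALSE`.
#'
#' @param x,y Numeric samples.
#' @return A list with `t`, `df`, `p` and `defined`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L ||
      (stats::var(x) == 0 && stats::var(y) == 0))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, defined = FALSE))
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, defined = TRUE)
}

#' Carrier-mating contrast for one litter trait
#'
#' Compares carrier x carrier (CxC) litters with carrier x
#' non-carrier (CxNC) litters for one trait: class means, the signed
#' percent difference `100 * (mean_CxC - mean_CxNC) / mean_CxNC`, and
#' a two-sided Welch t-test. NCxNC and unknown litters are excluded.
#' The contrast is untestable with fewer than two litters in either
#' class.
#'
#' @param classes Litter data frame with a `class` column
#'   ([classify_matings()]).
#' @param trait One of `"tnb"`, `"nba"`, `"nsb"`, `"mum"`.
#' @return A one-row data frame: `trait`, `n_cxc`, `n_cxnc`,
#'   `mean_cxc`, `mean_cxnc`, `percent_difference`, `welch_t`,
#'   `welch_df`, `welch_p`, `testable`.
#' @export
trait_effect <- function(classes, trait = c("tnb", "nba", "nsb", "mum")) {
  trait <- match.arg(trait)
  x <- classes[[trait]][classes$class == "CxC"]
  y <- classes[[trait]][classes$class == "CxNC"]
  n_cxc <- sum(!is.na(x)); n_cxnc <- sum(!is.na(y))
  testable <- n_cxc >= 2L && n_cxnc >= 2L
  mean_cxc <- if (n_cxc) mean(x, na.rm = TRUE) else NA_real_
  mean_cxnc <- if (n_cxnc) mean(y, na.rm = TRUE) else NA_real_
  pd <- if (testable && !is.na(mean_cxnc) && mean_cxnc != 0)
    100 * (mean_cxc - mean_cxnc) / mean_cxnc else NA_real_
  wt <- if (testable) welch_t(x, y)
        else list(t = NA_real_, df = NA_real_, p = NA_real_)
  data.frame(trait = trait, n_cxc = n_cxc, n_cxnc = n_cxnc,
             mean_cxc = mean_cxc, mean_cxnc = mean_cxnc,
             percent_difference = pd,
             welch_t = wt$t, welch_df = wt$df, welch_p = wt$p,
             testable = testable, stringsAsFactors = FALSE)
}

#' Distribution of mummified-piglet counts per litter
#'
#' For each mating class, the empirical fraction of litters with
#' exactly 0, 1, 2, ... mummified piglets. Fractions sum to 1 within
#' each class.
#'
#' @param classes Litter data frame with a `class` column.
#' @return Named list (one element per class present) of named
#'   numeric vectors; names are the mummified counts.
#' @export
mum_distribution <- function(classes) {
  out <- list()
  for (cl in intersect(c("CxC", "CxNC", "NCxNC", "unknown"),
                       unique(classes$class))) {
    m <- classes$mum[classes$class == cl]
    m <- m[!is.na(m)]
    if (!length(m)) { out[[cl]] <- numeric(0); next }
    tab <- table(factor(m, levels = 0:max(m)))
    out[[cl]] <- as.numeric(tab) / length(m)
    names(out[[cl]]) <- names(tab)
  }
  out
}

#' Chi-square test on the MUM/NSB/NBA composition of litters
#'
#' Builds a 2 x 3 contingency table of summed mummified, stillborn
#' and born-alive counts for CxC versus CxNC litters (integer totals
#' of the per-litter counts, never products of means) and applies
#' Pearson's chi-square test without continuity correction.
#'
#' @param classes Litter data frame with a `class` column.
#' @return A list with `table`, `statistic`, `df`, `p_value`,
#'   `low_expected` (`TRUE` when any expected cell is below 1, with a
#'   warning).
#' @export
ratio_chisq <- function(classes) {
  cxc <- classes[classes$class == "CxC", , drop = FALSE]
  cxnc <- classes[classes$class == "CxNC", , drop = FALSE]
  if (nrow(cxc) == 0L || nrow(cxnc) == 0L)
    stop("both CxC and CxNC classes must be non-empty")
  tab <- rbind(CxC = c(mum = sum(cxc$mum), nsb = sum(cxc$nsb), nba = sum(cxc$nba)),
               CxNC = c(mum = sum(cxnc$mum), nsb = sum(cxnc$nsb), nba = sum(cxnc$nba)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ct$expected < 1)
  if (low) warning("expected cell count below 1 in the MUM/NSB/NBA table")
  list(table = tab, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value, low_expected = low)
}

#' Population-level arithmetic for a fully penetrant recessive lethal
#'
#' Derives the rates implied by a carrier frequency under random
#' mating, together with the mummy accounting of the carrier
#' matings: the fraction of affected litters is the squared carrier
#' frequency, the fraction of affected piglets is a quarter of that
#' (one in four fetuses of a carrier mating is homozygous), the mean
#' mummified count per carrier x carrier litter, and the share of all
#' recorded mummies attributable to those matings. Percentages are
#' rounded to their conventional printed precision.
#'
#' @param carrier_freq Carrier frequency as a proportion (twice the
#'   haplotype frequency when live homozygotes are absent).
#' @param mum_cxc_total Total mummified piglets from carrier x
#'   carrier litters.
#' @param litters_cxc Number of carrier x carrier litters.
#' @param mum_population_total Total mummified piglets recorded in
#'   the population.
#' @return A list: `carrier_freq_pct`, `affected_litter_pct`,
#'   `affected_piglet_pct`, `mum_per_litter`, `mum_share_pct`.
#' @export
carrier_mating_rates <- function(carrier_freq, mum_cxc_total, litters_cxc,
                                 mum_population_total) {
  if (carrier_freq <= 0 || carrier_freq > 1)
    stop("carrier_freq must be a proportion in (0, 1]")
  if (litters_cxc <= 0 || mum_population_total <= 0)
    stop("litter and mummy totals must be positive")
  list(carrier_freq_pct = round(100 * carrier_freq, 1),
       affected_litter_pct = round(100 * carrier_freq^2, 2),
       affected_piglet_pct = round(100 * carrier_freq^2 / 4, 3),
       mum_per_litter = round(mum_cxc_total / litters_cxc, 2),
       mum_share_pct = round(100 * mum_cxc_total / mum_population_total, 2))
}
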