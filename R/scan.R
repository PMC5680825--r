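#' Enumerate sliding genomic windows
#'
#' For each window size `w` and each chromosome, windows start at
#' 0, `w * step_factor`, `2 w * step_factor`, ... while the start is
#' below the chromosome's last marker position. Each window is the
#' half-open interval `[start, start + w)`; windows containing fewer
#' than two markers are omitted.
#'
#' @param map A [marker_map()].
#' @param params A [scan_params()] object.
#' @return A data frame with one row per window: `chrom`, `start`,
#'   `end`, `size`, `m_start`, `m_end` (global marker index span into
#'   the map) and `n_markers`.
#' @export
enumerate_windows <- function(map, params = scan_params()) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), size = numeric(0),
                      m_start = integer(0), m_end = integer(0),
                      n_markers = integer(0))
  if (nrow(map) == 0L) return(empty)
  chroms <- unique(map$chrom)
  out <- vector("list", 0)
  for (cc in chroms) {
    idx <- which(map$chrom == cc)
    pos <- map$pos[idx]
    maxpos <- pos[length(pos)]
    for (w in params$window_sizes) {
      step <- w * params$step_factor
      starts <- seq(0, by = step, length.out = floor(maxpos / step) + 1L)
      starts <- starts[starts < maxpos]
      if (!length(starts)) next
      # markers with start <= pos < start + w (pos sorted within chrom)
      lo <- findInterval(starts - 0.5, pos) + 1L         # first pos >= start
      hi <- findInterval(starts + w - 0.5, pos)          # last pos < start + w
      keep <- (hi - lo + 1L) >= 2L
      if (!any(keep)) next
      out[[length(out) + 1L]] <-
        data.frame(chrom = cc, start = starts[keep], end = starts[keep] + w,
                   size = w,
                   m_start = idx[1] - 1L + lo[keep],
                   m_end = idx[1] - 1L + hi[keep],
                   n_markers = (hi - lo + 1L)[keep],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Phased allele strings of all animals over a marker span.
# Animals with any missing allele (either haplotype) in the span are
# flagged incomplete; their strings are NA.
window_strings <- function(panel, m_start, m_end) {
  j <- m_start:m_end
  h1 <- panel$hap1[, j, drop = FALSE]
  h2 <- panel$hap2[, j, drop = FALSE]
  complete <- rowSums(is.na(h1)) == 0L & rowSums(is.na(h2)) == 0L
  s1 <- do.call(paste0, as.data.frame(h1))
  s2 <- do.call(paste0, as.data.frame(h2))
  s1[!complete] <- NA_character_
  s2[!complete] <- NA_character_
  list(s1 = s1, s2 = s2, complete = complete)
}

#' Enumerate haplotypes in a window
#'
#' Distinct phased allele strings over the window's markers are
#' counted over the 2N chromosomes of animals with complete phase in
#' the window; haplotypes with frequency strictly greater than
#' `min_freq` are returned, sorted by descending frequency.
#'
#' @param panel A [haplotype_panel()].
#' @param window One row of [enumerate_windows()] output (or any list
#'   with `m_start`, `m_end`).
#' @param min_freq Frequency threshold (exclusive).
#' @return A data frame with columns `allele` (the allele string),
#'   `count` (chromosomes), `freq`, `carriers` (animals with exactly
#'   one copy), `homozygotes` (animals with two copies); the number
#'   of complete animals is attached as attribute `"n_complete"`.
#' @export
window_haplotypes <- function(panel, window, min_freq = 0.005) {
  ws <- window_strings(panel, window$m_start, window$m_end)
  n_complete <- sum(ws$complete)
  if (n_complete == 0L) {
    out <- data.frame(allele = character(0), count = integer(0),
                      freq = numeric(0), carriers = integer(0),
                      homozygotes = integer(0))
    attr(out, "n_complete") <- 0L
    return(out)
  }
  tab <- table(c(ws$s1[ws$complete], ws$s2[ws$complete]))
  freq <- as.numeric(tab) / (2 * n_complete)
  keep <- freq > min_freq
  alleles <- names(tab)[keep]
  o <- order(-freq[keep], alleles)
  alleles <- alleles[o]
  hom <- vapply(alleles, function(a)
    sum(ws$s1 == a & ws$s2 == a, na.rm = TRUE), 0L)
  het <- vapply(alleles, function(a)
    sum(xor(ws$s1 == a, ws$s2 == a), na.rm = TRUE), 0L)
  out <- data.frame(allele = alleles, count = as.integer(tab[alleles]),
                    freq = freq[keep][o],
                    carriers = as.integer(het),
                    homozygotes = as.integer(hom),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_complete") <- n_complete
  out
}

#' Haplotype copy number of each animal in a window
#'
#' @param panel A [haplotype_panel()].
#' @param window Window row (`m_start`, `m_end`).
#' @param allele Allele string of the haplotype under test.
#' @return Named integer vector (one element per panel animal) with
#'   values 0, 1, 2 or `NA` when the animal's phase is incomplete in
#'   the window.
#' @export
diplotype_copies <- function(panel, window, allele) {
  ws <- window_strings(panel, window$m_start, window$m_end)
  copies <- (ws$s1 == allele) + (ws$s2 == allele)
  copies[!ws$complete] <- NA_integer_
  names(copies) <- panel$ids
  copies
}

#' Diplotype state of one animal for one haplotype
#'
#' @param panel A [haplotype_panel()].
#' @param animal Animal identifier.
#' @param window Window row (`m_start`, `m_end`).
#' @param allele Allele string of the haplotype.
#' @return 0, 1 or 2 copies, or `NA` (undetermined) when the animal
#'   has missing phase in the window.
#' @export
diplotype_state <- function(panel, animal, window, allele) {
  i <- match(animal, panel$ids)
  if (is.na(i)) stop("unknown animal: ", animal)
  j <- window$m_start:window$m_end
  h1 <- panel$hap1[i, j]
  h2 <- panel$hap2[i, j]
  if (anyNA(h1) || anyNA(h2)) return(NA_integer_)
  as.integer(paste0(h1, collapse = "") == allele) +
    as.integer(paste0(h2, collapse = "") == allele)
}

#' Collect genotyped parent-offspring trios
#'
#' @param pedigree Pedigree data frame (`animal`, `sire`, `dam`).
#' @param panel A [haplotype_panel()].
#' @return A data frame of trios with all three members present in
#'   the panel: `offspring`, `sire`, `dam` plus their panel row
#'   indices `o_i`, `s_i`, `d_i`.
#' @export
collect_trios <- function(pedigree, panel) {
  o_i <- match(pedigree$animal, panel$ids)
  s_i <- match(pedigree$sire, panel$ids)
  d_i <- match(pedigree$dam, panel$ids)
  keep <- !is.na(o_i) & !is.na(s_i) & !is.na(d_i)
  data.frame(offspring = pedigree$animal[keep],
             sire = pedigree$sire[keep], dam = pedigree$dam[keep],
             o_i = o_i[keep], s_i = s_i[keep], d_i = d_i[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Trio-based statistics for one haplotype given the per-animal copy
# vector. Offspring of carrier x carrier parents (both parents with
# >= 1 determined copy, offspring state determined) contribute the
# transmission product (c_sire / 2) * (c_dam / 2) to the expected
# homozygote count.
trio_stats <- function(copies, trios) {
  cs <- copies[trios$s_i]
  cd <- copies[trios$d_i]
  co <- copies[trios$o_i]
  sel <- !is.na(cs) & !is.na(cd) & !is.na(co) & cs >= 1L & cd >= 1L
  n <- sum(sel)
  E <- sum(cs[sel] * cd[sel]) / 4
  cxc <- if (n) length(unique(paste(trios$sire[sel], trios$dam[sel]))) else 0L
  list(E = E, n = n, cxc_matings = cxc,
       het_off = sum(co[sel] == 1L), hom_off = sum(co[sel] == 2L))
}

#' Expected homozygotes from carrier-mating trios
#'
#' Over genotyped trio offspring whose sire and dam each carry at
#' least one copy of the haplotype, the expected number of homozygous
#' offspring is the sum of transmission products
#' `(c_sire / 2) * (c_dam / 2)`, where `c` is the parental copy
#' number. With exclusively heterozygous carrier parents this is
#' `n / 4`.
#'
#' @param panel A [haplotype_panel()].
#' @param window Window row (`m_start`, `m_end`).
#' @param allele Allele string of the haplotype.
#' @param trios Trio table from [collect_trios()].
#' @return A list with `E` (expected homozygotes), `n` (genotyped
#'   offspring of carrier x carrier trios) and `cxc_matings`
#'   (distinct sire-dam pairs among them).
#' @export
expected_homozygotes <- function(panel, window, allele, trios) {
  st <- trio_stats(diplotype_copies(panel, window, allele), trios)
  st[c("E", "n", "cxc_matings")]
}

#' Observed homozygotes over the whole panel
#'
#' Counted over all phased animals with determined diplotype state in
#' the window — not only trio offspring — because homozygotes may
#' exist outside genotyped trios.
#'
#' @inheritParams expected_homozygotes
#' @return Integer count of animals carrying two copies.
#' @export
observed_homozygotes <- function(panel, window, allele) {
  sum(diplotype_copies(panel, window, allele) == 2L, na.rm = TRUE)
}

#' Two-sided exact binomial test (point-probability method)
#'
#' The two-sided p-value is the sum of `Pr(j | n, p)` over all
#' outcomes `j` whose point probability does not exceed that of the
#' observed count `k`, with a relative tie tolerance of 1e-7:
#' `Pr(j) <= Pr(k) * (1 + 1e-7)`. Computed in log space and clamped
#' to at most 1.
#'
#' @param k Observed count (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param p Null success probability in (0, 1).
#' @return The two-sided p-value.
#' @export
binom_two_sided <- function(k, n, p) {
  if (length(k) != 1L || length(n) != 1L || length(p) != 1L ||
      is.na(k) || is.na(n) || is.na(p) ||
      k < 0 || k > n || n < 1 || k != round(k) || n != round(n) ||
      p <= 0 || p >= 1)
    stop("invalid arguments: need 0 <= k <= n, n >= 1, 0 < p < 1")
  ld <- stats::dbinom(0:n, n, p, log = TRUE)
  sel <- ld <= ld[k + 1] + log1p(1e-7)
  min(1, sum(exp(ld[sel])))
}

#' Test one haplotype for missing/deficit homozygosity
#'
#' Combines the trio-based expectation with the panel-wide observed
#' homozygote count. The null success probability of the exact
#' binomial test is `E / n` (0.25 when every carrier parent is
#' heterozygous) and the test statistic is `k = min(O, n)`; when
#' homozygotes outside genotyped trios push `O` above `n`, the record
#' carries a `non-trio homozygotes` note. Haplotypes with no
#' carrier x carrier trio progeny (`n = 0`) are flagged untestable.
#'
#' @inheritParams expected_homozygotes
#' @param params A [scan_params()] object.
#' @param freq Optional known haplotype frequency (recomputed when
#'   `NULL`).
#' @return A one-row data frame (a scan record): window coordinates,
#'   allele string, frequency, carrier/homozygote counts, `expected`,
#'   `observed`, `p_value`, `cxc_matings`, `progeny`, `het_carriers`,
#'   `het_pct`, `testable`, `note`, `classification`.
#' @export
test_haplotype <- function(panel, window, allele, trios,
                           params = scan_params(), freq = NULL) {
  copies <- diplotype_copies(panel, window, allele)
  n_complete <- sum(!is.na(copies))
  if (is.null(freq))
    freq <- if (n_complete) sum(copies, na.rm = TRUE) / (2 * n_complete) else NA_real_
  st <- trio_stats(copies, trios)
  O <- sum(copies == 2L, na.rm = TRUE)
  testable <- st$n > 0L
  note <- ""
  p_value <- NA_real_
  if (testable) {
    null_p <- if (is.null(params$null_p)) st$E / st$n else params$null_p
    null_p <- min(null_p, 1 - 1e-12)
    k <- min(O, st$n)
    if (O > st$n) note <- "non-trio homozygotes"
    p_value <- binom_two_sided(k, st$n, null_p)
  }
  rec <- data.frame(chrom = window$chrom, start = window$start,
                    end = window$end, size = window$end - window$start,
                    m_start = window$m_start, m_end = window$m_end,
                    n_markers = window$m_end - window$m_start + 1L,
                    allele = allele, freq = freq,
                    carriers = sum(copies == 1L, na.rm = TRUE),
                    expected = st$E, observed = O, p_value = p_value,
                    cxc_matings = st$cxc_matings, progeny = st$n,
                    het_carriers = st$het_off,
                    het_pct = if (st$n > 0) 100 * st$het_off / st$n else NA_real_,
                    testable = testable, note = note,
                    stringsAsFactors = FALSE)
  rec$classification <- classify_scan(rec$observed, rec$p_value, rec$testable, params)
  rec
}

#' Classify scan records as MH, DH or not significant
#'
#' MH (missing homozygosity): zero observed homozygotes and
#' `p < mh_alpha`. DH (deficit of homozygotes): at least one observed
#' homozygote and `p < dh_alpha`. Untestable records (no carrier
#' mating progeny) are labelled `not_testable`.
#'
#' @param observed Observed homozygote counts.
#' @param p_value Exact binomial p-values.
#' @param testable Logical vector.
#' @param params A [scan_params()] object.
#' @return Character vector: `"MH"`, `"DH"`, `"not_significant"` or
#'   `"not_testable"`.
#' @export
classify_scan <- function(observed, p_value, testable = TRUE,
                          params = scan_params()) {
  testable <- rep_len(testable, length(observed))
  out <- rep("not_significant", length(observed))
  out[testable & observed == 0L & p_value < params$mh_alpha] <- "MH"
  out[testable & observed > 0L & p_value < params$dh_alpha] <- "DH"
  out[!testable] <- "not_testable"
  out
}

#' Heterozygous carrier progeny from carrier matings
#'
#' Among genotyped offspring of carrier x carrier trios, the count
#' and percentage carrying exactly one copy of the haplotype. Under
#' Hardy-Weinberg segregation this is 50\%; for a fully lethal
#' haplotype the surviving offspring of het x het matings are 2:1
#' heterozygous : non-carrier, so the percentage tends to 66.7\%.
#'
#' @inheritParams expected_homozygotes
#' @return A list with `count` and `percent` (`NA` when there are no
#'   carrier-mating progeny).
#' @export
het_carrier_fraction <- function(panel, window, allele, trios) {
  st <- trio_stats(diplotype_copies(panel, window, allele), trios)
  list(count = st$het_off,
       percent = if (st$n > 0) 100 * st$het_off / st$n else NA_real_)
}

#' Genome scan for missing-homozygosity haplotypes
#'
#' The central fitting function: enumerates sliding windows over the
#' marker map, counts phased haplotypes above the frequency
#' threshold in each window, derives expected homozygote counts from
#' genotyped parent-offspring trios by the transmission-product rule,
#' counts observed homozygotes over the whole panel, and applies the
#' two-sided exact binomial test, classifying each haplotype as MH
#' (no homozygotes), DH (deficit of homozygotes) or not significant.
#'
#' @param panel A [haplotype_panel()], typically after
#'   [filter_markers()] and [filter_animals()].
#' @param pedigree Pedigree data frame (`animal`, `sire`, `dam`).
#' @param params A [scan_params()] object.
#' @param population Population label used for haplotype naming in
#'   summaries.
#' @param windows Optional precomputed window table (from
#'   [enumerate_windows()]); scanned windows can thereby be
#'   restricted, e.g. to one chromosome.
#' @return An object of class `lethal_scan` with elements `records`
#'   (one row per tested haplotype), `params`, `population`,
#'   `n_animals`, `n_markers`, `n_trios`, `n_windows`.
#' @seealso [collapse_loci()], [summary.lethal_scan()],
#'   [write_scan_table()]
#' @export
lethal_scan <- function(panel, pedigree, params = scan_params(),
                        population = "POP", windows = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  trios <- collect_trios(pedigree, panel)
  if (is.null(windows)) windows <- enumerate_windows(panel$map, params)
  recs <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    ws <- window_strings(panel, win$m_start, win$m_end)
    n_complete <- sum(ws$complete)
    if (n_complete == 0L) next
    tab <- table(c(ws$s1[ws$complete], ws$s2[ws$complete]))
    freq <- as.numeric(tab) / (2 * n_complete)
    keep <- freq > params$min_freq
    if (!any(keep)) next
    alleles <- names(tab)[keep]
    freqs <- freq[keep]
    o <- order(-freqs, alleles)
    alleles <- alleles[o]; freqs <- freqs[o]
    # integer haplotype indices: 0 = not a retained haplotype / missing
    ai1 <- match(ws$s1, alleles, nomatch = 0L)
    ai2 <- match(ws$s2, alleles, nomatch = 0L)
    K <- length(alleles)
    carr <- obs <- cxc <- prog <- hets <- integer(K)
    expd <- pval <- numeric(K)
    note <- character(K)
    for (a in seq_len(K)) {
      copies <- (ai1 == a) + (ai2 == a)
      copies[!ws$complete] <- NA_integer_
      st <- trio_stats(copies, trios)
      O <- sum(copies == 2L, na.rm = TRUE)
      carr[a] <- sum(copies == 1L, na.rm = TRUE)
      obs[a] <- O
      expd[a] <- st$E
      cxc[a] <- st$cxc_matings
      prog[a] <- st$n
      hets[a] <- st$het_off
      if (st$n > 0L) {
        null_p <- if (is.null(params$null_p)) st$E / st$n else params$null_p
        null_p <- min(null_p, 1 - 1e-12)
        if (O > st$n) note[a] <- "non-trio homozygotes"
        pval[a] <- binom_two_sided(min(O, st$n), st$n, null_p)
      } else {
        pval[a] <- NA_real_
      }
    }
    recs[[w]] <- data.frame(chrom = win$chrom, start = win$start,
                            end = win$end, size = win$size,
                            m_start = win$m_start, m_end = win$m_end,
                            n_markers = win$n_markers,
                            allele = alleles, freq = freqs,
                            carriers = carr, expected = expd, observed = obs,
                            p_value = pval, cxc_matings = cxc, progeny = prog,
                            het_carriers = hets,
                            het_pct = ifelse(prog > 0, 100 * hets / prog, NA_real_),
                            testable = prog > 0L, note = note,
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- test_haplotype(panel, list(chrom = NA, start = NA, end = NA,
                                          m_start = 1, m_end = 1),
                              allele = "zz", trios = trios)[0, ]
  records$classification <- classify_scan(records$observed, records$p_value,
                                          records$testable, params)
  rownames(records) <- NULL
  structure(list(records = records, params = params,
                 population = population,
                 n_animals = length(panel$ids),
                 n_markers = nrow(panel$map),
                 n_trios = nrow(trios),
                 n_windows = nrow(windows),
                 call = match.call()),
            class = "lethal_scan")
}
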