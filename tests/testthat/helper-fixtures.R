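# In-code fixtures shared across the suite.

# A tiny deterministic panel: `n` animals over `m` evenly spaced
# markers on one chromosome, haplotypes drawn Bernoulli(p) under a
# local seed (does not disturb the caller's RNG stream).
tiny_panel <- function(n = 6, m = 10, p = 0.5, seed = 42,
                       chrom = "1", spacing = 1e5) {
  withr::with_seed(seed, {
    h1 <- matrix(rbinom(n * m, 1L, p), n, m)
    h2 <- matrix(rbinom(n * m, 1L, p), n, m)
  })
  map <- marker_map(sprintf("m%02d", seq_len(m)), chrom,
                    as.integer(seq_len(m) * spacing))
  haplotype_panel(h1, h2, map, ids = sprintf("A%02d", seq_len(n)))
}

# Panel with every haplotype given explicitly: `haps` is a list of
# c(h1_string, h2_string) per animal, e.g. list(c("010", "110")).
panel_from_strings <- function(haps, pos = NULL, chrom = "1") {
  m <- nchar(haps[[1]][1])
  if (is.null(pos)) pos <- as.integer(seq_len(m) * 1e5)
  tochr <- function(s) as.integer(strsplit(chartr(".", "9", s), "")[[1]]) |>
    (\(x) replace(x, x == 9L, NA_integer_))()
  h1 <- do.call(rbind, lapply(haps, \(h) tochr(h[1])))
  h2 <- do.call(rbind, lapply(haps, \(h) tochr(h[2])))
  map <- marker_map(sprintf("m%02d", seq_len(m)), chrom, pos)
  haplotype_panel(h1, h2, map, ids = sprintf("A%02d", seq_along(haps)))
}

# Carrier-mating trio fixture: `n_off` genotyped offspring, all from
# het x het parents, none homozygous for the tracked 2-marker
# haplotype "11" unless `hom_off` > 0. Returns panel + pedigree.
carrier_trio_fixture <- function(n_off, hom_off = 0, het_off = NULL) {
  if (is.null(het_off)) het_off <- round(2 * (n_off - hom_off) / 3)
  sire <- c("10", "11")  # het carrier
  dam <- c("11", "00")   # het carrier
  states <- c(rep("hom", hom_off), rep("het", het_off),
              rep("non", n_off - hom_off - het_off))
  off <- lapply(states, function(s)
    switch(s, hom = c("11", "11"), het = c("11", "00"), non = c("10", "01")))
  haps <- c(list(sire, dam), off)
  panel <- panel_from_strings(haps)
  ped <- data.frame(animal = panel$ids,
                    sire = c("0", "0", rep(panel$ids[1], n_off)),
                    dam = c("0", "0", rep(panel$ids[2], n_off)),
                    stringsAsFactors = FALSE)
  w <- list(chrom = "1", start = 0, end = 3e5, m_start = 1, m_end = 2)
  list(panel = panel, ped = ped, window = w, allele = "11")
}

# Exact rational-arithmetic two-sided binomial oracle for p = a/b.
# All intermediate integers stay below 2^53 for n <= 12, b <= 10.
binom_oracle_rational <- function(k, n, a, b) {
  num <- vapply(0:n, function(j) choose(n, j) * a^j * (b - a)^(n - j), 0)
  sum(num[num <= num[k + 1]]) / b^n
}

# Brute-force ROH oracle: enumerate every marker interval, keep the
# valid ones (het/missing caps), drop intervals contained in a larger
# valid interval, then apply the size filters. Interval sums come
# from cumulative counts so that all L^2 intervals can be checked.
roh_oracle <- function(g, pos, min_markers, max_het, min_length,
                       max_missing = Inf) {
  L <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  lr <- expand.grid(l = seq_len(L), r = seq_len(L))
  lr <- lr[lr$l <= lr$r, ]
  ok <- (ch[lr$r + 1L] - ch[lr$l]) <= max_het &
    (cm[lr$r + 1L] - cm[lr$l]) <= max_missing
  if (!any(ok)) return(NULL)
  v <- cbind(lr$l[ok], lr$r[ok])
  # validity is monotone under shrinking, so an interval is maximal
  # iff both one-marker extensions are invalid (or off the ends)
  bad <- function(l, r) (ch[r + 1L] - ch[l]) > max_het |
    (cm[r + 1L] - cm[l]) > max_missing
  maximal <- (v[, 1] == 1L | bad(pmax(v[, 1] - 1L, 1L), v[, 2])) &
    (v[, 2] == L | bad(v[, 1], pmin(v[, 2] + 1L, L)))
  v <- v[maximal, , drop = FALSE]
  keep <- (v[, 2] - v[, 1] + 1L) >= min_markers &
    (pos[v[, 2]] - pos[v[, 1]]) >= min_length
  v <- v[keep, , drop = FALSE]
  if (!nrow(v)) return(NULL)
  v[order(v[, 1]), , drop = FALSE]
}

# Union-find oracle for transitive interval overlap grouping.
overlap_groups_oracle <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && start[i] < end[j] && start[j] < end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 0L)
}
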