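#' Specification of an embedded recessive lethal haplotype
#'
#' @param chrom Chromosome label (must exist in the simulated map).
#' @param start,end Base-pair interval of the lethal haplotype,
#'   half-open `[start, end)` like scan windows.
#' @param freq Target founder frequency of the lethal haplotype
#'   (proportion of founder chromosomes).
#' @param penetrance Probability that a homozygous fetus dies.
#' @param stage Death stage: `"early"` (fetus resorbed, never
#'   recorded), `"mid_gestation"` (fetus mummifies) or
#'   `"stillbirth"` (fetus counted stillborn).
#' @return An object of class `lethal_spec`.
#' @export
lethal_spec <- function(chrom, start, end, freq,
                        penetrance = 1,
                        stage = c("mid_gestation", "early", "stillbirth")) {
  stage <- match.arg(stage)
  stopifnot(end > start, freq > 0, freq <= 0.5,
            penetrance >= 0, penetrance <= 1)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 freq = freq, penetrance = penetrance, stage = stage),
            class = "lethal_spec")
}

#' Configuration of the gene-drop population simulator
#'
#' Describes a closed breeding line: founder counts, number of
#' discrete offspring generations, litter sizes (Poisson, truncated
#' at one conceived fetus), a biallelic marker map, a founder
#' haplotype pool, embedded recessive lethal haplotypes, baseline
#' per-fetus loss rates, and the genotyping scheme. All randomness
#' flows from the single `seed`.
#'
#' @param seed Integer seed.
#' @param generations Number of offspring generations.
#' @param founder_males,founder_females Number of breeding males and
#'   females per generation.
#' @param litters_per_sow Litters per sow per generation.
#' @param litter_lambda Mean number of conceived fetuses per litter
#'   (Poisson, truncated at >= 1). The default 16 leaves total-born
#'   means in the low teens after baseline and lethal losses, the
#'   scale typical of commercial sow lines.
#' @param chrom_lengths Named numeric vector of chromosome lengths in
#'   base pairs.
#' @param markers_per_chrom Markers per chromosome (evenly spaced).
#' @param morgans Genetic length per chromosome in Morgans (expected
#'   crossovers per meiosis); default 1 cM/Mb.
#' @param founder_pool Number of distinct founder haplotypes (the
#'   lethal haplotypes are added on top).
#' @param lethals List of [lethal_spec()] objects.
#' @param mum_rate Baseline probability that a fetus mummifies.
#' @param nsb_rate Baseline probability that a fetus is stillborn.
#' @param genotyped_fraction Fraction of live offspring genotyped.
#' @param trio_enrichment Also genotype the parents of every
#'   genotyped offspring (emulating trio-rich livestock panels)?
#' @param missing_rate Per-genotype missing-call probability.
#' @param mum_in_tnb Count mummified piglets inside TNB? The default
#'   `FALSE` matches the accounting in which TNB = NBA + NSB.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       generations = 2L,
                       founder_males = 25L,
                       founder_females = 125L,
                       litters_per_sow = 1L,
                       litter_lambda = 16,
                       chrom_lengths = c("1" = 2e7),
                       markers_per_chrom = 500L,
                       morgans = NULL,
                       founder_pool = 40L,
                       lethals = list(),
                       mum_rate = 0.01,
                       nsb_rate = 0.05,
                       genotyped_fraction = 1,
                       trio_enrichment = TRUE,
                       missing_rate = 0,
                       mum_in_tnb = FALSE) {
  if (founder_males < 1L || founder_females < 1L)
    stop("at least one founder of each sex is required")
  if (inherits(lethals, "lethal_spec")) lethals <- list(lethals)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  if (is.null(morgans)) morgans <- chrom_lengths / 1e8
  stopifnot(length(morgans) == length(chrom_lengths),
            mum_rate >= 0, mum_rate <= 1, nsb_rate >= 0, nsb_rate <= 1,
            mum_rate + nsb_rate <= 1,
            genotyped_fraction >= 0, genotyped_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            litter_lambda > 0, generations >= 1L)
  for (ls in lethals) {
    stopifnot(inherits(ls, "lethal_spec"))
    if (!ls$chrom %in% names(chrom_lengths) ||
        ls$end > chrom_lengths[[ls$chrom]])
      stop("lethal interval does not lie on the simulated map")
  }
  structure(list(seed = as.integer(seed), generations = as.integer(generations),
                 founder_males = as.integer(founder_males),
                 founder_females = as.integer(founder_females),
                 litters_per_sow = as.integer(litters_per_sow),
                 litter_lambda = litter_lambda,
                 chrom_lengths = chrom_lengths,
                 markers_per_chrom = as.integer(markers_per_chrom),
                 morgans = morgans, founder_pool = as.integer(founder_pool),
                 lethals = lethals, mum_rate = mum_rate, nsb_rate = nsb_rate,
                 genotyped_fraction = genotyped_fraction,
                 trio_enrichment = trio_enrichment,
                 missing_rate = missing_rate, mum_in_tnb = mum_in_tnb),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Gene-drop simulation config (seed", x$seed, ")\n")
  cat("  ", x$founder_males, "boars x", x$founder_females, "sows,",
      x$generations, "generation(s),",
      "lambda =", x$litter_lambda, "conceived/litter\n")
  cat("  map:", length(x$chrom_lengths), "chromosome(s),",
      x$markers_per_chrom, "markers each\n")
  cat("  lethal haplotypes:", length(x$lethals), "\n")
  invisible(x)
}

# Evenly spaced marker map over the configured chromosomes.
sim_marker_map <- function(config) {
  maps <- lapply(names(config$chrom_lengths), function(cc) {
    len <- config$chrom_lengths[[cc]]
    m <- config$markers_per_chrom
    pos <- as.integer(round((seq_len(m) - 0.5) * len / m))
    data.frame(marker = sprintf("SNP%s_%04d", cc, seq_len(m)),
               chrom = cc, pos = pos, a1 = "A", a2 = "B",
               stringsAsFactors = FALSE)
  })
  validate_marker_map(do.call(rbind, maps))
}

# Founder haplotype pool: `founder_pool` random haplotypes plus one
# dedicated haplotype per lethal spec, guaranteed unique within its
# lethal window.
make_founder_pool <- function(config, map) {
  M <- nrow(map)
  p <- stats::runif(M, 0.2, 0.8)
  n_pool <- config$founder_pool
  n_let <- length(config$lethals)
  alleles <- matrix(stats::rbinom(n_pool * M, 1L, rep(p, each = n_pool)),
                    nrow = n_pool)
  lethal_rows <- if (n_let)
    matrix(stats::rbinom(n_let * M, 1L, rep(p, each = n_let)), nrow = n_let)
  else matrix(integer(0), nrow = 0L, ncol = M)
  alleles <- rbind(alleles, lethal_rows)
  lethal_ids <- if (n_let) n_pool + seq_len(n_let) else integer(0)
  for (i in seq_len(n_let)) {
    win <- lethal_window(map, config$lethals[[i]])
    lstr <- paste0(alleles[lethal_ids[i], win], collapse = "")
    for (r in seq_len(n_pool)) {     # no neutral haplotype may alias the lethal string
      if (paste0(alleles[r, win], collapse = "") == lstr)
        alleles[r, win[1]] <- 1L - alleles[r, win[1]]
    }
  }
  list(alleles = alleles, p = p, lethal_ids = lethal_ids)
}

# Marker indices of a lethal spec's half-open window.
lethal_window <- function(map, spec) {
  w <- which(map$chrom == spec$chrom & map$pos >= spec$start & map$pos < spec$end)
  if (length(w) < 2L) stop("lethal window covers fewer than 2 markers")
  w
}

# One gamete: per chromosome, Poisson(morgans) crossovers at uniform
# positions between the parent's two label vectors.
meiosis_one <- function(l1, l2, chrs) {
  out <- integer(length(l1))
  for (c in seq_along(chrs$idx)) {
    jj <- chrs$idx[[c]]
    k <- stats::rpois(1L, chrs$morgans[[c]])
    if (k == 0L) {
      out[jj] <- if (stats::runif(1) < 0.5) l1[jj] else l2[jj]
    } else {
      x <- sort(stats::runif(k, 0, chrs$len[[c]]))
      seg <- findInterval(chrs$pos[[c]], x)
      pick <- (seg + sample(0:1, 1L)) %% 2L
      out[jj] <- ifelse(pick == 0L, l1[jj], l2[jj])
    }
  }
  out
}

chrom_index <- function(map, config) {
  ccs <- names(config$chrom_lengths)
  list(idx = lapply(ccs, function(cc) which(map$chrom == cc)),
       pos = lapply(ccs, function(cc) map$pos[map$chrom == cc]),
       len = as.list(config$chrom_lengths),
       morgans = as.list(config$morgans))
}

# Founder label matrices: each founder chromatid draws one neutral
# pool haplotype per chromosome; lethal haplotypes are then planted
# on round(2 N f) chromatids (at most one per founder, so no founder
# is born dead) on the lethal's chromosome.
founder_labels <- function(config, map, pool) {
  n0 <- config$founder_males + config$founder_females
  M <- nrow(map)
  ccs <- names(config$chrom_lengths)
  L1 <- matrix(0L, n0, M); L2 <- matrix(0L, n0, M)
  for (cc in ccs) {
    jj <- which(map$chrom == cc)
    L1[, jj] <- sample.int(config$founder_pool, n0, replace = TRUE)
    L2[, jj] <- sample.int(config$founder_pool, n0, replace = TRUE)
  }
  for (i in seq_along(config$lethals)) {
    spec <- config$lethals[[i]]
    k <- max(1L, round(2 * n0 * spec$freq))
    if (k > n0) stop("lethal frequency too high for the founder count")
    jj <- which(map$chrom == spec$chrom)
    who <- sample.int(n0, k)
    side <- sample(c(TRUE, FALSE), k, replace = TRUE)
    for (a in seq_len(k)) {
      if (side[a]) L1[who[a], jj] <- pool$lethal_ids[i]
      else L2[who[a], jj] <- pool$lethal_ids[i]
    }
  }
  list(L1 = L1, L2 = L2)
}

#' Build a multi-generation pedigree by random mating
#'
#' Neutral demography: discrete, non-overlapping generations; each
#' generation's breeding animals are drawn from the previous
#' generation's offspring (founders for generation 1); every sow
#' produces `litters_per_sow` litters, each sired by one randomly
#' chosen boar, with a truncated-Poisson number of conceived
#' fetuses. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `pedigree` (columns `animal`, `sire`, `dam`,
#'   `line`, `sex`, `generation`, `litter`) and `matings` (columns
#'   `litter`, `sow`, `boar`, `generation`, `conceived`).
#' @export
build_pedigree <- function(config) {
  set.seed(config$seed)
  .build_pedigree(config)
}

.build_pedigree <- function(config) {
  founders <- data.frame(
    animal = c(sprintf("G0M%03d", seq_len(config$founder_males)),
               sprintf("G0F%04d", seq_len(config$founder_females))),
    sire = "0", dam = "0", line = "SIM",
    sex = rep(c("M", "F"), c(config$founder_males, config$founder_females)),
    generation = 0L, litter = "0", stringsAsFactors = FALSE)
  ped <- list(founders)
  matings <- list()
  males <- founders$animal[founders$sex == "M"]
  females <- founders$animal[founders$sex == "F"]
  for (g in seq_len(config$generations)) {
    rows <- list(); mts <- list()
    lit_no <- 0L
    for (f in females) {
      for (l in seq_len(config$litters_per_sow)) {
        lit_no <- lit_no + 1L
        litter_id <- sprintf("G%dL%05d", g, lit_no)
        boar <- sample(males, 1L)
        conceived <- 0L
        while (conceived < 1L) conceived <- stats::rpois(1L, config$litter_lambda)
        sex <- sample(c("M", "F"), conceived, replace = TRUE)
        rows[[lit_no]] <- data.frame(
          animal = sprintf("%sA%02d", litter_id, seq_len(conceived)),
          sire = boar, dam = f, line = "SIM", sex = sex,
          generation = g, litter = litter_id, stringsAsFactors = FALSE)
        mts[[lit_no]] <- data.frame(litter = litter_id, sow = f, boar = boar,
                                    generation = g, conceived = conceived,
                                    stringsAsFactors = FALSE)
      }
    }
    gen <- do.call(rbind, rows)
    ped[[g + 1L]] <- gen
    matings[[g]] <- do.call(rbind, mts)
    males <- pick_parents(gen$animal[gen$sex == "M"], config$founder_males)
    females <- pick_parents(gen$animal[gen$sex == "F"], config$founder_females)
  }
  list(pedigree = do.call(rbind, ped), matings = do.call(rbind, matings))
}

pick_parents <- function(candidates, n) {
  if (length(candidates) <= n) return(candidates)
  sample(candidates, n)
}

#' Drop founder haplotypes through a pedigree
#'
#' Mendelian gene drop: founders receive haplotype labels from the
#' founder pool (with lethal haplotypes planted at their target
#' frequencies); every offspring inherits one recombined gamete from
#' each parent (Poisson crossovers, default 1 per Morgan).
#' Deterministic under the config seed.
#'
#' @param pedigree Pedigree data frame ([build_pedigree()] format).
#' @param config A [sim_config()].
#' @return An object of class `gene_drop`: list with `L1`, `L2`
#'   (label matrices, animals x markers), `ids`, `map`, `pool`.
#' @export
gene_drop <- function(pedigree, config) {
  set.seed(config$seed + 1L)
  map <- sim_marker_map(config)
  pool <- make_founder_pool(config, map)
  .gene_drop(pedigree, config, map, pool)
}

.gene_drop <- function(pedigree, config, map, pool) {
  n <- nrow(pedigree)
  M <- nrow(map)
  chrs <- chrom_index(map, config)
  L1 <- matrix(0L, n, M); L2 <- matrix(0L, n, M)
  is_founder <- pedigree$sire == "0" & pedigree$dam == "0"
  fl <- founder_labels_for(config, map, pool, sum(is_founder))
  L1[is_founder, ] <- fl$L1
  L2[is_founder, ] <- fl$L2
  idx <- seq_len(n)
  names(idx) <- pedigree$animal
  ord <- order(!is_founder)  # founders first; generations are already in order
  for (i in idx[ord][!is_founder[ord]]) {
    si <- idx[[pedigree$sire[i]]]
    di <- idx[[pedigree$dam[i]]]
    L1[i, ] <- meiosis_one(L1[si, ], L2[si, ], chrs)
    L2[i, ] <- meiosis_one(L1[di, ], L2[di, ], chrs)
  }
  structure(list(L1 = L1, L2 = L2, ids = pedigree$animal, map = map,
                 pool = pool),
            class = "gene_drop")
}

founder_labels_for <- function(config, map, pool, n0) {
  cfg <- config
  # founder_labels() sizes off the configured counts; keep them in sync
  stopifnot(n0 == config$founder_males + config$founder_females)
  founder_labels(cfg, map, pool)
}

# Per-lethal truth table, including the planted marker allele string
# inside each lethal window (the string the scan should flag).
lethal_truth_table <- function(config, map, pool) {
  do.call(rbind, lapply(seq_along(config$lethals), function(i) {
    s <- config$lethals[[i]]
    win <- lethal_window(map, s)
    data.frame(chrom = s$chrom, start = s$start, end = s$end, freq = s$freq,
               penetrance = s$penetrance, stage = s$stage,
               allele = paste0(pool$alleles[pool$lethal_ids[i], win],
                               collapse = ""),
               stringsAsFactors = FALSE)
  }))
}

#' Lethal-haplotype copy number of every animal in a gene drop
#'
#' A chromatid carries the lethal when every founder-haplotype label
#' inside the lethal window equals the lethal's label.
#'
#' @param drop A [gene_drop()] result.
#' @param spec One of the configured [lethal_spec()] objects.
#' @param config The [sim_config()] the drop was run under.
#' @return Named integer vector of true copy numbers (0/1/2).
#' @export
lethal_copies <- function(drop, spec, config) {
  win <- lethal_window(drop$map, spec)
  lid <- drop$pool$lethal_ids[vapply(config$lethals, identical, TRUE, spec)]
  if (!length(lid)) stop("spec is not one of the configured lethals")
  c1 <- rowSums(drop$L1[, win, drop = FALSE] == lid) == length(win)
  c2 <- rowSums(drop$L2[, win, drop = FALSE] == lid) == length(win)
  stats::setNames(as.integer(c1) + as.integer(c2), drop$ids)
}

#' Apply embedded lethality and baseline losses to conceived litters
#'
#' Every conceived fetus homozygous for a lethal haplotype dies with
#' probability equal to the penetrance, at the configured stage:
#' `early` losses disappear entirely (reduce total born),
#' `mid_gestation` deaths mummify, `stillbirth` deaths are counted
#' stillborn. Baseline mummification and stillbirth rates apply
#' independently to the surviving fetuses. Deterministic under the
#' config seed.
#'
#' @param pedigree Pedigree of conceived fetuses
#'   ([build_pedigree()] format).
#' @param drop A [gene_drop()] result over that pedigree.
#' @param config A [sim_config()].
#' @return An object of class `truth_set`: list with `litters`
#'   (per-litter conceived and loss counts), `animals` (per-animal
#'   lethal copy numbers and fate), `lethals` (the planted windows),
#'   `dead` (identifiers of dead fetuses).
#' @export
apply_lethality <- function(pedigree, drop, config) {
  set.seed(config$seed + 2L)
  .apply_lethality(pedigree, drop, config)
}

.apply_lethality <- function(pedigree, drop, config) {
  n <- nrow(pedigree)
  offspring <- pedigree$litter != "0"
  fate <- rep("live", n)
  copies <- matrix(0L, n, length(config$lethals))
  for (i in seq_along(config$lethals)) {
    spec <- config$lethals[[i]]
    copies[, i] <- lethal_copies(drop, spec, config)
    hom <- offspring & copies[, i] == 2L & fate == "live"
    dies <- hom & stats::runif(n) < spec$penetrance
    fate[dies] <- switch(spec$stage, early = "early",
                         mid_gestation = "mum_lethal",
                         stillbirth = "nsb_lethal")
  }
  u <- stats::runif(n)
  base_mum <- offspring & fate == "live" & u < config$mum_rate
  base_nsb <- offspring & fate == "live" & !base_mum &
    u < config$mum_rate + config$nsb_rate
  fate[base_mum] <- "mum_base"
  fate[base_nsb] <- "nsb_base"
  lit <- pedigree$litter[offspring]
  cnt <- function(what) {
    tab <- table(factor(lit[fate[offspring] == what], levels = unique(lit)))
    as.integer(tab)
  }
  litters <- data.frame(litter = unique(lit),
                        sow = pedigree$dam[offspring][!duplicated(lit)],
                        boar = pedigree$sire[offspring][!duplicated(lit)],
                        conceived = as.integer(table(factor(lit, levels = unique(lit)))),
                        early_lethal = cnt("early"),
                        mum_lethal = cnt("mum_lethal"),
                        nsb_lethal = cnt("nsb_lethal"),
                        mum_base = cnt("mum_base"),
                        nsb_base = cnt("nsb_base"),
                        stringsAsFactors = FALSE)
  animals <- data.frame(animal = pedigree$animal, fate = fate,
                        stringsAsFactors = FALSE)
  if (length(config$lethals))
    for (i in seq_along(config$lethals))
      animals[[paste0("copies_", i)]] <- copies[, i]
  lets <- lethal_truth_table(config, drop$map, drop$pool)
  structure(list(litters = litters, animals = animals, lethals = lets,
                 dead = pedigree$animal[fate != "live"]),
            class = "truth_set")
}

#' Litter records from a truth set
#'
#' Applies the count accounting: early losses are never recorded;
#' NBA is the number of live fetuses; NSB the stillborn count; MUM
#' the mummified count; TNB = NBA + NSB, plus MUM when
#' `config$mum_in_tnb` is set.
#'
#' @param truth A `truth_set` from [apply_lethality()].
#' @param config A [sim_config()].
#' @return A litter data frame (`litter`, `sow`, `boar`, `tnb`,
#'   `nba`, `nsb`, `mum`).
#' @export
make_litters <- function(truth, config) {
  tl <- truth$litters
  if (is.null(tl) || nrow(tl) == 0L)
    return(data.frame(litter = character(0), sow = character(0),
                      boar = character(0), tnb = integer(0), nba = integer(0),
                      nsb = integer(0), mum = integer(0)))
  mum <- tl$mum_lethal + tl$mum_base
  nsb <- tl$nsb_lethal + tl$nsb_base
  live <- tl$conceived - tl$early_lethal - mum - nsb
  tnb <- live + nsb + if (config$mum_in_tnb) mum else 0L
  data.frame(litter = tl$litter, sow = tl$sow, boar = tl$boar,
             tnb = tnb, nba = live, nsb = nsb, mum = mum,
             stringsAsFactors = FALSE)
}

#' Emit a phased marker panel from a gene drop
#'
#' Translates founder-haplotype labels into phased biallelic alleles,
#' selects the genotyped animals (a random fraction of live
#' offspring, optionally enriched with their parents to create
#' complete trios), and injects missing genotype calls.
#' Deterministic under the config seed.
#'
#' @param drop A [gene_drop()] result.
#' @param pedigree The pedigree the drop was run on.
#' @param config A [sim_config()].
#' @param exclude Animal identifiers never genotyped (e.g. dead
#'   fetuses from [apply_lethality()]).
#' @return A [haplotype_panel()].
#' @export
emit_markers <- function(drop, pedigree, config, exclude = character(0)) {
  set.seed(config$seed + 3L)
  .emit_markers(drop, pedigree, config, exclude)
}

.emit_markers <- function(drop, pedigree, config, exclude = character(0)) {
  alive <- setdiff(pedigree$animal, exclude)
  rows <- match(alive, pedigree$animal)
  is_off <- if (!is.null(pedigree$litter)) pedigree$litter[rows] != "0"
            else pedigree$sire[rows] != "0" | pedigree$dam[rows] != "0"
  offspring <- alive[is_off]
  ng <- round(length(offspring) * config$genotyped_fraction)
  genotyped <- if (ng >= length(offspring)) offspring else sample(offspring, ng)
  if (config$trio_enrichment) {
    rows <- match(genotyped, pedigree$animal)
    genotyped <- union(genotyped,
                       setdiff(intersect(c(pedigree$sire[rows], pedigree$dam[rows]),
                                         alive), "0"))
  }
  genotyped <- pedigree$animal[pedigree$animal %in% genotyped]  # pedigree order
  ii <- match(genotyped, drop$ids)
  M <- nrow(drop$map)
  col <- rep(seq_len(M), each = length(ii))
  h1 <- matrix(drop$pool$alleles[cbind(as.vector(drop$L1[ii, , drop = FALSE]), col)],
               nrow = length(ii))
  h2 <- matrix(drop$pool$alleles[cbind(as.vector(drop$L2[ii, , drop = FALSE]), col)],
               nrow = length(ii))
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(h1)) < config$missing_rate, nrow = nrow(h1))
    h1[mask] <- NA_integer_
    h2[mask] <- NA_integer_
  }
  haplotype_panel(h1, h2, drop$map, ids = genotyped)
}

#' Simulate a closed breeding line with embedded lethal haplotypes
#'
#' End-to-end gene-drop simulation: builds the pedigree generation by
#' generation, drops founder haplotypes with recombination, applies
#' embedded lethality and baseline losses to every conceived fetus,
#' and emits litter records and a phased, selectively genotyped
#' marker panel. Unlike the staged functions, breeding animals of
#' each generation are selected among the survivors only — a dead
#' fetus cannot breed — so planted lethals shape the pedigree as they
#' would in a real population. With no lethality configured the
#' output distribution matches the staged pipeline.
#'
#' @param config A [sim_config()].
#' @return An object of class `lethal_sim`: list with `panel`
#'   ([haplotype_panel()]), `pedigree` (live animals only),
#'   `litters`, `matings`, `truth` (a `truth_set`), `map`, `config`.
#' @export
sim_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- sim_marker_map(config)
  pool <- make_founder_pool(config, map)
  chrs <- chrom_index(map, config)
  M <- nrow(map)
  n0 <- config$founder_males + config$founder_females
  cap <- n0 + ceiling(config$generations * config$founder_females *
                        config$litters_per_sow * (config$litter_lambda + 6 * sqrt(config$litter_lambda)))
  L1 <- matrix(0L, cap, M); L2 <- matrix(0L, cap, M)
  fl <- founder_labels(config, map, pool)
  L1[seq_len(n0), ] <- fl$L1
  L2[seq_len(n0), ] <- fl$L2
  ped <- data.frame(
    animal = c(sprintf("G0M%03d", seq_len(config$founder_males)),
               sprintf("G0F%04d", seq_len(config$founder_females))),
    sire = "0", dam = "0", line = "SIM",
    sex = rep(c("M", "F"), c(config$founder_males, config$founder_females)),
    generation = 0L, litter = "0", stringsAsFactors = FALSE)
  n_animals <- n0
  idx <- seq_len(n0); names(idx) <- ped$animal
  ped_rows <- list(ped)
  truth_litters <- list()
  truth_animals <- list(data.frame(animal = ped$animal, fate = "live",
                                   stringsAsFactors = FALSE))
  matings <- list()
  males <- ped$animal[ped$sex == "M"]
  females <- ped$animal[ped$sex == "F"]
  lwins <- lapply(config$lethals, function(s) lethal_window(map, s))
  lids <- pool$lethal_ids
  for (g in seq_len(config$generations)) {
    lit_no <- 0L
    gen_rows <- list(); gen_truth <- list(); gen_mat <- list()
    for (f in females) {
      fi <- idx[[f]]
      for (l in seq_len(config$litters_per_sow)) {
        lit_no <- lit_no + 1L
        litter_id <- sprintf("G%dL%05d", g, lit_no)
        boar <- sample(males, 1L)
        bi <- idx[[boar]]
        conceived <- 0L
        while (conceived < 1L) conceived <- stats::rpois(1L, config$litter_lambda)
        fates <- character(conceived)
        kept_g1 <- vector("list", conceived); kept_g2 <- vector("list", conceived)
        for (k in seq_len(conceived)) {
          g1 <- meiosis_one(L1[bi, ], L2[bi, ], chrs)
          g2 <- meiosis_one(L1[fi, ], L2[fi, ], chrs)
          fate <- "live"
          for (s in seq_along(config$lethals)) {
            win <- lwins[[s]]
            if (all(g1[win] == lids[s]) && all(g2[win] == lids[s]) &&
                stats::runif(1) < config$lethals[[s]]$penetrance) {
              fate <- switch(config$lethals[[s]]$stage, early = "early",
                             mid_gestation = "mum_lethal",
                             stillbirth = "nsb_lethal")
              break
            }
          }
          if (fate == "live") {
            u <- stats::runif(1)
            if (u < config$mum_rate) fate <- "mum_base"
            else if (u < config$mum_rate + config$nsb_rate) fate <- "nsb_base"
          }
          fates[k] <- fate
          if (fate %in% c("live")) { kept_g1[[k]] <- g1; kept_g2[[k]] <- g2 }
        }
        live <- which(fates == "live")
        if (length(live)) {
          ids_new <- sprintf("%sA%02d", litter_id, seq_along(live))
          sexes <- sample(c("M", "F"), length(live), replace = TRUE)
          need <- n_animals + length(live)
          if (need > nrow(L1)) {
            L1 <- rbind(L1, matrix(0L, nrow(L1), M))
            L2 <- rbind(L2, matrix(0L, nrow(L2), M))
          }
          for (k in seq_along(live)) {
            n_animals <- n_animals + 1L
            L1[n_animals, ] <- kept_g1[[live[k]]]
            L2[n_animals, ] <- kept_g2[[live[k]]]
            idx[[ids_new[k]]] <- n_animals
          }
          gen_rows[[length(gen_rows) + 1L]] <-
            data.frame(animal = ids_new, sire = boar, dam = f, line = "SIM",
                       sex = sexes, generation = g, litter = litter_id,
                       stringsAsFactors = FALSE)
        }
        gen_truth[[lit_no]] <- data.frame(
          litter = litter_id, sow = f, boar = boar, conceived = conceived,
          early_lethal = sum(fates == "early"),
          mum_lethal = sum(fates == "mum_lethal"),
          nsb_lethal = sum(fates == "nsb_lethal"),
          mum_base = sum(fates == "mum_base"),
          nsb_base = sum(fates == "nsb_base"), stringsAsFactors = FALSE)
        gen_mat[[lit_no]] <- data.frame(litter = litter_id, sow = f, boar = boar,
                                        generation = g, conceived = conceived,
                                        stringsAsFactors = FALSE)
      }
    }
    gen <- do.call(rbind, gen_rows)
    ped_rows[[g + 1L]] <- gen
    truth_litters[[g]] <- do.call(rbind, gen_truth)
    matings[[g]] <- do.call(rbind, gen_mat)
    males <- pick_parents(gen$animal[gen$sex == "M"], config$founder_males)
    females <- pick_parents(gen$animal[gen$sex == "F"], config$founder_females)
  }
  pedigree <- do.call(rbind, ped_rows)
  L1 <- L1[seq_len(n_animals), , drop = FALSE]
  L2 <- L2[seq_len(n_animals), , drop = FALSE]
  drop <- structure(list(L1 = L1, L2 = L2, ids = pedigree$animal, map = map,
                         pool = pool), class = "gene_drop")
  tl <- do.call(rbind, truth_litters)
  animals <- data.frame(animal = pedigree$animal, fate = "live",
                        stringsAsFactors = FALSE)
  for (s in seq_along(config$lethals))
    animals[[paste0("copies_", s)]] <- unname(lethal_copies(drop, config$lethals[[s]], config))
  lets <- lethal_truth_table(config, map, pool)
  truth <- structure(list(litters = tl, animals = animals, lethals = lets,
                          dead = character(0)),
                     class = "truth_set")
  litters <- make_litters(truth, config)
  panel <- .emit_markers(drop, pedigree, config)
  structure(list(panel = panel, pedigree = pedigree, litters = litters,
                 matings = do.call(rbind, matings), truth = truth,
                 map = map, config = config),
            class = "lethal_sim")
}

#' @export
print.lethal_sim <- function(x, ...) {
  cat("Simulated breeding line (seed", x$config$seed, "):",
      nrow(x$pedigree), "live animals,",
      nrow(x$litters), "litters,",
      length(x$panel$ids), "genotyped\n")
  if (!is.null(x$truth$lethals) && nrow(x$truth$lethals))
    cat("  planted lethals:",
        paste(sprintf("%s:%g-%g (f=%.2f, %s)", x$truth$lethals$chrom,
                      x$truth$lethals$start, x$truth$lethals$end,
                      x$truth$lethals$freq, x$truth$lethals$stage),
              collapse = "; "), "\n")
  invisible(x)
}
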