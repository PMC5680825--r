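small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, generations = 2, founder_males = 4,
             founder_females = 10, litter_lambda = 6,
             markers_per_chrom = 30, ...)
}

test_that("pedigree builder is deterministic and conserves litter sizes", {
  cfg <- small_cfg(seed = 5)
  a <- build_pedigree(cfg)
  b <- build_pedigree(cfg)
  expect_identical(a, b)
  off <- a$pedigree[a$pedigree$generation > 0, ]
  expect_true(all(off$sire != "0" & off$dam != "0"))
  # offspring per generation equals the sum of conceived litter sizes
  for (g in 1:2)
    expect_equal(sum(off$generation == g),
                 sum(a$matings$conceived[a$matings$generation == g]))
  expect_equal(nrow(a$matings), 2 * 10)  # litters_per_sow x sows x generations
})

test_that("gene drop transmits one parental haplotype per gamete", {
  cfg <- small_cfg(seed = 9)
  bp <- build_pedigree(cfg)
  drop <- gene_drop(bp$pedigree, cfg)
  expect_identical(dim(drop$L1), c(nrow(bp$pedigree), 30L))
  # every offspring label exists in the corresponding parent
  off <- which(bp$pedigree$sire != "0")
  for (i in off[1:20]) {
    si <- match(bp$pedigree$sire[i], bp$pedigree$animal)
    expect_true(all(drop$L1[i, ] %in% c(drop$L1[si, ], drop$L2[si, ])))
  }
})

test_that("zero recombination transmits founder haplotypes intact", {
  cfg <- sim_config(seed = 13, generations = 2, founder_males = 4,
                    founder_females = 10, litter_lambda = 6,
                    markers_per_chrom = 30, morgans = 0)
  bp <- build_pedigree(cfg)
  drop <- gene_drop(bp$pedigree, cfg)
  # each chromatid carries a single founder-haplotype label
  expect_true(all(apply(drop$L1, 1, function(x) length(unique(x))) == 1))
  expect_true(all(apply(drop$L2, 1, function(x) length(unique(x))) == 1))
})

test_that("het x het matings produce a quarter homozygotes without selection", {
  # founders engineered via a drop on a flat pedigree, neutral inheritance
  cfg <- sim_config(seed = 17, generations = 1, founder_males = 1,
                    founder_females = 200, litter_lambda = 8,
                    markers_per_chrom = 20, founder_pool = 2, morgans = 0,
                    lethals = lethal_spec("1", 5e6, 15e6, freq = 0.5,
                                          penetrance = 0))
  bp <- build_pedigree(cfg)
  drop <- gene_drop(bp$pedigree, cfg)
  spec <- cfg$lethals[[1]]
  copies <- lethal_copies(drop, spec, cfg)
  founders <- bp$pedigree$sire == "0"
  off <- !founders
  het_s <- copies[match(bp$pedigree$sire[off], bp$pedigree$animal)] == 1
  het_d <- copies[match(bp$pedigree$dam[off], bp$pedigree$animal)] == 1
  hh_off <- copies[which(off)[het_s & het_d]]
  expect_gt(length(hh_off), 200)
  expect_lt(abs(mean(hh_off == 2) - 0.25), 3 * sqrt(0.25 * 0.75 / length(hh_off)))
})

test_that("early lethality removes a quarter of carrier-mating litters", {
  cfg <- sim_config(seed = 19, generations = 1, founder_males = 10,
                    founder_females = 120, litter_lambda = 16,
                    markers_per_chrom = 40,
                    mum_rate = 0, nsb_rate = 0,
                    lethals = lethal_spec("1", 5e6, 15e6, freq = 0.3,
                                          penetrance = 1, stage = "early"))
  sim <- sim_population(cfg)
  copies <- setNames(sim$truth$animals$copies_1, sim$truth$animals$animal)
  cls <- classify_matings(sim$litters, copies)
  # restrict to het x het parents: expected TNB = lambda * 0.75
  hh <- cls$class == "CxC" &
    copies[cls$boar] == 1 & copies[cls$sow] == 1
  tnb <- cls$tnb[hh]
  expect_gt(length(tnb), 5)
  se <- sd(tnb) / sqrt(length(tnb))
  expect_lt(abs(mean(tnb) - 16 * 0.75), 4 * se + 0.5)
})

test_that("mid-gestation lethality adds a quarter litter of mummies", {
  cfg <- sim_config(seed = 23, generations = 1, founder_males = 10,
                    founder_females = 150, litter_lambda = 16,
                    markers_per_chrom = 40, mum_rate = 0.01,
                    lethals = lethal_spec("1", 5e6, 15e6, freq = 0.3,
                                          penetrance = 1,
                                          stage = "mid_gestation"))
  sim <- sim_population(cfg)
  copies <- setNames(sim$truth$animals$copies_1, sim$truth$animals$animal)
  cls <- classify_matings(sim$litters, copies)
  hh <- cls$class == "CxC" & copies[cls$boar] == 1 & copies[cls$sow] == 1
  mum <- cls$mum[hh]
  expect_gt(length(mum), 5)
  expected <- 0.25 * 16 + 0.75 * 16 * 0.01
  se <- sd(mum) / sqrt(length(mum))
  expect_lt(abs(mean(mum) - expected), 4 * se + 0.5)
})

test_that("zero penetrance leaves classes statistically indistinguishable", {
  cfg <- sim_config(seed = 29, generations = 1, founder_males = 10,
                    founder_females = 100, litter_lambda = 12,
                    markers_per_chrom = 40,
                    lethals = lethal_spec("1", 5e6, 15e6, freq = 0.3,
                                          penetrance = 0))
  sim <- sim_population(cfg)
  copies <- setNames(sim$truth$animals$copies_1, sim$truth$animals$animal)
  cls <- classify_matings(sim$litters, copies)
  eff <- trait_effect(cls, "tnb")
  expect_true(eff$testable)
  expect_gt(eff$welch_p, 1e-3)
  expect_lt(abs(eff$percent_difference), 15)
})

test_that("litter accounting follows the configured mummy convention", {
  truth <- structure(list(litters = data.frame(
    litter = "L1", sow = "W", boar = "B", conceived = 12L,
    early_lethal = 1L, mum_lethal = 1L, nsb_lethal = 0L,
    mum_base = 0L, nsb_base = 0L, stringsAsFactors = FALSE)),
    class = "truth_set")
  out <- make_litters(truth, sim_config(mum_in_tnb = FALSE))
  expect_equal(out$tnb, 10L)   # mummies excluded: TNB = NBA + NSB
  expect_equal(out$nba, 10L)
  expect_equal(out$mum, 1L)
  alt <- make_litters(truth, sim_config(mum_in_tnb = TRUE))
  expect_equal(alt$tnb, 11L)   # mummies inside TNB: conceived - early losses
  expect_equal(alt$nba, 10L)
  expect_equal(make_litters(structure(list(litters = NULL),
                                      class = "truth_set"),
                            sim_config()) |> nrow(), 0)
})

test_that("fetus counts are conserved across the whole simulation", {
  sim <- sim_population(small_cfg(seed = 31,
    lethals = lethal_spec("1", 5e6, 15e6, freq = 0.2, penetrance = 1,
                          stage = "mid_gestation")))
  tl <- sim$truth$litters
  expect_equal(sum(tl$conceived),
               sum(sim$litters$nba) + sum(tl$early_lethal) +
                 sum(sim$litters$nsb) + sum(sim$litters$mum))
  # litters table mirrors the truth per litter
  expect_equal(sim$litters$mum, tl$mum_lethal + tl$mum_base)
  expect_equal(sim$litters$nsb, tl$nsb_lethal + tl$nsb_base)
})

test_that("marker emission respects missingness and genotyped fraction", {
  cfg <- sim_config(seed = 37, generations = 1, founder_males = 5,
                    founder_females = 40, litter_lambda = 10,
                    markers_per_chrom = 250, missing_rate = 0.1)
  sim <- sim_population(cfg)
  miss <- mean(is.na(sim$panel$hap1))
  expect_lt(abs(miss - 0.10), 0.01)

  cfg2 <- sim_config(seed = 37, generations = 1, founder_males = 5,
                     founder_females = 40, litter_lambda = 10,
                     markers_per_chrom = 30, genotyped_fraction = 0.5,
                     trio_enrichment = FALSE)
  sim2 <- sim_population(cfg2)
  n_off <- sum(sim2$pedigree$generation > 0)
  n_genotyped_off <- sum(sim2$panel$ids %in%
                           sim2$pedigree$animal[sim2$pedigree$generation > 0])
  expect_equal(n_genotyped_off, round(n_off * 0.5))

  # zero missingness: panel alleles equal the founder mosaic exactly
  cfg3 <- small_cfg(seed = 39)
  sim3 <- sim_population(cfg3)
  expect_false(anyNA(sim3$panel$hap1))
})

test_that("identical configs give byte-identical simulations", {
  cfg <- small_cfg(seed = 41,
                   lethals = lethal_spec("1", 5e6, 15e6, freq = 0.2))
  a <- sim_population(cfg)
  b <- sim_population(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$litters, b$litters)
  expect_identical(a$truth$litters, b$truth$litters)
})

test_that("neutral allele-frequency drift is centred on zero", {
  # morgans = 0 so the haplotype is not eroded by recombination and
  # the change in frequency is pure Mendelian sampling
  deltas <- vapply(1:60, function(s) {
    cfg <- sim_config(seed = 1000 + s, generations = 2, founder_males = 6,
                      founder_females = 20, litter_lambda = 6,
                      markers_per_chrom = 10, founder_pool = 10, morgans = 0,
                      lethals = lethal_spec("1", 2e6, 18e6, freq = 0.25,
                                            penetrance = 0))
    sim <- sim_population(cfg)
    cp <- sim$truth$animals$copies_1
    gen <- sim$pedigree$generation
    mean(cp[gen == max(gen)]) / 2 - mean(cp[gen == 0]) / 2
  }, 0)
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 0.01)
})

test_that("a planted lethal is recovered end-to-end at reduced scale", {
  cfg <- sim_config(seed = 47, generations = 2, founder_males = 15,
                    founder_females = 80, litter_lambda = 14,
                    markers_per_chrom = 120,
                    lethals = lethal_spec("1", 1e7, 1.1e7, freq = 0.12,
                                          penetrance = 1,
                                          stage = "mid_gestation"))
  sim <- sim_population(cfg)
  fit <- lethal_scan(sim$panel, sim$pedigree, scan_params(), population = "SIM")
  r <- fit$records
  planted <- r[r$chrom == "1" & r$start == 1e7 & r$end == 1.1e7 &
                 r$observed == 0, ]
  planted <- planted[which.min(planted$p_value), ]
  expect_equal(planted$classification, "MH")
  expect_lt(planted$p_value, 5e-3)
})
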