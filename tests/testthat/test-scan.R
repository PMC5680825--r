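test_that("window grid follows the half-step sliding rule", {
  m <- 27
  map <- marker_map(paste0("m", 1:m), "1",
                    as.integer(seq(0.05e6, 2.65e6, 0.1e6)))
  w <- enumerate_windows(map, scan_params(window_sizes = 1e6))
  expect_equal(w$start, seq(0, 2.5e6, 0.5e6))
  expect_equal(w$end - w$start, rep(1e6, nrow(w)))
  # consecutive same-size windows overlap by exactly half their length
  expect_equal(w$start[-1] - w$start[-nrow(w)], rep(0.5e6, nrow(w) - 1))
})

test_that("every marker is covered by each window size whose grid reaches it", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      m <- sample(10:60, 1)
      pos <- sort(sample.int(5e6, m))
      map <- marker_map(paste0("m", 1:m), "1", pos)
      params <- scan_params()
      w <- enumerate_windows(map, params)
      for (size in params$window_sizes) {
        ws <- w[w$size == size, , drop = FALSE]
        covered <- rep(FALSE, m)
        for (i in seq_len(nrow(ws)))
          covered[ws$m_start[i]:ws$m_end[i]] <- TRUE
        # a marker can only be uncovered if every grid window holding it
        # has < 2 markers
        for (j in which(!covered)) {
          starts <- seq(0, pos[j], size * params$step_factor)
          starts <- starts[starts <= pos[j] & starts + size > pos[j]]
          n_in <- vapply(starts, function(s)
            sum(pos >= s & pos < s + size), 0L)
          expect_true(all(n_in < 2))
        }
      }
    }
  })
})

test_that("window haplotype counting respects the strict frequency threshold", {
  # 4 animals all AB|AB -> one haplotype at f = 1
  panel <- panel_from_strings(rep(list(c("01", "01")), 4))
  win <- list(m_start = 1, m_end = 2)
  tags <- window_haplotypes(panel, win, 0.005)
  expect_equal(nrow(tags), 1)
  expect_equal(tags$freq, 1)
  expect_equal(tags$homozygotes, 4L)

  # 100 animals: one chromosome carries a unique string -> f = 0.005, excluded
  haps <- c(list(c("11", "00")), rep(list(c("00", "00")), 99))
  panel2 <- panel_from_strings(haps)
  tags2 <- window_haplotypes(panel2, win, 0.005)
  expect_false("11" %in% tags2$allele)
  expect_true("00" %in% tags2$allele)

  # animals with missing phase drop out of the denominator
  haps3 <- list(c("01", "01"), c("01", "01"), c("0.", "01"))
  tags3 <- window_haplotypes(panel_from_strings(haps3), win, 0.005)
  expect_equal(attr(tags3, "n_complete"), 2L)
  expect_equal(tags3$freq, 1)
})

test_that("planted haplotype frequency is recovered within sampling error", {
  withr::with_seed(33, {
    n <- 1000
    carrier <- runif(2 * n) < 0.05
    mk <- function(is_c) if (is_c) "111" else
      paste0(sample(0:1, 3, TRUE, prob = c(0.6, 0.4)), collapse = "")
    haps <- lapply(seq_len(n), function(i)
      c(mk(carrier[2 * i - 1]), mk(carrier[2 * i])))
  })
  panel <- panel_from_strings(haps)
  tags <- window_haplotypes(panel, list(m_start = 1, m_end = 3), 0.005)
  f_hat <- tags$freq[tags$allele == "111"]
  # "111" also arises from the background at rate 0.4^3 * (1 - 0.05)
  f_exp <- 0.05 + 0.95 * 0.4^3
  expect_lt(abs(f_hat - f_exp), 0.02)
})

test_that("diplotype state counts exact matches and flags missing phase", {
  panel <- panel_from_strings(list(c("11", "11"), c("11", "01"),
                                   c("1.", "11"), c("00", "01")))
  win <- list(m_start = 1, m_end = 2)
  expect_equal(diplotype_state(panel, "A01", win, "11"), 2L)
  expect_equal(diplotype_state(panel, "A02", win, "11"), 1L)
  expect_true(is.na(diplotype_state(panel, "A03", win, "11")))
  expect_equal(diplotype_state(panel, "A04", win, "11"), 0L)
  expect_error(diplotype_state(panel, "nope", win, "11"), "unknown animal")
  cp <- diplotype_copies(panel, win, "11")
  expect_equal(unname(cp), c(2L, 1L, NA, 0L))
})

test_that("trio collection equals a brute-force pedigree join", {
  sim <- sim_population(sim_config(seed = 41, generations = 2,
                                   founder_males = 4, founder_females = 12,
                                   litter_lambda = 5, markers_per_chrom = 20,
                                   genotyped_fraction = 0.6))
  trios <- collect_trios(sim$pedigree, sim$panel)
  ids <- sim$panel$ids
  brute <- sum(sim$pedigree$animal %in% ids &
                 sim$pedigree$sire %in% ids &
                 sim$pedigree$dam %in% ids)
  expect_equal(nrow(trios), brute)
  expect_equal(collect_trios(sim$pedigree[0, ], sim$panel) |> nrow(), 0)
  # offspring with only one genotyped parent is excluded
  ped1 <- data.frame(animal = ids[1], sire = ids[2], dam = "ungenotyped")
  expect_equal(nrow(collect_trios(ped1, sim$panel)), 0)
})

test_that("trio expectation follows the transmission-product rule", {
  fx <- carrier_trio_fixture(n_off = 75, hom_off = 0)
  trios <- collect_trios(fx$ped, fx$panel)
  eh <- expected_homozygotes(fx$panel, fx$window, fx$allele, trios)
  expect_equal(eh$E, 18.75)  # 75 het x het offspring -> n / 4
  expect_equal(eh$n, 75L)
  expect_equal(eh$cxc_matings, 1L)

  # homozygous sire x heterozygous dam: E = 1 * (2/2) * (1/2)
  haps <- list(c("11", "11"), c("11", "00"), c("11", "01"))
  panel <- panel_from_strings(haps)
  ped <- data.frame(animal = "A03", sire = "A01", dam = "A02")
  eh2 <- expected_homozygotes(panel, fx$window, "11", collect_trios(ped, panel))
  expect_equal(eh2$E, 0.5)
  expect_equal(eh2$n, 1L)
})

test_that("trio expectation equals a per-trio loop oracle on random data", {
  withr::with_seed(43, {
    for (rep in 1:10) {
      n <- 30
      haps <- lapply(seq_len(n), function(i)
        c(paste0(sample(0:1, 2, TRUE), collapse = ""),
          paste0(sample(0:1, 2, TRUE), collapse = "")))
      panel <- panel_from_strings(haps)
      no <- 15
      ped <- data.frame(animal = panel$ids[1:no],
                        sire = sample(panel$ids[16:22], no, TRUE),
                        dam = sample(panel$ids[23:30], no, TRUE))
      win <- list(m_start = 1, m_end = 2)
      allele <- "11"
      eh <- expected_homozygotes(panel, win, allele, collect_trios(ped, panel))
      E <- 0; nn <- 0L
      for (i in seq_len(no)) {
        cs <- diplotype_state(panel, ped$sire[i], win, allele)
        cd <- diplotype_state(panel, ped$dam[i], win, allele)
        if (!is.na(cs) && !is.na(cd) && cs >= 1 && cd >= 1) {
          E <- E + (cs / 2) * (cd / 2)
          nn <- nn + 1L
        }
      }
      expect_identical(eh$E, E)
      expect_equal(eh$n, nn)
    }
  })
})

test_that("observed homozygotes are counted over the whole panel", {
  haps <- list(c("11", "11"), c("11", "01"), c("00", "00"), c("1.", "11"))
  panel <- panel_from_strings(haps)
  win <- list(m_start = 1, m_end = 2)
  expect_equal(observed_homozygotes(panel, win, "11"), 1L)
  expect_equal(observed_homozygotes(panel, win, "00"), 1L)
  expect_equal(observed_homozygotes(panel, win, "10"), 0L)
})

test_that("neutral-haplotype homozygote count sits in the HWE band", {
  withr::with_seed(47, {
    n <- 2000; f <- 0.10
    draw <- function() if (runif(1) < f) "11" else
      paste0(sample(c("00", "01", "10"), 1))
    haps <- lapply(seq_len(n), function(i) c(draw(), draw()))
  })
  panel <- panel_from_strings(haps)
  O <- observed_homozygotes(panel, list(m_start = 1, m_end = 2), "11")
  expect_lt(abs(O - n * f^2), 3 * sqrt(n * f^2 * (1 - f^2)))
})

test_that("two-sided exact binomial matches the rational enumeration oracle", {
  for (ab in list(c(1, 10), c(1, 4), c(1, 2))) {
    for (n in 1:12) for (k in 0:n) {
      expect_equal(binom_two_sided(k, n, ab[1] / ab[2]),
                   binom_oracle_rational(k, n, ab[1], ab[2]),
                   tolerance = 1e-12,
                   info = sprintf("k=%d n=%d p=%d/%d", k, n, ab[1], ab[2]))
    }
  }
})

test_that("two-sided exact binomial agrees with stats::binom.test", {
  withr::with_seed(53, {
    for (i in 1:50) {
      n <- sample(1:200, 1)
      k <- sample(0:n, 1)
      p <- runif(1, 0.05, 0.95)
      expect_equal(binom_two_sided(k, n, p),
                   stats::binom.test(k, n, p)$p.value, tolerance = 1e-9)
    }
  })
  expect_error(binom_two_sided(-1, 5, 0.5), "invalid")
  expect_error(binom_two_sided(6, 5, 0.5), "invalid")
  expect_error(binom_two_sided(1, 5, 0), "invalid")
})

test_that("p-value is maximal at the mode and decays away from it", {
  for (n in c(7, 20)) for (p in c(0.25, 0.5)) {
    pv <- vapply(0:n, binom_two_sided, 0, n = n, p = p)
    mode <- which.max(stats::dbinom(0:n, n, p)) - 1L
    expect_equal(pv[mode + 1], 1)
    expect_true(all(diff(pv[seq_len(mode + 1)]) >= 0))           # rising to mode
    expect_true(all(diff(pv[(mode + 1):(n + 1)]) <= 0))          # falling after
  }
})

test_that("haplotype test composes expectation, observation and the binomial", {
  fx <- carrier_trio_fixture(n_off = 75, hom_off = 0, het_off = 50)
  trios <- collect_trios(fx$ped, fx$panel)
  rec <- test_haplotype(fx$panel, fx$window, fx$allele, trios)
  expect_equal(rec$expected / rec$progeny, 0.25)  # all-het parents
  expect_equal(rec$p_value, 5.70e-10, tolerance = 1e-3)
  expect_equal(rec$classification, "MH")
  expect_equal(rec$het_carriers, 50L)

  # no carrier x carrier progeny -> untestable
  haps <- list(c("00", "00"), c("00", "00"), c("00", "00"))
  panel <- panel_from_strings(haps)
  ped <- data.frame(animal = "A03", sire = "A01", dam = "A02")
  rec0 <- test_haplotype(panel, fx$window, "11", collect_trios(ped, panel))
  expect_false(rec0$testable)
  expect_equal(rec0$classification, "not_testable")
})

test_that("homozygotes outside trios cap the test statistic at n", {
  # 1 trio (het x het) + 3 non-trio homozygotes -> O = 3 > n = 1
  haps <- list(c("10", "11"), c("11", "00"), c("11", "00"),
               c("11", "11"), c("11", "11"), c("11", "11"))
  panel <- panel_from_strings(haps)
  ped <- data.frame(animal = "A03", sire = "A01", dam = "A02")
  win <- list(chrom = "1", start = 0, end = 3e5, m_start = 1, m_end = 2)
  rec <- test_haplotype(panel, win, "11", collect_trios(ped, panel))
  expect_equal(rec$observed, 3L)
  expect_equal(rec$progeny, 1L)
  expect_equal(rec$note, "non-trio homozygotes")
  expect_equal(rec$p_value, binom_two_sided(1, 1, 0.25))
})

test_that("MH/DH classification applies the dual thresholds", {
  p <- scan_params()
  expect_equal(classify_scan(0L, 1e-4, TRUE, p), "MH")
  expect_equal(classify_scan(3L, 1e-5, TRUE, p), "not_significant")
  expect_equal(classify_scan(1L, 8.22e-8, TRUE, p), "DH")
  expect_equal(classify_scan(0L, 6e-3, TRUE, p), "not_significant")
  expect_equal(classify_scan(0L, NA, FALSE, p), "not_testable")
})

test_that("het-carrier fraction distinguishes lethal from neutral segregation", {
  fx <- carrier_trio_fixture(n_off = 300, hom_off = 0)  # lethal-like: 2/3 het
  trios <- collect_trios(fx$ped, fx$panel)
  hf <- het_carrier_fraction(fx$panel, fx$window, fx$allele, trios)
  expect_equal(hf$percent, 100 * 200 / 300, tolerance = 1e-9)
  fx2 <- carrier_trio_fixture(n_off = 300, hom_off = 75, het_off = 150)
  hf2 <- het_carrier_fraction(fx2$panel, fx2$window, fx2$allele,
                              collect_trios(fx2$ped, fx2$panel))
  expect_equal(hf2$percent, 50)
  # no carrier matings -> undefined
  haps <- list(c("00", "00"), c("00", "00"), c("00", "00"))
  panel <- panel_from_strings(haps)
  ped <- data.frame(animal = "A03", sire = "A01", dam = "A02")
  hf0 <- het_carrier_fraction(panel, fx$window, "11", collect_trios(ped, panel))
  expect_equal(hf0$count, 0L)
  expect_true(is.na(hf0$percent))
})
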