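test_that("weighted_gc is the linear mass-fraction combination", {
  expect_equal(weighted_gc(c(40, 60), c(0.5, 0.5)), 50)
  expect_equal(weighted_gc(55, 1), 55)
  expect_equal(weighted_gc(c(43, 50, 66), c(0.2, 0.3, 0.5)), 56.6)
  expect_error(weighted_gc(c(40, 60), c(0.6, 0.6)), "sum to 1")
})

test_that("solve_fractions inverts the weighted-GC map", {
  # two strains: unique solution of the linear constraint
  f <- solve_fractions(c(40, 60), 47)
  expect_equal(f, c(0.65, 0.35), tolerance = 1e-9)
  # target equal to the prior mixture returns the prior
  expect_equal(solve_fractions(c(40, 50, 60), 50), rep(1 / 3, 3),
               tolerance = 1e-12)
  expect_error(solve_fractions(c(40, 60), 35), "attainable range")
  # the six published weighted-GC targets are feasible on the example pool
  pool <- example_mock_pool()
  for (t in c(47, 50, 53, 57, 60, 63)) {
    f <- solve_fractions(pool$strains$gc, t, prior = pool$strains$prior)
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_equal(weighted_gc(pool$strains$gc, f), t, tolerance = 1e-9)
  }
})

test_that("expected_abundance implements dosage-normalized percentages", {
  # one strain, one gene
  expect_equal(unname(expected_abundance(matrix(2, 1, 1,
                                                dimnames = list("s", "g")),
                                         1e6, 1)), 100)
  # dosage is copies / length: 2 Mb vs 4 Mb, one distinct gene each
  cp <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("gA", "gB")))
  ab <- expected_abundance(cp, c(2e6, 4e6), c(0.5, 0.5))
  expect_equal(unname(ab), c(200 / 3, 100 / 3), tolerance = 1e-9)
  # invariant under uniform genome-length scaling
  set.seed(3)
  cp2 <- matrix(rpois(12, 1.5), 3, 4,
                dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
  cp2[1, 1] <- cp2[1, 1] + 1
  lens <- c(3e6, 5e6, 2.5e6); fr <- c(0.2, 0.5, 0.3)
  expect_equal(expected_abundance(cp2, lens, fr),
               expected_abundance(cp2, lens / 100, fr), tolerance = 1e-12)
  expect_error(expected_abundance(0 * cp2, lens, fr), "empty design")
  expect_error(mock_design(data.frame(name = "s", length_bp = 1e4, gc = 50),
                           matrix(0, 1, 1, dimnames = list("s", "g")),
                           mass_fractions = 1),
               "empty design")
})

test_that("volumes_to_fractions converts via DNA mass", {
  expect_equal(volumes_to_fractions(c(10, 10), c(5, 15)), c(0.25, 0.75))
  expect_error(volumes_to_fractions(c(0, 0), c(5, 5)), "zero")
})

test_that("expected abundance matches a deep unbiased fragment tally", {
  fx <- fixture_ref()
  set.seed(53)
  n_strain <- 18
  fams <- fx$registry$families$name
  strains <- data.frame(name = sprintf("g%02d", 1:n_strain), kind = "genome",
                        length_bp = sample(seq(25000, 60000, 1000), n_strain),
                        gc = runif(n_strain, 38, 66))
  copies <- matrix(0L, n_strain, length(fams),
                   dimnames = list(strains$name, fams))
  for (i in 1:n_strain) {
    picked <- sample(fams, sample(2:4, 1))
    copies[i, picked] <- sample(1:3, length(picked), replace = TRUE)
  }
  des <- mock_design(strains, copies, target_gc = 53)
  comm <- synth_community(strains, copies, fx$ref$consensus, seed = 54)
  fr <- fragment_pool(des, comm$genomes, comm$truth, 120000, seed = 55)
  labs <- unlist(strsplit(fr$truth[nzchar(fr$truth)], ",", fixed = TRUE))
  obs <- 100 * as.numeric(table(factor(labs, fams))) /
    length(labs)
  # per-fragment tally of a deep unbiased simulation, within 1% absolute
  expect_true(all(abs(obs - unname(des$expected_abundance[fams])) < 1))
})

test_that("synth_strain plants genes faithfully and reproducibly", {
  fx <- fixture_ref()
  cons <- fx$ref$consensus
  # pure background at 100 kb: measured GC within 1.5 points of request
  g0 <- synth_strain("bg", 1e5, 47, c(nifH = 0L), cons, seed = 2)
  expect_lt(abs(g0$spec$gc_measured - 47), 1.5)
  expect_identical(nrow(g0$truth), 0L)
  # divergence 0: planted gene identical to consensus
  g1 <- synth_strain("s1", 20000, 50, data.frame(family = "mcrA", copies = 1,
                                                 divergence = 0),
                     cons, seed = 3)
  tr <- g1$truth
  got <- substr(g1$genome, tr$start + 1, tr$end)
  if (tr$strand == "-") got <- revcomp(got)
  expect_identical(unname(got), unname(cons[["mcrA"]]))
  # determinism
  g2 <- synth_strain("s1", 20000, 50, data.frame(family = "mcrA", copies = 1,
                                                 divergence = 0),
                     cons, seed = 3)
  expect_identical(g1$genome, g2$genome)
  expect_error(synth_strain("tiny", 800, 50, c(mcrA = 5L), cons, seed = 1),
               "overcrowded")
})

test_that("planted truth intervals never overlap and retranslate cleanly", {
  fx <- fixture_ref()
  set.seed(59)
  for (rep in 1:5) {
    g <- synth_strain(paste0("s", rep), 30000, runif(1, 35, 65),
                      c(nosZ = 3L, mcrA = 2L, nifH = 2L),
                      fx$ref$consensus, seed = 100 + rep)
    tr <- g$truth[order(g$truth$start), ]
    expect_true(all(tr$start[-1] >= head(tr$end, -1)))
    for (i in seq_len(nrow(tr))) {
      s <- substr(g$genome, tr$start[i] + 1, tr$end[i])
      if (tr$strand[i] == "-") s <- revcomp(s)
      pep <- probecap:::translate_cds(s)
      expect_false(grepl("*", pep, fixed = TRUE))
    }
  }
})

test_that("mutate_cds never introduces in-frame stops", {
  fx <- fixture_ref()
  set.seed(61)
  for (i in 1:10) {
    m <- mutate_cds(fx$ref$consensus[["nosZ"]], 0.25)
    expect_false(grepl("*", probecap:::translate_cds(m), fixed = TRUE))
  }
})
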