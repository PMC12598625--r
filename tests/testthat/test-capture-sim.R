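# small two-strain design used across capture tests
capture_fixture <- function() {
  fx <- fixture_ref()
  strains <- data.frame(name = c("sA", "sB"), kind = "genome",
                        length_bp = c(30000, 30000), gc = c(45, 60))
  copies <- matrix(c(2L, 0L, 0L, 2L), 2, 2, byrow = TRUE,
                   dimnames = list(strains$name, c("nosZ", "mcrA")))
  design <- mock_design(strains, copies, mass_fractions = c(0.7, 0.3))
  comm <- synth_community(strains, copies, fx$ref$consensus, seed = 71)
  list(design = design, comm = comm)
}

test_that("fragment_pool samples strains by mass fraction", {
  cf <- capture_fixture()
  expect_identical(nrow(fragment_pool(cf$design, cf$comm$genomes,
                                      cf$comm$truth, 0)), 0L)
  fr <- fragment_pool(cf$design, cf$comm$genomes, cf$comm$truth, 10000,
                      seed = 72)
  nA <- sum(fr$strain == "sA")
  expect_lt(abs(nA - 7000), 3 * sqrt(10000 * 0.7 * 0.3))
  # insert-size model: mean 630 by default, truncated at 50
  expect_equal(formals(fragment_pool)$mean_len, 630)
  lens <- fr$end - fr$start
  expect_true(all(lens >= 50))
  expect_lt(abs(mean(lens) - 630), 3 * 60 / sqrt(10000))
  expect_true(all(nchar(fr$seq) == lens))
  # truth labels come from >= 50 bp overlap with planted genes
  on <- fr[nzchar(fr$truth), ]
  i <- 1L
  tr <- cf$comm$truth
  ov <- pmin(on$end[i], tr$end[tr$chrom == on$strain[i]]) -
    pmax(on$start[i], tr$start[tr$chrom == on$strain[i]])
  expect_gte(max(ov), 50)
})

test_that("capture probability follows the stated formula", {
  m <- capture_model()  # defaults: p_max .95, kappa 30, x0 .8, bias on
  expect_equal(capture_probability(m, 1.0, 0.5),
               0.95 * (1 / (1 + exp(-6))) * 0.7, tolerance = 1e-12)
  off <- capture_model(gc_bias = FALSE)
  expect_equal(capture_probability(off, 1.0, 0.1),
               capture_probability(off, 1.0, 0.9))
  # limiting case: perfect match always captured
  lim <- capture_model(p_max = 1, kappa = 1000, gc_bias = FALSE)
  expect_equal(capture_probability(lim, 1.0, 0.5), 1, tolerance = 1e-9)
  # monotone in identity and (bias on) non-decreasing in GC
  xs <- seq(0, 1, 0.05)
  expect_true(all(diff(capture_probability(m, xs, 0.5)) > 0))
  expect_true(all(diff(capture_probability(m, 0.9, xs)) >= 0))
  # gamma clamps to [0, 1]
  wide <- capture_model(gamma0 = -1, gamma1 = 4)
  expect_equal(capture_probability(wide, 1, 0.1), 0)
  expect_equal(capture_probability(wide, 1, 0.9),
               capture_probability(capture_model(gamma0 = -1, gamma1 = 4,
                                                 gc_bias = FALSE), 1, 0.9))
})

test_that("hybridize is an enrichment filter", {
  cf <- capture_fixture()
  fr <- fragment_pool(cf$design, cf$comm$genomes, cf$comm$truth, 4000,
                      seed = 73)
  empty_panel <- assemble_panel(list())
  expect_identical(nrow(hybridize(fr, empty_panel, capture_model())), 0L)

  fx <- fixture_ref()
  tdb <- dereplicate(fx$ref$variants[fx$ref$variants$family %in%
                                       c("nosZ", "mcrA"), ])
  panel <- design_panel(tdb)
  cap <- hybridize(fr, panel, capture_model(), seed = 74)
  expect_true(all(cap$fragment_id %in% fr$fragment_id))  # subset
  expect_gt(mean(nzchar(cap$truth)), 0.5)                # enriched
  expect_gt(mean(nzchar(cap$truth)), mean(nzchar(fr$truth)))
  # determinism under seed
  cap2 <- hybridize(fr, panel, capture_model(), seed = 74)
  expect_identical(cap, cap2)

  # ideal model: every fragment containing an exact probe match is captured
  ideal <- capture_model(p_max = 1, kappa = 1000, x0 = 0.75, gc_bias = FALSE)
  exact <- vapply(fr$seq, function(s) {
    any(vapply(panel$sequence, function(p)
      grepl(p, s, fixed = TRUE) || grepl(p, revcomp(s), fixed = TRUE),
      logical(1)))
  }, logical(1))
  capi <- hybridize(fr, panel, ideal, seed = 75)
  expect_true(all(fr$fragment_id[exact] %in% capi$fragment_id))
  # probe-free random background passes only rarely
  bg <- fr[!nzchar(fr$truth), ]
  expect_lt(mean(bg$fragment_id %in% capi$fragment_id), 0.05)
})

test_that("sequence_reads produces faithful mate pairs", {
  cf <- capture_fixture()
  fr <- fragment_pool(cf$design, cf$comm$genomes, cf$comm$truth, 300,
                      seed = 76)
  rs <- sequence_reads(fr, read_len = 300, error_rate = 0, seed = 77)
  expect_identical(sum(rs$mate == 1), sum(rs$mate == 2))
  r1 <- rs[rs$mate == 1, ]; r2 <- rs[rs$mate == 2, ]
  i <- match(fr$fragment_id, r1$fragment_id)
  expect_identical(r1$seq[i], substring(fr$seq, 1, 300))
  j <- match(fr$fragment_id, r2$fragment_id)
  flen <- nchar(fr$seq)
  expect_identical(r2$seq[j],
                   revcomp(substring(fr$seq, pmax(1, flen - 299), flen)))
  expect_identical(r1$read_id[i], paste0(fr$fragment_id, "/1"))
  # default read length is 300 (PE300)
  expect_equal(formals(sequence_reads)$read_len, 300)

  # error model: observed mismatch rate within 3 SD of the nominal rate
  rs2 <- sequence_reads(fr, read_len = 300, error_rate = 0.01, seed = 78)
  r1e <- rs2[rs2$mate == 1, ]
  i <- match(fr$fragment_id, r1e$fragment_id)
  tot <- 0L; mm <- 0L
  for (k in seq_along(i)) {
    x <- strsplit(substring(fr$seq[k], 1, 300), "")[[1]]
    y <- strsplit(r1e$seq[i[k]], "")[[1]]
    tot <- tot + length(x); mm <- mm + sum(x != y)
  }
  expect_lt(abs(mm / tot - 0.01), 3 * sqrt(0.01 * 0.99 / tot))
})
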