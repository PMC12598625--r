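test_that("six-frame translation follows the standard code", {
  fr <- translate_six_frames("ATG")
  expect_identical(fr[["+1"]], "M")
  expect_identical(fr[["+2"]], "")
  expect_identical(fr[["+3"]], "")
  expect_identical(translate_six_frames("ATGAAATAG")[["+1"]], "MK*")
  expect_warning(fr2 <- translate_six_frames("AT"), "shorter")
  expect_true(all(fr2 == ""))
  # reverse-complement symmetry: frame -1 of s is frame +1 of revcomp(s)
  set.seed(83)
  for (i in 1:10) {
    s <- rand_dna(sample(30:90, 1))
    expect_identical(translate_six_frames(s)[["-1"]],
                     translate_six_frames(revcomp(s))[["+1"]])
  }
})

# a read synthesized from a known coding sequence, and dbs derived from it
classify_fixture <- function() {
  set.seed(89)
  gene <- probecap:::random_cds(120, gc = 0.5)   # 360 nt
  pep <- probecap:::translate_cds(gene)          # 120 aa
  rand_pep <- function(n) paste(sample(names(probecap:::AA_BACKGROUND), n,
                                       TRUE, probecap:::AA_BACKGROUND),
                                collapse = "")
  list(gene = gene, pep = pep, rand_pep = rand_pep)
}

test_that("map_and_retain applies identity, E and the overlap rule", {
  cf <- classify_fixture()
  read <- substr(cf$gene, 1, 300)                # aa 0..100 of pep in frame +1
  # dbA: hit covers read aa 0..50; dbB: aa 45..100 (5 aa overlap with dbA)
  # dbC: aa 30..100 (>= 20 aa overlap with dbA, scores higher than dbA)
  dbA <- paste0(substr(cf$pep, 1, 50), cf$rand_pep(60))
  dbB <- paste0(cf$rand_pep(45), substr(cf$pep, 46, 100), cf$rand_pep(20))
  dbC <- paste0(cf$rand_pep(30), substr(cf$pep, 31, 100))
  mk_db <- function(seqs, fams) {
    calibrate_protein_db(protein_db(setNames(seqs, paste0("t", seq_along(seqs))),
                                    family = fams), seed = 5)
  }
  # small-overlap pair: both retained
  db <- mk_db(c(dbA, dbB), c("famA", "famB"))
  hits <- map_and_retain(c(r1 = read), db)
  expect_setequal(hits$family, c("famA", "famB"))
  ov <- min(hits$nt_end) - max(hits$nt_start)
  expect_lte(ov, 3 * 15)
  # large-overlap pair: the lower-scoring hit is dropped
  db2 <- mk_db(c(dbA, dbC), c("famA", "famC"))
  hits2 <- map_and_retain(c(r1 = read), db2)
  expect_identical(unique(hits2$family), "famC")  # 70 aa beats 50 aa
  # no-similarity read yields nothing
  expect_identical(nrow(map_and_retain(c(r0 = rand_dna(300)), db)), 0L)
  # retained hits respect the caps
  expect_true(all(hits$percent_identity >= 60))
  expect_true(all(hits$E <= 0.001))
  expect_true(all(table(hits$read_id, hits$direction) <= 4))
})

test_that("decoy reads at 30-55% identity are never retained", {
  cf <- classify_fixture()
  db <- calibrate_protein_db(protein_db(c(t1 = cf$pep), family = "fam"),
                             seed = 6)
  set.seed(97)
  # mutation ladder: nucleotide divergence 0.30-0.55 pushes aa identity
  # well below the 60% floor
  for (d in c(0.30, 0.40, 0.55)) {
    read <- mutate_dna(substr(cf$gene, 1, 300), d)
    hits <- map_and_retain(setNames(read, paste0("r", d)), db)
    expect_identical(nrow(hits), 0L)
  }
  # while the clean read is retained
  expect_gt(nrow(map_and_retain(c(rc = substr(cf$gene, 1, 300)), db)), 0L)
})

test_that("resolve_homologs collapses and disambiguates", {
  reg <- default_registry()
  hit_row <- function(fam, E, dir = "fwd", score = 100) {
    data.frame(read_id = "r1", frame = "+1", direction = dir,
               target_id = paste0("t_", fam), family = fam,
               percent_identity = 90, score = score, E = E,
               aa_start = 0L, aa_end = 50L, nt_start = 0L, nt_end = 150L,
               stringsAsFactors = FALSE)
  }
  # single hit -> that family
  ann <- resolve_homologs(hit_row("nosZ", 1e-20), reg)
  expect_identical(ann$family, "nosZ")
  # amoA at better E displaces pmoA, which is recorded as reassigned
  ann2 <- resolve_homologs(rbind(hit_row("amoA", 1e-30),
                                 hit_row("pmoA", 1e-12)), reg)
  expect_identical(ann2$family, "amoA")
  re <- attr(ann2, "reassignments")
  expect_identical(re$from_family, "pmoA")
  expect_identical(re$to_family, "amoA")
  # same family twice in one direction collapses to the best E
  ann3 <- resolve_homologs(rbind(hit_row("nirK", 1e-8),
                                 hit_row("nirK", 1e-20)), reg)
  expect_identical(nrow(ann3), 1L)
  expect_equal(ann3$E, 1e-20)
  # families in different groups coexist
  ann4 <- resolve_homologs(rbind(hit_row("nosZ", 1e-10),
                                 hit_row("mcrA", 1e-8, dir = "rev")), reg)
  expect_setequal(ann4$family, c("nosZ", "mcrA"))
  # decoy competition: narH displaces both nxrB and narG when it wins
  ann5 <- resolve_homologs(rbind(hit_row("nxrB", 1e-10),
                                 hit_row("narH", 1e-25),
                                 hit_row("narG", 1e-12)), reg)
  expect_identical(ann5$family, "narH")
})

test_that("tabulate_families computes both normalizations", {
  ann <- data.frame(read_id = c(sprintf("a%02d", 1:30), sprintf("b%02d", 1:70)),
                    family = rep(c("gA", "gB"), c(30, 70)))
  tab <- tabulate_families(ann, total_reads = 1000)
  expect_equal(tab$rel_target, c(30, 70))
  expect_equal(tab$rel_total, c(3, 7))
  expect_equal(sum(tab$rel_target), 100, tolerance = 1e-9)
  # permutation invariance
  tab2 <- tabulate_families(ann[sample(nrow(ann)), ], total_reads = 1000)
  expect_equal(tab, tab2, ignore_attr = TRUE)
  # single family -> 100%
  expect_equal(tabulate_families(ann[1:5, ], 10)$rel_target, 100)
  expect_error(tabulate_families(ann, 0), "total_reads")
})

test_that("per-direction retention caps hold on real pipeline hits", {
  m6 <- fixture_mock6()
  des <- m6$design
  fr <- fragment_pool(des, m6$comm$genomes, m6$comm$truth, 3000, seed = 101)
  cap <- hybridize(fr, m6$panel, capture_model(), seed = 102)
  rds <- sequence_reads(cap, seed = 103)
  hits <- map_and_retain(rds, m6$pdb)
  expect_gt(nrow(hits), 0L)
  expect_true(all(hits$percent_identity >= 60))
  expect_true(all(hits$E <= 0.001))
  expect_true(all(table(hits$read_id, hits$direction) <= 4))
  # pairwise overlaps within a direction never exceed 15 aa
  for (key in unique(paste(hits$read_id, hits$direction))) {
    hh <- hits[paste(hits$read_id, hits$direction) == key, ]
    if (nrow(hh) < 2) next
    for (i in 1:(nrow(hh) - 1)) for (j in (i + 1):nrow(hh)) {
      ov <- min(hh$nt_end[i], hh$nt_end[j]) - max(hh$nt_start[i], hh$nt_start[j])
      expect_lte(ov, 3 * 15)
    }
  }
})
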