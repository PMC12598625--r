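test_that("greedy clustering separates at the 80% threshold", {
  set.seed(23)
  s1 <- rand_dna(300)
  s2 <- mutate_dna(s1, 0.10)   # ~90% identity -> joins s1
  s3 <- mutate_dna(s1, 0.30)   # ~70% identity -> separate cluster
  s4 <- rand_dna(280)
  s5 <- mutate_dna(s4, 0.05)
  df <- data.frame(id = paste0("s", 1:5), seq = c(s1, s2, s3, s4, s5))
  cl <- cluster_sequences(df, threshold = 0.80)
  a <- setNames(cl$assignments$cluster, cl$assignments$id)
  expect_identical(a[["s1"]], a[["s2"]])
  expect_false(a[["s1"]] == a[["s3"]])
  expect_identical(a[["s4"]], a[["s5"]])
  # equals the independently coded greedy oracle
  oc <- oracle_greedy_cluster(df$id, df$seq, 0.80)
  expect_identical(unname(a[df$id]), unname(oc$assign[df$id]))
  # single sequence: self-representative
  one <- cluster_sequences(c(only = "ACGTACGTAC"), 0.8)
  expect_identical(one$representatives$id, "only")
  expect_true(one$assignments$is_representative)
  # empty input
  expect_identical(nrow(cluster_sequences(character(0))$assignments), 0L)
})

test_that("cluster members satisfy the representative identity bound", {
  set.seed(29)
  base <- replicate(3, rand_dna(150))
  seqs <- c(base, unlist(lapply(base, function(b)
    replicate(2, mutate_dna(b, runif(1, 0, 0.12))))))
  df <- data.frame(id = sprintf("q%02d", seq_along(seqs)), seq = seqs)
  cl <- cluster_sequences(df, 0.80)
  for (i in seq_len(nrow(cl$assignments))) {
    rep_seq <- cl$representatives$seq[cl$assignments$cluster[i]]
    expect_gte(seq_identity(df$seq[match(cl$assignments$id[i], df$id)],
                            rep_seq), 0.80)
  }
  # partition: disjoint, covering
  expect_setequal(cl$assignments$id, df$id)
})

# independent exhaustive re-implementation of the candidate scoring
oracle_design <- function(rep_seq, members, k = 50, max_probes = 6,
                          tm_target = 47, max_mismatch = 5) {
  offs <- 0:(nchar(rep_seq) - k)
  cand <- substring(rep_seq, offs + 1, offs + k)
  ok <- !grepl("[^ACGT]", cand) &
    !grepl(sprintf("A{8}|C{8}|G{8}|T{8}"), cand)
  offs <- offs[ok]; cand <- cand[ok]
  cov <- vapply(cand, function(p) {
    sum(vapply(members, function(m) {
      if (nchar(m) < k) return(FALSE)
      ws <- 0:(nchar(m) - k)
      any(vapply(ws, function(w) {
        sum(strsplit(substring(m, w + 1, w + k), "")[[1]] !=
              strsplit(p, "")[[1]]) <= max_mismatch
      }, logical(1)))
    }, logical(1)))
  }, numeric(1))
  ngc <- vapply(strsplit(cand, ""), function(v) sum(v %in% c("G", "C")),
                numeric(1))
  tm <- 64.9 + 41 * (ngc - 16.4) / k
  ord <- order(-cov, abs(tm - tm_target), offs)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= max_probes) break
    if (all(abs(offs[sel] - offs[i]) >= k / 2)) sel <- c(sel, i)
  }
  data.frame(sequence = cand[sel], offset = offs[sel],
             member_coverage = cov[sel], row.names = NULL)
}

test_that("design_probes matches the exhaustive candidate oracle", {
  set.seed(31)
  rep_seq <- rand_dna(200)
  members <- c(rep_seq, mutate_dna(rep_seq, 0.08), mutate_dna(rep_seq, 0.15))
  got <- design_probes(rep_seq, members)
  want <- oracle_design(rep_seq, members)
  expect_identical(got$sequence, want$sequence)
  expect_identical(got$offset, want$offset)
  expect_identical(as.integer(got$member_coverage),
                   as.integer(want$member_coverage))
})

test_that("design_probes honours length, spacing and quality guards", {
  set.seed(37)
  # representative exactly 50 nt -> the single probe is the representative
  r50 <- rand_dna(50)
  one <- design_probes(r50, r50)
  expect_identical(one$sequence, r50)
  expect_identical(one$offset, 0L)
  expect_error(design_probes(rand_dna(30), character(0)), "shorter")
  # homopolymers and ambiguity codes are excluded
  rep_seq <- paste0(rand_dna(60), strrep("A", 10), rand_dna(60))
  pr <- design_probes(rep_seq, rep_seq)
  expect_false(any(grepl("A{8}", pr$sequence)))
  expect_error(design_probes(strrep("N", 60), strrep("N", 60)),
               "quality")
  # probes are k-mers of the representative at the stated offset
  big <- rand_dna(400)
  pr <- design_probes(big, big)
  expect_true(all(nchar(pr$sequence) == 50))
  expect_identical(pr$sequence,
                   substring(big, pr$offset + 1, pr$offset + 50))
  expect_lte(nrow(pr), 6L)
  d <- as.matrix(dist(pr$offset))
  expect_true(all(d[upper.tri(d)] >= 25))
  # Tm model: 25 G/C in a 50-mer -> 71.95 C
  expect_equal(probe_tm(strrep("GA", 25)), 64.9 + 41 * (25 - 16.4) / 50)
  expect_equal(probe_tm(strrep("GA", 25)), 71.952, tolerance = 1e-3)
})

test_that("assemble_panel deduplicates across clusters", {
  p1 <- design_probes(rand_dna(80), character(0), cluster_id = 1L,
                      family = "a")
  shared <- p1[1, , drop = FALSE]
  shared2 <- shared; shared2$cluster_id <- 2L; shared2$family <- "b"
  panel <- assemble_panel(list(p1, shared2))
  expect_identical(sum(panel$sequence == shared$sequence), 1L)
  expect_identical(panel$cluster_id[panel$sequence == shared$sequence], 1L)
  expect_identical(nrow(assemble_panel(list())), 0L)
  expect_false(anyDuplicated(panel$sequence) > 0)
})

test_that("panel over a generated suite respects per-cluster caps", {
  set.seed(43)
  seqs <- unlist(lapply(1:10, function(i) {
    b <- rand_dna(150)
    c(b, mutate_dna(b, 0.05))
  }))
  df <- data.frame(id = sprintf("t%02d", seq_along(seqs)), seq = seqs,
                   family = rep(sprintf("f%02d", 1:10), each = 2))
  panel <- design_panel(df)
  expect_lte(nrow(panel), 60L)
  expect_true(all(table(panel$cluster_id) <= 6))
  expect_false(anyDuplicated(panel$sequence) > 0)
})
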