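# In-silico hybridization capture: fragmentation, a parameterized capture
# probability model (probe identity x optional GC efficiency), and paired-end
# read simulation with truth labels.

#' Capture model parameters
#'
#' Capture probability of a fragment is
#' \code{p = p_max * s(x) * gamma(gc)} with
#' \code{s(x) = 1 / (1 + exp(-kappa (x - x0)))} the probe-identity logistic
#' and \code{gamma(gc) = clamp(gamma0 + gamma1 gc, 0, 1)} when
#' \code{gc_bias} is enabled (else 1). \code{x} is the best probe-match
#' identity of the fragment. The functional form and defaults are a
#' simulator model, not measured chemistry: the motivating observation is
#' only that high-GC targets are captured more efficiently.
#'
#' @param p_max capture ceiling in [0, 1].
#' @param kappa,x0 identity-logistic steepness and midpoint.
#' @param gamma0,gamma1 GC-efficiency intercept and slope (on GC fraction).
#' @param gc_bias enable the GC term.
#' @param probe_match_min_len minimum alignment footprint (bases); shorter
#'   local matches are penalized as matches / probe_match_min_len.
#' @param seed_len exact-seed length for the probe-match prescreen.
#' @param n_background_probes panel probes aligned to seed-free fragments to
#'   estimate their background identity.
#' @param background_span fragment prefix length used for the
#'   background-identity estimate of seed-free fragments.
#' @param max_candidates cap on exactly aligned seed-sharing (probe, strand)
#'   pairs per fragment, ranked by shared-seed count.
#' @return object of class \code{capture_model}.
#' @export
capture_model <- function(p_max = 0.95, kappa = 30, x0 = 0.8, gamma0 = 0.2,
                          gamma1 = 1.0, gc_bias = TRUE,
                          probe_match_min_len = 30, seed_len = 11,
                          n_background_probes = 2, background_span = 400,
                          max_candidates = 8) {
  stopifnot(p_max >= 0, p_max <= 1, kappa > 0, probe_match_min_len >= 1,
            seed_len >= 4, n_background_probes >= 0, background_span >= 50,
            max_candidates >= 1)
  structure(list(p_max = p_max, kappa = kappa, x0 = x0, gamma0 = gamma0,
                 gamma1 = gamma1, gc_bias = gc_bias,
                 probe_match_min_len = probe_match_min_len,
                 seed_len = seed_len,
                 n_background_probes = n_background_probes,
                 background_span = background_span,
                 max_candidates = max_candidates),
            class = "capture_model")
}

#' Capture probability under a capture model
#'
#' @param model a \code{capture_model}.
#' @param identity best probe-match identity x in [0, 1] (vectorized).
#' @param gc fragment GC fraction in [0, 1] (vectorized).
#' @return capture probability in [0, 1].
#' @export
capture_probability <- function(model, identity, gc) {
  stopifnot(inherits(model, "capture_model"))
  s <- 1 / (1 + exp(-model$kappa * (identity - model$x0)))
  g <- if (isTRUE(model$gc_bias)) {
    pmin(pmax(model$gamma0 + model$gamma1 * gc, 0), 1)
  } else 1
  model$p_max * s * g
}

#' Fragment pooled mock-community DNA
#'
#' Strains are sampled proportionally to mass fractions, fragment starts are
#' uniform, lengths are Normal(mean_len, sd_len) truncated to
#' [50, source length], strands uniform. Families overlapping a fragment by
#' at least \code{min_overlap} bp (from the planted-gene truth) are attached
#' as truth labels.
#'
#' @param design a \code{mock_design}.
#' @param genomes named character vector of strain sequences.
#' @param truth planted-gene truth data.frame (chrom, start, end, family,
#'   strand).
#' @param n_fragments number of fragments.
#' @param mean_len mean insert size (default 630 bp).
#' @param sd_len insert-size standard deviation (default 60 bp).
#' @param seed integer seed.
#' @param min_overlap bp overlap required to attach a truth family
#'   (default 50).
#' @return data.frame: fragment_id, strain, start, end (0-based half-open),
#'   strand, seq (sense strand of the molecule), gc, truth (comma-joined
#'   family labels, "" when off-target).
#' @export
fragment_pool <- function(design, genomes, truth, n_fragments,
                          mean_len = 630, sd_len = 60, seed = 1L,
                          min_overlap = 50) {
  stopifnot(inherits(design, "mock_design"), n_fragments >= 0)
  nm <- design$strains$name
  stopifnot(all(nm %in% names(genomes)))
  empty <- data.frame(fragment_id = character(), strain = character(),
                      start = integer(), end = integer(), strand = character(),
                      seq = character(), gc = numeric(), truth = character(),
                      stringsAsFactors = FALSE)
  if (n_fragments == 0L) return(empty)
  set.seed(seed)
  glen <- setNames(nchar(genomes)[nm], nm)
  strain <- sample(nm, n_fragments, replace = TRUE,
                   prob = design$mass_fractions)
  len <- pmin(pmax(round(rnorm(n_fragments, mean_len, sd_len)), 50L),
              glen[strain])
  start <- floor(runif(n_fragments) * (glen[strain] - len + 1))
  end <- start + len
  strand <- sample(c("+", "-"), n_fragments, replace = TRUE)
  seq <- substring(genomes[strain], start + 1, end)
  seq[strand == "-"] <- revcomp(seq[strand == "-"])
  tr <- character(n_fragments)
  for (s in unique(strain)) {
    ti <- truth[truth$chrom == s, , drop = FALSE]
    idx <- which(strain == s)
    if (nrow(ti) == 0L) { tr[idx] <- ""; next }
    tr[idx] <- vapply(idx, function(i) {
      ov <- pmin(end[i], ti$end) - pmax(start[i], ti$start)
      paste(sort(unique(ti$family[ov >= min_overlap])), collapse = ",")
    }, character(1))
  }
  data.frame(fragment_id = sprintf("frag%06d", seq_len(n_fragments)),
             strain = unname(strain), start = unname(start),
             end = unname(end), strand = strand, seq = unname(seq),
             gc = unname(gc_fraction(seq)), truth = tr,
             stringsAsFactors = FALSE)
}

# Best probe-match identity per fragment. Exact local alignment against
# (probe, strand) pairs sharing a seed_len-mer with the fragment; fragments
# with no seed hit are aligned against a fixed panel subset (truncated to
# background_span bases) as a background-identity estimate -- their capture
# probability is negligible under defaults.
probe_best_identity <- function(fragments, panel, model) {
  np <- nrow(panel)
  nf <- length(fragments)
  if (np == 0L || nf == 0L) return(numeric(nf))
  k <- model$seed_len
  seeds <- lapply(seq_len(np), function(p) {
    s <- toupper(panel$sequence[p])
    w <- nchar(s) - k + 1L
    if (w < 1L) return(list(fwd = character(0), rev = character(0)))
    list(fwd = unique(substring(s, 1:w, k:nchar(s))),
         rev = unique(substring(revcomp(s), 1:w, k:nchar(s))))
  })
  pat <- unlist(lapply(seeds, function(x) c(x$fwd, x$rev)), use.names = FALSE)
  n_per <- vapply(seeds, function(x) c(length(x$fwd), length(x$rev)),
                  integer(2))
  probe_of <- rep(rep(seq_len(np), each = 2L), as.integer(n_per))
  strand_of <- rep(rep(c(0L, 1L), np), as.integer(n_per))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pat))
  hits <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(toupper(fragments)))
  nb <- min(model$n_background_probes, np)
  fb_probe <- seq_len(nb); fb_strand <- rep(0L, nb)
  cand_probe <- vector("list", nf); cand_strand <- vector("list", nf)
  span <- integer(nf)
  for (i in seq_len(nf)) {
    h <- hits[[i]]
    if (length(h)) {
      # rank (probe, strand) pairs by shared-seed count; homologous families
      # share seeds, so cap the exact alignments at the best max_candidates
      key <- probe_of[h] * 2L + strand_of[h]
      cnt <- sort(table(key), decreasing = TRUE)
      top <- as.integer(names(cnt))[seq_len(min(length(cnt),
                                                model$max_candidates))]
      cand_probe[[i]] <- top %/% 2L
      cand_strand[[i]] <- top %% 2L
      span[i] <- 0L  # full fragment
    } else {
      cand_probe[[i]] <- fb_probe
      cand_strand[[i]] <- fb_strand
      span[i] <- model$background_span
    }
  }
  .best_probe_identity_cpp(toupper(fragments), toupper(panel$sequence),
                           cand_probe, cand_strand,
                           as.integer(model$probe_match_min_len),
                           as.integer(span))
}

#' Simulate probe hybridization capture
#'
#' Computes each fragment's best probe-match identity, converts it to a
#' capture probability with \code{\link{capture_probability}}, and keeps the
#' fragment with that probability. Deterministic under \code{seed}.
#'
#' @param fragments fragment data.frame from \code{\link{fragment_pool}}.
#' @param panel a \code{probe_panel}.
#' @param model a \code{capture_model}.
#' @param seed integer seed.
#' @return the captured subset of \code{fragments}, with columns
#'   \code{probe_identity} and \code{p_capture} appended.
#' @export
hybridize <- function(fragments, panel, model = capture_model(), seed = 1L) {
  stopifnot(inherits(model, "capture_model"))
  if (nrow(fragments) == 0L || nrow(panel) == 0L) {
    out <- fragments[integer(0), , drop = FALSE]
    out$probe_identity <- numeric(0); out$p_capture <- numeric(0)
    return(out)
  }
  x <- probe_best_identity(fragments$seq, panel, model)
  p <- capture_probability(model, x, fragments$gc)
  set.seed(seed)
  keep <- runif(nrow(fragments)) < p
  out <- fragments[keep, , drop = FALSE]
  out$probe_identity <- x[keep]
  out$p_capture <- p[keep]
  rownames(out) <- NULL
  out
}

#' Simulate paired-end sequencing of captured fragments
#'
#' Mate 1 reads the first \code{read_len} bases of the fragment; mate 2 the
#' reverse complement of the last \code{read_len} bases (reads are truncated
#' to the fragment when it is shorter). Substitution errors are uniform at
#' \code{error_rate}; qualities are constant Q30 (the classifier never
#' consumes them). Provenance and on-target flags are carried through.
#'
#' @param fragments captured fragment data.frame.
#' @param read_len read length (default 300, PE300 chemistry).
#' @param error_rate per-base substitution rate (default 0.005).
#' @param seed integer seed.
#' @return object of class \code{read_set}: data.frame read_id, mate, seq,
#'   fragment_id, strain, truth, on_target.
#' @export
sequence_reads <- function(fragments, read_len = 300, error_rate = 0.005,
                           seed = 1L) {
  stopifnot(read_len >= 1, error_rate >= 0, error_rate < 1)
  set.seed(seed)
  n <- nrow(fragments)
  if (n == 0L) {
    out <- data.frame(read_id = character(), mate = integer(),
                      seq = character(), fragment_id = character(),
                      strain = character(), truth = character(),
                      on_target = logical(), stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    return(out)
  }
  flen <- nchar(fragments$seq)
  r1 <- substring(fragments$seq, 1L, pmin(read_len, flen))
  r2 <- revcomp(substring(fragments$seq, pmax(1L, flen - read_len + 1L), flen))
  add_errors <- function(reads) {
    if (error_rate == 0 || length(reads) == 0L) return(reads)
    vapply(reads, function(s) {
      m <- nchar(s)
      nmut <- rbinom(1L, m, error_rate)
      if (nmut == 0L) return(s)
      pos <- sample.int(m, nmut)
      v <- strsplit(s, "", fixed = TRUE)[[1]]
      for (i in pos) v[i] <- sample(setdiff(DNA, v[i]), 1L)
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  r1 <- add_errors(r1); r2 <- add_errors(r2)
  out <- data.frame(
    read_id = c(paste0(fragments$fragment_id, "/1"),
                paste0(fragments$fragment_id, "/2")),
    mate = rep(c(1L, 2L), each = n),
    seq = c(r1, r2),
    fragment_id = rep(fragments$fragment_id, 2L),
    strain = rep(fragments$strain, 2L),
    truth = rep(fragments$truth, 2L),
    on_target = rep(nzchar(fragments$truth), 2L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write a read set as paired FASTQ files
#'
#' @param reads a \code{read_set}.
#' @param prefix path prefix; writes \code{<prefix>_R1.fastq},
#'   \code{<prefix>_R2.fastq} and \code{<prefix>_provenance.tsv}.
#' @export
write_fastq_pair <- function(reads, prefix) {
  for (m in 1:2) {
    sub <- reads[reads$mate == m, , drop = FALSE]
    ss <- Biostrings::DNAStringSet(sub$seq)
    names(ss) <- sub$read_id
    qual <- Biostrings::BStringSet(strrep("?", nchar(sub$seq)))  # Q30
    Biostrings::writeXStringSet(ss, sprintf("%s_R%d.fastq", prefix, m),
                                format = "fastq", qualities = qual)
  }
  write.table(reads[, c("read_id", "fragment_id", "strain", "truth",
                        "on_target")],
              paste0(prefix, "_provenance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
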