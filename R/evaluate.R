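# Scoring recovered profiles against planted truth: correlation,
# homolog-aware precision/recall, identity binning, rarefaction.

#' Compare expected and observed per-family abundances
#'
#' Pearson r over families shared between the expected profile and the
#' observed table (on rel_target percentages), plus per-family signed
#' deviations.
#'
#' @param expected named numeric of expected percentages (e.g.
#'   \code{mock_design$expected_abundance}).
#' @param observed an \code{abundance_table} (or named numeric of observed
#'   percentages).
#' @return list with \code{pearson_r}, \code{n_families} and \code{table}
#'   (family, expected, observed, deviation). \code{pearson_r} is NA with a
#'   warning when the observed vector is constant.
#' @export
compare_abundance <- function(expected, observed) {
  if (inherits(observed, "abundance_table") || is.data.frame(observed)) {
    obs <- setNames(observed$rel_target, observed$family)
  } else {
    obs <- observed
  }
  shared <- intersect(names(expected), names(obs))
  shared <- shared[!is.na(obs[shared])]
  if (length(shared) < 3L) {
    stop("insufficient data: need >= 3 shared families, got ", length(shared))
  }
  e <- as.numeric(expected[shared]); o <- as.numeric(obs[shared])
  r <- if (sd(o) < .Machine$double.eps^0.5 || sd(e) < .Machine$double.eps^0.5) {
    warning("degenerate variance: Pearson r undefined")
    NA_real_
  } else cor(e, o)
  list(pearson_r = r, n_families = length(shared),
       table = data.frame(family = shared, expected = e, observed = o,
                          deviation = o - e, stringsAsFactors = FALSE))
}

#' Per-family precision and recall of read-level assignments
#'
#' \code{precision = TP / (TP + FP)}, \code{recall = TP / (TP + FN)} of
#' per-read family labels against planted truth. With
#' \code{merge_homologs}, truth and predicted labels are first projected
#' onto homolog-group labels (the (a/p)moA treatment: a read from amoA
#' predicted as pmoA counts as a true positive for the merged group).
#'
#' @param predicted data.frame (read_id, family): the read annotations.
#' @param truth data.frame (read_id, family) of planted truth; reads without
#'   target content carry family "background" (or are absent). Multiple rows
#'   per read allowed on both sides.
#' @param registry a \code{gene_registry}.
#' @param merge_homologs project labels onto homolog groups first.
#' @return data.frame family, tp, fp, fn, precision, recall; precision is NA
#'   for a family with zero predictions, recall NA for one with zero truth.
#' @export
precision_recall <- function(predicted, truth, registry,
                             merge_homologs = FALSE) {
  stopifnot(inherits(registry, "gene_registry"))
  proj <- function(df) {
    df <- df[!is.na(df$family) & df$family != "background", , drop = FALSE]
    if (merge_homologs) df$family <- homolog_merge_label(registry, df$family)
    unique(df[, c("read_id", "family")])
  }
  p <- proj(predicted); t <- proj(truth)
  fams <- sort(unique(c(p$family, t$family)))
  pk <- paste(p$read_id, p$family, sep = "\r")
  tk <- paste(t$read_id, t$family, sep = "\r")
  out <- do.call(rbind, lapply(fams, function(f) {
    pf <- pk[p$family == f]; tf <- tk[t$family == f]
    tp <- sum(pf %in% tf)
    fp <- length(pf) - tp
    fn <- length(tf) - tp
    data.frame(family = f, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Greedy identity binning of sequences
#'
#' Same greedy rule as \code{\link{cluster_sequences}} (descending length,
#' ties by id; a member joins the first centroid it matches at >=
#' \code{cutoff} global identity under the shorter-sequence convention) --
#' the de-novo analogue of taxonomic binning at a fixed identity cutoff.
#'
#' @param seqs sequences (named character or data.frame id/seq).
#' @param cutoff identity cutoff in (0, 1]; default 0.90, the nosZ-style
#'   binning cutoff.
#' @return object of class \code{bin_set}: list with \code{assignments}
#'   (data.frame id, bin), \code{centroids} (data.frame bin, id, seq),
#'   \code{sizes}, \code{cutoff}.
#' @export
bin_at_identity <- function(seqs, cutoff = 0.90) {
  cl <- cluster_sequences(seqs, threshold = cutoff)
  assignments <- data.frame(id = cl$assignments$id, bin = cl$assignments$cluster,
                            stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 centroids = data.frame(bin = cl$representatives$cluster,
                                        id = cl$representatives$id,
                                        seq = cl$representatives$seq,
                                        stringsAsFactors = FALSE),
                 sizes = if (nrow(assignments)) table(assignments$bin)
                 else table(integer(0)),
                 cutoff = cutoff),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat("bin_set:", nrow(x$assignments), "sequences in",
      nrow(x$centroids), "bins at identity >=", x$cutoff, "\n")
  invisible(x)
}

#' Closed-form expected rarefaction richness
#'
#' Expected number of distinct bins in a without-replacement subsample of
#' depth d: \code{sum_b (1 - choose(N - n_b, d) / choose(N, d))}.
#'
#' @param sizes per-bin member counts.
#' @param depth subsample depth (0 <= depth <= sum(sizes)).
#' @return expected richness.
#' @export
rarefaction_expected <- function(sizes, depth) {
  N <- sum(sizes)
  stopifnot(depth >= 0, depth <= N)
  sum(1 - exp(lchoose(N - sizes, depth) - lchoose(N, depth)))
}

#' Rarefaction curve of bin richness
#'
#' Mean distinct-bin count over replicated without-replacement subsampling,
#' with the closed-form hypergeometric expectation attached for
#' cross-checking.
#'
#' @param bin_assignments per-read bin labels (vector; one entry per read).
#' @param depths subsample depths (each <= number of reads).
#' @param n_replicates Monte-Carlo replicates per depth (default 100).
#' @param seed integer seed.
#' @return object of class \code{rarefaction_curve}: data.frame depth,
#'   mean_richness, sd_richness, expected_richness; attributes
#'   \code{n_replicates} and \code{seed}.
#' @export
rarefy_bins <- function(bin_assignments, depths, n_replicates = 100,
                        seed = 1L) {
  N <- length(bin_assignments)
  if (any(depths > N)) stop("depth exceeds total reads (", N, ")")
  stopifnot(all(depths >= 0), n_replicates >= 1)
  sizes <- as.numeric(table(bin_assignments))
  set.seed(seed)
  rows <- lapply(sort(depths), function(d) {
    rich <- vapply(seq_len(n_replicates), function(r) {
      length(unique(bin_assignments[sample.int(N, d)]))
    }, numeric(1))
    data.frame(depth = d, mean_richness = mean(rich),
               sd_richness = sd(rich),
               expected_richness = rarefaction_expected(sizes, d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("rarefaction_curve", "data.frame"),
            n_replicates = n_replicates, seed = seed)
}
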