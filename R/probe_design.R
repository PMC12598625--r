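# Greedy identity clustering and 50-mer capture-probe design.

#' Greedy incremental clustering at an identity threshold
#'
#' Sequences are sorted by descending length (ties: id lexicographic); each
#' sequence joins the first existing cluster whose representative it matches
#' at >= \code{threshold} global identity (identical aligned positions over
#' the shorter sequence; see \code{\link{seq_identity}}), else it founds a
#' new cluster. Representatives are the cluster founders.
#'
#' @param seqs sequences (named character vector or data.frame id/seq,
#'   assumed dereplicated).
#' @param threshold identity fraction in (0, 1]; default 0.80, the panel
#'   design clustering threshold.
#' @return object of class \code{seq_clusters}: list with \code{assignments}
#'   (data.frame id, cluster, is_representative) and \code{representatives}
#'   (data.frame cluster, id, seq).
#' @export
cluster_sequences <- function(seqs, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  df <- as_seq_df(seqs)
  reps <- character(0); rep_ids <- character(0)
  assign_cluster <- integer(nrow(df))
  if (nrow(df) > 0L) {
    ord <- order(-nchar(df$seq), df$id)
    names(assign_cluster) <- df$id
    for (i in ord) {
      s <- df$seq[i]
      placed <- 0L
      for (cl in seq_along(reps)) {
        if (seq_identity(s, reps[cl], "global") >= threshold) {
          placed <- cl; break
        }
      }
      if (placed == 0L) {
        reps <- c(reps, s); rep_ids <- c(rep_ids, df$id[i])
        placed <- length(reps)
      }
      assign_cluster[df$id[i]] <- placed
    }
  }
  assignments <- data.frame(id = df$id,
                            cluster = unname(assign_cluster[df$id]),
                            is_representative = df$id %in% rep_ids,
                            stringsAsFactors = FALSE)
  representatives <- data.frame(cluster = seq_along(reps), id = rep_ids,
                                seq = reps, stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 representatives = representatives,
                 threshold = threshold),
            class = "seq_clusters")
}

#' @export
print.seq_clusters <- function(x, ...) {
  cat("seq_clusters:", nrow(x$assignments), "sequences in",
      nrow(x$representatives), "clusters at identity >=", x$threshold, "\n")
  invisible(x)
}

#' Length-adjusted GC melting temperature
#'
#' Tm = 64.9 + 41 * (nGC - 16.4) / length. Note that a 50-mer capture probe
#' under this formula melts well above the 47 degC hybridization temperature
#' used in capture protocols; the \code{tm_target} of
#' \code{\link{design_probes}} is a scoring preference, not the formula's
#' expected output.
#'
#' @param x character vector of probe sequences.
#' @return Tm in degrees Celsius.
#' @export
probe_tm <- function(x) {
  n_gc <- vapply(strsplit(toupper(x), "", fixed = TRUE),
                 function(v) sum(v %in% c("G", "C")), numeric(1))
  64.9 + 41 * (n_gc - 16.4) / nchar(x)
}

has_homopolymer <- function(x, max_run = 8L) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", max_run, max_run, max_run, max_run),
        toupper(x))
}

#' Design capture probes for one cluster
#'
#' Enumerates every k-mer of the representative, discards candidates with
#' ambiguity codes or homopolymer runs >= 8, scores candidates by member
#' coverage (a member is covered when it contains some length-k window with
#' <= \code{max_mismatch} mismatches), breaks ties by |Tm - tm_target| then
#' by smaller offset, and selects greedily up to \code{max_probes} subject to
#' pairwise offset spacing >= k/2. Deterministic.
#'
#' @param representative cluster representative sequence.
#' @param members character vector of cluster member sequences (including the
#'   representative).
#' @param k probe length (default 50).
#' @param max_probes maximum probes per cluster (default 6).
#' @param tm_target Tm scoring target in degC (default 47, the capture
#'   hybridization temperature).
#' @param max_mismatch member-coverage mismatch tolerance (default 5, i.e.
#'   90\% probe identity).
#' @param min_spacing minimum offset spacing between selected probes
#'   (default \code{k / 2}).
#' @param family,cluster_id annotations copied onto the output.
#' @return data.frame of probes: sequence, family, cluster_id, offset
#'   (0-based on the representative), gc_fraction, tm_celsius,
#'   member_coverage.
#' @export
design_probes <- function(representative, members = representative, k = 50,
                          max_probes = 6, tm_target = 47, max_mismatch = 5,
                          min_spacing = k / 2, family = NA_character_,
                          cluster_id = NA_integer_) {
  representative <- toupper(as.character(representative))
  stopifnot(length(representative) == 1L)
  L <- nchar(representative)
  if (L < k) stop("representative shorter than probe length: no candidates")
  offsets <- 0:(L - k)
  cand <- substring(representative, offsets + 1L, offsets + k)
  ok <- !grepl("[^ACGT]", cand) & !has_homopolymer(cand)
  offsets <- offsets[ok]; cand <- cand[ok]
  if (length(cand) == 0L) stop("no probe candidate passed quality filters")
  members <- toupper(as.character(members))
  mem_set <- Biostrings::DNAStringSet(members)
  coverage <- vapply(cand, function(p) {
    sum(Biostrings::vcountPattern(p, mem_set, max.mismatch = max_mismatch,
                                  fixed = TRUE) > 0L)
  }, numeric(1), USE.NAMES = FALSE)
  tm <- probe_tm(cand)
  ord <- order(-coverage, abs(tm - tm_target), offsets)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= max_probes) break
    if (all(abs(offsets[sel] - offsets[i]) >= min_spacing)) sel <- c(sel, i)
  }
  out <- data.frame(sequence = cand[sel], family = family,
                    cluster_id = cluster_id, offset = offsets[sel],
                    gc_fraction = gc_fraction(cand[sel]),
                    tm_celsius = tm[sel], member_coverage = coverage[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble per-cluster probes into a deduplicated panel
#'
#' Concatenates per-cluster probe tables, removes duplicate probe sequences
#' keeping the copy from the earlier cluster (cluster-id order), and records
#' per-family counts and the panel GC distribution.
#'
#' @param per_cluster_probes list of data.frames from
#'   \code{\link{design_probes}} (or one combined data.frame).
#' @return object of class \code{probe_panel}: data.frame of probes with
#'   attributes \code{family_counts} and \code{gc_summary}.
#' @export
assemble_panel <- function(per_cluster_probes) {
  if (is.data.frame(per_cluster_probes)) {
    per_cluster_probes <- list(per_cluster_probes)
  }
  if (length(per_cluster_probes) == 0L) {
    probes <- data.frame(sequence = character(), family = character(),
                         cluster_id = integer(), offset = integer(),
                         gc_fraction = numeric(), tm_celsius = numeric(),
                         member_coverage = numeric(), stringsAsFactors = FALSE)
  } else {
    probes <- do.call(rbind, per_cluster_probes)
    probes <- probes[order(probes$cluster_id), , drop = FALSE]
    probes <- probes[!duplicated(probes$sequence), , drop = FALSE]
  }
  probes$probe_id <- if (nrow(probes)) paste0("probe", seq_len(nrow(probes))) else character(0)
  rownames(probes) <- NULL
  structure(probes, class = c("probe_panel", "data.frame"),
            family_counts = if (nrow(probes)) table(probes$family) else table(character(0)),
            gc_summary = if (nrow(probes)) summary(probes$gc_fraction) else NULL)
}

#' @export
print.probe_panel <- function(x, ...) {
  cat("probe_panel:", nrow(x), "unique probes\n")
  fc <- attr(x, "family_counts")
  if (length(fc)) print(fc)
  invisible(x)
}

#' Cluster a target database and design a full probe panel
#'
#' Convenience wrapper: per family, greedy-cluster the (dereplicated) target
#' sequences at \code{threshold} and design up to \code{max_probes} k-mers
#' per cluster, then assemble the deduplicated panel.
#'
#' @param seqs data.frame with columns id, seq, family (a target database).
#' @param threshold clustering identity threshold (default 0.80).
#' @inheritParams design_probes
#' @return a \code{probe_panel}.
#' @export
design_panel <- function(seqs, threshold = 0.80, k = 50, max_probes = 6,
                         tm_target = 47, max_mismatch = 5) {
  df <- as_seq_df(seqs)
  if (is.null(df$family)) df$family <- "unknown"
  tabs <- list()
  cl_counter <- 0L
  for (fam in unique(df$family)) {
    sub <- df[df$family == fam, , drop = FALSE]
    cl <- cluster_sequences(sub, threshold)
    for (ci in cl$representatives$cluster) {
      member_ids <- cl$assignments$id[cl$assignments$cluster == ci]
      members <- sub$seq[match(member_ids, sub$id)]
      rep_seq <- cl$representatives$seq[ci]
      if (nchar(rep_seq) < k) next
      cl_counter <- cl_counter + 1L
      tabs[[length(tabs) + 1L]] <-
        design_probes(rep_seq, members, k = k, max_probes = max_probes,
                      tm_target = tm_target, max_mismatch = max_mismatch,
                      family = fam, cluster_id = cl_counter)
    }
  }
  assemble_panel(tabs)
}

#' Write a probe panel as FASTA plus TSV
#'
#' @param panel a \code{probe_panel}.
#' @param prefix output path prefix; writes \code{<prefix>.fasta} and
#'   \code{<prefix>.tsv}.
#' @export
write_panel <- function(panel, prefix) {
  headers <- sprintf("%s family=%s cluster=%s offset=%d gc=%.3f tm=%.2f coverage=%d",
                     panel$probe_id, panel$family, panel$cluster_id,
                     panel$offset, panel$gc_fraction, panel$tm_celsius,
                     as.integer(panel$member_coverage))
  ss <- Biostrings::DNAStringSet(panel$sequence)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, paste0(prefix, ".fasta"))
  write.table(as.data.frame(panel), paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
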