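# Read annotation: six-frame translation, identity-thresholded protein
# matching with the retention/overlap/collapse rules, and homolog
# disambiguation.

# vectorized six-frame translation: one Biostrings::translate call for all
# frames of all reads (per-read translate calls are prohibitively slow)
translate_frames_batch <- function(reads) {
  reads <- toupper(as.character(reads))
  n <- nchar(reads)
  rc <- revcomp(reads)
  frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  pieces <- character(0)
  idx <- list()
  for (f in 1:3) {
    m <- 3L * pmax((n - f + 1L) %/% 3L, 0L)
    fwd <- ifelse(m >= 3L, substr(reads, f, f + m - 1L), "")
    rev <- ifelse(m >= 3L, substr(rc, f, f + m - 1L), "")
    idx[[paste0("+", f)]] <- seq_along(reads) + length(pieces)
    pieces <- c(pieces, fwd)
    idx[[paste0("-", f)]] <- seq_along(reads) + length(pieces)
    pieces <- c(pieces, rev)
  }
  pep <- as.character(Biostrings::translate(Biostrings::DNAStringSet(pieces),
                                            no.init.codon = TRUE,
                                            if.fuzzy.codon = "X"))
  out <- matrix("", nrow = length(reads), ncol = 6L,
                dimnames = list(names(reads), frame_names))
  for (nm in frame_names) out[, nm] <- pep[idx[[nm]]]
  out
}

#' Six-frame translation of a read
#'
#' Frames +1..+3 are translated from the read, -1..-3 from its reverse
#' complement; standard genetic code, stops rendered '*', trailing partial
#' codons dropped.
#'
#' @param read a nucleotide string.
#' @return named character vector of 6 peptides ("+1","+2","+3","-1","-2","-3").
#' @export
translate_six_frames <- function(read) {
  read <- toupper(as.character(read))
  stopifnot(length(read) == 1L)
  if (nchar(read) < 3L) {
    warning("read shorter than 3 nt: empty frames")
    return(setNames(character(6), c("+1", "+2", "+3", "-1", "-2", "-3")))
  }
  translate_frames_batch(read)[1L, ]
}

#' Build a family-labelled protein database
#'
#' @param proteins named character vector of protein sequences, or a
#'   data.frame id/seq/family.
#' @param family family labels parallel to \code{proteins} (when a vector is
#'   given); decoy homolog entries (e.g. narH, fdhA) are ordinary rows.
#' @return object of class \code{protein_db} (uncalibrated).
#' @export
protein_db <- function(proteins, family = NULL) {
  df <- as_seq_df(proteins, family = family)
  if (is.null(df$family)) stop("protein db requires family labels")
  structure(list(db = df, calibration = NULL), class = "protein_db")
}

#' @export
print.protein_db <- function(x, ...) {
  cat("protein_db:", nrow(x$db), "sequences,",
      length(unique(x$db$family)), "families,",
      if (is.null(x$calibration)) "uncalibrated" else "calibrated", "\n")
  invisible(x)
}

blosum62 <- function() {
  # lazy-load the substitution matrix shipped with Biostrings
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# background amino-acid frequencies (Robinson & Robinson)
AA_BACKGROUND <- c(A = .0780, C = .0192, D = .0536, E = .0629, F = .0397,
                   G = .0738, H = .0219, I = .0514, K = .0572, L = .0901,
                   M = .0224, N = .0448, P = .0520, Q = .0426, R = .0512,
                   S = .0712, T = .0584, V = .0644, W = .0132, Y = .0321)

#' Calibrate protein-mapping E-values against decoy peptides
#'
#' Pools local-alignment scores (BLOSUM62, gap open 11 / extend 1) of
#' background-sampled decoy peptides against every database sequence and
#' fits a Gumbel null by the method of moments. A hit's
#' \code{E = n_db * P(S >= score)}.
#'
#' @param db a \code{protein_db}.
#' @param n_decoys number of decoy peptides (default 150).
#' @param decoy_length decoy length in aa (default 100, a PE300 frame).
#' @param seed integer seed.
#' @return the calibrated \code{protein_db}.
#' @export
calibrate_protein_db <- function(db, n_decoys = 150, decoy_length = 100,
                                 seed = 1L) {
  stopifnot(inherits(db, "protein_db"), n_decoys >= 50)
  set.seed(seed)
  decoys <- vapply(seq_len(n_decoys), function(i) {
    paste(sample(names(AA_BACKGROUND), decoy_length, replace = TRUE,
                 prob = AA_BACKGROUND), collapse = "")
  }, character(1))
  pat <- Biostrings::AAStringSet(decoys)
  sub <- blosum62()
  scores <- unlist(lapply(db$db$seq, function(s) {
    Biostrings::pairwiseAlignment(pat, Biostrings::AAString(s),
                                  type = "local", substitutionMatrix = sub,
                                  gapOpening = 11, gapExtension = 1,
                                  scoreOnly = TRUE)
  }))
  fit <- gumbel_fit(scores)
  db$calibration <- list(location = fit$location, scale = fit$scale,
                         n_decoys = n_decoys, decoy_length = decoy_length,
                         seed = seed)
  db
}

# internal: E-value of protein scores scaled to db size
protein_evalue <- function(db, scores) {
  cal <- db$calibration
  if (is.null(cal)) stop("protein db is not calibrated")
  nrow(db$db) * gumbel_tail(scores, cal$location, cal$scale)
}

# map aa interval on a frame peptide to 0-based half-open nt interval on the read
frame_aa_to_read_nt <- function(frame, read_len, aa_start0, aa_end0) {
  f <- abs(as.integer(frame))
  if (as.integer(frame) > 0) {
    c((f - 1L) + 3L * aa_start0, (f - 1L) + 3L * aa_end0)
  } else {
    c(read_len - (f - 1L) - 3L * aa_end0, read_len - (f - 1L) - 3L * aa_start0)
  }
}

#' Map translated frames against a protein database and retain hits
#'
#' Local alignment (BLOSUM62, gap open 11 / extend 1) of every reading frame
#' against every database protein. Hits below \code{min_identity} percent
#' identity (identities / alignment columns) or above \code{e_threshold} are
#' discarded; no minimum coverage is applied. Within each direction (the
#' three forward frames pooled, likewise reverse) hits are admitted in
#' descending score order, each admitted hit may overlap every other
#' admitted hit of that direction by at most \code{max_overlap_aa} amino
#' acids on read coordinates, up to \code{max_per_direction} hits.
#'
#' @param reads named character vector of reads (names are read ids), or a
#'   \code{read_set} / data.frame with read_id and seq.
#' @param db a calibrated \code{protein_db}.
#' @param min_identity percent identity floor (default 60).
#' @param max_per_direction retained matches per direction (default 4).
#' @param max_overlap_aa tolerated overlap between retained matches
#'   (default 15 aa).
#' @param e_threshold E-value ceiling (default 0.001).
#' @return data.frame of retained hits: read_id, frame, direction,
#'   target_id, family, percent_identity, score, E, aa_start, aa_end
#'   (0-based half-open on the frame peptide), nt_start, nt_end (on the
#'   read).
#' @export
map_and_retain <- function(reads, db, min_identity = 60,
                           max_per_direction = 4, max_overlap_aa = 15,
                           e_threshold = 0.001) {
  stopifnot(inherits(db, "protein_db"))
  if (is.null(db$calibration)) stop("protein db is not calibrated")
  if (nrow(db$db) == 0L) stop("protein db is empty")
  rdf <- if (is.data.frame(reads)) {
    data.frame(id = reads$read_id, seq = reads$seq, stringsAsFactors = FALSE)
  } else as_seq_df(reads)
  empty <- data.frame(read_id = character(), frame = character(),
                      direction = character(), target_id = character(),
                      family = character(), percent_identity = numeric(),
                      score = numeric(), E = numeric(), aa_start = integer(),
                      aa_end = integer(), nt_start = integer(),
                      nt_end = integer(), stringsAsFactors = FALSE)
  if (nrow(rdf) == 0L) return(empty)
  # all frames of all reads (vectorized translation)
  pepm <- translate_frames_batch(rdf$seq)
  fr <- data.frame(read_id = rep(rdf$id, 6L),
                   frame = rep(colnames(pepm), each = nrow(rdf)),
                   pep = as.vector(pepm),
                   read_len = rep(nchar(rdf$seq), 6L),
                   stringsAsFactors = FALSE)
  fr <- fr[nchar(fr$pep) >= 5L, , drop = FALSE]
  if (nrow(fr) == 0L) return(empty)
  cal <- db$calibration
  # score-only prescreen at the E threshold, then full alignment of passers
  s_min <- cal$location + cal$scale * log(nrow(db$db) / e_threshold) -
    2 * cal$scale
  sub <- blosum62()
  pat <- Biostrings::AAStringSet(fr$pep)
  hits <- list()
  for (t in seq_len(nrow(db$db))) {
    subj <- Biostrings::AAString(db$db$seq[t])
    sc <- Biostrings::pairwiseAlignment(pat, subj, type = "local",
                                        substitutionMatrix = sub,
                                        gapOpening = 11, gapExtension = 1,
                                        scoreOnly = TRUE)
    pass <- which(sc >= s_min)
    if (!length(pass)) next
    al <- Biostrings::pairwiseAlignment(pat[pass], subj, type = "local",
                                        substitutionMatrix = sub,
                                        gapOpening = 11, gapExtension = 1)
    pr <- Biostrings::pattern(al)
    cols <- Biostrings::nchar(al)  # alignment columns incl. gaps
    pid <- 100 * Biostrings::nmatch(al) / cols
    E <- protein_evalue(db, Biostrings::score(al))
    hits[[length(hits) + 1L]] <- data.frame(
      read_id = fr$read_id[pass], frame = fr$frame[pass],
      direction = ifelse(startsWith(fr$frame[pass], "+"), "fwd", "rev"),
      target_id = db$db$id[t], family = db$db$family[t],
      percent_identity = pid, score = Biostrings::score(al), E = E,
      aa_start = Biostrings::start(pr) - 1L, aa_end = Biostrings::end(pr),
      read_len = fr$read_len[pass], stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  h <- h[h$percent_identity >= min_identity & h$E <= e_threshold, ,
         drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  nt <- t(mapply(frame_aa_to_read_nt, h$frame, h$read_len, h$aa_start,
                 h$aa_end))
  h$nt_start <- as.integer(nt[, 1]); h$nt_end <- as.integer(nt[, 2])
  h$read_len <- NULL
  # per-direction retention with the overlap rule
  keep <- logical(nrow(h))
  for (grp in split(seq_len(nrow(h)),
                    list(h$read_id[seq_len(nrow(h))],
                         h$direction[seq_len(nrow(h))]), drop = TRUE)) {
    ord <- grp[order(-h$score[grp], h$E[grp], h$target_id[grp],
                     h$frame[grp])]
    adm <- integer(0)
    for (i in ord) {
      if (length(adm) >= max_per_direction) break
      ov_nt <- pmin(h$nt_end[adm], h$nt_end[i]) -
        pmax(h$nt_start[adm], h$nt_start[i])
      if (all(ov_nt <= 3 * max_overlap_aa)) adm <- c(adm, i)
    }
    keep[adm] <- TRUE
  }
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$read_id, out$direction, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse per-family hits and disambiguate homologous families
#'
#' Per direction, hits on the same family collapse to the best-E hit. Across
#' the read, when retained families fall in the same homolog group (e.g.
#' amoA vs pmoA, or the nitrate-reductase-like cluster including the decoy
#' labels narH/fdhA), only the best-E family is kept; the displaced families
#' are recorded as reassigned (audit trail in the \code{reassignments}
#' attribute).
#'
#' @param hits retained hits from \code{\link{map_and_retain}}.
#' @param registry a \code{gene_registry}.
#' @return data.frame of read annotations: read_id, family, score, E,
#'   n_hits; attribute \code{reassignments} records (read_id, from_family,
#'   to_family).
#' @export
resolve_homologs <- function(hits, registry) {
  stopifnot(inherits(registry, "gene_registry"))
  empty <- data.frame(read_id = character(), family = character(),
                      score = numeric(), E = numeric(), n_hits = integer(),
                      stringsAsFactors = FALSE)
  reass <- data.frame(read_id = character(), from_family = character(),
                      to_family = character(), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) {
    attr(empty, "reassignments") <- reass
    return(empty)
  }
  out <- list()
  for (rid in unique(hits$read_id)) {
    hh <- hits[hits$read_id == rid, , drop = FALSE]
    # collapse same family within a direction to its best-E hit
    key <- paste(hh$direction, hh$family, sep = "\r")
    best <- unlist(lapply(split(seq_len(nrow(hh)), key), function(ii) {
      ii[order(hh$E[ii], -hh$score[ii])][1L]
    }), use.names = FALSE)
    hh <- hh[best, , drop = FALSE]
    # one candidate per family (best E across directions)
    fam_best <- unlist(lapply(split(seq_len(nrow(hh)), hh$family),
                              function(ii) ii[order(hh$E[ii])][1L]),
                       use.names = FALSE)
    cand <- hh[fam_best, , drop = FALSE]
    cand <- cand[order(cand$E, cand$family), , drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(cand))) {
      clash <- any(vapply(kept, function(j) {
        same_homolog_group(registry, cand$family[i], cand$family[j])
      }, logical(1)))
      if (clash) {
        j <- kept[vapply(kept, function(j) {
          same_homolog_group(registry, cand$family[i], cand$family[j])
        }, logical(1))][1L]
        reass <- rbind(reass, data.frame(read_id = rid,
                                         from_family = cand$family[i],
                                         to_family = cand$family[j],
                                         stringsAsFactors = FALSE))
      } else {
        kept <- c(kept, i)
      }
    }
    ann <- cand[kept, c("read_id", "family", "score", "E"), drop = FALSE]
    ann$n_hits <- vapply(ann$family,
                         function(f) sum(hits$read_id == rid &
                                           hits$family == f), integer(1))
    out[[length(out) + 1L]] <- ann
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "reassignments") <- reass
  res
}

#' Tabulate per-family read counts under both normalizations
#'
#' Each read counts once per assigned family. \code{rel_target} is
#' \code{100 * count_g / sum_h count_h} over target families (the
#' mock-community normalization); \code{rel_total} is
#' \code{100 * count_g / total_reads} (the shotgun-style normalization).
#'
#' @param annotations annotations from \code{\link{resolve_homologs}}.
#' @param total_reads total sequenced reads (>= 1).
#' @param families optional target family vector defining the table rows and
#'   the rel_target denominator (default: families observed).
#' @return object of class \code{abundance_table}: data.frame family, count,
#'   rel_target, rel_total; attribute \code{total_reads}.
#' @export
tabulate_families <- function(annotations, total_reads, families = NULL) {
  if (is.null(total_reads) || total_reads < 1) {
    stop("total_reads must be >= 1")
  }
  fam <- families %||% sort(unique(annotations$family))
  cnt <- vapply(fam, function(f) {
    length(unique(annotations$read_id[annotations$family == f]))
  }, numeric(1))
  denom <- sum(cnt)
  out <- data.frame(family = fam, count = unname(cnt),
                    rel_target = if (denom > 0) 100 * unname(cnt) / denom
                    else rep(NA_real_, length(cnt)),
                    rel_total = 100 * unname(cnt) / total_reads,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("abundance_table", "data.frame"),
            total_reads = total_reads)
}

#' Classify a read set end to end
#'
#' Convenience wrapper: \code{\link{map_and_retain}} then
#' \code{\link{resolve_homologs}} then \code{\link{tabulate_families}}.
#'
#' @param reads a \code{read_set} (or named character vector of reads).
#' @param db a calibrated \code{protein_db}.
#' @param registry a \code{gene_registry}.
#' @param total_reads denominator for rel_total (default: number of reads).
#' @param families target family set for the table (default: registry
#'   families).
#' @inheritParams map_and_retain
#' @return list with \code{hits}, \code{annotations}, \code{abundance}.
#' @export
classify_reads <- function(reads, db, registry, min_identity = 60,
                           max_per_direction = 4, max_overlap_aa = 15,
                           e_threshold = 0.001, total_reads = NULL,
                           families = NULL) {
  n_reads <- if (is.data.frame(reads)) nrow(reads) else length(reads)
  total_reads <- total_reads %||% max(n_reads, 1L)
  hits <- map_and_retain(reads, db, min_identity = min_identity,
                         max_per_direction = max_per_direction,
                         max_overlap_aa = max_overlap_aa,
                         e_threshold = e_threshold)
  ann <- resolve_homologs(hits, registry)
  fam <- families %||% registry$families$name
  list(hits = hits, annotations = ann,
       abundance = tabulate_families(ann, total_reads, families = fam))
}
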