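# Position-specific scoring models with E-value calibration.
#
# The field's pipelines delegate profile search to HMMER; at desk scale the
# same filtering contract (report hits at E < 0.001) is reproduced with a
# log-odds position-specific scoring matrix, affine-gap local alignment, and
# an extreme-value (Gumbel) null fitted to background-sampled decoys.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

profile_alphabet <- function(alphabet) {
  switch(alphabet, nucleotide = DNA, amino_acid = AA20,
         stop("alphabet must be 'nucleotide' or 'amino_acid'"))
}

#' Build a position-specific scoring model from an alignment
#'
#' A column of the input alignment becomes a match column iff its gap
#' fraction is strictly below 0.5 (at exactly 0.5 the column is dropped).
#' Per-column scores are log-odds:
#' \code{log((count(symbol) + pseudocount) / (rows + pseudocount * |alphabet|))
#' - log(background(symbol))}.
#'
#' @param alignment character vector of equal-length aligned rows ('-' gaps),
#'   or a data.frame with columns \code{id}, \code{seq}.
#' @param family family name (stored on the model).
#' @param alphabet "nucleotide" or "amino_acid".
#' @param pseudocount additive pseudocount (default 1).
#' @param background named numeric of background frequencies (default
#'   uniform over the alphabet).
#' @param gap_open,gap_extend affine gap penalties used at search time.
#' @return object of class \code{profile_model} (uncalibrated).
#' @export
build_profile <- function(alignment, family, alphabet = "nucleotide",
                          pseudocount = 1, background = NULL,
                          gap_open = 4, gap_extend = 1) {
  df <- as_seq_df(alignment)
  if (nrow(df) < 2L) stop("alignment must have >= 2 rows")
  rows <- toupper(df$seq)
  w <- nchar(rows)
  if (length(unique(w)) != 1L) stop("ragged alignment: rows differ in length")
  ab <- profile_alphabet(alphabet)
  if (is.null(background)) {
    background <- setNames(rep(1 / length(ab), length(ab)), ab)
  }
  stopifnot(all(ab %in% names(background)), all(background[ab] > 0))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac < 0.5)
  if (length(keep) == 0L) stop("empty model: no column has < 50% gaps")
  n <- nrow(mat)
  scores <- matrix(NA_real_, length(keep), length(ab),
                   dimnames = list(NULL, ab))
  for (k in seq_along(keep)) {
    cnt <- table(factor(mat[, keep[k]], levels = ab))
    scores[k, ] <- log((as.numeric(cnt) + pseudocount) /
                         (n + pseudocount * length(ab))) -
      log(as.numeric(background[ab]))
  }
  structure(list(family = family, alphabet = alphabet,
                 length = length(keep), match_scores = scores,
                 columns_kept = keep, gap_open = gap_open,
                 gap_extend = gap_extend, background = background[ab],
                 pseudocount = pseudocount, n_train = n,
                 train_ids = df$id,
                 train_seqs = gsub("[-.]", "", rows),
                 calibration = NULL),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model [", x$family, "]: ", x$length, " ", x$alphabet,
      " columns, ", x$n_train, " training rows, ",
      if (is.null(x$calibration)) "uncalibrated" else "calibrated", "\n",
      sep = "")
  invisible(x)
}

# best local alignment score of sequences against the model
profile_score <- function(profile, seqs) {
  stopifnot(inherits(profile, "profile_model"))
  ab <- paste(colnames(profile$match_scores), collapse = "")
  .pssm_best_scores_cpp(profile$match_scores, toupper(as.character(seqs)),
                        ab, profile$gap_open, profile$gap_extend)
}

#' Calibrate a profile's E-values against background decoys
#'
#' Scores \code{n_decoys} i.i.d. background-sampled decoy sequences against
#' the profile and fits a Gumbel (extreme-value) distribution to the best
#' local-alignment scores by the method of moments. At search time
#' \code{E(score) = n_db * P(S >= score)} under that null.
#'
#' @param profile a \code{profile_model}.
#' @param n_decoys number of decoys (>= 100).
#' @param decoy_length decoy length; default the profile length.
#' @param seed integer RNG seed (calibration is reproducible under it).
#' @return the profile with a \code{calibration} element
#'   (location, scale, n_decoys, decoy_length).
#' @export
calibrate_profile <- function(profile, n_decoys = 300, decoy_length = NULL,
                              seed = 1L) {
  stopifnot(inherits(profile, "profile_model"))
  if (n_decoys < 100L) stop("n_decoys must be >= 100")
  decoy_length <- decoy_length %||% profile$length
  ab <- colnames(profile$match_scores)
  p <- as.numeric(profile$background)
  set.seed(seed)
  decoys <- vapply(seq_len(n_decoys), function(i) {
    paste(sample(ab, decoy_length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  sc <- profile_score(profile, decoys)
  fit <- gumbel_fit(sc)
  profile$calibration <- list(location = fit$location, scale = fit$scale,
                              n_decoys = n_decoys,
                              decoy_length = decoy_length, seed = seed)
  profile
}

# E-values for raw scores, scaled to a database of n_db sequences
profile_evalue <- function(profile, scores, n_db) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated; run calibrate_profile()")
  n_db * gumbel_tail(scores, cal$location, cal$scale)
}

#' Search a sequence set with a calibrated profile
#'
#' @param profile a calibrated \code{profile_model}.
#' @param seqs sequences (named character vector or data.frame id/seq).
#' @param e_threshold report hits with E <= this value (default 0.001).
#' @return data.frame (id, score, E) sorted by E ascending, ties broken by
#'   id lexicographic.
#' @export
search_profile <- function(profile, seqs, e_threshold = 0.001) {
  stopifnot(inherits(profile, "profile_model"), e_threshold > 0)
  if (is.null(profile$calibration)) {
    stop("profile is not calibrated; run calibrate_profile()")
  }
  df <- as_seq_df(seqs)
  if (nrow(df) == 0L) {
    return(data.frame(id = character(), score = numeric(), E = numeric()))
  }
  sc <- profile_score(profile, df$seq)
  E <- profile_evalue(profile, sc, nrow(df))
  hit <- E <= e_threshold
  out <- data.frame(id = df$id[hit], score = sc[hit], E = E[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(out$E, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
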