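# Shared small helpers: sequence utilities, seeds, validation.

DNA <- c("A", "C", "G", "T")

#' GC fraction of nucleotide sequences
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of G+C fractions in [0, 1].
#' @export
gc_fraction <- function(x) {
  stopifnot(is.character(x))
  out <- vapply(x, function(s) {
    if (!nzchar(s)) return(NA_real_)
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    mean(v %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements (names preserved).
#' @export
revcomp <- function(x) .revcomp_cpp(as.character(x))

#' Derive a per-stage RNG seed from a master seed
#'
#' Stage seeds are a deterministic hash of (master seed, stage name) so any
#' pipeline stage can be re-run in isolation with the seed recorded in the
#' run manifest. Result is a 31-bit non-negative integer.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 1000003
  as.integer(((abs(as.numeric(master_seed)) %% 1000003) * 1009 + h) %% 2147483647)
}

# i.i.d. random DNA at a given GC fraction (G/C and A/T split evenly).
# Uses the current RNG stream; callers are responsible for set.seed().
random_dna <- function(n_seq, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n_seq), function(i) {
    paste(sample(DNA, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Gumbel distribution helpers (method-of-moments fit; upper tail).
gumbel_fit <- function(scores) {
  if (length(scores) < 2L || sd(scores) < .Machine$double.eps^0.5) {
    stop("degenerate decoy score distribution; cannot calibrate")
  }
  beta <- sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649015329 * beta
  list(location = mu, scale = beta)
}

# P(S >= s) under Gumbel(location, scale), numerically stable in the far tail.
gumbel_tail <- function(s, location, scale) {
  z <- exp(-(s - location) / scale)
  -expm1(-z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_seq_df <- function(seqs, family = NULL) {
  if (is.data.frame(seqs)) {
    stopifnot(all(c("id", "seq") %in% names(seqs)))
    df <- seqs
  } else {
    s <- as.character(seqs)
    ids <- names(seqs)
    if (is.null(ids)) {
      ids <- sprintf("seq%d", seq_along(s))
      if (length(s)) warning("unnamed sequences; synthetic ids assigned")
    }
    df <- data.frame(id = ids, seq = unname(s), stringsAsFactors = FALSE)
  }
  if (!is.null(family) && is.null(df$family)) df$family <- family
  if (anyDuplicated(df$id)) stop("sequence ids must be unique")
  if (any(!nzchar(df$seq))) stop("empty sequence not allowed")
  df
}
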