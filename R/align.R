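#' Pairwise sequence identity under the package convention
#'
#' All nucleotide identity computations in the package (greedy clustering,
#' identity binning, probe/fragment matching) share one convention: the
#' optimal pairwise alignment under match +1, mismatch -1, gap -1 (linear),
#' with the deterministic tie-break diagonal > up > left. For
#' \code{mode = "global"} identity is identical aligned positions divided by
#' the length of the shorter sequence (the cd-hit convention); for
#' \code{mode = "local"} it is identities divided by alignment columns.
#'
#' @param a,b single sequences (character).
#' @param mode "global" or "local".
#' @return numeric identity in [0, 1].
#' @export
seq_identity <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  stopifnot(length(a) == 1L, length(b) == 1L, nzchar(a), nzchar(b))
  st <- .align_stats_cpp(a, b, mode == "local")
  if (mode == "global") {
    unname(st[["matches"]] / min(nchar(a), nchar(b)))
  } else {
    if (st[["columns"]] == 0L) 0 else unname(st[["matches"]] / st[["columns"]])
  }
}

# raw alignment statistics (score, matches, columns); internal
align_stats <- function(a, b, local = FALSE) {
  .align_stats_cpp(toupper(a), toupper(b), local)
}
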