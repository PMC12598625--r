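# Mock-community design: mass fractions hitting a target weighted GC mol%,
# and the dosage-based ground-truth gene abundances.

#' Mass-fraction-weighted GC mol\% of a DNA pool
#'
#' @param gc numeric vector of per-strain GC mol\% (0-100).
#' @param fractions mass fractions (must sum to 1 within 1e-6).
#' @return weighted GC mol\%: \code{sum(fractions * gc)}.
#' @export
weighted_gc <- function(gc, fractions) {
  stopifnot(length(gc) == length(fractions), all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 (got ", format(sum(fractions)), ")")
  }
  sum(fractions * gc)
}

#' Solve mass fractions for a target weighted GC mol\%
#'
#' Returns the fractions minimizing Kullback-Leibler divergence to
#' \code{prior} subject to sum(f) = 1, f >= 0 and
#' \code{weighted_gc(gc, f) = target_gc}. The solution is the exponential
#' tilt \code{f_i = prior_i exp(lambda gc_i) / Z}, with lambda found by
#' monotone root finding and polished by Newton steps to |deviation| <= 1e-9.
#'
#' @param gc per-strain GC mol\%.
#' @param target_gc target weighted GC mol\% (must lie within the attainable
#'   range [min(gc), max(gc)]).
#' @param prior prior fractions (default uniform).
#' @return numeric mass fractions summing to 1.
#' @export
solve_fractions <- function(gc, target_gc, prior = NULL) {
  stopifnot(length(gc) >= 1, all(is.finite(gc)))
  prior <- prior %||% rep(1 / length(gc), length(gc))
  stopifnot(length(prior) == length(gc), all(prior > 0))
  prior <- prior / sum(prior)
  lo <- min(gc); hi <- max(gc)
  if (target_gc < lo || target_gc > hi) {
    stop(sprintf("target GC %.4g infeasible; attainable range is [%.4g, %.4g]",
                 target_gc, lo, hi))
  }
  g <- function(lambda) {
    w <- prior * exp(lambda * (gc - mean(gc)))
    f <- w / sum(w)
    list(f = f, gc = sum(f * gc), var = sum(f * gc^2) - sum(f * gc)^2)
  }
  if (abs(g(0)$gc - target_gc) < 1e-12) return(g(0)$f)
  # bracket lambda, then root-find, then Newton-polish
  span <- max(hi - lo, 1e-8)
  lim <- 1
  while (lim < 1e6 / span) {
    if ((g(-lim)$gc - target_gc) * (g(lim)$gc - target_gc) <= 0) break
    lim <- lim * 2
  }
  r <- uniroot(function(l) g(l)$gc - target_gc, c(-lim, lim),
               tol = .Machine$double.eps^0.75)
  lambda <- r$root
  for (it in 1:50) {
    st <- g(lambda)
    dev <- target_gc - st$gc
    if (abs(dev) <= 1e-10 || st$var <= 0) break
    lambda <- lambda + dev / st$var
  }
  st <- g(lambda)
  if (abs(st$gc - target_gc) > 1e-9) {
    stop(sprintf("could not reach target GC %.4g (best %.6g); target too %s",
                 target_gc, st$gc,
                 if (target_gc < mean(gc)) "close to the minimum strain GC"
                 else "close to the maximum strain GC"))
  }
  st$f
}

#' Expected per-family relative gene abundance of a mock design
#'
#' Gene dosage (copies per unit DNA mass) is
#' \code{d_g = sum_i fraction_i * copies_{g,i} / length_i}; the expected
#' abundance is \code{100 * d_g / sum_h d_h}.
#'
#' @param copies strains x families matrix of gene copy counts (dimnames
#'   used for output names).
#' @param lengths per-strain genome/fragment lengths (bp).
#' @param fractions per-strain mass fractions.
#' @return named numeric vector of percentages summing to 100.
#' @export
expected_abundance <- function(copies, lengths, fractions) {
  copies <- as.matrix(copies)
  stopifnot(nrow(copies) == length(lengths),
            nrow(copies) == length(fractions), all(lengths > 0))
  d <- colSums(copies * (fractions / lengths))
  if (sum(d) <= 0) stop("empty design: no target genes anywhere")
  100 * d / sum(d)
}

#' Convert pipetted volumes and DNA concentrations to mass fractions
#'
#' @param volumes per-strain volumes (uL).
#' @param concentrations per-strain DNA concentrations (ng/uL).
#' @return mass fractions summing to 1.
#' @export
volumes_to_fractions <- function(volumes, concentrations) {
  stopifnot(length(volumes) == length(concentrations),
            all(volumes >= 0), all(concentrations >= 0))
  m <- volumes * concentrations
  if (sum(m) <= 0) stop("total DNA mass is zero")
  m / sum(m)
}

#' Design a mock community
#'
#' Binds strain metadata, mass fractions (given directly or solved for a
#' target weighted GC mol\%), the realized weighted GC, and the dosage-based
#' expected per-family abundance (the benchmark ground truth).
#'
#' @param strains data.frame with columns \code{name}, \code{kind}
#'   ("genome" or "fragment"), \code{length_bp}, \code{gc} (mol\%).
#' @param copies strains x families copy-count matrix (rownames matching
#'   strain names, colnames are family labels).
#' @param mass_fractions explicit fractions (overrides \code{target_gc}).
#' @param target_gc target weighted GC mol\% passed to
#'   \code{\link{solve_fractions}}.
#' @param prior prior fractions for \code{\link{solve_fractions}}.
#' @return object of class \code{mock_design}.
#' @export
mock_design <- function(strains, copies, mass_fractions = NULL,
                        target_gc = NULL, prior = NULL) {
  stopifnot(is.data.frame(strains),
            all(c("name", "length_bp", "gc") %in% names(strains)))
  if (is.null(strains$kind)) strains$kind <- "genome"
  stopifnot(all(strains$kind %in% c("genome", "fragment")),
            all(strains$gc > 0 & strains$gc < 100))
  copies <- as.matrix(copies)
  stopifnot(nrow(copies) == nrow(strains), all(copies >= 0))
  if (is.null(rownames(copies))) rownames(copies) <- strains$name
  if (is.null(mass_fractions)) {
    if (is.null(target_gc)) stop("give mass_fractions or target_gc")
    mass_fractions <- solve_fractions(strains$gc, target_gc, prior)
  }
  if (abs(sum(mass_fractions) - 1) > 1e-9) {
    stop("mass_fractions must sum to 1 within 1e-9")
  }
  structure(list(strains = strains, copies = copies,
                 mass_fractions = mass_fractions,
                 weighted_gc = sum(mass_fractions * strains$gc),
                 expected_abundance = expected_abundance(
                   copies, strains$length_bp, mass_fractions)),
            class = "mock_design")
}

#' @export
print.mock_design <- function(x, ...) {
  cat("mock_design:", nrow(x$strains), "strains, weighted GC",
      sprintf("%.2f", x$weighted_gc), "mol%\n")
  cat("expected abundance (%):\n")
  print(round(x$expected_abundance, 2))
  invisible(x)
}

#' Write a mock design as JSON (plus strain TSV)
#'
#' @param design a \code{mock_design}.
#' @param prefix path prefix; writes \code{<prefix>.json} and
#'   \code{<prefix>_strains.tsv}.
#' @export
write_mock_design <- function(design, prefix) {
  stopifnot(inherits(design, "mock_design"))
  jsonlite::write_json(
    list(mass_fractions = setNames(as.list(design$mass_fractions),
                                   design$strains$name),
         weighted_gc = design$weighted_gc,
         expected_abundance = as.list(design$expected_abundance)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  st <- design$strains
  st$mass_fraction <- design$mass_fractions
  write.table(st, paste0(prefix, "_strains.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
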