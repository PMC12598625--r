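# Gene-family registry: the marker genes targeted by the panel, their
# pathways, and the homolog groups that drive read disambiguation.

PATHWAYS <- c("N_fixation", "nitrification", "denitrification", "anammox",
              "DNRA", "methanogenesis", "methanotrophy")

#' Construct a gene-family registry
#'
#' @param families data.frame with columns \code{name}, \code{pathway},
#'   \code{homolog_group} (NA when none) and \code{sub_clades}
#'   (comma-separated string or NA).
#' @param homolog_groups named list mapping a group label to a character
#'   vector of member labels. Members may include decoy labels (e.g.
#'   \code{narH}) that are not registry families; a decoy label may occur in
#'   more than one group.
#' @return object of class \code{gene_registry}.
#' @export
gene_registry <- function(families, homolog_groups = list()) {
  stopifnot(is.data.frame(families),
            all(c("name", "pathway") %in% names(families)))
  if (anyDuplicated(families$name)) stop("family names must be unique")
  if (!all(families$pathway %in% PATHWAYS)) {
    stop("unknown pathway; must be one of: ", paste(PATHWAYS, collapse = ", "))
  }
  if (is.null(families$homolog_group)) families$homolog_group <- NA_character_
  if (is.null(families$sub_clades)) families$sub_clades <- NA_character_
  for (g in names(homolog_groups)) {
    if (length(homolog_groups[[g]]) < 2L) {
      stop("homolog group '", g, "' must name >= 2 members")
    }
  }
  # each family's homolog_group, when present, must be a declared group
  hg <- families$homolog_group
  bad <- !is.na(hg) & !(hg %in% names(homolog_groups))
  if (any(bad)) stop("undeclared homolog_group: ", paste(hg[bad], collapse = ", "))
  structure(list(families = families, homolog_groups = homolog_groups),
            class = "gene_registry")
}

#' The default 14-family registry
#'
#' Fourteen marker genes of inorganic nitrogen and methane cycling. Archaeal
#' and bacterial amoA are sub-clades of the single amoA entry. Homolog groups
#' capture the families whose cross-similarity requires competitive
#' disambiguation; the decoy labels narH (nitrate reductase beta subunit) and
#' fdhA (formate dehydrogenase, a napA homolog) are group members but not
#' registry families.
#'
#' @return a \code{gene_registry} with 14 families.
#' @export
default_registry <- function() {
  fam <- data.frame(
    name = c("nifH", "amoA", "nxrB", "hzoA", "nrfA", "napA", "narG",
             "nirK", "nirS", "norB", "nosZ", "pmoA", "mmoX", "mcrA"),
    pathway = c("N_fixation", "nitrification", "nitrification", "anammox",
                "DNRA", "denitrification", "denitrification",
                "denitrification", "denitrification", "denitrification",
                "denitrification", "methanotrophy", "methanotrophy",
                "methanogenesis"),
    homolog_group = c(NA, "amo_pmo", "nxr_nar", NA, "nap_nar_nrf",
                      "nap_nar_nrf", "nap_nar_nrf", NA, NA, NA, NA,
                      "amo_pmo", NA, NA),
    sub_clades = c(NA, "archaeal,bacterial", rep(NA_character_, 12L)),
    stringsAsFactors = FALSE
  )
  gene_registry(fam, homolog_groups = list(
    amo_pmo = c("amoA", "pmoA"),
    nap_nar_nrf = c("napA", "narG", "nrfA", "narH", "fdhA"),
    nxr_nar = c("nxrB", "narH")
  ))
}

#' @export
print.gene_registry <- function(x, ...) {
  cat("gene_registry:", nrow(x$families), "families;",
      length(x$homolog_groups), "homolog groups\n")
  print(x$families, row.names = FALSE)
  invisible(x)
}

#' Do two labels share a homolog group?
#'
#' @param registry a \code{gene_registry}.
#' @param f1,f2 family or decoy labels.
#' @return logical.
#' @export
same_homolog_group <- function(registry, f1, f2) {
  stopifnot(inherits(registry, "gene_registry"))
  any(vapply(registry$homolog_groups,
             function(m) f1 %in% m && f2 %in% m, logical(1)))
}

# label -> merged label (first group containing it, in declaration order)
homolog_merge_label <- function(registry, labels) {
  groups <- registry$homolog_groups
  vapply(labels, function(l) {
    for (g in names(groups)) if (l %in% groups[[g]]) return(g)
    l
  }, character(1), USE.NAMES = FALSE)
}

#' Read / write a registry as JSON
#'
#' @param path file path.
#' @return \code{read_registry} returns a \code{gene_registry}.
#' @export
read_registry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fam <- as.data.frame(j$families, stringsAsFactors = FALSE)
  fam$homolog_group[fam$homolog_group == ""] <- NA_character_
  if (!is.null(fam$sub_clades)) fam$sub_clades[fam$sub_clades == ""] <- NA_character_
  gene_registry(fam, lapply(j$homolog_groups, as.character))
}

#' @param registry a \code{gene_registry}.
#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "gene_registry"))
  fam <- registry$families
  fam$homolog_group[is.na(fam$homolog_group)] <- ""
  fam$sub_clades[is.na(fam$sub_clades)] <- ""
  jsonlite::write_json(list(families = fam,
                            homolog_groups = registry$homolog_groups),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Dereplicate a sequence set at 100\% identity
#'
#' cd-hit 100\% semantics: case-folded identical sequences collapse to one
#' record (first-seen id retained) and exact substrings of a longer retained
#' sequence are removed. Order of first occurrence is preserved. Idempotent.
#'
#' @param seqs named character vector of sequences, or a data.frame with
#'   columns \code{id} and \code{seq}.
#' @return data.frame with columns \code{id}, \code{seq} (plus any input
#'   columns) of retained records.
#' @export
dereplicate <- function(seqs) {
  df <- as_seq_df(seqs)
  if (nrow(df) == 0L) return(df)
  up <- toupper(df$seq)
  # collapse exact duplicates, first-seen id wins
  keep <- !duplicated(up)
  df <- df[keep, , drop = FALSE]
  up <- up[keep]
  # remove exact substrings of longer retained sequences
  ord <- order(-nchar(up))
  absorbed <- rep(FALSE, nrow(df))
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (absorbed[i]) next
    if (pos < length(ord)) {
      for (j in ord[(pos + 1L):length(ord)]) {
        if (!absorbed[j] && nchar(up[j]) <= nchar(up[i]) &&
            grepl(up[j], up[i], fixed = TRUE)) {
          absorbed[j] <- TRUE
        }
      }
    }
  }
  out <- df[!absorbed, , drop = FALSE]
  rownames(out) <- NULL
  out
}
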