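# Synthetic fixture generation: family consensus genes, target databases,
# strain genomes with planted marker genes, and the example strain pool.
#
# Everything here is an explicitly synthetic stand-in for reference material
# (curated alignments, cultured genomes) that a real deployment would load.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# one random protein-coding sequence: ATG + (n_codons - 1) non-stop codons
random_cds <- function(n_codons, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codons <- character(n_codons)
  codons[1] <- "ATG"
  for (i in 2:n_codons) {
    repeat {
      cd <- paste(sample(DNA, 3, replace = TRUE, prob = p), collapse = "")
      if (!(cd %in% STOP_CODONS)) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

#' Codon-aware point mutation of a coding sequence
#'
#' Substitutes positions at the given per-site divergence; a substitution
#' that would create an in-frame stop codon is skipped, so reading frames
#' stay intact (substitutions only, no indels). Uses the current RNG stream.
#'
#' @param seq coding sequence (length a multiple of 3).
#' @param divergence per-site substitution probability.
#' @return mutated sequence.
#' @export
mutate_cds <- function(seq, divergence) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stopifnot(n %% 3 == 0, divergence >= 0, divergence <= 0.9)
  if (divergence == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(n) < divergence)
  for (i in hit) {
    old <- v[i]
    new <- sample(setdiff(DNA, old), 1L)
    cstart <- 3L * ((i - 1L) %/% 3L) + 1L
    codon <- v[cstart:(cstart + 2L)]
    codon[(i - cstart) + 1L] <- new
    if (!(paste(codon, collapse = "") %in% STOP_CODONS)) v[i] <- new
  }
  paste(v, collapse = "")
}

translate_cds <- function(seq) {
  n <- 3L * (nchar(seq) %/% 3L)
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                     no.init.codon = TRUE))
}

#' Synthesize consensus genes, proteins and a target database for a registry
#'
#' Generates one consensus coding sequence per family (plus the decoy
#' homolog labels declared in the registry's homolog groups), with homolog
#' families derived from shared ancestors so that cross-family similarity is
#' realistic (amoA/pmoA and the nitrate-reductase-like cluster are mutually
#' alignable at roughly 60-80\% amino-acid identity; unrelated families are
#' independent random genes). Also emits \code{n_variants} within-family
#' variant sequences per family (a synthetic target database for probe
#' design and profile building).
#'
#' @param registry a \code{gene_registry}.
#' @param seed integer seed.
#' @param n_codons consensus length in codons (default 200, i.e. 600 nt:
#'   desk-scale stand-ins for the 0.7-2.5 kb real marker genes; equal length
#'   across families keeps read counts proportional to gene dosage).
#' @param n_variants variants per family in the target database (default 8).
#' @param max_variant_divergence variants span divergences from 0.02 up to
#'   this value (default 0.15).
#' @param gc_by_family optional named GC fractions per family; default a
#'   deterministic spread over 0.42-0.62.
#' @return list with \code{consensus} (named nt sequences, families then
#'   decoys), \code{proteins} (translations), \code{variants} (data.frame
#'   id/seq/family), \code{decoys} (decoy label vector), \code{gc} (named GC
#'   fractions used).
#' @export
synth_family_sequences <- function(registry, seed = 1L, n_codons = 200,
                                   n_variants = 8,
                                   max_variant_divergence = 0.15,
                                   gc_by_family = NULL) {
  stopifnot(inherits(registry, "gene_registry"))
  fams <- registry$families$name
  decoys <- setdiff(unique(unlist(registry$homolog_groups)), fams)
  set.seed(seed)
  if (is.null(gc_by_family)) {
    gc_by_family <- setNames(seq(0.42, 0.62, length.out = length(fams)), fams)
  }
  stopifnot(all(fams %in% names(gc_by_family)))
  consensus <- setNames(character(0), character(0))
  # shared ancestry inside homolog clusters; the two nar-like groups are
  # bridged through the narH decoy, mirroring the real gene superfamily
  anc_amo <- random_cds(n_codons, mean(gc_by_family[c("amoA", "pmoA")] %||% 0.5))
  anc_nar <- random_cds(n_codons,
                        mean(gc_by_family[intersect(c("napA", "narG", "nrfA"),
                                                    fams)] %||% 0.5))
  derive <- function(parent, div) mutate_cds(parent, div)
  narH <- derive(anc_nar, 0.10)
  for (f in fams) {
    consensus[f] <- switch(f,
      amoA = derive(anc_amo, 0.12),
      pmoA = derive(anc_amo, 0.12),
      napA = derive(anc_nar, 0.10),
      narG = derive(anc_nar, 0.10),
      nrfA = derive(anc_nar, 0.14),
      nxrB = derive(narH, 0.12),
      random_cds(n_codons, gc_by_family[f]))
  }
  for (d in decoys) {
    consensus[d] <- switch(d,
      narH = narH,
      fdhA = derive(consensus["napA"] %||% anc_nar, 0.12),
      derive(anc_nar, 0.15))
  }
  proteins <- vapply(consensus, translate_cds, character(1))
  divs <- seq(0.02, max_variant_divergence, length.out = n_variants)
  variants <- do.call(rbind, lapply(fams, function(f) {
    data.frame(id = sprintf("%s_v%02d", f, seq_len(n_variants)),
               seq = vapply(divs, function(d) mutate_cds(consensus[[f]], d),
                            character(1)),
               family = f, stringsAsFactors = FALSE)
  }))
  rownames(variants) <- NULL
  list(consensus = consensus, proteins = proteins, variants = variants,
       decoys = decoys, gc = gc_by_family)
}

#' Synthesize a strain genome with planted marker genes
#'
#' Background is sampled i.i.d. at the requested GC; each gene copy is the
#' family consensus mutated codon-aware at the given divergence and planted
#' at a non-overlapping position on a random strand. Truth coordinates are
#' 0-based half-open with strand.
#'
#' @param name strain name.
#' @param length_bp genome (or fragment) length.
#' @param gc_molpercent genome GC in mol\% (0-100).
#' @param genes named integer vector of copy counts per family, or a
#'   data.frame with columns \code{family}, \code{copies} and optional
#'   \code{divergence}.
#' @param consensus named consensus sequences (from
#'   \code{\link{synth_family_sequences}}).
#' @param seed integer seed (same seed, same genome).
#' @param divergence default per-copy divergence when \code{genes} has no
#'   divergence column (default 0.10).
#' @return list with \code{spec} (name, kind, length_bp, gc requested,
#'   gc_measured, gene_copies), \code{genome} (sequence string) and
#'   \code{truth} (data.frame chrom, start, end, family, strand, copy_id).
#' @export
synth_strain <- function(name, length_bp, gc_molpercent, genes, consensus,
                         seed = 1L, divergence = 0.10) {
  stopifnot(gc_molpercent > 0, gc_molpercent < 100)
  if (!is.data.frame(genes)) {
    genes <- data.frame(family = names(genes), copies = as.integer(genes),
                        stringsAsFactors = FALSE)
  }
  if (is.null(genes$divergence)) genes$divergence <- divergence
  genes <- genes[genes$copies > 0, , drop = FALSE]
  stopifnot(all(genes$family %in% names(consensus)))
  glens <- nchar(consensus[genes$family])
  total_gene_bp <- sum(glens * genes$copies)
  if (total_gene_bp > length_bp) {
    stop("overcrowded genome: ", total_gene_bp, " gene bp requested in ",
         length_bp, " bp")
  }
  set.seed(seed)
  genome <- random_dna(1L, length_bp, gc_molpercent / 100)
  # expand to one row per copy, mutate, place without overlap
  fam_rep <- rep(genes$family, genes$copies)
  div_rep <- rep(genes$divergence, genes$copies)
  inserts <- mapply(function(f, d) mutate_cds(consensus[[f]], d),
                    fam_rep, div_rep, USE.NAMES = FALSE)
  lens <- nchar(inserts)
  truth <- NULL
  if (length(inserts) > 0L) {
    if (sum(lens) > 0.6 * length_bp) {
      stop("overcrowded genome: placement infeasible at this density")
    }
    starts <- NULL
    for (try in 1:1000) {
      cand <- sort(sample.int(length_bp - max(lens) + 1L, length(inserts),
                              replace = TRUE) - 1L)
      ends <- cand + lens  # sorted starts paired with copies in input order
      if (all(cand[-1] >= head(ends, -1))) { starts <- cand; break }
    }
    if (is.null(starts)) stop("overcrowded genome: could not place genes")
    strands <- sample(c("+", "-"), length(inserts), replace = TRUE)
    for (i in seq_along(inserts)) {
      s <- if (strands[i] == "-") revcomp(inserts[i]) else inserts[i]
      substr(genome, starts[i] + 1L, starts[i] + lens[i]) <- s
    }
    truth <- data.frame(chrom = name, start = starts, end = starts + lens,
                        family = fam_rep, strand = strands,
                        copy_id = sprintf("%s_%s_c%d", name, fam_rep,
                                          stats::ave(seq_along(fam_rep),
                                                     fam_rep, FUN = seq_along)),
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), family = character(),
                        strand = character(), copy_id = character(),
                        stringsAsFactors = FALSE)
  }
  copies_named <- setNames(genes$copies, genes$family)
  list(spec = list(name = name, kind = "genome", length_bp = length_bp,
                   gc_molpercent = gc_molpercent,
                   gc_measured = 100 * gc_fraction(genome),
                   gene_copies = copies_named),
       genome = setNames(genome, name), truth = truth)
}

#' Synthesize all genomes of a strain pool
#'
#' @param strains strain data.frame (name, kind, length_bp, gc).
#' @param copies strains x families copy matrix.
#' @param consensus named consensus sequences.
#' @param seed master seed; per-strain seeds are derived with
#'   \code{\link{stage_seed}}.
#' @param divergence per-copy divergence from the family consensus.
#' @return list with \code{genomes} (named character) and \code{truth}
#'   (combined BED-like data.frame).
#' @export
synth_community <- function(strains, copies, consensus, seed = 1L,
                            divergence = 0.10) {
  copies <- as.matrix(copies)
  genomes <- character(0)
  truth <- list()
  for (i in seq_len(nrow(strains))) {
    g <- synth_strain(strains$name[i], strains$length_bp[i], strains$gc[i],
                      setNames(copies[i, ], colnames(copies)), consensus,
                      seed = stage_seed(seed, paste0("strain:", strains$name[i])),
                      divergence = divergence)
    genomes <- c(genomes, g$genome)
    truth[[i]] <- g$truth
  }
  list(genomes = genomes, truth = do.call(rbind, truth))
}

#' Example 19-entry mock-community strain pool (synthetic stand-in)
#'
#' A desk-scale stand-in for the published mock community: 18 cultured
#' organisms plus one anammox hzoA PCR fragment. Organism names and GC mol\%
#' follow the published genomes approximately; genome lengths are the real
#' sizes scaled down 100x (expected abundances are invariant under uniform
#' length scaling); gene content is a plausible reconstruction of each
#' organism's known repertoire, not a published table. Prior pooling
#' fractions are proportional to genome length so dosage is driven by copy
#' number.
#'
#' @param registry a \code{gene_registry} (families define the copy-matrix
#'   columns).
#' @return list with \code{strains} (data.frame name, kind, length_bp, gc,
#'   prior) and \code{copies} (strains x families matrix).
#' @export
example_mock_pool <- function(registry = default_registry()) {
  fams <- registry$families$name
  spec <- list(
    #                 name                        gc    kb   genes
    list("Nitrosospira_multiformis",   53.9, 32000, c(amoA = 2, nirK = 1, norB = 1)),
    list("Nitrososphaera_viennensis",  52.7, 25000, c(amoA = 1, nirK = 1)),
    list("Nitrospira_defluvii",        59.0, 43000, c(nxrB = 2)),
    list("Kuenenia_hzoA_fragment",     41.0,  1000, c(hzoA = 1)),
    list("Pseudomonas_aeruginosa",     66.6, 63000, c(narG = 1, nirS = 1, norB = 1, nosZ = 1)),
    list("Escherichia_coli",           50.8, 46000, c(narG = 2, napA = 1, nrfA = 1)),
    list("Shigella_sonnei",            51.0, 48000, c(narG = 1, napA = 1, nrfA = 1)),
    list("Cupriavidus_metallidurans",  63.9, 69000, c(narG = 1, norB = 1, nosZ = 1)),
    list("Cupriavidus_necator",        66.3, 74000, c(napA = 1, narG = 1, nirS = 1, norB = 1, nosZ = 1)),
    list("Dyadobacter_fermentans",     51.3, 61000, c(nosZ = 1)),
    list("Pseudomonas_stutzeri",       63.9, 46000, c(narG = 1, nirS = 1, norB = 1, nosZ = 1)),
    list("Rhodobacter_sphaeroides",    68.8, 46000, c(napA = 1, nirK = 1, norB = 1, nosZ = 1)),
    list("Salinibacter_ruber",         66.2, 36000, c(nirK = 1)),
    list("Sulfurimonas_denitrificans", 34.5, 22000, c(napA = 1, nirS = 1, norB = 1, nosZ = 1)),
    list("Methylosinus_trichosporium", 62.6, 50000, c(pmoA = 1, mmoX = 1, nifH = 1)),
    list("Methylocella_tundrae",       60.0, 42000, c(mmoX = 1, nifH = 1)),
    list("Methylomicrobium_buryatense", 49.0, 49000, c(pmoA = 2, mmoX = 1)),
    list("Methanoregula_boonei",       54.5, 25000, c(mcrA = 1)),
    list("Methanolacinia_petrolearia", 50.0, 28000, c(mcrA = 1, nifH = 1))
  )
  strains <- data.frame(
    name = vapply(spec, `[[`, character(1), 1L),
    kind = "genome",
    length_bp = vapply(spec, `[[`, numeric(1), 3L),
    gc = vapply(spec, `[[`, numeric(1), 2L),
    stringsAsFactors = FALSE
  )
  strains$kind[strains$name == "Kuenenia_hzoA_fragment"] <- "fragment"
  strains$prior <- strains$length_bp / sum(strains$length_bp)
  copies <- matrix(0L, nrow(strains), length(fams),
                   dimnames = list(strains$name, fams))
  for (i in seq_along(spec)) {
    g <- spec[[i]][[4L]]
    copies[i, names(g)] <- as.integer(g)
  }
  list(strains = strains, copies = copies)
}

#' Write planted-gene truth as BED (0-based half-open) and TSV
#'
#' @param truth truth data.frame from \code{\link{synth_community}}.
#' @param prefix path prefix; writes \code{<prefix>.bed} and
#'   \code{<prefix>.tsv}.
#' @export
write_truth <- function(truth, prefix) {
  bed <- data.frame(chrom = truth$chrom, start = truth$start, end = truth$end,
                    name = truth$copy_id, score = 0L, strand = truth$strand)
  write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(truth, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
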