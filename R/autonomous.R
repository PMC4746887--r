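## Autonomous-element identification and family classification.
## A LINE is called autonomous when it has at least two ORFs and its
## RT-bearing ORF ("ORF2") exceeds 700 aa; an LTR element when it carries an
## RT-bearing ORF above 500 aa.  Autonomous elements are grouped into
## families by single-linkage clustering at 80% amino-acid identity of the
## comparison ORF.

#' Find open reading frames in six frames
#'
#' Reports every ATG-to-stop ORF of at least `min_aa` codons (stop excluded
#' from the protein) across the three forward and three reverse frames,
#' sorted by protein length descending.  Coordinates are 1-based inclusive on
#' the input sequence and span start codon through stop codon; negative
#' frames report mirrored coordinates (`start` < `end` always).
#'
#' @param seq Nucleotide sequence (character or `DNAString`).
#' @param min_aa Minimum protein length in amino acids.
#' @return Data.frame with columns `frame` (+1..+3, -1..-3), `start`, `end`,
#'   `protein`, `length_aa`.
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet"))
    seq <- as.character(seq)[1L]
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else revcomp(seq)
    for (f in 0:2) {
      sub <- substr(s, f + 1L, nchar(s))
      sub <- substr(sub, 1L, nchar(sub) - nchar(sub) %% 3L)
      if (nchar(sub) < 6L) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
      m <- gregexpr("M[^*]*\\*", aa)[[1L]]
      if (m[1L] == -1L) next
      lens <- attr(m, "match.length")
      for (k in seq_along(m)) {
        prot <- substr(aa, m[k], m[k] + lens[k] - 2L)  # drop the stop
        if (nchar(prot) < min_aa) next
        nt_s <- f + 3L * (m[k] - 1L) + 1L              # on strand s
        nt_e <- nt_s + 3L * (nchar(prot) + 1L) - 1L    # through stop codon
        if (strand == -1L) { tmp <- nt_s; nt_s <- L - nt_e + 1L; nt_e <- L - tmp + 1L }
        out[[length(out) + 1L]] <- data.frame(
          frame = strand * (f + 1L), start = nt_s, end = nt_e,
          protein = prot, length_aa = nchar(prot), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      protein = character(), length_aa = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(-res$length_aa, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reference profile for reverse-transcriptase detection
#'
#' @param references Named character vector (or `AAStringSet`) of reference
#'   RT-domain amino-acid sequences.
#' @param min_coverage Minimum fraction of a reference covered by the local
#'   alignment for a detection call.
#' @param min_identity Minimum identity over aligned substitution columns.
#' @return An `rt_profile` list.
#' @export
rt_profile <- function(references, min_coverage = 0.80,
                       min_identity = 0.25) {
  if (methods::is(references, "AAStringSet"))
    references <- stats::setNames(as.character(references), names(references))
  if (length(references) == 0L) stop("empty RT reference set")
  structure(list(references = references, min_coverage = min_coverage,
                 min_identity = min_identity), class = "rt_profile")
}

#' Detect an intact RT domain in a protein
#'
#' Locally aligns the protein against each reference RT domain (BLOSUM62);
#' the domain is called intact when, for some reference, the alignment
#' covers at least `min_coverage` of the reference with identity at least
#' `min_identity`.
#'
#' @param protein Amino-acid string.
#' @param profile An [rt_profile()].
#' @return List with `detected`, `coverage`, `identity`, `reference` (best
#'   reference by coverage then identity).
#' @export
detect_rt <- function(protein, profile) {
  stopifnot(inherits(profile, "rt_profile"))
  if (nchar(protein) == 0L)
    return(list(detected = FALSE, coverage = 0, identity = 0,
                reference = NA_character_))
  best <- list(detected = FALSE, coverage = 0, identity = 0,
               reference = NA_character_)
  for (i in seq_along(profile$references)) {
    ref <- profile$references[[i]]
    aln <- align_local(ref, protein, aa = TRUE)
    cov <- (aln$pattern_end - aln$pattern_start + 1L) / nchar(ref)
    nsub <- aln$matches + aln$mismatches
    ident <- if (nsub > 0) aln$matches / nsub else 0
    det <- cov >= profile$min_coverage && ident >= profile$min_identity
    if (det && !best$detected ||
        (det == best$detected &&
         (cov > best$coverage ||
          (cov == best$coverage && ident > best$identity)))) {
      best <- list(detected = det, coverage = cov, identity = ident,
                   reference = names(profile$references)[i] %||%
                     as.character(i))
    }
  }
  best
}

#' Autonomy criteria
#' @param element_kind `"LINE"` or `"LTR"`.
#' @param min_orf_aa Minimum length (strict `>`) of the RT-bearing ORF:
#'   700 aa for LINEs (ORF2), 500 aa for LTR elements.
#' @param require_rt Require an intact RT domain.
#' @param orf_min_aa Floor used when enumerating ORFs (the LINE rule also
#'   requires a second ORF of at least this length).
#' @return An `autonomy_criteria` list.
#' @export
autonomy_criteria <- function(element_kind = c("LINE", "LTR"),
                              min_orf_aa = NULL, require_rt = TRUE,
                              orf_min_aa = 100L) {
  element_kind <- match.arg(element_kind)
  if (is.null(min_orf_aa))
    min_orf_aa <- if (element_kind == "LINE") 700L else 500L
  stopifnot(min_orf_aa > 0)
  structure(list(element_kind = element_kind,
                 min_orf_aa = as.integer(min_orf_aa),
                 require_rt = require_rt,
                 orf_min_aa = as.integer(orf_min_aa)),
            class = "autonomy_criteria")
}

#' Is an element autonomous?
#'
#' LINEs: autonomous iff the RT-bearing ORF (taken as ORF2 — robust to 5'
#' truncation) is longer than `min_orf_aa` (700 aa) and a second ORF lies
#' outside its footprint (the ORF1 of the canonical LINE structure).  LTR
#' elements: autonomous iff some ORF longer than `min_orf_aa` (500 aa)
#' carries an intact RT domain.
#'
#' @param element Nucleotide sequence of the element.
#' @param criteria An [autonomy_criteria()].
#' @param profile An [rt_profile()]; required when `criteria$require_rt`.
#' @return List with `autonomous` (logical), `orf2_aa` (length of the
#'   qualifying ORF, `NA` if none), `rt` (the [detect_rt()] result for it),
#'   and `orfs` (the full ORF table).
#' @export
is_autonomous <- function(element, criteria, profile = NULL) {
  stopifnot(inherits(criteria, "autonomy_criteria"))
  orfs <- find_orfs(element, min_aa = criteria$orf_min_aa)
  res <- list(autonomous = FALSE, orf2_aa = NA_integer_, rt = NULL,
              orfs = orfs)
  if (nrow(orfs) == 0L) return(res)
  if (criteria$require_rt && is.null(profile))
    stop("RT profile required when require_rt = TRUE")
  rt_hits <- if (criteria$require_rt)
    lapply(orfs$protein, detect_rt, profile = profile)
  else lapply(seq_len(nrow(orfs)), function(i)
    list(detected = TRUE, coverage = NA, identity = NA))
  carrying <- which(vapply(rt_hits, `[[`, TRUE, "detected"))
  if (length(carrying) == 0L) return(res)
  ## the RT-bearing ORF; orfs are sorted longest-first so [1] is the longest
  best <- carrying[1L]
  res$orf2_aa <- orfs$length_aa[best]
  res$rt <- rt_hits[[best]]
  long_enough <- orfs$length_aa[best] > criteria$min_orf_aa
  if (criteria$element_kind == "LINE") {
    ## the LINE structure requires a second ORF (ORF1) outside the
    ## RT-bearing ORF's footprint; overlapping ORFs on other frames of the
    ## same region do not count
    others <- orfs[-best, , drop = FALSE]
    has_orf1 <- any(others$end < orfs$start[best] |
                      others$start > orfs$end[best])
    res$autonomous <- long_enough && has_orf1
  } else {
    res$autonomous <- long_enough
  }
  res
}

#' Amino-acid identity of two proteins
#'
#' Ends-free (semi-global) alignment identity: matches divided by alignment
#' columns excluding terminal gaps — appropriate for elements that differ in
#' length by truncation.  The denominator is floored at the shorter
#' sequence's length, so a pair whose score-optimal ends-free alignment
#' covers only a short overlap cannot score high identity spuriously.
#' Symmetric in its arguments.
#'
#' @param a,b Amino-acid strings.
#' @return Identity in `[0, 1]`.
#' @export
aa_identity <- function(a, b) {
  ## canonical orientation so identity(a, b) == identity(b, a) exactly
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  aln <- align_local(a, b, type = "overlap", aa = TRUE)
  denom <- max(aln$columns, min(nchar(a), nchar(b)))
  if (denom == 0L) return(0)
  aln$matches / denom
}

#' Cluster autonomous elements into families
#'
#' Single-linkage clustering over pairs whose comparison proteins (ORF2 for
#' LINEs, the RT-bearing ORF for LTR elements) reach at least `threshold`
#' amino-acid identity.
#'
#' @param proteins Named character vector of comparison proteins.
#' @param threshold Identity threshold (default 0.80).
#' @return Data.frame with columns `name`, `family` (integer id numbered by
#'   sorted first member), `representative` (longest member, ties by name).
#' @export
cluster_families_aa <- function(proteins, threshold = 0.80) {
  nm <- names(proteins)
  if (is.null(nm)) nm <- paste0("el", seq_along(proteins))
  ord <- order(nm)
  proteins <- proteins[ord]; nm <- nm[ord]
  n <- length(proteins)
  comp <- seq_len(n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (aa_identity(proteins[[i]], proteins[[j]]) >= threshold) {
      ci <- comp[i]; cj <- comp[j]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  comp <- match(comp, unique(comp))
  rep_flag <- logical(n)
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    rep_flag[idx[order(-nchar(proteins[idx]), nm[idx])][1L]] <- TRUE
  }
  data.frame(name = nm, family = comp, representative = rep_flag,
             stringsAsFactors = FALSE)
}

#' Family-diversity table across species and clades
#'
#' Counts distinct families per species and clade; the per-species `Total`
#' row equals the sum of its clade rows.
#'
#' @param assignments Data.frame with columns `family`, `species`, `clade`.
#' @return Data.frame with one row per clade plus a `Total` row, one column
#'   per species, values = number of distinct families.
#' @export
family_diversity_table <- function(assignments) {
  if (nrow(assignments) == 0L)
    return(data.frame(clade = "Total", stringsAsFactors = FALSE))
  species <- sort(unique(assignments$species))
  clades <- sort(unique(assignments$clade))
  tab <- sapply(species, function(sp) vapply(clades, function(cl) {
    length(unique(assignments$family[assignments$species == sp &
                                       assignments$clade == cl]))
  }, 0L))
  tab <- matrix(tab, nrow = length(clades),
                dimnames = list(clades, species))
  out <- data.frame(clade = c(clades, "Total"), stringsAsFactors = FALSE)
  for (sp in species) out[[sp]] <- c(tab[, sp], sum(tab[, sp]))
  rownames(out) <- NULL
  out
}
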