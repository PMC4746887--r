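## Library curation: collect genomic copies of a query element, build
## majority-rule consensus sequences, and filter redundancy with the 80-80
## rule (two sequences belong to one family if they align over >80% of the
## shorter sequence's length at >80% identity).

#' Curation parameters
#'
#' @param top_hits_min,top_hits_max Number of non-overlapping genomic copies
#'   retained per query (consensus building needs at least 2; collection is
#'   capped at `top_hits_max`).
#' @param min_score Alignment-score significance threshold for collected
#'   copies (plays the role of an E-value cutoff for the internal aligner;
#'   see the shuffled-null calibration in the methods vignette).
#' @param flank_bp Genomic flank kept on each side of a collected copy.
#' @param rule_coverage,rule_identity The 80-80 rule thresholds (proportions,
#'   strict `>` comparisons).
#' @param coverage_denominator Which sequence's length the coverage fraction
#'   is taken over: `"shorter"` (default, the common 80-80-80 convention) or
#'   `"longer"`.
#' @return A `curation_params` list.
#' @export
curation_params <- function(top_hits_min = 10L, top_hits_max = 40L,
                            min_score = 50, flank_bp = 500L,
                            rule_coverage = 0.80, rule_identity = 0.80,
                            coverage_denominator = c("shorter", "longer")) {
  coverage_denominator <- match.arg(coverage_denominator)
  stopifnot(top_hits_min <= top_hits_max, rule_coverage > 0,
            rule_coverage <= 1, rule_identity > 0, rule_identity <= 1)
  structure(list(top_hits_min = as.integer(top_hits_min),
                 top_hits_max = as.integer(top_hits_max),
                 min_score = min_score, flank_bp = as.integer(flank_bp),
                 rule_coverage = rule_coverage,
                 rule_identity = rule_identity,
                 coverage_denominator = coverage_denominator),
            class = "curation_params")
}

#' Collect genomic copies of a query element
#'
#' Finds the top non-overlapping genomic matches of a nucleotide or protein
#' query (protein queries are searched against six-frame translations of
#' candidate windows), ranks them by alignment score, rejects hits below the
#' significance threshold, caps the list at `top_hits_max`, and returns each
#' hit with `flank_bp` of flanking genomic sequence, clipped at contig ends.
#'
#' @param genome One-record `DNAStringSet`/`DNAString` or character string.
#' @param query Query sequence (character); nucleotide by default.
#' @param params A [curation_params()].
#' @param query_type `"nucleotide"` or `"protein"`.
#' @param masker [masker_params()] controlling the underlying search.
#' @return A `DNAStringSet` of flanked copies named `copy1..copyN`, with
#'   `mcols` columns `start`, `end`, `strand`, `score` describing the
#'   unflanked hit.
#' @export
collect_copies <- function(genome, query, params = curation_params(),
                           query_type = c("nucleotide", "protein"),
                           masker = masker_params()) {
  query_type <- match.arg(query_type)
  if (methods::is(genome, "DNAStringSet")) genome <- genome[[1L]]
  if (methods::is(genome, "DNAString")) genome <- as.character(genome)
  masker$min_score <- max(masker$min_score, params$min_score)
  hits <- if (query_type == "nucleotide") {
    lib <- data.frame(name = "query", te_class = "Unknown",
                      superfamily = NA, family = NA, seq = query,
                      stringsAsFactors = FALSE)
    mask_genome(genome, lib, masker)
  } else {
    tblastn_hits(genome, query, masker)
  }
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  if (nrow(hits) > params$top_hits_max)
    hits <- hits[seq_len(params$top_hits_max), , drop = FALSE]
  if (nrow(hits) < 2L)
    stop("insufficient copies: ", nrow(hits),
         " significant non-overlapping hit(s); consensus needs >= 2")
  L <- nchar(genome)
  fs <- pmax(1L, hits$start - params$flank_bp)
  fe <- pmin(L, hits$end + params$flank_bp)
  seqs <- substring(genome, fs, fe)
  ## orient all copies on the query strand
  neg <- hits$strand == "-"
  seqs[neg] <- vapply(seqs[neg], revcomp, "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("copy", seq_along(seqs))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    start = hits$start, end = hits$end, strand = hits$strand,
    score = hits$score)
  out
}

## Protein-vs-genome search: exact amino-acid word seeds against six-frame
## translations locate candidate windows, which are refined by local
## protein alignment (BLOSUM62) and mapped back to genomic coordinates.
tblastn_hits <- function(genome, protein, masker, word = 5L) {
  L <- nchar(genome)
  grc <- revcomp(genome)
  offs <- seq.int(1L, max(1L, nchar(protein) - word + 1L))
  words <- unique(substring(protein, offs, offs + word - 1L))
  words <- words[nchar(words) == word & !grepl("[^A-Z]", words)]
  rows <- list()
  for (strand in c("+", "-")) {
    gseq <- if (strand == "+") genome else grc
    for (f in 0:2) {
      sub <- substr(gseq, f + 1L, nchar(gseq))
      sub <- substr(sub, 1L, nchar(sub) - nchar(sub) %% 3L)
      if (nchar(sub) < 3L) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
      pos <- unlist(lapply(words, function(wd)
        unlist(gregexpr(wd, aa, fixed = TRUE))))
      pos <- sort(unique(pos[pos > 0]))
      if (length(pos) == 0L) next
      qlen <- nchar(protein)
      brk <- c(TRUE, diff(pos) > qlen)
      grp <- cumsum(brk)
      for (p in split(pos, grp)) {
        ws <- max(1L, min(p) - qlen)
        we <- min(nchar(aa), max(p) + qlen)
        aln <- align_local(protein, substr(aa, ws, we), masker, aa = TRUE)
        if (aln$score < masker$min_score) next
        aas <- ws + aln$subject_start - 1L   # aa coords on this frame
        aae <- ws + aln$subject_end - 1L
        ns <- f + 3L * (aas - 1L) + 1L       # nt coords on gseq
        ne <- f + 3L * aae
        if (strand == "-") { tmp <- ns; ns <- L - ne + 1L; ne <- L - tmp + 1L }
        rows[[length(rows) + 1L]] <- data.frame(
          score = aln$score, divergence_D = NA_real_, query = "genome",
          start = ns, end = ne, strand = strand, library_name = "query",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- resolve_overlaps(hits, min_len = 3L * word)
  rownames(hits) <- NULL
  hits
}

#' Majority-rule consensus from an alignment
#'
#' Per column, the most frequent non-gap base is taken when non-gap
#' characters form the column majority; columns that are mostly gaps are
#' dropped.  Base ties are broken by the fixed precedence A > C > G > T.
#'
#' @param aligned Character vector (or `XStringSet`) of equal-length aligned
#'   rows, gaps as `-`.
#' @param name Name given to the consensus record.
#' @return A one-record `DNAStringSet`.
#' @export
build_consensus <- function(aligned, name = "consensus") {
  if (methods::is(aligned, "XStringSet")) aligned <- as.character(aligned)
  if (length(aligned) == 0L) stop("empty alignment")
  if (length(unique(nchar(aligned))) != 1L)
    stop("aligned rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  prec <- c("A", "C", "G", "T")
  cons <- apply(mat, 2L, function(col) {
    ngap <- col[col != "-"]
    if (length(ngap) * 2L <= length(col)) return(NA_character_)
    tab <- table(factor(ngap, levels = unique(c(prec, ngap))))
    names(tab)[which.max(tab)]   # which.max honors the precedence order
  })
  out <- Biostrings::DNAStringSet(paste(cons[!is.na(cons)], collapse = ""))
  names(out) <- name
  out
}

#' The 80-80 pair rule
#'
#' Two nucleotide sequences pass when a local alignment covers more than
#' `rule_coverage` of the shorter sequence's length with identity above
#' `rule_identity` over the aligned substitution columns (gap columns are
#' excluded from the identity denominator).
#'
#' @param a,b Nucleotide sequences (character).
#' @param params A [curation_params()].
#' @param masker Scoring scheme for the local aligner.
#' @return Logical scalar.
#' @export
pair_80_80 <- function(a, b, params = curation_params(),
                       masker = masker_params()) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  ## coverage is measured on the designated denominator sequence; align with
  ## that sequence as the pattern so its aligned span is directly available
  swap <- if (params$coverage_denominator == "shorter")
    nchar(b) < nchar(a) else nchar(b) > nchar(a)
  p <- if (swap) b else a
  s <- if (swap) a else b
  best <- NULL
  for (cand in c(s, revcomp(s))) {
    aln <- align_local(p, cand, masker)
    if (is.null(best) || aln$score > best$score) best <- aln
  }
  cov <- (best$pattern_end - best$pattern_start + 1L) / nchar(p)
  nsub <- best$matches + best$mismatches
  ident <- if (nsub > 0) best$matches / nsub else 0
  cov > params$rule_coverage && ident > params$rule_identity
}

#' Cluster library entries with the 80-80 rule
#'
#' Computes the full pairwise 80-80 relation and returns its single-linkage
#' connected components.  The cluster representative is a `known`-source
#' member when one exists, otherwise the longest member (ties broken by
#' lexicographic name).
#'
#' @param lib Library data.frame (columns `name`, `seq`, optionally
#'   `source`).
#' @param params,masker See [pair_80_80()].
#' @return A data.frame with columns `name`, `cluster`, `representative`
#'   (logical); clusters are numbered in order of their first member as the
#'   input is sorted by name, making the output invariant to input order.
#' @export
cluster_80_80 <- function(lib, params = curation_params(),
                          masker = masker_params()) {
  lib <- lib[order(lib$name), , drop = FALSE]
  n <- nrow(lib)
  comp <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (pair_80_80(lib$seq[i], lib$seq[j], params, masker)) {
        ci <- comp[i]; cj <- comp[j]
        if (ci != cj) comp[comp == cj] <- ci
      }
    }
  }
  comp <- match(comp, unique(comp))
  rep_flag <- logical(n)
  src <- lib$source %||% rep("de_novo", n)
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    known <- idx[src[idx] == "known"]
    pick <- if (length(known)) {
      known[order(-nchar(lib$seq[known]), lib$name[known])][1L]
    } else idx[order(-nchar(lib$seq[idx]), lib$name[idx])][1L]
    rep_flag[pick] <- TRUE
  }
  data.frame(name = lib$name, cluster = comp, representative = rep_flag,
             stringsAsFactors = FALSE)
}

#' Merge a known and a de novo library into a non-redundant custom library
#'
#' Clusters the union of the two libraries with the 80-80 rule and keeps one
#' representative per cluster, preferring known entries so their
#' classification is preserved; de novo singletons keep their (possibly
#' `Unknown`) classification.
#'
#' @param known,de_novo Library data.frames ([read_library()] layout); either
#'   may be empty or `NULL`.
#' @param params,masker See [pair_80_80()].
#' @return The merged non-redundant library data.frame.
#' @export
merge_libraries <- function(known, de_novo, params = curation_params(),
                            masker = masker_params()) {
  blank <- data.frame(name = character(), te_class = character(),
                      superfamily = character(), family = character(),
                      seq = character(), source = character(),
                      stringsAsFactors = FALSE)
  if (is.null(known) || nrow(known) == 0L) known <- blank
  if (is.null(de_novo) || nrow(de_novo) == 0L) de_novo <- blank
  known$source <- rep("known", nrow(known))
  de_novo$source <- rep("de_novo", nrow(de_novo))
  all <- rbind(known[, names(blank)], de_novo[, names(blank)])
  if (nrow(all) == 0L) return(blank)
  if (anyDuplicated(all$name))
    stop("duplicate entry names across libraries: ",
         all$name[duplicated(all$name)][1L])
  cl <- cluster_80_80(all, params, masker)
  reps <- cl$name[cl$representative]
  out <- all[match(reps, all$name), , drop = FALSE]
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
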