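## Seed-and-extend homology masking of a genome against a TE library.
## Exact k-mer seeds locate candidate loci; each locus is refined by local
## alignment (Smith-Waterman, affine gaps) of the consensus against a
## genomic window, on both strands.  Per-hit divergence D is the raw
## substitution proportion over aligned (non-gap) columns — the quantity the
## Jukes-Cantor correction expects.  No CpG adjustment is applied.

#' Masker parameters
#'
#' @param seed_length Exact-match seed length in bp (>= 4).
#' @param seed_step Spacing between consecutive seeds taken from each library
#'   consensus (1 = every k-mer).
#' @param match,mismatch Match reward and mismatch penalty (penalty given as
#'   a negative number).
#' @param gap_open,gap_extend Affine gap penalties (negative numbers).
#' @param min_score Minimum alignment score for a reported hit.
#' @param min_hit_length Minimum genomic span of a reported hit, bp.
#' @param window_margin Extra genomic context (bp) around a seed cluster
#'   passed to the aligner.
#' @return A `masker_params` list.
#' @export
masker_params <- function(seed_length = 11L, seed_step = 1L,
                          match = 1, mismatch = -1,
                          gap_open = -2, gap_extend = -1,
                          min_score = 30, min_hit_length = 50L,
                          window_margin = 50L) {
  stopifnot(seed_length >= 4L, seed_step >= 1L, min_hit_length > 0L,
            match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(seed_length = as.integer(seed_length),
                 seed_step = as.integer(seed_step),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_score = min_score,
                 min_hit_length = as.integer(min_hit_length),
                 window_margin = as.integer(window_margin)),
            class = "masker_params")
}

## Local alignment wrapper around Biostrings' Smith-Waterman.  Returns the
## alignment statistics the pipeline needs: matches, mismatches, gap columns,
## score, and the aligned intervals on both sequences.  Amino-acid mode uses
## BLOSUM62 with standard protein gap penalties (open 10, extend 1); the
## nucleotide scoring scheme comes from `params`.
align_local <- function(pattern, subject, params = masker_params(),
                        type = "local", aa = FALSE) {
  submat <- if (aa) "BLOSUM62" else
    Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                             mismatch = params$mismatch,
                                             baseOnly = FALSE)
  pat <- if (aa) Biostrings::AAString(pattern) else
    Biostrings::DNAString(pattern)
  sub <- if (aa) Biostrings::AAString(subject) else
    Biostrings::DNAString(subject)
  aln <- Biostrings::pairwiseAlignment(
    pat, sub, type = type, substitutionMatrix = submat,
    gapOpening = if (aa) 10 else abs(params$gap_open),
    gapExtension = if (aa) 1 else abs(params$gap_extend))
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(pa, "")[[1L]]
  sc <- strsplit(sa, "")[[1L]]
  gap <- pc == "-" | sc == "-"
  list(score = Biostrings::score(aln),
       matches = sum(!gap & pc == sc),
       mismatches = sum(!gap & pc != sc),
       gap_columns = sum(gap),
       columns = length(pc),
       pattern_start = Biostrings::start(Biostrings::pattern(aln)),
       pattern_end = Biostrings::end(Biostrings::pattern(aln)),
       subject_start = Biostrings::start(Biostrings::subject(aln)),
       subject_end = Biostrings::end(Biostrings::subject(aln)))
}

## Seed positions: exact matches of the consensus k-mers in `genome_dna`
## (a DNAString).  Returns genomic start positions of candidate windows via
## diagonal projection.
seed_windows <- function(cons, genome_dna, params) {
  k <- params$seed_length
  L <- nchar(cons)
  if (L < k || length(genome_dna) < k) return(NULL)
  offs <- seq.int(1L, L - k + 1L, by = params$seed_step)
  kmers <- substring(cons, offs, offs + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  if (!any(keep)) return(NULL)
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  m <- Biostrings::matchPDict(dict, genome_dna)
  starts <- unlist(lapply(seq_along(m), function(i) {
    s <- Biostrings::startIndex(m)[[i]]
    if (is.null(s) || length(s) == 0L) return(integer(0))
    s - offs[keep][i] + 1L   # implied element start on the genome
  }))
  if (length(starts) == 0L) return(NULL)
  starts <- sort(unique(starts))
  ## merge implied starts within one element length into candidate loci
  brk <- c(TRUE, diff(starts) > L)
  grp <- cumsum(brk)
  t(vapply(split(starts, grp), function(s) {
    c(max(1L, min(s) - params$window_margin),
      min(length(genome_dna), max(s) + L - 1L + params$window_margin))
  }, numeric(2)))
}

#' Mask a genome against a TE library
#'
#' Annotates every region of the genome homologous to a library consensus.
#' Candidate loci are found by exact seed matches on both strands and refined
#' by local alignment; hits below `min_score` or shorter than
#' `min_hit_length` are dropped, and overlaps between surviving hits are
#' resolved greedily by descending score (ties broken by earlier start, then
#' lexicographic library name), trimming or dropping the lower-scoring hit.
#'
#' @param genome A one-record `DNAStringSet`/`DNAString` or character string.
#' @param library Library data.frame (columns `name`, `te_class`,
#'   `superfamily`, `family`, `seq`), as from [read_library()] or
#'   [simulate_genome()].
#' @param params A [masker_params()].
#' @return A hit data.frame (see [read_rm_out()] for columns); `divergence_D`
#'   is `100 * mismatches / (matches + mismatches)`, gap columns excluded.
#' @export
mask_genome <- function(genome, library, params = masker_params()) {
  if (is.null(library) || nrow(library) == 0L) stop("empty TE library")
  qname <- "genome"
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  if (methods::is(genome, "DNAStringSet")) {
    if (length(genome) != 1L)
      stop("mask_genome() masks one contig at a time; iterate over records")
    qname <- names(genome) %||% "genome"
    genome <- genome[[1L]]
  }
  L <- length(genome)
  if (L < params$seed_length) return(empty_hits())
  genome_rc <- Biostrings::reverseComplement(genome)
  gchar <- as.character(genome)
  gchar_rc <- as.character(genome_rc)

  rows <- list()
  for (i in seq_len(nrow(library))) {
    cons <- toupper(library$seq[i])
    for (strand in c("+", "-")) {
      gdna <- if (strand == "+") genome else genome_rc
      gstr <- if (strand == "+") gchar else gchar_rc
      win <- seed_windows(cons, gdna, params)
      if (is.null(win)) next
      for (w in seq_len(nrow(win))) {
        ws <- win[w, 1L]; we <- win[w, 2L]
        aln <- align_local(cons, substr(gstr, ws, we), params)
        if (aln$score < params$min_score) next
        hs <- ws + aln$subject_start - 1L
        he <- ws + aln$subject_end - 1L
        if (he - hs + 1L < params$min_hit_length) next
        if (strand == "-") { tmp <- hs; hs <- L - he + 1L; he <- L - tmp + 1L }
        nsub <- aln$matches + aln$mismatches
        rows[[length(rows) + 1L]] <- data.frame(
          score = aln$score,
          divergence_D = if (nsub > 0) 100 * aln$mismatches / nsub else 0,
          perc_del = 100 * max(0L, (aln$pattern_end - aln$pattern_start + 1L) -
                                 nsub) / max(1L, aln$columns),
          perc_ins = 100 * max(0L, (aln$subject_end - aln$subject_start + 1L) -
                                 nsub) / max(1L, aln$columns),
          query = qname, start = hs, end = he, query_left = L - he,
          strand = strand, library_name = library$name[i],
          te_class = library$te_class[i] %||% "Unknown",
          superfamily = library$superfamily[i] %||% NA_character_,
          rep_start = aln$pattern_start, rep_end = aln$pattern_end,
          rep_left = nchar(cons) - aln$pattern_end,
          id = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- resolve_overlaps(hits, params$min_hit_length)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  hits$id <- as.character(seq_len(nrow(hits)))
  if (!is.null(library$family))
    hits$family <- library$family[match(hits$library_name, library$name)]
  rownames(hits) <- NULL
  hits
}

## Greedy overlap resolution: by descending score (ties: earlier start, then
## lexicographic library name), each accepted hit claims its genomic bases;
## later hits are trimmed to their longest unclaimed run, or dropped if that
## run is shorter than min_len.
resolve_overlaps <- function(hits, min_len) {
  ord <- order(-hits$score, hits$start, hits$library_name)
  hits <- hits[ord, , drop = FALSE]
  claimed_s <- numeric(0); claimed_e <- numeric(0)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- hits$end[i]
    if (length(claimed_s)) {
      ov <- which(claimed_s <= e & claimed_e >= s)
      for (j in ov) {
        ## trim from whichever end the overlap touches
        if (claimed_s[j] <= s) s <- max(s, claimed_e[j] + 1)
        if (claimed_e[j] >= e) e <- min(e, claimed_s[j] - 1)
      }
    }
    if (e - s + 1 >= min_len && s <= e) {
      keep[i] <- TRUE
      hits$start[i] <- s; hits$end[i] <- e
      claimed_s <- c(claimed_s, s); claimed_e <- c(claimed_e, e)
    }
  }
  hits[keep, , drop = FALSE]
}

#' Masked base pairs and genome fraction
#'
#' Collapses overlapping hit intervals and reports the union length and its
#' ratio to the genome length.
#'
#' @param hits Hit data.frame.
#' @param genome_length Genome length in bp.
#' @return List with `bp` (integer union length) and `fraction`.
#' @export
masked_bp <- function(hits, genome_length) {
  if (nrow(hits) == 0L) return(list(bp = 0L, fraction = 0))
  if (any(hits$start < 1 | hits$end > genome_length))
    stop("hit outside genome bounds [1, ", genome_length, "]")
  ir <- IRanges::reduce(IRanges::IRanges(hits$start, hits$end))
  bp <- sum(IRanges::width(ir))
  list(bp = bp, fraction = bp / genome_length)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
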