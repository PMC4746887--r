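## Synthetic genomes with planted TE copies and ground-truth annotation.
## The simulator emulates the statistical structure that divergence-landscape
## analysis assumes: a neutral background plus interspersed copies of
## consensus elements, each copy mutated to a drawn divergence, optionally
## 5'-truncated, and placed on either strand.

#' Specify one planted element
#'
#' @param name Consensus name (library entry name).
#' @param seq Consensus nucleotide sequence (character).
#' @param te_class,superfamily,family Classification carried into the planted
#'   library and truth annotation.
#' @param copy_number Number of copies to plant (>= 0).
#' @param divergence Divergence model, a list:
#'   * `list(model = "point", value = p)` — every copy at substitution
#'     proportion `p`;
#'   * `list(model = "uniform", min = a, max = b)` — per-copy proportion
#'     drawn uniformly;
#'   * `list(model = "mixture", values = v, weights = w)` — mixture of point
#'     masses;
#'   * `list(model = "jc", rate = k)` — a Jukes-Cantor process at `k`
#'     substitutions per site: each site receives `Poisson(k)` substitution
#'     events, so multiple hits occur and the observed mismatch proportion is
#'     below `k` (this is the regime the Jukes-Cantor correction inverts).
#'   All values are proportions of sites, not percent.
#' @param truncation_prob Probability that a copy is 5'-truncated.
#' @param truncation_max_frac Maximum fraction of the element removed;
#'   realized truncated length fraction is drawn uniformly on
#'   `(0, truncation_max_frac]`.
#' @param strand_prob Probability that a copy is placed on the `-` strand.
#' @return An `insertion_spec` list.
#' @export
insertion_spec <- function(name, seq, te_class = "Unknown",
                           superfamily = NA, family = NA,
                           copy_number = 0L,
                           divergence = list(model = "point", value = 0),
                           truncation_prob = 0, truncation_max_frac = 0.5,
                           strand_prob = 0.5) {
  stopifnot(copy_number >= 0, nchar(seq) > 0,
            truncation_prob >= 0, truncation_prob <= 1,
            truncation_max_frac > 0, truncation_max_frac < 1,
            strand_prob >= 0, strand_prob <= 1)
  structure(list(name = name, seq = toupper(seq), te_class = te_class,
                 superfamily = superfamily, family = family,
                 copy_number = as.integer(copy_number),
                 divergence = divergence,
                 truncation_prob = truncation_prob,
                 truncation_max_frac = truncation_max_frac,
                 strand_prob = strand_prob),
            class = "insertion_spec")
}

#' Simulation configuration
#'
#' @param genome_length Background genome length in bp.
#' @param gc_content Background GC proportion.
#' @param insertion_specs List of [insertion_spec()] objects.
#' @param seed Integer seed; fixes the output byte-for-byte.
#' @param seq_id Name of the simulated contig.
#' @param max_place_tries Bounded number of rejection-sampling attempts per
#'   copy before the packing is declared infeasible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(genome_length, gc_content = 0.4,
                              insertion_specs = list(), seed = 1L,
                              seq_id = "chrSim", max_place_tries = 1000L) {
  stopifnot(genome_length > 0, gc_content > 0, gc_content < 1)
  planted <- sum(vapply(insertion_specs,
                        function(s) s$copy_number * nchar(s$seq), 0))
  if (planted > genome_length)
    stop("total planted bp (", planted, ") exceeds genome length (",
         genome_length, ")")
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, insertion_specs = insertion_specs,
                 seed = as.integer(seed), seq_id = seq_id,
                 max_place_tries = as.integer(max_place_tries)),
            class = "simulation_config")
}

draw_divergence <- function(model, n) {
  switch(model$model,
    point = rep(model$value, n),
    uniform = stats::runif(n, model$min, model$max),
    mixture = sample(model$values, n, replace = TRUE, prob = model$weights),
    jc = rep(model$rate, n),
    stop("unknown divergence model: ", model$model))
}

## Substitute exactly round(p * L) sites, chosen uniformly without
## replacement, each replaced by one of the 3 alternative bases.
mutate_point <- function(seq, p) {
  L <- nchar(seq)
  nsub <- round(p * L)
  if (nsub == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1L]]
  idx <- sample.int(L, nsub)
  for (i in idx) {
    alt <- bases[bases != chars[i]]
    chars[i] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

#' Evolve a sequence under a Jukes-Cantor substitution process
#'
#' Each site receives a `Poisson(rate)` number of substitution events; each
#' event replaces the current base by one of the three alternatives chosen
#' uniformly.  Multiple hits at a site can revert it, so the expected
#' observed mismatch proportion is `3/4 * (1 - exp(-4/3 * rate))`, the
#' quantity the Jukes-Cantor correction maps back to `rate`.
#'
#' @param seq Nucleotide string.
#' @param rate Expected substitutions per site.
#' @return Mutated sequence string.
#' @export
evolve_jc <- function(seq, rate) {
  stopifnot(rate >= 0)
  chars <- strsplit(toupper(seq), "")[[1L]]
  bases <- c("A", "C", "G", "T")
  nev <- stats::rpois(length(chars), rate)
  for (i in which(nev > 0L)) {
    for (k in seq_len(nev[i])) {
      alt <- bases[bases != chars[i]]
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste(chars, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Simulate a genome with planted TE copies
#'
#' Draws an i.i.d. background at the configured GC content, then plants each
#' copy: the consensus is mutated to its drawn divergence (point-mass and
#' uniform models substitute exactly `round(p * L)` sites chosen without
#' replacement; the `"jc"` model runs a Poisson substitution process),
#' optionally 5'-truncated, reverse-complemented for `-` placements, and
#' written over the background at a uniformly drawn non-overlapping position.
#' Placement uses bounded rejection sampling and fails loudly when the copies
#' cannot be packed.
#'
#' @param config A [simulation_config()].
#' @return A list with elements
#'   * `genome`: a one-record [Biostrings::DNAStringSet];
#'   * `truth`: the truth annotation data.frame (`query`, `start`, `end`,
#'     `strand`, `library_name`, `te_class`, `superfamily`, `family`,
#'     `realized_divergence` in percent, `truncated`);
#'   * `library`: the planted-library data.frame (see [read_library()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  L <- config$genome_length
  gc <- config$gc_content
  bg <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  occupied <- integer(0)  # starts of occupied unit intervals, as IRanges
  occ <- NULL
  truth <- list()
  genome <- bg
  for (spec in config$insertion_specs) {
    if (spec$copy_number == 0L) next
    divs <- draw_divergence(spec$divergence, spec$copy_number)
    for (ci in seq_len(spec$copy_number)) {
      copy <- if (identical(spec$divergence$model, "jc"))
        evolve_jc(spec$seq, divs[ci]) else mutate_point(spec$seq, divs[ci])
      truncated <- stats::runif(1) < spec$truncation_prob
      if (truncated) {
        frac <- stats::runif(1, 0, spec$truncation_max_frac)
        drop <- max(1L, floor(frac * nchar(copy)))
        copy <- substr(copy, drop + 1L, nchar(copy))
      }
      strand <- if (stats::runif(1) < spec$strand_prob) "-" else "+"
      placed <- if (strand == "-") revcomp(copy) else copy
      w <- nchar(placed)
      pos <- NA_integer_
      for (try in seq_len(config$max_place_tries)) {
        cand <- sample.int(L - w + 1L, 1L)
        if (is.null(occ) ||
            !any(cand <= occ[, 2L] & (cand + w - 1L) >= occ[, 1L])) {
          pos <- cand
          break
        }
      }
      if (is.na(pos))
        stop("could not place copy ", ci, " of '", spec$name,
             "' without overlap after ", config$max_place_tries, " tries")
      occ <- rbind(occ, c(pos, pos + w - 1L))
      substr_chars <- strsplit(placed, "")[[1L]]
      genome[pos:(pos + w - 1L)] <- substr_chars
      truth[[length(truth) + 1L]] <- data.frame(
        query = config$seq_id, start = pos, end = pos + w - 1L,
        strand = strand, library_name = spec$name,
        te_class = spec$te_class, superfamily = spec$superfamily,
        family = spec$family,
        realized_divergence = realized_divergence(placed, spec$seq,
                                                  strand = strand),
        truncated = truncated, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    query = character(), start = numeric(), end = numeric(),
    strand = character(), library_name = character(),
    te_class = character(), superfamily = character(), family = character(),
    realized_divergence = numeric(), truncated = logical(),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  g <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(g) <- config$seq_id
  lib <- do.call(rbind, lapply(config$insertion_specs, function(s)
    data.frame(name = s$name, te_class = s$te_class,
               superfamily = s$superfamily, family = s$family,
               seq = s$seq, source = "known", stringsAsFactors = FALSE)))
  list(genome = g, truth = truth, library = lib)
}

#' Observed divergence of a planted copy from its consensus
#'
#' Defined for the simulator's substitution-only (optionally 5'-truncated)
#' copies: the copy is compared position-by-position against the matching
#' 3'-anchored window of the consensus and the mismatch proportion reported
#' in percent.  `-`-strand copies are reverse-complemented first, so the
#' value is strand-symmetric.
#'
#' @param copy_seq The copy as it appears in the genome.
#' @param consensus The source consensus.
#' @param strand `"+"` or `"-"`.
#' @return Divergence in percent (`100 * mismatches / compared positions`).
#' @export
realized_divergence <- function(copy_seq, consensus, strand = "+") {
  if (strand == "-") copy_seq <- revcomp(copy_seq)
  lc <- nchar(copy_seq); lk <- nchar(consensus)
  if (lc > lk)
    stop("copy longer than consensus: indels are outside this model")
  ref <- substr(consensus, lk - lc + 1L, lk)  # 5' truncation only
  a <- strsplit(copy_seq, "")[[1L]]
  b <- strsplit(ref, "")[[1L]]
  100 * sum(a != b) / lc
}

#' Write simulator outputs to plain-text files
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             truth = file.path(dir, "truth.tsv"),
             library = file.path(dir, "library.fa"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"], width = 70L)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_library(sim$library, paths["library"])
  paths
}
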