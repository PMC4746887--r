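## Pipeline orchestration: one config drives simulate/ingest -> mask ->
## summarize (-> trees), with deterministic seeds and a checksum manifest.

#' Validate a run configuration
#'
#' A run config is a list (typically read from YAML via
#' [yaml::read_yaml()]) with one entry per species under `species`, each
#' holding either a `simulation` block ([simulation_config()] arguments plus
#' an `insertions` list) or a `genome` FASTA path with a `library` path
#' and/or a precomputed `rm_out` annotation; optional top-level `seed`,
#' `masker` and `landscape` blocks override defaults.  All validation errors
#' are collected and reported together.
#'
#' @param config Config list.
#' @return The config, invisibly, or an error listing every problem.
#' @export
validate_config <- function(config) {
  errs <- character()
  if (is.null(config$species) || length(config$species) == 0L)
    errs <- c(errs, "config has no 'species' entries")
  for (nm in names(config$species)) {
    sp <- config$species[[nm]]
    if (is.null(sp$simulation) && is.null(sp$genome))
      errs <- c(errs, sprintf("species '%s': need 'simulation' or 'genome'",
                              nm))
    if (!is.null(sp$genome) && !file.exists(sp$genome))
      errs <- c(errs, sprintf("species '%s': genome file missing: %s",
                              nm, sp$genome))
    if (!is.null(sp$library) && !file.exists(sp$library))
      errs <- c(errs, sprintf("species '%s': library file missing: %s",
                              nm, sp$library))
    if (!is.null(sp$rm_out) && !file.exists(sp$rm_out))
      errs <- c(errs, sprintf("species '%s': rm_out file missing: %s",
                              nm, sp$rm_out))
    if (is.null(sp$simulation) && is.null(sp$library) && is.null(sp$rm_out))
      errs <- c(errs, sprintf(
        "species '%s': a real genome needs 'library' or 'rm_out'", nm))
  }
  if (length(errs))
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(config)
}

spec_from_list <- function(x) {
  do.call(insertion_spec, x)
}

#' Run the full comparative pipeline
#'
#' For each configured species: obtain the genome (simulate with a
#' species-specific seed derived from the global seed, or read from disk),
#' obtain hits (mask against the library, or ingest a precomputed
#' RepeatMasker `.out`), then write per-species outputs: genome/truth (for
#' simulations), hits (`.out`), coverage table, and divergence landscape.
#' A manifest of MD5 checksums is written last; re-running an unchanged
#' config reproduces identical checksums.
#'
#' @param config Run config (see [validate_config()]); a path to a YAML file
#'   is also accepted.
#' @param outdir Output directory.
#' @return The manifest data.frame (`species`, `stage`, `path`, `md5`),
#'   invisibly written to `manifest.tsv`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  mp <- do.call(masker_params, config$masker %||% list())
  bin_width <- config$landscape$bin_width %||% 1.0
  group_by <- config$landscape$group_by %||% "te_class"
  manifest <- list()
  summaries <- list()
  note <- function(species, stage, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      species = species, stage = stage, path = basename(path),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  for (si in seq_along(config$species)) {
    nm <- names(config$species)[si]
    sp <- config$species[[si]]
    spdir <- file.path(outdir, nm)
    dir.create(spdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sp$simulation)) {
      specs <- lapply(sp$simulation$insertions, spec_from_list)
      sc <- simulation_config(
        genome_length = sp$simulation$genome_length,
        gc_content = sp$simulation$gc_content %||% 0.4,
        insertion_specs = specs,
        seed = (seed * 1009L + si) %% .Machine$integer.max,
        seq_id = sp$simulation$seq_id %||% paste0(nm, "_chr"))
      sim <- simulate_genome(sc)
      paths <- write_simulation(sim, spdir)
      for (st in names(paths)) note(nm, st, paths[st])
      genome <- sim$genome
      lib <- sim$library
    } else {
      genome <- read_fasta(sp$genome, alphabet = "dna")
      lib <- if (!is.null(sp$library)) read_library(sp$library) else NULL
    }
    glen <- sum(Biostrings::width(genome))
    hits <- if (!is.null(sp$rm_out)) read_rm_out(sp$rm_out)
            else mask_genome(genome, lib, mp)
    hits_path <- file.path(spdir, "hits.out")
    write_rm_out(hits, hits_path); note(nm, "hits", hits_path)
    cov <- coverage_table(hits, glen)
    cov_path <- file.path(spdir, "coverage.tsv")
    utils::write.table(cov, cov_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(nm, "coverage", cov_path)
    land <- landscape(hits, glen, bin_width = bin_width, group_by = group_by)
    land_path <- file.path(spdir, "landscape.tsv")
    utils::write.table(land, land_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(nm, "landscape", land_path)
    summaries[[nm]] <- list(
      species = nm, genome_length = glen, hits = hits,
      coverage = cov, landscape = land,
      te_fraction = 100 * masked_bp(hits, glen)$fraction)
  }
  manifest <- do.call(rbind, manifest)
  mpath <- file.path(outdir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(manifest, "summaries") <- summaries
  invisible(manifest)
}

#' Cross-species comparison report
#'
#' Merges per-species coverage tables side by side, regresses TE fraction on
#' genome size across species, and totals family diversity when family
#' assignments are present.
#'
#' @param summaries Named list of per-species summaries (the `summaries`
#'   attribute of [run_pipeline()]'s manifest), >= 2 species.
#' @return List with `coverage` (merged table, one `count/bp/pct` block per
#'   species), `points` (size/TE data.frame) and `regression`
#'   ([size_te_regression()] output, or `NULL` with a warning when the
#'   species points are degenerate).
#' @export
compare_species <- function(summaries) {
  if (length(summaries) < 2L)
    stop("cross-species comparison needs at least 2 species")
  for (s in summaries)
    if (is.null(s$genome_length)) stop("species summary missing genome_length")
  points <- data.frame(
    species = vapply(summaries, `[[`, "", "species"),
    genome_size = vapply(summaries, function(s) s$genome_length / 1e6, 0),
    te_fraction = vapply(summaries, `[[`, 0, "te_fraction"),
    stringsAsFactors = FALSE)
  reg <- tryCatch(size_te_regression(points), error = function(e) {
    warning("size~TE regression not computed: ", conditionMessage(e))
    NULL
  })
  keys <- unique(do.call(rbind, lapply(summaries, function(s)
    s$coverage[, c("level", "parent", "group")])))
  keys <- keys[order(keys$level, keys$parent, keys$group), , drop = FALSE]
  merged <- keys
  for (nm in names(summaries)) {
    cov <- summaries[[nm]]$coverage
    idx <- match(paste(keys$level, keys$parent, keys$group),
                 paste(cov$level, cov$parent, cov$group))
    for (col in c("count", "bp", "pct"))
      merged[[paste(nm, col, sep = ".")]] <- cov[[col]][idx]
  }
  rownames(merged) <- NULL
  list(coverage = merged, points = points, regression = reg)
}
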