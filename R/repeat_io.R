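## File readers/writers: FASTA, library headers, RepeatMasker .out tables.
## Coordinates are 1-based inclusive throughout (RepeatMasker convention).

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file into a [Biostrings::XStringSet].  Record
#' ids are the first whitespace-delimited token of each header; the remainder
#' of the header is kept as a `description` metadata column.  Sequences are
#' uppercased on read: masking state is never inferred from case.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"auto"`, `"dna"`, `"aa"`.  With `"auto"` the
#'   alphabet is inferred: records whose letters all belong to the IUPAC
#'   nucleotide code are returned as a [Biostrings::DNAStringSet], anything
#'   else as an [Biostrings::AAStringSet].
#' @return A `DNAStringSet` or `AAStringSet` named by record id, with a
#'   `description` column in its `mcols`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a first", "ACGT"), tf)
#' x <- read_fasta(tf)
#' names(x)          # "a"
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("malformed FASTA header (empty id) at record ",
                           which(ids == "")[1L], " in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id in ", path, ": ",
         ids[duplicated(ids)][1L])
  if (any(Biostrings::width(raw) == 0L))
    stop("empty sequence for record '", ids[Biostrings::width(raw) == 0L][1L],
         "' in ", path)
  seqs <- toupper(as.character(raw))
  is_dna <- !grepl(sprintf("[^%s-]", .IUPAC_DNA), seqs)
  out <- switch(alphabet,
    dna = {
      if (!all(is_dna))
        stop("non-IUPAC nucleotide characters in record '",
             ids[!is_dna][1L], "'")
      Biostrings::DNAStringSet(seqs)
    },
    aa = Biostrings::AAStringSet(seqs),
    auto = if (all(is_dna)) Biostrings::DNAStringSet(seqs)
           else Biostrings::AAStringSet(seqs)
  )
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()]: headers are `id description` (description
#' omitted when empty), one sequence per line.
#'
#' @param x An `XStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all records must be named")
  desc <- S4Vectors::mcols(x)$description
  hdr <- names(x)
  if (!is.null(desc)) {
    keep <- !is.na(desc) & desc != ""
    hdr[keep] <- paste(hdr[keep], desc[keep])
  }
  lines <- character(2L * length(x))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- as.character(x)
  writeLines(lines, path)
  invisible(path)
}

.IUPAC_DNA <- "ACGTRYSWKMBDHVN"
.TE_CLASSES <- c("DNA", "LINE", "SINE", "LTR", "Unknown")

#' Parse TE library headers
#'
#' Library entries are named with the RepBase/RepeatMasker convention
#' `name#Class/Superfamily` (e.g. `"L2-1#LINE/L2"`).  Headers without a `#`
#' fall back to class `"Unknown"`; a classification token that is not one of
#' `DNA`, `LINE`, `SINE`, `LTR` is also mapped to `"Unknown"` while the
#' superfamily string is retained.
#'
#' @param header Character vector of headers.
#' @return A data.frame with columns `name`, `te_class`, `superfamily`
#'   (`NA` when absent).
#' @examples
#' parse_library_header(c("Tc1-7#DNA/TcMar-Tc1", "cons42"))
#' @export
parse_library_header <- function(header) {
  name <- sub("#.*$", "", header)
  cls <- rep("Unknown", length(header))
  supfam <- rep(NA_character_, length(header))
  has <- grepl("#", header, fixed = TRUE)
  tok <- sub("^[^#]*#", "", header[has])
  cls_tok <- sub("/.*$", "", tok)
  sf <- ifelse(grepl("/", tok, fixed = TRUE), sub("^[^/]*/", "", tok),
               NA_character_)
  cls[has] <- ifelse(cls_tok %in% .TE_CLASSES, cls_tok, "Unknown")
  supfam[has] <- sf
  data.frame(name = name, te_class = cls, superfamily = supfam,
             stringsAsFactors = FALSE)
}

#' Build a library header from its parts
#' @param name,te_class,superfamily Vectors recycled to common length.
#' @return Character vector of `name#Class/Superfamily` headers; entries of
#'   class `"Unknown"` are serialized as the bare name.
#' @export
make_library_header <- function(name, te_class, superfamily = NA) {
  n <- max(length(name), length(te_class), length(superfamily))
  name <- rep_len(name, n); te_class <- rep_len(te_class, n)
  superfamily <- rep_len(superfamily, n)
  out <- name
  known <- te_class != "Unknown"
  out[known] <- ifelse(is.na(superfamily[known]),
                       paste0(name[known], "#", te_class[known]),
                       paste0(name[known], "#", te_class[known], "/",
                              superfamily[known]))
  out
}

#' Read a TE library FASTA
#'
#' Reads a library whose headers follow the `name#Class/Superfamily`
#' convention into a library data.frame.  Family assignments, which the
#' header convention cannot carry, are supplied through an optional sidecar
#' TSV with columns `name` and `family`.
#'
#' @param path Library FASTA path.
#' @param sidecar Optional path to the `name<TAB>family` sidecar TSV.
#' @param source Provenance flag stored per entry, `"known"` or `"de_novo"`.
#' @return A data.frame with columns `name`, `te_class`, `superfamily`,
#'   `family`, `seq`, `source`.
#' @export
read_library <- function(path, sidecar = NULL,
                         source = c("known", "de_novo")) {
  source <- match.arg(source)
  x <- read_fasta(path, alphabet = "dna")
  info <- parse_library_header(names(x))
  if (anyDuplicated(info$name))
    stop("duplicate library entry name: ", info$name[duplicated(info$name)][1L])
  fam <- rep(NA_character_, nrow(info))
  if (!is.null(sidecar)) {
    sc <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    fam <- sc$family[match(info$name, sc$name)]
  }
  data.frame(name = info$name, te_class = info$te_class,
             superfamily = info$superfamily, family = fam,
             seq = unname(as.character(x)), source = source,
             stringsAsFactors = FALSE)
}

#' Write a TE library FASTA (and optional family sidecar)
#' @param lib Library data.frame as returned by [read_library()].
#' @param path Output FASTA path.
#' @param sidecar Optional output path for the `name`/`family` TSV.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, sidecar = NULL) {
  hdr <- make_library_header(lib$name, lib$te_class, lib$superfamily)
  x <- Biostrings::DNAStringSet(lib$seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 70L)
  if (!is.null(sidecar)) {
    sc <- data.frame(name = lib$name,
                     family = ifelse(is.na(lib$family), "", lib$family))
    utils::write.table(sc, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.RM_OUT_HEADER <- c(
  "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
  "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)     ID",
  "")

#' Read RepeatMasker-format annotation
#'
#' Parses the 15-column RepeatMasker `.out` dialect (3 header lines, then
#' whitespace-delimited rows).  Coordinates stay 1-based inclusive; the `C`
#' strand code is mapped to `"-"`; the `%div` column is stored as
#' `divergence_D`.
#'
#' @param path Path to a `.out` file.
#' @return A hit data.frame with columns `score`, `divergence_D`, `perc_del`,
#'   `perc_ins`, `query`, `start`, `end`, `query_left`, `strand`,
#'   `library_name`, `te_class`, `superfamily`, `rep_start`, `rep_end`,
#'   `rep_left`, `id`.
#' @export
read_rm_out <- function(path) {
  if (!file.exists(path)) stop(".out file not found: ", path)
  lines <- readLines(path)
  if (length(lines) > 0 && grepl("^\\s*(SW|score|bit)", lines[1L]))
    lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L))
    stop("malformed .out line ", which(nf < 14L)[1L] + 3L,
         ": expected >= 14 columns")
  get <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(gsub("[()]", "", get(i))))
    if (anyNA(v))
      stop("non-numeric ", what, " in .out line ", which(is.na(v))[1L] + 3L)
    v
  }
  strand <- get(9L)
  if (!all(strand %in% c("+", "C", "-")))
    stop("bad strand code in .out line ",
         which(!strand %in% c("+", "C", "-"))[1L] + 3L)
  cf <- parse_library_header(paste0("x#", get(11L)))
  id <- if (all(nf >= 15L)) get(15L) else as.character(seq_along(fields))
  out <- data.frame(
    score = num(1L, "score"),
    divergence_D = num(2L, "divergence"),
    perc_del = num(3L, "deletion percent"),
    perc_ins = num(4L, "insertion percent"),
    query = get(5L),
    start = num(6L, "begin coordinate"),
    end = num(7L, "end coordinate"),
    query_left = num(8L, "left coordinate"),
    strand = ifelse(strand == "+", "+", "-"),
    library_name = get(10L),
    te_class = cf$te_class,
    superfamily = cf$superfamily,
    rep_start = num(12L, "repeat begin"),
    rep_end = num(13L, "repeat end"),
    rep_left = num(14L, "repeat left"),
    id = id,
    stringsAsFactors = FALSE)
  if (any(out$start > out$end))
    stop("start > end in .out line ", which(out$start > out$end)[1L] + 3L)
  if (any(out$divergence_D < 0))
    stop("negative divergence in .out line ",
         which(out$divergence_D < 0)[1L] + 3L)
  out
}

#' @rdname read_rm_out
#' @param hits Hit data.frame (columns of [read_rm_out()]'s output; missing
#'   bookkeeping columns are filled with zeros).
#' @return `write_rm_out()` returns `path` invisibly.
#' @export
write_rm_out <- function(hits, path) {
  hits <- normalize_hits(hits)
  body <- sprintf("%5d %5.1f %4.1f %4.1f %s %8d %8d (%d) %s %s %s %6d %6d (%d) %s",
    as.integer(round(hits$score)), hits$divergence_D, hits$perc_del,
    hits$perc_ins, hits$query, as.integer(hits$start), as.integer(hits$end),
    as.integer(hits$query_left), ifelse(hits$strand == "-", "C", "+"),
    hits$library_name,
    sub("^[^#]*#", "", make_library_header("x", hits$te_class,
                                           hits$superfamily)),
    as.integer(hits$rep_start), as.integer(hits$rep_end),
    as.integer(hits$rep_left), hits$id)
  writeLines(c(.RM_OUT_HEADER, body), path)
  invisible(path)
}

#' An empty hit table with the canonical column set
#' @return Zero-row hit data.frame.
#' @export
empty_hits <- function() {
  data.frame(score = numeric(), divergence_D = numeric(),
             perc_del = numeric(), perc_ins = numeric(),
             query = character(), start = numeric(), end = numeric(),
             query_left = numeric(), strand = character(),
             library_name = character(), te_class = character(),
             superfamily = character(), rep_start = numeric(),
             rep_end = numeric(), rep_left = numeric(), id = character(),
             stringsAsFactors = FALSE)
}

## Fill bookkeeping columns absent from internally produced hit tables so
## that the .out writer always has its 15 columns.
normalize_hits <- function(hits) {
  defaults <- list(score = 0, divergence_D = 0, perc_del = 0, perc_ins = 0,
                   query = "seq", start = NA_real_, end = NA_real_,
                   query_left = 0, strand = "+", library_name = "unknown",
                   te_class = "Unknown", superfamily = NA_character_,
                   rep_start = 0, rep_end = 0, rep_left = 0,
                   id = NA_character_)
  for (nm in names(defaults)) {
    if (is.null(hits[[nm]])) hits[[nm]] <- rep(defaults[[nm]], nrow(hits))
  }
  if (anyNA(hits$id)) hits$id <- as.character(seq_len(nrow(hits)))
  hits
}
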