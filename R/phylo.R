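## Distance phylogenetics over conserved protein domains: p-distances,
## Saitou-Nei neighbor-joining, and nonparametric bootstrap support.
## Trees are `ape::phylo` objects; Newick serialization carries support
## values as internal node labels.

#' Alignment to character matrix
#' @noRd
aln_matrix <- function(alignment) {
  if (methods::is(alignment, "XStringSet")) {
    m <- do.call(rbind, strsplit(as.character(alignment), ""))
    rownames(m) <- names(alignment)
    return(m)
  }
  if (is.matrix(alignment)) return(alignment)
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment) %||% paste0("t", seq_len(nrow(m)))
  m
}

#' Uncorrected p-distance matrix
#'
#' `d(i, j)` is the proportion of differing residues over comparable
#' columns.  Under `"pairwise_deletion"` a column is excluded for a pair
#' when either row has a gap there; under `"complete_deletion"` any column
#' containing a gap in any row is excluded for all pairs.
#'
#' @param alignment An aligned `AAStringSet`, character vector, or character
#'   matrix (equal-length rows, gaps `-`).
#' @param gap_handling `"pairwise_deletion"` or `"complete_deletion"`.
#' @return Symmetric distance matrix with taxa as dimnames.
#' @export
p_distance <- function(alignment,
                       gap_handling = c("pairwise_deletion",
                                        "complete_deletion")) {
  gap_handling <- match.arg(gap_handling)
  m <- aln_matrix(alignment)
  if (nrow(m) < 2L) stop("alignment needs at least 2 rows")
  if (gap_handling == "complete_deletion") {
    keep <- colSums(m == "-") == 0L
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns between '", rownames(m)[i], "' and '",
           rownames(m)[j], "'")
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining: iteratively joins the pair
#' minimizing the Q criterion, with the usual branch-length formulas.
#' Negative branch lengths are clamped to zero and the deficit transferred
#' to the sister branch, preserving the path length through the new node.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n0 <- nrow(dm)
  if (n0 < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(dm) %||% paste0("t", seq_len(n0))
  d <- dm
  nwk <- labs           # growing Newick fragment per active node
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1L, ]  # deterministic first min
    i <- min(ij); j <- max(ij)
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], li, nwk[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    d <- d2
  }
  ## terminal trichotomy
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[1], la, nwk[2], lb, nwk[3], lc)
  ape::read.tree(text = txt)
}

#' Canonical bipartitions of an unrooted tree
#'
#' Encodes every internal split as the sorted tip-label set of the side not
#' containing the alphabetically first taxon, making split identity
#' independent of rooting and taxon input order.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of split signatures (one per internal edge).
#' @export
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  parts <- ape::prop.part(tree)
  sigs <- vapply(parts, function(p) {
    side <- sort(tree$tip.label[p])
    if (anchor %in% side) side <- setdiff(tips, side)
    paste(side, collapse = "|")
  }, "")
  ## drop trivial splits (whole tree / single tips)
  sigs <- sigs[vapply(strsplit(sigs, "|", fixed = TRUE), length, 0L) >= 2L]
  sigs <- sigs[vapply(strsplit(sigs, "|", fixed = TRUE), length, 0L) <=
                 length(tips) - 2L]
  unique(sigs)
}

#' Phylogeny parameters
#' @param bootstrap_replicates Number of bootstrap replicates (default 1000,
#'   the conventional production setting).
#' @param seed RNG seed for column resampling.
#' @param gap_handling Passed to [p_distance()].
#' @return A `phylo_params` list.
#' @export
phylo_params <- function(bootstrap_replicates = 1000L, seed = 1L,
                         gap_handling = "pairwise_deletion") {
  stopifnot(bootstrap_replicates >= 1L)
  structure(list(bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed), gap_handling = gap_handling),
            class = "phylo_params")
}

#' Bootstrapped neighbor-joining tree
#'
#' Builds the NJ tree on the full alignment, then resamples alignment
#' columns with replacement `bootstrap_replicates` times, rebuilds the tree
#' on each replicate, and reports per-split support (percent of replicates
#' containing the split) as internal node labels.
#'
#' @param alignment Aligned sequences (see [p_distance()]).
#' @param params A [phylo_params()].
#' @return List with `tree` (`ape::phylo`, `node.label` carrying support
#'   percentages, `""` for the root node) and `support` (named numeric
#'   vector keyed by split signature).
#' @export
bootstrap_support <- function(alignment, params = phylo_params()) {
  m <- aln_matrix(alignment)
  ## canonical taxon order so results are invariant to input order
  m <- m[order(rownames(m)), , drop = FALSE]
  full <- nj_tree(p_distance(m, params$gap_handling))
  sigs <- tree_splits(full)
  counts <- stats::setNames(numeric(length(sigs)), sigs)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(params$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  B <- params$bootstrap_replicates
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- try(nj_tree(p_distance(m[, cols, drop = FALSE],
                                       params$gap_handling)), silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rs <- tree_splits(rep_tree)
    hit <- sigs %in% rs
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / B
  ## attach supports as node labels of the full tree
  tree <- full
  nnode <- tree$Nnode
  tree$node.label <- rep("", nnode)
  parts <- ape::prop.part(tree)
  tips <- sort(tree$tip.label)
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]])
    if (tips[1L] %in% side) side <- setdiff(tips, side)
    sig <- paste(side, collapse = "|")
    if (sig %in% names(support))
      tree$node.label[k] <- format(round(support[[sig]], 1))
  }
  list(tree = tree, support = support)
}
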