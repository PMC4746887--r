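## Shared fixture generators and independent oracles.  Everything is built
## in code at test time; no binary fixtures.

DNA <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")
rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

## substitute exactly round(p * L) positions, never to the same base
mutate_dna <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), round(p * length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(DNA, ch[i]), 1L)
  paste(ch, collapse = "")
}

mutate_aa <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), round(p * length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

## deterministic reverse translation (first codon per amino acid)
backtranslate <- function(prot) {
  tab <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(prot, "")[[1]],
               function(a) names(tab)[tab == a][1L], ""), collapse = "")
}

rc <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## Independent connected-components oracle: depth-first search over an
## explicit boolean adjacency matrix.
components_oracle <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

## partition equality up to label renaming
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b))) ||
    all(outer(a, a, "==") == outer(b, b, "=="))
}

## random additive (tree) distance matrix with its generating ape tree
rand_additive <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, dm = stats::cophenetic(tr))
}

## interval-overlap helpers built on IRanges (oracle side uses raw sets)
union_bp <- function(starts, ends)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))

overlap_bp <- function(s1, e1, s2, e2) {
  a <- IRanges::reduce(IRanges::IRanges(s1, e1))
  b <- IRanges::reduce(IRanges::IRanges(s2, e2))
  sum(IRanges::width(IRanges::intersect(a, b)))
}

## a small planted-TE simulation shared by several tests
small_sim <- function(seed = 33, copies = 30, glen = 150000,
                      divergence = list(model = "point", value = 0.10)) {
  withr::with_seed(seed, {
    cons <- rand_dna(400)
    spec <- insertion_spec("TE1", cons, te_class = "DNA",
                           superfamily = "hAT", copy_number = copies,
                           divergence = divergence)
    simulate_genome(simulation_config(glen, insertion_specs = list(spec),
                                      seed = seed))
  })
}
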