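test_that("collect_copies returns flanked, clipped, oriented copies", {
  withr::with_seed(30, {
    cons <- rand_dna(400)
    spec <- insertion_spec("el", cons, copy_number = 20,
                           divergence = list(model = "point", value = 0.08))
    sim <- simulate_genome(simulation_config(200000,
                                             insertion_specs = list(spec),
                                             seed = 31))
    cps <- collect_copies(sim$genome, cons)
    expect_equal(length(cps), 20L)
    ## each copy corresponds to one truth interval
    md <- S4Vectors::mcols(cps)
    hit_bp <- overlap_bp(md$start, md$end, sim$truth$start, sim$truth$end)
    expect_gte(hit_bp / union_bp(sim$truth$start, sim$truth$end), 0.98)
    ## flanks: width = hit + up to 2 * 500, clipped at contig ends
    expect_true(all(Biostrings::width(cps) <=
                      md$end - md$start + 1 + 1000))
  })
})

test_that("collect_copies caps at top_hits_max and needs two copies", {
  withr::with_seed(32, {
    cons <- rand_dna(300)
    spec <- insertion_spec("el", cons, copy_number = 50,
                           divergence = list(model = "point", value = 0.05))
    sim <- simulate_genome(simulation_config(300000,
                                             insertion_specs = list(spec),
                                             seed = 35))
    cps <- collect_copies(sim$genome, cons,
                          curation_params(top_hits_max = 12))
    expect_equal(length(cps), 12L)
    expect_error(collect_copies(rand_dna(5000), cons),
                 "insufficient copies")
  })
})

test_that("protein queries find copies through six-frame translation", {
  withr::with_seed(36, {
    prot <- rand_aa(150)
    cons <- backtranslate(prot)
    spec <- insertion_spec("el", cons, copy_number = 6,
                           divergence = list(model = "point", value = 0.02))
    sim <- simulate_genome(simulation_config(80000,
                                             insertion_specs = list(spec),
                                             seed = 37))
    cps <- collect_copies(sim$genome, prot, query_type = "protein")
    expect_equal(length(cps), 6L)
    md <- S4Vectors::mcols(cps)
    cov <- overlap_bp(md$start, md$end, sim$truth$start, sim$truth$end)
    expect_gte(cov / union_bp(sim$truth$start, sim$truth$end), 0.9)
  })
})

test_that("build_consensus takes column majorities with A>C>G>T ties", {
  expect_identical(as.character(build_consensus(rep("ACGT", 3)))[[1]],
                   "ACGT")
  expect_identical(as.character(build_consensus(c("AAAA", "AAAA", "CCCC")))[[1]],
                   "AAAA")
  ## two-row tie falls to precedence
  expect_identical(as.character(build_consensus(c("A", "C")))[[1]], "A")
  expect_identical(as.character(build_consensus(c("G", "T")))[[1]], "G")
  ## gap-majority columns are dropped (columns 1 and 2 are 2/3 gaps)
  expect_identical(as.character(build_consensus(c("A-T", "--T", "-CT")))[[1]],
                   "T")
  ## a column with a non-gap majority is kept
  expect_identical(as.character(build_consensus(c("ACT", "-CT", "ACT")))[[1]],
                   "ACT")
  expect_error(build_consensus(character()), "empty")
  expect_error(build_consensus(c("AC", "A")), "equal length")
})

test_that("consensus rebuilt from divergent copies recovers the source", {
  withr::with_seed(38, {
    cons <- rand_dna(500)
    copies <- vapply(1:50, function(i) mutate_dna(cons, 0.10), "")
    reb <- as.character(build_consensus(copies))[[1]]
    ident <- mean(strsplit(reb, "")[[1]] == strsplit(cons, "")[[1]])
    expect_gte(ident, 0.99)
  })
})

test_that("the 80-80 pair rule follows both thresholds", {
  withr::with_seed(41, {
    a <- rand_dna(1000)
    expect_true(pair_80_80(a, a))
    ## identity ~75% < 80 -> fails on identity (known by construction:
    ## substitution-only pair, no indels)
    expect_false(pair_80_80(a, mutate_dna(a, 0.25)))
    expect_true(pair_80_80(a, mutate_dna(a, 0.10)))
    ## exact 500 bp fragment: covers 100% of the shorter sequence
    expect_true(pair_80_80(a, substr(a, 301, 800)))
    ## with the longer-sequence denominator the same fragment fails coverage
    expect_false(pair_80_80(a, substr(a, 301, 800),
                            curation_params(coverage_denominator = "longer")))
    expect_false(pair_80_80(a, rand_dna(1000)))
    expect_true(pair_80_80(a, rc(a)))  # strand-agnostic
    expect_error(pair_80_80(a, ""), "empty")
  })
})

test_that("80-80 clustering matches the brute-force components oracle", {
  withr::with_seed(44, {
    for (trial in 1:6) {
      n_fam <- sample(2:4, 1)
      lib <- do.call(rbind, lapply(seq_len(n_fam), function(f) {
        anc <- rand_dna(sample(200:400, 1))
        k <- sample(2:5, 1)
        data.frame(name = paste0("f", f, "_", seq_len(k)),
                   seq = vapply(seq_len(k), function(i)
                     mutate_dna(anc, stats::runif(1, 0, 0.12)), ""),
                   source = "de_novo", stringsAsFactors = FALSE)
      }))
      got <- cluster_80_80(lib)
      ## oracle: exhaustive pair matrix + DFS components
      libo <- lib[order(lib$name), ]
      n <- nrow(libo)
      adj <- matrix(FALSE, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
        adj[i, j] <- pair_80_80(libo$seq[i], libo$seq[j])
      expect_true(all(adj == t(adj)))
      oracle <- components_oracle(adj | t(adj))
      expect_true(same_partition(got$cluster[match(libo$name, got$name)],
                                 oracle))
    }
  })
})

test_that("clustering is invariant to input order", {
  withr::with_seed(46, {
    anc <- rand_dna(300)
    lib <- data.frame(name = paste0("e", 1:8),
                      seq = c(vapply(1:4, function(i) mutate_dna(anc, 0.08), ""),
                              vapply(1:4, function(i) rand_dna(300), "")),
                      source = "de_novo", stringsAsFactors = FALSE)
    a <- cluster_80_80(lib)
    b <- cluster_80_80(lib[sample(nrow(lib)), ])
    expect_identical(a[order(a$name), ], b[order(b$name), ])
  })
})

test_that("merge_libraries removes redundancy and keeps known entries", {
  withr::with_seed(48, {
    anc <- rand_dna(500)
    known <- data.frame(name = "K1", te_class = "DNA", superfamily = "hAT",
                        family = NA, seq = anc, source = "known",
                        stringsAsFactors = FALSE)
    ## 5 de novo entries all 80-80-linked to the known entry
    dn <- data.frame(name = paste0("d", 1:5), te_class = "Unknown",
                     superfamily = NA, family = NA,
                     seq = vapply(1:5, function(i) mutate_dna(anc, 0.05), ""),
                     source = "de_novo", stringsAsFactors = FALSE)
    m <- merge_libraries(known, dn)
    expect_identical(m$name, "K1")
    expect_identical(m$te_class, "DNA")
    ## identity cases
    expect_identical(merge_libraries(known, NULL)$name, "K1")
    distinct <- data.frame(name = paste0("x", 1:3), te_class = "Unknown",
                           superfamily = NA, family = NA,
                           seq = vapply(1:3, function(i) rand_dna(400), ""),
                           source = "de_novo", stringsAsFactors = FALSE)
    expect_equal(nrow(merge_libraries(NULL, distinct)), 3L)
    ## output self-check: no surviving 80-80 pair
    out <- merge_libraries(known, rbind(dn, distinct))
    n <- nrow(out)
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
      expect_false(pair_80_80(out$seq[i], out$seq[j]))
  })
})
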