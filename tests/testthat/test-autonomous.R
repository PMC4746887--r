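## Helper: build a LINE-like element with a given ORF1/ORF2 structure.
## make_orf(n) returns a protein of n aa starting with M; the element is
## ORF1 + stop + spacer + ORF2 + stop.
make_orf_prot <- function(n, core = NULL) {
  body <- if (is.null(core)) rand_aa(n - 1L) else {
    stopifnot(nchar(core) <= n - 1L)
    paste0(rand_aa(n - 1L - nchar(core)), core)
  }
  paste0("M", body)
}

make_line_element <- function(orf1_aa, orf2_aa, rt_core) {
  orf1 <- make_orf_prot(orf1_aa)
  orf2 <- make_orf_prot(orf2_aa, core = rt_core)
  paste0("GG", backtranslate(orf1), "TAA", "CCT",
         backtranslate(orf2), "TAA", "GG")
}

test_that("find_orfs reports ATG-to-stop ORFs with exact coordinates", {
  got <- find_orfs("ATGAAATAG", min_aa = 1)
  expect_equal(nrow(got), 1L)
  expect_identical(got$protein, "MK")
  expect_equal(got$frame, 1L)
  expect_equal(got$start, 1L)
  expect_equal(got$end, 9L)
  expect_equal(got$length_aa, (got$end - got$start + 1 - 3) / 3)

  ## reverse-complement symmetry: mirrored coordinates, negative frame
  seq <- paste0("CC", "ATGGCTGCTTTTAAATAA", "GG")
  f <- find_orfs(seq, min_aa = 3)
  r <- find_orfs(rc(seq), min_aa = 3)
  expect_equal(nrow(f), 1L)
  expect_equal(nrow(r), 1L)
  expect_identical(r$protein, f$protein)
  expect_true(r$frame < 0)
  expect_equal(r$start, nchar(seq) - f$end + 1)
  expect_equal(r$end, nchar(seq) - f$start + 1)
})

test_that("random sequence carries no long ORFs", {
  withr::with_seed(52, {
    expect_equal(nrow(find_orfs(rand_dna(5000), min_aa = 700)), 0L)
  })
})

test_that("RT detection needs both coverage and identity", {
  withr::with_seed(53, {
    ref <- rand_aa(200)
    prof <- rt_profile(c(RT = ref))
    hit <- detect_rt(paste0(rand_aa(100), ref, rand_aa(100)), prof)
    expect_true(hit$detected)
    expect_equal(hit$coverage, 1.0)
    expect_equal(hit$identity, 1.0)
    ## half the reference: coverage below 0.8
    half <- detect_rt(paste0(rand_aa(50), substr(ref, 1, 100), rand_aa(50)),
                      prof)
    expect_false(half$detected)
    expect_lt(half$coverage, 0.8)
    ## shuffled-reference null: never called intact over 20 shuffles
    shuffled <- vapply(1:20, function(i) {
      sh <- paste(sample(strsplit(ref, "")[[1]]), collapse = "")
      detect_rt(paste0(rand_aa(80), sh, rand_aa(80)), prof)$detected
    }, TRUE)
    expect_false(any(shuffled))
    expect_error(detect_rt("MKL", rt_profile(character())), "empty")
  })
})

test_that("LINE autonomy requires ORF2 > 700 aa plus an intact RT domain", {
  withr::with_seed(54, {
    rt_core <- rand_aa(180)
    prof <- rt_profile(c(RT = rt_core))
    crit <- autonomy_criteria("LINE")
    yes <- is_autonomous(make_line_element(300, 900, rt_core), crit, prof)
    expect_true(yes$autonomous)
    expect_equal(yes$orf2_aa, 900L)
    ## the >700 aa threshold is strict: 699 fails, 701 passes
    expect_false(is_autonomous(make_line_element(300, 699, rt_core),
                               crit, prof)$autonomous)
    expect_true(is_autonomous(make_line_element(300, 701, rt_core),
                              crit, prof)$autonomous)
    ## missing second ORF fails the LINE structure requirement
    lone <- paste0("GG", backtranslate(make_orf_prot(900, rt_core)),
                   "TAA", "GG")
    expect_false(is_autonomous(lone, crit, prof)$autonomous)
    ## RT deleted fails when require_rt
    expect_false(is_autonomous(make_line_element(300, 900, rand_aa(180)),
                               crit, prof)$autonomous)
  })
})

test_that("LTR autonomy requires an RT-bearing ORF > 500 aa", {
  withr::with_seed(55, {
    rt_core <- rand_aa(150)
    prof <- rt_profile(c(RT = rt_core))
    crit <- autonomy_criteria("LTR")
    el <- paste0("AA", backtranslate(make_orf_prot(600, rt_core)), "TAA")
    expect_true(is_autonomous(el, crit, prof)$autonomous)
    short <- paste0("AA", backtranslate(make_orf_prot(450, rt_core)), "TAA")
    expect_false(is_autonomous(short, crit, prof)$autonomous)
    no_rt <- paste0("AA", backtranslate(make_orf_prot(600)), "TAA")
    expect_false(is_autonomous(no_rt, crit, prof)$autonomous)
  })
})

test_that("autonomy is monotone under ORF2 extension", {
  ## growing ORF2 never flips an autonomous call back to FALSE
  withr::with_seed(56, {
    rt_core <- rand_aa(150)
    prof <- rt_profile(c(RT = rt_core))
    crit <- autonomy_criteria("LINE")
    lengths <- sort(sample(500:1000, 8))
    calls <- vapply(lengths, function(n)
      is_autonomous(make_line_element(200, n, rt_core), crit,
                    prof)$autonomous, TRUE)
    expect_true(all(diff(as.integer(calls)) >= 0))
    expect_identical(calls, lengths > 700)
  })
})

test_that("aa family clustering matches the brute-force oracle", {
  withr::with_seed(57, {
    for (trial in 1:5) {
      k <- sample(2:4, 1)
      prots <- unlist(lapply(seq_len(k), function(f) {
        anc <- rand_aa(sample(150:250, 1))
        vapply(seq_len(sample(2:4, 1)), function(i)
          mutate_aa(anc, stats::runif(1, 0, 0.10)), "")
      }))
      names(prots) <- paste0("p", seq_along(prots))
      got <- cluster_families_aa(prots)
      n <- length(prots)
      ord <- order(names(prots))
      adj <- matrix(FALSE, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
        adj[i, j] <- aa_identity(prots[[ord[i]]], prots[[ord[j]]]) >= 0.80
      oracle <- components_oracle(adj | t(adj))
      expect_true(same_partition(got$family, oracle))
    }
  })
})

test_that("planted families are recovered exactly", {
  ## k families, 5% within-family and ~50% between-family aa divergence
  withr::with_seed(58, {
    for (k in c(2, 5, 8)) {
      prots <- unlist(lapply(seq_len(k), function(f) {
        anc <- mutate_aa(rand_aa(200), 0)
        stats::setNames(vapply(1:3, function(i) mutate_aa(anc, 0.05), ""),
                        paste0("fam", f, "_", 1:3))
      }))
      got <- cluster_families_aa(prots)
      expect_equal(length(unique(got$family)), k)
      truth <- sub("_.*$", "", got$name)
      expect_true(same_partition(got$family, match(truth, unique(truth))))
    }
  })
})

test_that("family diversity table adds up per species", {
  asg <- data.frame(
    family = c("A", "A", "B", "C", "D", "E"),
    species = c("sp1", "sp1", "sp1", "sp2", "sp2", "sp1"),
    clade = c("L1", "L1", "L1", "L2", "L2", "L2"),
    stringsAsFactors = FALSE)
  tab <- family_diversity_table(asg)
  tot <- tab[tab$clade == "Total", ]
  for (sp in c("sp1", "sp2"))
    expect_equal(tot[[sp]], sum(tab[[sp]][tab$clade != "Total"]))
  expect_equal(tot$sp1, 3L)  # families A, B (L1) + E (L2)
  expect_equal(tot$sp2, 2L)
  empty <- family_diversity_table(asg[0, ])
  expect_identical(empty$clade, "Total")
})
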