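test_that("distances: closed forms, pairwise deletion, undefined pairs", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  for (model in c("p", "JC69", "K80")) {
    d <- pairwise_distance(seqs, model)
    expect_equal(d["a", "b"], 0)
  }
  # p = 0.1 -> JC69 = -3/4 log(1 - 4*0.1/3)
  s10 <- c(x = paste(rep("A", 10), collapse = ""),
           y = paste(c(rep("A", 9), "C"), collapse = ""))
  expect_equal(pairwise_distance(s10, "p")["x", "y"], 0.1)
  expect_equal(pairwise_distance(s10, "JC69")["x", "y"],
               -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(pairwise_distance(s10, "JC69")["x", "y"], 0.10732,
               tolerance = 1e-4)

  # saturation: p >= 3/4 is undefined under JC69
  sat <- c(x = "AAAA", y = "CCCC")
  expect_true(is.na(pairwise_distance(sat, "JC69")["x", "y"]))
  expect_equal(pairwise_distance(sat, "p")["x", "y"], 1)

  # sites with N or gaps are deleted pairwise
  pd <- c(x = "ANGTAC", y = "AC-TAC")
  d <- pairwise_distance(pd, "p")
  expect_equal(attr(d, "overlap")["x", "y"], 4L)
  expect_equal(d["x", "y"], 0)
})

test_that("JC69 correction always inflates the p distance", {
  set.seed(139)
  for (rep in 1:10) {
    seqs <- c(a = random_dna(200), b = random_dna(200))
    p <- pairwise_distance(seqs, "p")["a", "b"]
    jc <- pairwise_distance(seqs, "JC69")["a", "b"]
    if (!is.na(jc)) expect_gte(jc, p)
  }
})

test_that("distances agree with an established implementation on clean data", {
  set.seed(149)
  seqs <- vapply(1:6, function(i) random_dna(300), character(1))
  names(seqs) <- paste0("s", 1:6)
  # plant realistic similarity
  for (i in 2:6) {
    s <- strsplit(seqs[1], "")[[1]]
    pos <- sample(300, 15 * (i - 1))
    s[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    seqs[i] <- paste(s, collapse = "")
  }
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(s, "")[[1]])))
  for (pair in list(c("p", "raw"), c("JC69", "JC69"), c("K80", "K80"))) {
    mine <- pairwise_distance(seqs, pair[1])
    theirs <- as.matrix(ape::dist.dna(bin, model = pair[2]))
    expect_equal(unname(mine[names(seqs), names(seqs)]),
                 unname(theirs[names(seqs), names(seqs)]),
                 tolerance = 1e-10)
  }
})

test_that("NJ recovers trees exactly from additive matrices", {
  set.seed(151)
  for (n in c(4, 6, 9, 12)) {
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    true_tree <- ape::unroot(true_tree)
    d <- cophenetic(true_tree)
    est <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(est), true_tree)[1], 0)
    expect_equal(cophenetic(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("three taxa resolve by the closed form", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  # branch lengths: x = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(bl["c"]), (0.4 + 0.5 - 0.3) / 2)
})

test_that("NJ input validation and label-permutation invariance", {
  set.seed(157)
  tr <- ape::rtree(7)
  d <- cophenetic(tr)
  perm <- sample(rownames(d))
  est1 <- nj_tree(d)
  est2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(est1, est2)[1], 0)

  bad <- d; bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(nj_tree(bad), "not symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")

  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(est1, f)
  expect_equal(ape::dist.topo(ape::read.tree(f), est1)[1], 0)
})

test_that("assignment by nearest type isolate with concordance", {
  set.seed(163)
  typeA <- random_dna(200); typeB <- random_dna(200)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  queries <- list(l1 = c(q1 = typeA, q2 = mutate(typeB, 3)))
  types <- list(l1 = c(tA = typeA, tB = typeB))
  res <- assign_by_types(queries, types, c(tA = "alpha", tB = "beta"))
  expect_equal(res$overall$call[res$overall$isolate == "q1"], "alpha")
  expect_equal(res$overall$call[res$overall$isolate == "q2"], "beta")
  # margin of an exact match equals the distance to the other species' type
  m <- res$per_locus[res$per_locus$isolate == "q1", ]
  d <- pairwise_distance(c(q1 = typeA, tB = typeB), "JC69")
  expect_equal(m$margin, unname(d["q1", "tB"]))

  # equidistant query: deterministic lexicographic tie, flagged ambiguous
  tie <- list(l1 = c(q = "AAAA"))
  tie_types <- list(l1 = c(t1 = "AAAC", t2 = "AAAG"))
  res_tie <- assign_by_types(tie, tie_types, c(t1 = "zeta", t2 = "eta"),
                             min_overlap = 4)
  expect_equal(res_tie$per_locus$call, "eta")  # 'eta' < 'zeta'
  expect_true(res_tie$per_locus$ambiguous)

  # too little overlap -> untestable
  short <- list(l1 = c(q = paste0(strrep("N", 196), "ACGT")))
  res_short <- assign_by_types(short, types, c(tA = "alpha", tB = "beta"))
  expect_equal(res_short$per_locus$call, "untestable")
  expect_equal(res_short$overall$call, "untestable")
})

test_that("adding a distant outgroup type never changes assignments", {
  sim <- simulate_locus_alignments(
    complex_sim_config(n_isolates_per_species = 3, seed = 167))
  aln <- sim$alignment
  truth <- sim$truth
  ingroup <- names(truth)[truth != "flavigenum"]
  type_ids <- unlist(lapply(unique(truth[ingroup]), function(sp) {
    names(truth)[truth == sp][1]
  }))
  query_ids <- setdiff(ingroup, type_ids)
  queries <- lapply(aln$sequences, function(s) s[query_ids])
  types <- lapply(aln$sequences, function(s) s[type_ids])
  res1 <- assign_by_types(queries, types, truth[type_ids])
  og_id <- names(truth)[truth == "flavigenum"][1]
  types2 <- lapply(aln$sequences, function(s) s[c(type_ids, og_id)])
  res2 <- assign_by_types(queries, types2,
                          c(truth[type_ids], truth[og_id]))
  expect_equal(res1$overall$call, res2$overall$call)
})

test_that("species recovery on the synthetic complex is essentially perfect", {
  sim <- simulate_locus_alignments(
    complex_sim_config(n_isolates_per_species = 6,
                       within_species_polymorphism = 0, seed = 173))
  aln <- sim$alignment
  truth <- sim$truth
  type_ids <- unlist(lapply(unique(truth), function(sp) {
    names(truth)[truth == sp][1]
  }))
  query_ids <- setdiff(names(truth), type_ids)
  res <- assign_by_types(lapply(aln$sequences, function(s) s[query_ids]),
                         lapply(aln$sequences, function(s) s[type_ids]),
                         truth[type_ids])
  calls <- setNames(res$overall$call, res$overall$isolate)
  expect_gte(mean(calls[query_ids] == truth[query_ids]), 0.99)
  expect_equal(sum(calls == "discordant"), 0)
})

test_that("node heights convert linearly to calendar ages", {
  expect_equal(node_height_to_years(2.25e-3), 7.5e5)
  expect_equal(node_height_to_years(8.25e-3), 2.75e6)
  expect_equal(node_height_to_years(0), 0)
  set.seed(179)
  h <- runif(5, 0, 0.01)
  expect_equal(node_height_to_years(2 * h), 2 * node_height_to_years(h))
  expect_equal(node_height_to_years(h[1] + h[2]),
               node_height_to_years(h[1]) + node_height_to_years(h[2]))
  expect_error(clock_params(0), "> 0")
  expect_error(node_height_to_years(-1e-4), ">= 0")
})
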