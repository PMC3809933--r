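test_that("binding: exact match, clamp rule, and edge cases", {
  set.seed(73)
  primer <- "CATGTGAGTACAATGACTGGGAATCTT"
  template <- paste0(random_dna(40), primer, random_dna(40))
  hits <- find_binding_sites(template, primer)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 40L)
  expect_equal(hits$total_mismatches, 0L)

  # flipping the 3'-terminal base kills binding under the default clamp
  flipped <- template
  substr(flipped, 40 + nchar(primer), 40 + nchar(primer)) <- "A"  # T -> A
  expect_equal(nrow(find_binding_sites(flipped, primer)), 0)
  # ...but an internal mismatch within tolerance does not
  internal <- template
  substr(internal, 45, 45) <- if (substr(internal, 45, 45) == "A") "C" else "A"
  expect_equal(nrow(find_binding_sites(internal, primer)), 1)

  # primer longer than template: empty, not an error
  expect_equal(nrow(find_binding_sites("ACGT", primer)), 0)
  expect_error(find_binding_sites("AC-GT", "ACGT"), "ungapped")
  expect_error(find_binding_sites("ACGT", "ACNT"), "A/C/G/T")
})

test_that("ambiguous template bases match optimistically and are flagged", {
  hits <- find_binding_sites(paste0("AAAA", "ACGTACGTAT", "AAAA"),
                             "ACGTACGTAT", pcr_tolerance(0, 3))
  expect_equal(nrow(hits), 1)
  expect_false(hits$degenerate)
  # N in the template counts as a match but is flagged
  hits2 <- find_binding_sites(paste0("AAAA", "ACGTNCGTAT", "AAAA"),
                              "ACGTACGTAT", pcr_tolerance(0, 3))
  expect_equal(nrow(hits2), 1)
  expect_true(hits2$degenerate)
  # Y matches C or T, not G
  expect_equal(nrow(find_binding_sites("AAYA", "AACA", pcr_tolerance(0, 0))), 1)
  expect_equal(nrow(find_binding_sites("AAYA", "AAGA", pcr_tolerance(0, 0))), 0)
})

test_that("binding equals the sliding-window oracle on random templates", {
  set.seed(79)
  for (rep in 1:3) {
    template <- random_dna(1000)
    primer <- substr(random_dna(22), 1, 22)
    # plant a few imperfect copies so hits exist
    for (pos in sample(900, 3)) {
      copy <- strsplit(primer, "")[[1]]
      nmut <- sample(0:2, 1)
      if (nmut > 0) {
        at <- sample(22 - 3, nmut)  # keep the clamp clean
        copy[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      substr(template, pos, pos + 21) <- paste(copy, collapse = "")
    }
    for (strand in c("plus", "minus")) {
      got <- find_binding_sites(template, primer, pcr_tolerance(2, 3), strand)
      want <- oracle_binding_sites(template, primer, 2, 3, strand)
      expect_equal(got$start, want$start)
      expect_equal(got$total_mismatches, want$total)
    }
  }
})

test_that("loosening the mismatch tolerance never removes a binding site", {
  set.seed(83)
  template <- random_dna(600)
  primer <- substr(template, 101, 122)
  substr(template, 300, 321) <- primer  # second copy
  for (m in 0:3) {
    a <- find_binding_sites(template, primer, pcr_tolerance(m, 3))
    b <- find_binding_sites(template, primer, pcr_tolerance(m + 1, 3))
    expect_true(all(a$start %in% b$start))
  }
})

test_that("constructed templates amplify at the published lengths", {
  primers <- complex_primer_sets()
  for (i in seq_len(nrow(primers))) {
    template <- constructed_template(primers$forward[i], primers$reverse[i],
                                     primers$amplicon_length[i],
                                     seed = 90 + i)
    amp <- amplify(template, primers$forward[i], primers$reverse[i],
                   set_name = primers$set_name[i])
    expect_equal(nrow(amp), 1)
    expect_equal(amp$length, primers$amplicon_length[i])
  }
})

test_that("orientation rules: same-strand primers never amplify", {
  set.seed(97)
  fwd <- "CATGTGAGTACAATGACTGGG"
  rev <- "TCGACCAGAACGGCACG"
  # both primers appear only in forward orientation on the plus strand
  template <- paste0(random_dna(30), fwd, random_dna(60), rev, random_dna(30))
  expect_equal(nrow(amplify(template, fwd, rev)), 0)
  # reverse order (reverse site upstream of forward site) also fails
  template2 <- paste0(random_dna(30), revcomp_naive(rev), random_dna(60), fwd,
                      random_dna(30))
  expect_equal(nrow(amplify(template2, fwd, rev)), 0)
})

test_that("multiple binding sites enumerate all in-bounds products", {
  set.seed(101)
  fwd <- "GTACCGATCGGATTACGGAC"
  rev <- "CCATTGCGGATCCTAGGTCA"
  template <- paste0(fwd, random_dna(40), fwd, random_dna(40),
                     revcomp_naive(rev))
  amp <- amplify(template, fwd, rev)
  expect_equal(nrow(amp), 2)
  expect_equal(sort(amp$length),
               sort(c(nchar(template), nchar(template) - 60L)))
  # and the enumeration matches first principles: every (fwd, rev) pair
  f <- find_binding_sites(template, fwd, strand = "plus")
  r <- find_binding_sites(template, rev, strand = "minus")
  expect_equal(nrow(amp), nrow(f) * nrow(r))
})

test_that("reverse-complementing the template and swapping roles preserves lengths", {
  set.seed(103)
  primers <- complex_primer_sets()
  template <- constructed_template(primers$forward[2], primers$reverse[2],
                                   180, seed = 7)
  template <- paste0(random_dna(25), template, random_dna(31))
  a <- amplify(template, primers$forward[2], primers$reverse[2])
  b <- amplify(revcomp_naive(template), primers$reverse[2],
               primers$forward[2])
  expect_equal(sort(a$length), sort(b$length))
})

test_that("classification applies the no-overlap contract", {
  sim <- simulate_locus_alignments(
    complex_sim_config(n_isolates_per_species = 4,
                       within_species_polymorphism = 0, seed = 107))
  opts <- site_options(outgroup_species = "flavigenum")
  sets <- suppressMessages(design_primer_sets(
    sim$alignment, c("chrysogenum", "rubens", "chainii", "floreyi"),
    options = opts))
  expect_gte(nrow(sets), 2)

  truth <- sim$truth
  mk_templates <- function(ids) {
    out <- lapply(ids, function(id) {
      vapply(sim$alignment$loci, function(l) sim$alignment$sequences[[l]][[id]],
             character(1))
    })
    names(out) <- ids
    out
  }
  target <- sets$target_species[1]
  tgt_iso <- names(truth)[truth == target][1]
  outg <- names(truth)[truth == "flavigenum"][1]
  res <- classify_isolates(mk_templates(c(tgt_iso, outg)), sets)
  expect_equal(res$calls$call[res$calls$isolate_id == tgt_iso], target)
  expect_equal(res$calls$call[res$calls$isolate_id == outg], "other")

  # an isolate missing an assay's locus is untested there, never positive
  partial <- mk_templates(tgt_iso)
  keep <- setdiff(sim$alignment$loci, sets$locus[sets$target_species ==
                                                   target])
  partial[[tgt_iso]] <- partial[[tgt_iso]][keep]
  res2 <- classify_isolates(partial, sets)
  expect_match(res2$calls$untested,
               sets$set_name[sets$target_species == target])
  expect_false(res2$calls$call == target)
})
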