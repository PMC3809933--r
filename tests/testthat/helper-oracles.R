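# Independent oracles and fixture builders. Everything here is written
# deliberately naively (explicit loops, no shared code with the package
# internals) so the tests compare two independent routes to the same answer.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcomp_naive <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small 4-species, 2-isolates-each alignment fixture with known answer:
# 0-based column 4 is diagnostic for sp1 (fixed T; others A/C) and for sp2
# (fixed C); column 6 is polymorphic within sp1 (G/T) hence never
# diagnostic; column 8 is diagnostic for sp2 (fixed G; others A)
tiny_alignment <- function() {
  base <- "ACGTACGTACGT"
  seqs <- c(
    sp1_a = "ACGTTCGTACGT", sp1_b = "ACGTTCTTACGT",
    sp2_a = "ACGTCCGTGCGT", sp2_b = "ACGTCCGTGCGT",
    sp3_a = base, sp3_b = base,
    sp4_a = base, sp4_b = base)
  part <- c(sp1_a = "sp1", sp1_b = "sp1", sp2_a = "sp2", sp2_b = "sp2",
            sp3_a = "sp3", sp3_b = "sp3", sp4_a = "sp4", sp4_b = "sp4")
  multilocus_alignment(list(locusA = seqs), part)
}

# brute-force diagnostic-site scan: per column, per species, check fixation
# and absence from every other sequence, skipping columns with non-ACGT
oracle_diagnostic_sites <- function(alignment, target) {
  out <- NULL
  for (locus in alignment$loci) {
    seqs <- alignment$sequences[[locus]]
    part <- alignment$partition[names(seqs)]
    mat <- do.call(rbind, strsplit(unname(seqs), ""))
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j]
      if (any(!col %in% c("A", "C", "G", "T"))) next
      tb <- col[part == target]
      ob <- col[part != target & part != "unassigned"]
      if (length(tb) == 0 || length(ob) == 0) next
      if (length(unique(tb)) != 1) next
      if (unique(tb) %in% ob) next
      out <- rbind(out, data.frame(locus = locus, column = j - 1L,
                                   target_allele = unique(tb),
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(locus = character(0), column = integer(0),
                               target_allele = character(0))
  else out[order(out$locus, out$column), ]
}

# sliding-window primer binding oracle (plus strand = forward role)
oracle_binding_sites <- function(template, primer, max_mm, clamp,
                                 strand = "plus") {
  pat <- if (strand == "plus") primer else revcomp_naive(primer)
  tc <- strsplit(template, "")[[1]]
  pc <- strsplit(pat, "")[[1]]
  k <- length(pc)
  hits <- NULL
  if (k <= length(tc)) {
    for (s in 0:(length(tc) - k)) {
      mm <- logical(k)
      for (i in seq_len(k)) {
        set <- IUPAC_SETS[[tc[s + i]]]
        mm[i] <- !(pc[i] %in% set)
      }
      idx3 <- if (clamp == 0) integer(0) else if (strand == "plus") {
        (k - clamp + 1):k
      } else 1:min(clamp, k)
      if (sum(mm) <= max_mm && sum(mm[idx3]) == 0) {
        hits <- rbind(hits, data.frame(start = s, end = s + k,
                                       total = sum(mm)))
      }
    }
  }
  if (is.null(hits)) data.frame(start = integer(0), end = integer(0),
                                total = integer(0))
  else hits
}

# independent nearest-neighbour Tm (same published unified parameter table,
# organised as a lookup over both strands' dinucleotides, computed pairwise)
oracle_nn_tm <- function(seq, na = 0.05, conc = 250e-9) {
  dh_tab <- list(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
                 TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
                 GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
                 CC = -8.0)
  ds_tab <- list(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
                 TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
                 GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
                 CC = -19.9)
  ch <- strsplit(seq, "")[[1]]
  dh <- 0; ds <- 0
  for (i in 1:(length(ch) - 1)) {
    key <- paste0(ch[i], ch[i + 1])
    dh <- dh + dh_tab[[key]]
    ds <- ds + ds_tab[[key]]
  }
  for (endb in c(ch[1], ch[length(ch)])) {
    if (endb %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (length(ch) - 1) * log(na)
  1000 * dh / (ds + 1.987 * log(conc / 4)) - 273.15
}

# numerical-integration CDF of the studentized range (k groups, df error df)
oracle_ptukey <- function(q, k, df) {
  prange <- function(r) {
    if (r <= 0) return(0)
    f <- function(z) stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - r))^(k - 1)
    k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  # S = sqrt(chi2_df / df); integrate over its density
  fs <- function(s) 2 * df * s * stats::dchisq(df * s^2, df)
  g <- function(s) vapply(s, function(si) fs(si) * prange(q * si), numeric(1))
  stats::integrate(g, 0, Inf, rel.tol = 1e-9)$value
}

# exact conditional (permutation-limit) p-value for a 2x2 table: enumerate
# the hypergeometric support and sum probabilities of tables with a
# chi-square statistic >= observed
oracle_exact_perm_p <- function(tab) {
  r <- rowSums(tab); c <- colSums(tab); n <- sum(tab)
  stat <- function(a) {
    m <- matrix(c(a, r[1] - a, c[1] - a, n - r[1] - c[1] + a), 2)
    e <- outer(rowSums(m), colSums(m)) / n
    sum((m - e)^2 / e)
  }
  support <- max(0, c[1] - r[2]):min(r[1], c[1])
  probs <- stats::dhyper(support, r[1], r[2], c[1])
  obs <- stat(tab[1, 1])
  sum(probs[vapply(support, stat, numeric(1)) >= obs - 1e-9])
}

# Table 1 assay fixture: build a template that must amplify at the printed
# length (forward primer + filler + reverse complement of reverse primer)
constructed_template <- function(forward, reverse, amplicon_length,
                                 seed = 99) {
  set.seed(seed)
  filler_n <- amplicon_length - nchar(forward) - nchar(reverse)
  stopifnot(filler_n >= 0)
  paste0(forward, random_dna(filler_n), revcomp_naive(reverse))
}
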