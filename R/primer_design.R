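# Species-specific primer design. Candidates are enumerated so that the
# 3'-terminal base of a primer sits exactly on a diagnostic site (the basis
# of allele-specific PCR: polymerase extension requires a perfectly paired
# 3' end), then paired under the 100-200 bp amplicon constraint and scored.
# The published assays delegated primer metrics to commercial software, so
# the Tm model, scoring weights and tie-breaks here are package decisions,
# all surfaced in the configuration objects below.

#' GC content of a primer
#'
#' @param sequence non-empty A/C/G/T string.
#' @return fraction of G+C bases in `[0, 1]`.
#' @export
#' @examples
#' gc_content("ACGGCCCCTCCTTACGAAA") # 11/19
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("A", "C", "G", "T"))) {
    stop("gc_content requires a pure A/C/G/T sequence")
  }
  sum(ch %in% c("G", "C")) / length(ch)
}

# SantaLucia (1998) unified nearest-neighbour parameters.
# dH in kcal/mol, dS in cal/(mol K), per 5'->3' dinucleotide step.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
# initiation terms per terminal base pair
NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Primer melting temperature
#'
#' `"wallace"` is the rule of thumb 2(A+T) + 4(G+C). `"nn"` is
#' nearest-neighbour thermodynamics with the unified duplex parameter table
#' (SantaLucia 1998): Tm = 1000 dH / (dS + R ln(C/4)) - 273.15, with the
#' entropic salt correction dS + 0.368 (N-1) ln[Na+]. Defaults: 50 mM
#' monovalent salt, 250 nM total primer.
#'
#' @param sequence A/C/G/T string; length >= 8 for the `"nn"` method.
#' @param method `"wallace"` or `"nn"`.
#' @param na_molar monovalent cation concentration (mol/L), `"nn"` only.
#' @param primer_molar total primer concentration (mol/L), `"nn"` only.
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("ACGT", "wallace") # 12
melting_temperature <- function(sequence, method = c("wallace", "nn"),
                                na_molar = 0.05, primer_molar = 250e-9) {
  method <- match.arg(method)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("A", "C", "G", "T"))) {
    stop("melting_temperature requires a pure A/C/G/T sequence")
  }
  if (method == "wallace") {
    return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
  }
  if (length(ch) < 8) stop("nearest-neighbour method needs length >= 8")
  steps <- paste0(ch[-length(ch)], ch[-1])
  dh <- sum(NN_DH[steps]) + NN_INIT_DH[ch[1]] + NN_INIT_DH[ch[length(ch)]]
  ds <- sum(NN_DS[steps]) + NN_INIT_DS[ch[1]] + NN_INIT_DS[ch[length(ch)]]
  ds <- ds + 0.368 * (length(ch) - 1) * log(na_molar)
  r_gas <- 1.987 # cal/(mol K)
  unname(1000 * dh / (ds + r_gas * log(primer_molar / 4)) - 273.15)
}

#' Constraints for primer enumeration and pairing
#'
#' Defaults follow the observed range of the published assays: primer
#' lengths 17-29 nt, amplicons 100-200 bp.
#'
#' @param min_len,max_len primer length bounds (nt).
#' @param amplicon_min,amplicon_max amplicon length bounds (bp, 5' end to 5'
#'   end inclusive of both primers).
#' @param tm_min,tm_max optional melting-temperature window (degrees C);
#'   `NULL` disables the filter.
#' @param tm_method Tm model used for filtering and scoring.
#' @return list of class `primer_constraints`.
#' @export
primer_constraints <- function(min_len = 17L, max_len = 29L,
                               amplicon_min = 100L, amplicon_max = 200L,
                               tm_min = NULL, tm_max = NULL,
                               tm_method = "wallace") {
  stopifnot(min_len >= 8, max_len >= min_len, amplicon_min > 0,
            amplicon_max >= amplicon_min)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 amplicon_min = as.integer(amplicon_min),
                 amplicon_max = as.integer(amplicon_max),
                 tm_min = tm_min, tm_max = tm_max, tm_method = tm_method),
            class = "primer_constraints")
}

#' Consensus sequence of a set of aligned sequences
#'
#' Majority base per column among A/C/G/T (ties broken alphabetically);
#' columns with no unambiguous base become `N`.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return single consensus string.
#' @export
consensus_sequence <- function(seqs) {
  m <- seq_char_matrix(seqs)
  bases <- c("A", "C", "G", "T")
  cons <- apply(m, 2, function(col) {
    col <- col[col %in% bases]
    if (length(col) == 0) return("N")
    tab <- table(factor(col, levels = bases))
    bases[which.max(tab)]  # which.max takes the first (alphabetic) maximum
  })
  paste0(cons, collapse = "")
}

empty_primers <- function() {
  data.frame(sequence = character(0), strand = character(0),
             start = integer(0), end = integer(0), length = integer(0),
             locus = character(0), target_species = character(0),
             site_column = integer(0), anchored = logical(0),
             gc = numeric(0), tm = numeric(0), stringsAsFactors = FALSE)
}

primer_row <- function(sequence, strand, start, end, locus, species,
                       site_column, anchored, constraints) {
  if (grepl("[^ACGT]", sequence)) return(NULL)
  tm <- melting_temperature(sequence, constraints$tm_method)
  if (!is.null(constraints$tm_min) && tm < constraints$tm_min) return(NULL)
  if (!is.null(constraints$tm_max) && tm > constraints$tm_max) return(NULL)
  data.frame(sequence = sequence, strand = strand, start = as.integer(start),
             end = as.integer(end), length = nchar(sequence), locus = locus,
             target_species = species, site_column = as.integer(site_column),
             anchored = anchored, gc = gc_content(sequence), tm = tm,
             stringsAsFactors = FALSE)
}

#' Enumerate 3'-anchored primer candidates on diagnostic sites
#'
#' For each diagnostic site, forward candidates end (3') on the site read on
#' the plus strand of the target-species consensus; reverse candidates end on
#' the site read on the minus strand. Anchors are 0-based half-open template
#' intervals. Sites too close to a sequence edge for any in-bounds primer are
#' skipped with a message, not an error.
#'
#' @param consensus target-species consensus string for one locus (see
#'   [consensus_sequence()]).
#' @param sites data.frame of diagnostic sites for that locus/species (as
#'   from [find_diagnostic_sites()]).
#' @param constraints a [primer_constraints()] list.
#' @return data.frame of candidate primers (columns sequence, strand, start,
#'   end, length, locus, target_species, site_column, anchored, gc, tm).
#' @export
enumerate_candidates <- function(consensus, sites,
                                 constraints = primer_constraints()) {
  if (nrow(sites) == 0) return(empty_primers())
  L <- nchar(consensus)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    col <- sites$column[i]
    if (col >= L) stop("site column ", col, " beyond sequence length ", L)
    if (substr(consensus, col + 1, col + 1) != sites$target_allele[i]) {
      message("consensus does not carry the target allele at column ", col,
              "; site skipped")
      next
    }
    found <- FALSE
    for (len in constraints$min_len:constraints$max_len) {
      # forward: spans [col-len+1, col+1), 3' base at `col`
      s <- col - len + 1L
      if (s >= 0) {
        fwd <- substr(consensus, s + 1, col + 1)
        row <- primer_row(fwd, "forward", s, col + 1L,
                          sites$locus[i], sites$target_species[i], col,
                          TRUE, constraints)
        if (!is.null(row)) { out[[length(out) + 1]] <- row; found <- TRUE }
      }
      # reverse: spans [col, col+len), 3' base at `col` on the minus strand
      e <- col + len
      if (e <= L) {
        rev <- reverse_complement(substr(consensus, col + 1, e))
        row <- primer_row(rev, "reverse", col, e,
                          sites$locus[i], sites$target_species[i], col,
                          TRUE, constraints)
        if (!is.null(row)) { out[[length(out) + 1]] <- row; found <- TRUE }
      }
    }
    if (!found) {
      message("no valid primer for site at locus ", sites$locus[i],
              " column ", col, " (edge or filter); skipped")
    }
  }
  if (length(out) == 0) return(empty_primers())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Unanchored partner candidates on the opposite strand of one or more
# anchored primers, positioned so the amplicon stays within bounds. Windows
# shared between anchored primers are enumerated once.
enumerate_partners <- function(consensus, anchored_df, constraints) {
  L <- nchar(consensus)
  win <- list()
  for (r in seq_len(nrow(anchored_df))) {
    a <- anchored_df[r, ]
    for (len in constraints$min_len:constraints$max_len) {
      if (a$strand == "forward") {
        # partner is a reverse primer: amplicon = rev_end - fwd_start
        e <- (a$start + constraints$amplicon_min):
             (a$start + constraints$amplicon_max)
        s <- e - len
        keep <- s >= a$end & e <= L
        if (any(keep)) {
          win[[length(win) + 1]] <- data.frame(strand = "reverse",
                                               s = s[keep], e = e[keep])
        }
      } else {
        s <- (a$end - constraints$amplicon_max):
             (a$end - constraints$amplicon_min)
        e <- s + len
        keep <- s >= 0 & e <= a$start
        if (any(keep)) {
          win[[length(win) + 1]] <- data.frame(strand = "forward",
                                               s = s[keep], e = e[keep])
        }
      }
    }
  }
  if (length(win) == 0) return(empty_primers())
  win <- unique(do.call(rbind, win))
  out <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    seqv <- if (win$strand[i] == "forward") {
      substr(consensus, win$s[i] + 1, win$e[i])
    } else {
      reverse_complement(substr(consensus, win$s[i] + 1, win$e[i]))
    }
    out[[i]] <- primer_row(seqv, win$strand[i], win$s[i], win$e[i],
                           anchored_df$locus[1],
                           anchored_df$target_species[1], NA_integer_,
                           FALSE, constraints)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_primers())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scoring weights for primer-pair selection
#'
#' The pair score is
#' `- w_tm |Tm_f - Tm_r| - w_gc (|gc_f - 0.5| + |gc_r - 0.5|)
#'  + w_anchor [both primers 3'-anchored] - w_dimer dimer3(f, r)`,
#' where `dimer3` counts consecutive complementary bases at the two 3' ends
#' (a primer-dimer proxy). Higher is better.
#'
#' @param w_tm,w_gc,w_anchor,w_dimer non-negative weights.
#' @return list of class `pair_weights`.
#' @export
pair_weights <- function(w_tm = 1, w_gc = 2, w_anchor = 5, w_dimer = 1) {
  structure(list(w_tm = w_tm, w_gc = w_gc, w_anchor = w_anchor,
                 w_dimer = w_dimer), class = "pair_weights")
}

# consecutive complementary bases when the two 3' ends are apposed
dimer3_score <- function(fwd, rev) {
  a <- rev(strsplit(fwd, "", fixed = TRUE)[[1]])
  b <- rev(strsplit(rev, "", fixed = TRUE)[[1]])
  k <- 0
  for (i in seq_len(min(length(a), length(b)))) {
    if (COMPLEMENT[a[i]] == b[i]) k <- k + 1 else break
  }
  k
}

#' Pair candidate primers and select the best pair per species
#'
#' All forward x reverse combinations within one locus and target species are
#' formed; pairs whose amplicon (reverse-anchor end minus forward-anchor
#' start, i.e. 5' end to 5' end inclusive) falls outside the configured
#' bounds are dropped; the highest-scoring pair wins, with a deterministic
#' tie-break (smaller amplicon, then lexicographic forward sequence).
#'
#' @param candidates data.frame of primers from [enumerate_candidates()]
#'   (optionally plus unanchored partners).
#' @param constraints a [primer_constraints()] list.
#' @param weights a [pair_weights()] list.
#' @return data.frame with one row per target species (set_name,
#'   target_species, locus, forward, reverse, amplicon_length, score, both
#'   anchor coordinates); species with no feasible pair are reported in the
#'   `failures` attribute (species, reason), never as an error.
#' @export
pair_and_select <- function(candidates, constraints = primer_constraints(),
                            weights = pair_weights()) {
  species <- unique(candidates$target_species)
  rows <- list()
  failures <- list()
  for (sp in species) {
    cand <- candidates[candidates$target_species == sp, , drop = FALSE]
    if (length(unique(cand$locus)) > 1) {
      stop("pair_and_select expects candidates from a single locus per ",
           "species; got ", paste(unique(cand$locus), collapse = ", "))
    }
    cand <- cand[!duplicated(cand[c("sequence", "strand", "start")]), ,
                 drop = FALSE]
    fwd <- cand[cand$strand == "forward", , drop = FALSE]
    rev <- cand[cand$strand == "reverse", , drop = FALSE]
    if (nrow(fwd) == 0 || nrow(rev) == 0) {
      failures[[sp]] <- "missing forward or reverse candidates"
      next
    }
    best <- NULL
    # vectorise over reverse candidates for each forward primer; only the
    # (usually few) pairs inside the amplicon window are scored
    for (i in seq_len(nrow(fwd))) {
      amp <- rev$end - fwd$start[i]
      ok <- fwd$start[i] < rev$start &            # primers must not cross
        amp >= constraints$amplicon_min & amp <= constraints$amplicon_max &
        (fwd$anchored[i] | rev$anchored)          # >=1 primer on a site
      for (j in which(ok)) {
        score <- -weights$w_tm * abs(fwd$tm[i] - rev$tm[j]) -
          weights$w_gc * (abs(fwd$gc[i] - 0.5) + abs(rev$gc[j] - 0.5)) +
          weights$w_anchor * (fwd$anchored[i] && rev$anchored[j]) -
          weights$w_dimer * dimer3_score(fwd$sequence[i], rev$sequence[j])
        better <- is.null(best) || score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
             (amp[j] < best$amp ||
                (amp[j] == best$amp && fwd$sequence[i] < best$fseq)))
        if (better) {
          best <- list(score = score, amp = amp[j], fseq = fwd$sequence[i],
                       f = fwd[i, ], r = rev[j, ])
        }
      }
    }
    if (is.null(best)) {
      failures[[sp]] <- "no pair satisfies the amplicon length bounds"
      next
    }
    rows[[sp]] <- data.frame(
      set_name = paste0(best$f$locus, "_", sp),
      target_species = sp, locus = best$f$locus,
      forward = best$f$sequence, reverse = best$r$sequence,
      amplicon_length = as.integer(best$amp),
      forward_start = best$f$start, reverse_end = best$r$end,
      score = best$score, cycles = 35L, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(set_name = character(0), target_species = character(0),
               locus = character(0), forward = character(0),
               reverse = character(0), amplicon_length = integer(0),
               forward_start = integer(0), reverse_end = integer(0),
               score = numeric(0), cycles = integer(0))
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures) > 0) {
    data.frame(species = names(failures),
               reason = unlist(failures, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else NULL
  out
}

#' Design a species-specific primer set for every species
#'
#' End-to-end design: scan for diagnostic sites, enumerate 3'-anchored
#' candidates on the target-species consensus of each locus, pair within the
#' amplicon bounds and pick the best pair per species. When no
#' anchored-anchored pair is feasible, an anchored primer is paired with
#' unanchored partners on the opposite strand (only one 3' anchor is
#' required; both anchors earn a score bonus).
#'
#' @param alignment a [multilocus_alignment()].
#' @param species species to design for; default all non-outgroup species.
#' @param constraints a [primer_constraints()] list.
#' @param weights a [pair_weights()] list.
#' @param options a [site_options()] list for the site scan.
#' @return data.frame, one row per species with a feasible assay, in the
#'   primer-table schema plus design metadata; failures in the `failures`
#'   attribute.
#' @export
design_primer_sets <- function(alignment, species = NULL,
                               constraints = primer_constraints(),
                               weights = pair_weights(),
                               options = site_options()) {
  sites <- diagnostic_catalog(alignment, species, options)
  if (is.null(species)) species <- unique(sites$target_species)
  rows <- list(); failures <- list()
  for (sp in species) {
    sp_sites <- sites[sites$target_species == sp & !sites$low_support, ,
                      drop = FALSE]
    if (nrow(sp_sites) == 0) {
      failures[[sp]] <- "no diagnostic sites"
      next
    }
    part <- alignment$partition
    ids <- names(part)[part == sp]
    best <- NULL
    for (locus in unique(sp_sites$locus)) {
      cons <- consensus_sequence(alignment$sequences[[locus]][ids])
      cand <- enumerate_candidates(cons, sp_sites[sp_sites$locus == locus, ],
                                   constraints)
      if (nrow(cand) == 0) next
      sel <- pair_and_select(cand, constraints, weights)
      if (nrow(sel) == 0) {
        # fall back: anchor one primer only, partner unanchored
        anchored <- cand[order(-cand$anchored, cand$start, cand$sequence), ]
        anchored <- utils::head(anchored, 12)   # cap the fallback search
        cand2 <- rbind(cand, enumerate_partners(cons, anchored, constraints))
        sel <- pair_and_select(cand2, constraints, weights)
      }
      if (nrow(sel) == 1 &&
          (is.null(best) || sel$score > best$score + 1e-12 ||
             (abs(sel$score - best$score) <= 1e-12 &&
                sel$set_name < best$set_name))) {
        best <- sel
      }
    }
    if (is.null(best)) failures[[sp]] <- "no feasible pair in any locus"
    else rows[[sp]] <- best
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    pair_and_select(empty_primers())
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures) > 0) {
    data.frame(species = names(failures),
               reason = unlist(failures, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else NULL
  out
}
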