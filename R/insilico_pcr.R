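# In-silico PCR: primer binding with a 3' mismatch clamp, amplicon
# prediction, and species classification of isolates under the
# no-overlapping-positives contract.
#
# Binding model: a window qualifies iff it has zero mismatches within the
# terminal `clamp` bases of the primer's 3' end and at most `max_mismatch`
# mismatches in total. A 3' clamp with perfect pairing is what polymerase
# extension requires; mismatches elsewhere mostly lower efficiency. IUPAC
# ambiguity codes in the template count as a match when the primer base is in
# the code's set (optimistic for sensitivity) and are flagged in the output.

#' Mismatch tolerance for in-silico PCR
#'
#' @param max_mismatch maximum total mismatches tolerated per primer binding
#'   site (default 2).
#' @param clamp number of 3'-terminal primer bases in which zero mismatches
#'   are allowed (default 3).
#' @return list of class `pcr_tolerance`.
#' @export
pcr_tolerance <- function(max_mismatch = 2L, clamp = 3L) {
  stopifnot(max_mismatch >= 0, clamp >= 0)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 clamp = as.integer(clamp)), class = "pcr_tolerance")
}

# per-position match of primer chars against template chars (IUPAC-aware on
# the template side; primer is pure ACGT)
iupac_match <- function(primer_chars, template_chars) {
  mapply(function(p, t) {
    s <- IUPAC_DNA[[t]]
    !is.null(s) && p %in% s
  }, primer_chars, template_chars, USE.NAMES = FALSE)
}

#' Find primer binding sites on a template
#'
#' Scans an ungapped DNA template for windows where the primer anneals under
#' the tolerance. `strand = "plus"` means the primer acts as a forward primer
#' (its sequence, 5'->3', matches the plus strand; 3' end at the right edge
#' of the window). `strand = "minus"` means it acts as a reverse primer (its
#' reverse complement matches the plus strand; 3' end at the left edge).
#' Intervals are 0-based half-open in plus-strand coordinates.
#'
#' @param template DNA string (IUPAC codes allowed, no gaps).
#' @param primer A/C/G/T primer string, 5'->3'.
#' @param tolerance a [pcr_tolerance()] list.
#' @param strand `"plus"` or `"minus"`.
#' @param template_id id recorded in the result.
#' @return data.frame: template_id, strand, start, end, total_mismatches,
#'   three_prime_mismatches, degenerate (TRUE when an ambiguous template base
#'   was counted as a match).
#' @export
find_binding_sites <- function(template, primer,
                               tolerance = pcr_tolerance(),
                               strand = c("plus", "minus"),
                               template_id = "template") {
  strand <- match.arg(strand)
  stopifnot(is.character(template), length(template) == 1,
            is.character(primer), length(primer) == 1)
  template <- toupper(template)
  primer <- toupper(primer)
  if (grepl("[^ACGT]", primer)) stop("primer must be pure A/C/G/T")
  if (grepl("-", template, fixed = TRUE)) stop("template must be ungapped")
  empty <- data.frame(template_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      total_mismatches = integer(0),
                      three_prime_mismatches = integer(0),
                      degenerate = logical(0), stringsAsFactors = FALSE)
  n <- nchar(template); k <- nchar(primer)
  if (k > n) return(empty)

  pattern <- if (strand == "plus") primer else reverse_complement(primer)
  subject <- Biostrings::DNAString(template)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), subject,
    max.mismatch = tolerance$max_mismatch,
    fixed = c(pattern = TRUE, subject = FALSE))
  if (length(hits) == 0) return(empty)

  pat_chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tmpl_chars <- strsplit(template, "", fixed = TRUE)[[1]]
  rows <- list()
  for (i in seq_along(hits)) {
    s <- BiocGenerics::start(hits)[i]          # 1-based
    win <- tmpl_chars[s:(s + k - 1)]
    ok <- iupac_match(pat_chars, win)
    total <- sum(!ok)
    if (total > tolerance$max_mismatch) next
    # 3'-terminal bases: right edge of the window on plus strand, left edge
    # for a minus-strand (reverse) primer
    idx3 <- if (tolerance$clamp == 0) integer(0) else if (strand == "plus") {
      (k - tolerance$clamp + 1):k
    } else seq_len(min(tolerance$clamp, k))
    three <- sum(!ok[idx3])
    if (three > 0) next
    degenerate <- any(ok & !win %in% c("A", "C", "G", "T"))
    rows[[length(rows) + 1]] <- data.frame(
      template_id = template_id, strand = strand,
      start = s - 1L, end = s - 1L + k,
      total_mismatches = as.integer(total),
      three_prime_mismatches = as.integer(three),
      degenerate = degenerate, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict amplicons of a primer pair on a template
#'
#' Every combination of a forward site (plus strand) and a reverse site
#' (minus strand) with the forward 5' end upstream of the reverse 5' end
#' yields an amplicon when the product length falls within `length_bounds`.
#' Length is measured 5' end to 5' end, inclusive of both primers.
#'
#' @param template DNA string.
#' @param forward,reverse primer strings 5'->3'.
#' @param tolerance a [pcr_tolerance()] list.
#' @param length_bounds detectable product lengths in bp (default 50-2000).
#' @param set_name,template_id ids recorded in the result.
#' @return data.frame: set_name, template_id, start, end, length, plus the
#'   mismatch counts of both binding sites; zero rows = no amplification.
#' @export
amplify <- function(template, forward, reverse,
                    tolerance = pcr_tolerance(),
                    length_bounds = c(50L, 2000L),
                    set_name = "set", template_id = "template") {
  f <- find_binding_sites(template, forward, tolerance, "plus", template_id)
  r <- find_binding_sites(template, reverse, tolerance, "minus", template_id)
  out <- list()
  if (nrow(f) > 0 && nrow(r) > 0) {
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      if (f$start[i] >= r$end[j]) next
      len <- r$end[j] - f$start[i]
      if (len < length_bounds[1] || len > length_bounds[2]) next
      out[[length(out) + 1]] <- data.frame(
        set_name = set_name, template_id = template_id,
        start = f$start[i], end = r$end[j], length = as.integer(len),
        forward_mismatches = f$total_mismatches[i],
        reverse_mismatches = r$total_mismatches[j],
        degenerate = f$degenerate[i] || r$degenerate[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(set_name = character(0), template_id = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), forward_mismatches = integer(0),
                      reverse_mismatches = integer(0),
                      degenerate = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify isolates by in-silico PCR with an assay panel
#'
#' Runs every primer set against every isolate and applies the
#' no-overlapping-positives contract: an isolate is called to a species iff
#' exactly the one assay targeting that species is positive; no positives =
#' `"other"`; more than one positive = `"conflict"`. An assay whose template
#' locus the isolate does not supply is recorded `"untested"` and never
#' counted positive.
#'
#' @param panel an `isolate_panel` from [simulate_isolate_panel()], or a
#'   named list of per-isolate sequence vectors (names = locus names when
#'   assays declare a locus).
#' @param primer_sets data.frame in the [read_primer_table()] schema (a
#'   `locus` column routes each assay to the matching isolate sequence;
#'   assays with `NA` locus are run against all sequences of the isolate).
#' @param tolerance a [pcr_tolerance()] list.
#' @param length_bounds detectable amplicon lengths in bp.
#' @return list with `calls` (data.frame isolate_id, positives, untested,
#'   call) and, when the panel carries a `true_species` column,
#'   `specificity_matrix` (assays x true species positive rates).
#' @export
classify_isolates <- function(panel, primer_sets,
                              tolerance = pcr_tolerance(),
                              length_bounds = c(50L, 2000L)) {
  if (inherits(panel, "isolate_panel")) {
    sequences <- panel$sequences
    info <- panel$info
  } else {
    sequences <- panel
    info <- NULL
  }
  calls <- list()
  pos_by_assay <- matrix(0L, nrow = nrow(primer_sets),
                         ncol = length(sequences),
                         dimnames = list(primer_sets$set_name,
                                         names(sequences)))
  for (iso in names(sequences)) {
    seqs <- sequences[[iso]]
    positives <- character(0)
    untested <- character(0)
    for (a in seq_len(nrow(primer_sets))) {
      locus <- primer_sets$locus[a]
      templates <- if (!is.na(locus) && !is.null(names(seqs))) {
        if (locus %in% names(seqs)) seqs[locus] else character(0)
      } else seqs
      if (length(templates) == 0) {
        untested <- c(untested, primer_sets$set_name[a])
        next
      }
      hit <- FALSE
      for (t in seq_along(templates)) {
        amp <- amplify(templates[[t]], primer_sets$forward[a],
                       primer_sets$reverse[a], tolerance, length_bounds,
                       set_name = primer_sets$set_name[a], template_id = iso)
        if (nrow(amp) > 0) { hit <- TRUE; break }
      }
      if (hit) {
        positives <- c(positives, primer_sets$set_name[a])
        pos_by_assay[a, iso] <- 1L
      }
    }
    call <- if (length(positives) == 0) "other"
      else if (length(positives) == 1) {
        primer_sets$target_species[match(positives, primer_sets$set_name)]
      } else "conflict"
    calls[[iso]] <- data.frame(
      isolate_id = iso,
      positives = paste(positives, collapse = ","),
      untested = paste(untested, collapse = ","),
      call = call, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  out <- list(calls = calls)
  if (!is.null(info) && "true_species" %in% names(info)) {
    truth <- info$true_species[match(colnames(pos_by_assay),
                                     info$isolate_id)]
    species <- sort(unique(truth))
    m <- sapply(species, function(s) {
      rowMeans(pos_by_assay[, truth == s, drop = FALSE])
    })
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(primer_sets),
                                     dimnames = list(primer_sets$set_name,
                                                     species))
    out$specificity_matrix <- m
  }
  out
}
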