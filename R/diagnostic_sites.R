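# Diagnostic-site discovery: alignment columns that allow exclusive
# detection of one species. A column qualifies for a target species iff
# (a) every target-species sequence carries the same unambiguous base, and
# (b) that base occurs in zero non-target sequences. This is the conservative
# reading of "exclusive detection": fixation is required in the target, and a
# non-target ambiguity code whose set contains the target allele disqualifies
# the column (specificity over sensitivity).

#' Options for diagnostic-site scanning
#'
#' @param min_target_depth minimum number of target sequences scored at a
#'   column for full support; columns below it are returned flagged
#'   `low_support`, not rejected (per-species samples can be small).
#' @param allow_missing if `FALSE` (default) a column containing a gap or
#'   ambiguity code in any counted sequence is skipped; if `TRUE` those
#'   sequences are ignored at that column, provided at least one target and
#'   one non-target sequence remain. A non-target ambiguity code whose IUPAC
#'   set contains the target allele always disqualifies the column (it may
#'   hide the target base).
#' @param outgroup_species species excluded from the non-target comparison
#'   unless `include_outgroups` is `TRUE`.
#' @param include_outgroups require outgroup species to differ at sites too.
#' @return list of class `site_options`.
#' @export
site_options <- function(min_target_depth = 2L, allow_missing = FALSE,
                         outgroup_species = character(0),
                         include_outgroups = FALSE) {
  stopifnot(min_target_depth >= 1)
  structure(list(min_target_depth = as.integer(min_target_depth),
                 allow_missing = isTRUE(allow_missing),
                 outgroup_species = outgroup_species,
                 include_outgroups = isTRUE(include_outgroups)),
            class = "site_options")
}

empty_sites <- function() {
  data.frame(locus = character(0), column = integer(0),
             target_species = character(0), target_allele = character(0),
             other_alleles = character(0), n_target = integer(0),
             n_other = integer(0), low_support = logical(0),
             stringsAsFactors = FALSE)
}

#' Find species-diagnostic alignment columns
#'
#' Scans every locus of a multilocus alignment for columns where the target
#' species is fixed for an unambiguous base that no non-target sequence
#' carries. Coordinates are 0-based.
#'
#' @param alignment a [multilocus_alignment()].
#' @param target_species species to diagnose; must occur in the partition.
#' @param options a [site_options()] list.
#' @return data.frame of diagnostic sites sorted by (locus, column), with
#'   columns locus, column (0-based), target_species, target_allele,
#'   other_alleles (comma-separated), n_target, n_other, low_support.
#' @export
find_diagnostic_sites <- function(alignment, target_species,
                                  options = site_options()) {
  stopifnot(inherits(alignment, "multilocus_alignment"))
  part <- alignment$partition
  if (!target_species %in% part) {
    stop("unknown target species: '", target_species, "'")
  }
  skip <- if (options$include_outgroups) character(0) else
    options$outgroup_species
  target_ids <- names(part)[part == target_species]
  other_ids <- names(part)[part != target_species & !part %in% skip &
                             part != "unassigned"]
  if (length(other_ids) == 0) stop("no non-target sequences to compare against")

  out <- list()
  for (locus in alignment$loci) {
    seqs <- alignment$sequences[[locus]]
    t_ids <- intersect(target_ids, names(seqs))
    o_ids <- intersect(other_ids, names(seqs))
    if (length(t_ids) == 0 || length(o_ids) == 0) next
    m <- seq_char_matrix(seqs[c(t_ids, o_ids)])
    n_t <- length(t_ids)
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      tb <- col[seq_len(n_t)]
      ob <- col[-seq_len(n_t)]
      clean <- c("A", "C", "G", "T")
      t_miss <- !tb %in% clean
      o_miss <- !ob %in% clean
      o_amb <- ob[o_miss & ob != "-"]        # ambiguity codes, not gaps
      if (!options$allow_missing) {
        if (any(t_miss) || any(o_miss)) next
      } else {
        tb <- tb[!t_miss]
        ob <- ob[!o_miss]
        if (length(tb) < 1 || length(ob) < 1) next
      }
      allele <- unique(tb)
      if (length(allele) != 1) next          # fixation required in target
      # a non-target base disqualifies; so does a non-target ambiguity code
      # whose set contains the target allele (it may hide the target base),
      # even when missing data are otherwise ignored
      if (any(iupac_contains(ob, allele))) next
      if (any(iupac_contains(o_amb, allele))) next
      out[[length(out) + 1]] <- data.frame(
        locus = locus, column = j - 1L, target_species = target_species,
        target_allele = allele,
        other_alleles = paste(sort(unique(ob)), collapse = ","),
        n_target = length(tb), n_other = length(ob),
        low_support = length(tb) < options$min_target_depth,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_sites())
  res <- do.call(rbind, out)
  res[order(res$locus, res$column), , drop = FALSE]
}

#' Catalogue diagnostic sites for every species
#'
#' Applies [find_diagnostic_sites()] to each species of the partition (or a
#' supplied subset) and binds the results. A column may appear under several
#' species with different alleles (e.g. an A/A vs C/C column in a two-species
#' alignment is diagnostic for both).
#'
#' @param alignment a [multilocus_alignment()].
#' @param species species to catalogue; default all partition species except
#'   `"unassigned"` and the configured outgroups.
#' @param options a [site_options()] list.
#' @return data.frame in the [find_diagnostic_sites()] schema.
#' @export
diagnostic_catalog <- function(alignment, species = NULL,
                               options = site_options()) {
  if (is.null(species)) {
    species <- sort(setdiff(unique(alignment$partition),
                            c("unassigned", options$outgroup_species)))
  }
  res <- lapply(species, function(s) {
    find_diagnostic_sites(alignment, s, options)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty_sites()
  rownames(out) <- NULL
  out
}

#' Write a diagnostic-site catalogue as TSV
#'
#' @param sites data.frame from [diagnostic_catalog()].
#' @param path output path.
#' @param header optional comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(sites, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(sites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
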