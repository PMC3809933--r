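# Readers and writers for the plain-text formats the pipeline touches:
# FASTA (plain and aligned), primer tables (TSV), count tables (CSV).
# Readers validate on ingest and never silently alter data beyond the stated
# normalisations (uppercase, U->T). Lines starting '#' are treated as
# comments in tabular files (provenance headers written by the CLI).

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and RNA-style `U` is mapped to `T` on ingest.
#' Gaps (`-`) are accepted so aligned FASTA reads with the same function;
#' all other characters must be IUPAC nucleotide codes.
#'
#' @param path path to a FASTA file.
#' @param locus optional locus name attached as an attribute.
#' @return named character vector of sequences (names are record ids) with
#'   attribute `locus`.
#' @export
read_fasta <- function(path, locus = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id in ", path, ": '", dup[1], "'")
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for id '", ids[i], "'")
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% c(IUPAC_LETTERS, "-"))
    if (length(bad) > 0) {
      stop("non-IUPAC character '", ch[bad[1]], "' at position ", bad[1],
           " of record '", ids[i], "'")
    }
  }
  names(seqs) <- ids
  attr(seqs, "locus") <- locus
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Multilocus alignment with species partition
#'
#' Container for per-locus aligned sequences over a shared isolate panel,
#' plus the species partition used for diagnostic scanning.
#'
#' @param sequences named list, one element per locus, each a named character
#'   vector of equal-length aligned sequences (names are isolate ids).
#' @param partition named character vector mapping isolate id to species
#'   name. Isolates present in `sequences` but absent from `partition` are
#'   kept and flagged `"unassigned"`.
#' @return object of class `multilocus_alignment` with fields `loci`,
#'   `sequences`, `partition`.
#' @export
multilocus_alignment <- function(sequences, partition) {
  stopifnot(is.list(sequences), length(sequences) > 0,
            !is.null(names(sequences)))
  for (locus in names(sequences)) {
    s <- sequences[[locus]]
    if (is.null(names(s)) || any(!nzchar(names(s)))) {
      stop("sequences in locus '", locus, "' must be named by isolate id")
    }
    if (length(unique(nchar(s))) > 1) {
      stop("unequal sequence lengths within locus '", locus, "'")
    }
  }
  stopifnot(is.character(partition), !is.null(names(partition)))
  ids <- unique(unlist(lapply(sequences, names), use.names = FALSE))
  missing <- setdiff(ids, names(partition))
  if (length(missing) > 0) {
    partition[missing] <- "unassigned"
  }
  structure(
    list(loci = names(sequences), sequences = sequences,
         partition = partition[ids]),
    class = "multilocus_alignment"
  )
}

#' @export
print.multilocus_alignment <- function(x, ...) {
  cat("multilocus_alignment:", length(x$loci), "loci,",
      length(x$partition), "isolates\n")
  for (locus in x$loci) {
    cat(sprintf("  %-8s %3d seqs x %4d bp\n", locus,
                length(x$sequences[[locus]]),
                nchar(x$sequences[[locus]][1])))
  }
  tab <- table(x$partition)
  cat("  species:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Read a species-specific primer table
#'
#' Expects a TSV with columns `set_name`, `target_species`, `forward`,
#' `reverse`, `amplicon_length`, `cycles`; an optional `locus` column names
#' the assay's template locus. Primer strings must be pure A/C/G/T.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per primer set.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("set_name", "target_species", "forward", "reverse",
                "amplicon_length", "cycles")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("primer table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"locus" %in% names(df)) df$locus <- NA_character_
  df$forward <- toupper(df$forward)
  df$reverse <- toupper(df$reverse)
  for (col in c("forward", "reverse")) {
    bad <- grepl("[^ACGT]", df[[col]])
    if (any(bad)) {
      stop("non-ACGT character in ", col, " primer of set '",
           df$set_name[which(bad)[1]], "'")
    }
  }
  if (any(df$cycles <= 0)) stop("cycles must be > 0")
  if (any(df$amplicon_length <= 0)) stop("amplicon_length must be > 0")
  df[c("set_name", "target_species", "locus", "forward", "reverse",
       "amplicon_length", "cycles")]
}

#' Write a primer table as TSV
#'
#' @param primers data.frame in the [read_primer_table()] schema.
#' @param path output path.
#' @param header optional character vector of comment lines (without `#`)
#'   written above the table.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(primers, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(primers, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a location x category count table
#'
#' CSV with row labels in the first column and non-negative integer counts in
#' the remaining columns. Rows or columns labelled `total` (or ending in
#' `" total"`, case-insensitive) are stripped: they are marginals,
#' re-derivable from the body of the table.
#'
#' @param path path to the CSV file.
#' @return integer matrix with row and column names.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        comment.char = "#")
  if (ncol(df) < 2) stop("count table needs a label column and >=1 count column")
  labels <- as.character(df[[1]])
  body <- df[-1]
  is_total <- function(x) grepl("(^|\\s)total$", trimws(x), ignore.case = TRUE)
  keep_rows <- !is_total(labels)
  keep_cols <- !is_total(names(body))
  body <- body[keep_rows, keep_cols, drop = FALSE]
  labels <- labels[keep_rows]
  m <- as.matrix(body)
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop("invalid count '", m[bad[1], j], "' at row '", labels[bad[1]],
           "', column '", colnames(m)[j], "' (non-negative integer required)")
    }
  }
  out <- matrix(as.integer(m), nrow = nrow(m),
                dimnames = list(labels, colnames(m)))
  out
}

#' Write a count table as CSV
#'
#' @param counts integer matrix with dimnames, as from [read_count_table()].
#' @param path output path.
#' @param label name for the row-label column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, label = "location") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged primer sets for the Chrysogenum complex
#'
#' The four published species-specific assays (benA_Chrysogenum, crt1_Rubens,
#' crt1_Chainii, parA_Floreyii) with their expected amplicon lengths and
#' optimised cycle numbers.
#'
#' @return data.frame in the [read_primer_table()] schema.
#' @export
complex_primer_sets <- function() {
  read_primer_table(system.file("extdata", "table1_primers.tsv",
                                package = "chrysodiag", mustWork = TRUE))
}

#' Packaged London isolate survey counts
#'
#' Distribution of 430 Penicillium isolates (P. chrysogenum / P. rubens /
#' other Penicillium) across 18 sampling sites in London and the Underground,
#' optionally aggregated to the five location groups (Bakerloo Line, Central
#' Line, Jubilee Line, St Mary's Hospital, Outdoors).
#'
#' @param by `"station"` for the per-site table, `"group"` for location-group
#'   totals.
#' @return integer count matrix (rows = locations, columns = chrysogenum,
#'   rubens, other).
#' @export
london_survey_counts <- function(by = c("group", "station")) {
  by <- match.arg(by)
  counts <- read_count_table(system.file("extdata", "table2_stations.csv",
                                         package = "chrysodiag",
                                         mustWork = TRUE))
  if (by == "station") return(counts)
  groups <- utils::read.delim(
    system.file("extdata", "table2_station_groups.tsv",
                package = "chrysodiag", mustWork = TRUE),
    stringsAsFactors = FALSE)
  g <- groups$group[match(rownames(counts), groups$station)]
  if (anyNA(g)) stop("station missing from group map")
  out <- rowsum(counts, g, reorder = FALSE)
  out[unique(groups$group), , drop = FALSE]
}
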