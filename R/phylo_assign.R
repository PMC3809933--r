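isTRUE_vec <- function(x) !is.na(x) & x

# Distance-based species assignment against type isolates, neighbour-joining
# trees for inspection, and fixed-clock conversion of node heights to
# calendar ages.
#
# Distances use strict pairwise deletion: for each sequence pair, any site
# where either sequence carries a gap, N or other ambiguity code is dropped
# before counting differences. JC69 and K80 are the standard closed-form
# corrections; "maximum likelihood distances" in typical tree software with
# an unstated model are approximated here by JC69 (default) or K80.

#' Pairwise distance matrix under simple substitution models
#'
#' Models: `"p"` = mismatch fraction over compared sites; `"JC69"` =
#' -3/4 log(1 - 4p/3); `"K80"` = the two-parameter closed form
#' 1/2 log(1/(1-2P-Q)) + 1/4 log(1/(1-2Q)) from transition (P) and
#' transversion (Q) proportions. Pairs whose correction is undefined
#' (p >= 3/4 under JC69, or a non-positive log argument under K80) get `NA`.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param model `"p"`, `"JC69"` or `"K80"`.
#' @param min_overlap minimum number of jointly scored sites per pair;
#'   below it the pair's distance is `NA`.
#' @return symmetric distance matrix with zero diagonal, labelled by
#'   sequence names. The attribute `overlap` holds the per-pair count of
#'   compared sites.
#' @export
pairwise_distance <- function(seqs, model = c("p", "JC69", "K80"),
                              min_overlap = 1L) {
  model <- match.arg(model)
  stopifnot(is.character(seqs), length(seqs) >= 2, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1) stop("sequences must be aligned")
  m <- seq_char_matrix(seqs)
  clean <- m %in% c("A", "C", "G", "T")
  dim(clean) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  ov <- matrix(0L, n, n, dimnames = dimnames(d))
  purine <- m %in% c("A", "G")
  dim(purine) <- dim(m)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    use <- clean[i, ] & clean[j, ]
    L <- sum(use)
    ov[i, j] <- ov[j, i] <- L
    if (L < min_overlap) { d[i, j] <- d[j, i] <- NA_real_; next }
    diff <- m[i, use] != m[j, use]
    p <- sum(diff) / L
    val <- switch(model,
      p = p,
      JC69 = if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3),
      K80 = {
        ts <- sum(diff & (purine[i, use] == purine[j, use])) / L
        tv <- p - ts
        a1 <- 1 - 2 * ts - tv; a2 <- 1 - 2 * tv
        if (a1 <= 0 || a2 <= 0) NA_real_
        else 0.5 * log(1 / a1) + 0.25 * log(1 / a2)
      })
    d[i, j] <- d[j, i] <- val
  }
  attr(d, "overlap") <- ov
  attr(d, "model") <- model
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical NJ agglomeration on a symmetric distance matrix; the tree is
#' intended for visual inspection of species groupings (assignment itself is
#' done by nearest type isolate, see [assign_by_types()]).
#'
#' @param d symmetric numeric matrix with zero diagonal, >= 3 labels.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbour-joining needs >= 3 labels")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  ape::nj(d)
}

#' Write a tree in newick format
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Assign query isolates to species by nearest type isolate
#'
#' Per locus, each query is assigned to the species of its nearest type
#' isolate (with the margin to the runner-up species reported); the overall
#' call is that species if all informative loci agree, otherwise
#' `"discordant"`. Ties between species go to the lexicographically first
#' species and are flagged ambiguous; ambiguous loci carry no discriminating
#' signal (e.g. two species identical over the locus) and are ignored by the
#' concordance verdict — a query informative at no locus is called
#' `"ambiguous"` overall. Loci where a query shares fewer than `min_overlap`
#' scored sites with every type are marked `"untestable"`.
#'
#' @param queries named list: locus -> named character vector of query
#'   sequences (each locus aligned with the types of that locus).
#' @param types named list: locus -> named character vector of type-isolate
#'   sequences.
#' @param type_species named character vector mapping type isolate id ->
#'   species; every candidate species needs >= 1 type per locus.
#' @param model distance model passed to [pairwise_distance()].
#' @param min_overlap minimum jointly scored sites for a usable distance.
#' @return list with `per_locus` (data.frame isolate, locus, call, margin,
#'   ambiguous) and `overall` (data.frame isolate, call).
#' @export
assign_by_types <- function(queries, types, type_species,
                            model = c("JC69", "p", "K80"),
                            min_overlap = 50L) {
  model <- match.arg(model)
  stopifnot(is.list(queries), is.list(types),
            all(names(queries) %in% names(types)))
  per_locus <- list()
  for (locus in names(queries)) {
    q <- queries[[locus]]
    t <- types[[locus]]
    if (is.null(type_species[names(t)]) || anyNA(type_species[names(t)])) {
      stop("every type isolate needs a species label")
    }
    d <- pairwise_distance(c(q, t), model, min_overlap = 1L)
    ov <- attr(d, "overlap")
    for (iso in names(q)) {
      dt <- d[iso, names(t)]
      usable <- !is.na(dt) & ov[iso, names(t)] >= min_overlap
      if (!any(usable)) {
        per_locus[[length(per_locus) + 1]] <- data.frame(
          isolate = iso, locus = locus, call = "untestable",
          margin = NA_real_, ambiguous = NA, stringsAsFactors = FALSE)
        next
      }
      dt <- dt[usable]
      sp <- type_species[names(dt)]
      best_by_sp <- tapply(dt, sp, min)
      ord <- order(best_by_sp, names(best_by_sp))  # ties: first species
      call <- names(best_by_sp)[ord[1]]
      margin <- if (length(best_by_sp) > 1) {
        unname(best_by_sp[ord[2]] - best_by_sp[ord[1]])
      } else NA_real_
      ambiguous <- length(best_by_sp) > 1 &&
        isTRUE(all.equal(unname(best_by_sp[ord[1]]),
                         unname(best_by_sp[ord[2]])))
      per_locus[[length(per_locus) + 1]] <- data.frame(
        isolate = iso, locus = locus, call = call, margin = margin,
        ambiguous = ambiguous, stringsAsFactors = FALSE)
    }
  }
  per_locus <- do.call(rbind, per_locus)
  rownames(per_locus) <- NULL
  overall <- do.call(rbind, lapply(split(per_locus, per_locus$isolate),
    function(df) {
      informative <- df$call != "untestable" & !isTRUE_vec(df$ambiguous)
      calls <- unique(df$call[informative])
      call <- if (length(calls) == 1) calls
        else if (length(calls) > 1) "discordant"
        else if (any(df$call != "untestable")) "ambiguous"
        else "untestable"
      data.frame(isolate = df$isolate[1], call = call,
                 stringsAsFactors = FALSE)
    }))
  rownames(overall) <- NULL
  list(per_locus = per_locus, overall = overall)
}

#' Molecular-clock parameters
#'
#' @param subst_rate_per_site_per_year fixed mean substitution rate
#'   (default 3e-9/site/yr, the standard Eurotiomycete clock).
#' @return list of class `clock_params`.
#' @export
clock_params <- function(subst_rate_per_site_per_year = 3e-9) {
  if (subst_rate_per_site_per_year <= 0) {
    stop("substitution rate must be > 0")
  }
  structure(list(subst_rate_per_site_per_year = subst_rate_per_site_per_year),
            class = "clock_params")
}

#' Convert a node height to a divergence date
#'
#' Under a strict clock a node height in expected substitutions per site
#' divides by the rate to give an age in years: 2.25e-3 at 3e-9/yr is
#' 7.5e5 yr.
#'
#' @param height_subs_per_site node height (>= 0).
#' @param clock a [clock_params()] list.
#' @return age in years.
#' @export
node_height_to_years <- function(height_subs_per_site,
                                 clock = clock_params()) {
  if (any(height_subs_per_site < 0)) stop("node height must be >= 0")
  height_subs_per_site / clock$subst_rate_per_site_per_year
}
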