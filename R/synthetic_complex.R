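# Synthetic multilocus data for a cryptic four-species complex.
#
# The generator emulates the statistical structure the diagnostics assume:
# four in-group species that diverged ~0.75 million years ago under a fixed
# molecular clock of 3e-9 substitutions/site/yr, a more distant outgroup
# split (~2.75 MYA), four loci of a few hundred bp, low within-species
# polymorphism, and location-structured isolate panels with multinomial
# species proportions and ~1:1 mating types.

#' Configuration for the species-complex sequence simulator
#'
#' Defaults encode the stated world: a four-species in-group whose root is
#' 7.5e5 yr deep, secondary splits at 4.7e5 / 4.5e5 yr, an outgroup splitting
#' 2.75e6 yr ago, and a clock of 3e-9 substitutions/site/yr.
#'
#' @param species_names four in-group species names; the first two form one
#'   cherry (diverging at `split1`), the last two the other (`split2`), and
#'   the two cherries join at `root`. The default places chrysogenum with
#'   chainii and rubens with floreyi, the two-branch arrangement the
#'   divergence dating supports.
#' @param outgroup_names outgroup species names.
#' @param tree_heights_years named numeric: node heights in years for
#'   `root` (in-group crown), `split1` (first cherry), `split2` (second
#'   cherry) and `outgroup` (stem to the outgroups). Children must be
#'   shallower than parents.
#' @param subst_rate_per_site_per_year molecular-clock rate (default 3e-9).
#' @param locus_lengths named integer vector of locus lengths (bp, >= 50).
#' @param n_isolates_per_species isolates simulated per species (in-group and
#'   outgroup alike).
#' @param within_species_polymorphism expected pairwise diversity between two
#'   isolates of the same species (substitutions/site).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return object of class `complex_sim_config`.
#' @export
complex_sim_config <- function(
    species_names = c("chrysogenum", "chainii", "rubens", "floreyi"),
    outgroup_names = "flavigenum",
    tree_heights_years = c(root = 7.5e5, split1 = 4.5e5, split2 = 4.7e5,
                           outgroup = 2.75e6),
    subst_rate_per_site_per_year = 3e-9,
    locus_lengths = c(benA = 450L, trpC = 500L, crt1 = 600L, ITS = 550L),
    n_isolates_per_species = 10L,
    within_species_polymorphism = 1e-3,
    seed = 1L) {
  stopifnot(length(species_names) == 4, length(outgroup_names) >= 1,
            all(c("root", "split1", "split2", "outgroup") %in%
                  names(tree_heights_years)))
  h <- tree_heights_years
  if (any(h <= 0)) stop("tree heights must be positive")
  if (h["split1"] >= h["root"] || h["split2"] >= h["root"]) {
    stop("cherry splits must be shallower than the in-group root")
  }
  if (h["outgroup"] <= h["root"]) {
    stop("outgroup split must be deeper than the in-group root")
  }
  if (subst_rate_per_site_per_year <= 0) stop("substitution rate must be > 0")
  if (any(locus_lengths < 50)) stop("locus lengths must be >= 50 bp")
  if (within_species_polymorphism < 0) stop("polymorphism must be >= 0")
  structure(list(
    species_names = species_names,
    outgroup_names = outgroup_names,
    tree_heights_years = h,
    subst_rate_per_site_per_year = subst_rate_per_site_per_year,
    locus_lengths = locus_lengths,
    n_isolates_per_species = as.integer(n_isolates_per_species),
    within_species_polymorphism = within_species_polymorphism,
    seed = as.integer(seed)
  ), class = "complex_sim_config")
}

# Jukes-Cantor substitution along a branch of `d` expected subs/site:
# each site differs from its parent with probability 3/4 (1 - exp(-4d/3)),
# and a differing site takes one of the three other bases uniformly.
jc_evolve <- function(seq_chars, d) {
  p_diff <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- stats::runif(length(seq_chars)) < p_diff
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- seq_chars[hit]
    seq_chars[hit] <- vapply(cur, function(b) sample(setdiff(bases, b), 1),
                             character(1), USE.NAMES = FALSE)
  }
  seq_chars
}

# sprinkle Poisson(L * theta) random substitutions onto one isolate
add_polymorphism <- function(seq_chars, theta) {
  if (theta <= 0) return(seq_chars)
  n_mut <- stats::rpois(1, length(seq_chars) * theta)
  if (n_mut == 0) return(seq_chars)
  pos <- sample.int(length(seq_chars), min(n_mut, length(seq_chars)))
  bases <- c("A", "C", "G", "T")
  seq_chars[pos] <- vapply(seq_chars[pos],
                           function(b) sample(setdiff(bases, b), 1),
                           character(1), USE.NAMES = FALSE)
  seq_chars
}

#' Simulate multilocus alignments for the species complex
#'
#' Sequences evolve by a Jukes-Cantor process along the fixed species tree
#' `(outgroups, ((sp3, sp4)split2, (sp1, sp2)split1)root)` with branch
#' lengths `years x rate`; each isolate then receives independent Poisson
#' within-species substitutions so that the expected pairwise diversity
#' inside a species equals `within_species_polymorphism`.
#'
#' @param config a [complex_sim_config()].
#' @return list with `alignment` (a [multilocus_alignment()]; partition is
#'   the truth) and `truth` (named character vector isolate -> species).
#' @export
simulate_locus_alignments <- function(config) {
  stopifnot(inherits(config, "complex_sim_config"))
  set.seed(config$seed)
  mu <- config$subst_rate_per_site_per_year
  h <- config$tree_heights_years
  sp <- config$species_names
  # tip branch years: species 1,2 hang under split1; 3,4 under split2
  tip_parent <- c(h["split1"], h["split1"], h["split2"], h["split2"])
  names(tip_parent) <- sp
  n <- config$n_isolates_per_species
  theta <- config$within_species_polymorphism / 2
  all_species <- c(sp, config$outgroup_names)
  ids <- unlist(lapply(all_species, function(s) {
    sprintf("%s_%02d", s, seq_len(n))
  }))
  truth <- rep(all_species, each = n)
  names(truth) <- ids

  sequences <- list()
  for (locus in names(config$locus_lengths)) {
    L <- config$locus_lengths[[locus]]
    root_anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE) # at outgroup split
    ingroup_root <- jc_evolve(root_anc, mu * (h["outgroup"] - h["root"]))
    split1_anc <- jc_evolve(ingroup_root, mu * (h["root"] - h["split1"]))
    split2_anc <- jc_evolve(ingroup_root, mu * (h["root"] - h["split2"]))
    anc <- list(split1_anc, split1_anc, split2_anc, split2_anc)
    tips <- list()
    for (i in seq_along(sp)) {
      tips[[sp[i]]] <- jc_evolve(anc[[i]], mu * tip_parent[sp[i]])
    }
    for (og in config$outgroup_names) {
      tips[[og]] <- jc_evolve(root_anc, mu * h["outgroup"])
    }
    seqs <- character(0)
    for (s in all_species) {
      for (i in seq_len(n)) {
        iso <- add_polymorphism(tips[[s]], theta)
        seqs[sprintf("%s_%02d", s, i)] <- paste0(iso, collapse = "")
      }
    }
    sequences[[locus]] <- seqs
  }
  list(alignment = multilocus_alignment(sequences, truth), truth = truth,
       outgroups = config$outgroup_names)
}

#' Configuration for a location-structured isolate panel
#'
#' @param locations location names.
#' @param n_isolates named integer vector (per location) or single integer.
#' @param species_proportions named list: per location, a named probability
#'   vector over species labels (labels must exist in the complex alignment
#'   or be `"other"`, which draws from the outgroup isolates). Each vector
#'   must sum to 1.
#' @param mating_ratio probability of mating type MAT1-1 (default 0.5).
#' @param seed integer seed.
#' @return object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(locations, n_isolates, species_proportions,
                             mating_ratio = 0.5, seed = 1L) {
  if (length(n_isolates) == 1) {
    n_isolates <- stats::setNames(rep(n_isolates, length(locations)),
                                  locations)
  }
  stopifnot(all(locations %in% names(n_isolates)),
            all(locations %in% names(species_proportions)),
            mating_ratio > 0, mating_ratio < 1)
  if (any(n_isolates < 0)) stop("n_isolates must be >= 0")
  for (loc in locations) {
    pr <- species_proportions[[loc]]
    if (abs(sum(pr) - 1) > 1e-9) {
      stop("species proportions at '", loc, "' do not sum to 1")
    }
  }
  structure(list(locations = locations,
                 n_isolates = n_isolates[locations],
                 species_proportions = species_proportions[locations],
                 mating_ratio = mating_ratio, seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Simulate an isolate panel over sampling locations
#'
#' Species counts per location are a multinomial draw from the configured
#' proportions; mating types are Bernoulli(`mating_ratio`). Each isolate
#' carries the multilocus sequences of a randomly chosen simulated isolate of
#' its species (`"other"` draws from the outgroup species).
#'
#' @param config a [panel_sim_config()].
#' @param complex result of [simulate_locus_alignments()] (or a compatible
#'   list with `alignment` and `truth`).
#' @return object of class `isolate_panel`: list with `info` (data.frame:
#'   isolate_id, location, true_species, mating_type) and `sequences` (named
#'   list isolate -> named character vector per locus).
#' @export
simulate_isolate_panel <- function(config, complex) {
  stopifnot(inherits(config, "panel_sim_config"))
  aln <- complex$alignment
  truth <- complex$truth
  set.seed(config$seed)
  species_pool <- split(names(truth), truth)
  known <- names(species_pool)
  all_loc <- character(0); all_lab <- character(0); all_src <- character(0)
  for (loc in config$locations) {
    n <- config$n_isolates[[loc]]
    if (n == 0) next
    pr <- config$species_proportions[[loc]]
    labels <- names(pr)
    unknown <- setdiff(setdiff(labels, "other"), known)
    if (length(unknown) > 0) {
      stop("proportions at '", loc, "' reference unknown species: ",
           paste(unknown, collapse = ", "))
    }
    og <- if (!is.null(complex$outgroups)) complex$outgroups else
      setdiff(known, labels)  # fall back: species with no proportion label
    other_pool <- unlist(species_pool[intersect(og, known)],
                         use.names = FALSE)
    draw <- sample(labels, n, replace = TRUE, prob = pr)
    src <- vapply(draw, function(lab) {
      if (lab == "other") {
        if (length(other_pool) == 0) {
          stop("no outgroup isolates available for 'other'")
        }
        sample(other_pool, 1)
      } else sample(species_pool[[lab]], 1)
    }, character(1), USE.NAMES = FALSE)
    all_loc <- c(all_loc, rep(loc, n))
    all_lab <- c(all_lab, draw)
    all_src <- c(all_src, src)
  }
  n_tot <- length(all_lab)
  ids <- sprintf("iso_%04d", seq_len(n_tot))
  info <- data.frame(
    isolate_id = ids, location = all_loc, true_species = all_lab,
    mating_type = ifelse(stats::runif(n_tot) < config$mating_ratio,
                         "MAT1-1", "MAT1-2"),
    stringsAsFactors = FALSE)
  if (n_tot == 0) info$mating_type <- character(0)
  # per-locus lookup of the source isolate's sequence, then regroup by isolate
  by_locus <- lapply(aln$sequences, function(s) unname(s[all_src]))
  sequences <- lapply(seq_len(n_tot), function(i) {
    vapply(aln$loci, function(l) by_locus[[l]][i], character(1))
  })
  names(sequences) <- ids
  structure(list(info = info, sequences = sequences),
            class = "isolate_panel")
}

#' Estimate the complex divergence time from an alignment
#'
#' Computes Nei's net between-species divergence
#' \eqn{d_a = d_{xy} - (\pi_x + \pi_y)/2} from p-distances (averaged over
#' loci, weighted by locus length) and converts it to years under the fixed
#' clock: \eqn{\hat T = d_a / (2\mu)}.
#'
#' @param alignment a [multilocus_alignment()].
#' @param species_a,species_b the two species compared.
#' @param rate substitutions/site/yr (default 3e-9).
#' @return estimated divergence time in years.
#' @export
estimate_divergence_time <- function(alignment, species_a, species_b,
                                     rate = 3e-9) {
  stopifnot(inherits(alignment, "multilocus_alignment"), rate > 0)
  part <- alignment$partition
  ids_a <- names(part)[part == species_a]
  ids_b <- names(part)[part == species_b]
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    stop("species not present in the alignment partition")
  }
  num <- 0; den <- 0
  for (locus in alignment$loci) {
    seqs <- alignment$sequences[[locus]]
    L <- nchar(seqs[1])
    d <- pairwise_distance(seqs[c(ids_a, ids_b)], model = "p")
    dxy <- mean(d[ids_a, ids_b])
    pia <- if (length(ids_a) > 1) mean(d[ids_a, ids_a][lower.tri(diag(length(ids_a)))]) else 0
    pib <- if (length(ids_b) > 1) mean(d[ids_b, ids_b][lower.tri(diag(length(ids_b)))]) else 0
    num <- num + L * (dxy - (pia + pib) / 2)
    den <- den + L
  }
  (num / den) / (2 * rate)
}
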