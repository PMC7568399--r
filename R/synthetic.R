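#' Simulate a protein family along a known tree
#'
#' Evolves an ancestral sequence down a rooted tree under a Poisson
#' substitution process: along an edge of length `l`, each site substitutes
#' with probability `1 - exp(-rate * l)`, the replacement drawn uniformly
#' from the other 19 residues. The simulation is indel-free, so the leaves
#' form a gap-free alignment whose ground truth (tree, ancestor, event log)
#' is known exactly.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param ancestral Ancestral sequence over the 20-letter alphabet.
#' @param rate Substitutions per site per unit branch length (> 0).
#' @param seed Optional integer seed (deterministic output under a fixed
#'   seed).
#' @param query_id Which leaf to designate as the family query (default:
#'   first tip).
#' @return A `simulated_family`: list with `family` ([aligned_family]),
#'   `tree`, `ancestral`, and `events` (data.frame: node, site, from, to).
#' @export
simulate_family <- function(tree, ancestral, rate = 1, seed = NULL,
                            query_id = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (rate <= 0) pc_error("rate must be > 0", "validation_error")
  anc <- strsplit(toupper(ancestral), "", fixed = TRUE)[[1]]
  if (!all(anc %in% AA_ALPHABET))
    pc_error("ancestral sequence must use the 20-letter alphabet",
             "validation_error")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  nseq <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  nseq[[root]] <- anc
  ev <- list()
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    s <- nseq[[par]]
    p <- 1 - exp(-rate * tree$edge.length[e])
    hit <- which(stats::runif(length(s)) < p)
    for (i in hit) {
      from <- s[i]
      s[i] <- sample(setdiff(AA_ALPHABET, from), 1L)
      ev[[length(ev) + 1L]] <- data.frame(node = child, site = i, from = from,
                                          to = s[i], stringsAsFactors = FALSE)
    }
    nseq[[child]] <- s
  }
  seqs <- vapply(seq_len(ntip), function(i) paste(nseq[[i]], collapse = ""),
                 character(1))
  names(seqs) <- tree$tip.label
  if (is.null(query_id)) query_id <- tree$tip.label[1]
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(node = integer(0), site = integer(0), from = character(0),
               to = character(0), stringsAsFactors = FALSE)
  structure(list(family = aligned_family(seqs, query_id), tree = tree,
                 ancestral = ancestral, events = events),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf("simulated_family: %d leaves, %d sites, %d substitution events\n",
              length(x$family$seqs), x$family$alignment_length, nrow(x$events)))
  invisible(x)
}

#' Oversample a clade to create a deliberately biased family
#'
#' Emulates database over-representation of a subfamily: `extra_copies`
#' near-identical descendants (branch length 1e-4) are attached inside the
#' chosen clade, and a clade-specific substitution is planted at
#' `n_planted` sites — every member of the clade (and its copies) receives
#' a residue different from the ancestral one, while all outside leaves
#' keep the ancestral residue. With enough copies the planted residue wins
#' a plain majority consensus while branch weighting still recovers the
#' ancestor, which is the bias this package exists to remove.
#'
#' @param sim A `simulated_family`.
#' @param clade Internal node number, or a character vector of tip labels
#'   whose most recent common ancestor defines the clade. Must not be the
#'   root.
#' @param extra_copies Number of near-identical copies to add (0 is a
#'   no-op).
#' @param seed Optional integer seed.
#' @param n_planted Number of planted clade-specific sites (default 1).
#' @return A `simulated_family` with updated `family` and `tree`, plus a
#'   `planted` data.frame (site, ancestral_residue, planted_residue) and
#'   `clade_ids` (labels of the oversampled leaves, copies included).
#' @export
bias_family <- function(sim, clade, extra_copies, seed = NULL, n_planted = 1) {
  stopifnot(inherits(sim, "simulated_family"))
  if (extra_copies == 0) return(sim)
  if (extra_copies < 0) pc_error("extra_copies must be >= 0", "config_error")
  if (!is.null(seed)) set.seed(seed)
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (is.character(clade))
    clade <- ape::getMRCA(tree, clade)
  if (clade == root)
    pc_error("cannot oversample the root clade (whole family)", "config_error")
  clade_tips <- tree$tip.label[phangorn::Descendants(tree, clade, "tips")[[1]]]
  rep_tip <- setdiff(clade_tips, sim$family$query_id)[1]
  if (is.na(rep_tip))
    pc_error("clade contains only the query", "config_error")

  seqs <- sim$family$seqs
  anc <- strsplit(sim$ancestral, "", fixed = TRUE)[[1]]
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  outside <- setdiff(names(seqs), clade_tips)

  # plant clade-specific substitutions at sites still ancestral outside
  eligible <- which(vapply(seq_along(anc), function(s)
    all(mat[outside, s] == anc[s]), logical(1)))
  if (length(eligible) < n_planted)
    pc_error("not enough sites ancestral outside the clade to plant", "config_error")
  planted_at <- sort(sample(eligible, n_planted))
  planted <- data.frame(site = planted_at,
                        ancestral_residue = anc[planted_at],
                        planted_residue = NA_character_,
                        stringsAsFactors = FALSE)
  for (r in seq_len(n_planted)) {
    s <- planted_at[r]
    y <- sample(setdiff(AA_ALPHABET, anc[s]), 1L)
    mat[clade_tips, s] <- y
    planted$planted_residue[r] <- y
  }
  seqs <- apply(mat, 1, paste, collapse = "")

  copy_ids <- paste0(rep_tip, "_dup", seq_len(extra_copies))
  p_sub <- 1 - exp(-1e-4)
  for (i in seq_len(extra_copies)) {
    s <- strsplit(seqs[[rep_tip]], "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(s)) < p_sub)
    for (h in hit) s[h] <- sample(setdiff(AA_ALPHABET, s[h]), 1L)
    seqs[copy_ids[i]] <- paste(s, collapse = "")
    graft <- ape::read.tree(text = sprintf("(%s:1e-4);", copy_ids[i]))
    tree <- ape::bind.tree(tree, graft,
                           where = match(rep_tip, tree$tip.label),
                           position = 1e-4)
  }
  structure(list(family = aligned_family(seqs, sim$family$query_id),
                 tree = tree, ancestral = sim$ancestral, events = sim$events,
                 planted = planted,
                 clade_ids = c(clade_tips, copy_ids)),
            class = "simulated_family")
}

#' Simulate a thermal-inactivation decay curve
#'
#' `y(t) = 100 exp(k t) (1 + eps)`, `eps ~ Normal(0, noise_sigma)`
#' (multiplicative noise), clipped to `[0, 120]` activity percent.
#'
#' @param k First-order inactivation rate in 1/min (negative).
#' @param times Sampling times in minutes (strictly increasing).
#' @param noise_sigma Multiplicative noise s.d. as a fraction (default 0).
#' @param seed Optional integer seed.
#' @param variant Variant label for the curve metadata.
#' @return A decay [assay_curve()].
#' @export
simulate_decay <- function(k, times, noise_sigma = 0, seed = NULL,
                           variant = NA_character_) {
  if (k >= 0) pc_error("k must be negative (decay)", "validation_error")
  if (!is.null(seed)) set.seed(seed)
  y <- 100 * exp(k * times) * (1 + stats::rnorm(length(times), 0, noise_sigma))
  y <- pmin(pmax(y, 0), 120)
  assay_curve("decay", times, y, variant = variant)
}

#' Simulate a T50 thermal-inactivation profile
#'
#' Boltzmann sigmoid `A2 + (A1 - A2)/(1 + exp((T - t50)/dT))` sampled over
#' `temps`, with optional additive noise in activity percent.
#'
#' @param t50 Inflection temperature in C.
#' @param dT Transition width in C (default 2).
#' @param temps Incubation temperatures (default 35 to 70 C in 2.5 C steps).
#' @param A1,A2 High and low plateaus in percent (default 100 and 0).
#' @param noise_sigma Additive noise s.d. in activity percent (default 0).
#' @param seed Optional integer seed.
#' @param variant Variant label.
#' @return A t50 [assay_curve()].
#' @export
simulate_t50 <- function(t50, dT = 2, temps = seq(35, 70, by = 2.5),
                         A1 = 100, A2 = 0, noise_sigma = 0, seed = NULL,
                         variant = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  y <- A2 + (A1 - A2) / (1 + exp((temps - t50) / dT))
  y <- y + stats::rnorm(length(temps), 0, noise_sigma)
  y <- pmin(pmax(y, 0), 120)
  assay_curve("t50", temps, y, variant = variant)
}

#' Simulate a nanoDSF melting curve
#'
#' Two-state unfolding: the 350/330 nm ratio interpolates between a folded
#' and an unfolded baseline with logistic fraction unfolded
#' `f(T) = 1/(1 + exp((midpoint - T)/width))`; with flat baselines the
#' first-derivative peak sits exactly at `midpoint`.
#'
#' @param midpoint Melting midpoint in C (within the ramp).
#' @param width Transition width in C (default 2.5).
#' @param temps Ramp temperatures (default 20 to 95 C in 1 C steps,
#'   emulating a 1 C/min ramp).
#' @param baseline_low,baseline_high Folded / unfolded baseline intercepts
#'   (default 0.85 and 1.05, typical 350/330 ratios).
#' @param slope_low,slope_high Baseline slopes per C (default 0).
#' @param noise_sigma Additive noise s.d. in ratio units (default 0).
#' @param seed Optional integer seed.
#' @param variant Variant label.
#' @return A melt [assay_curve()].
#' @export
simulate_melt <- function(midpoint, width = 2.5, temps = seq(20, 95, by = 1),
                          baseline_low = 0.85, baseline_high = 1.05,
                          slope_low = 0, slope_high = 0, noise_sigma = 0,
                          seed = NULL, variant = NA_character_) {
  if (midpoint < min(temps) || midpoint > max(temps))
    pc_error("midpoint must lie within the thermal ramp", "validation_error")
  if (!is.null(seed)) set.seed(seed)
  f <- 1 / (1 + exp((midpoint - temps) / width))
  y <- (baseline_low + slope_low * temps) * (1 - f) +
    (baseline_high + slope_high * temps) * f
  y <- y + stats::rnorm(length(temps), 0, noise_sigma)
  assay_curve("melt", temps, y, variant = variant)
}
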