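# Fixture builders shared across the suite. Everything is generated in code;
# no binary files are stored.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  for (id in names(seqs)) writeLines(c(paste0(">", id), seqs[[id]]), con)
  close(con)
  path
}

write_clustal <- function(seqs, path = tempfile(fileext = ".aln")) {
  width <- max(nchar(names(seqs))) + 4
  lines <- c("CLUSTAL W (2.1) multiple sequence alignment", "", "")
  n <- nchar(seqs[[1]])
  for (start in seq(1, n, by = 60)) {
    chunk <- vapply(seqs, substr, "", start, min(start + 59, n))
    lines <- c(lines,
               sprintf(paste0("%-", width, "s%s"), names(seqs), chunk), "")
  }
  writeLines(lines, path)
  path
}

# Minimal PDB writer: atoms is a data.frame with columns
# resno, resid, elety, x, y, z, elem and optionally alt, occ.
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb"),
                          chain = "A") {
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    name4 <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety) else a$elety
    sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name4, a$alt, a$resid, chain, a$resno,
            a$x, a$y, a$z, a$occ, 0, a$elem)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# A balanced 8-leaf tree used by the simulation-based tests.
balanced8 <- function(bl = 0.05) {
  nwk <- gsub("L", sprintf("%g", bl), paste0(
    "(((A:L,B:L):L,(C:L,D:L):L):L,",
    "((E:L,F:L):L,(G:L,H:L):L):L);"))
  ape::read.tree(text = nwk)
}

# Least-squares branch lengths of a fixed topology against a distance
# matrix; returns the residual sum of squares. Used to pick the best
# topology by exhaustive enumeration (the brute-force oracle for NJ).
topology_rss <- function(topo, D) {
  tips <- topo$tip.label
  n <- length(tips)
  pairs <- t(utils::combn(n, 2))
  nedge <- nrow(topo$edge)
  A <- matrix(0, nrow(pairs), nedge)
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    path_nodes <- ape::nodepath(topo, i, j)
    for (s in seq_len(length(path_nodes) - 1L)) {
      e <- which((topo$edge[, 1] == path_nodes[s] & topo$edge[, 2] == path_nodes[s + 1]) |
                 (topo$edge[, 2] == path_nodes[s] & topo$edge[, 1] == path_nodes[s + 1]))
      A[r, e] <- 1
    }
    d[r] <- D[tips[i], tips[j]]
  }
  fit <- stats::lm.fit(A, d)
  sum(fit$residuals^2)
}

# Exhaustive best topology for a distance matrix over <= 6 taxa.
best_topology_bruteforce <- function(D) {
  labs <- rownames(D)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(topos, topology_rss, numeric(1), D = D)
  topos[[which.min(rss)]]
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

uniform_weights <- function(family) {
  ids <- names(family$seqs)
  stats::setNames(rep(1 / length(ids), length(ids)), ids)
}

top_residue <- function(profile, position) {
  colnames(profile$freq)[which.max(profile$freq[position, ])]
}
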