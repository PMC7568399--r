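#' Run the full consensus-design pipeline
#'
#' One reproducible run of: homolog filtering, pairwise distances,
#' neighbor-joining, outgroup rooting, branch weighting, weighted consensus,
#' candidate nomination, and (when a structure is supplied) structural
#' filtering. Writes the candidate table, the rooted tree, the sequence
#' weights, the homolog filter report, and a manifest echoing the
#' configuration, so a run can be replayed bit-identically.
#'
#' @param alignment Path to a FASTA/Clustal alignment, or an
#'   [aligned_family].
#' @param query_id Query sequence id.
#' @param outgroup_id Optional outgroup id used to root the tree (excluded
#'   from weights and consensus). Without it the tree is rooted on the
#'   longest terminal edge's leaf, which is reported in the manifest.
#' @param out_dir Output directory (created if missing).
#' @param structure_path Optional PDB path of the query structure; when
#'   `NULL`, structural filtering is skipped with a warning.
#' @param active_site Active-site query positions (required with a
#'   structure).
#' @param format Alignment format, `"fasta"` or `"clustal"`.
#' @param min_identity,length_tolerance Homolog filter settings (see
#'   [filter_homologs()]).
#' @param cutoff Consensus frequency cutoff in percent (default 40).
#' @param min_distance Active-site exclusion radius in Angstrom (default 6).
#' @param hbond_max,salt_max Bond thresholds in Angstrom.
#' @param chain,offset Structure mapping (see [load_structure()]).
#' @return Invisibly, a list with `family`, `tree`, `weights`, `profile`,
#'   `candidates`, and `paths` of the written files.
#' @export
run_design <- function(alignment, query_id, out_dir, outgroup_id = NULL,
                       structure_path = NULL, active_site = NULL,
                       format = "fasta", min_identity = 0.5,
                       length_tolerance = 0.2, cutoff = 40,
                       min_distance = 6.0, hbond_max = 3.5, salt_max = 4.0,
                       chain = "A", offset = 0) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  out <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("pipeline_error", class(e))))
    })
  }

  family <- stage("read_alignment", {
    if (inherits(alignment, "aligned_family")) alignment
    else read_alignment(alignment, query_id, format)
  })
  family <- stage("filter_homologs",
    filter_homologs(family, min_identity, length_tolerance,
                    report_path = out("filter_report.tsv")))
  D <- stage("distance_matrix", distance_matrix(family))
  tree <- stage("neighbor_joining", neighbor_joining(D))
  if (is.null(outgroup_id)) {
    tip_edges <- match(seq_along(tree$tip.label), tree$edge[, 2])
    root_leaf <- tree$tip.label[which.max(tree$edge.length[tip_edges])]
  } else {
    root_leaf <- outgroup_id
  }
  rooted <- stage("root_with_outgroup", root_with_outgroup(tree, root_leaf))
  stage("write_tree", write_newick(rooted, out("tree.nwk")))
  weights <- stage("branch_weights", branch_weights(rooted, outgroup_id))
  stage("write_weights", write_weights(weights, out("weights.tsv")))
  profile <- stage("column_frequencies", column_frequencies(family, weights))
  stage("write_profile", write_consensus_tsv(profile, out("profile.tsv")))
  candidates <- stage("candidate_sites", candidate_sites(profile, cutoff))
  if (!is.null(structure_path)) {
    model <- stage("load_structure", {
      q <- ungap(family$seqs[[family$query_id]])
      load_structure(structure_path, query = q, chain = chain, offset = offset)
    })
    candidates <- stage("apply_structural_filters",
      apply_structural_filters(candidates, model, active_site,
                               min_distance, hbond_max, salt_max))
  } else {
    pc_warning("no structure supplied; structural filtering skipped",
               "config_warning")
  }
  stage("write_candidates", write_consensus_tsv(candidates, out("candidates.tsv")))

  manifest <- c(
    sprintf("phyloconsensus_version=%s",
            as.character(utils::packageVersion("phyloconsensus"))),
    sprintf("query_id=%s", query_id),
    sprintf("outgroup_id=%s", if (is.null(outgroup_id)) "" else outgroup_id),
    sprintf("root_leaf=%s", root_leaf),
    sprintf("min_identity=%g", min_identity),
    sprintf("length_tolerance=%g", length_tolerance),
    sprintf("consensus_cutoff_pct=%g", cutoff),
    sprintf("min_active_site_distance_A=%g", min_distance),
    sprintf("hbond_max_A=%g", hbond_max),
    sprintf("salt_max_A=%g", salt_max),
    sprintf("structure=%s", if (is.null(structure_path)) "" else structure_path),
    sprintf("n_sequences=%d", length(family$seqs)),
    sprintf("n_candidates=%d", nrow(candidates)))
  writeLines(manifest, out("manifest.txt"))
  ok <- TRUE
  invisible(list(family = family, tree = rooted, weights = weights,
                 profile = profile, candidates = candidates,
                 paths = written))
}
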