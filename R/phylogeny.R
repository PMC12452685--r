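#' UPGMA tree from a distance matrix
#'
#' Agglomerative clustering with arithmetic-mean (average) linkage; the
#' closest pair is merged iteratively and each internal node sits at half
#' the merge distance, giving an ultrametric (rooted, clock-like) tree.
#'
#' @param dm Symmetric, non-negative distance matrix with zero diagonal
#'   (labelled), or a `dist` object.
#' @return An object of class `upgma_tree` wrapping an `ape` phylo tree
#'   plus the merge structure used for cluster cutting.
#' @export
upgma <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm))
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (nrow(dm) < 2) stop("need at least 2 leaves")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distances must be non-negative")
  if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero")
  if (any(!is.finite(dm))) stop("distances must be finite")
  if (is.null(rownames(dm)))
    rownames(dm) <- colnames(dm) <- paste0("L", seq_len(nrow(dm)))
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(phylo = phy, hclust = hc, labels = hc$labels),
            class = "upgma_tree")
}

#' Guide tree for progressive alignment
#'
#' Identical to [upgma()]; the UPGMA tree doubles as the guide tree that
#' orders the profile merges of [progressive_align()].
#'
#' @inheritParams upgma
#' @return An `upgma_tree`.
#' @export
build_guide_tree <- function(dm) upgma(dm)

as_phylo <- function(tree) {
  if (inherits(tree, "upgma_tree")) return(tree$phylo)
  if (inherits(tree, "phylo")) return(tree)
  stop("not a tree object")
}

#' @export
print.upgma_tree <- function(x, ...) {
  phy <- x$phylo
  cat(sprintf("<upgma_tree> %d leaves, root height %.4f\n",
              length(phy$tip.label), max(tree_node_heights(x))))
  invisible(x)
}

# height above the leaves of every node (leaves are at 0 for an
# ultrametric tree); vector indexed by ape node id
tree_node_heights <- function(tree) {
  phy <- as_phylo(tree)
  depth <- ape::node.depth.edgelength(phy)
  max(depth) - depth
}

#' Serialize a tree to Newick
#'
#' @param tree An `upgma_tree` or `phylo` object.
#' @return A single Newick string with branch lengths.
#' @export
to_newick <- function(tree) {
  ape::write.tree(as_phylo(tree))
}

#' Parse a Newick string
#'
#' Parenthesis balance is checked first so malformed input fails with the
#' offending character position.
#'
#' @param text A Newick string.
#' @return An `upgma_tree` (without merge structure; cluster cutting works
#'   directly on the tree topology).
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0) stop("malformed Newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0) stop("malformed Newick: ", depth, " unclosed '(' at end")
  if (!grepl(";\\s*$", text)) stop("malformed Newick: missing final ';'")
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy)) stop("malformed Newick: could not be parsed")
  structure(list(phylo = phy, hclust = NULL, labels = phy$tip.label),
            class = "upgma_tree")
}

#' Cut an ultrametric tree into k monophyletic clusters
#'
#' Removes the k-1 highest internal nodes; each remaining subtree is a
#' cluster. Clusters are numbered by the order in which their first leaf
#' appears among the tree's leaf labels.
#'
#' @param tree An `upgma_tree`.
#' @param k Number of clusters, `1 <= k <=` leaf count.
#' @return A named integer vector (leaf -> cluster id, class
#'   `cluster_assignment`) with attributes `k` and `cut_height`.
#' @export
cut_clusters <- function(tree, k) {
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  if (!is.null(tree$hclust)) {
    cl <- stats::cutree(tree$hclust, k = k)
    cl <- stats::setNames(match(cl, unique(cl)), names(cl))
    h <- sort(tree$hclust$height, decreasing = TRUE) / 2
  } else {
    cl <- cut_phylo(phy, k)
    hts <- tree_node_heights(tree)
    h <- sort(hts[(n + 1):(n + phy$Nnode)], decreasing = TRUE)
  }
  cut_height <- if (k == 1) Inf else h[k - 1]
  structure(as.integer(cl), names = names(cl), k = k,
            cut_height = cut_height, class = "cluster_assignment")
}

# cluster cutting on a plain phylo: drop the k-1 highest internal nodes,
# take the connected subtrees that remain
cut_phylo <- function(phy, k) {
  n <- length(phy$tip.label)
  hts <- tree_node_heights(phy)
  internal <- (n + 1):(n + phy$Nnode)
  removed <- internal[order(-hts[internal], internal)][seq_len(k - 1)]
  parent <- rep(NA_integer_, n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root_of <- function(leaf) {
    node <- leaf
    while (!is.na(parent[node]) && !(parent[node] %in% removed))
      node <- parent[node]
    node
  }
  roots <- vapply(seq_len(n), root_of, integer(1))
  ids <- match(roots, unique(roots))  # numbered by first leaf appearance
  stats::setNames(ids, phy$tip.label)
}

#' Group clusters into supergroups by shared ancestry
#'
#' Cuts the same tree into `groups` parts; each cluster (a complete
#' subtree) falls entirely inside one part, which becomes its supergroup
#' label (A, B, C, ... in order of first appearance).
#'
#' @param tree The `upgma_tree` the assignment came from.
#' @param assignment A `cluster_assignment` from [cut_clusters()].
#' @param groups Number of supergroups (default 4); must not exceed k.
#' @return Named character vector, cluster id -> group label.
#' @export
supergroup_clusters <- function(tree, assignment, groups = 4) {
  k <- attr(assignment, "k")
  if (groups > k) stop("group count (", groups, ") exceeds k (", k, ")")
  coarse <- cut_clusters(tree, groups)
  coarse <- coarse[names(assignment)]
  map <- integer(k)
  for (cl in seq_len(k)) {
    g <- unique(coarse[assignment == cl])
    if (length(g) != 1) stop("cluster ", cl, " spans multiple supergroups")
    map[cl] <- g
  }
  stats::setNames(LETTERS[match(map, unique(map))], seq_len(k))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d, cut height %.4f\n",
              attr(x, "k"), attr(x, "cut_height")))
  print(table(cluster = as.integer(x)))
  invisible(x)
}

#' Cluster composition by taxonomy class and ontology subtype
#'
#' Cross-tabulates a cluster assignment with the records' taxonomy classes
#' and grouped ontology subtypes, and summarizes the per-cluster fraction
#' of a focal subtype (median taken across all clusters, zeros included).
#'
#' @param assignment A `cluster_assignment`.
#' @param records The `gox_records` the leaves came from; every leaf must
#'   be present.
#' @param focal_subtype Subtype whose per-cluster fraction is summarized.
#' @return A list of class `cluster_composition`: `class_counts` and
#'   `subtype_counts` (cluster x label count matrices), `subtype_fractions`,
#'   `focal_fraction` (per-cluster vector) and `focal_median`.
#' @export
cluster_composition <- function(assignment, records,
                                focal_subtype = "(D-) amino acid dehydrogenase") {
  idx <- match(names(assignment), records$accession)
  if (anyNA(idx))
    stop("no record for leaf: ",
         paste(names(assignment)[is.na(idx)], collapse = ", "))
  rec <- records[idx, , drop = FALSE]
  cl <- factor(as.integer(assignment), levels = seq_len(attr(assignment, "k")))
  cls <- ifelse(nzchar(rec$tax_class), rec$tax_class, "unclassified")
  class_counts <- as.matrix(table(cluster = cl, class = cls))
  subtype_counts <- as.matrix(table(cluster = cl, subtype = rec$ontology_grouped))
  sizes <- as.integer(table(cl))
  subtype_fractions <- sweep(subtype_counts, 1, pmax(sizes, 1), "/")
  focal <- if (focal_subtype %in% colnames(subtype_fractions))
    subtype_fractions[, focal_subtype] else stats::setNames(rep(0, nlevels(cl)),
                                                            levels(cl))
  structure(list(class_counts = class_counts,
                 subtype_counts = subtype_counts,
                 subtype_fractions = subtype_fractions,
                 cluster_sizes = sizes,
                 focal_subtype = focal_subtype,
                 focal_fraction = focal,
                 focal_median = stats::median(focal)),
            class = "cluster_composition")
}

#' @export
print.cluster_composition <- function(x, ...) {
  cat("<cluster_composition>\n")
  print(x$class_counts)
  cat(sprintf("median %s fraction across clusters: %.4f\n",
              x$focal_subtype, x$focal_median))
  invisible(x)
}

#' Select representative sequences across clusters and subtypes
#'
#' Greedy coverage: the reference (when given) is always included, then
#' one record per ontology subtype and one per cluster, then the remainder
#' is filled proportionally to cluster size. Seeded and reproducible.
#'
#' @param records A `gox_records` data.frame.
#' @param assignment A `cluster_assignment` covering the records.
#' @param n Number of representatives.
#' @param seed Integer seed.
#' @param reference Accession always included, or NULL.
#' @return The selected subset of `records`.
#' @export
select_representatives <- function(records, assignment, n = 120, seed = 1,
                                   reference = NULL) {
  cl <- assignment[match(records$accession, names(assignment))]
  if (anyNA(cl)) stop("every record must be assigned to a cluster")
  subtypes <- unique(records$ontology_grouped)
  clusters <- sort(unique(as.integer(cl)))
  if (n < length(subtypes) + length(clusters))
    stop("n = ", n, " is infeasible: need at least ",
         length(subtypes) + length(clusters))
  if (n > nrow(records)) stop("n exceeds the number of records")
  set.seed(seed)
  chosen <- character(0)
  if (!is.null(reference)) {
    if (!reference %in% records$accession) stop("reference not in records")
    chosen <- reference
  }
  sample_one <- function(x) x[sample.int(length(x), 1)]
  for (st in subtypes) {
    pool <- records$accession[records$ontology_grouped == st]
    if (!any(pool %in% chosen))
      chosen <- c(chosen, sample_one(pool))
  }
  for (cc in clusters) {
    pool <- records$accession[as.integer(cl) == cc]
    if (!any(pool %in% chosen))
      chosen <- c(chosen, sample_one(pool))
  }
  left <- setdiff(records$accession, chosen)
  need <- n - length(chosen)
  if (need > 0) {
    sizes <- table(factor(as.integer(cl), levels = clusters))
    w <- as.numeric(sizes[as.character(cl[match(left, records$accession)])])
    chosen <- c(chosen, left[sample.int(length(left), need, prob = w)])
  }
  records[records$accession %in% chosen, , drop = FALSE]
}
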