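#' Concatenate the A, B and C subunit proteins of a cluster
#'
#' Always A then B then C, regardless of gene order on the genome (the
#' sub-type III cluster, transcribed C-A-B, concatenates identically to
#' the others). Uses the first member per role in canonical order.
#'
#' @param cluster A `gene_cluster`.
#' @param proteins Named character vector of protein sequences (e.g.
#'   `annotation$proteins`).
#' @return Single concatenated amino-acid string.
#' @export
concat_abc <- function(cluster, proteins) {
  co <- canonical_order(cluster)
  m <- co$members
  parts <- vapply(c("A", "B", "C"), function(role) {
    ids <- m$gene_id[m$role == role]
    if (!length(ids)) stop("cluster lacks subunit ", role,
                           " (was it retained?)")
    unname(proteins[[ids[[1]]]])
  }, character(1))
  paste(parts, collapse = "")
}

#' Alignment-free k-mer Jaccard distance matrix
#'
#' d(i, j) = 1 - |K_i intersect K_j| / |K_i union K_j| where K is the
#' set of amino-acid k-mers of a sequence. A deterministic pseudometric
#' used as a lightweight stand-in for alignment-based distances when
#' only a clustering cross-check is needed.
#'
#' @param seqs Named character vector of sequences (all of length >= k).
#' @param k k-mer length (default 4).
#' @return Symmetric numeric matrix with zero diagonal, dimnames from
#'   `seqs`.
#' @export
kmer_distance <- function(seqs, k = 4L) {
  stopifnot(length(seqs) >= 1L, k >= 1L)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  short <- nchar(seqs) < k
  if (any(short))
    stop("sequence(s) shorter than k: ",
         paste(names(seqs)[short], collapse = ", "))
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - inter / uni
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining; negative branch lengths are
#' clamped to zero. The matrix must be symmetric with at least three
#' labels.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 labels for a tree")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is asymmetric")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# All clades of an unrooted tree: for every edge, the leaf set on each
# side (tip sets of every node plus their complements).
unrooted_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tips_under <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tips_under[[i]] <- tree$tip.label[i]
  # edges are listed parent-before-child from the root; process in
  # reverse so children are resolved first
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    tips_under[[p]] <- c(tips_under[[p]], tips_under[[ch]])
  }
  sets <- lapply(tips_under, sort)
  all_tips <- sort(tree$tip.label)
  comp <- lapply(sets, function(s) setdiff(all_tips, s))
  unique(c(sets, comp[lengths(comp) > 0]))
}

#' Sub-type purity of tree leaves
#'
#' For each sub-type, finds the smallest clade (over all edges of the
#' unrooted tree, both directions) containing all of its leaves.
#' Purity = (sub-type size) / (smallest containing clade size); a
#' sub-type is monophyletic iff purity = 1.
#'
#' @param tree A `phylo` tree.
#' @param labels Named character vector mapping every leaf to a
#'   sub-type.
#' @return Object of class `purity_report`: data.frame `per_subtype`
#'   (subtype, n, clade_size, purity, monophyletic) and `mean_purity`.
#' @export
subtype_purity <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  unlabeled <- setdiff(tree$tip.label, names(labels))
  if (length(unlabeled))
    stop("unlabeled leaf/leaves: ", paste(unlabeled, collapse = ", "))
  labels <- labels[tree$tip.label]
  clades <- unrooted_clades(tree)
  per <- lapply(sort(unique(labels)), function(st) {
    members <- sort(tree$tip.label[labels == st])
    sizes <- vapply(clades, function(cl)
      if (all(members %in% cl)) length(cl) else NA_integer_, integer(1))
    smallest <- min(sizes, na.rm = TRUE)
    data.frame(subtype = st, n = length(members),
               clade_size = smallest,
               purity = length(members) / smallest,
               monophyletic = smallest == length(members),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_subtype = per, mean_purity = mean(per$purity)),
            class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  cat("<purity_report> mean purity ", sprintf("%.3f", x$mean_purity),
      "\n", sep = "")
  print(x$per_subtype, row.names = FALSE)
  invisible(x)
}
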