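B_SERIES <- c("B1", "B2", "B3", "B4", "B5")
A_SERIES <- c("A1", "A2", "A3", "A4", "A5")

#' Assign a subunit role from a declared domain architecture
#'
#' Roles of genes around a catalytic-subunit anchor are read off their
#' declared domain architectures: `A` for the anchor itself (an H-cluster
#' motif call); `T` for a sensory group C3 hydrogenase (H-cluster `2Fe`
#' domain together with `PAS` or `His_kinase_dom`); `B` for the
#' FMN-bearing bifurcating subunit (`FMN` plus at least one B-series FeS
#' label); `C` for the small FeS subunit (`C1` label); `D` when the
#' architecture equals the declared accessory-subunit architecture
#' (default a lone `Nqo1` SLBB domain); anything else is `X`. Precedence
#' A > T > B > C > D; multiply-matching architectures are flagged.
#'
#' @param domains Ordered character vector of domain labels (may be
#'   empty).
#' @param is_bfua Is this gene an H-cluster motif (BfuA) call?
#' @param d_architecture Declared D-subunit architecture.
#' @return Single role letter; attribute `"ambiguous"` is TRUE when more
#'   than one rule matched.
#' @export
assign_role <- function(domains, is_bfua = FALSE,
                        d_architecture = c("Nqo1")) {
  domains <- as.character(domains)
  matches <- c(
    A = isTRUE(is_bfua),
    T = ("2Fe" %in% domains) &&
      any(c("PAS", "His_kinase_dom") %in% domains),
    B = ("FMN" %in% domains) && any(B_SERIES %in% domains),
    C = "C1" %in% domains,
    D = length(domains) > 0 && setequal(domains, d_architecture)
  )
  role <- if (any(matches)) names(matches)[which(matches)[1]] else "X"
  attr(role, "ambiguous") <- sum(matches) > 1L
  role
}

#' Extract the gene neighborhood around a BfuA anchor
#'
#' Collects every gene whose rank along the anchor's contig lies within
#' `window` of the anchor's rank (genes, not base pairs), clips at
#' contig ends (setting `truncated`), and assigns each member a subunit
#' role. Members on the strand opposite the anchor are flagged
#' antisense but still participate in pattern matching. Other BfuA
#' calls falling inside the window keep role `X` here — each anchor
#' seeds its own cluster — and are flagged as overlapping anchors.
#'
#' @param annotation A [genome_annotation()] object.
#' @param anchor Gene id of the BfuA anchor.
#' @param window Neighborhood half-width in genes (default 5).
#' @param bfua_calls Optional precomputed [call_bfuA()] result.
#' @param d_architecture Declared D-subunit architecture, passed to
#'   [assign_role()].
#' @return Object of class `gene_cluster`: anchor, members table
#'   (gene_id, role, offset, strand, partial, antisense), canonical
#'   orientation (the anchor strand), truncation flag and partial roles.
#' @export
extract_neighborhood <- function(annotation, anchor, window = 5L,
                                 bfua_calls = NULL,
                                 d_architecture = c("Nqo1")) {
  stopifnot(inherits(annotation, "genome_annotation"), window >= 1L)
  g <- annotation$genes
  i <- match(anchor, g$gene_id)
  if (is.na(i)) stop("unknown anchor gene id: ", anchor)
  if (is.null(bfua_calls)) bfua_calls <- call_bfuA(annotation)
  ctg <- g$contig_id[i]
  r0 <- g$rank[i]
  on_ctg <- g[g$contig_id == ctg, , drop = FALSE]
  sel <- on_ctg[abs(on_ctg$rank - r0) <= window, , drop = FALSE]
  sel <- sel[order(sel$rank), , drop = FALSE]
  truncated <- (r0 - window) < 1L || (r0 + window) > max(on_ctg$rank)

  roles <- character(nrow(sel))
  ambiguous <- logical(nrow(sel))
  for (k in seq_len(nrow(sel))) {
    gid <- sel$gene_id[k]
    role <- assign_role(annotation$domains[[gid]],
                        is_bfua = identical(gid, anchor),
                        d_architecture = d_architecture)
    roles[k] <- as.character(role)
    ambiguous[k] <- isTRUE(attr(role, "ambiguous"))
  }
  overlapping <- sel$gene_id %in% setdiff(bfua_calls, anchor)

  members <- data.frame(
    gene_id = sel$gene_id, role = roles, offset = sel$rank - r0,
    strand = sel$strand, partial = sel$partial,
    antisense = sel$strand != g$strand[i],
    ambiguous = ambiguous, overlapping_anchor = overlapping,
    stringsAsFactors = FALSE)
  partial_roles <- unique(members$role[members$partial &
                                         members$role != "X"])
  structure(list(genome_id = annotation$genome_id, contig_id = ctg,
                 anchor = anchor, members = members,
                 canonical_orientation = g$strand[i],
                 truncated = truncated, partial_members = partial_roles),
            class = "gene_cluster")
}

#' @export
print.gene_cluster <- function(x, ...) {
  co <- canonical_order(x)
  cat("<gene_cluster> anchor ", x$anchor, " (", x$genome_id, ":",
      x$contig_id, ", strand ", x$canonical_orientation, ")\n",
      "  canonical roles: ", co$role_string,
      if (x$truncated) "  [window truncated]", "\n", sep = "")
  invisible(x)
}

#' Canonical role ordering of a cluster
#'
#' Orders members in the anchor's transcription direction (5'->3' of the
#' BfuA coding strand): coordinate order for a `+` anchor, reversed for
#' a `-` anchor. The same physical cluster therefore yields the same
#' role string regardless of which genomic strand carries it. The
#' reverse reading — the convention used when clusters are displayed on
#' the negative strand — is returned alongside.
#'
#' @param cluster A `gene_cluster`.
#' @return List with `members` (reordered table), `role_string`
#'   (non-X roles in canonical order) and `display_string` (the reverse
#'   reading).
#' @export
canonical_order <- function(cluster) {
  stopifnot(inherits(cluster, "gene_cluster"))
  m <- cluster$members[order(cluster$members$offset), , drop = FALSE]
  if (cluster$canonical_orientation == "-")
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  roles <- m$role[m$role != "X"]
  list(members = m,
       role_string = paste(roles, collapse = ""),
       display_string = paste(rev(roles), collapse = ""))
}

#' Reverse-complement a contig's gene layout
#'
#' Mirrors all gene coordinates on one contig and flips strands, as if
#' the contig had been assembled in the opposite orientation. Protein
#' sequences and domains are untouched. Canonical role strings,
#' sub-type labels and capability calls are invariant under this
#' transformation.
#'
#' @param annotation A [genome_annotation()] object.
#' @param contig_id Contig to flip.
#' @return A new `genome_annotation`.
#' @export
flip_contig <- function(annotation, contig_id) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ctg <- annotation$contigs
  L <- ctg$length[match(contig_id, ctg$contig_id)]
  if (is.na(L)) stop("unknown contig: ", contig_id)
  g <- annotation$genes
  sel <- g$contig_id == contig_id
  ns <- L - g$end[sel] + 1L
  ne <- L - g$start[sel] + 1L
  g$start[sel] <- ns
  g$end[sel] <- ne
  g$strand[sel] <- ifelse(g$strand[sel] == "+", "-", "+")
  genome_annotation(annotation$genome_id, g, annotation$proteins,
                    annotation$domains, ctg)
}
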