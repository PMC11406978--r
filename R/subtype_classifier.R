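SUBTYPE_PATTERNS <- c(I = "ABDC", II = "ABC", III = "CAB",
                      IV = "ABCT", V = "TABC")

#' Cluster-intactness retention filter
#'
#' A cluster is retained only when the bifurcating core is intact:
#' at least one non-partial B member whose architecture carries both
#' `FMN` and `B1`, and at least one non-partial C member carrying `C1`.
#' Clusters with no or an incomplete B or C subunit within the window
#' are dropped, with a reason code per failed condition (`no_B`,
#' `incomplete_B`, `no_C`, `incomplete_C`).
#'
#' @param cluster A `gene_cluster` (extracted with the default window).
#' @param annotation The [genome_annotation()] the cluster came from.
#' @return List with `retained` (logical) and `reasons` (character).
#' @export
intactness_filter <- function(cluster, annotation) {
  stopifnot(inherits(cluster, "gene_cluster"))
  m <- cluster$members
  reasons <- character()
  ok_member <- function(role, needed) {
    rows <- m[m$role == role, , drop = FALSE]
    if (!nrow(rows)) return(paste0("no_", role))
    good <- vapply(seq_len(nrow(rows)), function(k) {
      dom <- annotation$domains[[rows$gene_id[k]]]
      !rows$partial[k] && all(needed %in% dom)
    }, logical(1))
    if (!any(good)) paste0("incomplete_", role) else character()
  }
  reasons <- c(reasons, ok_member("B", c("FMN", "B1")),
               ok_member("C", "C1"))
  list(retained = length(reasons) == 0L, reasons = reasons)
}

#' Classify a retained cluster into sub-types I-V
#'
#' Matches the canonical (anchor-transcription-order) role string,
#' ignoring X members, against the five organizational patterns:
#' `ABDC` (I), `ABC` (II), `CAB` (III), `ABCT` (IV; the variant `ATBC`
#' with the sensory gene adjacent downstream of the anchor is also IV,
#' flagged `T_downstream_of_A`) and `TABC` (V, flagged
#' `T_upstream_of_A`). Clusters carrying both D and T, or two T genes
#' (flagged `double_T`), or matching no pattern, are `unclassified`
#' with a nearest-pattern reason. D-less `ABC` clusters are labelled II
#' and flagged `D_absent`; sub-type I calls are flagged `D_present`.
#'
#' @param cluster A `gene_cluster`.
#' @return List with `label`, `flags`, `reasons`.
#' @export
assign_subtype <- function(cluster) {
  co <- canonical_order(cluster)
  s <- co$role_string
  roles <- strsplit(s, "")[[1]]
  nT <- sum(roles == "T")
  hasD <- "D" %in% roles
  flags <- character()
  if (any(cluster$members$antisense)) flags <- c(flags, "antisense_member")
  if (cluster$truncated) flags <- c(flags, "truncated_window")

  nearest <- function(s) {
    d <- utils::adist(s, SUBTYPE_PATTERNS)[1, ]
    paste0("nearest_", names(SUBTYPE_PATTERNS)[which.min(d)])
  }
  unclassified <- function(reason)
    list(label = "unclassified", flags = flags, reasons = reason)

  if (nT >= 2L) {
    flags <- c(flags, "double_T")
    return(unclassified(c("double_T", nearest(gsub("T", "", s)))))
  }
  if (hasD && nT >= 1L) return(unclassified(c("D_and_T", nearest(s))))

  label <- switch(s,
    ABDC = "I",
    ABC  = "II",
    CAB  = "III",
    ABCT = "IV",
    ATBC = "IV",
    TABC = "V",
    NULL)
  if (is.null(label)) return(unclassified(nearest(s)))
  flags <- c(flags, switch(label,
    I  = "D_present",
    II = "D_absent",
    IV = if (s == "ATBC") "T_downstream_of_A",
    V  = "T_upstream_of_A"))
  list(label = label, flags = flags, reasons = character())
}

#' Filter and classify one cluster
#'
#' Runs [intactness_filter()] then, for retained clusters,
#' [assign_subtype()]. Unretained clusters keep label `unclassified`
#' with the rejection reasons.
#'
#' @inheritParams intactness_filter
#' @return Object of class `subtype_call`: cluster reference plus
#'   `retained`, `label`, `flags`, `reasons`, and the canonical /
#'   display role strings.
#' @export
classify_cluster <- function(cluster, annotation) {
  filt <- intactness_filter(cluster, annotation)
  co <- canonical_order(cluster)
  if (filt$retained) {
    st <- assign_subtype(cluster)
  } else {
    st <- list(label = "unclassified", flags = character(),
               reasons = filt$reasons)
  }
  structure(list(genome_id = cluster$genome_id,
                 contig_id = cluster$contig_id,
                 anchor = cluster$anchor,
                 roles = co$role_string,
                 display_roles = co$display_string,
                 retained = filt$retained,
                 label = st$label, flags = st$flags,
                 reasons = unique(c(filt$reasons, st$reasons)),
                 cluster = cluster),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat("<subtype_call> ", x$anchor, ": roles ", x$roles,
      " -> ", if (x$retained) paste("sub-type", x$label) else "rejected",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

calls_to_df <- function(calls, capability = NULL) {
  if (!length(calls)) {
    return(data.frame(genome_id = character(), contig_id = character(),
                      anchor = character(), roles = character(),
                      subtype = character(), flags = character(),
                      retained = logical(), capability = character(),
                      reasons = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(calls, function(x)
    data.frame(genome_id = x$genome_id, contig_id = x$contig_id,
               anchor = x$anchor, roles = x$roles, subtype = x$label,
               flags = paste(x$flags, collapse = ","),
               retained = x$retained, capability = "",
               reasons = paste(x$reasons, collapse = ","),
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (!is.null(capability)) df$capability <- capability
  df
}

#' Summarize sub-type calls
#'
#' @param calls List of `subtype_call` objects or the calls data.frame.
#' @return List with `overall` (counts by label), `per_genome` (label x
#'   genome table), `flag_counts`, `n_retained` and `n_distinct_labels`
#'   (distinct non-unclassified labels).
#' @export
summarize_subtypes <- function(calls) {
  labels <- c("I", "II", "III", "IV", "V", "unclassified")
  if (is.data.frame(calls)) {
    df <- calls
  } else {
    df <- calls_to_df(calls)
  }
  lab <- factor(df$subtype, levels = labels)
  overall <- table(label = lab)
  per_genome <- table(genome = df$genome_id, label = lab)
  flag_counts <- table(unlist(strsplit(df$flags[nzchar(df$flags)], ",")))
  real <- setdiff(unique(df$subtype[df$retained]), "unclassified")
  list(overall = overall, per_genome = per_genome,
       flag_counts = flag_counts,
       n_retained = sum(df$retained),
       n_distinct_labels = length(real))
}
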