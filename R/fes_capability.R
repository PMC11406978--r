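FE2S2_LABELS <- c("A1", "A5", "B2", "B5", "C1")
FE4S4_LABELS <- c("A2", "A3", "A4", "B1", "B3", "B4")
KNOWN_LABELS <- c("2Fe", FE2S2_LABELS, FE4S4_LABELS,
                  "FMN", "Nqo1", "DPD_II", "FAD", "PAS", "His_kinase_dom")

count_fes <- function(labels, types) {
  n <- sum(labels %in% types)
  # the DPD_II domain itself carries two [4Fe-4S] clusters
  if (identical(types, FE4S4_LABELS))
    n <- n + 2L * sum(labels == "DPD_II")
  n
}

#' Build an FeS/flavin complement from subunit architectures
#'
#' Maps the declared per-subunit domain labels of a cluster onto counts
#' of [2Fe-2S] and [4Fe-4S] iron-sulfur clusters and flavin slots. The
#' label/type map is fixed: A1, A5, B2, B5 and C1 are [2Fe-2S]; A2, A3,
#' A4, B1, B3 and B4 are [4Fe-4S]; DPD_II contributes two [4Fe-4S]
#' clusters of its own. Duplicate labels count with multiplicity (a
#' double B5 is preserved and noted). The catalytic-subunit modular
#' class is `M3c` when the accessory A1/A5 [2Fe-2S] pair is present
#' (full A1-A5 complement; sub-type IV), `M3a` otherwise.
#'
#' @param A,B,C Character vectors of domain labels for the catalytic
#'   (A), flavin-bearing (B) and small FeS (C) subunits.
#' @param architecture Optional override, `"M3a"` or `"M3c"`; by default
#'   derived from the A labels.
#' @return Object of class `fes_complement`: per-subunit label sets,
#'   per-subunit and total [2Fe-2S]/[4Fe-4S] counts, flavins present,
#'   modular architecture, and notes.
#' @export
complement_from_architecture <- function(A = character(),
                                         B = character(),
                                         C = character(),
                                         architecture = NULL) {
  subunits <- list(A = as.character(A), B = as.character(B),
                   C = as.character(C))
  unknown <- setdiff(unlist(subunits), KNOWN_LABELS)
  if (length(unknown))
    stop("unknown domain label(s): ", paste(unique(unknown), collapse = ", "))
  if (is.null(architecture))
    architecture <- if (all(c("A1", "A5") %in% subunits$A)) "M3c" else "M3a"
  stopifnot(architecture %in% c("M3a", "M3c"))
  per <- lapply(subunits, function(lab)
    c(fe2s2 = count_fes(lab, FE2S2_LABELS),
      fe4s4 = count_fes(lab, FE4S4_LABELS)))
  all_lab <- unlist(subunits)
  notes <- character()
  if (sum(subunits$B == "B5") >= 2L) notes <- c(notes, "double_B5")
  structure(list(subunits = subunits, architecture = architecture,
                 per_subunit = per,
                 fe2s2 = sum(vapply(per, `[[`, 0, "fe2s2")),
                 fe4s4 = sum(vapply(per, `[[`, 0, "fe4s4")),
                 flavins = intersect(c("FMN", "FAD"), all_lab),
                 notes = notes),
            class = "fes_complement")
}

#' @export
print.fes_complement <- function(x, ...) {
  cat("<fes_complement> ", x$architecture, ": ", x$fe4s4, " x [4Fe-4S], ",
      x$fe2s2, " x [2Fe-2S]; flavins: ",
      paste(x$flavins, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Predicted electron-bifurcation capability
#'
#' Rule-based verdict from the FeS/flavin complement. A complete B1-B5
#' set plus FMN in the B subunit and C1 in the C subunit predicts a
#' bifurcating enzyme; absence of B3 or B4 without any FAD predicts a
#' non-bifurcating one (the pattern of hydrogenases shown
#' experimentally to lack bifurcation); a DPD_II domain together with
#' FAD marks a dual-center candidate — a possible second, canonical
#' flavin-only bifurcation site replacing the B3/B4 ferredoxin arm —
#' regardless of B3/B4; anything else (notably B5 missing with B1-B4
#' present, whose role is contested) is indeterminate. A double B5 is
#' noted but never changes the verdict. All verdicts are structural
#' predictions, not biochemical measurements.
#'
#' @param complement An `fes_complement`.
#' @return Object of class `capability_call` with `verdict`
#'   (`bifurcating`, `non_bifurcating`, `dual_center_candidate` or
#'   `indeterminate`), `rationale` codes and `notes`.
#' @export
bifurcation_call <- function(complement) {
  stopifnot(inherits(complement, "fes_complement"))
  b <- complement$subunits$B
  has <- function(lab) lab %in% unlist(complement$subunits)
  b_full <- all(B_SERIES %in% b)
  fmn <- "FMN" %in% b
  c1 <- "C1" %in% complement$subunits$C
  fad <- has("FAD")
  dpd <- has("DPD_II")
  b34 <- all(c("B3", "B4") %in% b)

  if (dpd && fad) {
    verdict <- "dual_center_candidate"
    rationale <- "DPD_II_FAD_second_center"
  } else if (b_full && fmn && c1) {
    verdict <- "bifurcating"
    rationale <- "complete_B1_B5_FMN_C1"
  } else if (!b34 && !fad) {
    verdict <- "non_bifurcating"
    rationale <- "missing_B3_B4"
  } else {
    verdict <- "indeterminate"
    rationale <- if (b34 && !("B5" %in% b)) "B5_absent" else "partial_complement"
  }
  structure(list(verdict = verdict, rationale = rationale,
                 notes = complement$notes),
            class = "capability_call")
}

#' @export
print.capability_call <- function(x, ...) {
  cat("<capability_call> predicted ", x$verdict, " (", x$rationale, ")",
      if (length(x$notes)) paste0(" notes: ", paste(x$notes, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

#' Electron-path completeness check
#'
#' Checks the two proposed transport chains of the bifurcating complex:
#' the hydrogen arm, H-cluster 2Fe center (through the accessory A-series
#' clusters when the catalytic subunit is M3c) to B1 to FMN, where the
#' electron pair is split; and the ferredoxin arm C1-B2-B3-B4. Reports
#' which links are absent, in chain order.
#'
#' @param complement An `fes_complement`.
#' @return List with `path_ok` and `missing` (character vector of absent
#'   links).
#' @export
electron_path_check <- function(complement) {
  stopifnot(inherits(complement, "fes_complement"))
  su <- complement$subunits
  links <- c("2Fe" = "2Fe" %in% su$A)
  if (complement$architecture == "M3c")
    for (a in A_SERIES) links[a] <- a %in% su$A
  links["B1"] <- "B1" %in% su$B
  links["FMN"] <- "FMN" %in% su$B
  links["C1"] <- "C1" %in% su$C
  for (bb in c("B2", "B3", "B4")) links[bb] <- bb %in% su$B
  missing <- names(links)[!links]
  list(path_ok = length(missing) == 0L, missing = missing)
}

#' Capability call for an extracted cluster
#'
#' Convenience wrapper: builds the complement from the cluster's A, B
#' and C member architectures (first member per role in canonical
#' order) and returns the verdict plus path check.
#'
#' @param cluster A `gene_cluster`.
#' @param annotation Its [genome_annotation()].
#' @return List with `complement`, `call`, `path`.
#' @export
cluster_capability <- function(cluster, annotation) {
  co <- canonical_order(cluster)
  m <- co$members
  pick <- function(role) {
    ids <- m$gene_id[m$role == role]
    if (!length(ids)) character() else
      as.character(annotation$domains[[ids[[1]]]])
  }
  comp <- complement_from_architecture(A = pick("A"), B = pick("B"),
                                       C = pick("C"))
  list(complement = comp, call = bifurcation_call(comp),
       path = electron_path_check(comp))
}
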