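#' Catalog of H-cluster binding motifs
#'
#' The catalytic subunit (BfuA) of group A3 [FeFe]-hydrogenases ligates
#' the H-cluster through three conserved signature motifs. Patterns are
#' strings over the 20 residue letters plus the wildcard `x`, which
#' matches any residue; position numbering within a pattern is 1-based,
#' so "the fifth position in P1" is pattern index 5.
#'
#' @return Named list of patterns `P1`, `P2`, `P3`.
#' @export
motif_catalog <- function() {
  list(P1 = "xTSCxPxWx", P2 = "xxMPCxAKK", P3 = "ExMxCPGGCxxGxGQ")
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 3L)
    stop("pattern must be a single string of length >= 3")
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, c(AA_LETTERS, "x"))
  if (length(bad))
    stop("pattern contains illegal character(s): ",
         paste(unique(bad), collapse = ", "))
  chars
}

#' Scan a protein for a degenerate motif
#'
#' Slides the pattern along the sequence and reports every window whose
#' mismatch count at non-wildcard positions is within tolerance. `X`
#' residues never match a non-wildcard pattern position. Overlapping
#' hits are all reported, sorted by start.
#'
#' @param sequence Amino-acid string.
#' @param pattern Degenerate pattern (see [motif_catalog()]).
#' @param max_mismatch Maximum mismatches at non-wildcard positions.
#' @param name Motif name recorded in the result.
#' @return data.frame with columns `motif`, `start` (1-based), `match`,
#'   `mismatches`; zero rows when nothing matches.
#' @export
scan_motif <- function(sequence, pattern, max_mismatch = 0L, name = NA) {
  pchars <- check_pattern(pattern)
  stopifnot(max_mismatch >= 0L)
  m <- length(pchars)
  L <- nchar(sequence)
  empty <- data.frame(motif = character(), start = integer(),
                      match = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (L < m) return(empty)
  s <- strsplit(toupper(sequence), "")[[1]]
  fixed <- which(pchars != "x")
  starts <- seq_len(L - m + 1L)
  mm <- integer(length(starts))
  for (j in fixed) mm <- mm + (s[starts + j - 1L] != pchars[j])
  keep <- starts[mm <= max_mismatch]
  if (!length(keep)) return(empty)
  data.frame(motif = if (is.na(name)) pattern else name, start = keep,
             match = substring(sequence, keep, keep + m - 1L),
             mismatches = mm[mm <= max_mismatch],
             stringsAsFactors = FALSE)
}

#' Call catalytic-subunit (BfuA) candidates in a genome
#'
#' A gene is a BfuA candidate iff its protein carries at least one hit of
#' each of P1, P2 and P3 with the leftmost hits ordered P1 < P2 < P3
#' along the protein. With `tolerant = TRUE`, near-misses (one mismatch
#' allowed per motif) are additionally reported; they never enter the
#' canonical candidate call.
#'
#' @param annotation A [genome_annotation()] object.
#' @param catalog Motif catalog (must contain P1, P2, P3).
#' @param max_mismatch Mismatch tolerance for the canonical call.
#' @param tolerant Also report near-miss candidates at tolerance
#'   `max_mismatch + 1`.
#' @return Character vector of candidate gene ids, sorted by genome
#'   position. With `tolerant = TRUE`, the extra candidates are attached
#'   as attribute `"near_miss"`.
#' @export
call_bfuA <- function(annotation, catalog = motif_catalog(),
                      max_mismatch = 0L, tolerant = FALSE) {
  stopifnot(inherits(annotation, "genome_annotation"),
            all(c("P1", "P2", "P3") %in% names(catalog)))
  is_candidate <- function(prot, mm) {
    lm <- integer(3)
    for (i in 1:3) {
      h <- scan_motif(prot, catalog[[i]], mm)
      if (!nrow(h)) return(FALSE)
      lm[i] <- min(h$start)
    }
    lm[1] < lm[2] && lm[2] < lm[3]
  }
  ids <- names(annotation$proteins)
  hit <- vapply(ids, function(g)
    is_candidate(annotation$proteins[[g]], max_mismatch), logical(1))
  called <- ids[hit]
  # order by genome position
  g <- annotation$genes
  ord <- match(called, g$gene_id)
  called <- called[order(g$contig_id[ord], g$rank[ord])]
  if (tolerant) {
    near <- ids[!hit & vapply(ids, function(g2)
      is_candidate(annotation$proteins[[g2]], max_mismatch + 1L),
      logical(1))]
    attr(called, "near_miss") <- near
  }
  called
}

#' Per-position conservation of aligned motif instances
#'
#' Computes, for each column of a set of equal-length matched
#' substrings, the residue frequency vector, the information content
#' R_i = log2(20) - H_i (Shannon entropy in bits over the residue
#' frequencies), and letter heights frequency x R_i — the quantities a
#' sequence logo displays. No small-sample correction is applied.
#'
#' @param instances Character vector of equal-length sequences.
#' @return Object of class `conservation_profile`: list with `length`,
#'   `n`, `bits` (per-position information content), `freq` (residue x
#'   position matrix) and `heights` (same shape, frequency x bits).
#' @export
column_information <- function(instances) {
  instances <- as.character(instances)
  if (!length(instances)) stop("need at least one instance")
  w <- unique(nchar(instances))
  if (length(w) != 1L) stop("instances have ragged lengths")
  mat <- do.call(rbind, strsplit(toupper(instances), ""))
  bits <- numeric(w)
  freq <- matrix(0, nrow = length(AA_LETTERS), ncol = w,
                 dimnames = list(AA_LETTERS, NULL))
  for (i in seq_len(w)) {
    tab <- table(factor(mat[, i], levels = AA_LETTERS))
    p <- as.numeric(tab) / sum(tab)
    freq[, i] <- p
    nz <- p[p > 0]
    h <- -sum(nz * log2(nz))
    bits[i] <- log2(20) - h
  }
  heights <- sweep(freq, 2, bits, `*`)
  structure(list(length = w, n = length(instances), bits = bits,
                 freq = freq, heights = heights),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> ", x$n, " instances, width ", x$length,
      "\n  bits: ", paste(sprintf("%.2f", x$bits), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Export a conservation profile as a logo table
#'
#' @param profile A [column_information()] result.
#' @param path Output TSV path (columns position, residue, height, bits).
#' @export
write_logo_table <- function(profile, path) {
  stopifnot(inherits(profile, "conservation_profile"))
  rows <- do.call(rbind, lapply(seq_len(profile$length), function(i) {
    p <- profile$heights[, i]
    keep <- p > 0
    data.frame(position = i, residue = rownames(profile$heights)[keep],
               height = p[keep], bits = profile$bits[i],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
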