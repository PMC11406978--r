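AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                              collapse = "")

# Naive window-by-window motif scanner: the independent oracle for
# scan_motif. Deliberately loop-based and structured differently from
# the package implementation.
brute_scan <- function(sequence, pattern, max_mismatch) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(sequence, "")[[1]]
  hits <- list()
  if (length(s) < length(p)) return(matrix(numeric(0), ncol = 2))
  for (start in 1:(length(s) - length(p) + 1)) {
    mm <- 0
    for (j in seq_along(p)) {
      if (p[j] == "x") next
      if (s[start + j - 1] != p[j]) mm <- mm + 1
    }
    if (mm <= max_mismatch) hits[[length(hits) + 1]] <- c(start, mm)
  }
  if (!length(hits)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, hits)
}

# Canonical catalytic-subunit protein (carries P1, P2, P3 in order).
bfua_protein <- function() bfuscan:::SUBUNIT_TEMPLATES$A

role_protein <- function(role) {
  switch(role,
         A = bfua_protein(),
         B = bfuscan:::SUBUNIT_TEMPLATES$B,
         C = bfuscan:::SUBUNIT_TEMPLATES$C,
         D = bfuscan:::SUBUNIT_TEMPLATES$D,
         T = bfuscan:::SUBUNIT_TEMPLATES$T,
         X = paste(rep("LIVMARND", 15), collapse = ""))
}

role_domains <- function(role, subtype = "V") {
  switch(role,
         A = if (subtype == "IV") c("2Fe", "A1", "A2", "A3", "A4", "A5")
             else c("2Fe", "A2", "A3", "A4"),
         B = switch(subtype,
                    I = c("FMN", "Nqo1", "B1", "B2", "B5", "DPD_II", "FAD"),
                    II = c("FMN", "Nqo1", "B1", "B2"),
                    III = c("FMN", "Nqo1", "B1", "B2", "B3", "B4", "B5", "B5"),
                    c("FMN", "Nqo1", "B1", "B2", "B3", "B4", "B5")),
         C = "C1",
         D = "Nqo1",
         T = c("2Fe", "PAS"),
         X = NULL)
}

# Hand-built single-contig genome: `roles` gives the gene roles in
# coordinate order; strands may be one value or one per gene.
toy_annotation <- function(roles, strands = "+", subtype = "V",
                           genome_id = "TOY", partial = NULL) {
  n <- length(roles)
  strands <- rep(strands, length.out = n)
  if (is.null(partial)) partial <- rep(FALSE, n)
  ids <- sprintf("%s_g%02d", genome_id, seq_len(n))
  proteins <- list(); domains <- list()
  starts <- integer(n); ends <- integer(n)
  pos <- 100L
  for (i in seq_len(n)) {
    prot <- role_protein(roles[i])
    starts[i] <- pos
    ends[i] <- pos + 3L * nchar(prot) + 2L
    pos <- ends[i] + 60L
    proteins[[ids[i]]] <- prot
    dom <- role_domains(roles[i], subtype)
    if (!is.null(dom)) domains[[ids[i]]] <- dom
  }
  genes <- data.frame(gene_id = ids, contig_id = "c1", start = starts,
                      end = ends, strand = strands, partial = partial,
                      stringsAsFactors = FALSE)
  contigs <- data.frame(contig_id = "c1", length = pos + 500L,
                        stringsAsFactors = FALSE)
  genome_annotation(genome_id, genes, proteins, domains, contigs)
}

# Annotation holding a single protein (for anchor-call tests).
single_protein_annotation <- function(prot, gene_id = "g1") {
  genes <- data.frame(gene_id = gene_id, contig_id = "c1",
                      start = 100L, end = 100L + 3L * nchar(prot) + 2L,
                      strand = "+", partial = FALSE,
                      stringsAsFactors = FALSE)
  genome_annotation("ONE", genes,
                    stats::setNames(list(prot), gene_id),
                    contigs = data.frame(contig_id = "c1",
                                         length = 10000L))
}

anchor_id_of <- function(annotation) {
  calls <- call_bfuA(annotation)
  stopifnot(length(calls) == 1L)
  calls
}
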