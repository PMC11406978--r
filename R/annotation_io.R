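#' In-memory genome annotation model
#'
#' Bundles everything the pipeline needs to know about one genome: gene
#' coordinates, the proteins they encode, and each protein's declared
#' domain architecture. Coordinates follow the GFF3 convention (1-based,
#' inclusive on both ends); genes are ranked 1, 2, ... along each contig
#' in coordinate order, and neighborhood windows downstream count ranks,
#' not base pairs.
#'
#' @param genome_id Genome identifier.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` ("+" or "-") and optionally `partial` (logical;
#'   truncated gene model). Ranks are (re)computed from coordinate order.
#' @param proteins Named character vector of amino-acid sequences, one per
#'   gene. Only the 20 canonical residues plus `X` are allowed.
#' @param domains Named list mapping gene ids to ordered character vectors
#'   of domain labels (may omit genes with no annotated domains).
#' @param contigs Optional data.frame with columns `contig_id`, `length`.
#'   When absent, contig lengths default to the last gene end. Genes whose
#'   coordinates touch a contig terminus are flagged partial.
#'
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, genes, proteins = character(),
                              domains = list(), contigs = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), rank = integer(),
                        partial = logical(), stringsAsFactors = FALSE)
  } else {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    req <- c("gene_id", "contig_id", "start", "end", "strand")
    miss <- setdiff(req, names(genes))
    if (length(miss))
      stop("genes table lacks column(s): ", paste(miss, collapse = ", "))
    if (!"partial" %in% names(genes)) genes$partial <- FALSE
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    if (any(genes$start < 1L)) stop("gene start coordinates must be >= 1")
    if (any(genes$end < genes$start)) stop("gene end must be >= start")
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (anyDuplicated(genes$gene_id))
      stop("duplicated gene ids: ",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                 collapse = ", "))
    genes <- genes[order(genes$contig_id, genes$start, genes$end), ,
                   drop = FALSE]
    genes$rank <- stats::ave(seq_len(nrow(genes)), genes$contig_id,
                             FUN = seq_along)
    rownames(genes) <- NULL
  }

  if (is.null(contigs)) {
    if (nrow(genes)) {
      len <- tapply(genes$end, genes$contig_id, max)
      contigs <- data.frame(contig_id = names(len),
                            length = as.integer(len),
                            stringsAsFactors = FALSE)
    } else {
      contigs <- data.frame(contig_id = character(), length = integer(),
                            stringsAsFactors = FALSE)
    }
  } else {
    contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
    stopifnot(all(c("contig_id", "length") %in% names(contigs)))
  }
  rownames(contigs) <- NULL

  # contig-terminus overlap implies a truncated gene model
  if (nrow(genes)) {
    clen <- stats::setNames(contigs$length, contigs$contig_id)
    at_edge <- genes$start == 1L | genes$end >= clen[genes$contig_id]
    genes$partial <- genes$partial | at_edge
  }

  proteins <- unlist(proteins)
  if (length(proteins)) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", proteins)
    if (any(bad))
      stop("non-canonical residues in protein(s): ",
           paste(utils::head(names(proteins)[bad], 5), collapse = ", "))
    orphan_prot <- setdiff(names(proteins), genes$gene_id)
    orphan_gene <- setdiff(genes$gene_id, names(proteins))
    if (length(orphan_prot) || length(orphan_gene))
      stop("protein/gene ID mismatch; orphans: ",
           paste(c(orphan_prot, orphan_gene), collapse = ", "))
  }
  if (length(domains)) {
    unknown <- setdiff(names(domains), genes$gene_id)
    if (length(unknown))
      stop("domain table references unknown gene id(s): ",
           paste(unknown, collapse = ", "))
  }

  structure(list(genome_id = genome_id, contigs = contigs, genes = genes,
                 proteins = proteins, domains = domains),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, "\n", sep = "")
  cat("  contigs: ", nrow(x$contigs), "; genes: ", nrow(x$genes),
      "; proteins: ", length(x$proteins), "\n", sep = "")
  invisible(x)
}

# Line-level GFF3 validation so parse failures name the offending line.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L)
      stop("malformed GFF3 line ", i, " in ", path,
           ": expected 9 tab-separated fields, found ", length(fields))
    if (is.na(suppressWarnings(as.integer(fields[4]))) ||
        is.na(suppressWarnings(as.integer(fields[5]))))
      stop("malformed GFF3 line ", i, " in ", path,
           ": non-numeric coordinates")
  }
  lines
}

#' Read one genome bundle (protein FASTA + GFF3 + domain TSV)
#'
#' Gene features must carry `ID` attributes matching the FASTA headers;
#' the optional `partial` attribute (`true`/`1`) marks truncated gene
#' models, and genes overlapping a contig terminus (from the GFF3
#' `##sequence-region` pragmas) are flagged partial as well. The domain
#' table is a TSV with columns `gene_id`, `ordinal`, `domain_label`.
#'
#' @param fasta_path Protein FASTA file.
#' @param gff_path GFF3 file with `gene` features.
#' @param domains_path Domain-architecture TSV (may be absent/NULL for a
#'   genome with no domain annotations).
#' @param genome_id Genome identifier; defaults to the GFF3 basename.
#' @return A [genome_annotation()] object.
#' @export
read_genome <- function(fasta_path, gff_path, domains_path = NULL,
                        genome_id = NULL) {
  for (p in c(fasta_path, gff_path))
    if (!file.exists(p)) stop("no such file: ", p)
  if (is.null(genome_id))
    genome_id <- sub("\\.gff3?$", "", basename(gff_path))

  lines <- validate_gff3_lines(gff_path)
  sr <- lines[startsWith(lines, "##sequence-region")]
  contigs <- NULL
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "[ \t]+")
    contigs <- data.frame(
      contig_id = vapply(parts, `[`, "", 2L),
      length = as.integer(vapply(parts, `[`, "", 4L)),
      stringsAsFactors = FALSE)
  }

  aa <- Biostrings::readAAStringSet(fasta_path)
  proteins <- stats::setNames(as.character(aa),
                              sub("\\s.*$", "", names(aa)))

  has_features <- any(!startsWith(lines, "#") & nzchar(lines))
  if (has_features) {
    gr <- rtracklayer::import(gff_path, format = "gff3")
    df <- as.data.frame(gr)
    df <- df[df$type == "gene", , drop = FALSE]
    if (is.null(df$ID) || anyNA(df$ID))
      stop("GFF3 gene feature(s) without ID attribute in ", gff_path)
    partial <- rep(FALSE, nrow(df))
    if (!is.null(df$partial))
      partial <- tolower(as.character(df$partial)) %in% c("true", "1")
    genes <- data.frame(gene_id = as.character(df$ID),
                        contig_id = as.character(df$seqnames),
                        start = df$start, end = df$end,
                        strand = as.character(df$strand),
                        partial = partial, stringsAsFactors = FALSE)
  } else {
    genes <- NULL
  }

  domains <- list()
  if (!is.null(domains_path) && file.exists(domains_path)) {
    dt <- utils::read.delim(domains_path, stringsAsFactors = FALSE)
    if (nrow(dt)) {
      stopifnot(all(c("gene_id", "ordinal", "domain_label") %in% names(dt)))
      dt <- dt[order(dt$gene_id, dt$ordinal), , drop = FALSE]
      domains <- split(dt$domain_label, dt$gene_id)
    }
  }

  genome_annotation(genome_id, genes, proteins, domains, contigs)
}

#' Read every genome bundle in a directory
#'
#' A bundle directory holds, per genome, `<id>.faa`, `<id>.gff3` and
#' optionally `<id>.domains.tsv` (plus, for synthetic bundles,
#' `truth.tsv`).
#'
#' @param dir Bundle directory.
#' @return Named list of [genome_annotation()] objects.
#' @export
read_genome_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  gffs <- sort(list.files(dir, pattern = "\\.gff3$", full.names = TRUE))
  out <- list()
  for (g in gffs) {
    id <- sub("\\.gff3$", "", basename(g))
    fa <- file.path(dir, paste0(id, ".faa"))
    if (!file.exists(fa)) stop("bundle incomplete, missing ", fa)
    out[[id]] <- read_genome(fa, g, file.path(dir, paste0(id, ".domains.tsv")),
                             genome_id = id)
  }
  out
}

#' Write the per-cluster classification report
#'
#' Tab-separated, one row per anchored cluster, fixed column order:
#' `genome_id`, `contig_id`, `anchor`, `roles` (canonical role string),
#' `subtype`, `flags` (comma-joined), `retained`, `capability`
#' (predicted verdict), `reasons` (comma-joined rejection codes).
#'
#' @param calls data.frame of sub-type calls as produced by
#'   [classify_genome()] / [run_pipeline()].
#' @param path Output path.
#' @export
write_cluster_report <- function(calls, path) {
  cols <- c("genome_id", "contig_id", "anchor", "roles", "subtype",
            "flags", "retained", "capability", "reasons")
  if (is.null(calls) || nrow(as.data.frame(calls)) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
  } else {
    df <- as.data.frame(calls, stringsAsFactors = FALSE)
    for (cc in setdiff(cols, names(df))) df[[cc]] <- ""
    df <- df[, cols, drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write cluster report to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
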