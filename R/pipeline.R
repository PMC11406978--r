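#' Detect and classify hydrogenase clusters in one genome
#'
#' Scans proteins for the three H-cluster motifs, extracts the gene
#' neighborhood around each anchor, filters for an intact bifurcating
#' core and assigns sub-types and capability verdicts.
#'
#' @param annotation A [genome_annotation()].
#' @param window Neighborhood half-width in genes.
#' @param max_mismatch Motif mismatch tolerance.
#' @param catalog Motif catalog.
#' @return List with `anchors`, `calls` (list of `subtype_call`) and
#'   `capability` (character verdict per call, "" for rejected
#'   clusters).
#' @export
classify_genome <- function(annotation, window = 5L, max_mismatch = 0L,
                            catalog = motif_catalog()) {
  anchors <- call_bfuA(annotation, catalog, max_mismatch)
  calls <- list(); capability <- character()
  for (a in anchors) {
    cl <- extract_neighborhood(annotation, a, window = window,
                               bfua_calls = anchors)
    sc <- classify_cluster(cl, annotation)
    cap <- if (sc$retained)
      cluster_capability(cl, annotation)$call$verdict else ""
    calls[[length(calls) + 1L]] <- sc
    capability <- c(capability, cap)
  }
  list(anchors = anchors, calls = calls, capability = capability)
}

#' Run the full detection/classification pipeline
#'
#' Orchestrates scan -> extract -> filter -> classify -> capability ->
#' phylogeny over a genome bundle. The analysis is fully deterministic;
#' the only randomness in the package lives in the synthetic-genome
#' generator.
#'
#' @param input A bundle directory (see [read_genome_bundle()]) or a
#'   (possibly named) list of [genome_annotation()] objects.
#' @param window Neighborhood half-width in genes (default 5).
#' @param max_mismatch Motif mismatch tolerance (default 0).
#' @param k k-mer length for the phylogeny cross-check (default 4).
#' @param out_dir Optional output directory; when given, writes
#'   `cluster_report.tsv`, `capability_report.tsv`, `tree.nwk`,
#'   `purity.tsv` and `summary.yaml`.
#' @return Object of class `bfu_run`: `calls` (report data.frame),
#'   `capability` (per-retained-cluster detail), `tree` (phylo or
#'   NULL), `purity` (purity_report or NULL) and `summary`.
#' @export
run_pipeline <- function(input, window = 5L, max_mismatch = 0L, k = 4L,
                         out_dir = NULL) {
  genomes <- if (is.character(input)) read_genome_bundle(input) else input
  stopifnot(all(vapply(genomes, inherits, logical(1),
                       "genome_annotation")))
  all_calls <- list(); cap <- character()
  cap_detail <- list()
  concat <- character(); concat_label <- character()
  n_anchors <- 0L
  for (ann in genomes) {
    res <- classify_genome(ann, window = window,
                           max_mismatch = max_mismatch)
    n_anchors <- n_anchors + length(res$anchors)
    all_calls <- c(all_calls, res$calls)
    cap <- c(cap, res$capability)
    for (sc in res$calls) {
      if (!sc$retained) next
      detail <- cluster_capability(sc$cluster, ann)
      cap_detail[[sc$anchor]] <- data.frame(
        genome_id = sc$genome_id, anchor = sc$anchor,
        subtype = sc$label,
        verdict = detail$call$verdict,
        rationale = detail$call$rationale,
        notes = paste(detail$call$notes, collapse = ","),
        path_ok = detail$path$path_ok,
        path_missing = paste(detail$path$missing, collapse = ","),
        fe4s4 = detail$complement$fe4s4,
        fe2s2 = detail$complement$fe2s2,
        architecture = detail$complement$architecture,
        stringsAsFactors = FALSE)
      if (sc$label != "unclassified") {
        concat[sc$anchor] <- concat_abc(sc$cluster, ann$proteins)
        concat_label[sc$anchor] <- sc$label
      }
    }
  }
  calls_df <- calls_to_df(all_calls, capability = cap)
  cap_df <- if (length(cap_detail)) {
    out <- do.call(rbind, cap_detail); rownames(out) <- NULL; out
  } else NULL

  tree <- NULL; purity <- NULL
  if (length(concat) >= 3L) {
    d <- kmer_distance(concat, k = k)
    tree <- nj_tree(d)
    purity <- subtype_purity(tree, concat_label)
  }

  summ <- summarize_subtypes(calls_df)
  summary <- list(
    genomes = length(genomes),
    anchors = n_anchors,
    clusters_retained = summ$n_retained,
    counts = as.list(stats::setNames(as.integer(summ$overall),
                                     names(summ$overall))),
    distinct_labels = summ$n_distinct_labels,
    mean_purity = if (is.null(purity)) NA_real_ else purity$mean_purity)

  run <- structure(list(calls = calls_df, capability = cap_df,
                        tree = tree, purity = purity, summary = summary,
                        params = list(window = window,
                                      max_mismatch = max_mismatch,
                                      k = k)),
                   class = "bfu_run")
  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

# TSV reports carry a YAML front-matter block (commented) recording the
# parameters, so every count is traceable to its configuration.
report_header <- function(run) {
  y <- yaml::as.yaml(list(tool = "bfuscan", params = run$params))
  paste0("# ", strsplit(y, "\n")[[1]])
}

write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- report_header(run)
  wr <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cr <- file.path(out_dir, "cluster_report.tsv")
  tmp <- tempfile(); write_cluster_report(run$calls, tmp)
  writeLines(c(hdr, readLines(tmp)), cr); unlink(tmp)
  if (!is.null(run$capability))
    wr(run$capability, file.path(out_dir, "capability_report.tsv"))
  if (!is.null(run$tree))
    ape::write.tree(run$tree, file.path(out_dir, "tree.nwk"),
                    digits = 6)
  if (!is.null(run$purity))
    wr(run$purity$per_subtype, file.path(out_dir, "purity.tsv"))
  yaml::write_yaml(run$summary, file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}

#' @export
print.bfu_run <- function(x, ...) {
  s <- x$summary
  cat("<bfu_run> ", s$genomes, " genome(s): ", s$anchors,
      " anchor(s), ", s$clusters_retained, " cluster(s) retained\n",
      sep = "")
  cnt <- unlist(s$counts)
  cnt <- cnt[cnt > 0]
  if (length(cnt))
    cat("  sub-types: ",
        paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n",
        sep = "")
  if (!is.na(s$mean_purity))
    cat("  phylogeny cross-check mean purity: ",
        sprintf("%.3f", s$mean_purity), "\n", sep = "")
  invisible(x)
}

#' @method summary bfu_run
#' @export
summary.bfu_run <- function(object, ...) object$summary
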