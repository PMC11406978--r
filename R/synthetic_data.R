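# Fixed subunit template sequences (one per role). The catalytic A
# template embeds canonical instances of the three H-cluster motifs at
# positions 90 (P1), 140 (P2) and 210 (P3); mutation never touches
# those windows. P1 position 5 (protein position 94) is Ser here and is
# switched to Cys for sub-type IV templates.
SUBUNIT_TEMPLATES <- list(
  A = "LWHCRIDIRINWYIVRGSEMGCEGMITQEDPKIPRKCNILQISVFGDKSISVVIGLPHNGESTMPNVATANMSCKTIKKYQMYIVDVPVATSCSPVWAMCYCVIFTSKRMIMPNCYAPELHNPHWELTGNQMKIAMLVNGAMPCVAKKDRFVCAMHCAGQIRRCRMEDCDVIPVSGIRYMKKHPEIDQNQFPDWMRTAWPMGLHSGCQHEAMTCPGGCVIGAGQDVLVNRFEQIYTSQCYDDDCEIRVIQCSTTDQTFGQQLYLLADKRADFHMLDRAKWVLSHLWAKHETGEFEVSRKCYHAASYCKLTYMKTTINEPLWCDLARMNFCLRDNSLECAVPYPPLQPEMMNWPHYMREKLHALTWCRDQEINIFHGRSWSKHKVQWKYHCYYENETLESNRNQDLPAHIAPLFVGYTEML",
  B = "CMVFKVTMTMTKVIKFPTVAPGASACHDFAVAWQGECNNQSESTLMASVCPTQTKHRCDFESCPQMFYEGYFYMTQQARKPQAALGPAIIGFGVITKYWACDPCKRDLNTMEECMSLRLEGVWYWNDDVMGPRDKKQPPVPYGNRIVMGEHWCDDIHVMTEDYWDWCRFPCGYSSEYIHGLTEHVQLMGVVTAWWNPLNWMNCKLESREMAVAMTPVIFWNCPVWACHRLLIDFLNRCHDCYKPTARAIVWITVGTSSVHTGYRQWTHFNDYPIDMCLMQPGNHQPYYYPNQNTQDPRPHCFHSVQIQVLAQMIAPNMNKACNDEYGKYYNDIGCVYGHEMWSAWNCMCFIYEVFERTRSLGLVPWYSFHTNPSRWDMPM",
  C = "HLHTNKYALSWEEKMLHHCQSHNPSPMYSCLSWREQVWIYNNVQHDFIDTMDPMSPHWTLYPFKMLQWGGDHENAFCGEMIWQSNFSMSYTEYECSIYVVIRLGRPSLSRENPDNYVPSYARCKTMSAIPHNVNGCCWELAYTMFAWFRM",
  D = "KASFYMLMRTRIQGSDNVNRHWDDTPNWLWHKGEFCLDNVASYSAQLGIRSQYIRSQCCPSWLWGFDEQGCQSEYCGMVELKWPIWKAWPFMTNDDVIMKNVCDRNWYSTVAHIMVAEQF",
  T = "KYRPTKIPKTRNGHCLQCYQVDLKTALLEHKFWYCIYSSCHWSMCHVNGCRWSICPEFFMNGKFWASILASVTFYVHYELIRFNAQIKAFYILGRKKISSPDFDAVLIVRHQGKMSLESSDQGLWCNGEWTQEDHQKNKDKEDCTWYLKVQQAEMGLDCNMYLTQWCQHICNSTKGRSCQHPSFYTSLECHDFRPPVQPEQIYRGDPELDALMDFTKSEWPQRYNIYQKPIYSIWWLNIVGHRQYRVQRIEQKAVWGMAC"
)
A_MOTIF_PROTECT <- c(90:98, 140:148, 210:224)
P1_POS5 <- 94L

SUBTYPE_ORDER <- list(I = c("A", "B", "D", "C"),
                      II = c("A", "B", "C"),
                      III = c("C", "A", "B"),
                      IV = c("A", "B", "C", "T"),
                      V = c("T", "A", "B", "C"))

# Declared per-sub-type domain architectures (what an upstream HMM
# annotation would report for each subunit).
subtype_domains <- function(subtype, role) {
  switch(role,
    A = if (subtype == "IV") c("2Fe", "A1", "A2", "A3", "A4", "A5")
        else c("2Fe", "A2", "A3", "A4"),
    B = switch(subtype,
      I   = c("FMN", "Nqo1", "B1", "B2", "B5", "DPD_II", "FAD"),
      II  = c("FMN", "Nqo1", "B1", "B2"),
      III = c("FMN", "Nqo1", "B1", "B2", "B3", "B4", "B5", "B5"),
      c("FMN", "Nqo1", "B1", "B2", "B3", "B4", "B5")),
    C = "C1",
    D = "Nqo1",
    T = if (subtype == "V") c("2Fe", "His_kinase_dom") else c("2Fe", "PAS"))
}

rand_aa <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE),
                             collapse = "")

# Substitute a fixed proportion of positions (outside `protect`) with a
# different residue.
mutate_seq <- function(seq, proportion, protect = integer()) {
  if (proportion <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_along(chars), protect)
  k <- round(proportion * length(free))
  if (k < 1L) return(seq)
  pos <- sample(free, k)
  for (p in pos) chars[p] <- sample(setdiff(AA_LETTERS, chars[p]), 1)
  paste(chars, collapse = "")
}

run_with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Specification of one planted hydrogenase cluster
#'
#' @param subtype One of "I".."V".
#' @param strand Strand carrying the cluster ("+" or "-").
#' @param intervening_decoys Number of non-subunit genes inserted inside
#'   the cluster (0-5).
#' @param omit_subunit Optional role ("A","B","C","D","T") to delete.
#' @param edge_truncate Place the cluster at the contig boundary,
#'   cutting the last gene (partial gene model).
#' @param t_variant Optional sensory-gene placement exception:
#'   `"downstream_adjacent_A"` (sub-type IV variant, T immediately after
#'   the anchor) or `"double_T"` (an extra T on both ends).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(subtype, strand = "+", intervening_decoys = 0L,
                       omit_subunit = NULL, edge_truncate = FALSE,
                       t_variant = NULL) {
  stopifnot(subtype %in% names(SUBTYPE_ORDER), strand %in% c("+", "-"),
            intervening_decoys >= 0L, intervening_decoys <= 5L)
  if (!is.null(omit_subunit))
    stopifnot(omit_subunit %in% c("A", "B", "C", "D", "T"))
  if (!is.null(t_variant))
    stopifnot(t_variant %in% c("downstream_adjacent_A", "double_T"))
  structure(list(subtype = subtype, strand = strand,
                 intervening_decoys = as.integer(intervening_decoys),
                 omit_subunit = omit_subunit,
                 edge_truncate = isTRUE(edge_truncate),
                 t_variant = t_variant),
            class = "plant_spec")
}

#' Generator configuration
#'
#' Defaults describe the study conditions used throughout the test
#' suite: 20 genomes with 3 planted clusters each, a uniform sub-type
#' mix, between-sub-type template divergence 0.15 and within-sub-type
#' divergence 0.02, seed 42.
#'
#' @param n_genomes Number of genomes.
#' @param clusters_per_genome Planted clusters per genome.
#' @param subtype_mix Named probability weights over sub-types I-V
#'   (must sum to 1).
#' @param decoy_gene_count Decoy genes per contig.
#' @param divergence_between Substitution proportion applied once per
#'   sub-type to each role template (in `[0, 0.5]`).
#' @param divergence_within Substitution proportion applied per planted
#'   instance (in `[0, 0.5]`).
#' @param decoy_p1_fraction Fraction of decoy proteins carrying a single
#'   isolated P1 motif instance (tests that anchor calls require all
#'   three motifs).
#' @param omit_mix Named weights over `none`, `A`, `B`, `C`, `D`, `T`
#'   for the omitted subunit of each plant (default: never omit).
#' @param edge_truncate_prob Probability that a plant is truncated at
#'   its contig edge.
#' @param seed Random seed (one seeded generator drives the whole run).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_genomes = 20L, clusters_per_genome = 3L,
                             subtype_mix = c(I = 0.2, II = 0.2, III = 0.2,
                                             IV = 0.2, V = 0.2),
                             decoy_gene_count = 8L,
                             divergence_between = 0.15,
                             divergence_within = 0.02,
                             decoy_p1_fraction = 0.1,
                             omit_mix = c(none = 1),
                             edge_truncate_prob = 0,
                             seed = 42L) {
  if (any(subtype_mix < 0) || abs(sum(subtype_mix) - 1) > 1e-6)
    stop("subtype_mix weights must be non-negative and sum to 1")
  if (!all(names(subtype_mix) %in% names(SUBTYPE_ORDER)))
    stop("subtype_mix names must be among I..V")
  for (d in c(divergence_between, divergence_within))
    if (d < 0 || d > 0.5) stop("divergence must lie in [0, 0.5]")
  if (any(omit_mix < 0) || abs(sum(omit_mix) - 1) > 1e-6 ||
      !all(names(omit_mix) %in% c("none", "A", "B", "C", "D", "T")))
    stop("omit_mix must be weights over none/A/B/C/D/T summing to 1")
  structure(list(n_genomes = as.integer(n_genomes),
                 clusters_per_genome = as.integer(clusters_per_genome),
                 subtype_mix = subtype_mix,
                 decoy_gene_count = as.integer(decoy_gene_count),
                 divergence_between = divergence_between,
                 divergence_within = divergence_within,
                 decoy_p1_fraction = decoy_p1_fraction,
                 omit_mix = omit_mix,
                 edge_truncate_prob = edge_truncate_prob,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Per-sub-type role templates: one between-sub-type mutation pass over
# the shared role template, motif windows protected on A; P1 position 5
# is Cys in sub-type IV, Ser elsewhere. Uses the current RNG stream.
make_subtype_templates <- function(between) {
  out <- list()
  for (st in names(SUBTYPE_ORDER)) {
    tpl <- list()
    for (role in c("A", "B", "C", "D", "T")) {
      protect <- if (role == "A") A_MOTIF_PROTECT else integer()
      s <- mutate_seq(SUBUNIT_TEMPLATES[[role]], between, protect)
      if (role == "A")
        substr(s, P1_POS5, P1_POS5) <- if (st == "IV") "C" else "S"
      tpl[[role]] <- s
    }
    out[[st]] <- tpl
  }
  out
}

decoy_protein <- function(with_p1 = FALSE) {
  s <- rand_aa(sample(80:200, 1))
  if (with_p1) {
    at <- sample(seq_len(nchar(s) - 9L), 1)
    substr(s, at, at + 8L) <- "ATSCSPVWA"
  }
  s
}

# Internal builder: genes/proteins/domains rows for one planted cluster,
# in coordinate order (not yet placed on a contig).
build_cluster_genes <- function(spec, templates, within) {
  roles <- SUBTYPE_ORDER[[spec$subtype]]
  if (identical(spec$t_variant, "downstream_adjacent_A") &&
      spec$subtype == "IV")
    roles <- c("A", "T", "B", "C")
  if (identical(spec$t_variant, "double_T"))
    roles <- c("T", setdiff(SUBTYPE_ORDER[[spec$subtype]], "T"), "T")
  if (!is.null(spec$omit_subunit))
    roles <- roles[-match(spec$omit_subunit, roles, nomatch = 0L)]
  tpl <- templates[[spec$subtype]]
  units <- lapply(roles, function(role) {
    protect <- if (role == "A") A_MOTIF_PROTECT else integer()
    list(role = role,
         protein = mutate_seq(tpl[[role]], within, protect),
         domains = subtype_domains(spec$subtype, role))
  })
  # interleave decoys at interior positions (transcription order)
  n_dec <- spec$intervening_decoys
  if (n_dec > 0L && length(units) > 1L) {
    gaps <- sample(seq_len(length(units) - 1L), n_dec, replace = TRUE)
    for (gp in sort(gaps, decreasing = TRUE)) {
      dec <- list(role = "X", protein = decoy_protein(), domains = NULL)
      units <- append(units, list(dec), after = gp)
    }
  }
  if (spec$strand == "-") units <- rev(units)  # coordinate order
  units
}

#' Plant a hydrogenase cluster on a contig
#'
#' Appends the cluster's genes (in the sub-type's canonical
#' transcription order on the requested strand, with any intervening
#' decoys) after the existing genes of `contig_id`, honouring omission
#' and edge-truncation requests, and returns the updated annotation
#' with the anchor id and a truth record.
#'
#' @param annotation A [genome_annotation()].
#' @param spec A [plant_spec()].
#' @param templates Per-sub-type role templates (made internally by
#'   [generate_genome_set()]; defaults to undiverged role templates).
#' @param contig_id Target contig (default: last contig).
#' @param divergence_within Per-instance substitution proportion.
#' @return List with `annotation` (updated), `anchor` (gene id or NA if
#'   the catalytic subunit was omitted) and `truth` (one-row
#'   data.frame).
#' @export
plant_cluster <- function(annotation, spec, templates = NULL,
                          contig_id = NULL, divergence_within = 0) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(spec, "plant_spec"))
  if (is.null(templates))
    templates <- stats::setNames(
      rep(list(SUBUNIT_TEMPLATES), length(SUBTYPE_ORDER)),
      names(SUBTYPE_ORDER))
  if (is.null(contig_id)) {
    if (!nrow(annotation$contigs)) stop("annotation has no contigs")
    contig_id <- annotation$contigs$contig_id[nrow(annotation$contigs)]
  }
  units <- build_cluster_genes(spec, templates,
                               within = divergence_within)

  g <- annotation$genes
  on_ctg <- g[g$contig_id == contig_id, , drop = FALSE]
  pos <- if (nrow(on_ctg)) max(on_ctg$end) else 0L
  n0 <- nrow(g)
  new <- list(); proteins <- annotation$proteins
  domains <- annotation$domains
  anchor <- NA_character_
  for (k in seq_along(units)) {
    u <- units[[k]]
    gid <- sprintf("%s_%s_pg%03d", annotation$genome_id, contig_id,
                   nrow(on_ctg) + k)
    protein <- u$protein
    partial <- FALSE
    start <- pos + sample(20:120, 1)
    end <- start + 3L * nchar(protein) + 2L
    if (spec$edge_truncate && k == length(units)) {
      keep <- ceiling(nchar(protein) * 0.5)
      protein <- substr(protein, 1L, keep)
      end <- start + 3L * keep + 2L
      partial <- TRUE
    }
    pos <- end
    if (u$role == "A") anchor <- gid
    new[[k]] <- data.frame(gene_id = gid, contig_id = contig_id,
                           start = start, end = end,
                           strand = spec$strand, partial = partial,
                           stringsAsFactors = FALSE)
    proteins[[gid]] <- protein
    if (!is.null(u$domains)) domains[[gid]] <- u$domains
  }
  genes <- rbind(g[, c("gene_id", "contig_id", "start", "end", "strand",
                       "partial")], do.call(rbind, new))
  contigs <- annotation$contigs
  ci <- match(contig_id, contigs$contig_id)
  contigs$length[ci] <- if (spec$edge_truncate) pos else pos + 150L

  ann <- genome_annotation(annotation$genome_id, genes, proteins,
                           domains, contigs)
  trunc_role <- if (spec$edge_truncate)
    units[[length(units)]]$role else NA_character_
  core_hit <- (!is.null(spec$omit_subunit) &&
                 spec$omit_subunit %in% c("B", "C")) ||
    (!is.na(trunc_role) && trunc_role %in% c("B", "C"))
  intact <- is.null(spec$omit_subunit) && !spec$edge_truncate
  truth <- data.frame(
    genome_id = annotation$genome_id, contig_id = contig_id,
    anchor = anchor, subtype = spec$subtype, strand = spec$strand,
    omit = if (is.null(spec$omit_subunit)) "none" else spec$omit_subunit,
    edge_truncate = spec$edge_truncate,
    truncated_role = trunc_role,
    t_variant = if (is.null(spec$t_variant)) "none" else spec$t_variant,
    intact = intact,
    expected_retained = !core_hit && !is.na(anchor),
    stringsAsFactors = FALSE)
  list(annotation = ann, anchor = anchor, truth = truth)
}

#' Generate a set of synthetic genomes with planted clusters
#'
#' Builds `n_genomes` multi-contig genomes. Each genome carries
#' `clusters_per_genome` planted hydrogenase clusters (one per contig,
#' sub-type drawn from `subtype_mix`, random strand, 0-2 intervening
#' decoys) plus one decoy-only contig. Subunit proteins derive from
#' per-role templates diverged once per sub-type
#' (`divergence_between`) and again per instance
#' (`divergence_within`), so concatenated A+B+C sequences cluster by
#' sub-type. The run is deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return List with `genomes` (named list of [genome_annotation()])
#'   and `truth` (data.frame, one row per planted cluster).
#' @export
generate_genome_set <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  run_with_seed(config$seed, {
    templates <- make_subtype_templates(config$divergence_between)
    genomes <- list()
    truth <- list()
    for (gi in seq_len(config$n_genomes)) {
      gid <- sprintf("SYNG%03d", gi)
      n_ctg <- config$clusters_per_genome + 1L
      genes <- list(); proteins <- list(); domains <- list()
      contigs <- data.frame(contig_id = sprintf("%s_c%02d", gid,
                                                seq_len(n_ctg)),
                            length = 0L, stringsAsFactors = FALSE)
      # decoy background on every contig
      for (cj in seq_len(n_ctg)) {
        ctg <- contigs$contig_id[cj]
        n_dec <- if (cj == n_ctg) config$decoy_gene_count
                 else sample(2:4, 1)
        pos <- 0L
        for (k in seq_len(n_dec)) {
          with_p1 <- stats::runif(1) < config$decoy_p1_fraction
          prot <- decoy_protein(with_p1)
          gid2 <- sprintf("%s_%s_d%03d", gid, ctg, k)
          start <- pos + sample(20:120, 1)
          end <- start + 3L * nchar(prot) + 2L
          pos <- end
          genes[[length(genes) + 1L]] <- data.frame(
            gene_id = gid2, contig_id = ctg, start = start, end = end,
            strand = sample(c("+", "-"), 1), partial = FALSE,
            stringsAsFactors = FALSE)
          proteins[[gid2]] <- prot
        }
        contigs$length[cj] <- pos + 150L
      }
      ann <- genome_annotation(gid, do.call(rbind, genes), proteins,
                               domains, contigs)
      # one planted cluster per non-background contig
      for (cj in seq_len(config$clusters_per_genome)) {
        st <- sample(names(config$subtype_mix), 1,
                     prob = config$subtype_mix)
        omit <- sample(names(config$omit_mix), 1,
                       prob = config$omit_mix)
        spec <- plant_spec(
          subtype = st, strand = sample(c("+", "-"), 1),
          intervening_decoys = sample(0:2, 1),
          omit_subunit = if (omit == "none") NULL else omit,
          edge_truncate = stats::runif(1) < config$edge_truncate_prob)
        res <- plant_cluster(ann, spec, templates,
                             contig_id = contigs$contig_id[cj],
                             divergence_within = config$divergence_within)
        ann <- res$annotation
        truth[[length(truth) + 1L]] <- res$truth
      }
      genomes[[gid]] <- ann
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(genome_id = character(), contig_id = character(),
                 anchor = character(), subtype = character(),
                 strand = character(), omit = character(),
                 edge_truncate = logical(), truncated_role = character(),
                 t_variant = character(), intact = logical(),
                 expected_retained = logical(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(genomes = genomes, truth = truth)
  })
}

#' Write a genome-bundle directory
#'
#' Per genome: `<id>.faa` (protein FASTA), `<id>.gff3` (gene features
#' with `ID` and `partial` attributes plus `##sequence-region`
#' pragmas) and `<id>.domains.tsv` (`gene_id`, `ordinal`,
#' `domain_label`); plus `truth.tsv` when a truth table is given.
#'
#' @param genomes Named list of [genome_annotation()] objects.
#' @param dir Output directory (created if needed).
#' @param truth Optional truth data.frame.
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(genomes, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ann in genomes) {
    id <- ann$genome_id
    aa <- Biostrings::AAStringSet(ann$proteins)
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(id, ".faa")),
                                width = 70L)
    g <- ann$genes
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d",
                       ann$contigs$contig_id, ann$contigs$length))
    if (nrow(g))
      lines <- c(lines, sprintf(
        "%s\tbfuscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;partial=%s",
        g$contig_id, g$start, g$end, g$strand, g$gene_id,
        ifelse(g$partial, "true", "false")))
    writeLines(lines, file.path(dir, paste0(id, ".gff3")))
    dom <- ann$domains
    rows <- if (length(dom)) do.call(rbind, lapply(names(dom), function(gid)
      data.frame(gene_id = gid, ordinal = seq_along(dom[[gid]]),
                 domain_label = dom[[gid]], stringsAsFactors = FALSE)))
    else data.frame(gene_id = character(), ordinal = integer(),
                    domain_label = character(), stringsAsFactors = FALSE)
    utils::write.table(rows, file.path(dir, paste0(id, ".domains.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
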