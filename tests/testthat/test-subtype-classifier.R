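# `roles` is the transcription order of the cluster: on the minus
# strand the coordinate order along the contig is its reverse.
cluster_for <- function(roles, strands = "+", subtype = "V",
                        partial = NULL) {
  if (all(strands == "-")) {
    roles <- rev(roles)
    if (!is.null(partial)) partial <- rev(partial)
  }
  ann <- toy_annotation(roles, strands = strands, subtype = subtype,
                        partial = partial)
  anchor <- ann$genes$gene_id[match("A", roles)]
  list(ann = ann,
       cl = extract_neighborhood(ann, anchor,
                                 bfua_calls = call_bfuA(ann)))
}

test_that("the intactness filter keeps clusters with a complete B and C core", {
  x <- cluster_for(c("A", "B", "D", "C"), subtype = "I")
  filt <- intactness_filter(x$cl, x$ann)
  expect_true(filt$retained)
  expect_length(filt$reasons, 0L)
})

test_that("a partial B subunit rejects the cluster with reason incomplete_B", {
  x <- cluster_for(c("A", "B", "C"), partial = c(FALSE, TRUE, FALSE))
  filt <- intactness_filter(x$cl, x$ann)
  expect_false(filt$retained)
  expect_equal(filt$reasons, "incomplete_B")
})

test_that("a missing C subunit rejects the cluster with reason no_C", {
  x <- cluster_for(c("A", "B", "X"))
  filt <- intactness_filter(x$cl, x$ann)
  expect_false(filt$retained)
  expect_equal(filt$reasons, "no_C")
})

test_that("a B architecture without B1 is domain-incomplete", {
  ann <- toy_annotation(c("A", "B", "C"))
  bid <- ann$genes$gene_id[2]
  ann$domains[[bid]] <- c("FMN", "Nqo1", "B2")
  cl <- extract_neighborhood(ann, ann$genes$gene_id[1])
  filt <- intactness_filter(cl, ann)
  expect_false(filt$retained)
  expect_equal(filt$reasons, "incomplete_B")
})

test_that("the five organizational patterns map to sub-types I-V", {
  cases <- list(
    list(roles = c("A", "B", "D", "C"), subtype = "I", label = "I"),
    list(roles = c("A", "B", "C"), subtype = "II", label = "II"),
    list(roles = c("C", "A", "B"), subtype = "III", label = "III"),
    list(roles = c("A", "B", "C", "T"), subtype = "IV", label = "IV"),
    list(roles = c("T", "A", "B", "C"), subtype = "V", label = "V"))
  for (cs in cases) {
    for (strand in c("+", "-")) {
      x <- cluster_for(cs$roles, strands = strand, subtype = cs$subtype)
      st <- assign_subtype(x$cl)
      expect_equal(st$label, cs$label,
                   info = paste(cs$label, strand))
    }
  }
})

test_that("interspersed non-subunit genes do not break pattern matching", {
  x <- cluster_for(c("A", "X", "B", "C", "X", "T"), subtype = "IV")
  expect_equal(assign_subtype(x$cl)$label, "IV")
})

test_that("sensory-gene placement drives the IV/V split and its variant flags", {
  x4 <- cluster_for(c("A", "T", "B", "C"), subtype = "IV")
  st4 <- assign_subtype(x4$cl)
  expect_equal(st4$label, "IV")
  expect_true("T_downstream_of_A" %in% st4$flags)

  x5 <- cluster_for(c("T", "A", "B", "C"), subtype = "V")
  st5 <- assign_subtype(x5$cl)
  expect_equal(st5$label, "V")
  expect_true("T_upstream_of_A" %in% st5$flags)

  xdt <- cluster_for(c("T", "A", "B", "C", "T"), subtype = "V")
  stdt <- assign_subtype(xdt$cl)
  expect_equal(stdt$label, "unclassified")
  expect_true("double_T" %in% stdt$flags)
})

test_that("accessory-subunit presence is flagged, not a new label", {
  x1 <- cluster_for(c("A", "B", "D", "C"), subtype = "I")
  expect_true("D_present" %in% assign_subtype(x1$cl)$flags)
  x2 <- cluster_for(c("A", "B", "C"), subtype = "II")
  expect_true("D_absent" %in% assign_subtype(x2$cl)$flags)
})

test_that("unmatched arrangements are unclassified with a nearest pattern", {
  x <- cluster_for(c("B", "A", "C"))
  st <- assign_subtype(x$cl)
  expect_equal(st$label, "unclassified")
  expect_true(any(grepl("^nearest_", st$reasons)))
})

test_that("identical clusters always receive identical calls", {
  x <- cluster_for(c("A", "B", "C", "T"), subtype = "IV")
  c1 <- classify_cluster(x$cl, x$ann)
  c2 <- classify_cluster(x$cl, x$ann)
  expect_identical(c1, c2)
  expect_true(c1$retained)
  expect_equal(c1$label, "IV")
})

test_that("sub-type summaries count labels and report distinct labels", {
  empty <- summarize_subtypes(list())
  expect_equal(empty$n_retained, 0L)
  expect_equal(empty$n_distinct_labels, 0L)
  expect_true(all(empty$overall == 0))

  calls <- list()
  specs <- list(c("A","B","D","C"), c("A","B","C"), c("C","A","B"),
                c("A","B","C","T"), c("T","A","B","C"))
  subs <- c("I", "II", "III", "IV", "V")
  for (i in seq_along(specs)) {
    x <- cluster_for(specs[[i]], subtype = subs[i])
    calls[[i]] <- classify_cluster(x$cl, x$ann)
  }
  s <- summarize_subtypes(calls)
  expect_equal(s$n_distinct_labels, 5L)
  expect_equal(s$n_retained, 5L)
  expect_equal(unname(as.integer(s$overall[c("I","II","III","IV","V")])),
               rep(1L, 5))
})
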