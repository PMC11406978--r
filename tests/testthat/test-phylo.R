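test_that("concatenation is always A then B then C regardless of gene order", {
  ann <- toy_annotation(c("C", "A", "B"), subtype = "III")
  cl <- extract_neighborhood(ann, ann$genes$gene_id[2])
  cc <- concat_abc(cl, ann$proteins)
  want <- paste0(role_protein("A"), role_protein("B"), role_protein("C"))
  expect_equal(cc, want)
  expect_equal(nchar(cc), sum(nchar(vapply(c("A", "B", "C"),
                                           role_protein, ""))))

  ann2 <- toy_annotation(c("A", "B", "C"), subtype = "V")
  cl2 <- extract_neighborhood(ann2, ann2$genes$gene_id[1])
  expect_equal(concat_abc(cl2, ann2$proteins), cc)

  ann3 <- toy_annotation(c("A", "B", "X"))
  cl3 <- extract_neighborhood(ann3, ann3$genes$gene_id[1])
  expect_error(concat_abc(cl3, ann3$proteins), "lacks subunit C")
})

test_that("k-mer Jaccard distance matches hand-enumerated sets", {
  expect_equal(kmer_distance(c(a = "MKLVNP", b = "MKLVNP"))["a", "b"], 0)
  d <- kmer_distance(c(a = "AAAAA", b = "CCCCC"), k = 4)
  expect_equal(d["a", "b"], 1)
  # "ABCDE" vs "BCDEF": sets {ABCD,BCDE} and {BCDE,CDEF}, Jaccard 1/3
  d2 <- kmer_distance(c(a = "ABCDE", b = "BCDEF"), k = 4)
  expect_equal(d2["a", "b"], 1 - 1 / 3)
  expect_error(kmer_distance(c(a = "MK"), k = 4), "shorter than k")
})

test_that("k-mer distance is an empirical pseudometric", {
  set.seed(88)
  for (rep in 1:30) {
    seqs <- c(a = rand_seq(30), b = rand_seq(30), c = rand_seq(30))
    d <- kmer_distance(seqs)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 3))
    expect_true(all(d >= 0 & d <= 1))
    expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-12)
  }
})

test_that("neighbor joining recovers an additive 4-taxon tree exactly", {
  # tree: (a,b) vs (c,d); terminal branches 2,3,4,5; internal branch 6
  d <- matrix(c(0, 5, 12, 13,
                5, 0, 13, 14,
                12, 13, 0, 9,
                13, 14, 9, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_equal(as.matrix(stats::cophenetic(tr))[letters[1:4], letters[1:4]],
               d, tolerance = 1e-10)
  # a and b are siblings
  sib <- ape::extract.clade(ape::root(tr, "c"), ape::getMRCA(
    ape::root(tr, "c"), c("a", "b")))$tip.label
  expect_setequal(sib, c("a", "b"))
})

test_that("neighbor joining recovers a random additive 8-taxon tree", {
  set.seed(99)
  true <- ape::rtree(8, br = function(n) runif(n, 0.5, 2))
  true <- ape::unroot(true)
  d <- as.matrix(stats::cophenetic(true))
  tr <- nj_tree(d)
  expect_equal(ape::dist.topo(tr, true), 0, ignore_attr = TRUE)
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(d), rownames(d)],
               d, tolerance = 1e-8)
})

test_that("three taxa get the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(unname(bl[c("x", "y", "z")]), c(1, 2, 3),
               tolerance = 1e-10)
})

test_that("degenerate all-equal distances give equal terminal branches", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- nj_tree(d)
  term <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_true(max(term) - min(term) < 1e-10)
  expect_true(all(tr$edge.length >= 0))
})

test_that("matrix validation rejects bad input", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 9, 0), 3, 3,
               dimnames = list(1:3, 1:3))
  expect_error(nj_tree(d3), "asymmetric")
})

test_that("purity is 1 for separated sub-types and < 1 for an intruder", {
  sep <- ape::read.tree(text = "((a:1,b:1):2,(c:1,(d:1,e:1):1):2,f:3);")
  rep1 <- subtype_purity(sep, c(a = "II", b = "II", c = "III",
                                d = "III", e = "III", f = "I"))
  expect_true(all(rep1$per_subtype$monophyletic))
  expect_equal(rep1$mean_purity, 1.0)

  # hand-worked: x (sub-type II) sits inside the III clade. The
  # bipartitions of this unrooted tree are ab|cxde, cx|abde and
  # de|abcx (plus trivial ones), so the smallest clade holding
  # {c,d,e} is {c,x,d,e} and the smallest holding {a,b,x} is
  # {a,b,c,x}: both purities 3/4
  mixed <- ape::read.tree(text = "((a:1,b:1):1,((c:1,x:1):1,(d:1,e:1):1):1);")
  rep2 <- subtype_purity(mixed, c(a = "II", b = "II", x = "II",
                                  c = "III", d = "III", e = "III"))
  p <- stats::setNames(rep2$per_subtype$purity, rep2$per_subtype$subtype)
  expect_equal(unname(p["III"]), 3 / 4)
  expect_equal(unname(p["II"]), 3 / 4)
  expect_equal(rep2$mean_purity, 3 / 4)
  expect_false(any(rep2$per_subtype$monophyletic))

  single <- subtype_purity(sep, c(a = "I", b = "I", c = "I",
                                  d = "I", e = "I", f = "I"))
  expect_equal(single$mean_purity, 1.0)

  expect_error(subtype_purity(sep, c(a = "I")), "unlabeled")
})
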