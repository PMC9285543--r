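test_that("parse_newick reads trees and validates input", {
  tr <- parse_newick("(A:1,B:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(sort(tr$edge.length), c(1, 1))

  tr3 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr3), 3)
  expect_equal(unname(tip_depths_brute(tr3)), c(2, 2, 2))

  expect_error(parse_newick("(A:1,B:1"), "position")
  expect_error(parse_newick("(A:1,B:1));"), "position 10")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "Duplicate")
  expect_error(parse_newick("((A,B),C);"), "branch lengths")
})

test_that("newick round-trip preserves topology and branch lengths", {
  tr <- simulate_tree(25, style = "fossil", seed = 11)
  back <- parse_newick(write_newick(tr))
  expect_setequal(back$tip.label, tr$tip.label)
  d0 <- tip_depths_brute(tr)
  d1 <- tip_depths_brute(back)
  expect_equal(d1[names(d0)], d0, tolerance = 1e-9)
})

test_that("timescale_fad_lad extends terminal branches to the LAD", {
  # F1/F2 diverge from their common ancestor at 150 Ma (root age 200)
  tr <- parse_newick("((F1:1,F2:1):50,E:200);")
  ranges <- data.frame(taxon = c("F1", "F2"),
                       fad_ma = c(145, 130), lad_ma = c(140, 120))
  out <- timescale_fad_lad(tr, ranges)
  d <- tip_depths_brute(out)
  # terminal branches span divergence (150) down to the LADs
  expect_equal(unname(d["F1"]), 200 - 140)
  expect_equal(unname(d["F2"]), 200 - 120)
  term <- out$edge.length[out$edge[, 2] <= 3]
  expect_false(isTRUE(all.equal(d[["F1"]], d[["F2"]])))  # non-ultrametric
  # extant tip extended to the present
  expect_equal(unname(d["E"]), 200)

  # single fossil diverging at 110 with FAD 100 / LAD 90: branch = 20
  tr2 <- parse_newick("((F:1,E1:110):10,E2:120);")
  out2 <- timescale_fad_lad(tr2, data.frame(taxon = "F", fad_ma = 100,
                                            lad_ma = 90))
  e_f <- which(out2$edge[, 2] == match("F", out2$tip.label))
  expect_equal(out2$edge.length[e_f], 20)
})

test_that("timescale_fad_lad validates ranges and taxa", {
  tr <- parse_newick("((F1:1,F2:1):50,E:200);")
  expect_error(
    timescale_fad_lad(tr, data.frame(taxon = "F1", fad_ma = 100,
                                     lad_ma = 120)),
    "FAD must be >= LAD")
  expect_error(
    timescale_fad_lad(tr, data.frame(taxon = "F1", fad_ma = 170,
                                     lad_ma = 160)),
    "older than its divergence")
  expect_error(
    timescale_fad_lad(tr, data.frame(taxon = "F1", fad_ma = 145,
                                     lad_ma = 140), extant = "E"),
    "F2")
  expect_error(
    timescale_fad_lad(tr, data.frame(taxon = "nope", fad_ma = 10,
                                     lad_ma = 5)),
    "nope")
})

test_that("the equal rule shares ancestral time into zero branches", {
  # chain root -2- n1 -0- n2 -2- {A,B}; expected branches 1, 1, 2
  tr <- parse_newick("(((A:2,B:2):0,C:2):2,D:4);")
  out <- resolve_zero_branches_equal(tr)
  expect_true(all(out$edge.length[out$edge[, 2] > ape::Ntip(out)] > 0))
  d0 <- tip_depths_brute(tr)
  d1 <- tip_depths_brute(out)
  expect_equal(d1[names(d0)], d0, tolerance = 1e-9)
  # the donor branch and the zero branch each get 1 Myr
  root_child <- out$edge.length[out$edge[, 1] == ape::Ntip(out) + 1L]
  expect_true(any(abs(root_child - 1) < 1e-9))

  # run of two zero branches: 3 Myr split into 1, 1, 1
  tr2 <- parse_newick("((((A:3,B:3):0,C:3):0,D:3):3,E:6);")
  out2 <- resolve_zero_branches_equal(tr2)
  internal_len <- sort(out2$edge.length[out2$edge[, 2] > ape::Ntip(out2)])
  expect_equal(internal_len, c(1, 1, 1), tolerance = 1e-9)
  expect_equal(tip_depths_brute(out2), tip_depths_brute(tr2),
               tolerance = 1e-9)
})

test_that("equal resolution is identity without zero branches and errors at the root", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(resolve_zero_branches_equal(tr)$edge.length, tr$edge.length)
  expect_error(resolve_zero_branches_equal(parse_newick("((A:1,B:1):0,C:1);")),
               "no positive-length ancestral branch")
})

test_that("equal resolution preserves all root-to-tip depths on random trees", {
  for (s in 1:5) {
    tr <- random_zero_branch_tree(20, n_zero = 3, seed = s)
    out <- resolve_zero_branches_equal(tr)
    expect_equal(tip_depths_brute(out), tip_depths_brute(tr),
                 tolerance = 1e-9)
    expect_true(all(out$edge.length[out$edge[, 2] > ape::Ntip(out)] > 0))
  }
})

test_that("phylo_vcv returns shared root-to-MRCA path lengths", {
  V2 <- phylo_vcv(parse_newick("(A:1,B:1);"))
  expect_equal(unname(V2), diag(2))

  V3 <- phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(unname(diag(V3)), c(2, 2, 2))
  expect_equal(V3["A", "B"], 1)
  expect_equal(V3["A", "C"], 0)
  expect_equal(V3, t(V3))

  # requested taxa order is respected
  Vs <- phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"), taxa = c("C", "A"))
  expect_equal(rownames(Vs), c("C", "A"))
  expect_equal(Vs["C", "A"], 0)
  expect_error(phylo_vcv(V3 <- parse_newick("(A:1,B:1);"), taxa = "Z"), "Z")
})

test_that("phylo_vcv is positive semi-definite on random trees", {
  for (s in 1:6) {
    tr <- simulate_tree(15, style = if (s %% 2) "fossil" else "ultrametric",
                        seed = s)
    ev <- eigen(phylo_vcv(tr), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8))
  }
})

test_that("fossil diagonal entries equal root age minus LAD after timescaling", {
  tr <- parse_newick("((F1:1,F2:1):50,E:200);")
  out <- timescale_fad_lad(tr, data.frame(taxon = c("F1", "F2"),
                                          fad_ma = c(145, 130),
                                          lad_ma = c(140, 120)))
  V <- phylo_vcv(out)
  expect_equal(V["F1", "F1"], 200 - 140)
  expect_equal(V["F2", "F2"], 200 - 120)
})

test_that("tip labels match with space/underscore equivalence", {
  tr <- parse_newick("((Tyrannosaurus_rex:1,B:1):1,C:2);")
  V <- phylo_vcv(tr, taxa = c("Tyrannosaurus rex", "C"))
  expect_equal(rownames(V)[1], "Tyrannosaurus_rex")
})
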