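test_that("p_distance handles gaps, ambiguity and undefined pairs", {
  expect_equal(p_distance("ACGT", "ACGT"), list(distance = 0, n_comparable = 4L))
  expect_equal(p_distance("ACGT", "ACGA"), list(distance = 0.25, n_comparable = 4L))
  # sites 1,2,4 comparable, all matching (gap and N excluded)
  expect_equal(p_distance("AC-TN", "ACGTA"), list(distance = 0, n_comparable = 3L))
  expect_error(p_distance("ACG", "ACGT"), "equal-length")
  expect_error(p_distance("NNNN", "ACGT"), "no comparable sites")
})

test_that("p_distance agrees with the brute-force counter on random pairs", {
  set.seed(101)
  alphabet <- c("A", "C", "G", "T", "N", "R", "-", "Y")
  for (i in 1:200) {
    n <- sample(20:80, 1)
    a <- random_dna(n, alphabet)
    b <- random_dna(n, alphabet)
    want <- oracle_p_distance(a, b)
    if (want$n_comparable == 0) {
      expect_error(p_distance(a, b), "no comparable sites")
    } else {
      expect_identical(p_distance(a, b),
                       list(distance = want$distance,
                            n_comparable = want$n_comparable))
    }
  }
})

test_that("distance_matrix assembles pairwise calls; complete deletion drops columns", {
  aln <- make_alignment(
    c("ACGTACGT", "ACGTACGA", "AC-TACGA"),
    species = c("x", "y", "z"),
    role = c("target", "non_target", "non_target")
  )
  dm <- distance_matrix(aln, "pairwise")
  expect_identical(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  for (i in 1:2) for (j in (i + 1):3) {
    want <- p_distance(aln$residues[i], aln$residues[j])
    expect_equal(dm$d[i, j], want$distance)
    expect_equal(dm$n_comparable[i, j], want$n_comparable)
  }

  # complete deletion drops column 3 (gap in record 3) for every pair
  dmc <- distance_matrix(aln, "complete")
  expect_true(all(dmc$n_comparable[upper.tri(dmc$n_comparable)] == 7L))
  expect_equal(dmc$d["s01", "s02"], 1 / 7)

  # k identical sequences -> all off-diagonal zero; one distinct third
  aln2 <- make_alignment(c("AAAA", "AAAA", "TTTT"), rep("s", 3),
                         c("target", "target", "non_target"))
  dm2 <- distance_matrix(aln2)
  expect_equal(dm2$d["s01", "s02"], 0)
  expect_equal(sum(dm2$d[upper.tri(dm2$d)] == 0), 1L)

  expect_error(
    distance_matrix(make_alignment(c("N-", "AN"), c("a", "b"),
                                   c("target", "non_target"))),
    "no comparable sites between 's01' and 's02'"
  )
})

test_that("distance_matrix is symmetric with zero diagonal on random alignments", {
  set.seed(77)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    n <- sample(30:90, 1)
    aln <- make_alignment(
      replicate(k, random_dna(n, c("A", "C", "G", "T", "N", "-"))),
      species = sprintf("sp%d", seq_len(k)),
      role = c("target", rep("non_target", k - 1))
    )
    dm <- tryCatch(distance_matrix(aln), error = function(e) NULL)
    if (is.null(dm)) next
    expect_identical(dm$d, t(dm$d))
    expect_true(all(diag(dm$d) == 0))
    expect_true(all(dm$d >= 0 & dm$d <= 1))
    expect_true(all(dm$n_comparable[upper.tri(dm$n_comparable)] >= 1))
  }
})

test_that("nj_tree reproduces the worked additive example", {
  # additive matrix of tree ((A:1,B:2):1,C:3,D:4); four-point condition holds
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_true(D["A", "B"] + D["C", "D"] <= max(D["A", "C"] + D["B", "D"],
                                               D["A", "D"] + D["B", "C"]))
  tr <- nj_tree(D)
  expect_setequal(tree_bipartitions_for_test(tr), "C|D")
  path <- ape::cophenetic.phylo(tr)
  expect_equal(path[rownames(D), colnames(D)], D, tolerance = 1e-9)
  # leaf edges 1,2,3,4 and internal edge 1
  lens <- sort(tr$edge.length)
  expect_equal(lens, c(1, 1, 2, 3, 4))
})

test_that("nj_tree: 3 taxa closed form, zero matrix, error cases", {
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  a <- (D["A", "B"] + D["A", "C"] - D["B", "C"]) / 2
  b <- (D["A", "B"] + D["B", "C"] - D["A", "C"]) / 2
  c_ <- (D["A", "C"] + D["B", "C"] - D["A", "B"]) / 2
  expect_equal(sort(tr$edge.length), sort(c(a, b, c_)))

  Z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  trz <- nj_tree(Z)
  expect_true(all(trz$edge.length == 0))
  expect_equal(length(trz$tip.label), 4L)

  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3 taxa")
})

test_that("nj_tree recovers random additive topologies (n <= 12)", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    gen <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
    gen <- ape::unroot(gen)
    D <- ape::cophenetic.phylo(gen)   # additive by construction
    tr <- nj_tree(D)
    expect_setequal(tree_bipartitions_for_test(tr), ape_bipartitions(gen))
    path <- ape::cophenetic.phylo(tr)
    expect_equal(path[rownames(D), colnames(D)], D, tolerance = 1e-9)
  }
})

test_that("bootstrap support is 100 on a perfectly informative alignment and deterministic", {
  aln <- make_alignment(
    c(strrep("A", 40), strrep("A", 40), strrep("G", 40), strrep("G", 40)),
    species = c("t", "t", "x", "y"),
    role = c("target", "target", "non_target", "non_target"),
    ids = LETTERS[1:4]
  )
  tr <- bootstrap_support(aln, replicates = 50, seed = 7)
  support <- attr(tr, "bootstrap")$support
  expect_equal(unname(support[["C|D"]]), 100L)

  tr2 <- bootstrap_support(aln, replicates = 50, seed = 7)
  expect_identical(attr(tr2, "bootstrap")$support, support)
  expect_identical(tr2$node.label, tr$node.label)

  expect_error(bootstrap_support(aln, replicates = 0, seed = 1), ">= 1")
})

test_that("bootstrap support on simulated 4-taxon data with strong signal is high", {
  # two clades separated by many fixed differences, light within-clade noise
  set.seed(9)
  core <- random_dna(200)
  other <- chartr("ACGT", "GTAC", core)        # every column informative
  noise <- function(s) mutate_sequence(s, 0.01, sample.int(1e6, 1))
  aln <- make_alignment(
    c(noise(core), noise(core), noise(other), noise(other)),
    species = c("t", "t", "x", "x"),
    role = c("target", "target", "non_target", "non_target"),
    ids = c("A", "B", "C", "D")
  )
  tr <- bootstrap_support(aln, replicates = 100, seed = 3)
  expect_gte(attr(tr, "bootstrap")$support[["C|D"]], 95L)
  expect_true(all(attr(tr, "bootstrap")$support >= 0 &
                  attr(tr, "bootstrap")$support <= 100))
})

test_that("bootstrap supports are invariant under input-order permutation", {
  set.seed(31)
  core <- random_dna(150)
  other <- chartr("ACGT", "GTAC", core)
  seqs <- c(mutate_sequence(core, 0.02, 1), mutate_sequence(core, 0.02, 2),
            mutate_sequence(other, 0.02, 3), mutate_sequence(other, 0.02, 4))
  aln <- make_alignment(seqs, c("t", "t", "x", "x"),
                        c("target", "target", "non_target", "non_target"),
                        ids = c("A", "B", "C", "D"))
  perm <- c(4, 2, 1, 3)
  aln_p <- make_alignment(aln$residues[perm], aln$species[perm],
                          aln$role[perm], ids = aln$id[perm])
  s1 <- attr(bootstrap_support(aln, 30, seed = 5), "bootstrap")$support
  s2 <- attr(bootstrap_support(aln_p, 30, seed = 5), "bootstrap")$support
  expect_identical(s1[sort(names(s1))], s2[sort(names(s2))])
})
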