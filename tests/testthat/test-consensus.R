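# label helper: string shorthand like "AABB" -> Partition
P <- function(s, k = NULL) {
  l <- match(strsplit(s, "")[[1]], LETTERS)
  Partition(l, k = if (is.null(k)) max(l) else k)
}

test_that("co-association of identical partitions is the 0/1 co-membership matrix", {
  p <- P("AABBC")
  ens <- clusterEnsemble(list(p, p, p))
  S <- buildCoassociation(ens)
  co <- outer(p@labels, p@labels, `==`) * 1
  expect_equal(S, co)
  expect_equal(diag(S), rep(1, 5))
})

test_that("co-association averages agreement across partitions", {
  ens <- clusterEnsemble(list(P("AABB"), P("ABAB")))
  S <- buildCoassociation(ens)
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[1, 3], 0.5)
  expect_equal(S[1, 4], 0)
  expect_equal(S[3, 4], 0.5)
})

test_that("CSPA recovers unanimous and block structure", {
  p <- P("AABBB")
  S <- buildCoassociation(clusterEnsemble(list(p, p, p)))
  expect_equal(adjustedRandIndex(cspaPartition(S, 2), p), 1)
  Sblk <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
                cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
  got <- cspaPartition(Sblk, 2)
  expect_equal(adjustedRandIndex(got, P("AAABBB")), 1)
  expect_error(cspaPartition(Sblk, 7), "targetK")
})

test_that("CSPA consensus is at least as faithful as a noisy minority member", {
  # majority structure AABBCC supported by 3 members, 1 scrambled member
  maj <- P("AABBCC")
  ens <- clusterEnsemble(list(maj, maj, maj, P("ABCABC")), targetK = 3)
  cons <- cspaPartition(buildCoassociation(ens), 3)
  ariCons <- adjustedRandIndex(cons, maj)
  ariNoisy <- adjustedRandIndex(P("ABCABC"), maj)
  expect_gte(ariCons, ariNoisy)
  expect_equal(ariCons, 1)
})

test_that("the hypergraph has one hyperedge per nonempty cluster", {
  ens <- clusterEnsemble(list(P("AABBCC"), P("ABABAB", k = 3)))
  H <- buildHypergraph(ens)
  expect_equal(length(H@edges), 5)   # 3 + 2 nonempty (C empty in 2nd)
  ens2 <- clusterEnsemble(list(P("AABB"), P("ABAB")))
  H2 <- buildHypergraph(ens2)
  expect_equal(H2@edges[[1]], c(1L, 2L))
  expect_equal(H2@edges[[2]], c(3L, 4L))
  # each partition's edges disjointly cover the vertex set
  expect_setequal(unlist(H2@edges[1:2]), 1:4)
  expect_setequal(unlist(H2@edges[3:4]), 1:4)
})

test_that("HGPA finds the zero-cut optimum when one exists", {
  p <- P("AAABBB")
  ens <- clusterEnsemble(list(p, p, p))
  H <- buildHypergraph(ens)
  got <- hgpaPartition(H, 2, seed = 1)
  expect_equal(hyperedgeCut(H, got), 0)
  expect_equal(adjustedRandIndex(got, p), 1)
})

test_that("HGPA cut is bounded below by the exhaustive balanced minimum", {
  for (seed in 1:20) {
    labs <- randomEnsemble(n = 10, B = 3, kmax = 3, seed = 100 + seed)
    ens <- clusterEnsemble(asPartitions(labs), targetK = 2)
    H <- buildHypergraph(ens)
    got <- hgpaPartition(H, 2, imbalanceTolerance = 0.2, restarts = 20,
                         seed = seed)
    lo <- ceiling(0.8 * 10 / 2); hi <- floor(1.2 * 10 / 2)
    best <- bruteMinBipartitionCut(H@edges, 10, lo, hi)
    expect_gte(hyperedgeCut(H, got), best)
  }
})

test_that("HGPA validates the imbalance constraint", {
  p <- P("AAABBB")
  H <- buildHypergraph(clusterEnsemble(list(p, p)))
  expect_error(hgpaPartition(H, 4, imbalanceTolerance = 0), "infeasible")
  expect_error(hgpaPartition(H, 1), "targetK")
})

test_that("label alignment inverts a permutation and is idempotent on itself", {
  ref <- P("AABBCC")
  perm <- Partition(c(3L, 3L, 1L, 1L, 2L, 2L), k = 3)   # relabeled copy
  aligned <- alignLabels(ref, perm)
  expect_identical(partitionLabels(aligned), partitionLabels(ref))
  self <- alignLabels(ref, ref)
  expect_identical(partitionLabels(self), partitionLabels(ref))
})

test_that("alignment maximizes overlap, verified by exhaustive mapping search", {
  ref <- P("AABBB")
  other <- P("BBAAA")
  # two possible bijections of {A,B}: identity overlap 0, swap overlap 5
  aligned <- alignLabels(ref, other)
  expect_equal(sum(partitionLabels(aligned) == partitionLabels(ref)), 5)

  ref2 <- P("AABBC")
  other2 <- P("BABAC")   # one disagreeing row under the best mapping
  aligned2 <- alignLabels(ref2, other2)
  overlap <- sum(partitionLabels(aligned2) == partitionLabels(ref2))
  # exhaustive search over all 3! label bijections
  best <- 0
  for (pm in list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
    best <- max(best, sum(pm[other2@labels] == ref2@labels))
  expect_equal(overlap, best)
})

test_that("surplus clusters keep fresh labels", {
  ref <- P("AABB")
  other <- P("ABCD")
  aligned <- alignLabels(ref, other)
  expect_equal(aligned@k, 4L)
  expect_equal(length(unique(partitionLabels(aligned))), 4)
})

test_that("the Hungarian solver matches brute force on random cost matrices", {
  solveAssignment <- UPDRSens:::solveAssignment
  perms4 <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms4 <- perms4[apply(perms4, 1, function(r) length(unique(r)) == 4), ]
  for (s in 1:50) {
    set.seed(300 + s)
    cost <- matrix(runif(16, -5, 5), 4, 4)
    got <- solveAssignment(cost)
    gotCost <- sum(cost[cbind(1:4, got)])
    bruteCost <- min(apply(perms4, 1, function(pm) sum(cost[cbind(1:4, pm)])))
    expect_equal(gotCost, bruteCost, tolerance = 1e-10)
  }
})

test_that("majority voting takes the modal aligned label per row", {
  # the 2-vs-1 worked case: algorithms 1 and 2 put patient 1 in cluster A,
  # algorithm 3 puts it in cluster B -> cluster A wins
  a1 <- P("ABAB"); a2 <- P("ABBA"); a3 <- P("BBAA")
  cons <- majorityVote(clusterEnsemble(list(a1, a2, a3)))
  expect_equal(partitionLabels(cons)[1], 1L)

  # unanimity returns the common partition
  u <- P("AABBC")
  expect_identical(partitionLabels(majorityVote(clusterEnsemble(list(u, u, u)))),
                   partitionLabels(u))

  # per-row tally oracle with one dissent per row
  base <- P("AABBCC")
  d1 <- Partition(c(2L, 1L, 2L, 2L, 3L, 3L), k = 3)  # row 1 dissents
  d2 <- Partition(c(1L, 1L, 2L, 3L, 3L, 1L), k = 3)  # rows 4, 6 dissent
  cons2 <- majorityVote(clusterEnsemble(list(base, d1, d2)))
  expect_identical(partitionLabels(cons2), partitionLabels(base))
})

test_that("all consensus functions are label-permutation invariant and idempotent", {
  for (s in 1:10) {
    labs <- randomEnsemble(n = 12, B = 3, kmax = 3, seed = 400 + s)
    parts <- asPartitions(labs)
    ens <- clusterEnsemble(parts, targetK = 2)
    # permute the label names of one member
    permuted <- parts
    k1 <- parts[[2]]@k
    pm <- withr::with_seed(s, sample(k1))
    permuted[[2]] <- Partition(pm[parts[[2]]@labels], k = k1)
    ensP <- clusterEnsemble(permuted, targetK = 2)

    for (fun in list(
      function(e) majorityVote(e),
      function(e) cspaPartition(buildCoassociation(e), e@targetK),
      function(e) hgpaPartition(buildHypergraph(e), e@targetK, seed = 7))) {
      expect_equal(adjustedRandIndex(fun(ens), fun(ensP)), 1)
    }
  }
  # consensus of B copies is the partition itself, all three methods
  p <- P("AAABBBCCC")
  ens <- clusterEnsemble(list(p, p, p), targetK = 3)
  expect_equal(adjustedRandIndex(majorityVote(ens), p), 1)
  expect_equal(adjustedRandIndex(cspaPartition(buildCoassociation(ens), 3), p), 1)
  expect_equal(adjustedRandIndex(
    hgpaPartition(buildHypergraph(ens), 3, seed = 2), p), 1)
})

test_that("CSPA and HGPA are deterministic given their seed", {
  labs <- randomEnsemble(n = 12, B = 4, kmax = 3, seed = 77)
  ens <- clusterEnsemble(asPartitions(labs), targetK = 2)
  S <- buildCoassociation(ens)
  expect_identical(partitionLabels(cspaPartition(S, 2)),
                   partitionLabels(cspaPartition(S, 2)))
  H <- buildHypergraph(ens)
  expect_identical(partitionLabels(hgpaPartition(H, 2, seed = 5)),
                   partitionLabels(hgpaPartition(H, 2, seed = 5)))
})
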