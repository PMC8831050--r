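# Consensus functions fusing a ClusterEnsemble into one Partition:
# evidence accumulation (co-association + similarity reclustering, CSPA),
# balanced minimal hyperedge cut (HGPA), and Hungarian-aligned majority
# voting.

#' Co-association matrix of a cluster ensemble
#'
#' Entry (i, j) is the fraction of ensemble partitions that place rows i
#' and j in the same cluster: the evidence-accumulation similarity the
#' CSPA consensus reclusters.
#'
#' @param ensemble a [ClusterEnsemble-class].
#' @return Symmetric numeric matrix with unit diagonal and entries in
#'   [0, 1].
#' @export
buildCoassociation <- function(ensemble) {
  stopIfNot(is(ensemble, "ClusterEnsemble"), "ensemble must be a ClusterEnsemble")
  ps <- ensemble@partitions
  n <- length(ps[[1]]@labels)
  S <- matrix(0, n, n)
  for (p in ps) {
    l <- p@labels
    S <- S + (outer(l, l, `==`) * 1)
  }
  S / length(ps)
}

#' CSPA consensus: recluster the co-association similarity
#'
#' Cluster-based similarity partitioning: rows are regrouped by
#' average-linkage agglomerative clustering of the co-association
#' similarity (distance = 1 - similarity) cut at `targetK`. Fully
#' deterministic.
#'
#' @param S co-association matrix from [buildCoassociation()].
#' @param targetK consensus cluster count, 2..rows.
#' @return A [Partition-class] tagged `"CSPA"`.
#' @export
cspaPartition <- function(S, targetK) {
  n <- nrow(S)
  stopIfNot(targetK >= 2 && targetK <= n, "targetK must lie in 2..rows")
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  Partition(stats::cutree(hc, k = targetK), k = targetK, source = "CSPA")
}

#' Hypergraph: clusters as hyperedges over row vertices
#'
#' @slot nVertices integer row count.
#' @slot edges list of integer vertex subsets, one per nonempty cluster of
#'   each ensemble partition.
#' @export
setClass("Hypergraph",
  representation(nVertices = "integer", edges = "list"))

setValidity("Hypergraph", function(object) {
  if (any(vapply(object@edges, length, integer(1)) == 0))
    return("no empty hyperedge allowed")
  ix <- unlist(object@edges)
  if (length(ix) && (min(ix) < 1L || max(ix) > object@nVertices))
    return("hyperedge vertices out of range")
  TRUE
})

setMethod("show", "Hypergraph", function(object) {
  cat(sprintf("Hypergraph: %d vertices, %d hyperedges\n", object@nVertices,
              length(object@edges)))
})

#' Build the hypergraph of a cluster ensemble
#'
#' One hyperedge per nonempty cluster of each partition (empty SOM
#' clusters are dropped); each partition's hyperedges disjointly cover
#' the vertex set.
#'
#' @param ensemble a [ClusterEnsemble-class].
#' @return A [Hypergraph-class].
#' @export
buildHypergraph <- function(ensemble) {
  stopIfNot(is(ensemble, "ClusterEnsemble"), "ensemble must be a ClusterEnsemble")
  n <- length(ensemble@partitions[[1]]@labels)
  edges <- list()
  for (p in ensemble@partitions)
    for (cc in seq_len(p@k)) {
      v <- which(p@labels == cc)
      if (length(v)) edges[[length(edges) + 1L]] <- v
    }
  new("Hypergraph", nVertices = as.integer(n), edges = edges)
}

#' Number of cut hyperedges under a partition
#'
#' A hyperedge is cut when its vertices span more than one part.
#'
#' @param H a [Hypergraph-class].
#' @param partition a [Partition-class] over the vertices.
#' @return Integer cut count.
#' @export
hyperedgeCut <- function(H, partition) {
  l <- partition@labels
  sum(vapply(H@edges, function(e) length(unique(l[e])) > 1L, logical(1)))
}

#' HGPA consensus: balanced minimal hyperedge cut
#'
#' Splits the vertices into `targetK` parts, each of size within
#' `(1 +/- imbalanceTolerance) * n / targetK`, minimizing the number of
#' cut hyperedges by multi-restart greedy vertex-move refinement
#' (Fiduccia-Mattheyses-style gains). Deterministic given `seed`.
#'
#' @param H a [Hypergraph-class].
#' @param targetK number of parts (>= 2).
#' @param imbalanceTolerance allowed relative part-size deviation
#'   (default 0.2).
#' @param restarts independent seeded restarts (default 20); the best cut
#'   is returned.
#' @param seed integer RNG seed.
#' @return A [Partition-class] tagged `"HGPA"`.
#' @export
hgpaPartition <- function(H, targetK, imbalanceTolerance = 0.2,
                          restarts = 20, seed = 1) {
  n <- H@nVertices
  k <- as.integer(targetK)
  stopIfNot(k >= 2, "targetK must be >= 2")
  lo <- ceiling((1 - imbalanceTolerance) * n / k)
  hi <- floor((1 + imbalanceTolerance) * n / k)
  if (k * lo > n || k * hi < n || hi < 1)
    stop(sprintf("imbalance constraint infeasible: n=%d, k=%d, tolerance=%g",
                 n, k, imbalanceTolerance), call. = FALSE)

  edges <- H@edges
  nE <- length(edges)
  vEdges <- vector("list", n)
  for (e in seq_len(nE)) for (v in edges[[e]])
    vEdges[[v]] <- c(vEdges[[v]], e)
  eLen <- vapply(edges, length, integer(1))

  best <- NULL; bestCut <- Inf
  for (r in seq_len(restarts)) {
    res <- withSeed(subSeed(seed, r), {
      lab <- integer(n)
      lab[sample.int(n)] <- rep_len(seq_len(k), n)
      cnt <- matrix(0L, nE, k)
      for (e in seq_len(nE))
        cnt[e, ] <- tabulate(lab[edges[[e]]], nbins = k)
      sizes <- tabulate(lab, nbins = k)

      # (cut gain, majority-mass gain) of moving one vertex from -> to,
      # restricted to the given incident edges; a vertex is in every
      # incident edge, so cnt[e, from] >= 1 there
      moveDelta <- function(edgesIdx, from, to) {
        if (!length(edgesIdx)) return(c(0L, 0L))
        cv <- cnt[edgesIdx, , drop = FALSE]
        span <- rowSums(cv > 0L)
        newSpan <- span - (cv[, from] == 1L) + (cv[, to] == 0L)
        gain <- sum(span > 1L) - sum(newSpan > 1L)
        cv2 <- cv
        cv2[, from] <- cv2[, from] - 1L; cv2[, to] <- cv2[, to] + 1L
        mass <- sum(apply(cv2, 1, max)) - sum(apply(cv, 1, max))
        c(gain, mass)
      }
      applyMove <- function(v, to) {
        ev <- vEdges[[v]]; from <- lab[v]
        cnt[ev, from] <<- cnt[ev, from] - 1L
        cnt[ev, to] <<- cnt[ev, to] + 1L
        sizes[from] <<- sizes[from] - 1L; sizes[to] <<- sizes[to] + 1L
        lab[v] <<- to
      }

      for (pass in seq_len(25)) {
        moved <- FALSE
        for (v in sample.int(n)) {
          p <- lab[v]
          if (sizes[p] <= lo) next
          ev <- vEdges[[v]]
          if (is.null(ev)) next
          bestGain <- 0L; bestMass <- 0L; bestQ <- 0L
          for (q in seq_len(k)) {
            if (q == p || sizes[q] >= hi) next
            d <- moveDelta(ev, p, q)
            # the majority-mass potential breaks ties on the plateau of
            # large cut edges, where single moves never change the cut
            if ((d[1] > bestGain ||
                 (d[1] == bestGain && d[2] > bestMass)) &&
                (d[1] > 0L || d[2] > 0L)) {
              bestGain <- d[1]; bestMass <- d[2]; bestQ <- q
            }
          }
          if (bestQ > 0L) { applyMove(v, bestQ); moved <- TRUE }
        }
        if (!moved && hi - lo < 2L) {
          # tight size bounds can block every single move; try pairwise
          # swaps with a bounded sample of partners from other parts
          # (wide bounds never need this, and the scan is quadratic)
          for (v in sample.int(n)) {
            p <- lab[v]
            others <- which(lab != p)
            if (length(others) > 30)
              others <- sample(others, 30)
            ev <- vEdges[[v]]
            for (u in others) {
              q <- lab[u]
              shared <- intersect(ev, vEdges[[u]])
              dv <- moveDelta(setdiff(ev, shared), p, q)
              du <- moveDelta(setdiff(vEdges[[u]], shared), q, p)
              g <- dv[1] + du[1]; ms <- dv[2] + du[2]
              if (g > 0L || (g == 0L && ms > 0L)) {
                applyMove(v, q); applyMove(u, p)
                moved <- TRUE
                break
              }
            }
            if (moved) break
          }
        }
        if (!moved) break
      }
      list(lab = lab, cut = sum(rowSums(cnt > 0L) > 1L))
    })
    if (res$cut < bestCut) { bestCut <- res$cut; best <- res$lab }
  }
  Partition(best, k = k, source = "HGPA")
}

## Hungarian assignment -------------------------------------------------

# minimal-cost perfect assignment on a square cost matrix; O(n^3)
# shortest-augmenting-path Hungarian with row/column potentials
solveAssignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        }
      }
      for (j in seq_len(n)) if (!used[j + 1]) minv[j] <- minv[j] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) assign[p[j + 1]] <- j
  assign
}

#' Align one partition's labels to a reference
#'
#' Relabels `other`'s clusters to maximize total overlap with
#' `reference`, by optimal assignment (Hungarian method) on the
#' contingency-table overlaps. When `other` has more clusters than the
#' reference, surplus clusters keep fresh labels beyond the reference's
#' range.
#'
#' @param reference,other [Partition-class] objects over the same rows.
#' @return `other` relabeled; `k` is `max(k_reference, k_other)`.
#' @export
alignLabels <- function(reference, other) {
  stopIfNot(length(reference@labels) == length(other@labels),
            "partitions must label the same rows")
  kr <- reference@k; ko <- other@k
  M <- matrix(0, ko, kr)
  tab <- table(factor(other@labels, levels = seq_len(ko)),
               factor(reference@labels, levels = seq_len(kr)))
  M[] <- as.numeric(tab)
  # canonical content order (cluster's smallest member row) so that
  # assignment ties resolve independently of arbitrary label names
  firstRow <- function(p, k) vapply(seq_len(k), function(cc) {
    w <- which(p@labels == cc)
    if (length(w)) w[1] else Inf
  }, numeric(1))
  oOrd <- order(firstRow(other, ko))
  rOrd <- order(firstRow(reference, kr))
  s <- max(kr, ko)
  cost <- matrix(0, s, s)
  cost[seq_len(ko), seq_len(kr)] <- -M[oOrd, rOrd, drop = FALSE]
  assign <- solveAssignment(cost)   # canonical other slot -> canonical slot
  mapping <- integer(ko)
  fresh <- kr
  for (oi in seq_len(ko)) {
    tgt <- assign[oi]
    mapping[oOrd[oi]] <- if (tgt <= kr) rOrd[tgt] else {
      fresh <- fresh + 1L; fresh
    }
  }
  Partition(mapping[other@labels], k = max(kr, fresh),
            source = paste0(other@source, " (aligned)"))
}

#' Majority-voting consensus
#'
#' All partitions are aligned to the first via [alignLabels()]; each row
#' then receives its modal aligned label. Ties are broken by the label of
#' the earliest partition in ensemble order. Fully deterministic.
#'
#' @param ensemble a [ClusterEnsemble-class].
#' @return A [Partition-class] tagged `"majority vote"`.
#' @export
majorityVote <- function(ensemble) {
  stopIfNot(is(ensemble, "ClusterEnsemble"), "ensemble must be a ClusterEnsemble")
  ps <- ensemble@partitions
  ref <- ps[[1]]
  aligned <- c(list(ref), lapply(ps[-1], function(p) alignLabels(ref, p)))
  L <- vapply(aligned, partitionLabels, integer(length(ref@labels)))
  L <- matrix(L, ncol = length(aligned))
  maxLab <- max(L)
  lab <- integer(nrow(L))
  for (i in seq_len(nrow(L))) {
    counts <- tabulate(L[i, ], nbins = maxLab)
    winners <- which(counts == max(counts))
    if (length(winners) == 1L) lab[i] <- winners
    else {
      # earliest partition whose aligned label is among the tied winners
      first <- L[i, ][L[i, ] %in% winners][1]
      lab[i] <- first
    }
  }
  Partition(lab, k = max(lab), source = "majority vote")
}
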