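#' Pairwise distance matrix over aligned LTR rows
#'
#' Distances use [countDivergence()] proportions under the requested model
#' (default K2P, consistent with the dating module). Rows with fewer than
#' `minBases` aligned bases are dropped with a warning — short LTR fragments
#' are not informative for pairing analysis.
#'
#' @param x An [ErvAlignment-class].
#' @param names Rows to include (default: all rows except the reference).
#' @param model `"raw"`, `"JC"` or `"K2P"`.
#' @param kappa Passed through to [consensusDistance()].
#' @param minBases Minimum number of base characters per row (default 250).
#' @return Symmetric numeric matrix with zero diagonal and the row names as
#'   dimnames.
#' @export
ltrDistanceMatrix <- function(x, names = NULL, model = "K2P", kappa = 2,
                              minBases = 250L) {
  names <- names %||% setdiff(alignmentNames(x), referenceName(x))
  m <- as.matrix(x)[names, , drop = FALSE]
  nb <- rowSums(matrix(m %in% BASES, nrow = nrow(m)))
  if (any(nb < minBases)) {
    warning(sprintf("dropping %d row(s) with < %d aligned bases: %s",
                    sum(nb < minBases), minBases,
                    paste(names[nb < minBases], collapse = ", ")))
    names <- names[nb >= minBases]
    m <- m[names, , drop = FALSE]
  }
  n <- length(names)
  dm <- matrix(0, n, n, dimnames = list(names, names))
  if (n < 2L) return(dm)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- tryCatch(consensusDistance(m[i, ], m[j, ], model = model, kappa = kappa),
                    error = function(e) NA_real_)
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

#' Build a neighbor-joining tree from a distance matrix
#'
#' A from-scratch implementation of the canonical neighbor-joining
#' agglomeration (Saitou-Nei Q-criterion, standard branch-length and
#' distance-reduction formulas), deterministic under ties (the
#' lowest-index pair is joined first). Returns an unrooted `phylo` object
#' (the `ape` tree container) so standard tree utilities apply.
#'
#' @param dm Symmetric numeric distance matrix (size >= 3, zero diagonal,
#'   non-negative entries) with dimnames.
#' @return An object of class `phylo` with an extra attribute `cherries`: a
#'   character matrix of label pairs that were joined as two leaves (used as
#'   confirmatory evidence of cognate-LTR pairing).
#' @export
buildNjTree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("dm must be a square matrix")
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(is.na(dm))) stop("dm contains NA distances")
  if (max(abs(dm - t(dm))) > 1e-8) stop("dm must be symmetric")
  if (any(dm < 0)) stop("dm must be non-negative")
  if (any(diag(dm) != 0)) stop("dm must have zero diagonal")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))

  D <- dm
  nodeId <- seq_len(n)           # current node ids (tips 1..n, then internals)
  nextId <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  elen <- numeric(0)
  cherries <- matrix(character(0), 0, 2)

  while (length(nodeId) > 3L) {
    r <- length(nodeId)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    ## lowest-index pair among minima (column-major order of which())
    k <- which(Q == min(Q))[1L]
    i <- (k - 1L) %% r + 1L; j <- (k - 1L) %/% r + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    u <- nextId; nextId <- nextId + 1L
    edges <- rbind(edges, c(u, nodeId[i]), c(u, nodeId[j]))
    elen <- c(elen, bi, bj)
    if (nodeId[i] <= n && nodeId[j] <= n) {
      cherries <- rbind(cherries, c(labels[nodeId[i]], labels[nodeId[j]]))
    }
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]), c(dNew[keep], 0))
    nodeId <- c(nodeId[keep], u)
  }
  ## final star join of the remaining three nodes
  u <- nextId
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  edges <- rbind(edges, c(u, nodeId[1L]), c(u, nodeId[2L]), c(u, nodeId[3L]))
  elen <- c(elen, b)
  if (nodeId[1L] <= n && nodeId[2L] <= n) {
    cherries <- rbind(cherries, c(labels[nodeId[1L]], labels[nodeId[2L]]))
  }

  ## renumber internals to the phylo convention: root = n+1, then the rest
  internals <- unique(edges[, 1L])
  oldOrder <- c(u, setdiff(rev(internals), u))  # root first
  map <- integer(max(edges))
  map[seq_len(n)] <- seq_len(n)
  map[oldOrder] <- n + seq_along(oldOrder)
  edges2 <- cbind(map[edges[, 1L]], map[edges[, 2L]])
  tree <- structure(list(edge = edges2, edge.length = elen,
                         tip.label = labels, Nnode = length(internals)),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "cherries") <- cherries
  tree
}

#' Detect non-paired cognate LTRs (post-integration recombination)
#'
#' The 5' and 3' LTRs of a provirus are identical at integration and evolve
#' independently afterwards, so each should be the other's nearest neighbor
#' among all LTRs. Gene conversion or recombination after integration
#' violates this: a provirus is flagged unpaired when some other LTR is
#' closer to one of its LTRs than the cognate is, by more than a noise floor
#' (ties and sub-floor margins resolve toward paired — distance differences
#' of a few substitutions are sampling noise, while a conversion leaves a
#' near-identical twin of the converted LTR elsewhere in the genome, a
#' signal of several percent). When a tree is supplied, whether the two LTRs
#' form a cherry is recorded and used as confirmatory evidence.
#'
#' @param dm Distance matrix from [ltrDistanceMatrix()] over all provirus
#'   5'/3' LTR rows.
#' @param pairing data.frame with columns `provirus_id`, `ltr5`, `ltr3`
#'   naming the cognate rows.
#' @param tree Optional `phylo`/[buildNjTree()] result for the cherry check.
#' @param marginFloor Minimum excess (substitutions/site) by which another
#'   LTR must beat the cognate before the pair is called non-paired
#'   (default 0.015).
#' @return data.frame with columns `provirus_id`, `paired`,
#'   `mutual_nearest_neighbor`, `clade_monophyly`, `nearest_other`.
#' @export
detectUnpairedLtrs <- function(dm, pairing, tree = NULL, marginFloor = 0.015) {
  cherries <- if (!is.null(tree)) attr(tree, "cherries") else NULL
  res <- lapply(seq_len(nrow(pairing)), function(k) {
    p <- pairing[k, ]
    if (!(p$ltr5 %in% rownames(dm)) || !(p$ltr3 %in% rownames(dm))) {
      warning(sprintf("provirus %s skipped: cognate LTR missing from matrix", p$provirus_id))
      return(NULL)
    }
    dCog <- dm[p$ltr5, p$ltr3]
    others5 <- setdiff(rownames(dm), c(p$ltr5, p$ltr3))
    if (!length(others5)) {
      return(data.frame(provirus_id = p$provirus_id, paired = TRUE,
                        mutual_nearest_neighbor = TRUE, clade_monophyly = NA,
                        nearest_other = NA_character_, stringsAsFactors = FALSE))
    }
    d5 <- dm[p$ltr5, others5]; d3 <- dm[p$ltr3, others5]
    minOther <- min(c(d5, d3), na.rm = TRUE)
    mnn <- dCog <= minOther + marginFloor   # ties and sub-floor margins toward paired
    nearestOther <- others5[which.min(pmin(d5, d3))]
    mono <- NA
    if (!is.null(cherries)) {
      mono <- nrow(cherries) > 0 &&
        any((cherries[, 1L] == p$ltr5 & cherries[, 2L] == p$ltr3) |
            (cherries[, 1L] == p$ltr3 & cherries[, 2L] == p$ltr5))
    }
    ## headline call: the distance criterion, confirmed by the tree when one
    ## is supplied — a provirus is reported unpaired only when its LTRs are
    ## neither mutual nearest neighbors nor sisters in the NJ tree
    paired <- if (is.na(mono)) mnn else (mnn || mono)
    data.frame(provirus_id = p$provirus_id, paired = paired,
               mutual_nearest_neighbor = mnn, clade_monophyly = mono,
               nearest_other = nearestOther, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(provirus_id = character(0), paired = logical(0),
                      mutual_nearest_neighbor = logical(0),
                      clade_monophyly = logical(0), nearest_other = character(0)))
  }
  do.call(rbind, res)
}

#' Scan a proviral genome for inter-subgroup recombination breakpoints
#'
#' Slides a window along the alignment, assigns each window to the subgroup
#' consensus with the highest percent identity, and merges consecutive
#' same-call windows into segments that tile the scanned range (boundaries
#' fall midway between adjacent window centers). Windows whose best-vs-
#' runner-up identity margin is below `marginFloor` (percentage points) or
#' with fewer than `minCompared` comparable columns inherit the previous
#' call — subgroup consensuses are >95% identical, so small margins are
#' noise.
#'
#' @param x An [ErvAlignment-class].
#' @param element Row name of the provirus to scan.
#' @param subgroupConsensus Named list of consensus rows (same frame).
#' @param window Window width in columns (default 500).
#' @param step Step in columns (default 100).
#' @param marginFloor Minimum identity margin (percentage points, default 1).
#' @param minCompared Minimum base-vs-base columns per window (default 50).
#' @return data.frame of segments: `provirus_id`, `start_col`, `end_col`,
#'   `best_subgroup`, `margin` (mean over the segment's confident windows).
#' @export
scanBreakpoints <- function(x, element, subgroupConsensus, window = 500L,
                            step = 100L, marginFloor = 1, minCompared = 50L) {
  if (length(subgroupConsensus) < 2L) stop("need at least 2 subgroup references")
  row <- .splitRow(alignmentRow(x, element))
  cons <- lapply(subgroupConsensus, .splitRow)
  w <- alignmentWidth(x)
  starts <- seq(1L, max(1L, w - window + 1L), by = step)
  centers <- pmin(starts + (window - 1L) / 2, w)
  calls <- character(length(starts)); margins <- numeric(length(starts))
  for (k in seq_along(starts)) {
    cols <- seq(starts[k], min(w, starts[k] + window - 1L))
    ids <- vapply(cons, function(cc) {
      a <- row[cols]; b <- cc[cols]
      both <- .isBase(a) & .isBase(b)
      if (sum(both) < minCompared) return(NA_real_)
      100 * sum(a[both] == b[both]) / sum(both)
    }, numeric(1))
    if (all(is.na(ids))) { calls[k] <- NA_character_; margins[k] <- NA_real_; next }
    o <- order(ids, decreasing = TRUE)
    margins[k] <- if (length(ids) > 1L && !is.na(ids[o[2L]])) ids[o[1L]] - ids[o[2L]] else Inf
    calls[k] <- names(ids)[o[1L]]
    if (margins[k] < marginFloor) calls[k] <- NA_character_  # ambiguous
  }
  ## ambiguous/NA windows inherit the previous confident call
  lastCall <- NA_character_
  for (k in seq_along(calls)) {
    if (is.na(calls[k])) calls[k] <- lastCall else lastCall <- calls[k]
  }
  ## leading NAs inherit the first confident call
  firstOk <- which(!is.na(calls))[1L]
  if (is.na(firstOk)) stop("no confident window calls; margin floor too high?")
  calls[seq_len(firstOk - 1L)] <- calls[firstOk]
  ## merge runs into segments tiling [1, w]
  r <- rle(calls)
  ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
  segs <- lapply(seq_along(r$values), function(s) {
    startCol <- if (s == 1L) 1L else floor((centers[begs[s]] + centers[begs[s] - 1L]) / 2) + 1L
    endCol <- if (s == length(r$values)) w else floor((centers[ends[s]] + centers[ends[s] + 1L]) / 2)
    data.frame(provirus_id = element, start_col = as.integer(startCol),
               end_col = as.integer(endCol), best_subgroup = r$values[s],
               margin = mean(margins[begs[s]:ends[s]], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}
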