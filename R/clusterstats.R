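## Cluster-based Monte Carlo permutation test on time-frequency maps.
##
## Per-bin two-sample pooled-variance t (first group minus second), bins
## thresholded at p < alphaBin, split by sign, grouped under 4-connectivity
## on the frequency x time lattice, filtered by size > minSize.  The
## family-wise correction uses the max-statistic over cluster mass (sum of
## member t values): for each random relabelling of subjects the maximum
## |mass| over that permutation's candidate clusters enters the null
## distribution, and an observed cluster's p is (1 + #{null >= |mass|}) /
## (nPerm + 1).

#' Per-bin two-sample t map
#'
#' Pooled-variance two-sample t (groupOrder[1] minus groupOrder[2]) per
#' time-frequency bin, with df = n1 + n2 - 2 and two-tailed p.  Bins with an
#' NA in any subject or zero pooled variance give NA.
#'
#' @param maps subjects x bins matrix, or a list of
#'   \code{\linkS4class{TimeFreqMap}} / freq x time matrices (one per
#'   subject, shared grid).
#' @param group group label per subject (two levels).
#' @param groupOrder length-2 character: which group is the positive side of
#'   the contrast; default \code{c("Control", "PD")} when present, else the
#'   sorted levels.
#' @return list(t = , p = , df = ) where t and p have one entry per bin (in
#'   matrix form if the input was a list of maps).
#' @export
tMap <- function(maps, group, groupOrder = NULL) {
  X <- stackMaps(maps)
  group <- as.character(group)
  if (is.null(groupOrder)) {
    lv <- unique(group)
    groupOrder <- if (all(c("Control", "PD") %in% lv)) c("Control", "PD") else sort(lv)
  }
  a <- group == groupOrder[1L]
  b <- group == groupOrder[2L]
  n1 <- sum(a)
  n2 <- sum(b)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  df <- n1 + n2 - 2L
  m1 <- colMeans(X$values[a, , drop = FALSE])
  m2 <- colMeans(X$values[b, , drop = FALSE])
  ss1 <- colSums(X$values[a, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X$values[b, , drop = FALSE]^2) - n2 * m2^2
  s2 <- (ss1 + ss2) / df
  denom <- sqrt(s2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / denom
  t[!is.finite(t)] <- NA_real_
  p <- 2 * pt(-abs(t), df)
  if (!is.null(X$dim)) {
    t <- matrix(t, X$dim[1L], X$dim[2L])
    p <- matrix(p, X$dim[1L], X$dim[2L])
  }
  list(t = t, p = p, df = df)
}

## normalize input to a subjects x bins matrix (+ original matrix dims)
stackMaps <- function(maps) {
  if (is.matrix(maps)) return(list(values = maps, dim = NULL))
  vals <- lapply(maps, function(m) {
    if (is(m, "TimeFreqMap")) m@values else m
  })
  d <- dim(vals[[1L]])
  for (m in vals) {
    if (!identical(dim(m), d)) stop("all subject maps must share one grid")
  }
  list(values = do.call(rbind, lapply(vals, as.vector)), dim = d)
}

## 4-connected component labelling of a logical matrix via column runs +
## union-find.  Returns an integer label matrix (0 = background).
connComp4 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  runCol <- integer(0)
  runLo <- integer(0)
  runHi <- integer(0)
  for (j in seq_len(nc)) {
    v <- mask[, j]
    if (!any(v)) next
    dd <- diff(c(FALSE, v, FALSE))
    lo <- which(dd == 1L)
    hi <- which(dd == -1L) - 1L
    runCol <- c(runCol, rep(j, length(lo)))
    runLo <- c(runLo, lo)
    runHi <- c(runHi, hi)
  }
  nRun <- length(runCol)
  if (!nRun) return(lab)
  parent <- seq_len(nRun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prevIdx <- integer(0)
  prevCol <- -1L
  colIdx <- split(seq_len(nRun), runCol)
  cols <- as.integer(names(colIdx))
  for (ci in seq_along(cols)) {
    cur <- colIdx[[ci]]
    if (prevCol == cols[ci] - 1L) {
      for (i in cur) {
        for (k in prevIdx) {
          if (runLo[i] <= runHi[k] && runLo[k] <= runHi[i]) {
            ri <- find(i)
            rk <- find(k)
            if (ri != rk) parent[ri] <- rk
          }
        }
      }
    }
    prevIdx <- cur
    prevCol <- cols[ci]
  }
  roots <- vapply(seq_len(nRun), find, integer(1L))
  relab <- match(roots, unique(roots))
  for (i in seq_len(nRun)) {
    lab[runLo[i]:runHi[i], runCol[i]] <- relab[i]
  }
  lab
}

#' Find candidate supra-threshold clusters
#'
#' Threshold bins at p < alphaBin, split by the sign of t, group into
#' maximal 4-connected components on the frequency x time lattice, and keep
#' components larger than minSize bins.
#'
#' @param t,p freq x time matrices (NA bins never enter a cluster).
#' @param alphaBin per-bin threshold (default 0.05).
#' @param minSize retain clusters with size strictly greater than this
#'   (default 100 bins on the full grid).
#' @param freqs,times map axes (for onset/peak bookkeeping); indices are
#'   used when absent.
#' @return list of clusters, each a list(bins, size, mass, sign, onsetTime,
#'   minFreq, peak, pPerm = NA), ordered by decreasing |mass|.
#' @export
findClusters <- function(t, p, alphaBin = 0.05, minSize = 100,
                         freqs = NULL, times = NULL) {
  if (is.null(freqs)) freqs <- seq_len(nrow(t))
  if (is.null(times)) times <- seq_len(ncol(t))
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- !is.na(p) & p < alphaBin & !is.na(t) & sign(t) == sgn
    if (!any(mask)) next
    lab <- connComp4(mask)
    for (id in seq_len(max(lab))) {
      bins <- which(lab == id)
      if (length(bins) <= minSize) next
      rc <- arrayInd(bins, dim(t))
      tv <- t[bins]
      pk <- which.max(abs(tv))
      out[[length(out) + 1L]] <- list(
        bins = bins, size = length(bins), mass = sum(tv), sign = sgn,
        onsetTime = min(times[rc[, 2L]]), minFreq = min(freqs[rc[, 1L]]),
        peak = c(
          freq = freqs[rc[pk, 1L]], time = times[rc[pk, 2L]],
          t = abs(tv[pk])
        ),
        pPerm = NA_real_
      )
    }
  }
  if (length(out) > 1L) {
    out <- out[order(-vapply(out, function(cl) abs(cl$mass), numeric(1L)))]
  }
  out
}

## max |cluster mass| among candidate clusters of one t map (0 if none);
## threshold via |t| > tcrit (equivalent to p < alphaBin)
maxClusterMass <- function(tmat, tcrit, minSize) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- !is.na(tmat) & (sgn * tmat) > tcrit
    if (!any(mask)) next
    lab <- connComp4(mask)
    if (max(lab) == 0L) next
    sizes <- tabulate(lab)
    masses <- vapply(
      seq_along(sizes),
      function(id) sum(tmat[lab == id]), numeric(1L)
    )
    keep <- sizes > minSize
    if (any(keep)) best <- max(best, abs(masses[keep]))
  }
  best
}

#' Cluster-based Monte Carlo permutation test
#'
#' Compares subject-level contrast maps between two groups with the
#' max-statistic cluster-mass correction: nPerm random relabellings of
#' subjects into groups of the original sizes build the null distribution of
#' the maximum absolute candidate-cluster mass, and each observed cluster
#' gets p = (1 + #\{null >= |mass|\}) / (nPerm + 1).  Clusters are retained
#' when p < alphaCluster and size > minSize.  Seeded and reproducible.
#'
#' @inheritParams tMap
#' @param nPerm number of permutations (default 1000; < 100 warns about p
#'   resolution).
#' @param alphaBin per-bin threshold.
#' @param minSize minimum cluster size (strict).
#' @param alphaCluster cluster-level threshold (default 0.05).
#' @param seed integer seed.
#' @param chunk permutations per vectorized block (memory/speed knob, no
#'   effect on results).
#' @param freqs,times map axes for bookkeeping.
#' @return a \code{\linkS4class{ClusterResult}}.
#' @export
permutationTest <- function(maps, group, nPerm = 1000, alphaBin = 0.05,
                            minSize = 100, alphaCluster = 0.05, seed = 1,
                            chunk = 250, groupOrder = NULL,
                            freqs = NULL, times = NULL) {
  X <- stackMaps(maps)
  if (is.list(maps) && is(maps[[1L]], "TimeFreqMap")) {
    if (is.null(freqs)) freqs <- maps[[1L]]@freqs
    if (is.null(times)) times <- maps[[1L]]@times
  }
  dims <- X$dim
  if (is.null(dims)) {
    if (is.null(freqs) || is.null(times)) {
      stop("matrix input requires explicit 'freqs' and 'times'")
    }
    dims <- c(length(freqs), length(times))
  }
  if (is.null(freqs)) freqs <- seq_len(dims[1L])
  if (is.null(times)) times <- seq_len(dims[2L])
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) != 2L) stop("exactly two groups required")
  if (min(table(group)) < 3L) stop("need at least 3 subjects per group")
  if (nPerm < 100) warning("fewer than 100 permutations: coarse p resolution")

  obs <- tMap(X$values, group, groupOrder)
  tObs <- matrix(obs$t, dims[1L], dims[2L])
  pObs <- matrix(obs$p, dims[1L], dims[2L])
  clusters <- findClusters(tObs, pObs, alphaBin, minSize, freqs, times)

  nSub <- length(group)
  if (is.null(groupOrder)) {
    groupOrder <- if (all(c("Control", "PD") %in% lv)) c("Control", "PD") else sort(lv)
  }
  n1 <- sum(group == groupOrder[1L])
  n2 <- nSub - n1
  df <- n1 + n2 - 2L
  tcrit <- qt(1 - alphaBin / 2, df)

  valid <- colSums(is.na(X$values)) == 0L
  Xv <- X$values[, valid, drop = FALSE]
  Xsq <- Xv^2
  totS <- colSums(Xv)
  totQ <- colSums(Xsq)

  set.seed(seed)
  nullMax <- numeric(nPerm)
  done <- 0L
  tFull <- rep(NA_real_, length(valid))
  while (done < nPerm) {
    m <- min(chunk, nPerm - done)
    I <- matrix(0, m, nSub)
    for (i in seq_len(m)) I[i, sample.int(nSub, n1)] <- 1
    S1 <- I %*% Xv
    Q1 <- I %*% Xsq
    S2 <- matrix(totS, m, ncol(Xv), byrow = TRUE) - S1
    Q2 <- matrix(totQ, m, ncol(Xv), byrow = TRUE) - Q1
    m1 <- S1 / n1
    m2 <- S2 / n2
    s2 <- ((Q1 - n1 * m1^2) + (Q2 - n2 * m2^2)) / df
    tP <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
    for (i in seq_len(m)) {
      tFull[valid] <- tP[i, ]
      nullMax[done + i] <- maxClusterMass(
        matrix(tFull, dims[1L], dims[2L]), tcrit, minSize
      )
    }
    done <- done + m
  }

  for (i in seq_along(clusters)) {
    clusters[[i]]$pPerm <-
      (1 + sum(nullMax >= abs(clusters[[i]]$mass))) / (nPerm + 1)
  }
  retained <- vapply(
    clusters, function(cl) cl$pPerm < alphaCluster, logical(1L)
  )

  new("ClusterResult",
    tMap = tObs, pMap = pObs, df = df, clusters = clusters,
    retained = retained, nullMax = nullMax, nPerm = nPerm, seed = seed,
    alphaBin = alphaBin, minSize = minSize, freqs = freqs, times = times
  )
}
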