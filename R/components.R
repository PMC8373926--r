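## Components: retained clusters ordered by latency, subject/trial scoring,
## and ICC(2,k) trial-level reliability.

#' Extract ordered components from a cluster result
#'
#' Retained clusters are sorted by their earliest member time bin (ties:
#' lower minimum frequency first) and labelled "Component 1", "Component 2",
#' ...; the sign records the direction of the group contrast (+1 when the
#' first contrast group, e.g. Control, has higher power).
#'
#' @param result a \code{\linkS4class{ClusterResult}}.
#' @param retainedOnly use only retained clusters (default) or all
#'   candidates.
#' @return a \code{\linkS4class{ComponentSet}} (empty when no cluster was
#'   retained).
#' @export
extractComponents <- function(result, retainedOnly = TRUE) {
  cls <- if (retainedOnly) retainedClusters(result) else result@clusters
  d <- dim(result@tMap)
  ord <- order(
    vapply(cls, function(cl) cl$onsetTime, numeric(1L)),
    vapply(cls, function(cl) cl$minFreq, numeric(1L))
  )
  cls <- cls[ord]
  masks <- lapply(cls, function(cl) {
    m <- matrix(FALSE, d[1L], d[2L])
    m[cl$bins] <- TRUE
    m
  })
  peaks <- if (length(cls)) {
    do.call(rbind, lapply(cls, function(cl) {
      data.frame(freq = cl$peak[["freq"]], time = cl$peak[["time"]], t = cl$peak[["t"]])
    }))
  } else {
    data.frame(freq = numeric(), time = numeric(), t = numeric())
  }
  new("ComponentSet",
    masks = masks,
    labels = if (length(cls)) paste("Component", seq_along(cls)) else character(),
    signs = vapply(cls, function(cl) cl$sign, numeric(1L)),
    onsets = vapply(cls, function(cl) cl$onsetTime, numeric(1L)),
    peaks = peaks, freqs = result@freqs, times = result@times
  )
}

#' Score subjects (and trials) on components
#'
#' A subject's score on a component is the mean contrast value (dB) over the
#' component's mask bins, NaN bins excluded; trial scores are computed
#' identically from single-trial contrast maps.  z-scoring is pooled across
#' both groups (all subjects on one scale).
#'
#' @param components a \code{\linkS4class{ComponentSet}}.
#' @param maps list of subject contrast maps
#'   (\code{\linkS4class{TimeFreqMap}} or matrices) on the component grid.
#' @param trialMaps optional list (per subject) of trials x freq x time
#'   arrays of single-trial contrast maps.
#' @param subjects,groups subject ids and group labels (recovered from
#'   TimeFreqMap info when absent).
#' @return the \code{ComponentSet} with \code{scores}, \code{zScores} and
#'   \code{trialScores} filled in.
#' @export
scoreSubjects <- function(components, maps, trialMaps = NULL,
                          subjects = NULL, groups = NULL) {
  k <- nComponents(components)
  vals <- lapply(maps, function(m) if (is(m, "TimeFreqMap")) m@values else m)
  if (is.null(subjects)) {
    subjects <- vapply(seq_along(maps), function(i) {
      m <- maps[[i]]
      if (is(m, "TimeFreqMap") && !is.null(m@info$subject)) m@info$subject else sprintf("s%02d", i)
    }, character(1L))
  }
  if (is.null(groups)) {
    groups <- vapply(seq_along(maps), function(i) {
      m <- maps[[i]]
      if (is(m, "TimeFreqMap") && !is.null(m@info$group)) m@info$group else NA_character_
    }, character(1L))
  }
  scores <- matrix(NA_real_, length(vals), k,
    dimnames = list(subjects, components@labels)
  )
  for (s in seq_along(vals)) {
    for (j in seq_len(k)) {
      v <- vals[[s]][components@masks[[j]]]
      scores[s, j] <- mean(v, na.rm = TRUE)
    }
  }
  if (anyNA(scores)) {
    warning("some subjects have all-NaN mask bins; their scores are NA")
  }
  z <- scale(scores)
  trialScores <- list()
  if (!is.null(trialMaps)) {
    trialScores <- lapply(seq_along(trialMaps), function(s) {
      tm <- trialMaps[[s]]
      nt <- dim(tm)[1L]
      out <- matrix(NA_real_, nt, k, dimnames = list(NULL, components@labels))
      for (tr in seq_len(nt)) {
        m <- matrix(tm[tr, , ], dim(tm)[2L], dim(tm)[3L])
        for (j in seq_len(k)) out[tr, j] <- mean(m[components@masks[[j]]], na.rm = TRUE)
      }
      out
    })
    names(trialScores) <- subjects
  }
  out <- components
  out@scores <- scores
  out@zScores <- z[, , drop = FALSE]
  out@trialScores <- trialScores
  out@subjects <- subjects
  out@groups <- groups
  out
}

#' Long-format trial scores of a scored ComponentSet
#'
#' @param components a scored \code{\linkS4class{ComponentSet}} with trial
#'   scores.
#' @param z z-score the component columns across all trials pooled?
#' @return data.frame with columns subject, group and one column per
#'   component (\code{comp1}, \code{comp2}, ...).
#' @export
trialScoreTable <- function(components, z = TRUE) {
  if (!length(components@trialScores)) stop("no trial scores present")
  k <- nComponents(components)
  rows <- lapply(seq_along(components@trialScores), function(s) {
    ts <- components@trialScores[[s]]
    data.frame(
      subject = components@subjects[s], group = components@groups[s],
      ts, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  compCols <- seq(3L, 2L + k)
  names(out)[compCols] <- paste0("comp", seq_len(k))
  if (z && k > 0) {
    for (j in compCols) out[[j]] <- as.numeric(scale(out[[j]]))
  }
  rownames(out) <- NULL
  out
}

#' ICC(2,k): two-way random effects, average measures
#'
#' ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n) with MSR the between-rows
#' mean square, MSC the between-columns mean square, MSE the residual, n the
#' number of rows and k the number of columns.
#'
#' @param mat rows x columns score matrix (e.g. subjects x trial splits);
#'   rows with missing cells are dropped listwise.
#' @return list(icc2k, msr, msc, mse, n, k).
#' @export
icc2k <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 columns")
  grand <- mean(mat)
  rowm <- rowMeans(mat)
  colm <- colMeans(mat)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0) stop("zero between-row variance: ICC undefined")
  list(
    icc2k = (msr - mse) / (msr + (msc - mse) / n),
    msr = msr, msc = msc, mse = mse, n = n, k = k
  )
}

#' Subjects x trial-split score matrix for ICC
#'
#' Splits each subject's trials into k random equal-count groups and
#' averages the component score within each split: rows = subjects, columns
#' = splits, the design matrix for \code{\link{icc2k}}.
#'
#' @param components a scored \code{\linkS4class{ComponentSet}} with trial
#'   scores.
#' @param component component index.
#' @param nSplits number of trial splits (columns), default 4.
#' @param seed integer seed for the random split.
#' @param subjects optional subset of subject ids (e.g. one group).
#' @return subjects x nSplits numeric matrix.
#' @export
iccSplitScores <- function(components, component = 1L, nSplits = 4L,
                           seed = 1, subjects = NULL) {
  if (!length(components@trialScores)) stop("no trial scores present")
  set.seed(seed)
  ids <- components@subjects
  if (!is.null(subjects)) ids <- intersect(ids, subjects)
  out <- matrix(NA_real_, length(ids), nSplits, dimnames = list(ids, NULL))
  for (s in seq_along(ids)) {
    ts <- components@trialScores[[ids[s]]][, component]
    ts <- ts[is.finite(ts)]
    nt <- length(ts)
    if (nt < nSplits) next
    grp <- sample(rep(seq_len(nSplits), length.out = nt))
    out[s, ] <- vapply(
      seq_len(nSplits),
      function(g) mean(ts[grp == g]), numeric(1L)
    )
  }
  out
}
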