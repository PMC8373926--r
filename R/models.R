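## Classification and association models: mixed-effect logistic regression
## on trial-level component scores, AIC comparison, forward stepwise
## selection, confusion metrics, hyposmia labelling, mixed-effect linear
## clinical associations and 80% subsample bootstrap validation.

#' Mixed-effect logistic classification of group from trial scores
#'
#' Fits group (positive class = PD) on trial-level predictors with a
#' by-participant random intercept (Laplace approximation via
#' \code{lme4::glmer}).  Subject-level predicted probability is the mean of
#' the trial-level population predictions (random effects excluded from
#' prediction, so the intercepts cannot memorize the outcome); the predicted
#' label uses threshold 0.5.  Perfect separation is flagged; if the mixed
#' fit fails outright, a weakly ridge-penalized trial-level logistic
#' regression is used instead and flagged.
#'
#' @param trialScores data.frame with columns \code{subject}, \code{group}
#'   and the predictor columns (z-scored trial scores).
#' @param predictors character vector of predictor column names.
#' @param positive label of the positive class (default \code{"PD"}).
#' @return object of class \code{"LogisticFit"}: list with coefficients,
#'   \code{logLik}, \code{aic}, \code{nObs}, \code{nParams},
#'   \code{subjectProb}, \code{subjectPred}, \code{subjectGroup},
#'   \code{separation}, \code{fallback} and \code{predictors}.
#' @export
fitLogistic <- function(trialScores, predictors, positive = "PD") {
  stopifnot(all(c("subject", "group") %in% names(trialScores)))
  missing <- setdiff(predictors, names(trialScores))
  if (length(missing)) {
    stop(sprintf("predictor(s) not found: %s", paste(missing, collapse = ", ")))
  }
  df <- trialScores
  df$y <- as.integer(df$group == positive)
  if (length(unique(df$y)) < 2L) stop("both classes must be present")
  form <- stats::as.formula(paste(
    "y ~", paste(c("1", predictors), collapse = " + "), "+ (1 | subject)"
  ))
  fit <- NULL
  fallback <- FALSE
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::glmer(form, data = df, family = stats::binomial)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fallback <- TRUE
    X <- cbind(1, as.matrix(df[, predictors, drop = FALSE]))
    beta <- ridgeLogistic(X, df$y, lambda = 1e-4)
    eta <- drop(X %*% beta)
    ll <- sum(df$y * eta - log1p(exp(eta)))
    kpar <- length(beta)
    coefs <- setNames(beta, c("(Intercept)", predictors))
    trialProb <- plogis(eta)
    aicv <- 2 * kpar - 2 * ll
  } else {
    coefs <- lme4::fixef(fit)
    ll <- as.numeric(logLik(fit))
    kpar <- attr(logLik(fit), "df")
    aicv <- AIC(fit)
    trialProb <- predict(fit, type = "response", re.form = NA)
  }
  agg <- tapply(trialProb, df$subject, mean)
  subj <- names(agg)
  subjectGroup <- df$group[match(subj, df$subject)]
  subjectProb <- as.numeric(agg)
  subjectPred <- ifelse(subjectProb > 0.5, positive,
    setdiff(unique(df$group), positive)[1L]
  )
  separation <- max(abs(coefs[-1L]), 0) > 10
  structure(
    list(
      coefficients = coefs, logLik = ll, aic = aicv, nParams = kpar,
      nObs = nrow(df), subjects = subj, subjectProb = subjectProb,
      subjectPred = subjectPred, subjectGroup = as.character(subjectGroup),
      positive = positive, separation = separation, fallback = fallback,
      predictors = predictors
    ),
    class = "LogisticFit"
  )
}

#' @export
print.LogisticFit <- function(x, ...) {
  cat(sprintf(
    "Mixed logistic fit: %s ~ %s; AIC %.2f (logLik %.2f, %d params, %d obs)%s\n",
    x$positive, paste(x$predictors, collapse = " + "), x$aic, x$logLik,
    x$nParams, x$nObs,
    if (x$separation) " [separation]" else ""
  ))
  invisible(x)
}

## IRLS ridge-penalized logistic regression (intercept unpenalized)
ridgeLogistic <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) {
      beta <- new
      break
    }
    beta <- new
  }
  drop(beta)
}

#' Subject-level classification accuracy of a fit
#' @param fit a \code{"LogisticFit"}.
#' @return fraction of subjects whose predicted label matches their group.
#' @export
subjectAccuracy <- function(fit) mean(fit$subjectPred == fit$subjectGroup)

#' Compare fits by AIC
#'
#' @param fits named list of \code{"LogisticFit"} objects fitted to the same
#'   observations.
#' @return data.frame ordered by ascending AIC with a delta-AIC column.
#' @export
aicCompare <- function(fits) {
  n <- vapply(fits, function(f) f$nObs, numeric(1L))
  if (length(unique(n)) != 1L) {
    stop("fits must be computed on the same observations")
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1L))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  out <- data.frame(model = nm, aic = aic, stringsAsFactors = FALSE)
  out <- out[order(out$aic), ]
  out$delta <- out$aic - out$aic[1L]
  rownames(out) <- NULL
  out
}

#' Forward stepwise component selection
#'
#' At each step the candidate maximizing subject-level in-sample accuracy is
#' added (ties broken by lower AIC); the returned subset is the one at the
#' first maximum of the accuracy path.
#'
#' @inheritParams fitLogistic
#' @param candidates candidate predictor column names.
#' @return list(path = data.frame(step, added, accuracy, aic), selected =
#'   character vector, fits = list of the fits along the path).
#' @export
stepwiseSelect <- function(trialScores, candidates, positive = "PD") {
  stopifnot(length(candidates) >= 1L)
  current <- character()
  remaining <- candidates
  path <- data.frame(
    step = integer(), added = character(), accuracy = numeric(),
    aic = numeric(), stringsAsFactors = FALSE
  )
  fits <- list()
  while (length(remaining)) {
    accs <- numeric(length(remaining))
    aics <- numeric(length(remaining))
    cand <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      f <- fitLogistic(trialScores, c(current, remaining[i]), positive)
      accs[i] <- subjectAccuracy(f)
      aics[i] <- f$aic
      cand[[i]] <- f
    }
    best <- which(accs == max(accs))
    if (length(best) > 1L) best <- best[which.min(aics[best])]
    current <- c(current, remaining[best])
    fits[[length(fits) + 1L]] <- cand[[best]]
    path <- rbind(path, data.frame(
      step = length(current), added = remaining[best],
      accuracy = accs[best], aic = aics[best], stringsAsFactors = FALSE
    ))
    remaining <- remaining[-best]
  }
  bestStep <- which.max(path$accuracy) # first maximum on a plateau
  list(
    path = path, selected = path$added[seq_len(bestStep)],
    fits = fits, bestStep = bestStep
  )
}

#' Confusion matrix and sensitivity/specificity
#'
#' Positive class = PD; sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/n.
#'
#' @param pred predicted labels (or a \code{"LogisticFit"}, whose
#'   subject-level predictions are used).
#' @param truth true labels (ignored for a fit).
#' @param positive positive-class label.
#' @return list(tp, fp, tn, fn, sensitivity, specificity, accuracy, n).
#' @export
confusionReport <- function(pred, truth = NULL, positive = "PD") {
  if (inherits(pred, "LogisticFit")) {
    truth <- pred$subjectGroup
    positive <- pred$positive
    pred <- pred$subjectPred
  }
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(pred), n = length(pred)
  )
}

#' Label hyposmia from a 16-item odor identification score
#'
#' Scores below 11 (the 10th percentile of normative data) are labelled
#' hyposmic; 11 and above count as normosmic (a score of exactly 11 passes).
#'
#' @param score integer-valued score(s) in [0, 16].
#' @param threshold cutoff (default 11).
#' @return character vector \code{"hyposmic"}/\code{"normosmic"}.
#' @export
classifyHyposmia <- function(score, threshold = 11) {
  if (any(!is.finite(score)) || any(score < 0 | score > 16) ||
    any(score != round(score))) {
    stop("scores must be integers in [0, 16]")
  }
  ifelse(score < threshold, "hyposmic", "normosmic")
}

#' Mixed-effect linear association between component scores and a clinical
#' outcome
#'
#' Regresses the outcome on trial-level component scores with a
#' by-participant random intercept (one model per component), reporting the
#' slope, t, df, p, the 95\% CI and the residual SD.
#'
#' Clinical outcomes are constant within participant.  In that case the
#' trial-level mixed model is degenerate -- the within-participant
#' observations, where the outcome never varies, drive the slope to zero --
#' so the model reduces to its between-participant component: OLS of the
#' outcome on the participant-mean score (\code{method = "lm-subject"}).
#' Outcomes that do vary across trials are fitted with
#' \code{lmerTest::lmer} (Satterthwaite t, Wald CI; \code{method =
#' "lmer"}), falling back to the subject-level fit if the mixed model
#' fails.
#'
#' @param trialScores data.frame with columns \code{subject} and the
#'   component columns.
#' @param clinical data.frame with columns \code{subject} (or \code{id}) and
#'   the outcome.
#' @param outcome outcome column name.
#' @param components component column names (default: all \code{comp*}
#'   columns, or a single \code{score} column).
#' @return data.frame with one row per component: slope, se, t, df, p, ciLo,
#'   ciHi, resid (residual SD), method.
#' @export
associate <- function(trialScores, clinical, outcome, components = NULL) {
  idCol <- if ("subject" %in% names(clinical)) "subject" else "id"
  if (is.null(components)) {
    components <- grep("^comp", names(trialScores), value = TRUE)
    if (!length(components) && "score" %in% names(trialScores)) components <- "score"
  }
  y <- clinical[[outcome]][match(trialScores$subject, clinical[[idCol]])]
  if (all(is.na(y))) stop("no matching subjects between scores and clinical table")
  if (sd(y, na.rm = TRUE) == 0) stop("outcome is constant")

  subjectLm <- function(df) {
    agg <- stats::aggregate(cbind(x, y) ~ subject, df, mean)
    fit <- stats::lm(y ~ x, agg)
    sm <- suppressWarnings(summary(fit)$coefficients)
    ci <- tryCatch(
      suppressWarnings(stats::confint(fit, "x")),
      error = function(e) c(NA_real_, NA_real_)
    )
    data.frame(
      slope = sm["x", "Estimate"], se = sm["x", "Std. Error"],
      t = sm["x", "t value"], df = fit$df.residual,
      p = sm["x", "Pr(>|t|)"], ciLo = ci[1L], ciHi = ci[2L],
      resid = sqrt(sum(stats::residuals(fit)^2) / max(fit$df.residual, 1L)),
      method = "lm-subject", stringsAsFactors = FALSE
    )
  }

  out <- NULL
  for (comp in components) {
    df <- data.frame(
      subject = trialScores$subject, x = trialScores[[comp]], y = y
    )
    df <- df[complete.cases(df), ]
    withinVar <- tapply(df$y, df$subject, var)
    subjectLevel <- all(is.na(withinVar) | withinVar < 1e-12)
    row <- if (subjectLevel) {
      subjectLm(df)
    } else {
      tryCatch(
        {
          fit <- suppressWarnings(suppressMessages(
            lmerTest::lmer(y ~ x + (1 | subject), data = df)
          ))
          sm <- summary(fit)$coefficients
          ci <- suppressWarnings(stats::confint(fit, parm = "x", method = "Wald"))
          data.frame(
            slope = sm["x", "Estimate"], se = sm["x", "Std. Error"],
            t = sm["x", "t value"], df = sm["x", "df"],
            p = sm["x", "Pr(>|t|)"], ciLo = ci[1L], ciHi = ci[2L],
            resid = stats::sigma(fit), method = "lmer",
            stringsAsFactors = FALSE
          )
        },
        error = function(e) subjectLm(df)
      )
    }
    out <- rbind(out, cbind(data.frame(component = comp), row))
  }
  rownames(out) <- NULL
  out
}

#' Subsample bootstrap validation of an association
#'
#' Repeatedly draws 80\% of each group's subjects without replacement,
#' refits the mixed-effect association, and converts the resampled slope
#' signs into a two-sided p value: p = 2 min(frac > 0, frac < 0), floored at
#' 1/nBoot.  Seeded and reproducible.
#'
#' @inheritParams associate
#' @param component single component column name.
#' @param nBoot number of resamples (default 1000).
#' @param frac per-group subsample fraction (default 0.8).
#' @param seed integer seed.
#' @return list(p, slopes, nBoot, frac, seed).
#' @export
bootstrapAssociations <- function(trialScores, clinical, outcome,
                                  component = "comp1", nBoot = 1000,
                                  frac = 0.8, seed = 1) {
  idCol <- if ("subject" %in% names(clinical)) "subject" else "id"
  grpCol <- if ("group" %in% names(clinical)) clinical$group else rep("all", nrow(clinical))
  keep <- !is.na(clinical[[outcome]])
  ids <- clinical[[idCol]][keep]
  grp <- as.character(grpCol)[keep]
  byGroup <- split(ids, grp)
  nDraw <- vapply(byGroup, function(g) floor(frac * length(g)), numeric(1L))
  if (any(nDraw < 2)) stop("group too small for the subsample fraction")
  set.seed(seed)
  slopes <- numeric(nBoot)
  for (i in seq_len(nBoot)) {
    take <- unlist(lapply(seq_along(byGroup), function(g) {
      sample(byGroup[[g]], nDraw[g])
    }))
    ts <- trialScores[trialScores$subject %in% take, , drop = FALSE]
    cl <- clinical[clinical[[idCol]] %in% take, , drop = FALSE]
    slopes[i] <- associate(ts, cl, outcome, components = component)$slope
  }
  pos <- mean(slopes > 0)
  neg <- mean(slopes < 0)
  p <- max(2 * min(pos, neg), 1 / nBoot)
  list(p = p, slopes = slopes, nBoot = nBoot, frac = frac, seed = seed)
}

#' Two-sample pooled-variance t test
#'
#' Two-tailed pooled-variance t test with the 95\% CI of the mean
#' difference (thin wrapper over \code{stats::t.test(var.equal = TRUE)}).
#'
#' @param a,b numeric vectors.
#' @return list(t, df, p, ci, meanDiff).
#' @export
groupTtest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = length(a) + length(b) - 2L, p = 1, ci = c(0, 0), meanDiff = 0))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, ci = unname(tt$conf.int),
    meanDiff = unname(diff(rev(tt$estimate)))
  )
}
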