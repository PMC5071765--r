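## PLS-DA / OPLS-DA by NIPALS, venetian-blind cross-validated Q2,
## CV-ANOVA, and correlation-coefficient biomarker calling.

## encode a two-class factor/character/numeric y as -1 (control) / +1
## (exposed); returns list(y, groups = c(control, exposed))
encodeClasses <- function(y) {
  if (is.numeric(y) && all(y %in% c(-1, 1)) && length(unique(y)) == 2)
    return(list(y = as.numeric(y), groups = c("-1", "+1")))
  if (is.numeric(y) && all(y %in% c(0, 1)) && length(unique(y)) == 2)
    return(list(y = ifelse(y == 0, -1, 1), groups = c("0", "1")))
  f <- as.factor(y)
  lev <- levels(f)
  if (length(lev) < 2) stop("y must contain two classes")
  if (length(lev) > 2) stop("only two-class contrasts are supported")
  # put a recognizable reference class first
  ref <- intersect(c("control", "Control", "0h"), lev)
  if (length(ref)) lev <- c(ref[1], setdiff(lev, ref[1]))
  list(y = ifelse(as.character(f) == lev[1], -1, 1), groups = lev)
}

asValueMatrix <- function(x) {
  if (is(x, "BinMatrix")) binValues(x) else as.matrix(x)
}

modelY <- function(x, y) {
  if (is.null(y)) {
    if (!is(x, "BinMatrix"))
      stop("y must be given unless x is a BinMatrix with group labels")
    y <- sampleInfo(x)$group
  }
  encodeClasses(y)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Sequential NIPALS components for a single response: for each
#' component, `w` is proportional to `X'y` (unit norm), `t = Xw`,
#' `p = X't / t't`, `q = y't / t't`, then `X` and `y` are deflated.
#' `X` is column-centered internally; `y` is the centered +/-1 class
#' coding. Components whose score variance vanishes (beyond the rank of
#' `X`) are dropped with a warning.
#'
#' @param x samples x variables matrix or a [BinMatrix-class].
#' @param y two-class labels (factor, character, 0/1 or -1/+1); taken
#'   from the BinMatrix `group` column when `NULL`.
#' @param nComponents number of components requested.
#' @return a [PlsModel-class].
#' @examples
#' bm <- buildBinMatrix(simulateSpectra(syntheticDesign(nPerGroup = 5)))
#' fitPlsda(bm, nComponents = 1)
#' @export
fitPlsda <- function(x, y = NULL, nComponents = 1) {
  enc <- modelY(x, y)
  X <- asValueMatrix(x)
  yc <- enc$y - mean(enc$y)
  xMeans <- colMeans(X)
  Xd <- sweep(X, 2, xMeans)
  yd <- yc
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, 0); Tm <- matrix(0, n, 0); q <- numeric(0)
  for (a in seq_len(nComponents)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sum(abs(Xd)))) {
      warning("rank exhausted after ", a - 1L,
              " component(s); truncating")
      break
    }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-30) { warning("rank exhausted; truncating"); break }
    pv <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yd <- yd - qa * t
    W <- cbind(W, w); P <- cbind(P, pv); Tm <- cbind(Tm, t); q <- c(q, qa)
  }
  if (ncol(Tm) == 0) stop("no class-covarying variation in x")
  fitted <- drop(Tm %*% q)
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)
  new("PlsModel", scores = Tm, weights = W, loadings = P, yLoadings = q,
      xMeans = xMeans, yMean = mean(enc$y), r2y = r2y, y = enc$y)
}

## one OPLS pass on centered data: remove nOrtho orthogonal components,
## then one predictive component. Returns the pieces needed both for the
## model object and for predicting held-out samples.
oplsCore <- function(Xc, yc, nOrtho) {
  p <- ncol(Xc)
  Wo <- Po <- matrix(0, p, 0)
  To <- matrix(0, nrow(Xc), 0)
  Xf <- Xc
  for (a in seq_len(nOrtho)) {
    w <- drop(crossprod(Xf, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    t <- drop(Xf %*% w)
    pv <- drop(crossprod(Xf, t)) / sum(t^2)
    wo <- pv - sum(w * pv) * w            # p - (w'p / w'w) w, w unit norm
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break                # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  w <- drop(crossprod(Xf, yc))
  nw <- sqrt(sum(w^2))
  degenerate <- nw < 1e-14
  if (degenerate) {
    w <- rep(0, p); t <- rep(0, nrow(Xc)); pv <- rep(0, p); q <- 0
  } else {
    w <- w / nw
    t <- drop(Xf %*% w)
    pv <- drop(crossprod(Xf, t)) / sum(t^2)
    q <- sum(yc * t) / sum(t^2)
  }
  list(w = w, t = t, p = pv, q = q, Wo = Wo, Po = Po, To = To,
       degenerate = degenerate)
}

## filter new (train-centered) data through the orthogonal components
## and predict the class score
oplsPredict <- function(core, Xnew) {
  for (j in seq_len(ncol(core$Wo))) {
    to <- drop(Xnew %*% core$Wo[, j])
    Xnew <- Xnew - tcrossprod(to, core$Po[, j])
  }
  drop(Xnew %*% core$w) * core$q
}

#' Fit an OPLS-DA model
#'
#' Removes `nOrtho` orthogonal components (constructed from
#' `p - (w'p / w'w) w` and deflated from X) before fitting a single
#' predictive NIPALS component, so that the predictive scores capture
#' the class contrast free of y-orthogonal structured variation. The
#' predictive score sign is fixed so the exposed (second) class mean is
#' positive. Cross-validated Q2 (venetian blinds) and the CV-ANOVA
#' p-value are computed alongside.
#'
#' @param x samples x variables matrix or [BinMatrix-class].
#' @param y two-class labels; from the BinMatrix groups when `NULL`.
#' @param nOrtho number of orthogonal components (must be below
#'   `n - 2`).
#' @param cv logical, compute venetian-blind Q2 and CV-ANOVA.
#' @param nFolds folds for cross-validation.
#' @return an [OplsModel-class].
#' @examples
#' bm <- buildBinMatrix(simulateSpectra(syntheticDesign(nPerGroup = 5)))
#' fitOplsda(bm)
#' @export
fitOplsda <- function(x, y = NULL, nOrtho = 1, cv = TRUE, nFolds = 5) {
  enc <- modelY(x, y)
  X <- asValueMatrix(x)
  n <- nrow(X)
  nOrtho <- as.integer(nOrtho)
  if (nOrtho < 0) stop("nOrtho must be nonnegative")
  if (nOrtho >= n - 2) stop("nOrtho must be below n - 2")
  yc <- enc$y - mean(enc$y)
  xMeans <- colMeans(X)
  core <- oplsCore(sweep(X, 2, xMeans), yc, nOrtho)
  if (core$degenerate)
    warning("no class-covarying variation: degenerate model (zero scores)")
  # sign convention: exposed group has positive mean predictive score
  if (!core$degenerate && mean(core$t[enc$y == 1]) < 0) {
    core$t <- -core$t; core$w <- -core$w; core$p <- -core$p
    core$q <- -core$q
  }
  r2y <- if (core$degenerate) 0 else
    1 - sum((yc - core$q * core$t)^2) / sum(yc^2)
  q2v <- NA_real_; pv <- NA_real_
  if (cv && !core$degenerate) {
    cvres <- crossValidateQ2(X, enc$y, nFolds = nFolds, method = "oplsda",
                             nOrtho = nOrtho)
    q2v <- min(cvres$q2, r2y)  # CV prediction cannot beat the fit
    pv <- cvAnova(cvres)
  } else if (cv) {
    pv <- 1
  }
  centers <- if (is(x, "BinMatrix")) binCenters(x) else
    rep(NA_real_, ncol(X))
  new("OplsModel", predictiveScores = core$t, predictiveWeights = core$w,
      predictiveLoadings = core$p, yLoading = core$q,
      orthoScores = core$To, orthoWeights = core$Wo,
      orthoLoadings = core$Po, nOrtho = ncol(core$To),
      q2 = q2v, r2y = r2y, cvAnovaP = pv, xMeans = xMeans,
      yMean = mean(enc$y), y = enc$y, groups = enc$groups,
      binCenters = centers)
}

#' Venetian-blind fold assignment
#'
#' Fold of sample i (in sample-sheet order) is `(i - 1) mod nFolds + 1`.
#' If any training split would contain a single class, folds are
#' reassigned stratified (round-robin within each class, preserving
#' order) with a warning.
#'
#' @param y class vector (any two-class coding).
#' @param nFolds number of folds.
#' @return integer fold per sample.
#' @export
venetianFolds <- function(y, nFolds = 5) {
  n <- length(y)
  if (nFolds < 2 || nFolds > n) stop("nFolds must be in [2, n]")
  folds <- as.integer((seq_len(n) - 1L) %% nFolds) + 1L
  ok <- vapply(seq_len(nFolds), function(k)
    length(unique(y[folds != k])) == 2, logical(1))
  if (!all(ok)) {
    warning("single-class training split; reassigning folds stratified")
    folds <- integer(n)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- ((seq_along(idx) - 1L) %% nFolds) + 1L
    }
  }
  folds
}

#' Cross-validated Q2 by venetian blinds
#'
#' `Q2 = 1 - PRESS / SSY`, with PRESS accumulated over held-out
#' predictions from models refitted on each training split, and SSY the
#' total sum of squares of y about its mean.
#'
#' @param x samples x variables matrix or [BinMatrix-class].
#' @param y two-class labels; from the BinMatrix groups when `NULL`.
#' @param nFolds number of folds.
#' @param method `"oplsda"` or `"plsda"`.
#' @param nOrtho orthogonal components (oplsda).
#' @param nComponents components (plsda).
#' @return list of class `q2cv`: `q2`, `press`, `ssy`, `predictions`,
#'   `folds`, `n`, `dfModel`.
#' @export
crossValidateQ2 <- function(x, y = NULL, nFolds = 5,
                            method = c("oplsda", "plsda"),
                            nOrtho = 1, nComponents = 1) {
  method <- match.arg(method)
  enc <- modelY(x, y)
  X <- asValueMatrix(x)
  n <- nrow(X)
  folds <- venetianFolds(enc$y, nFolds)
  pred <- numeric(n)
  for (k in sort(unique(folds))) {
    tr <- folds != k
    yTr <- enc$y[tr]
    xm <- colMeans(X[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, xm)
    Xte <- sweep(X[!tr, , drop = FALSE], 2, xm)
    ycTr <- yTr - mean(yTr)
    if (method == "oplsda") {
      core <- oplsCore(Xtr, ycTr, nOrtho)
      pred[!tr] <- mean(yTr) + oplsPredict(core, Xte)
    } else {
      m <- fitPlsda(Xtr, factor(yTr, levels = c(-1, 1)),
                    nComponents = nComponents)
      # regression coefficients B = W (P'W)^-1 q
      B <- m@weights %*% solve(crossprod(m@loadings, m@weights), m@yLoadings)
      pred[!tr] <- mean(yTr) + drop(Xte %*% B)
    }
  }
  ssy <- sum((enc$y - mean(enc$y))^2)
  press <- sum((enc$y - pred)^2)
  dfModel <- if (method == "oplsda") nOrtho + 1L else as.integer(nComponents)
  structure(list(q2 = 1 - press / ssy, press = press, ssy = ssy,
                 predictions = pred, folds = folds, n = n,
                 dfModel = dfModel), class = "q2cv")
}

#' CV-ANOVA significance of a cross-validated model
#'
#' F test of the cross-validated residuals against the total class
#' variation: `F = ((SSY - PRESS) / d1) / (PRESS / d2)` with `d1` the
#' model degrees of freedom (number of fitted components by default)
#' and `d2 = n - d1 - 1`; the p-value comes from the F distribution.
#' When PRESS >= SSY the model predicts no better than the mean and
#' p = 1.
#'
#' @param cv a `q2cv` result from [crossValidateQ2()].
#' @param dfModel override the model degrees of freedom `d1`.
#' @return p-value in \[0, 1\].
#' @export
cvAnova <- function(cv, dfModel = NULL) {
  stopifnot(inherits(cv, "q2cv"))
  d1 <- dfModel %||% cv$dfModel
  d2 <- cv$n - d1 - 1
  if (d2 <= 0) stop("too few samples for CV-ANOVA with d1 = ", d1)
  if (cv$press >= cv$ssy) return(1)
  f <- ((cv$ssy - cv$press) / d1) / (cv$press / d2)
  pf(f, d1, d2, lower.tail = FALSE)
}

#' Critical correlation coefficient
#'
#' The two-tailed critical value of the Pearson correlation at level
#' `alpha` for sample size `n`:
#' `r_crit = sqrt(t*^2 / (t*^2 + n - 2))` with `t*` the Student-t
#' critical value on `n - 2` degrees of freedom. For example,
#' `criticalR(0.05, 11)` is 0.602, the conventional cutoff for
#' coefficient-coded OPLS-DA loadings at that sample size.
#'
#' @param alpha two-tailed significance level.
#' @param n sample size (>= 3).
#' @return critical |r| in (0, 1).
#' @examples
#' round(criticalR(0.05, 11), 3)
#' @export
criticalR <- function(alpha, n) {
  if (n < 3) stop("n must be >= 3")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  df <- n - 2
  tc <- qt(1 - alpha / 2, df)
  sqrt(tc^2 / (tc^2 + df))
}

#' Correlation-coded loadings
#'
#' Pearson correlation of each (processed) spectral variable with the
#' predictive score vector of an OPLS-DA model, with significance
#' cutoff `criticalR(alpha, n)`. Because predictive scores are oriented
#' so the exposed class is positive, positive `r` marks variables
#' elevated under exposure. Zero-variance bins get `r = 0` and are
#' flagged.
#'
#' @param model an [OplsModel-class].
#' @param x the data the model was fitted to (matrix or
#'   [BinMatrix-class]).
#' @param alpha significance level.
#' @return a [CoefficientLoadings-class].
#' @export
coefficientLoadings <- function(model, x, alpha = 0.05) {
  stopifnot(is(model, "OplsModel"))
  X <- asValueMatrix(x)
  t <- model@predictiveScores
  n <- length(t)
  sdX <- apply(X, 2, stats::sd)
  flat <- which(sdX == 0)
  r <- rep(0, ncol(X))
  if (stats::sd(t) > 0 && length(flat) < ncol(X)) {
    live <- setdiff(seq_len(ncol(X)), flat)
    r[live] <- drop(cor(X[, live, drop = FALSE], t))
  }
  rc <- criticalR(alpha, n)
  centers <- if (is(x, "BinMatrix")) binCenters(x) else model@binCenters
  if (length(centers) != ncol(X)) centers <- rep(NA_real_, ncol(X))
  new("CoefficientLoadings", r = r, rCrit = rc, alpha = alpha,
      significantBins = which(abs(r) > rc),
      binCenters = centers, zeroVarianceBins = as.integer(flat))
}

#' Call significant metabolites from coefficient loadings
#'
#' A metabolite is called when any bin inside one of its assignment
#' regions is significant; its direction (up/down in the exposed group)
#' is the sign of `r` at its largest-|r| significant bin. Significant
#' bins falling in no assignment region are reported as unassigned
#' regions. Output is sorted by decreasing max |r|.
#'
#' @param loadings a [CoefficientLoadings-class].
#' @param library metabolite template library (or a regions data.frame
#'   from [metaboliteRegions()]).
#' @param pad assignment window half-width passed to
#'   [metaboliteRegions()] when `library` is a template library.
#' @return data.frame with columns metabolite, direction, maxAbsR, ppm.
#' @export
callSignificantMetabolites <- function(loadings, library = defaultMetaboliteLibrary(),
                                       pad = 0.0125) {
  stopifnot(is(loadings, "CoefficientLoadings"))
  regions <- if (all(c("low", "high") %in% names(library))) library
             else metaboliteRegions(library, pad)
  sig <- loadings@significantBins
  out <- data.frame(metabolite = character(), direction = character(),
                    maxAbsR = numeric(), ppm = numeric())
  if (!length(sig)) return(out)
  centers <- loadings@binCenters[sig]
  rs <- loadings@r[sig]
  assigned <- rep(FALSE, length(sig))
  for (m in unique(regions$metabolite)) {
    reg <- regions[regions$metabolite == m, , drop = FALSE]
    inReg <- rep(FALSE, length(sig))
    for (j in seq_len(nrow(reg)))
      inReg <- inReg | (centers >= reg$low[j] & centers <= reg$high[j])
    if (any(inReg)) {
      assigned <- assigned | inReg
      best <- which(inReg)[which.max(abs(rs[inReg]))]
      out <- rbind(out, data.frame(
        metabolite = m,
        direction = if (rs[best] > 0) "up" else "down",
        maxAbsR = abs(rs[best]), ppm = centers[best]))
    }
  }
  # unassigned significant bins, grouped into contiguous runs
  un <- which(!assigned)
  if (length(un)) {
    runs <- split(un, cumsum(c(1, diff(un) > 1)))
    for (rn in runs) {
      best <- rn[which.max(abs(rs[rn]))]
      out <- rbind(out, data.frame(
        metabolite = sprintf("unassigned region (%.3f ppm)", centers[best]),
        direction = if (rs[best] > 0) "up" else "down",
        maxAbsR = abs(rs[best]), ppm = centers[best]))
    }
  }
  out[order(-out$maxAbsR), , drop = FALSE]
}
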