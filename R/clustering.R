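#' Overcluster the selected features
#'
#' Fits a full-covariance Gaussian mixture with deliberately more components
#' than the expected number of neurons (12 for single-wire configurations,
#' 20 for tetrodes). The surplus components act as a smoothing of the
#' mixture density rather than as extra clusters: the subsequent density-peak
#' search ([findDensityPeaks()]) recovers the number of modes, which is
#' robust to the exact component count.
#'
#' @param features spikes x d matrix of selected features (or a
#'   [FeatureMatrix-class]; typically d = 5).
#' @param nGaussians number of mixture components (default 12).
#' @param options a [fitOptions()] list.
#' @return a [MixtureModel-class].
#' @export
overcluster <- function(features, nGaussians = 12L, options = fitOptions()) {
  # k-means starts keep every component inside one region of the feature
  # cloud, so the fit partitions the data instead of occasionally placing a
  # broad component across two disjoint clusters (which would flatten the
  # density valley between them and defeat the peak search)
  fitGmm(features, k = nGaussians, options = options, init = "kmeans")
}

#' Find cluster centers as peaks of the mixture density
#'
#' Runs one Nelder-Mead simplex search per mixture component, started at the
#' component center, maximizing the mixture density (by minimizing its
#' negative log). Converged endpoints are then merged: endpoints whose
#' range-normalized Euclidean distance (each coordinate difference divided by
#' that dimension's data range) is below `mergeThreshold` (default 0.01, i.e.
#' 1% of the data range) are counted as one peak, represented by the
#' highest-density endpoint. Non-converged searches are discarded with a
#' warning.
#'
#' Because the overclustered mixture is a finite-sample density estimate,
#' its raw local maxima include insignificant modes: shallow ripples on top
#' of one cluster (the extra components' residual structure) and isolated
#' "needles" from tiny-weight components. Two mode-significance filters
#' clean these up after the distance merge:
#' \itemize{
#'   \item \emph{valley merge} — two peaks are counted as one mode when the
#'     mixture density along the segment joining them never drops below
#'     `valleyThreshold` times the lower peak density (they sit on one
#'     connected high-density region);
#'   \item \emph{mass filter} — a peak must attract at least `minPeakMass`
#'     of the total mixture weight (the weights of the components whose
#'     searches converged to it); isolated micro-modes fail this.
#' }
#' Both filters can be disabled (`valleyThreshold = 0`, `minPeakMass = 0`)
#' to obtain the raw distance-merged peaks.
#'
#' @param model a fitted [MixtureModel-class] (d >= 1).
#' @param dataRange d x 2 matrix of per-dimension (min, max); a vector of
#'   length 2 is accepted for univariate models.
#' @param mergeThreshold range-normalized merge distance (default 0.01).
#' @param mergeMode "joint" (default) merges on the range-normalized
#'   Euclidean distance across all dimensions; "per_axis" merges when every
#'   per-axis normalized difference is below the threshold.
#' @param valleyThreshold valley-to-peak density ratio above which two peaks
#'   count as one mode (default 0.2; 0 disables).
#' @param minPeakMass minimum fraction of total mixture weight a retained
#'   peak must attract (default 0.02; 0 disables). The highest-mass peak is
#'   always retained.
#' @param maxEvaluations Nelder-Mead evaluation cap per start.
#' @return a [ClusterCenters-class].
#' @export
findDensityPeaks <- function(model, dataRange, mergeThreshold = 0.01,
                             mergeMode = c("joint", "per_axis"),
                             valleyThreshold = 0.2, minPeakMass = 0.02,
                             maxEvaluations = 2000L) {
  mergeMode <- match.arg(mergeMode)
  d <- ncol(model@means)
  if (is.vector(dataRange) && d == 1L)
    dataRange <- matrix(range(dataRange), nrow = 1L)
  dataRange <- as.matrix(dataRange)
  if (nrow(dataRange) != d || ncol(dataRange) != 2L)
    stop("dataRange must be a d x 2 matrix of per-dimension (min, max)")
  ext <- dataRange[, 2L] - dataRange[, 1L]
  if (any(!is.finite(ext)) || any(ext <= 0))
    stop("dataRange must be finite with positive extent in every dimension")

  negLogDens <- function(x) -modelDensity(model, matrix(x, nrow = 1L),
                                          log = TRUE)
  k <- nrow(model@means)
  ends <- matrix(NA_real_, k, d)
  dens <- rep(NA_real_, k)
  conv <- logical(k)
  for (j in seq_len(k)) {
    start <- model@means[j, ]
    if (d == 1L) {
      # the simplex degenerates in 1-D; quasi-Newton hill climbing on the
      # same objective is the local equivalent
      opt <- stats::optim(start, negLogDens, method = "BFGS",
                          control = list(maxit = maxEvaluations,
                                         reltol = 1e-12))
      ends[j, ] <- opt$par
      conv[j] <- opt$convergence == 0L
    } else {
      opt <- stats::optim(start, negLogDens, method = "Nelder-Mead",
                          control = list(maxit = maxEvaluations,
                                         reltol = 1e-10))
      ends[j, ] <- opt$par
      conv[j] <- opt$convergence == 0L
    }
    dens[j] <- -negLogDens(ends[j, ])
  }
  if (!all(conv))
    warning(sum(!conv), " peak search(es) did not converge and were discarded")
  keep <- which(conv)
  if (!length(keep)) stop("no converged density peaks")

  # greedy merge by decreasing density: the highest-density endpoint of each
  # group is its representative (the actual mode estimate)
  ord <- keep[order(dens[keep], decreasing = TRUE)]
  scaled <- sweep(ends, 2L, ext, "/")
  reps <- integer()
  assign <- rep(NA_integer_, k)
  for (j in ord) {
    merged <- FALSE
    for (ri in seq_along(reps)) {
      delta <- abs(scaled[j, ] - scaled[reps[ri], ])
      close <- if (mergeMode == "joint") {
        sqrt(sum(delta^2)) < mergeThreshold
      } else {
        all(delta < mergeThreshold)
      }
      if (close) {
        assign[j] <- ri
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      reps <- c(reps, j)
      assign[j] <- length(reps)
    }
  }
  # valley merge: peaks on one connected high-density region are one mode
  group <- seq_along(reps)
  rootOf <- function(i) { while (group[i] != i) i <- group[i]; i }
  if (valleyThreshold > 0 && length(reps) > 1L) {
    segMinLogDens <- function(a, b) {
      tt <- seq(0, 1, length.out = 50L)
      seg <- outer(1 - tt, a) + outer(tt, b)
      min(modelDensity(model, seg, log = TRUE))
    }
    for (i in seq_along(reps)) {
      for (jj in seq_len(i - 1L)) {
        ri <- rootOf(i); rj <- rootOf(jj)
        if (ri == rj) next
        valley <- segMinLogDens(ends[reps[i], ], ends[reps[jj], ])
        lower <- min(dens[reps[i]], dens[reps[jj]])
        if (valley - lower > log(valleyThreshold)) {
          # union; the denser representative becomes the root
          if (dens[reps[ri]] >= dens[reps[rj]]) group[rj] <- ri else
            group[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_along(reps), rootOf, integer(1))
  compRoot <- rep(NA_integer_, k)
  okAssign <- !is.na(assign)
  compRoot[okAssign] <- roots[assign[okAssign]]

  # mass per mode: total mixture weight of the components whose searches
  # landed on it (non-converged searches contribute nothing)
  uroots <- unique(roots)
  mass <- vapply(uroots, function(r) {
    sum(model@weights[which(compRoot == r)])
  }, numeric(1))
  repIdx <- reps[uroots]
  ord2 <- order(dens[repIdx], decreasing = TRUE)
  uroots <- uroots[ord2]; repIdx <- repIdx[ord2]; mass <- mass[ord2]

  keepMode <- mass >= minPeakMass
  if (!any(keepMode)) keepMode[which.max(mass)] <- TRUE
  finalRoots <- uroots[keepMode]
  peakId <- match(compRoot, finalRoots)
  # mode location: mixture-weight-weighted mean of the constituent
  # components' centers -- the aggregate's mode estimate, insensitive to
  # which finite-sample ripple the searches landed on
  centers <- t(vapply(seq_along(finalRoots), function(g) {
    comp <- which(!is.na(peakId) & peakId == g)
    w <- model@weights[comp]
    colSums(model@means[comp, , drop = FALSE] * w) / sum(w)
  }, numeric(d)))

  trace <- data.frame(
    start = I(asplit(model@means, 1L)),
    endpoint = I(asplit(ends, 1L)),
    logDensity = dens,
    converged = conv,
    peak = peakId,
    componentWeight = model@weights
  )
  attr(trace, "peakMass") <- mass[keepMode]
  new("ClusterCenters",
    centers = centers, searchTrace = trace,
    dataRange = dataRange, mergeThreshold = mergeThreshold
  )
}

#' Classify spikes with a fixed-mean mixture
#'
#' Fits a Gaussian mixture whose component centers are held at the supplied
#' cluster centers (one component per center) and assigns every spike to the
#' component of highest posterior probability. Exact posterior ties are
#' broken toward the lower cluster index.
#'
#' @param features spikes x d matrix (or [FeatureMatrix-class]) of the
#'   selected features.
#' @param centers a [ClusterCenters-class] or a plain k x d matrix.
#' @param options a [fitOptions()] list.
#' @param featureInfo optional provenance table of the selected features.
#' @param config optional list recorded in the result.
#' @param fitMask optional logical: spikes used for fitting the fixed-mean
#'   model (all spikes are classified regardless); used by the outlier path.
#' @return a [SortingResult-class].
#' @export
classifySpikes <- function(features, centers, options = fitOptions(),
                           featureInfo = NULL, config = list(),
                           fitMask = NULL) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features) else
    as.matrix(features)
  cc <- if (is(centers, "ClusterCenters")) centers else {
    cm <- as.matrix(centers)
    rng <- t(apply(X, 2L, range))
    ext <- rng[, 2L] - rng[, 1L]
    rng[, 1L] <- pmin(rng[, 1L], apply(cm, 2L, min))
    rng[, 2L] <- pmax(rng[, 2L], apply(cm, 2L, max))
    new("ClusterCenters",
      centers = cm, searchTrace = data.frame(),
      dataRange = rng, mergeThreshold = 0
    )
  }
  fitX <- if (is.null(fitMask)) X else X[fitMask, , drop = FALSE]
  model <- fitGmmFixedMeans(fitX, cc@centers, options = options)
  resp <- posteriorResponsibilities(model, X)
  labels <- max.col(resp, ties.method = "first")
  post <- resp[cbind(seq_len(nrow(resp)), labels)]
  if (is.null(featureInfo))
    featureInfo <- data.frame(id = paste0("f", seq_len(ncol(X))),
                              method = "unknown", stringsAsFactors = FALSE)
  new("SortingResult",
    labels = as.integer(labels),
    posteriors = pmin(pmax(post, .Machine$double.xmin), 1),
    model = model, centers = cc, featureInfo = featureInfo,
    outlierMask = if (is.null(fitMask)) logical() else !fitMask,
    config = config
  )
}

#' Core-sample selection by k-nearest-neighbor distance
#'
#' Flags spikes whose distance to their k-th nearest neighbor in feature
#' space exceeds a cutoff as outliers. Outliers are excluded from mixture
#' fitting and reinserted afterwards by template matching — i.e. assigned to
#' the cluster of highest posterior under the final fixed-mean model (this
#' happens in [sortSpikes()] / [classifySpikes()] via `fitMask`).
#'
#' @param features spikes x d matrix or [FeatureMatrix-class].
#' @param kNN neighbor order (default 20).
#' @param cutoff absolute distance cutoff; if NULL, defaults to
#'   `cutoffQuantile`-th quantile of the k-NN distances times
#'   `cutoffFactor`.
#' @param cutoffQuantile,cutoffFactor parameters of the default cutoff
#'   (0.95 and 2).
#' @return list with `core` (logical mask), `knnDistance`, and `cutoff`.
#' @export
handleOutliers <- function(features, kNN = 20L, cutoff = NULL,
                           cutoffQuantile = 0.95, cutoffFactor = 2) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features) else
    as.matrix(features)
  n <- nrow(X)
  if (kNN < 1L || kNN >= n) stop("kNN must be in [1, nSpikes)")
  D <- as.matrix(stats::dist(X))
  dk <- apply(D, 1L, function(r) sort(r, partial = kNN + 1L)[kNN + 1L])
  if (is.null(cutoff))
    cutoff <- stats::quantile(dk, cutoffQuantile, names = FALSE) * cutoffFactor
  core <- dk <= cutoff
  if (mean(!core) > 0.5)
    stop("cutoff excludes more than half of the spikes; misconfiguration")
  list(core = core, knnDistance = dk, cutoff = cutoff)
}

#' Merge clusters in a sorting result
#'
#' Relabels the spikes of explicitly listed clusters to a single id and
#' renumbers the labels 1..k'. Mirrors manual post-processing merges; no
#' automatic merge heuristic is applied.
#'
#' @param result a [SortingResult-class].
#' @param ids cluster ids to merge (length >= 2).
#' @param to id the merged cluster keeps (default `min(ids)`).
#' @return a [SortingResult-class] with updated labels and centers (the
#'   merged cluster keeps the center of `to`); the mixture model is left as
#'   fitted.
#' @export
mergeClusters <- function(result, ids, to = min(ids)) {
  k <- nFound(result)
  ids <- as.integer(ids)
  if (any(ids < 1L | ids > k)) stop("cluster id out of range 1..", k)
  if (!to %in% ids) stop("'to' must be one of the merged ids")
  labels <- spikeLabels(result)
  labels[labels %in% ids] <- as.integer(to)
  dropped <- setdiff(ids, to)
  keepIds <- setdiff(seq_len(k), dropped)
  relabel <- match(labels, keepIds)
  cc <- result@centers
  cc@centers <- cc@centers[keepIds, , drop = FALSE]
  # relaxed validity after manual merging: centers may now be close
  cc@mergeThreshold <- 0
  out <- result
  out@labels <- as.integer(relabel)
  out@centers <- cc
  out@config <- c(result@config, list(merged = list(ids = ids, to = to)))
  validObject(out)
  out
}
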