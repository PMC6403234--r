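newFeatureMatrix <- function(values, info, params) {
  rownames(values) <- NULL
  colnames(values) <- info$id
  new("FeatureMatrix",
    values = values, featureInfo = info, methodParams = params
  )
}

#' Principal component analysis of waveforms
#'
#' Projects the (column-centered) waveform matrix onto the eigenvectors of
#' its sample covariance, ordered by decreasing eigenvalue, so each output
#' column is a PC score. For run-to-run determinism the sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param wfs a [WaveformSet-class] or a plain spikes x samples matrix.
#' @return a [FeatureMatrix-class]; `methodParams` holds the loadings
#'   (orthonormal columns), eigenvalues and column centers.
#' @export
pcaTransform <- function(wfs) {
  X <- if (is(wfs, "WaveformSet")) waveforms(wfs) else as.matrix(wfs)
  if (nrow(X) < 2L) stop("PCA requires at least 2 observations")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation
  scores <- pr$x
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pr$sdev^2
  zeroVar <- ev <= max(ev) * 1e-12
  info <- data.frame(
    id = paste0("PC", seq_len(ncol(scores))),
    method = "pca",
    scale = NA_integer_, translation = NA_integer_,
    component = seq_len(ncol(scores)),
    channel = NA_integer_,
    padded = FALSE,
    zeroVariance = zeroVar,
    stringsAsFactors = FALSE
  )
  newFeatureMatrix(scores, info, list(
    loadings = rot, eigenvalues = ev, center = pr$center
  ))
}

# one-level orthonormal Haar analysis step
haarStep <- function(a) {
  odd <- a[seq(1L, length(a), by = 2L)]
  even <- a[seq(2L, length(a), by = 2L)]
  list(approx = (odd + even) / sqrt(2), detail = (odd - even) / sqrt(2))
}

# full multiresolution decomposition of one vector; x length must be a
# multiple of 2^levels
haarDecompose <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- haarStep(a)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(details = details, approx = a)
}

haarReconstructVec <- function(details, approx) {
  a <- approx
  for (j in rev(seq_along(details))) {
    d <- details[[j]]
    out <- numeric(2L * length(a))
    out[seq(1L, length(out), by = 2L)] <- (a + d) / sqrt(2)
    out[seq(2L, length(out), by = 2L)] <- (a - d) / sqrt(2)
    a <- out
  }
  a
}

#' Multiresolution Haar wavelet decomposition
#'
#' Decomposes each waveform with the orthonormal Haar filter bank: the
#' signal is split into detail (high-pass) and approximation (low-pass)
#' halves, each downsampled by 2, and the split is repeated on the
#' approximation up to `levels` times (default 4). With the orthonormal
#' \eqn{1/\sqrt{2}}-per-level normalization the map is an orthogonal linear
#' transform: coefficient energy equals signal energy and the inverse
#' transform ([haarReconstruct()]) is exact.
#'
#' Multi-channel waveforms are decomposed per channel and the coefficients
#' concatenated. If the per-channel length is not a multiple of
#' `2^levels`, the snippet is padded by reflecting its tail to the next
#' multiple; coefficients whose support touches padded samples are flagged
#' `padded` in `featureInfo` (energy conservation then holds for the padded
#' signal, not the original).
#'
#' @param wfs a [WaveformSet-class] or spikes x samples matrix.
#' @param levels decomposition depth (default 4).
#' @param nChannels number of concatenated channels when `wfs` is a plain
#'   matrix (ignored for a WaveformSet).
#' @return a [FeatureMatrix-class] with one column per coefficient, ordered
#'   per channel as details of level 1..levels followed by the level-`levels`
#'   approximation. `featureInfo$scale` is the level j (0 for approximation
#'   coefficients means: recorded as `levels` with `component` NA; see ids).
#' @export
haarWd <- function(wfs, levels = 4L, nChannels = 1L) {
  if (is(wfs, "WaveformSet")) {
    X <- waveforms(wfs)
    nch <- nChannels(wfs)
  } else {
    X <- as.matrix(wfs)
    nch <- as.integer(nChannels)
  }
  levels <- as.integer(levels)
  spc <- ncol(X) %/% nch
  block <- 2L^levels
  if (spc < block)
    stop("samples per channel (", spc, ") must be at least 2^levels (",
         block, ")")
  padded <- spc %% block != 0L
  padLen <- if (padded) (block - spc %% block) else 0L
  Lp <- spc + padLen

  # per-channel coefficient bookkeeping
  nPerLevel <- Lp / 2L^seq_len(levels)
  chanInfo <- do.call(rbind, c(
    lapply(seq_len(levels), function(j) {
      k <- seq_len(nPerLevel[j])
      # original-sample support of detail (j, k): ((k-1)*2^j, k*2^j]
      data.frame(
        scale = j, translation = k, kind = "d",
        padFlag = k * 2L^j > spc, stringsAsFactors = FALSE
      )
    }),
    list(data.frame(
      scale = levels, translation = seq_len(nPerLevel[levels]), kind = "a",
      padFlag = seq_len(nPerLevel[levels]) * block > spc,
      stringsAsFactors = FALSE
    ))
  ))

  decomposeRow <- function(row) {
    unlist(lapply(seq_len(nch), function(ch) {
      x <- row[((ch - 1L) * spc + 1L):(ch * spc)]
      if (padLen > 0L) x <- c(x, rev(x)[seq_len(padLen)])
      dec <- haarDecompose(x, levels)
      c(unlist(dec$details), dec$approx)
    }), use.names = FALSE)
  }
  vals <- t(apply(X, 1L, decomposeRow))

  info <- do.call(rbind, lapply(seq_len(nch), function(ch) {
    ci <- chanInfo
    ci$channel <- ch
    ci
  }))
  info <- data.frame(
    id = sprintf("wd.c%d.%s%d.k%d", info$channel, info$kind, info$scale,
                 info$translation),
    method = "wd",
    scale = info$scale, translation = info$translation,
    component = NA_integer_, channel = info$channel,
    padded = info$padFlag, zeroVariance = FALSE,
    stringsAsFactors = FALSE
  )
  info$zeroVariance <- apply(vals, 2L, stats::var) == 0
  newFeatureMatrix(vals, info, list(
    levels = levels, samplesPerChannel = spc, padLength = padLen,
    nChannels = nch, kind = chanInfo$kind
  ))
}

#' Inverse Haar transform
#'
#' Reconstructs the waveform matrix from a [haarWd()] coefficient matrix.
#' Exact (to floating point) because the orthonormal Haar transform is
#' orthogonal; padded samples, if any, are dropped.
#'
#' @param fm a [FeatureMatrix-class] produced by [haarWd()].
#' @return spikes x samples matrix.
#' @export
haarReconstruct <- function(fm) {
  p <- fm@methodParams
  if (is.null(p$levels)) stop("not a Haar coefficient matrix")
  levels <- p$levels
  spc <- p$samplesPerChannel
  Lp <- spc + p$padLength
  nPerLevel <- Lp / 2L^seq_len(levels)
  perChan <- Lp
  vals <- fm@values
  recRow <- function(row) {
    unlist(lapply(seq_len(p$nChannels), function(ch) {
      x <- row[((ch - 1L) * perChan + 1L):(ch * perChan)]
      offs <- 0L
      details <- vector("list", levels)
      for (j in seq_len(levels)) {
        details[[j]] <- x[(offs + 1L):(offs + nPerLevel[j])]
        offs <- offs + nPerLevel[j]
      }
      approx <- x[(offs + 1L):(offs + nPerLevel[levels])]
      haarReconstructVec(details, approx)[seq_len(spc)]
    }), use.names = FALSE)
  }
  t(apply(vals, 1L, recRow))
}

#' Separability-weighted PCA
#'
#' Implements the weighted-PCA feature construction: every coefficient
#' column is z-scored, multiplied by its clustering-separability weight
#' (so separable coefficients contribute more variance), and the result is
#' decomposed by PCA. The output columns (weighted PC scores) are ordered by
#' variance; the first few are used for clustering.
#'
#' Zero-variance columns cannot be z-scored and are dropped (with a message)
#' before weighting.
#'
#' @param coeffs a [FeatureMatrix-class] (typically Haar coefficients) or a
#'   plain matrix.
#' @param weights non-negative separability score per coefficient column
#'   (e.g. `separabilityScores(scoreFeatures(coeffs, "i_dist"))`).
#' @return a [FeatureMatrix-class] of weighted PC scores; `methodParams`
#'   records the weights, the retained source columns, and the PCA basis.
#' @export
weightedPca <- function(coeffs, weights) {
  X <- if (is(coeffs, "FeatureMatrix")) featureValues(coeffs) else
    as.matrix(coeffs)
  srcInfo <- if (is(coeffs, "FeatureMatrix")) featureInfo(coeffs) else NULL
  weights <- as.numeric(weights)
  if (length(weights) != ncol(X))
    stop("need one weight per coefficient column")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  v <- apply(X, 2L, stats::var)
  keep <- v > 0
  if (!all(keep))
    message(sum(!keep), " zero-variance coefficient column(s) dropped ",
            "before weighting")
  X <- X[, keep, drop = FALSE]
  w <- weights[keep]
  if (all(w == 0)) stop("no informative features: all weights are zero")
  Z <- scale(X) # z-score: zero mean, unit variance
  W <- sweep(Z, 2L, w, "*")
  pc <- pcaTransform(W)
  info <- featureInfo(pc)
  info$method <- "wpca"
  info$id <- paste0("wPC", info$component)
  newFeatureMatrix(featureValues(pc), info, list(
    weights = w, keptColumns = which(keep),
    sourceInfo = if (!is.null(srcInfo)) srcInfo[keep, , drop = FALSE] else NULL,
    loadings = pc@methodParams$loadings,
    eigenvalues = pc@methodParams$eigenvalues,
    center = attr(Z, "scaled:center"), scale = attr(Z, "scaled:scale")
  ))
}
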