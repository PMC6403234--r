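#' Contingency table of true vs assigned classes
#'
#' @param true integer/factor vector of ground-truth classes.
#' @param assigned integer/factor vector of assigned cluster ids.
#' @return an integer matrix, true classes in rows, assigned classes in
#'   columns, with dimnames.
#' @export
contingencyTable <- function(true, assigned) {
  if (length(true) != length(assigned))
    stop("true and assigned must have the same length")
  tab <- table(true = true, assigned = assigned)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Mutual information of a contingency table
#'
#' Plug-in estimate, in bits, of
#' \eqn{MI(X,Y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}} with
#' `0 log 0 = 0`, where X are the true and Y the assigned classes. An
#' optional Miller-Madow correction
#' (adds \eqn{(r-1)(c-1)/(2 N \ln 2)}) is available; at typical spike
#' counts the plug-in bias is negligible for the normalized ratio.
#'
#' @param table a true x assigned count matrix ([contingencyTable()]).
#' @param millerMadow apply the Miller-Madow bias correction.
#' @return mutual information in bits.
#' @export
mutualInformation <- function(table, millerMadow = FALSE) {
  tab <- as.matrix(table)
  n <- sum(tab)
  if (n <= 0) stop("empty contingency table")
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / e[nz]))
  if (millerMadow) {
    r <- sum(px > 0); s <- sum(py > 0)
    mi <- mi + (r - 1) * (s - 1) / (2 * n * log(2))
  }
  max(mi, 0)
}

entropyBits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized mutual information (percentage of extracted spike information)
#'
#' \eqn{MI_{norm} = 100 \, MI(X,Y) / H(X)}: the mutual information between
#' true and assigned classes normalized by its maximum possible value, the
#' entropy of the true classes. 100 means the assignment preserves all
#' class information (any bijective relabeling, and also splits of one true
#' class across several clusters); 0 means independence.
#'
#' @inheritParams mutualInformation
#' @return a percentage in [0, 100].
#' @export
miNorm <- function(table, millerMadow = FALSE) {
  tab <- as.matrix(table)
  hx <- entropyBits(rowSums(tab))
  if (hx == 0)
    stop("MI_norm is undefined for a single true class (zero entropy)")
  val <- 100 * mutualInformation(tab, millerMadow = millerMadow) / hx
  min(max(val, 0), 100)
}

#' Classification error rate by predominant neuron
#'
#' Each assigned cluster is identified with its predominant (majority) true
#' class — ties broken toward the lower class index — and the error rate is
#' the percentage of spikes whose true class differs from their cluster's
#' identity.
#'
#' @inheritParams mutualInformation
#' @return error percentage in [0, 100].
#' @export
errorRate <- function(table) {
  tab <- as.matrix(table)
  n <- sum(tab)
  if (n <= 0) stop("empty contingency table")
  correct <- sum(apply(tab, 2L, function(col) col[which.max(col)]))
  100 * (n - correct) / n
}

#' Consistency of sorting across runs
#'
#' Summarizes repeated sorting runs of the same data: per-run MI_norm
#' against ground truth, its mean and variance (low variance = the
#' algorithm lands on similar solutions across restarts), and the mean
#' number of clusters found.
#'
#' @param results list of [SortingResult-class] objects (>= 2).
#' @param truth integer vector of true classes, or a list of such vectors
#'   (one per run).
#' @return list with `miNorm` (per run), `mean`, `variance`, `meanNFound`.
#' @export
consistency <- function(results, truth) {
  if (length(results) < 2L) stop("need at least 2 runs")
  if (!is.list(truth)) truth <- rep(list(truth), length(results))
  mis <- mapply(function(r, tr) {
    miNorm(contingencyTable(tr, spikeLabels(r)))
  }, results, truth)
  list(
    miNorm = as.numeric(mis),
    mean = mean(mis),
    variance = stats::var(mis),
    meanNFound = mean(vapply(results, nFound, numeric(1)))
  )
}

#' Sorting performance under unbalanced cluster sizes
#'
#' Emulates firing-rate asymmetry: true classes are first equalized in
#' count, then one class at a time is subsampled to each symmetry index
#' (percentage of its spikes retained) and the full pipeline is rerun.
#' Reports, per (target class, index): the overall MI_norm and the MI_norm
#' of the subsampled class against the rest (all other true classes joined
#' before computing MI), which isolates how well the rare cluster is still
#' discriminated.
#'
#' @param wfs a labeled [WaveformSet-class] (>= 2 true classes).
#' @param indexes symmetry indexes in percent (default 8 log-spaced values
#'   from 1 to 100).
#' @param seed integer seed for the subsampling and the pipeline.
#' @param classes true classes to subsample, one at a time (default: all).
#' @param ... pipeline configuration forwarded to [sortSpikes()].
#' @return data.frame with columns targetClass, index, nSpikes, miNorm,
#'   miNormSmallest.
#' @export
symmetrySweep <- function(wfs, indexes = 10^seq(0, 2, length.out = 8),
                          seed = 1L, classes = NULL, ...) {
  labs <- trueLabels(wfs)
  present <- sort(unique(labs[labs > 0L]))
  if (length(present) < 2L) stop("need at least 2 true classes")
  classes <- if (is.null(classes)) present else intersect(classes, present)
  rows <- list()
  for (cl in classes) {
    for (ix in indexes) {
      sub <- tryCatch(
        subsampleForSymmetry(wfs, targetClass = cl, index = ix,
                             seed = childSeed(seed, cl * 1000L + round(ix))),
        error = function(e) NULL
      )
      if (is.null(sub) ||
          sum(trueLabels(sub) == cl) < 10L) {
        warning(sprintf(
          "symmetry index %.3g%% leaves fewer than 10 spikes of class %d; skipped",
          ix, cl
        ))
        next
      }
      res <- sortSpikes(sub, seed = childSeed(seed, cl * 100000L + round(ix)),
                        ...)
      tr <- trueLabels(sub)
      overall <- miNorm(contingencyTable(tr, spikeLabels(res)))
      binary <- miNorm(contingencyTable(ifelse(tr == cl, 1L, 2L),
                                        spikeLabels(res)))
      rows[[length(rows) + 1L]] <- data.frame(
        targetClass = cl, index = ix, nSpikes = nSpikes(sub),
        miNorm = overall, miNormSmallest = binary
      )
    }
  }
  do.call(rbind, rows)
}
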