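#' Split capture targets into copy-ratio bins
#'
#' Each target is split into bins no longer than `maxSize`; bins shorter
#' than `minSize` are merged into a neighbouring bin of the same target.
#' A target shorter than `minSize` yields a single bin flagged `short`.
#' Bins never span targets, so their union equals the union of the targets.
#'
#' @param targets GRanges of sorted, non-overlapping target intervals
#' @param minSize minimum bin length (bases)
#' @param maxSize maximum bin length (bases)
#' @return GRanges of bins with metadata columns `on_target` and `short`
#' @export
makeBins <- function(targets, minSize = 100L, maxSize = 100000L) {
  if (length(targets) == 0)
    return(GRanges(on_target = logical(), short = logical()))
  stopifnot(minSize >= 1, maxSize >= minSize)
  pieces <- lapply(seq_along(targets), function(i) {
    w <- width(targets)[i]
    nb <- max(1L, ceiling(w / maxSize))
    # equal split, then fold a trailing short bin into its neighbour
    bnd <- unique(c(seq(0L, w, by = ceiling(w / nb)), w))
    sizes <- diff(bnd)
    while (length(sizes) > 1 && any(sizes < minSize)) {
      j <- which(sizes < minSize)[1]
      nb2 <- if (j == 1) 2L else j - 1L
      sizes[nb2] <- sizes[nb2] + sizes[j]
      sizes <- sizes[-j]
    }
    st <- start(targets)[i] + cumsum(c(0L, head(sizes, -1L)))
    GRanges(seqnames(targets)[i], IRanges(start = st, width = sizes),
            on_target = TRUE, short = sizes < minSize)
  })
  sort(do.call(c, pieces))
}

#' Normalised log2 tumor/normal copy ratios per bin
#'
#' `log2((tumor_bin / normal_bin) * (normal_total / tumor_total))`. Bins
#' with zero depth in either sample are marked undefined (`NA` ratio) and
#' are excluded from segmentation downstream. Totals default to the column
#' sums, so scaling all tumor depths by a constant leaves the ratios
#' unchanged.
#'
#' @param tumor,normal non-negative bin read counts (equal length)
#' @param tumorTotal,normalTotal library sizes used for normalisation
#' @return numeric vector of log2 ratios with `NA` at undefined bins
#' @export
computeCopyRatios <- function(tumor, normal, tumorTotal = sum(tumor),
                              normalTotal = sum(normal)) {
  if (length(tumor) != length(normal)) stop("mismatched bin lists")
  stopifnot(tumorTotal > 0, normalTotal > 0, all(tumor >= 0),
            all(normal >= 0))
  ok <- tumor > 0 & normal > 0
  out <- rep(NA_real_, length(tumor))
  out[ok] <- log2((tumor[ok] / normal[ok]) * (normalTotal / tumorTotal))
  out
}

# max |t| over all circular arcs of x; returns the statistic and arc (i, j]
# in 0-based boundary coordinates. prep caches permutation-invariant pieces.
cbs_arc_prep <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (n < 2 || !is.finite(s) || s < 1e-12) return(NULL)
  kmat <- outer(0:n, 0:n, function(a, b) a - b)
  valid <- which(kmat >= 1 & kmat <= n - 1)
  ai <- ((valid - 1) %% (n + 1)) + 1   # row = j + 1
  bi <- ((valid - 1) %/% (n + 1)) + 1  # col = i + 1
  k <- kmat[valid]
  list(n = n, tot = sum(x), ai = ai, bi = bi,
       i = bi - 1L, j = ai - 1L,
       invk = 1 / k, invnk = 1 / (n - k),
       invD = 1 / (s * sqrt(1 / k + 1 / (n - k))))
}

cbs_max_t <- function(x, prep, arg = FALSE) {
  v <- cumsum(c(0, x))
  sumin <- v[prep$ai] - v[prep$bi]
  t <- (sumin * prep$invk - (prep$tot - sumin) * prep$invnk) * prep$invD
  at <- abs(t)
  if (!arg) return(max(at))
  w <- which.max(at)
  list(t = at[w], i = prep$i[w], j = prep$j[w])
}

#' Circular binary segmentation of a copy-ratio profile
#'
#' Recursive change-point search: within each current segment, the arc
#' maximising the absolute two-sample t-statistic (arc vs complement, with
#' the segment's overall SD) is tested against a permutation reference
#' distribution of the same statistic; the split is accepted when the
#' permutation p-value is below `alpha`. The permutation loop stops early
#' once significance can no longer be reached. An all-equal (or
#' single-bin) input returns one segment.
#'
#' @param x numeric vector of bin log2 ratios for one chromosome (no NAs)
#' @param alpha permutation significance level for accepting a split
#' @param nPerm number of permutations
#' @param seed optional integer seed (set once at entry)
#' @return data.frame with one row per segment: start, end (1-based bin
#'   indices), n_bins, mean
#' @export
cbsSegment <- function(x, alpha = 0.01, nPerm = 1000L, seed = NULL) {
  stopifnot(length(x) >= 1, !anyNA(x))
  if (!is.null(seed)) set.seed(seed)
  bounds <- sort(unique(c(0L, length(x), cbs_recurse(x, 0L, alpha, nPerm))))
  st <- head(bounds, -1L) + 1L
  en <- tail(bounds, -1L)
  data.frame(start = st, end = en, n_bins = en - st + 1L,
             mean = vapply(seq_along(st),
                           function(i) mean(x[st[i]:en[i]]), numeric(1)))
}

# returns accepted split boundaries (0-based, relative to whole profile)
cbs_recurse <- function(x, offset, alpha, nPerm) {
  prep <- cbs_arc_prep(x)
  if (is.null(prep)) return(integer(0))
  obs <- cbs_max_t(x, prep, arg = TRUE)
  exceedMax <- floor(alpha * nPerm)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    if (cbs_max_t(sample(x), prep) >= obs$t) {
      exceed <- exceed + 1L
      if (exceed > exceedMax) return(integer(0))
    }
  }
  # accepted: split at i and j (either may be an end of the segment)
  cuts <- setdiff(sort(unique(c(obs$i, obs$j))), c(0L, length(x)))
  if (length(cuts) == 0) return(integer(0))
  bnd <- c(0L, cuts, length(x))
  out <- offset + cuts
  for (p in seq_len(length(bnd) - 1L)) {
    lo <- bnd[p] + 1L; hi <- bnd[p + 1L]
    if (hi - lo >= 1L)
      out <- c(out, cbs_recurse(x[lo:hi], offset + lo - 1L, alpha, nPerm))
  }
  out
}

#' Undo segmentation splits below a significance-of-difference threshold
#'
#' Adjacent segments whose mean difference is less than `sdMultiplier`
#' times the residual SD (pooled SD of bin deviations from their segment
#' means, estimated once from the input segmentation) are merged
#' iteratively, smallest difference first, until every adjacent difference
#' meets the threshold.
#'
#' @param segs segmentation data.frame from [cbsSegment()] (columns start,
#'   end, n_bins, mean)
#' @param x the bin log2 ratios the segmentation refers to
#' @param sdMultiplier required separation in residual SDs
#' @return merged segmentation data.frame, means recomputed from `x`
#' @export
undoSplits <- function(segs, x, sdMultiplier = 3) {
  if (nrow(segs) <= 1) return(segs)
  fitted <- rep(segs$mean, segs$n_bins)
  df <- length(x) - nrow(segs)
  rsd <- if (df > 0) sqrt(sum((x - fitted)^2) / df) else 0
  thr <- sdMultiplier * rsd
  repeat {
    if (nrow(segs) <= 1) break
    d <- abs(diff(segs$mean))
    j <- which.min(d)
    if (d[j] >= thr) break
    segs$end[j] <- segs$end[j + 1]
    segs$n_bins[j] <- segs$end[j] - segs$start[j] + 1L
    segs$mean[j] <- mean(x[segs$start[j]:segs$end[j]])
    segs <- segs[-(j + 1), , drop = FALSE]
  }
  rownames(segs) <- NULL
  segs
}

seg_state <- function(mean, ampThr = 0.2, delThr = -0.2) {
  ifelse(mean > ampThr, "amp", ifelse(mean < delThr, "del", "neutral"))
}

#' Remove off-target-only segments and re-fuse equal neighbours
#'
#' Segments with zero overlap with any capture target are removed
#' (coverage-only regions generated from off-target reads); consecutive
#' segments on the same chromosome whose mean log2 ratios agree within
#' `tol` are then merged. The operation is idempotent.
#'
#' @param segs data.frame with columns chrom, start, end, n_bins, mean_log2
#'   (genomic coordinates, 1-based inclusive)
#' @param targets GRanges of capture targets
#' @param tol equality tolerance for re-fusion
#' @return filtered and re-fused segment data.frame
#' @export
filterOfftargetAndRefuse <- function(segs, targets, tol = 1e-9) {
  if (nrow(segs) == 0) return(segs)
  gr <- GRanges(segs$chrom, IRanges(segs$start, segs$end))
  keep <- countOverlaps(gr, targets) > 0
  segs <- segs[keep, , drop = FALSE]
  if (nrow(segs) <= 1) { rownames(segs) <- NULL; return(segs) }
  i <- 1L
  while (i < nrow(segs)) {
    if (segs$chrom[i] == segs$chrom[i + 1] &&
        abs(segs$mean_log2[i] - segs$mean_log2[i + 1]) <= tol) {
      w <- c(segs$n_bins[i], segs$n_bins[i + 1])
      segs$mean_log2[i] <- sum(w * c(segs$mean_log2[i],
                                     segs$mean_log2[i + 1])) / sum(w)
      segs$end[i] <- segs$end[i + 1]
      segs$n_bins[i] <- sum(w)
      segs <- segs[-(i + 1), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(segs) <- NULL
  segs
}

#' Residual variance of a segmented sample
#'
#' Mean squared deviation of bin log2 ratios from their segment means; the
#' sample-level copy-ratio noise metric used for QC exclusion.
#'
#' @param x bin log2 ratios
#' @param segs segmentation over `x` (columns start, end, mean as bin
#'   indices, e.g. [cbsSegment()] output)
#' @return non-negative scalar
#' @export
residualVariance <- function(x, segs) {
  fitted <- rep(segs$mean, segs$n_bins)
  stopifnot(length(fitted) == length(x))
  mean((x - fitted)^2)
}

#' Flag samples with unstable copy-ratio profiles
#'
#' A sample is excluded when its residual variance exceeds the cohort
#' median plus `k` MADs (and strictly exceeds the median, so degenerate
#' all-identical cohorts yield no flags). An absolute `cutoff` can be used
#' instead.
#'
#' @param rv named numeric vector of per-sample residual variances
#' @param k MAD multiplier
#' @param cutoff optional absolute residual-variance cutoff overriding the
#'   cohort-relative rule
#' @return data.frame: sample_id, residual_variance, exclude
#' @export
residualVarianceQC <- function(rv, k = 3, cutoff = NULL) {
  stopifnot(length(rv) >= 3, !is.null(names(rv)))
  if (is.null(cutoff)) {
    m <- median(rv); s <- mad(rv)
    excl <- rv > m + k * s & rv > m
  } else {
    excl <- rv > cutoff
  }
  data.frame(sample_id = names(rv), residual_variance = unname(rv),
             exclude = unname(excl), stringsAsFactors = FALSE)
}

#' Segment one sample's binned copy ratios
#'
#' Runs [cbsSegment()] per chromosome on the defined bins, applies
#' [undoSplits()], maps segments back to genomic coordinates, optionally
#' removes off-target-only segments and re-fuses equal neighbours, and
#' assigns amp/neutral/del states at the +/-0.2 log2 thresholds.
#'
#' @param bins data.frame with columns chrom, start, end, log2 (NA allowed;
#'   undefined bins are dropped)
#' @param alpha,nPerm,seed CBS parameters
#' @param sdMultiplier undo-splits separation threshold
#' @param targets optional GRanges for the off-target filter
#' @param ampThr,delThr state thresholds on the segment mean
#' @return list with `segments` (chrom, start, end, n_bins, mean_log2,
#'   state) and `residual_variance`
#' @export
segmentSample <- function(bins, alpha = 0.01, nPerm = 1000L, seed = NULL,
                          sdMultiplier = 3, targets = NULL,
                          ampThr = 0.2, delThr = -0.2) {
  if (!is.null(seed)) set.seed(seed)
  bins <- bins[!is.na(bins$log2), , drop = FALSE]
  segList <- list(); rvNum <- 0; rvDen <- 0L
  for (chrom in unique(bins$chrom)) {
    cb <- bins[bins$chrom == chrom, , drop = FALSE]
    x <- cb$log2
    segs <- cbsSegment(x, alpha = alpha, nPerm = nPerm)
    segs <- undoSplits(segs, x, sdMultiplier = sdMultiplier)
    # residual variance over on-target bins only: off-target coverage is
    # sparse and would dominate the metric through counting noise alone
    resid2 <- (x - rep(segs$mean, segs$n_bins))^2
    onMask <- if ("on_target" %in% names(cb)) cb$on_target else
      rep(TRUE, length(x))
    rvNum <- rvNum + sum(resid2[onMask])
    rvDen <- rvDen + sum(onMask)
    segList[[chrom]] <- data.frame(
      chrom = chrom,
      start = cb$start[segs$start], end = cb$end[segs$end],
      n_bins = segs$n_bins, mean_log2 = segs$mean,
      stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, segList)
  rownames(segs) <- NULL
  if (!is.null(targets)) segs <- filterOfftargetAndRefuse(segs, targets)
  segs$state <- seg_state(segs$mean_log2, ampThr, delThr)
  list(segments = segs,
       residual_variance = if (rvDen > 0) rvNum / rvDen else NA_real_)
}

#' Segment every sample of a synthetic cohort
#'
#' Computes normalised copy ratios from the cohort's bin depth matrices,
#' segments each sample with [segmentSample()] (off-target filter applied
#' against the cohort targets) and runs [residualVarianceQC()].
#'
#' @param cohort a [PJCohort-class]
#' @param alpha,nPerm CBS parameters
#' @param seed integer seed for the permutation streams
#' @param k residual-variance MAD multiplier
#' @return list: `seg` (SEG-style data.frame with a sample column), `qc`
#'   ([residualVarianceQC()] output), `binTables` (per-sample bin
#'   data.frames with log2 ratios)
#' @export
segmentCohort <- function(cohort, alpha = 0.01, nPerm = 200L, seed = 1L,
                          k = 3) {
  se <- binDepths(cohort)
  bins <- rowRanges(se)
  tum <- assay(se, "tumor"); nor <- assay(se, "normal")
  ids <- colnames(tum)
  set.seed(seed)
  segAll <- list(); rv <- setNames(numeric(length(ids)), ids)
  binTables <- list()
  for (id in ids) {
    lr <- computeCopyRatios(tum[, id], nor[, id])
    bt <- data.frame(chrom = as.character(seqnames(bins)),
                     start = start(bins), end = end(bins), log2 = lr,
                     on_target = bins$on_target, stringsAsFactors = FALSE)
    res <- segmentSample(bt, alpha = alpha, nPerm = nPerm,
                         targets = targets(cohort))
    segAll[[id]] <- cbind(sample = id, res$segments,
                          stringsAsFactors = FALSE)
    rv[id] <- res$residual_variance
    binTables[[id]] <- bt
  }
  seg <- do.call(rbind, segAll)
  rownames(seg) <- NULL
  list(seg = seg, qc = residualVarianceQC(rv, k = k),
       binTables = binTables)
}

#' Write / read segmented copy-number (SEG) files
#'
#' Standard 6-column tab-delimited SEG dialect (ID, chrom, loc.start,
#' loc.end, num.mark, seg.mean), 1-based inclusive coordinates.
#'
#' @param seg data.frame with columns sample, chrom, start, end, n_bins,
#'   mean_log2
#' @param path output / input file path
#' @return `readSeg` returns the data.frame; `writeSeg` returns the path
#'   invisibly
#' @export
writeSeg <- function(seg, path) {
  out <- data.frame(ID = seg$sample, chrom = seg$chrom,
                    loc.start = seg$start, loc.end = seg$end,
                    num.mark = seg$n_bins,
                    seg.mean = sprintf("%.6g", seg$mean_log2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSeg
#' @export
readSeg <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  data.frame(sample = as.character(x$ID), chrom = as.character(x$chrom),
             start = x$loc.start, end = x$loc.end, n_bins = x$num.mark,
             mean_log2 = as.numeric(x$seg.mean), stringsAsFactors = FALSE)
}
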