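#' Build a marker-level log2 matrix from segmented samples
#'
#' Markers are bin midpoints; each sample's marker value is the mean log2
#' ratio of the segment covering the marker (0 where no segment covers it,
#' i.e. copy-neutral by assumption).
#'
#' @param seg SEG-style data.frame (sample, chrom, start, end, mean_log2)
#' @param bins GRanges (or data.frame with chrom/start/end) defining marker
#'   positions; typically the on-target copy-ratio bins
#' @param samples optional character vector fixing sample order
#' @return list with `X` (samples x markers numeric matrix), `chrom`,
#'   `pos` (marker coordinates)
#' @export
markerMatrix <- function(seg, bins, samples = NULL) {
  if (is(bins, "GRanges")) {
    chrom <- as.character(seqnames(bins))
    pos <- floor((start(bins) + end(bins)) / 2)
  } else {
    chrom <- as.character(bins$chrom)
    pos <- floor((bins$start + bins$end) / 2)
  }
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  if (is.null(samples)) samples <- unique(seg$sample)
  X <- matrix(0, nrow = length(samples), ncol = length(pos),
              dimnames = list(samples, NULL))
  for (r in seq_len(nrow(seg))) {
    s <- seg$sample[r]
    if (!s %in% samples) next
    hit <- chrom == seg$chrom[r] & pos >= seg$start[r] & pos <= seg$end[r]
    X[s, hit] <- seg$mean_log2[r]
  }
  list(X = X, chrom = chrom, pos = pos)
}

#' Per-marker recurrence G-score
#'
#' Sums, across samples, the above-threshold amplitude at each marker:
#' amplification `G(m) = sum_s max(0, x[s,m] - threshold)`, deletion
#' `G(m) = sum_s max(0, -threshold - x[s,m])`. Amplitudes are capped at
#' `|x| <= cap` first so a single extreme sample cannot dominate.
#'
#' @param X samples x markers log2 matrix (missing values treated as 0)
#' @param direction `"amp"` or `"del"`
#' @param threshold alteration threshold on the log2 scale
#' @param cap amplitude cap
#' @return numeric vector of per-marker G-scores (all >= 0)
#' @export
gscore <- function(X, direction = c("amp", "del"), threshold = 0.2,
                   cap = 2) {
  direction <- match.arg(direction)
  X[is.na(X)] <- 0
  X <- pmin(pmax(X, -cap), cap)  # pmax/pmin keep dims of the first arg
  if (direction == "amp") colSums(pmax(X - threshold, 0))
  else colSums(pmax(-threshold - X, 0))
}

#' Permutation reference distribution for the G-score
#'
#' Each permutation applies an independent random cyclic shift to every
#' sample's marker vector (preserving within-sample segmental structure)
#' and recomputes the per-marker G-score. Returns the per-permutation
#' maximum G and the pooled null G values used for marker-level empirical
#' p-values.
#'
#' @param X samples x markers log2 matrix
#' @param direction `"amp"` or `"del"`
#' @param nPerm number of permutations
#' @param seed optional integer seed
#' @param threshold,cap passed to [gscore()]
#' @return list: `maxG` (length nPerm), `nullG` (nPerm x markers matrix),
#'   `nPerm`
#' @export
permutationNull <- function(X, direction = c("amp", "del"), nPerm = 1000L,
                            seed = NULL, threshold = 0.2, cap = 2) {
  direction <- match.arg(direction)
  if (ncol(X) < 2) stop("need at least 2 markers")
  if (nrow(X) < 1) stop("need at least 1 sample")
  if (!is.null(seed)) set.seed(seed)
  M <- ncol(X); S <- nrow(X)
  nullG <- matrix(0, nPerm, M)
  Xp <- X
  for (b in seq_len(nPerm)) {
    shifts <- sample.int(M, S, replace = TRUE) - 1L
    for (s in seq_len(S)) {
      if (shifts[s] > 0) {
        Xp[s, ] <- X[s, c((M - shifts[s] + 1L):M, 1L:(M - shifts[s]))]
      } else Xp[s, ] <- X[s, ]
    }
    nullG[b, ] <- gscore(Xp, direction, threshold, cap)
  }
  list(maxG = apply(nullG, 1, max), nullG = nullG, nPerm = nPerm)
}

#' Significant recurrent regions from G-scores and a permutation null
#'
#' Marker-level empirical p-values are the fraction of pooled null G values
#' at least as large as the observed G; Benjamini-Hochberg q-values are
#' computed across markers; maximal runs of contiguous markers (within a
#' chromosome) with `q < qThreshold` become regions. The peak is the
#' maximal-G marker span of the region and the wide (driver-confidence)
#' interval is the smallest sub-run around the peak whose G stays above
#' the peak G minus the `confidence` quantile of the null maximum G.
#'
#' @param G per-marker G-scores ([gscore()])
#' @param null [permutationNull()] output from the same matrix
#' @param chrom,pos marker coordinates (parallel to `G`)
#' @param direction `"amp"` or `"del"` (annotated on the output)
#' @param qThreshold q-value cutoff defining significant markers
#' @param confidence driver-region confidence level for the wide interval
#' @return data.frame: direction, chrom, peak_start, peak_end, wide_start,
#'   wide_end, g_peak, q, n_markers; sorted by q then coordinate
#' @export
significantRegions <- function(G, null, chrom, pos,
                               direction = "amp", qThreshold = 0.25,
                               confidence = 0.90) {
  pool <- sort(as.vector(null$nullG))
  npool <- length(pool)
  # p = P_null(G* >= g), via right-tail rank in the pooled null
  pvals <- (npool - findInterval(G - 1e-12, pool) + 1) / (npool + 1)
  q <- p.adjust(pvals, method = "BH")
  sig <- q < qThreshold & G > 0
  if (!any(sig)) return(empty_regions())
  delta <- quantile(null$maxG, confidence, names = FALSE)
  w <- which(sig)
  newRun <- if (length(w) > 1)
    c(TRUE, diff(w) != 1 | chrom[w[-1]] != chrom[w[-length(w)]])
  else TRUE
  runs <- split(w, cumsum(newRun))
  out <- lapply(runs, function(idx) {
    gPeak <- max(G[idx])
    peak <- idx[G[idx] == gPeak]
    wideOk <- idx[G[idx] > gPeak - delta]
    # grow the smallest contiguous sub-run around the peak
    lo <- min(peak); hi <- max(peak)
    while ((lo - 1) %in% wideOk) lo <- lo - 1
    while ((hi + 1) %in% wideOk) hi <- hi + 1
    data.frame(direction = direction, chrom = chrom[idx[1]],
               peak_start = pos[min(peak)], peak_end = pos[max(peak)],
               wide_start = pos[lo], wide_end = pos[hi],
               g_peak = gPeak, q = min(q[idx]),
               n_markers = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$q, out$chrom, out$peak_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_regions <- function() {
  data.frame(direction = character(), chrom = character(),
             peak_start = integer(), peak_end = integer(),
             wide_start = integer(), wide_end = integer(),
             g_peak = numeric(), q = numeric(), n_markers = integer(),
             stringsAsFactors = FALSE)
}

#' Recurrent-region analysis of a marker matrix
#'
#' Convenience wrapper running [gscore()], [permutationNull()] and
#' [significantRegions()] for both directions.
#'
#' @param mm [markerMatrix()] output
#' @param nPerm,seed,threshold,cap,qThreshold,confidence see the component
#'   functions
#' @return data.frame of amp and del regions
#' @export
recurrentRegions <- function(mm, nPerm = 1000L, seed = 1L, threshold = 0.2,
                             cap = 2, qThreshold = 0.25,
                             confidence = 0.90) {
  out <- lapply(c("amp", "del"), function(dir) {
    G <- gscore(mm$X, dir, threshold, cap)
    null <- permutationNull(mm$X, dir, nPerm = nPerm, seed = seed,
                            threshold = threshold, cap = cap)
    significantRegions(G, null, mm$chrom, mm$pos, direction = dir,
                       qThreshold = qThreshold, confidence = confidence)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-grade recurrence runs (benign vs malignant)
#'
#' Runs the recurrence analysis separately on the benign (LGD) subset and
#' the malignant (HGD + INC) subset. A subset with fewer than 2 samples is
#' skipped with a warning and returns an empty region set.
#'
#' @param mm [markerMatrix()] output for the whole cohort
#' @param grades named grade vector (names = sample ids, values in
#'   LGD/HGD/INC) or a sample sheet data.frame with sample_id and grade
#' @param ... passed to [recurrentRegions()]
#' @return list with elements `benign` and `malignant`, each carrying the
#'   region data.frame and an `n_samples` attribute
#' @export
perGradeRuns <- function(mm, grades, ...) {
  if (is.data.frame(grades))
    grades <- setNames(as.character(grades$grade), grades$sample_id)
  grades <- grades[rownames(mm$X)]
  run <- function(ids) {
    if (length(ids) < 2) {
      warning("subset with fewer than 2 samples skipped")
      res <- empty_regions()
    } else {
      res <- recurrentRegions(list(X = mm$X[ids, , drop = FALSE],
                                   chrom = mm$chrom, pos = mm$pos), ...)
    }
    attr(res, "n_samples") <- length(ids)
    res
  }
  list(benign = run(rownames(mm$X)[grades == "LGD"]),
       malignant = run(rownames(mm$X)[grades %in% c("HGD", "INC")]))
}

#' Per-sample alteration flags for a recurrent region
#'
#' A sample is flagged altered when any of its segments overlapping the
#' region's wide interval crosses the direction's threshold.
#'
#' @param region one row of a region data.frame
#' @param seg SEG-style data.frame
#' @param samples character vector of sample ids
#' @param threshold alteration threshold
#' @return named logical vector over `samples`
#' @export
regionAltered <- function(region, seg, samples, threshold = 0.2) {
  hit <- seg$chrom == region$chrom & seg$start <= region$wide_end &
    seg$end >= region$wide_start
  alt <- if (region$direction == "amp") seg$mean_log2 > threshold
         else seg$mean_log2 < -threshold
  flagged <- unique(seg$sample[hit & alt])
  setNames(samples %in% flagged, samples)
}
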