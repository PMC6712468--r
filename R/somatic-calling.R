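#' Caller configuration
#'
#' Thresholds of the paired tumor/normal Fisher-exact caller. Defaults:
#' minimum filtered depth 8 (applied to tumor and normal), minimum mapping
#' quality 20, minimum base quality 15, at least 3 variant-supporting reads,
#' tumor allele fraction at least 0.05, normal allele fraction at most 0.1,
#' and a Fisher p-value call threshold of 0.05.
#'
#' @param minDepth minimum filtered depth in each of tumor and normal
#' @param minMapq minimum read mapping quality
#' @param minBaseq minimum base quality
#' @param minVariantReads minimum tumor reads supporting the variant
#' @param minTumorAf minimum tumor variant allele fraction
#' @param maxNormalAf maximum normal variant allele fraction
#' @param fisherThreshold p-value call threshold
#' @param alternative `"greater"` (tumor alt enrichment, default) or
#'   `"two.sided"`
#' @return a list of class `CallerConfig`
#' @export
callerConfig <- function(minDepth = 8L, minMapq = 20L, minBaseq = 15L,
                         minVariantReads = 3L, minTumorAf = 0.05,
                         maxNormalAf = 0.1, fisherThreshold = 0.05,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(minDepth >= 0, minMapq >= 0, minBaseq >= 0,
            minVariantReads >= 0,
            minTumorAf >= 0, minTumorAf <= 1,
            maxNormalAf >= 0, maxNormalAf <= 1,
            fisherThreshold > 0, fisherThreshold <= 1)
  structure(list(minDepth = minDepth, minMapq = minMapq,
                 minBaseq = minBaseq, minVariantReads = minVariantReads,
                 minTumorAf = minTumorAf, maxNormalAf = maxNormalAf,
                 fisherThreshold = fisherThreshold,
                 alternative = alternative),
            class = "CallerConfig")
}

#' Quality-filter the reads of one pileup site
#'
#' Retains only reads with mapping quality >= `minMapq` and base quality >=
#' `minBaseq`, and returns per-allele read counts for tumor and normal.
#'
#' @param site data.frame with columns role, allele, baseq, mapq, count
#'   (aggregated read observations of a single site)
#' @param config a [callerConfig()] list
#' @return list with elements `tumor` and `normal`, each a named integer
#'   vector of per-allele filtered read counts
#' @export
filterReads <- function(site, config = callerConfig()) {
  keep <- site$mapq >= config$minMapq & site$baseq >= config$minBaseq
  site <- site[keep, , drop = FALSE]
  cnt <- function(role) {
    sub <- site[site$role == role, , drop = FALSE]
    if (nrow(sub) == 0) return(setNames(integer(0), character(0)))
    tapply_counts <- tapply(sub$count, sub$allele, sum)
    setNames(as.integer(tapply_counts), names(tapply_counts))
  }
  list(tumor = cnt("tumor"), normal = cnt("normal"))
}

#' One-sided Fisher exact p-value for tumor alt-allele enrichment
#'
#' Conditions on the margins of the 2x2 table
#' \[tumor_alt, tumor_ref; normal_alt, normal_ref\] and sums the
#' hypergeometric tail of tables at least as enriched in tumor alt reads as
#' the observed one. `alternative = "two.sided"` sums all tables whose
#' conditional probability does not exceed the observed table's.
#'
#' @param tumorAlt,tumorRef,normalAlt,normalRef non-negative read counts;
#'   vectors are recycled to common length and tested element-wise
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @return p-value(s) in (0, 1]
#' @examples
#' fisherTestSite(20, 80, 0, 100)
#' @export
fisherTestSite <- function(tumorAlt, tumorRef, normalAlt, normalRef,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(tumorAlt), length(tumorRef), length(normalAlt),
           length(normalRef))
  a <- rep_len(as.numeric(tumorAlt), n)
  b <- rep_len(as.numeric(tumorRef), n)
  c_ <- rep_len(as.numeric(normalAlt), n)
  d <- rep_len(as.numeric(normalRef), n)
  if (any(a < 0 | b < 0 | c_ < 0 | d < 0)) stop("negative counts")
  if (any(a + b == 0 | c_ + d == 0)) stop("zero depth in tumor or normal")
  if (alternative == "greater") {
    # P(X >= a), X ~ Hypergeom(white = alt total, black = ref total,
    # draws = tumor depth)
    p <- phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  } else {
    p <- vapply(seq_len(n), function(i) {
      k <- max(0, a[i] + b[i] - (b[i] + d[i])):min(a[i] + b[i],
                                                   a[i] + c_[i])
      pr <- dhyper(k, a[i] + c_[i], b[i] + d[i], a[i] + b[i])
      pObs <- dhyper(a[i], a[i] + c_[i], b[i] + d[i], a[i] + b[i])
      sum(pr[pr <= pObs * (1 + 1e-7)])
    }, numeric(1))
  }
  pmin(1, p)
}

FILTER_ORDER <- c("depth_fail", "min_variant_reads_fail", "tumor_af_fail",
                  "normal_af_fail", "fisher_fail", "PASS")

#' Call somatic variants in one sample
#'
#' For every pileup site, applies the read-quality filter, picks the tested
#' alt allele (non-reference allele with the lowest one-sided Fisher p;
#' other alleles are dropped), computes allele fractions over the ref+alt
#' read pair, and assigns PASS or the first failed filter in the order
#' depth, variant reads, tumor AF, normal AF, Fisher p.
#'
#' @param pileup data.frame pileup table for one sample (columns chrom, pos,
#'   ref, context, role, allele, baseq, mapq, count), sorted by chrom, pos
#' @param config a [callerConfig()] list
#' @return data.frame with one row per site carrying a non-reference allele:
#'   chrom, pos, ref, alt, context, t_alt, t_ref, n_alt, n_ref, t_vaf,
#'   n_vaf, p, filter, class
#' @export
callSample <- function(pileup, config = callerConfig()) {
  req <- c("chrom", "pos", "ref", "context", "role", "allele", "baseq",
           "mapq", "count")
  stopifnot(all(req %in% names(pileup)))
  if (nrow(pileup)) {
    o <- order(pileup$chrom, pileup$pos)
    if (!identical(paste(pileup$chrom, pileup$pos),
                   paste(pileup$chrom[o], pileup$pos[o])))
      stop("pileup must be sorted by chrom, pos")
  }
  dt <- as.data.table(pileup)
  dt <- dt[mapq >= config$minMapq & baseq >= config$minBaseq]
  if (nrow(dt) == 0) return(empty_calls())
  counts <- dt[, list(count = sum(count)),
               by = c("chrom", "pos", "ref", "context", "role", "allele")]
  out <- counts[, call_one_site(.SD, .BY$ref, config),
                by = c("chrom", "pos", "ref", "context")]
  out <- as.data.frame(out)
  out <- out[!is.na(out$alt), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             context = character(), alt = character(), t_alt = integer(),
             t_ref = integer(), n_alt = integer(), n_ref = integer(),
             t_vaf = numeric(), n_vaf = numeric(), p = numeric(),
             filter = character(), class = character(),
             stringsAsFactors = FALSE)
}

call_one_site <- function(sd, refA, config) {
  tum <- sd[sd$role == "tumor", ]
  nor <- sd[sd$role == "normal", ]
  gc <- function(tab, al) {
    i <- match(al, tab$allele)
    if (is.na(i)) 0L else as.integer(tab$count[i])
  }
  alts <- setdiff(unique(sd$allele), refA)
  if (length(alts) == 0)
    return(list(alt = NA_character_, t_alt = NA_integer_,
                t_ref = NA_integer_, n_alt = NA_integer_,
                n_ref = NA_integer_, t_vaf = NA_real_, n_vaf = NA_real_,
                p = NA_real_, filter = NA_character_,
                class = NA_character_))
  tRef <- gc(tum, refA); nRef <- gc(nor, refA)
  best <- NULL
  for (al in alts) {
    tAlt <- gc(tum, al); nAlt <- gc(nor, al)
    p <- if (tAlt + tRef > 0 && nAlt + nRef > 0)
      fisherTestSite(tAlt, tRef, nAlt, nRef,
                     alternative = config$alternative) else 1
    if (is.null(best) || p < best$p)
      best <- list(alt = al, tAlt = tAlt, nAlt = nAlt, p = p)
  }
  tAlt <- best$tAlt; nAlt <- best$nAlt
  tDepth <- tAlt + tRef; nDepth <- nAlt + nRef
  tVaf <- if (tDepth > 0) tAlt / tDepth else NA_real_
  nVaf <- if (nDepth > 0) nAlt / nDepth else NA_real_
  filt <- if (tDepth < config$minDepth || nDepth < config$minDepth)
    "depth_fail"
  else if (tAlt < config$minVariantReads) "min_variant_reads_fail"
  else if (tVaf < config$minTumorAf) "tumor_af_fail"
  else if (nVaf > config$maxNormalAf) "normal_af_fail"
  else if (best$p > config$fisherThreshold) "fisher_fail"
  else "PASS"
  list(alt = best$alt, t_alt = tAlt, t_ref = tRef, n_alt = nAlt,
       n_ref = nRef, t_vaf = tVaf, n_vaf = nVaf, p = best$p,
       filter = filt, class = "unknown")
}

#' Attach consequence-class labels from a truth table
#'
#' Joins calls to a truth event table on (chrom, pos, alt); unmatched calls
#' keep class `"unknown"`.
#'
#' @param calls output of [callSample()]
#' @param truth truth event data.frame (chrom, pos, alt, class)
#' @return calls with the `class` column filled in
#' @export
annotateCalls <- function(calls, truth) {
  if (nrow(calls) == 0 || nrow(truth) == 0) return(calls)
  key <- paste(calls$chrom, calls$pos, calls$alt)
  tkey <- paste(truth$chrom, truth$pos, truth$alt)
  i <- match(key, tkey)
  calls$class <- ifelse(is.na(i), "unknown", truth$class[i])
  calls
}

#' Count and summarise mutation consequence classes
#'
#' Tallies PASS calls per consequence class and reports the percentage of
#' the total, rounded half-up to two decimals.
#'
#' @param x either a calls data.frame (rows with `filter == "PASS"` are
#'   tallied by their `class` column) or a named numeric vector of
#'   pre-tallied class counts
#' @return data.frame with columns class, count, pct, sorted by decreasing
#'   count
#' @examples
#' classifyAndCount(c(missense = 494, frameshift_del = 30, nonsense = 25,
#'                    frameshift_ins = 15, splice = 10, inframe_del = 5))
#' @export
classifyAndCount <- function(x) {
  if (is.data.frame(x)) {
    pass <- x[x$filter == "PASS", , drop = FALSE]
    cls <- pass$class
    cls[is.na(cls) | cls == ""] <- "unknown"
    counts <- table(cls)
  } else {
    counts <- x
  }
  total <- sum(counts)
  out <- data.frame(class = names(counts), count = as.numeric(counts),
                    pct = if (total > 0)
                      roundHalfUp(100 * as.numeric(counts) / total, 2)
                    else 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
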