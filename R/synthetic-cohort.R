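#' @import methods
#' @importFrom stats rnbinom rbinom rpois rnorm rbeta runif qnbinom median
#'   mad quantile setNames p.adjust sd var cor pt phyper dhyper
#' @importFrom utils head tail write.table read.table
#' @importFrom data.table data.table as.data.table setorder rbindlist := .N
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps reduce mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom Biostrings DNAStringSet subseq reverseComplement
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

# median-calibrated negative binomial mean: pick mu whose NB median is
# closest to the target burden
nb_mu_for_median <- function(target, size) {
  if (target <= 0) return(0)
  grid <- seq(max(0.5, 0.5 * target), 2 * target + 2, length.out = 400)
  med <- qnbinom(0.5, size = size, mu = grid)
  grid[which.min(abs(med - target) + 1e-9 * abs(grid - target))]
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

random_reference <- function(nChrom, chromLength) {
  seqs <- vapply(seq_len(nChrom), function(i) {
    paste(sample(DNA_BASES, chromLength, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(nChrom))
  DNAStringSet(seqs)
}

random_targets <- function(nChrom, chromLength, perChrom) {
  tabs <- lapply(seq_len(nChrom), function(i) {
    slots <- floor(seq(1000, chromLength - 2000, length.out = perChrom))
    w <- sample(150:400, perChrom, replace = TRUE)
    gap <- if (perChrom > 1) diff(slots)[1] else chromLength
    w <- pmin(w, gap - 100L)
    data.frame(chrom = paste0("chr", i), start = slots, width = w)
  })
  tab <- do.call(rbind, tabs)
  gr <- GRanges(tab$chrom, IRanges(start = tab$start, width = tab$width),
                seqinfo = GenomeInfoDb::Seqinfo(
                  paste0("chr", seq_len(nChrom)),
                  rep(chromLength, nChrom)))
  sort(gr)
}

# plain-character view of the reference for fast vectorised slicing
ref_str <- function(reference) {
  setNames(as.character(reference), names(reference))
}

ref_base_at <- function(refStr, chrom, pos, len = 1L) {
  substring(refStr[chrom], pos, pos + len - 1L)
}

context_at <- function(refStr, chrom, pos) {
  out <- substring(refStr[chrom], pos - 1L, pos + 1L)
  bad <- pos < 2L | pos > nchar(refStr[chrom]) - 1L
  out[bad] <- NA_character_
  unname(out)
}

# consequence class frequencies used for truth labels (nonsynonymous calls)
CLASS_LEVELS <- c("missense", "frameshift_del", "nonsense", "frameshift_ins",
                  "splice", "inframe_del")
CLASS_PROBS <- c(0.8532, 0.0518, 0.0432, 0.0259, 0.0173, 0.0086)

# one truth event: SNV classes get a substitution, indel classes an
# anchored deletion/insertion in minimal left-aligned representation
draw_event <- function(refStr, chrom, pos, cls) {
  if (cls %in% c("frameshift_del", "inframe_del")) {
    delLen <- if (cls == "frameshift_del") sample(c(1L, 2L, 4L), 1) else 3L
    ref <- ref_base_at(refStr, chrom, pos, delLen + 1L)
    alt <- substr(ref, 1, 1)
  } else if (cls == "frameshift_ins") {
    ref <- ref_base_at(refStr, chrom, pos, 1L)
    alt <- paste0(ref, paste(sample(DNA_BASES, sample(1:2, 1),
                                    replace = TRUE), collapse = ""))
  } else {
    ref <- ref_base_at(refStr, chrom, pos, 1L)
    alt <- sample(setdiff(DNA_BASES, ref), 1)
  }
  list(ref = ref, alt = alt)
}

# substitution-error targets: for each reference base, the three others
ERR_MAP <- local({
  m <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b), character(3)))
  rownames(m) <- DNA_BASES
  m
})

# vectorised pileup generator: one aggregated table for many sites.
# siteTab needs chrom, pos, ref, context, alt, pAlt (tumor alt prob).
gen_pileup <- function(siteTab, depthT, depthN, seqError) {
  nS <- nrow(siteTab)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), context = character(),
                      role = character(), allele = character(),
                      baseq = integer(), mapq = integer(),
                      count = integer(), stringsAsFactors = FALSE)
  if (nS == 0) return(empty)
  dT <- rpois(nS, depthT); dN <- rpois(nS, depthN)
  idx <- c(rep.int(seq_len(nS), dT), rep.int(seq_len(nS), dN))
  role <- rep(c("tumor", "normal"), c(sum(dT), sum(dN)))
  nR <- length(idx)
  if (nR == 0) return(empty)
  pAlt <- siteTab$pAlt[idx] * (role == "tumor")
  isAlt <- runif(nR) < pAlt
  allele <- ifelse(isAlt, siteTab$alt[idx], siteTab$ref[idx])
  err <- !isAlt & runif(nR) < seqError
  if (any(err)) {
    refFirst <- substr(siteTab$ref[idx[err]], 1, 1)
    allele[err] <- ERR_MAP[cbind(match(refFirst, DNA_BASES),
                                 sample.int(3L, sum(err), replace = TRUE))]
  }
  dt <- data.table(i = idx, role = role, allele = allele,
                   baseq = as.integer(clamp(round(rnorm(nR, 30, 8)), 2, 41)),
                   mapq = as.integer(clamp(round(rnorm(nR, 50, 12)), 0, 60)))
  agg <- dt[, list(count = .N), by = c("i", "role", "allele", "baseq",
                                       "mapq")]
  agg[, `:=`(chrom = siteTab$chrom[i], pos = siteTab$pos[i],
             ref = siteTab$ref[i], context = siteTab$context[i])]
  out <- as.data.frame(agg[, c("chrom", "pos", "ref", "context", "role",
                               "allele", "baseq", "mapq", "count"),
                           with = FALSE])
  out <- out[order(out$chrom, out$pos, out$role, out$allele, out$baseq,
                   out$mapq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sample_positions_in_targets <- function(tgt, n) {
  w <- width(tgt)
  idx <- sample(length(tgt), n, replace = TRUE, prob = w)
  pos <- as.integer(start(tgt)[idx] + floor(runif(n) * w[idx]))
  data.frame(chrom = as.character(seqnames(tgt))[idx], pos = pos,
             stringsAsFactors = FALSE)
}

local_log2 <- function(segs, chrom, pos) {
  if (is.null(segs) || nrow(segs) == 0) return(0)
  hit <- segs$chrom == chrom & segs$start <= pos & segs$end >= pos
  if (any(hit)) segs$log2[which(hit)[1]] else 0
}

simulate_sample_pileup <- function(refStr, tgt, events, nNull, purity,
                                   depthT, depthN, seqError, truthSegs) {
  evt <- events
  parts <- list()
  if (nrow(evt)) {
    s <- vapply(seq_len(nrow(evt)), function(j)
      local_log2(truthSegs, evt$chrom[j], evt$pos[j]), numeric(1))
    parts$somatic <- data.frame(
      chrom = evt$chrom, pos = evt$pos, ref = evt$ref,
      context = context_at(refStr, evt$chrom, evt$pos),
      alt = evt$alt,
      pAlt = pmin(0.99, purity * evt$cf / (2 * 2^s)),
      stringsAsFactors = FALSE)
  }
  if (nNull > 0) {
    np <- sample_positions_in_targets(tgt, nNull)
    refA <- unname(ref_base_at(refStr, np$chrom, np$pos))
    parts$null <- data.frame(
      chrom = np$chrom, pos = np$pos, ref = refA,
      context = context_at(refStr, np$chrom, np$pos),
      alt = ERR_MAP[cbind(match(refA, DNA_BASES),
                          sample.int(3L, nrow(np), replace = TRUE))],
      pAlt = 0, stringsAsFactors = FALSE)
  }
  siteTab <- do.call(rbind, parts)
  if (is.null(siteTab)) siteTab <- data.frame()
  gen_pileup(siteTab, depthT, depthN, seqError)
}

#' Simulate a grade-labelled paired tumor/normal PJD cohort
#'
#' Generates a synthetic reference sequence, exome-like capture targets,
#' a sample sheet with histologic grades, per-sample somatic truth events
#' whose grade-wise burden medians follow the configured values, paired
#' pileup tables with read-level base/mapping qualities, bin-level
#' tumor/normal depths carrying the configured recurrent copy-number events
#' and noise pathologies, and OxoG artifact contamination in the configured
#' number of samples. Identical configurations (including the seed) produce
#' identical cohorts.
#'
#' @param config a [CohortConfig-class]
#' @return a [PJCohort-class]
#' @examples
#' cfg <- CohortConfig(nSamplesPerGrade = c(LGD = 2L, HGD = 2L, INC = 2L),
#'                     burdenMedianByGrade = c(LGD = 5, HGD = 8, INC = 15),
#'                     nNullSitesPerSample = 10L, targetsPerChrom = 30L,
#'                     nOxogSamples = 0L, nNoisySamples = 0L, seed = 7L)
#' coh <- simulateCohort(cfg)
#' coh
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  methods::validObject(config)
  set.seed(config@seed)

  reference <- random_reference(config@nChrom, config@chromLength)
  refStr <- ref_str(reference)
  tgt <- random_targets(config@nChrom, config@chromLength,
                        config@targetsPerChrom)
  if (length(tgt) == 0) stop("empty target set")

  grades <- rep(c("LGD", "HGD", "INC"), times = config@nSamplesPerGrade)
  n <- length(grades)
  ids <- sprintf("S%02d", seq_len(n))

  # purity: Beta moment-matched to (mean, sd), truncated
  m <- config@purityMean; s2 <- config@puritySd^2
  k <- m * (1 - m) / s2 - 1
  purity <- clamp(rbeta(n, m * k, (1 - m) * k), 0.02, 0.95)

  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(23, 16))
  duct <- sample(c("branch", "main", "mix"), n, replace = TRUE,
                 prob = c(13, 11, 15))
  oxog <- rep(FALSE, n); noisy <- rep(FALSE, n)
  if (config@nOxogSamples > 0)
    oxog[sample(n, min(config@nOxogSamples, n))] <- TRUE
  pool <- which(!oxog)
  if (config@nNoisySamples > 0 && length(pool))
    noisy[sample(pool, min(config@nNoisySamples, length(pool)))] <- TRUE

  ss <- data.frame(sample_id = ids, grade = factor(grades,
                   levels = c("LGD", "HGD", "INC"), ordered = TRUE),
                   sex = sex, duct_type = duct, purity = purity,
                   oxog = oxog, noisy = noisy, stringsAsFactors = FALSE)

  # burdens: NB with median-calibrated mean per grade
  muByGrade <- vapply(config@burdenMedianByGrade, nb_mu_for_median,
                      numeric(1), size = config@burdenDispersion)
  names(muByGrade) <- names(config@burdenMedianByGrade)
  burden <- integer(n)
  for (i in seq_len(n)) {
    mu <- muByGrade[[as.character(ss$grade[i])]]
    burden[i] <- if (mu > 0) rnbinom(1, size = config@burdenDispersion,
                                     mu = mu) else 0L
  }

  # truth copy-number segments per sample
  prof <- config@cnaProfiles
  truthSegs <- lapply(seq_len(n), function(i) {
    if (nrow(prof) == 0) return(prof[, c("chrom", "start", "end", "log2"),
                                     drop = FALSE])
    prev <- switch(as.character(ss$grade[i]), LGD = prof$prevLGD,
                   HGD = prof$prevHGD, INC = prof$prevINC)
    keep <- runif(nrow(prof)) < prev
    out <- prof[keep, c("chrom", "start", "end", "log2"), drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(truthSegs) <- ids

  # truth somatic events
  truth <- vector("list", n); names(truth) <- ids
  for (i in seq_len(n)) {
    nb <- burden[i]
    if (nb == 0) {
      truth[[i]] <- data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               cf = numeric(), class = character(),
                               artifact = logical(),
                               stringsAsFactors = FALSE)
      next
    }
    posTab <- sample_positions_in_targets(tgt, nb)
    posTab <- posTab[!duplicated(paste(posTab$chrom, posTab$pos)), ,
                     drop = FALSE]
    cls <- sample(CLASS_LEVELS, nrow(posTab), replace = TRUE,
                  prob = CLASS_PROBS)
    clonal <- runif(nrow(posTab)) < config@cfClonalProb
    cf <- ifelse(clonal, 1, runif(nrow(posTab), config@cfMin, 1))
    ev <- lapply(seq_len(nrow(posTab)), function(j)
      draw_event(refStr, posTab$chrom[j], posTab$pos[j], cls[j]))
    truth[[i]] <- data.frame(
      chrom = posTab$chrom, pos = posTab$pos,
      ref = vapply(ev, `[[`, character(1), "ref"),
      alt = vapply(ev, `[[`, character(1), "alt"),
      cf = cf, class = cls, artifact = FALSE, stringsAsFactors = FALSE)
    o <- order(truth[[i]]$chrom, truth[[i]]$pos)
    truth[[i]] <- truth[[i]][o, , drop = FALSE]
    rownames(truth[[i]]) <- NULL
  }

  # pileups
  plps <- vector("list", n); names(plps) <- ids
  for (i in seq_len(n)) {
    plps[[i]] <- simulate_sample_pileup(
      refStr, tgt, truth[[i]], config@nNullSitesPerSample, purity[i],
      config@depthTumor, config@depthNormal, config@seqError, truthSegs[[i]])
  }

  # bin depth matrices (on-target bins plus sparse off-target coverage)
  bins <- makeBins(tgt)
  gaps <- GenomicRanges::gaps(reduce(tgt))
  gaps <- gaps[GenomicRanges::strand(gaps) == "*" & width(gaps) > 2000]
  if (length(gaps) && config@offTargetFraction > 0) {
    keep <- runif(length(gaps)) < config@offTargetFraction
    off <- gaps[keep]
    if (length(off)) {
      mcols(off) <- S4Vectors::DataFrame(on_target = FALSE,
                                         short = FALSE)
      bins <- sort(c(bins, off))
    }
  }
  # expected reads per bin at 1x site depth: width / read length (100 bp).
  # Bins aggregate many reads, so Poisson counting noise stays well below
  # the configured binNoiseSd and does not silently inflate bin-level
  # log2-ratio noise beyond its documented scale.
  wScale <- width(bins) / 100
  wScale[!bins$on_target] <- 0.15 * pmin(wScale[!bins$on_target], 6)
  nBins <- length(bins)
  tumorMat <- matrix(0L, nBins, n); normalMat <- matrix(0L, nBins, n)
  binChrom <- as.character(seqnames(bins))
  binMid <- (start(bins) + end(bins)) / 2
  for (i in seq_len(n)) {
    shift <- numeric(nBins)
    segs <- truthSegs[[i]]
    if (nrow(segs)) for (j in seq_len(nrow(segs))) {
      hit <- binChrom == segs$chrom[j] & binMid >= segs$start[j] &
        binMid <= segs$end[j]
      shift[hit] <- shift[hit] + segs$log2[j]
    }
    sdBin <- config@binNoiseSd * if (noisy[i]) config@noisyInflation else 1
    lamN <- config@depthNormal * wScale
    lamT <- config@depthTumor * wScale * 2^(shift + rnorm(nBins, 0, sdBin))
    normalMat[, i] <- rpois(nBins, lamN)
    tumorMat[, i] <- rpois(nBins, lamT)
  }
  colnames(tumorMat) <- colnames(normalMat) <- ids
  se <- SummarizedExperiment(assays = list(tumor = tumorMat,
                                           normal = normalMat),
                             rowRanges = bins)

  coh <- new("PJCohort", sampleSheet = ss, pileups = plps,
             truthEvents = truth, truthSegments = truthSegs,
             targets = tgt, reference = reference, binDepths = se,
             config = config)

  # inject OxoG contamination into the flagged samples
  for (id in ids[oxog]) {
    coh <- injectOxoG(coh, id, nSites = config@oxogNSites,
                      vafMean = config@oxogVafMean)
  }
  coh
}

#' Inject 8-oxoguanine artifact reads into a sample's tumor pileup
#'
#' Artifacts are low-VAF C>A substitutions placed at positions whose
#' pyrimidine-strand reference context is 5'-CC(N)-3' (equivalently G>T where
#' the reference shows NGG). Injected sites are appended to the sample's
#' pileup and flagged `artifact = TRUE` in the truth table. With
#' `nSites = 0` the cohort is returned unchanged.
#'
#' @param cohort a [PJCohort-class]
#' @param sample sample id to contaminate
#' @param nSites number of artifact sites to inject
#' @param vafMean mean of the Beta-distributed artifact allele fraction
#' @param seed optional integer; when given, seeds the injection so that it
#'   is reproducible independently of the surrounding RNG state
#' @return the modified cohort
#' @export
injectOxoG <- function(cohort, sample, nSites, vafMean = 0.05, seed = NULL) {
  stopifnot(is(cohort, "PJCohort"), sample %in% cohort@sampleSheet$sample_id)
  if (nSites == 0) return(cohort)
  if (!is.null(seed)) set.seed(seed)
  cfg <- cohort@config
  refStr <- ref_str(cohort@reference)
  tgt <- cohort@targets

  # candidate positions: middle base of CCN on either strand, inside targets
  cand <- oxog_candidate_sites(refStr, tgt, nSites * 6L)
  if (nrow(cand) < nSites)
    stop("not enough CCN-context sites in targets")
  cand <- cand[sample(nrow(cand), nSites), , drop = FALSE]

  a <- vafMean * 40; b <- (1 - vafMean) * 40
  art <- data.frame(chrom = cand$chrom, pos = cand$pos, ref = cand$ref,
                    alt = ifelse(cand$ref == "C", "A", "T"),
                    cf = NA_real_, class = "unknown", artifact = TRUE,
                    stringsAsFactors = FALSE)
  siteTab <- data.frame(
    chrom = art$chrom, pos = art$pos, ref = art$ref,
    context = context_at(refStr, art$chrom, art$pos),
    alt = art$alt, pAlt = rbeta(nSites, a, b), stringsAsFactors = FALSE)
  add <- gen_pileup(siteTab, cfg@depthTumor, cfg@depthNormal, cfg@seqError)
  plp <- rbind(cohort@pileups[[sample]], add)
  plp <- plp[order(plp$chrom, plp$pos, plp$role, plp$allele, plp$baseq,
                   plp$mapq), , drop = FALSE]
  rownames(plp) <- NULL
  cohort@pileups[[sample]] <- plp

  tr <- rbind(cohort@truthEvents[[sample]], art)
  tr <- tr[order(tr$chrom, tr$pos), , drop = FALSE]
  rownames(tr) <- NULL
  cohort@truthEvents[[sample]] <- tr
  cohort@sampleSheet$oxog[cohort@sampleSheet$sample_id == sample] <- TRUE
  cohort
}

# positions within targets whose reference context is CCN (ref C, 5' C) or
# its reverse complement NGG (ref G, 3' G); returns up to maxN of them
oxog_candidate_sites <- function(refStr, tgt, maxN) {
  out <- list()
  for (i in seq_along(tgt)) {
    chrom <- as.character(seqnames(tgt))[i]
    s <- max(2L, start(tgt)[i]); e <- min(end(tgt)[i],
                                          nchar(refStr[chrom]) - 1L)
    if (e <= s) next
    seqStr <- strsplit(substring(refStr[chrom], s - 1L, e + 1L), "")[[1]]
    # seqStr index j corresponds to genome position s - 2 + j
    mid <- seq(2L, length(seqStr) - 1L)
    isCC <- seqStr[mid] == "C" & seqStr[mid - 1L] == "C"
    isGG <- seqStr[mid] == "G" & seqStr[mid + 1L] == "G"
    hit <- mid[isCC | isGG]
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = s - 2L + hit, ref = seqStr[hit],
        stringsAsFactors = FALSE)
    if (sum(vapply(out, nrow, integer(1))) >= maxN) break
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character()))
  res <- do.call(rbind, out)
  head(res, maxN)
}
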