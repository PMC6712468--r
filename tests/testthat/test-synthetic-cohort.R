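library(GenomicRanges)

coh <- simulateCohort(small_cfg(seed = 101L))

test_that("the cohort matches its configuration", {
  ss <- sampleSheet(coh)
  expect_equal(nrow(ss), 6L)
  expect_equal(as.vector(table(ss$grade)), c(2L, 2L, 2L))
  expect_true(is.ordered(ss$grade))
  expect_equal(levels(ss$grade), c("LGD", "HGD", "INC"))
  expect_equal(sum(ss$oxog), 1L)
  expect_equal(sum(ss$noisy), 1L)
  expect_true(all(ss$purity >= 0.02 & ss$purity <= 0.95))
  # noisy and contaminated flags never coincide
  expect_false(any(ss$oxog & ss$noisy))
})

test_that("simulation is deterministic in the seed", {
  coh2 <- simulateCohort(small_cfg(seed = 101L))
  expect_identical(pileups(coh), pileups(coh2))
  expect_identical(truthEvents(coh), truthEvents(coh2))
  expect_identical(sampleSheet(coh), sampleSheet(coh2))
  coh3 <- simulateCohort(small_cfg(seed = 102L))
  expect_false(identical(pileups(coh), pileups(coh3)))
})

test_that("truth events lie within targets with consistent alleles", {
  tgt <- targets(coh)
  refStr <- setNames(as.character(reference(coh)),
                     names(reference(coh)))
  for (id in sampleSheet(coh)$sample_id) {
    tr <- truthEvents(coh, id)
    if (nrow(tr) == 0) next
    gr <- GRanges(tr$chrom, IRanges(tr$pos, tr$pos))
    expect_true(all(countOverlaps(gr, tgt) > 0))
    expect_true(all(tr$cf[!tr$artifact] > 0 & tr$cf[!tr$artifact] <= 1))
    # the stored ref allele matches the reference sequence
    obs <- substring(refStr[tr$chrom], tr$pos,
                     tr$pos + nchar(tr$ref) - 1L)
    expect_equal(unname(obs), tr$ref)
  }
})

test_that("pileups are aggregated, sorted read observations", {
  for (id in sampleSheet(coh)$sample_id) {
    p <- pileups(coh, id)
    expect_true(all(p$count >= 1))
    expect_true(all(p$role %in% c("tumor", "normal")))
    expect_true(all(p$baseq >= 2 & p$baseq <= 41))
    expect_true(all(p$mapq >= 0 & p$mapq <= 60))
    expect_false(is.unsorted(order(p$chrom, p$pos)[order(p$chrom, p$pos)]))
    o <- order(p$chrom, p$pos)
    expect_identical(paste(p$chrom, p$pos),
                     paste(p$chrom[o], p$pos[o]))
    # SNV contexts carry the ref as their middle base
    snv <- nchar(p$ref) == 1 & !is.na(p$context)
    expect_equal(substr(p$context[snv], 2, 2), p$ref[snv])
  }
})

test_that("grade-wise burden medians track the configured targets", {
  cfg <- CohortConfig(nSamplesPerGrade = c(LGD = 40L, HGD = 40L,
                                           INC = 40L),
                      burdenMedianByGrade = c(LGD = 8, HGD = 16, INC = 48),
                      nNullSitesPerSample = 0L, targetsPerChrom = 40L,
                      nOxogSamples = 0L, nNoisySamples = 0L, seed = 55L)
  big <- simulateCohort(cfg)
  ss <- sampleSheet(big)
  burdens <- vapply(ss$sample_id, function(id)
    nrow(truthEvents(big, id)), numeric(1))
  med <- tapply(burdens, ss$grade, median)
  expect_lt(abs(med[["LGD"]] - 8) / 8, 0.5)
  expect_lt(abs(med[["HGD"]] - 16) / 16, 0.5)
  expect_lt(abs(med[["INC"]] - 48) / 48, 0.5)
  # and the ordering is preserved
  expect_lt(med[["LGD"]], med[["HGD"]])
  expect_lt(med[["HGD"]], med[["INC"]])
})

test_that("bin depths reflect the truth copy-number segments", {
  se <- binDepths(coh)
  bins <- SummarizedExperiment::rowRanges(se)
  expect_equal(colnames(SummarizedExperiment::assay(se, "tumor")),
               sampleSheet(coh)$sample_id)
  expect_true(all(c("on_target", "short") %in%
                    names(S4Vectors::mcols(bins))))
  # pick a sample with a truth amplification and compare mean ratios
  found <- FALSE
  for (id in sampleSheet(coh)$sample_id) {
    segs <- truthSegments(coh, id)
    amp <- segs[segs$log2 > 0, , drop = FALSE]
    if (nrow(amp) == 0) next
    tum <- SummarizedExperiment::assay(se, "tumor")[, id]
    nor <- SummarizedExperiment::assay(se, "normal")[, id]
    lr <- computeCopyRatios(tum, nor)
    mid <- (start(bins) + end(bins)) / 2
    inAmp <- as.character(seqnames(bins)) == amp$chrom[1] &
      mid >= amp$start[1] & mid <= amp$end[1] & bins$on_target
    outside <- !inAmp & bins$on_target
    expect_gt(mean(lr[inAmp], na.rm = TRUE),
              mean(lr[outside], na.rm = TRUE) + 0.4)
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("injectOxoG appends flagged CC(N)-context artifacts", {
  ss <- sampleSheet(coh)
  flagged <- ss$sample_id[ss$oxog][1]
  tr <- truthEvents(coh, flagged)
  art <- tr[tr$artifact, , drop = FALSE]
  expect_equal(nrow(art), 150L)
  expect_true(all((art$ref == "C" & art$alt == "A") |
                    (art$ref == "G" & art$alt == "T")))
  refStr <- setNames(as.character(reference(coh)),
                     names(reference(coh)))
  ctx <- substring(refStr[art$chrom], art$pos - 1L, art$pos + 1L)
  fwd <- art$ref == "C"
  expect_true(all(substr(ctx[fwd], 1, 1) == "C"))
  expect_true(all(substr(ctx[!fwd], 3, 3) == "G"))
  expect_true(all(is.na(art$cf)))
  # artifact reads push the flagged sample's C>A content far up
  calls <- callSample(pileups(coh, flagged))
  expect_gt(oxidationScore(calls), 0.3)
})

test_that("injectOxoG with zero sites is the identity", {
  out <- injectOxoG(coh, "S01", nSites = 0L)
  expect_identical(pileups(out), pileups(coh))
  expect_identical(truthEvents(out), truthEvents(coh))
})

test_that("accessors expose the slots coherently", {
  expect_s4_class(cohortConfig(coh), "CohortConfig")
  expect_s4_class(targets(coh), "GRanges")
  expect_error(pileups(coh, "nope"), "unknown sample")
  expect_output(show(coh), "PJCohort with 6 samples")
  expect_output(show(cohortConfig(coh)), "CohortConfig")
})

test_that("configuration validity is enforced", {
  expect_error(CohortConfig(nSamplesPerGrade = c(a = 1L, b = 2L, c = 3L)),
               "nSamplesPerGrade")
  expect_error(CohortConfig(purityMean = 1.2), "purityMean")
  expect_error(CohortConfig(depthTumor = 0), "depths")
})
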