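test_that("filterReads matches a brute-force per-read recount", {
  set.seed(41)
  n <- 200
  site <- data.frame(
    chrom = "chr1", pos = 10L, ref = "A", context = "CAG",
    role = sample(c("tumor", "normal"), n, replace = TRUE),
    allele = sample(c("A", "T", "G"), n, replace = TRUE,
                    prob = c(0.8, 0.15, 0.05)),
    baseq = sample(0:41, n, replace = TRUE),
    mapq = sample(0:60, n, replace = TRUE),
    count = sample(1:3, n, replace = TRUE), stringsAsFactors = FALSE)
  cfg <- callerConfig()
  got <- filterReads(site, cfg)
  keep <- site$mapq >= 20 & site$baseq >= 15
  for (role in c("tumor", "normal")) {
    sub <- site[keep & site$role == role, ]
    want <- tapply(sub$count, sub$allele, sum)
    expect_equal(got[[role]][sort(names(want))],
                 setNames(as.integer(want[sort(names(want))]),
                          sort(names(want))))
  }
})

test_that("filterReads drops everything below the quality thresholds", {
  site <- make_site(tAlt = 5L, tRef = 20L, nRef = 25L, mapq = 19L)
  out <- filterReads(site)
  expect_length(out$tumor, 0)
  expect_length(out$normal, 0)
  empty <- make_site()
  expect_null(empty)
})

test_that("fisherTestSite handles the boundary and enrichment cases", {
  expect_equal(fisherTestSite(0, 100, 0, 100), 1)
  # enrichment p equals the direct hypergeometric enumeration
  expect_equal(fisherTestSite(20, 80, 0, 100),
               enum_fisher_2x2(20, 80, 0, 100), tolerance = 1e-14)
  expect_gt(fisherTestSite(5, 95, 5, 95), 0.5)
  expect_error(fisherTestSite(-1, 10, 0, 10), "negative")
  expect_error(fisherTestSite(0, 0, 5, 5), "zero depth")
})

test_that("fisherTestSite agrees with stats::fisher.test", {
  set.seed(7)
  for (i in 1:40) {
    a <- sample(0:15, 1); b <- sample(1:30, 1)
    c_ <- sample(0:15, 1); d <- sample(1:30, 1)
    tab <- matrix(c(a, c_, b, d), 2)
    expect_equal(fisherTestSite(a, b, c_, d, "greater"),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(fisherTestSite(a, b, c_, d, "two.sided"),
                 fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("one-sided p is monotone decreasing in tumor alt reads", {
  depth <- 60
  p <- fisherTestSite(0:depth, depth:0, 3, 57)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("callSample applies the filters in the documented order", {
  cfg <- callerConfig()
  # tumor depth 7 -> depth_fail even though everything else would fail too
  p1 <- make_pileup(make_site(tAlt = 1L, tRef = 6L, nAlt = 0L, nRef = 50L))
  expect_equal(callSample(p1, cfg)$filter, "depth_fail")
  # 2 alt reads of 100 -> min_variant_reads_fail
  p2 <- make_pileup(make_site(tAlt = 2L, tRef = 98L, nAlt = 0L,
                              nRef = 100L))
  expect_equal(callSample(p2, cfg)$filter, "min_variant_reads_fail")
  # 4 alt of 100 (VAF 0.04) -> tumor_af_fail
  p3 <- make_pileup(make_site(tAlt = 4L, tRef = 96L, nAlt = 0L,
                              nRef = 100L))
  expect_equal(callSample(p3, cfg)$filter, "tumor_af_fail")
  # normal VAF 0.2 -> normal_af_fail
  p4 <- make_pileup(make_site(tAlt = 30L, tRef = 70L, nAlt = 20L,
                              nRef = 80L))
  expect_equal(callSample(p4, cfg)$filter, "normal_af_fail")
  # weak enrichment -> fisher_fail
  p5 <- make_pileup(make_site(tAlt = 8L, tRef = 92L, nAlt = 8L,
                              nRef = 92L))
  expect_equal(callSample(p5, cfg)$filter, "fisher_fail")
  # clean somatic site -> PASS with consistent counts and VAFs
  p6 <- make_pileup(make_site(tAlt = 30L, tRef = 70L, nAlt = 0L,
                              nRef = 100L))
  call <- callSample(p6, cfg)
  expect_equal(call$filter, "PASS")
  expect_equal(call$t_vaf, 0.3)
  expect_equal(call$n_vaf, 0)
  expect_true(call$p <= 0.05)
})

test_that("PASS implies every configured threshold is met", {
  set.seed(11)
  sites <- lapply(1:150, function(i)
    make_site(pos = 100L + 7L * i,
              tAlt = sample(0:30, 1), tRef = sample(0:90, 1),
              nAlt = sample(0:10, 1), nRef = sample(0:90, 1)))
  p <- do.call(make_pileup, sites[!vapply(sites, is.null, logical(1))])
  cfg <- callerConfig()
  calls <- callSample(p, cfg)
  pass <- calls[calls$filter == "PASS", ]
  if (nrow(pass)) {
    expect_true(all(pass$t_alt + pass$t_ref >= cfg$minDepth))
    expect_true(all(pass$n_alt + pass$n_ref >= cfg$minDepth))
    expect_true(all(pass$t_alt >= cfg$minVariantReads))
    expect_true(all(pass$t_vaf >= cfg$minTumorAf))
    expect_true(all(pass$n_vaf <= cfg$maxNormalAf))
    expect_true(all(pass$p <= cfg$fisherThreshold))
  }
  # determinism: calling is a pure function of its inputs
  expect_identical(calls, callSample(p, cfg))
})

test_that("callSample rejects unsorted pileups", {
  p <- rbind(make_site(pos = 200L, tAlt = 10L, tRef = 40L, nRef = 50L),
             make_site(pos = 100L, tAlt = 10L, tRef = 40L, nRef = 50L))
  expect_error(callSample(p), "sorted")
})

test_that("multi-allelic sites report the best alt only", {
  site <- rbind(
    make_site(tAlt = 25L, tRef = 60L, nAlt = 0L, nRef = 100L, alt = "T"),
    data.frame(chrom = "chr1", pos = 100L, ref = "A", context = "CAG",
               role = "tumor", allele = "G", baseq = 30L, mapq = 60L,
               count = 4L, stringsAsFactors = FALSE))
  p <- make_pileup(site)
  call <- callSample(p)
  expect_equal(nrow(call), 1L)
  expect_equal(call$alt, "T")
  # VAF denominator excludes the dropped third allele
  expect_equal(call$t_vaf, 25 / 85)
})

test_that("caller recovers high-VAF truth events with high sensitivity", {
  set.seed(23)
  depth <- 200L
  truthPos <- 1000L + 10L * (1:100)
  sites <- lapply(seq_along(truthPos), function(i) {
    vaf <- runif(1, 0.1, 0.5)
    ta <- rbinom(1, depth, vaf)
    make_site(pos = truthPos[i], tAlt = ta, tRef = depth - ta,
              nAlt = 0L, nRef = depth)
  })
  p <- do.call(make_pileup, sites)
  calls <- callSample(p)
  sens <- mean(truthPos %in% calls$pos[calls$filter == "PASS"])
  expect_gte(sens, 0.95)
})

test_that("annotateCalls joins class labels on chrom/pos/alt", {
  calls <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                      alt = c("T", "G"), filter = "PASS",
                      class = "unknown", stringsAsFactors = FALSE)
  truth <- data.frame(chrom = "chr1", pos = 10L, alt = "T",
                      class = "missense", stringsAsFactors = FALSE)
  out <- annotateCalls(calls, truth)
  expect_equal(out$class, c("missense", "unknown"))
})

test_that("classifyAndCount reports counts and rounded percentages", {
  out <- classifyAndCount(c(missense = 494, frameshift_del = 30,
                            nonsense = 25, frameshift_ins = 15,
                            splice = 10, inframe_del = 5))
  expect_equal(sum(out$count), 579)
  expect_equal(out$pct[out$class == "missense"], 85.32)
  expect_equal(out$pct[out$class == "frameshift_del"], 5.18)
  one <- classifyAndCount(data.frame(filter = "PASS", class = "nonsense",
                                     stringsAsFactors = FALSE))
  expect_equal(one$pct, 100)
})
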