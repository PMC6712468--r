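# shared builders and independent oracle implementations used across the
# test files; the oracles deliberately avoid the package's own code paths

# aggregated pileup rows for a single site (one row per distinct read group)
make_site <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                      context = paste0("C", ref, "G"),
                      tAlt = 0L, tRef = 0L, nAlt = 0L, nRef = 0L,
                      baseq = 30L, mapq = 60L) {
  rows <- list()
  add <- function(role, allele, count) {
    if (count > 0)
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, pos = pos, ref = ref, context = context,
        role = role, allele = allele, baseq = baseq, mapq = mapq,
        count = as.integer(count), stringsAsFactors = FALSE)
  }
  add("tumor", alt, tAlt); add("tumor", ref, tRef)
  add("normal", alt, nAlt); add("normal", ref, nRef)
  do.call(rbind, rows)
}

# stack several sites into a sorted pileup
make_pileup <- function(...) {
  p <- do.call(rbind, list(...))
  p <- p[order(p$chrom, p$pos), , drop = FALSE]
  rownames(p) <- NULL
  p
}

# direct 2x2 Fisher enumeration over all tables with the observed margins
enum_fisher_2x2 <- function(a, b, c_, d, alternative = "greater") {
  m <- a + c_; nn <- b + d; kk <- a + b
  ks <- max(0, kk - nn):min(kk, m)
  pr <- dhyper(ks, m, nn, kk)
  if (alternative == "greater") sum(pr[ks >= a])
  else sum(pr[pr <= dhyper(a, m, nn, kk) * (1 + 1e-7)])
}

# naive per-marker G-score by explicit double loop
naive_gscore <- function(X, direction, threshold = 0.2, cap = 2) {
  G <- numeric(ncol(X))
  for (m in seq_len(ncol(X))) {
    for (s in seq_len(nrow(X))) {
      x <- X[s, m]
      if (is.na(x)) x <- 0
      x <- max(-cap, min(cap, x))
      G[m] <- G[m] + if (direction == "amp") max(0, x - threshold)
                     else max(0, -threshold - x)
    }
  }
  G
}

# independent 96-bin spectrum recount (PASS SNVs only)
naive_spectrum <- function(calls) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  bins <- character(0)
  skipped <- 0L
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  for (i in seq_len(nrow(pass))) {
    ref <- pass$ref[i]; alt <- pass$alt[i]; ctx <- pass$context[i]
    if (is.na(ctx) || nchar(ref) != 1 || nchar(alt) != 1 ||
        nchar(ctx) != 3 || !ref %in% names(comp) || !alt %in% names(comp)) {
      skipped <- skipped + 1L
      next
    }
    if (ref %in% c("A", "G")) {
      ref <- unname(comp[ref]); alt <- unname(comp[alt]); ctx <- rc(ctx)
    }
    bins <- c(bins, paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                           substr(ctx, 3, 3)))
  }
  list(bins = table(bins), skipped = skipped)
}

# a calls data.frame of PASS SNVs with consistent ref/context
random_calls <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ctx <- paste0(sample(bases, n, replace = TRUE), ref,
                sample(bases, n, replace = TRUE))
  data.frame(chrom = "chr1", pos = seq_len(n), ref = ref, alt = alt,
             context = ctx, t_vaf = runif(n, 0.1, 0.6),
             filter = "PASS", class = "unknown", stringsAsFactors = FALSE)
}

# a small, fast cohort configuration for structural tests
small_cfg <- function(seed = 1L, ...) {
  CohortConfig(nSamplesPerGrade = c(LGD = 2L, HGD = 2L, INC = 2L),
               burdenMedianByGrade = c(LGD = 5, HGD = 8, INC = 14),
               nNullSitesPerSample = 25L, targetsPerChrom = 25L,
               nOxogSamples = 1L, nNoisySamples = 1L, seed = seed, ...)
}

# pileup of clonal heterozygous diploid events for tumor-fraction recovery:
# tumor alt reads ~ Binomial(depth, purity / 2), normal pure reference
sim_tf_pileup <- function(purity, nEvents, depth) {
  sites <- lapply(seq_len(nEvents), function(i) {
    ta <- rbinom(1, depth, purity / 2)
    make_site(pos = 1000L + 10L * i, ref = "A", alt = "T",
              tAlt = ta, tRef = depth - ta, nAlt = 0L, nRef = depth)
  })
  do.call(make_pileup, sites)
}
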