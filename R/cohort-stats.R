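#' Estimate the tumor-derived DNA fraction of a juice sample
#'
#' Twice the median variant allele frequency of the sample's PASS somatic
#' calls, clipped to \[0, 1\]. Samples with 10 or fewer PASS SNV/indel
#' calls return `NA` (too few events for a stable median).
#'
#' @param calls a calls data.frame ([callSample()] output)
#' @param minCalls minimum PASS call count (exclusive) required
#' @return estimated tumor fraction, or `NA`
#' @export
estimateTumorFraction <- function(calls, minCalls = 10L) {
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  if (nrow(pass) <= minCalls) return(NA_real_)
  min(1, max(0, 2 * median(pass$t_vaf)))
}

#' Spearman correlation between histologic grade and mutation burden
#'
#' Rank correlation on (grade ordinal, PASS mutation count) using mid-ranks
#' for ties. The p-value uses the t approximation for n >= 10 and exact
#' enumeration of all burden permutations for n < 10 (two-sided).
#'
#' @param grade ordered grades (factor LGD<HGD<INC, or their 1/2/3 codes)
#' @param burden per-sample PASS mutation counts
#' @return list with `rho` and `p`; `rho` is `NA` when either vector is
#'   constant
#' @export
spearmanBurdenGrade <- function(grade, burden) {
  g <- if (is.factor(grade)) as.integer(grade) else as.numeric(grade)
  stopifnot(length(g) == length(burden))
  n <- length(g)
  if (n < 3) stop("need at least 3 samples")
  if (length(unique(g)) < 2 || length(unique(burden)) < 2)
    return(list(rho = NA_real_, p = NA_real_))
  rg <- rank(g); rb <- rank(burden)
  rho <- cor(rg, rb)
  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  } else {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(ix) cor(rg, rb[ix]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(1, p))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Exact test for a 2xK contingency table
#'
#' Freeman-Halton extension of Fisher's exact test: conditioning on both
#' margins, the p-value is the total probability (multivariate
#' hypergeometric) of tables whose probability does not exceed the observed
#' table's. Full enumeration is used when the enumeration size is
#' tractable; otherwise a seeded Monte-Carlo estimate over tables drawn
#' from the conditional null (Patefield algorithm) is returned together
#' with its standard error.
#'
#' @param tab 2 x K matrix of non-negative counts (rows: altered / not
#'   altered; columns: categories)
#' @param maxEnum enumeration size bound before switching to Monte Carlo
#' @param nDraws Monte-Carlo sample size
#' @param seed integer seed for the Monte-Carlo fallback
#' @return list: `p`, `method` ("enumeration" or "monte-carlo"), `se`
#'   (0 for enumeration)
#' @examples
#' fisherExact2xK(matrix(c(1, 6, 1, 16, 7, 4), nrow = 2))  # p ~ 0.002
#' @export
fisherExact2xK <- function(tab, maxEnum = 1e7, nDraws = 1e6, seed = 1L) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2, ncol(tab) >= 2, all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero table")
  colTot <- colSums(tab)
  r1 <- sum(tab[1, ]); N <- sum(tab)
  logp_table <- function(a) {
    # log conditional probability of row-1 counts a given margins
    sum(lchoose(colTot, a)) - lchoose(N, r1)
  }
  obsLog <- logp_table(tab[1, ])
  enumSize <- prod(pmin(colTot, r1) + 1)
  if (enumSize <= maxEnum) {
    p <- enum_2xk(colTot, r1, obsLog)
    list(p = min(1, p), method = "enumeration", se = 0)
  } else {
    set.seed(seed)
    draws <- stats::r2dtable(nDraws, c(r1, N - r1), colTot)
    lp <- vapply(draws, function(m) logp_table(m[1, ]), numeric(1))
    hits <- lp <= obsLog + 1e-7
    p <- mean(hits)
    list(p = p, method = "monte-carlo",
         se = sqrt(p * (1 - p) / nDraws))
  }
}

# recursive enumeration over row-1 allocations with fixed margins,
# accumulating probability of tables no more probable than observed
enum_2xk <- function(colTot, r1, obsLog, tol = 1e-7) {
  K <- length(colTot)
  total <- 0
  lchooseN <- lchoose(sum(colTot), r1)
  rec <- function(k, remaining, logAcc) {
    if (k == K) {
      if (remaining <= colTot[K]) {
        lp <- logAcc + lchoose(colTot[K], remaining) - lchooseN
        if (lp <= obsLog + tol) total <<- total + exp(lp)
      }
      return(invisible(NULL))
    }
    restMax <- sum(colTot[(k + 1):K])
    lo <- max(0, remaining - restMax)
    hi <- min(colTot[k], remaining)
    if (hi < lo) return(invisible(NULL))
    for (a in lo:hi)
      rec(k + 1, remaining - a, logAcc + lchoose(colTot[k], a))
  }
  rec(1, r1, 0)
  total
}

#' Region-by-grade association tables
#'
#' For each recurrent region, builds the 2xK (altered / not altered by
#' grade) contingency table, reports per-grade alteration fractions
#' (percent, rounded half-up to 2 decimals) and the exact p-value.
#' A region altered in no sample gets fractions 0 and p = 1.
#'
#' @param altered logical matrix (regions x samples) or a single named
#'   logical vector of per-sample flags
#' @param grade grade vector parallel to the samples (factor or character)
#' @return data.frame with one row per region: per-grade pct columns, p
#'   (sorted by p)
#' @export
regionGradeAssociation <- function(altered, grade) {
  if (is.vector(altered)) altered <- matrix(altered, nrow = 1,
                                            dimnames = list("region1",
                                                            names(altered)))
  grade <- factor(as.character(grade), levels = c("LGD", "HGD", "INC"))
  out <- lapply(seq_len(nrow(altered)), function(r) {
    fl <- altered[r, ]
    tab <- rbind(altered = tapply(fl, grade, sum, default = 0),
                 not = tapply(!fl, grade, sum, default = 0))
    tot <- colSums(tab)
    pct <- ifelse(tot > 0, roundHalfUp(100 * tab[1, ] / pmax(tot, 1), 2), 0)
    p <- if (sum(tab[1, ]) == 0) 1 else fisherExact2xK(tab)$p
    data.frame(region = rownames(altered)[r],
               pct_LGD = pct[["LGD"]], pct_HGD = pct[["HGD"]],
               pct_INC = pct[["INC"]],
               n_altered = sum(tab[1, ]), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-occurrence of two alteration flags, stratified by grade
#'
#' @param flagA,flagB logical vectors over the same samples
#' @param grade grade vector parallel to the flags
#' @return list: `table` (counts of both, A_only, B_only, neither) and
#'   `by_grade` (the same counts per grade)
#' @export
cooccurrence <- function(flagA, flagB, grade) {
  stopifnot(length(flagA) == length(flagB),
            length(flagA) == length(grade))
  cat4 <- function(a, b) c(both = sum(a & b), A_only = sum(a & !b),
                           B_only = sum(!a & b), neither = sum(!a & !b))
  grade <- factor(as.character(grade), levels = c("LGD", "HGD", "INC"))
  byg <- t(vapply(levels(grade), function(g) {
    i <- grade == g
    cat4(flagA[i], flagB[i])
  }, numeric(4)))
  list(table = cat4(flagA, flagB), by_grade = byg)
}
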