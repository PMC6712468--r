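PYR_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

spectrum_bin_names <- function() {
  ctx <- as.vector(outer(DNA_BASES, DNA_BASES,
                         function(a, b) paste0(a, "_", b)))
  as.vector(vapply(PYR_SUBS, function(s)
    paste0(substr(ctx, 1, 1), "[", s, "]", substr(ctx, 3, 3)),
    character(16)))
}

# collapse a call (ref, alt, 3-mer context) onto the pyrimidine strand;
# returns the 96-bin name or NA for non-SNVs
pyr_bin <- function(ref, alt, context) {
  if (is.na(context) || nchar(ref) != 1 || nchar(alt) != 1 ||
      nchar(context) != 3 || !(ref %in% DNA_BASES) ||
      !(alt %in% DNA_BASES))
    return(NA_character_)
  if (ref %in% c("A", "G")) {
    ref <- unname(comp_base(ref)); alt <- unname(comp_base(alt))
    context <- revcomp_str(context)
  }
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
         substr(context, 3, 3))
}

#' Build the 96-bin trinucleotide mutation spectrum of a call set
#'
#' Each PASS SNV is counted in exactly one of the 96 pyrimidine-strand
#' substitution bins (6 substitution types x 16 flanking contexts); G>T and
#' other purine-reference events are reverse-complemented onto the
#' pyrimidine strand. Indels and calls without context are skipped; the
#' number of skipped events is attached as attribute `skipped`.
#'
#' @param calls a calls data.frame ([callSample()] output); only rows with
#'   `filter == "PASS"` are counted
#' @return named numeric vector of length 96 with attribute `skipped`
#' @export
buildSpectrum <- function(calls) {
  bins <- spectrum_bin_names()
  spec <- setNames(numeric(96), bins)
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  skipped <- 0L
  for (i in seq_len(nrow(pass))) {
    b <- pyr_bin(pass$ref[i], pass$alt[i], pass$context[i])
    if (is.na(b)) skipped <- skipped + 1L else spec[b] <- spec[b] + 1
  }
  attr(spec, "skipped") <- skipped
  spec
}

is_cca_event <- function(ref, alt, context) {
  snv <- nchar(ref) == 1 & nchar(alt) == 1 & !is.na(context) &
    nchar(context) == 3
  fwd <- snv & ref == "C" & alt == "A" & substr(context, 1, 1) == "C"
  rev <- snv & ref == "G" & alt == "T" & substr(context, 3, 3) == "G"
  fwd | rev
}

#' Oxidation score of a call set
#'
#' Fraction of PASS SNVs that are C>A (or G>T on the opposite strand) with
#' pyrimidine-strand context 5'-CC(N)-3', the configuration characteristic
#' of 8-oxoguanine artifacts. Returns 0 for an empty call set.
#'
#' @param calls a calls data.frame; only `filter == "PASS"` rows are used
#' @return fraction in \[0, 1\]
#' @export
oxidationScore <- function(calls) {
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  if (nrow(pass) == 0) return(0)
  mean(is_cca_event(pass$ref, pass$alt, pass$context))
}

#' Spectrum signature score for OxoG contamination
#'
#' Fraction of total 96-bin spectrum mass falling in the four C>A bins with
#' 5' flanking base C (`C[C>A]A/C/G/T`).
#'
#' @param spectrum output of [buildSpectrum()]
#' @return fraction in \[0, 1\] (0 for an empty spectrum)
#' @export
spectrumSignatureScore <- function(spectrum) {
  tot <- sum(spectrum)
  if (tot == 0) return(0)
  oxo <- grep("^C\\[C>A\\]", names(spectrum), value = TRUE)
  sum(spectrum[oxo]) / tot
}

#' Per-sample OxoG evidence scores
#'
#' Computes the three evidences used for artifact sample exclusion: the
#' median VAF of PASS SNVs (contaminated samples skew low), the oxidation
#' score, and the spectrum signature score.
#'
#' @param calls a calls data.frame for one sample
#' @return one-row data.frame: median_vaf, oxidation_score, spectrum_score,
#'   n_pass
#' @export
oxogEvidence <- function(calls) {
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  snv <- pass[nchar(pass$ref) == 1 & nchar(pass$alt) == 1, , drop = FALSE]
  data.frame(
    median_vaf = if (nrow(snv)) median(snv$t_vaf) else NA_real_,
    oxidation_score = oxidationScore(calls),
    spectrum_score = spectrumSignatureScore(buildSpectrum(calls)),
    n_pass = nrow(pass))
}

#' Flag OxoG-contaminated samples in a cohort
#'
#' Cohort-relative outlier detection on the three evidences: a sample is
#' flagged on evidence (a) when its median VAF falls below the cohort median
#' minus `k` MADs, on (b)/(c) when its oxidation or spectrum score exceeds
#' the cohort median plus `k` MADs. The exclusion flag is set when at least
#' `rule` of the three evidences fire. With all-identical cohorts no sample
#' is flagged.
#'
#' The two fraction-score evidences are binomial fractions over a sample's
#' (often small) call count, so the cohort MAD can collapse well below
#' their sampling noise; their outlier thresholds therefore use
#' `max(MAD, minSpread, binomial SE)`, where the binomial standard error
#' `sqrt(m * (1 - m) / n_pass)` is evaluated per sample at the cohort
#' median `m`. A sample with few PASS calls thus needs a proportionally
#' larger excess before its fraction scores can fire, and a sample with
#' no PASS calls carries no fraction evidence at all.
#'
#' @param evidence data.frame with one row per sample (rbind of
#'   [oxogEvidence()] rows) and a `sample_id` column
#' @param k MAD multiplier for the outlier threshold
#' @param rule number of evidences required for exclusion (2 by default;
#'   3 reproduces an all-three-evidences rule)
#' @param minSpread spread floor (fraction units) for the oxidation and
#'   spectrum score thresholds
#' @return the evidence data.frame with logical columns flag_vaf, flag_oxo,
#'   flag_spectrum and exclude
#' @export
flagOxoGSamples <- function(evidence, k = 3, rule = 2, minSpread = 0.05) {
  stopifnot(nrow(evidence) >= 3, "sample_id" %in% names(evidence))
  lowOut <- function(x) {
    m <- median(x, na.rm = TRUE); s <- mad(x, na.rm = TRUE)
    !is.na(x) & x < m - k * s & x < m
  }
  nPass <- if ("n_pass" %in% names(evidence)) evidence$n_pass else Inf
  highOut <- function(x) {
    m <- median(x, na.rm = TRUE)
    binomSe <- ifelse(nPass > 0, sqrt(m * (1 - m) / nPass), Inf)
    s <- pmax(mad(x, na.rm = TRUE), minSpread, binomSe)
    !is.na(x) & x > m + k * s & x > m
  }
  evidence$flag_vaf <- lowOut(evidence$median_vaf)
  evidence$flag_oxo <- highOut(evidence$oxidation_score)
  evidence$flag_spectrum <- highOut(evidence$spectrum_score)
  evidence$exclude <- (evidence$flag_vaf + evidence$flag_oxo +
                         evidence$flag_spectrum) >= rule
  evidence
}
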