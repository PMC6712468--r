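#' Run the full PJD analysis pipeline on a cohort
#'
#' Calls somatic variants per sample, applies the three-evidence OxoG
#' sample QC (flagged samples are excluded from SNV-derived statistics but
#' retained for copy-number analysis), estimates tumor fractions, segments
#' copy ratios with CBS and applies the residual-variance QC (flagged
#' samples are excluded from copy-number statistics only), runs the
#' recurrence analysis on the retained samples, and computes the
#' grade-association statistics.
#'
#' @param cohort a [PJCohort-class]
#' @param caller a [callerConfig()]
#' @param seed integer seed driving all permutation streams
#' @param nPermCbs,nPermRecurrence permutation counts
#' @param qcRule OxoG evidence combination rule (2-of-3 default)
#' @return list with components calls, oxogQC, cnaQC, seg, regions,
#'   markerInfo, burden, tumorFraction, regionFlags, stats
#' @export
runPipeline <- function(cohort, caller = callerConfig(), seed = 1L,
                        nPermCbs = 200L, nPermRecurrence = 500L,
                        qcRule = 2) {
  ss <- sampleSheet(cohort)
  ids <- ss$sample_id

  calls <- lapply(ids, function(id)
    annotateCalls(callSample(pileups(cohort, id), caller),
                  truthEvents(cohort, id)))
  names(calls) <- ids

  evid <- do.call(rbind, lapply(ids, function(id)
    cbind(sample_id = id, oxogEvidence(calls[[id]]),
          stringsAsFactors = FALSE)))
  oxogQC <- flagOxoGSamples(evid, rule = qcRule)
  snvKeep <- ids[!oxogQC$exclude]

  burden <- vapply(calls, function(x) sum(x$filter == "PASS"), numeric(1))
  tf <- vapply(calls, estimateTumorFraction, numeric(1))

  cna <- segmentCohort(cohort, nPerm = nPermCbs, seed = seed)
  cnaKeep <- cna$qc$sample_id[!cna$qc$exclude]

  segKeep <- cna$seg[cna$seg$sample %in% cnaKeep, , drop = FALSE]
  onBins <- rowRanges(binDepths(cohort))
  onBins <- onBins[onBins$on_target]
  mm <- markerMatrix(segKeep, onBins, samples = cnaKeep)
  regions <- recurrentRegions(mm, nPerm = nPermRecurrence, seed = seed)

  gradeOf <- setNames(as.character(ss$grade), ids)
  regionFlags <- NULL
  assoc <- NULL
  if (nrow(regions) > 0) {
    regionFlags <- t(vapply(seq_len(nrow(regions)), function(r)
      regionAltered(regions[r, ], segKeep, cnaKeep), logical(length(cnaKeep))))
    rownames(regionFlags) <- sprintf("%s_%s_%d", regions$direction,
                                     regions$chrom, regions$peak_start)
    assoc <- regionGradeAssociation(regionFlags, gradeOf[cnaKeep])
  }

  sb <- spearmanBurdenGrade(ss$grade[ids %in% snvKeep], burden[snvKeep])
  classes <- classifyAndCount(do.call(rbind, calls[snvKeep]))

  list(calls = calls, oxogQC = oxogQC, cnaQC = cna$qc, seg = cna$seg,
       regions = regions, markerInfo = mm[c("chrom", "pos")],
       burden = burden, tumorFraction = tf, regionFlags = regionFlags,
       stats = list(spearman = sb, classes = classes,
                    regionAssociation = assoc,
                    median_tumor_fraction =
                      median(tf[snvKeep], na.rm = TRUE)))
}

#' Machine-readable cohort report
#'
#' Collects the pipeline outputs into a versioned, JSON-serialisable
#' report: per-sample burden, tumor fraction and QC flags, region flags,
#' the burden-grade correlation, per-region association p-values, and the
#' consequence-class breakdown. All numbers come directly from the pipeline
#' result (no recomputation).
#'
#' @param pipeline output of [runPipeline()]
#' @param cohort the analysed [PJCohort-class]
#' @param path optional file path; when given, the JSON report (and a
#'   per-sample TSV next to it) are written
#' @return the report list, invisibly when `path` is given
#' @export
cohortReport <- function(pipeline, cohort, path = NULL) {
  ss <- sampleSheet(cohort)
  perSample <- data.frame(
    sample_id = ss$sample_id,
    grade = as.character(ss$grade),
    burden = unname(pipeline$burden[ss$sample_id]),
    tumor_fraction = unname(pipeline$tumorFraction[ss$sample_id]),
    oxog_excluded = pipeline$oxogQC$exclude[
      match(ss$sample_id, pipeline$oxogQC$sample_id)],
    cna_excluded = pipeline$cnaQC$exclude[
      match(ss$sample_id, pipeline$cnaQC$sample_id)],
    stringsAsFactors = FALSE)
  report <- list(
    schema = "pjflow-report/1",
    n_samples = nrow(ss),
    samples = perSample,
    spearman_burden_grade = pipeline$stats$spearman,
    median_tumor_fraction = pipeline$stats$median_tumor_fraction,
    class_breakdown = pipeline$stats$classes,
    regions = pipeline$regions,
    region_association = pipeline$stats$regionAssociation)
  if (!is.null(path)) {
    write_json(report, path, auto_unbox = TRUE, digits = 6,
               dataframe = "rows", pretty = TRUE)
    fwrite(perSample, sub("\\.json$", ".tsv", path), sep = "\t")
    return(invisible(report))
  }
  report
}
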