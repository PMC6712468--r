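#' @importFrom rtracklayer export.bed import.bed
#' @importFrom Biostrings writeXStringSet readDNAStringSet
#' @importFrom VariantAnnotation readVcf info ref alt
#' @importFrom data.table fwrite fread
#' @importFrom jsonlite toJSON fromJSON write_json
NULL

config_to_list <- function(cfg) {
  sn <- methods::slotNames("CohortConfig")
  out <- lapply(sn, function(s) slot(cfg, s))
  names(out) <- sn
  # named vectors must become objects (not arrays) to keep their names
  out$nSamplesPerGrade <- as.list(out$nSamplesPerGrade)
  out$burdenMedianByGrade <- as.list(out$burdenMedianByGrade)
  out
}

config_from_list <- function(lst) {
  lst$nSamplesPerGrade <- setNames(as.integer(unlist(lst$nSamplesPerGrade)),
                                   names(unlist(lst$nSamplesPerGrade)))
  lst$burdenMedianByGrade <- setNames(
    as.numeric(unlist(lst$burdenMedianByGrade)),
    names(unlist(lst$burdenMedianByGrade)))
  lst$cnaProfiles <- as.data.frame(lst$cnaProfiles)
  do.call(CohortConfig, lst)
}

truth_vcf_lines <- function(truth, reference) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pjflow-synthetic-truth",
    '##INFO=<ID=CF,Number=1,Type=Float,Description="True cellular fraction">',
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="Consequence class label">',
    '##INFO=<ID=ART,Number=0,Type=Flag,Description="Injected OxoG artifact">',
    vapply(names(reference), function(ch)
      sprintf("##contig=<ID=%s,length=%d>", ch, length(reference[[ch]])),
      character(1)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(truth) == 0) return(hdr)
  info <- vapply(seq_len(nrow(truth)), function(i) {
    parts <- character(0)
    if (!is.na(truth$cf[i]))
      parts <- c(parts, sprintf("CF=%.17g", truth$cf[i]))
    parts <- c(parts, paste0("CLASS=", truth$class[i]))
    if (isTRUE(truth$artifact[i])) parts <- c(parts, "ART")
    paste(parts, collapse = ";")
  }, character(1))
  c(hdr, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", truth$chrom, truth$pos,
                 truth$ref, truth$alt, info))
}

#' Write a synthetic cohort to a fixture directory
#'
#' Emits plain-text files: `targets.bed` (0-based half-open), per-sample
#' pileup TSVs under `pileups/`, per-sample truth VCFs (v4.2) under
#' `truth/`, the truth copy-number profile `truth_segments.tsv`, the sample
#' sheet `samples.tsv`, the synthetic reference `reference.fa`, bin depth
#' matrices (`bins.tsv`, `depth_tumor.tsv`, `depth_normal.tsv`), and a JSON
#' `manifest.json` with the seed and full configuration. Writing is
#' deterministic: the same cohort produces byte-identical files.
#'
#' @param cohort a [PJCohort-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeFixture <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pileups"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  export.bed(targets(cohort), file.path(dir, "targets.bed"))
  writeXStringSet(reference(cohort), file.path(dir, "reference.fa"))
  ss <- sampleSheet(cohort)
  out <- ss; out$grade <- as.character(out$grade)
  fwrite(out, file.path(dir, "samples.tsv"), sep = "\t")
  for (id in ss$sample_id) {
    fwrite(pileups(cohort, id),
           file.path(dir, "pileups", paste0(id, ".tsv")), sep = "\t")
    writeLines(truth_vcf_lines(truthEvents(cohort, id),
                               reference(cohort)),
               file.path(dir, "truth", paste0(id, ".vcf")))
  }
  segs <- do.call(rbind, lapply(ss$sample_id, function(id) {
    ts <- truthSegments(cohort, id)
    if (nrow(ts) == 0) return(NULL)
    cbind(sample = id, ts, stringsAsFactors = FALSE)
  }))
  if (is.null(segs))
    segs <- data.frame(sample = character(), chrom = character(),
                       start = integer(), end = integer(),
                       log2 = numeric())
  fwrite(segs, file.path(dir, "truth_segments.tsv"), sep = "\t")
  se <- binDepths(cohort)
  bins <- rowRanges(se)
  fwrite(data.frame(chrom = as.character(seqnames(bins)),
                    start = start(bins), end = end(bins),
                    on_target = bins$on_target, short = bins$short),
         file.path(dir, "bins.tsv"), sep = "\t")
  fwrite(as.data.frame(assay(se, "tumor")),
         file.path(dir, "depth_tumor.tsv"), sep = "\t")
  fwrite(as.data.frame(assay(se, "normal")),
         file.path(dir, "depth_normal.tsv"), sep = "\t")
  manifest <- list(format = "pjflow-fixture/1",
                   seed = cohortConfig(cohort)@seed,
                   n_samples = nrow(ss),
                   config = config_to_list(cohortConfig(cohort)))
  write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  invisible(dir)
}

read_truth_vcf <- function(path) {
  v <- suppressWarnings(readVcf(path, genome = "synthetic"))
  n <- length(v)
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(), cf = numeric(),
                      class = character(), artifact = logical(),
                      stringsAsFactors = FALSE))
  rr <- SummarizedExperiment::rowRanges(v)
  inf <- info(v)
  cf <- as.numeric(inf$CF)
  data.frame(
    chrom = as.character(seqnames(rr)), pos = start(rr),
    ref = as.character(ref(v)),
    alt = vapply(alt(v), function(a) as.character(a)[1], character(1)),
    cf = cf,
    class = as.character(inf$CLASS),
    artifact = as.logical(inf$ART), stringsAsFactors = FALSE)
}

#' Read a fixture directory back into a cohort object
#'
#' Inverse of [writeFixture()]; truth VCFs are parsed with
#' `VariantAnnotation::readVcf`.
#'
#' @param dir fixture directory
#' @return a [PJCohort-class]
#' @export
readFixture <- function(dir) {
  manifest <- fromJSON(file.path(dir, "manifest.json"),
                       simplifyVector = TRUE)
  cfg <- config_from_list(manifest$config)
  reference <- readDNAStringSet(file.path(dir, "reference.fa"))
  tgt <- import.bed(file.path(dir, "targets.bed"))
  mcols(tgt) <- NULL
  ssRaw <- as.data.frame(fread(file.path(dir, "samples.tsv")))
  ss <- data.frame(sample_id = ssRaw$sample_id,
                   grade = factor(ssRaw$grade,
                                  levels = c("LGD", "HGD", "INC"),
                                  ordered = TRUE),
                   sex = ssRaw$sex, duct_type = ssRaw$duct_type,
                   purity = ssRaw$purity, oxog = ssRaw$oxog,
                   noisy = ssRaw$noisy, stringsAsFactors = FALSE)
  plps <- lapply(ss$sample_id, function(id)
    as.data.frame(fread(file.path(dir, "pileups", paste0(id, ".tsv")))))
  names(plps) <- ss$sample_id
  truth <- lapply(ss$sample_id, function(id)
    read_truth_vcf(file.path(dir, "truth", paste0(id, ".vcf"))))
  names(truth) <- ss$sample_id
  segRaw <- as.data.frame(fread(file.path(dir, "truth_segments.tsv")))
  # whole-valued log2 shifts must not collapse to integer on re-read
  segRaw$log2 <- as.numeric(segRaw$log2)
  truthSegs <- lapply(ss$sample_id, function(id) {
    x <- segRaw[segRaw$sample == id, c("chrom", "start", "end", "log2"),
                drop = FALSE]
    rownames(x) <- NULL
    x
  })
  names(truthSegs) <- ss$sample_id
  binsRaw <- as.data.frame(fread(file.path(dir, "bins.tsv")))
  bins <- GRanges(binsRaw$chrom, IRanges(binsRaw$start, binsRaw$end),
                  on_target = binsRaw$on_target, short = binsRaw$short)
  tum <- as.matrix(as.data.frame(fread(file.path(dir, "depth_tumor.tsv"))))
  nor <- as.matrix(as.data.frame(fread(file.path(dir,
                                                 "depth_normal.tsv"))))
  se <- SummarizedExperiment(assays = list(tumor = tum, normal = nor),
                             rowRanges = bins)
  new("PJCohort", sampleSheet = ss, pileups = plps, truthEvents = truth,
      truthSegments = truthSegs, targets = tgt, reference = reference,
      binDepths = se, config = cfg)
}
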