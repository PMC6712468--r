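#' @name PJCohort-accessors
#' @title Accessors for PJCohort objects
#' @param x a [PJCohort-class]
#' @param sample optional sample id to extract a single element
#' @return `sampleSheet` a data.frame; `pileups`/`truthEvents`/
#'   `truthSegments` a named list (or one element when `sample` is given);
#'   `targets` a GRanges; `reference` a DNAStringSet; `binDepths` a
#'   SummarizedExperiment; `cohortConfig` the generating CohortConfig.
NULL

#' @rdname PJCohort-accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))
#' @rdname PJCohort-accessors
#' @export
setGeneric("pileups", function(x, sample = NULL) standardGeneric("pileups"))
#' @rdname PJCohort-accessors
#' @export
setGeneric("truthEvents", function(x, sample = NULL)
  standardGeneric("truthEvents"))
#' @rdname PJCohort-accessors
#' @export
setGeneric("truthSegments", function(x, sample = NULL)
  standardGeneric("truthSegments"))
#' @rdname PJCohort-accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))
#' @rdname PJCohort-accessors
#' @export
setGeneric("reference", function(x) standardGeneric("reference"))
#' @rdname PJCohort-accessors
#' @export
setGeneric("binDepths", function(x) standardGeneric("binDepths"))
#' @rdname PJCohort-accessors
#' @export
setGeneric("cohortConfig", function(x) standardGeneric("cohortConfig"))

pick <- function(lst, sample) {
  if (is.null(sample)) return(lst)
  if (!sample %in% names(lst)) stop("unknown sample: ", sample)
  lst[[sample]]
}

#' @rdname PJCohort-accessors
#' @export
setMethod("sampleSheet", "PJCohort", function(x) x@sampleSheet)
#' @rdname PJCohort-accessors
#' @export
setMethod("pileups", "PJCohort", function(x, sample = NULL)
  pick(x@pileups, sample))
#' @rdname PJCohort-accessors
#' @export
setMethod("truthEvents", "PJCohort", function(x, sample = NULL)
  pick(x@truthEvents, sample))
#' @rdname PJCohort-accessors
#' @export
setMethod("truthSegments", "PJCohort", function(x, sample = NULL)
  pick(x@truthSegments, sample))
#' @rdname PJCohort-accessors
#' @export
setMethod("targets", "PJCohort", function(x) x@targets)
#' @rdname PJCohort-accessors
#' @export
setMethod("reference", "PJCohort", function(x) x@reference)
#' @rdname PJCohort-accessors
#' @export
setMethod("binDepths", "PJCohort", function(x) x@binDepths)
#' @rdname PJCohort-accessors
#' @export
setMethod("cohortConfig", "PJCohort", function(x) x@config)
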