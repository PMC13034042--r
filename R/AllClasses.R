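#' ProximityExperiment: proteins x runs iBAQ intensities with run metadata
#'
#' The central container of the package. It extends
#' \linkS4class{SummarizedExperiment}: rows are protein groups, columns are
#' purification runs. The \code{"ibaq"} assay holds non-negative intensities
#' with \code{NA} marking "not detected" (a recorded 0 in a MaxQuant-style
#' table means the same thing and is converted to \code{NA} on import).
#'
#' Row metadata carries \code{protein_id}, \code{gene_name} and the three
#' per-protein flags used for filtering: \code{contaminant}, \code{decoy}
#' (reverse-database hit) and \code{endogenous_biotin} (proteins biotinylated
#' by the endogenous ligase Bpl1 regardless of bait, e.g. Acc1/Hfa1, Arc1,
#' Dur12, Pyc1/Pyc2 in yeast). Column metadata carries the run design:
#' \code{bait_name}, \code{tag_terminus} (N or C), \code{role} (bait or
#' control), \code{series_id}, \code{replicate_index} and \code{mode}.
#'
#' After \code{\link{medianNormalize}} the object gains a \code{"norm"} assay
#' (per-run nonzero median scaled to 1) and, after \code{\link{imputeMissing}},
#' an \code{"imputed"} logical assay recording per-cell provenance.
#'
#' @slot normalized logical scalar; TRUE once medianNormalize has run.
#' @aliases ProximityExperiment-class
#' @exportClass ProximityExperiment
setClass("ProximityExperiment",
         contains = "SummarizedExperiment",
         representation(normalized = "logical"),
         prototype(normalized = FALSE))

setValidity("ProximityExperiment", function(object) {
    msg <- character()
    if (!"ibaq" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'ibaq' is required")
    else {
        v <- SummarizedExperiment::assay(object, "ibaq")
        if (any(v < 0, na.rm = TRUE))
            msg <- c(msg, "intensities must be non-negative")
    }
    rd <- SummarizedExperiment::rowData(object)
    need_rd <- c("protein_id", "contaminant", "decoy", "endogenous_biotin")
    miss <- setdiff(need_rd, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks: ", paste(miss, collapse = ", ")))
    if ("protein_id" %in% colnames(rd) && anyDuplicated(rd$protein_id))
        msg <- c(msg, "protein ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "run ids must be unique")
    cd <- SummarizedExperiment::colData(object)
    need_cd <- c("bait_name", "role", "series_id", "replicate_index")
    miss <- setdiff(need_cd, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
    if ("role" %in% colnames(cd) &&
        !all(cd$role %in% c("bait", "control")))
        msg <- c(msg, "role must be 'bait' or 'control'")
    if (length(msg)) msg else TRUE
})

#' ReferenceScheme: how a bait's reference run set is assembled
#'
#' Three variants mirror the three quantification designs supported by the
#' pipeline:
#' \describe{
#'   \item{\code{paired_controls}}{reference = the (two) control runs of the
#'     series; the log2 reference values are averaged (mean).}
#'   \item{\code{pooled_median}}{reference = the control runs plus the runs of
#'     all other candidate baits in the series, minus any per-bait exclusions
#'     (e.g. two functionally linked baits excluded from each other's
#'     reference); aggregated by the median of the log2 values.}
#'   \item{\code{replicate_averaged}}{reference = control replicate runs;
#'     replicate values are averaged on the linear scale, excluding missing
#'     values, before the log2 difference is taken.}
#' }
#'
#' @slot variant character; one of the three variants above.
#' @slot control_run_ids character; control run ids.
#' @slot candidate_bait_ids character; pooled_median only: the baits whose
#'   runs are pooled into each other's references.
#' @slot exclusions named list; pooled_median only: bait -> baits excluded
#'   from its reference.
#' @slot aggregator character; "mean" or "median" over log2 reference values.
#' @aliases ReferenceScheme-class
#' @exportClass ReferenceScheme
setClass("ReferenceScheme",
         representation(variant = "character",
                        control_run_ids = "character",
                        candidate_bait_ids = "character",
                        exclusions = "list",
                        aggregator = "character"))

setValidity("ReferenceScheme", function(object) {
    msg <- character()
    if (!object@variant %in%
        c("paired_controls", "pooled_median", "replicate_averaged"))
        msg <- c(msg, "unknown variant")
    if (!object@aggregator %in% c("mean", "median"))
        msg <- c(msg, "aggregator must be 'mean' or 'median'")
    if (object@variant == "paired_controls" && object@aggregator != "mean")
        msg <- c(msg, "paired_controls requires aggregator 'mean'")
    if (object@variant == "pooled_median" && object@aggregator != "median")
        msg <- c(msg, "pooled_median requires aggregator 'median'")
    if (!length(object@control_run_ids))
        msg <- c(msg, "control_run_ids must be non-empty")
    if (length(msg)) msg else TRUE
})

#' GradientProfiles: sucrose-gradient band intensities over 20 fractions
#'
#' One row per (protein, replicate) western-blot series: 20 non-negative
#' intensities indexed by fraction 1..20 (gradient top to bottom), plus the
#' polysomal reference fractions (default 13 and 14) used to anchor the
#' normalization.
#'
#' @slot protein_id character vector, one per profile.
#' @slot replicate_id character vector, one per profile.
#' @slot intensities numeric matrix, profiles x 20 fractions.
#' @slot reference_fractions integer vector, subset of 1..20.
#' @aliases GradientProfiles-class
#' @exportClass GradientProfiles
setClass("GradientProfiles",
         representation(protein_id = "character",
                        replicate_id = "character",
                        intensities = "matrix",
                        reference_fractions = "integer"))

setValidity("GradientProfiles", function(object) {
    msg <- character()
    n <- length(object@protein_id)
    if (length(object@replicate_id) != n)
        msg <- c(msg, "protein_id and replicate_id lengths differ")
    if (nrow(object@intensities) != n)
        msg <- c(msg, "intensity rows must match profile count")
    if (ncol(object@intensities) != 20L)
        msg <- c(msg, "exactly 20 fractions are required")
    if (any(object@intensities < 0, na.rm = TRUE))
        msg <- c(msg, "intensities must be non-negative")
    rf <- object@reference_fractions
    if (!length(rf) || any(rf < 1L) || any(rf > 20L) || anyDuplicated(rf))
        msg <- c(msg, "reference_fractions must be a distinct subset of 1..20")
    if (length(msg)) msg else TRUE
})

#' PkaSet: ionizable-group pKa values for charge and pI computation
#'
#' Holds the pKa of the free alpha-amino (N-terminal) and alpha-carboxyl
#' (C-terminal) groups and of the seven ionizable side chains (D, E, C, Y
#' negative when deprotonated; H, K, R positive when protonated). The default
#' set (\code{\link{bjellqvistPkaSet}}) is the Bjellqvist set used by common
#' pI/MW web services.
#'
#' @slot n_term numeric; N-terminal amino group pKa.
#' @slot c_term numeric; C-terminal carboxyl group pKa.
#' @slot side_chains named numeric; pKa for D, E, C, Y, H, K, R.
#' @aliases PkaSet-class
#' @exportClass PkaSet
setClass("PkaSet",
         representation(n_term = "numeric",
                        c_term = "numeric",
                        side_chains = "numeric"))

setValidity("PkaSet", function(object) {
    msg <- character()
    all_pka <- c(object@n_term, object@c_term, object@side_chains)
    if (any(all_pka <= 0) || any(all_pka >= 14))
        msg <- c(msg, "all pKa values must lie in (0, 14)")
    need <- c("D", "E", "C", "Y", "H", "K", "R")
    if (!all(need %in% names(object@side_chains)))
        msg <- c(msg, paste0("side_chains must name: ",
                             paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

setMethod("show", "ProximityExperiment", function(object) {
    cat(sprintf("ProximityExperiment: %d proteins x %d runs\n",
                nrow(object), ncol(object)))
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("  baits: %s\n",
                paste(unique(cd$bait_name[cd$role == "bait"]), collapse = ", ")))
    cat(sprintf("  controls: %d run(s); normalized: %s; assays: %s\n",
                sum(cd$role == "control"), object@normalized,
                paste(SummarizedExperiment::assayNames(object),
                      collapse = ", ")))
})

setMethod("show", "ReferenceScheme", function(object) {
    cat(sprintf("ReferenceScheme '%s' (aggregator: %s)\n",
                object@variant, object@aggregator))
    cat(sprintf("  controls: %s\n",
                paste(object@control_run_ids, collapse = ", ")))
    if (object@variant == "pooled_median") {
        cat(sprintf("  pooled baits: %s\n",
                    paste(object@candidate_bait_ids, collapse = ", ")))
        for (b in names(object@exclusions))
            cat(sprintf("  exclusion: %s -> %s\n", b,
                        paste(object@exclusions[[b]], collapse = ", ")))
    }
})

setMethod("show", "GradientProfiles", function(object) {
    cat(sprintf("GradientProfiles: %d profile(s), proteins: %s; replicates: %s\n",
                length(object@protein_id),
                paste(unique(object@protein_id), collapse = ", "),
                paste(unique(object@replicate_id), collapse = ", ")))
    cat(sprintf("  reference fractions: %s\n",
                paste(object@reference_fractions, collapse = ", ")))
})

setMethod("show", "PkaSet", function(object) {
    cat(sprintf("PkaSet: N-term %.2f, C-term %.2f\n",
                object@n_term, object@c_term))
    print(object@side_chains)
})
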