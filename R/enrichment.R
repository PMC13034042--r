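#' Construct a ReferenceScheme
#'
#' @param variant "paired_controls", "pooled_median" or
#'   "replicate_averaged".
#' @param control_run_ids character; control run ids.
#' @param candidate_bait_ids character; pooled_median only.
#' @param exclusions named list, bait -> character vector of baits excluded
#'   from its reference (pooled_median only, e.g. two functionally coupled
#'   chaperone baits reciprocally excluded).
#' @param aggregator "mean" or "median"; defaults to the variant's canonical
#'   choice.
#' @return A \linkS4class{ReferenceScheme}.
#' @export
referenceScheme <- function(variant, control_run_ids,
                            candidate_bait_ids = character(),
                            exclusions = list(),
                            aggregator = NULL) {
    if (is.null(aggregator))
        aggregator <- switch(variant,
                             paired_controls = "mean",
                             pooled_median = "median",
                             replicate_averaged = "mean",
                             "mean")
    new("ReferenceScheme", variant = variant,
        control_run_ids = as.character(control_run_ids),
        candidate_bait_ids = as.character(candidate_bait_ids),
        exclusions = exclusions, aggregator = aggregator)
}

#' Build the ordered reference run set for a bait
#'
#' \code{paired_controls}: the scheme's control runs. \code{pooled_median}:
#' the control runs plus the runs of every candidate bait except the bait
#' itself and any baits listed in its exclusion entry.
#' \code{replicate_averaged}: the control replicate runs (the averaging
#' itself happens in \code{\link{aggregateReplicates}}). A bait's own runs
#' never appear in its reference.
#'
#' @param meta run-metadata data.frame (see \code{\link{runMeta}}).
#' @param scheme a \linkS4class{ReferenceScheme}.
#' @param bait bait name (must appear in \code{meta$bait_name}).
#' @return Character vector of reference run ids, in \code{meta} order.
#' @export
buildReference <- function(meta, scheme, bait) {
    if (!bait %in% meta$bait_name)
        stop(sprintf("bait '%s' not present in run metadata", bait))
    keep <- switch(scheme@variant,
        paired_controls = meta$run_id %in% scheme@control_run_ids,
        replicate_averaged = meta$run_id %in% scheme@control_run_ids,
        pooled_median = {
            excluded <- c(bait, scheme@exclusions[[bait]])
            (meta$run_id %in% scheme@control_run_ids) |
                (meta$bait_name %in%
                     setdiff(scheme@candidate_bait_ids, excluded) &
                 meta$role == "bait")
        },
        stop("unknown scheme variant"))
    keep <- keep & !(meta$bait_name == bait & meta$role == "bait")
    ref <- meta$run_id[keep]
    if (!length(ref))
        stop(sprintf("empty reference set for bait '%s'", bait))
    ref
}

#' Control-referenced log2 enrichment per protein
#'
#' For each protein observed in the bait run, the log2 enrichment is
#' log2(normalized bait value) minus the aggregate (mean or median) of the
#' log2 normalized reference values. Reference values are expected to be
#' complete after control-run imputation; proteins missing in the bait run
#' are dropped (never imputed) and counted in
#' \code{attr(result, "n_dropped_bait_missing")}. If imputation was skipped
#' and a protein has no reference value at all, it is dropped with a
#' warning count in \code{attr(result, "n_dropped_no_reference")}.
#'
#' @param x a normalized \linkS4class{ProximityExperiment}.
#' @param bait_run a single bait run id.
#' @param reference_runs character vector of reference run ids.
#' @param aggregator "mean" or "median" over the log2 reference values.
#' @return data.frame with one row per emitted protein: protein_id,
#'   gene_name, bait, normalized_abundance (linear), log10_abundance,
#'   log2_enrichment, n_reference_runs, any_imputed_reference.
#' @export
computeEnrichment <- function(x, bait_run, reference_runs,
                              aggregator = c("mean", "median")) {
    aggregator <- match.arg(aggregator)
    stopifnot(length(bait_run) == 1L)
    runs <- c(bait_run, reference_runs)
    miss <- setdiff(runs, colnames(x))
    if (length(miss))
        stop("run(s) not in matrix: ", paste(miss, collapse = ", "))
    v <- normIntensities(x)
    imp <- imputedMask(x)
    rd <- SummarizedExperiment::rowData(x)
    bait_name <- runMeta(x)[bait_run, "bait_name"]
    agg <- if (aggregator == "mean") mean else stats::median
    bv <- v[, bait_run]
    detected <- which(!is.na(bv) & !imp[, bait_run])
    n_no_ref <- 0L
    rows <- lapply(detected, function(i) {
        refs <- v[i, reference_runs]
        refs <- refs[!is.na(refs)]
        if (!length(refs)) {
            n_no_ref <<- n_no_ref + 1L
            return(NULL)
        }
        data.frame(protein_id = rd$protein_id[i],
                   gene_name = rd$gene_name[i],
                   bait = bait_name,
                   normalized_abundance = bv[i],
                   log10_abundance = log10(bv[i]),
                   log2_enrichment = log2(bv[i]) - agg(log2(refs)),
                   n_reference_runs = length(refs),
                   any_imputed_reference = any(imp[i, reference_runs]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(protein_id = character(), gene_name = character(),
                          bait = character(), normalized_abundance = numeric(),
                          log10_abundance = numeric(),
                          log2_enrichment = numeric(),
                          n_reference_runs = integer(),
                          any_imputed_reference = logical())
    if (n_no_ref)
        warning(sprintf("%d protein(s) dropped: no reference value", n_no_ref))
    attr(out, "n_dropped_bait_missing") <- sum(is.na(bv))
    attr(out, "n_dropped_no_reference") <- n_no_ref
    out
}

#' Replicate-averaged enrichment (multi-replicate design)
#'
#' Per protein, the normalized values are averaged on the LINEAR scale over
#' the non-missing bait replicates and, separately, over the non-missing
#' control replicates; the log2 of the two averages is then differenced.
#' Averaging before the log matters: bait replicates \{1, 4\} give
#' log2(2.5), not 1. Proteins missing in every bait replicate are dropped.
#'
#' @param x a normalized \linkS4class{ProximityExperiment}.
#' @param bait_runs character; bait replicate run ids (>= 1).
#' @param control_runs character; control replicate run ids (>= 1).
#' @return data.frame in the same shape as \code{\link{computeEnrichment}}.
#' @export
aggregateReplicates <- function(x, bait_runs, control_runs) {
    stopifnot(length(bait_runs) >= 1L, length(control_runs) >= 1L)
    miss <- setdiff(c(bait_runs, control_runs), colnames(x))
    if (length(miss))
        stop("run(s) not in matrix: ", paste(miss, collapse = ", "))
    v <- normIntensities(x)
    imp <- imputedMask(x)
    rd <- SummarizedExperiment::rowData(x)
    bait_name <- unique(runMeta(x)[bait_runs, "bait_name"])[1]
    bmean <- apply(v[, bait_runs, drop = FALSE], 1,
                   function(r) if (all(is.na(r))) NA_real_
                               else mean(r, na.rm = TRUE))
    cmean <- apply(v[, control_runs, drop = FALSE], 1,
                   function(r) if (all(is.na(r))) NA_real_
                               else mean(r, na.rm = TRUE))
    ncontrol <- rowSums(!is.na(v[, control_runs, drop = FALSE]))
    keep <- which(!is.na(bmean) & !is.na(cmean))
    data.frame(protein_id = rd$protein_id[keep],
               gene_name = rd$gene_name[keep],
               bait = bait_name,
               normalized_abundance = bmean[keep],
               log10_abundance = log10(bmean[keep]),
               log2_enrichment = log2(bmean[keep]) - log2(cmean[keep]),
               n_reference_runs = ncontrol[keep],
               any_imputed_reference =
                   rowSums(imp[keep, control_runs, drop = FALSE]) > 0,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize a protein's enrichment across assays
#'
#' For each protein, collects its log2 enrichments over a set of assays and
#' reports the across-assay median, quartiles (linear-interpolation
#' quantiles), min, max and Tukey-rule outliers (beyond 1.5 x IQR from the
#' quartiles). The box/whisker quantities of a multi-assay variation plot.
#'
#' @param tables named list of enrichment data.frames, one per assay.
#' @param proteins character; protein ids to summarize (each must appear in
#'   at least one assay).
#' @return data.frame: protein_id, n_assays, median, q1, q3, iqr, min, max,
#'   plus a list-column \code{outliers} of values beyond the whiskers.
#' @export
summarizeAcrossAssays <- function(tables, proteins) {
    rows <- lapply(proteins, function(p) {
        vals <- unlist(lapply(tables, function(t)
            t$log2_enrichment[t$protein_id == p]), use.names = FALSE)
        if (!length(vals))
            stop(sprintf("protein '%s' absent from every assay", p))
        q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        iqr <- q[3] - q[1]
        out <- sort(vals[vals < q[1] - 1.5 * iqr | vals > q[3] + 1.5 * iqr])
        data.frame(protein_id = p, n_assays = length(vals),
                   median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                   min = min(vals), max = max(vals),
                   n_outliers = length(out),
                   outliers = I(list(out)), stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Rank candidate proximal proteins
#'
#' Filters enrichment records by minimum log2 enrichment and minimum
#' normalized abundance, optionally removes flagged classes, and orders by
#' descending enrichment (ties: descending abundance, then protein id).
#'
#' @param records enrichment data.frame.
#' @param min_enrichment numeric, log2 units.
#' @param min_abundance numeric, normalized linear units.
#' @param exclude_flagged optional \linkS4class{ProximityExperiment}; when
#'   given, contaminant/endogenous-biotin proteins are removed first.
#' @return The filtered records, fully ordered.
#' @export
rankCandidates <- function(records, min_enrichment = 0, min_abundance = 0,
                           exclude_flagged = NULL) {
    if (!is.null(exclude_flagged)) {
        rd <- SummarizedExperiment::rowData(exclude_flagged)
        bad <- rd$protein_id[rd$contaminant | rd$endogenous_biotin | rd$decoy]
        records <- records[!records$protein_id %in% bad, ]
    }
    records <- records[records$log2_enrichment >= min_enrichment &
                       records$normalized_abundance >= min_abundance, ]
    records[order(-records$log2_enrichment, -records$normalized_abundance,
                  records$protein_id), ]
}
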