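#' Construct a ProximityExperiment from an intensity matrix and run metadata
#'
#' @param values numeric matrix, proteins x runs; rownames are protein ids,
#'   colnames are run ids. \code{NA} (or 0, converted) marks "not detected".
#' @param run_meta data.frame with one row per run: \code{run_id},
#'   \code{bait_name}, \code{tag_terminus} ("N"/"C"), \code{role}
#'   ("bait"/"control"), \code{series_id}, \code{replicate_index},
#'   \code{mode} ("yeast"/"hela").
#' @param gene_names optional character vector of gene labels per protein.
#' @param contaminant,decoy,endogenous_biotin logical flag vectors per
#'   protein; default all \code{FALSE}.
#' @return A \linkS4class{ProximityExperiment}.
#' @export
ProximityExperiment <- function(values, run_meta, gene_names = NULL,
                                contaminant = NULL, decoy = NULL,
                                endogenous_biotin = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("'values' needs protein ids as rownames")
    if (any(values < 0, na.rm = TRUE)) {
        bad <- which(values < 0, arr.ind = TRUE)[1, ]
        stop(sprintf("negative intensity for protein '%s' in run '%s'",
                     rownames(values)[bad[1]], colnames(values)[bad[2]]))
    }
    values[!is.na(values) & values == 0] <- NA_real_
    run_meta <- as.data.frame(run_meta)
    need <- c("run_id", "bait_name", "role", "series_id", "replicate_index")
    miss <- setdiff(need, colnames(run_meta))
    if (length(miss))
        stop("run_meta lacks column(s): ", paste(miss, collapse = ", "))
    if (!"tag_terminus" %in% colnames(run_meta)) run_meta$tag_terminus <- "C"
    if (!"mode" %in% colnames(run_meta)) run_meta$mode <- "yeast"
    if (is.null(colnames(values))) colnames(values) <- run_meta$run_id
    if (!setequal(colnames(values), run_meta$run_id) ||
        anyDuplicated(run_meta$run_id))
        stop("run ids in 'values' and 'run_meta' must match one-to-one")
    run_meta <- run_meta[match(colnames(values), run_meta$run_id), ]
    n <- nrow(values)
    flag <- function(f) if (is.null(f)) rep(FALSE, n) else as.logical(f)
    rd <- S4Vectors::DataFrame(
        protein_id = rownames(values),
        gene_name = if (is.null(gene_names)) rownames(values) else gene_names,
        contaminant = flag(contaminant),
        decoy = flag(decoy),
        endogenous_biotin = flag(endogenous_biotin))
    cd <- S4Vectors::DataFrame(run_meta, row.names = run_meta$run_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ibaq = values), rowData = rd, colData = cd)
    new("ProximityExperiment", se, normalized = FALSE)
}

#' Intensity, normalized-intensity and imputation-provenance accessors
#'
#' \code{intensities} returns the raw iBAQ matrix (NA = not detected);
#' \code{normIntensities} the median-normalized matrix (after
#' \code{\link{medianNormalize}}); \code{imputedMask} the logical per-cell
#' provenance matrix (TRUE = value drawn by \code{\link{imputeMissing}}).
#'
#' @param x a \linkS4class{ProximityExperiment}.
#' @param ... unused.
#' @return A numeric (or logical) proteins x runs matrix.
#' @rdname intensities
#' @export
setMethod("intensities", "ProximityExperiment", function(x, ...)
    SummarizedExperiment::assay(x, "ibaq"))

#' @rdname intensities
#' @export
setMethod("normIntensities", "ProximityExperiment", function(x, ...) {
    if (!x@normalized)
        stop("matrix is not normalized; run medianNormalize() first")
    SummarizedExperiment::assay(x, "norm")
})

#' @rdname intensities
#' @export
setMethod("imputedMask", "ProximityExperiment", function(x, ...) {
    if ("imputed" %in% SummarizedExperiment::assayNames(x))
        SummarizedExperiment::assay(x, "imputed")
    else
        matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
})

#' Run metadata of a ProximityExperiment
#'
#' @param x a \linkS4class{ProximityExperiment}.
#' @param ... unused.
#' @return colData as a base data.frame (one row per run).
#' @rdname runMeta
#' @export
setMethod("runMeta", "ProximityExperiment", function(x, ...)
    as.data.frame(SummarizedExperiment::colData(x)))

#' Read a protein-group intensity table plus a YAML run configuration
#'
#' The table is a UTF-8 TSV with a header; the run configuration names, for
#' each run, the exact intensity column to use and the design metadata
#' (bait, tag terminus, role, series, replicate). Recorded zeros are
#' converted to missing values (MaxQuant writes 0 for "not detected").
#'
#' The YAML layout:
#' \preformatted{
#' id_column: protein_id          # default
#' gene_column: gene_name         # optional
#' flag_columns:                  # optional; cells "+"/TRUE/1 mark the flag
#'   contaminant: contaminant
#'   decoy: reverse
#' endogenous_biotin_genes: [ACC1, HFA1, ARC1, PYC1, PYC2]
#' runs:
#'   - run_id: ctrl1
#'     column: "iBAQ GFP-TurboID"
#'     bait_name: GFP
#'     tag_terminus: C
#'     role: control
#'     series_id: S1
#'     replicate_index: 1
#'     mode: yeast
#' }
#'
#' @param path TSV file path.
#' @param run_config YAML file path, or an already-parsed list with the same
#'   structure.
#' @return A \linkS4class{ProximityExperiment}.
#' @export
readIntensityTable <- function(path, run_config) {
    cfg <- if (is.character(run_config)) yaml::read_yaml(run_config)
           else run_config
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    id_col <- cfg$id_column %||% "protein_id"
    gene_col <- cfg$gene_column %||% "gene_name"
    if (!id_col %in% colnames(tab))
        stop(sprintf("id column '%s' not found in %s", id_col, path))
    ids <- as.character(tab[[id_col]])
    if (anyDuplicated(ids))
        stop(sprintf("duplicate protein id '%s' in %s",
                     ids[duplicated(ids)][1], path))
    run_meta <- do.call(rbind, lapply(cfg$runs, function(r)
        data.frame(run_id = r$run_id, bait_name = r$bait_name,
                   tag_terminus = r$tag_terminus %||% "C",
                   role = r$role, series_id = r$series_id,
                   replicate_index = as.integer(r$replicate_index %||% 1L),
                   mode = r$mode %||% "yeast",
                   stringsAsFactors = FALSE)))
    cols <- vapply(cfg$runs, function(r) r$column %||% r$run_id, "")
    miss <- setdiff(cols, colnames(tab))
    if (length(miss))
        stop("run column(s) missing from table: ",
             paste(miss, collapse = ", "))
    values <- matrix(NA_real_, length(ids), length(cols),
                     dimnames = list(ids, run_meta$run_id))
    for (j in seq_along(cols)) {
        v <- suppressWarnings(as.numeric(tab[[cols[j]]]))
        if (anyNA(v) && !anyNA(suppressWarnings(tab[[cols[j]]])))
            stop(sprintf("non-numeric value in column '%s'", cols[j]))
        bad <- which(!is.na(v) & v < 0)
        if (length(bad))
            stop(sprintf(
                "negative intensity %g for protein '%s' in column '%s'",
                v[bad[1]], ids[bad[1]], cols[j]))
        values[, j] <- v
    }
    parse_flag <- function(colname) {
        if (is.null(colname) || !colname %in% colnames(tab))
            return(rep(FALSE, length(ids)))
        raw <- tab[[colname]]
        if (is.logical(raw)) !is.na(raw) & raw
        else raw %in% c("+", "TRUE", "True", "true", "1")
    }
    fc <- cfg$flag_columns %||% list()
    genes <- if (gene_col %in% colnames(tab)) as.character(tab[[gene_col]])
             else ids
    biotin <- toupper(genes) %in%
        toupper(unlist(cfg$endogenous_biotin_genes %||% character()))
    ProximityExperiment(values, run_meta, gene_names = genes,
                        contaminant = parse_flag(fc$contaminant %||%
                                                     "contaminant"),
                        decoy = parse_flag(fc$decoy %||% "reverse"),
                        endogenous_biotin = biotin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ProximityExperiment back to a protein-group TSV
#'
#' Missing values are written as 0 (the "not detected" convention of the
#' input format), so read-write-read is the identity.
#'
#' @param x a \linkS4class{ProximityExperiment}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeIntensityTable <- function(x, path) {
    v <- intensities(x)
    v[is.na(v)] <- 0
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    out <- cbind(rd[c("protein_id", "gene_name", "contaminant", "decoy",
                      "endogenous_biotin")],
                 as.data.frame(v, check.names = FALSE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' The run configuration matching writeIntensityTable output
#'
#' Convenience for round-tripping: builds the parsed-config list that
#' \code{\link{readIntensityTable}} accepts, from an object's own metadata.
#'
#' @param x a \linkS4class{ProximityExperiment}.
#' @return A list with \code{runs} and \code{flag_columns} entries.
#' @export
runConfig <- function(x) {
    rm <- runMeta(x)
    list(id_column = "protein_id", gene_column = "gene_name",
         flag_columns = list(contaminant = "contaminant", decoy = "decoy"),
         endogenous_biotin_genes = as.list(
             SummarizedExperiment::rowData(x)$gene_name[
                 SummarizedExperiment::rowData(x)$endogenous_biotin]),
         runs = lapply(seq_len(nrow(rm)), function(i)
             list(run_id = rm$run_id[i], column = rm$run_id[i],
                  bait_name = rm$bait_name[i],
                  tag_terminus = rm$tag_terminus[i], role = rm$role[i],
                  series_id = rm$series_id[i],
                  replicate_index = rm$replicate_index[i],
                  mode = rm$mode[i])))
}

#' Drop flagged protein classes from a ProximityExperiment
#'
#' Contaminants, decoy (reverse) hits and endogenously biotinylated
#' background proteins are identifiable classes that are typically removed
#' before ranking or plotting. The original object is untouched.
#'
#' @param x a \linkS4class{ProximityExperiment}.
#' @param drop_contaminants,drop_decoys,drop_endogenous_biotin logical;
#'   which flag classes to remove.
#' @param ... unused.
#' @return A \linkS4class{ProximityExperiment} containing exactly the
#'   proteins whose selected flags are all FALSE.
#' @rdname filterProteins
#' @export
setMethod("filterProteins", "ProximityExperiment",
    function(x, drop_contaminants = TRUE, drop_decoys = TRUE,
             drop_endogenous_biotin = FALSE, ...) {
        rd <- SummarizedExperiment::rowData(x)
        drop <- rep(FALSE, nrow(x))
        if (drop_contaminants) drop <- drop | rd$contaminant
        if (drop_decoys) drop <- drop | rd$decoy
        if (drop_endogenous_biotin) drop <- drop | rd$endogenous_biotin
        x[!drop, ]
    })

#' Write (and read back) an enrichment record table
#'
#' Fixed column order (protein_id, gene_name, bait, normalized_abundance,
#' log10_abundance, log2_enrichment, n_reference_runs,
#' any_imputed_reference); rows sorted by descending log2_enrichment with
#' ties broken by protein_id; numbers written with 6 significant digits.
#'
#' @param records data.frame of enrichment records, as returned by
#'   \code{\link{computeEnrichment}}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeEnrichmentTable <- function(records, path) {
    cols <- c("protein_id", "gene_name", "bait", "normalized_abundance",
              "log10_abundance", "log2_enrichment", "n_reference_runs",
              "any_imputed_reference")
    miss <- setdiff(cols, colnames(records))
    if (length(miss))
        stop("records lack column(s): ", paste(miss, collapse = ", "))
    records <- records[order(-records$log2_enrichment, records$protein_id),
                       cols]
    num <- vapply(records, is.numeric, TRUE) &
        !colnames(records) %in% "n_reference_runs"
    records[num] <- lapply(records[num], signif, digits = 6)
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeEnrichmentTable
#' @export
readEnrichmentTable <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
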