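#' Construct GradientProfiles from intensities
#'
#' @param protein_id,replicate_id character vectors, one entry per profile.
#' @param intensities numeric matrix (profiles x 20 fractions) or a single
#'   length-20 vector; fraction 1 is the gradient top.
#' @param reference_fractions integer fractions used as the polysomal
#'   anchor; default c(13, 14).
#' @return A \linkS4class{GradientProfiles}.
#' @export
GradientProfiles <- function(protein_id, replicate_id, intensities,
                             reference_fractions = c(13L, 14L)) {
    if (is.null(dim(intensities)))
        intensities <- matrix(intensities, nrow = 1)
    intensities <- as.matrix(intensities)
    colnames(intensities) <- paste0("f", seq_len(ncol(intensities)))
    new("GradientProfiles",
        protein_id = as.character(protein_id),
        replicate_id = as.character(replicate_id),
        intensities = intensities,
        reference_fractions = as.integer(reference_fractions))
}

#' Read a gradient band-intensity TSV
#'
#' Expected columns: protein_id, replicate_id, f1..f20.
#'
#' @param path TSV path.
#' @param reference_fractions integer; polysomal anchor fractions.
#' @return A \linkS4class{GradientProfiles}.
#' @export
readGradientTable <- function(path, reference_fractions = c(13L, 14L)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    fcols <- paste0("f", 1:20)
    miss <- setdiff(c("protein_id", "replicate_id", fcols), colnames(tab))
    if (length(miss))
        stop("gradient table lacks column(s): ", paste(miss, collapse = ", "))
    GradientProfiles(tab$protein_id, tab$replicate_id,
                     as.matrix(tab[fcols]), reference_fractions)
}

#' Polysome-anchored profile normalization
#'
#' Each profile is divided by the mean of its intensities over the
#' reference (polysomal) fractions, so that the reference-fraction average
#' of every normalized profile is exactly 1. This anchors both proteins to
#' the translating-ribosome population, where co-occupancy is assumed.
#'
#' @param x a \linkS4class{GradientProfiles}.
#' @param ... unused.
#' @return A \linkS4class{GradientProfiles} with normalized intensities.
#' @rdname normalizeProfiles
#' @export
setMethod("normalizeProfiles", "GradientProfiles", function(x, ...) {
    v <- x@intensities
    for (i in seq_len(nrow(v))) {
        ref_mean <- mean(v[i, x@reference_fractions])
        if (!is.finite(ref_mean) || ref_mean <= 0)
            stop(sprintf(
                "zero reference-fraction mean for protein '%s' replicate '%s'",
                x@protein_id[i], x@replicate_id[i]))
        v[i, ] <- v[i, ] / ref_mean
    }
    GradientProfiles(x@protein_id, x@replicate_id, v, x@reference_fractions)
})

# Pull one profile (protein within replicate) as a length-20 vector.
profileRow <- function(x, protein, replicate) {
    i <- which(x@protein_id == protein & x@replicate_id == replicate)
    if (length(i) != 1L)
        stop(sprintf("expected one profile for '%s'/'%s', found %d",
                     protein, replicate, length(i)))
    x@intensities[i, ]
}

#' Per-fraction occupancy ratio of two normalized profiles
#'
#' Elementwise numerator/denominator ratio across the 20 fractions for one
#' replicate; fractions where the denominator is 0 are returned as NA
#' (undefined), never imputed.
#'
#' @param x a normalized \linkS4class{GradientProfiles}.
#' @param numerator,denominator protein ids (e.g. the probed protein and
#'   the obligatory subunit protein).
#' @param replicate replicate id; both profiles must come from it.
#' @return Named numeric vector of 20 per-fraction ratios.
#' @export
occupancyRatio <- function(x, numerator, denominator, replicate) {
    num <- profileRow(x, numerator, replicate)
    den <- profileRow(x, denominator, replicate)
    ratio <- ifelse(den > 0, num / den, NA_real_)
    names(ratio) <- paste0("f", 1:20)
    ratio
}

#' Fraction-group replicate statistics of occupancy ratios
#'
#' Pools, per fraction group (default 60S = fraction 9, 80S = fractions
#' 10-11, polysomes = fractions 13-15), all replicate x fraction ratio
#' values and reports their mean and standard deviation (n-1 denominator;
#' SD = 0 when only one value). Undefined ratios are excluded and counted.
#'
#' @param ratios list of per-fraction ratio vectors, one per replicate (as
#'   from \code{\link{occupancyRatio}}).
#' @param groups named list of integer fraction vectors.
#' @param pool logical; TRUE (default) pools fraction values within a group
#'   across replicates before mean/SD, FALSE averages per-replicate group
#'   means instead.
#' @return data.frame: group, n_values, mean, sd, n_undefined.
#' @export
replicateStats <- function(ratios,
                           groups = list("60S" = 9L, "80S" = c(10L, 11L),
                                         polysomes = c(13L, 14L, 15L)),
                           pool = TRUE) {
    stopifnot(length(ratios) >= 1L)
    rows <- lapply(names(groups), function(g) {
        fr <- groups[[g]]
        if (any(fr < 1L | fr > 20L))
            stop("group fractions must lie in 1..20")
        vals <- if (pool) {
            unlist(lapply(ratios, function(r) r[fr]), use.names = FALSE)
        } else {
            vapply(ratios, function(r) mean(r[fr], na.rm = TRUE), 0)
        }
        n_undef <- sum(is.na(vals))
        vals <- vals[!is.na(vals)]
        data.frame(group = g, n_values = length(vals),
                   mean = mean(vals),
                   sd = if (length(vals) > 1) stats::sd(vals) else 0,
                   n_undefined = n_undef, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' One-call occupancy summary for a numerator/denominator protein pair
#'
#' Normalizes the profiles, computes per-replicate ratios and returns the
#' fraction-group statistics across replicates.
#'
#' @param x a raw \linkS4class{GradientProfiles}.
#' @param numerator,denominator protein ids.
#' @param groups named list of fraction groups (see
#'   \code{\link{replicateStats}}).
#' @return data.frame as from \code{\link{replicateStats}}.
#' @export
occupancyTable <- function(x, numerator, denominator,
                           groups = list("60S" = 9L, "80S" = c(10L, 11L),
                                         polysomes = c(13L, 14L, 15L))) {
    nx <- normalizeProfiles(x)
    reps <- unique(nx@replicate_id)
    ratios <- lapply(reps, function(r)
        occupancyRatio(nx, numerator, denominator, r))
    replicateStats(ratios, groups)
}
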