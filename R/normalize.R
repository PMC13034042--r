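#' Per-run median normalization of iBAQ intensities
#'
#' Each run's intensities are divided by the median of that run's nonzero
#' (observed) values, so that after normalization every run's observed
#' median equals 1. Missing values stay missing. The per-run post-hoc
#' medians are recorded in \code{metadata(x)$norm_certificate} as a check
#' that the invariant holds to 1e-12.
#'
#' @param x a \linkS4class{ProximityExperiment}.
#' @param ... unused.
#' @return The object with a \code{"norm"} assay added and
#'   \code{normalized = TRUE}.
#' @rdname medianNormalize
#' @export
setMethod("medianNormalize", "ProximityExperiment", function(x, ...) {
    v <- intensities(x)
    norm <- v
    med <- numeric(ncol(v))
    names(med) <- colnames(v)
    for (j in seq_len(ncol(v))) {
        obs <- v[, j][!is.na(v[, j]) & v[, j] > 0]
        if (!length(obs))
            stop(sprintf("run '%s' has no nonzero values to normalize by",
                         colnames(v)[j]))
        norm[, j] <- v[, j] / stats::median(obs)
        med[j] <- stats::median(norm[, j][!is.na(norm[, j]) & norm[, j] > 0])
    }
    stopifnot(all(abs(med - 1) < 1e-12))
    SummarizedExperiment::assay(x, "norm", withDimnames = FALSE) <- norm
    S4Vectors::metadata(x)$norm_certificate <- med
    x@normalized <- TRUE
    x
})

#' Imputation parameters for downshifted-Gaussian imputation
#'
#' Parameters of the left-censored imputation applied to designated runs
#' (by default the control purifications): per run, the mean \eqn{\mu} and
#' standard deviation \eqn{\sigma} of the log2 observed values are computed
#' and each missing cell is drawn from
#' \eqn{N(\mu - d\sigma, (w\sigma)^2)} in log2 space. The defaults
#' \code{width = 0.3}, \code{downshift = 1.8} are the canonical defaults of
#' the Perseus "replace from normal distribution" step.
#'
#' @param width w >= 0, multiplier of the per-run log2 SD (unitless).
#' @param downshift d >= 0, shift in per-run log2 SD units (unitless).
#' @param target_runs character vector of run ids to impute, or NULL for
#'   the default (all control runs).
#' @param seed integer seed driving the imputation draws.
#' @return A list of class \code{"ImputationParams"}.
#' @export
imputationParams <- function(width = 0.3, downshift = 1.8,
                             target_runs = NULL, seed = 1L) {
    stopifnot(width >= 0, downshift >= 0)
    structure(list(width = width, downshift = downshift,
                   target_runs = target_runs, seed = as.integer(seed)),
              class = "ImputationParams")
}

#' Impute missing values in designated runs (left-censored Gaussian)
#'
#' Only runs in \code{params$target_runs} are touched (default: control
#' runs). Observed values are never altered; every imputed cell is recorded
#' in the \code{"imputed"} provenance assay. Draws are reproducible from
#' \code{params$seed}; the draw order is fixed by the matrix (runs in
#' column order, proteins in row order), so results are
#' platform-independent.
#'
#' @param x a normalized \linkS4class{ProximityExperiment}.
#' @param params an \code{\link{imputationParams}} object.
#' @param ... unused.
#' @return The object with missing cells in the target runs filled in and
#'   the \code{"imputed"} assay set.
#' @rdname imputeMissing
#' @export
setMethod("imputeMissing", "ProximityExperiment", function(x, params, ...) {
    if (!x@normalized)
        stop("run medianNormalize() before imputeMissing()")
    targets <- params$target_runs
    if (is.null(targets))
        targets <- colnames(x)[runMeta(x)$role == "control"]
    miss <- setdiff(targets, colnames(x))
    if (length(miss))
        stop("target run(s) not in matrix: ", paste(miss, collapse = ", "))
    v <- SummarizedExperiment::assay(x, "norm")
    imp <- imputedMask(x)
    withSeed(params$seed, {
        for (run in colnames(v)[colnames(v) %in% targets]) {
            obs <- v[, run][!is.na(v[, run])]
            if (length(obs) < 3)
                stop(sprintf(
                    "run '%s' has %d observed values; >=3 needed for mu, sigma",
                    run, length(obs)))
            lo <- log2(obs)
            mu <- mean(lo)
            sigma <- stats::sd(lo)     # n-1 denominator
            idx <- which(is.na(v[, run]))
            if (length(idx)) {
                draws <- stats::rnorm(length(idx),
                                      mean = mu - params$downshift * sigma,
                                      sd = params$width * sigma)
                v[idx, run] <- 2^draws
                imp[idx, run] <- TRUE
            }
        }
    })
    SummarizedExperiment::assay(x, "norm", withDimnames = FALSE) <- v
    SummarizedExperiment::assay(x, "imputed", withDimnames = FALSE) <- imp
    S4Vectors::metadata(x)$imputation <- list(
        width = params$width, downshift = params$downshift,
        target_runs = targets, seed = params$seed,
        note = "downshifted-normal defaults w=0.3, d=1.8 (assumed, configurable)")
    x
})
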