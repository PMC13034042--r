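#' Configuration for the proximity-labelling series simulator
#'
#' Describes a synthetic TurboID-like series with known ground truth: bait
#' runs, control runs, configured log2 proximity effects, per-run scale
#' factors, log-normal base abundances, residual log2 noise,
#' intensity-dependent (left-censored) missingness and an endogenously
#' biotinylated background class boosted in every run.
#'
#' Missingness follows P(missing | x) = 1 / (1 + exp((log2 x - tau) / s)),
#' so low-intensity values are preferentially lost (the regime that
#' motivates downshifted imputation). \code{missing_tau = NULL} disables
#' missingness entirely.
#'
#' @param n_proteins total protein count (baits and biotin background
#'   included).
#' @param baits character vector of bait names; each bait is itself a
#'   protein row of the matrix (one bait run each).
#' @param n_controls number of control runs (default 2, i.e. a GFP-ligase
#'   and an NLS-GFP-ligase purification).
#' @param n_proximal number of proximal proteins per bait (ignored when
#'   \code{proximal} is given).
#' @param delta log2 effect size shared by the default proximal sets, or a
#'   vector recycled over baits.
#' @param proximal optional named list: bait -> named numeric vector of
#'   log2 effects keyed by protein id. Default: disjoint sets of
#'   \code{n_proximal} upper-quartile proteins per bait with effect
#'   \code{delta}.
#' @param bait_self_effect log2 self-enrichment of each bait protein in its
#'   own run.
#' @param scale_range range to draw per-run linear scale factors from, or a
#'   vector of fixed per-run factors via \code{scale_factors}.
#' @param scale_factors optional fixed per-run scale factors (baits then
#'   controls).
#' @param noise_sd residual log2 noise SD per cell.
#' @param missing_tau logistic missingness midpoint on the log2-intensity
#'   scale (NULL = no missingness).
#' @param missing_s logistic missingness slope (> 0).
#' @param n_biotin count of endogenously biotinylated background proteins.
#' @param biotin_boost log2 boost applied to them in every run.
#' @param base_meanlog2,base_sdlog2 mean and SD of the log2 base
#'   abundances (log-normal abundance model).
#' @param seed integer seed.
#' @return A list of class \code{"TurboidSimConfig"}.
#' @export
turboidSimConfig <- function(n_proteins = 2000, baits = paste0("BAIT", 1:5),
                             n_controls = 2, n_proximal = 10, delta = 6,
                             proximal = NULL, bait_self_effect = 6,
                             scale_range = c(0.5, 2), scale_factors = NULL,
                             noise_sd = 0, missing_tau = NULL,
                             missing_s = 1, n_biotin = 4, biotin_boost = 4,
                             base_meanlog2 = 20, base_sdlog2 = 2,
                             seed = 1L) {
    stopifnot(noise_sd >= 0, missing_s > 0, n_controls >= 1,
              n_proteins > length(baits) + n_biotin)
    structure(list(n_proteins = n_proteins, baits = baits,
                   n_controls = n_controls, n_proximal = n_proximal,
                   delta = delta, proximal = proximal,
                   bait_self_effect = bait_self_effect,
                   scale_range = scale_range, scale_factors = scale_factors,
                   noise_sd = noise_sd, missing_tau = missing_tau,
                   missing_s = missing_s, n_biotin = n_biotin,
                   biotin_boost = biotin_boost,
                   base_meanlog2 = base_meanlog2,
                   base_sdlog2 = base_sdlog2, seed = as.integer(seed)),
              class = "TurboidSimConfig")
}

#' Simulate a proximity-labelling intensity matrix with known truth
#'
#' Per-run cell values are base x scale x 2^effect x 2^noise, where the
#' effect is the configured log2 proximity effect (proximal proteins in
#' their bait's run), the bait self-effect (bait protein in its own run) or
#' the biotin boost (background proteins in every run). Missing cells are
#' then drawn by the logistic left-censoring rule. The draw order is fixed
#' (base abundances, then run scales, then per-run noise, then per-run
#' missingness), so output is byte-identical for a given seed.
#'
#' Bait and default proximal proteins are placed in the upper quartile of
#' the base-abundance distribution; positive effects on upper-quartile
#' proteins leave every run's nonzero median untouched, so in the
#' noise-free limit the downstream enrichment equals the configured effect
#' exactly.
#'
#' @param cfg a \code{\link{turboidSimConfig}}.
#' @return list(experiment = \linkS4class{ProximityExperiment},
#'   truth = list(proximal, expected_enrichment matrix proteins x baits,
#'   scale_factors, seed)).
#' @export
simulateTurboidSeries <- function(cfg) {
    n <- cfg$n_proteins
    baits <- cfg$baits
    nb <- length(baits)
    biotin_ids <- if (cfg$n_biotin > 0) paste0("BIOTIN", seq_len(cfg$n_biotin))
                  else character()
    filler <- paste0("P", formatC(seq_len(n - nb - length(biotin_ids)),
                                  width = 5, flag = "0"))
    ids <- c(baits, biotin_ids, filler)
    run_ids <- c(paste0(baits, "_run"),
                 paste0("ctrl", seq_len(cfg$n_controls)))
    n_runs <- length(run_ids)
    run_meta <- data.frame(
        run_id = run_ids,
        bait_name = c(baits, paste0("GFPctl", seq_len(cfg$n_controls))),
        tag_terminus = "C",
        role = c(rep("bait", nb), rep("control", cfg$n_controls)),
        series_id = "S1",
        replicate_index = 1L,
        mode = "yeast", stringsAsFactors = FALSE)

    out <- withSeed(cfg$seed, {
        base_log2 <- stats::rnorm(n, cfg$base_meanlog2, cfg$base_sdlog2)
        names(base_log2) <- ids
        # baits sit in the upper quartile: swap their draws with high ones
        q3 <- stats::quantile(base_log2, 0.75, type = 7)
        hi_pool <- setdiff(ids[base_log2 > q3], c(baits, biotin_ids))
        for (b in baits) {
            if (base_log2[b] <= q3 && length(hi_pool)) {
                swap <- hi_pool[1]
                hi_pool <- hi_pool[-1]
                tmp <- base_log2[b]
                base_log2[b] <- base_log2[swap]
                base_log2[swap] <- tmp
            }
        }
        hi_pool <- setdiff(ids[base_log2 > q3], c(baits, biotin_ids))
        proximal <- cfg$proximal
        if (is.null(proximal)) {
            deltas <- rep_len(cfg$delta, nb)
            proximal <- list()
            used <- 0
            for (k in seq_len(nb)) {
                pick <- hi_pool[used + seq_len(cfg$n_proximal)]
                if (anyNA(pick))
                    stop("not enough upper-quartile proteins for proximal sets")
                proximal[[baits[k]]] <- stats::setNames(
                    rep(deltas[k], cfg$n_proximal), pick)
                used <- used + cfg$n_proximal
            }
        }
        scale <- cfg$scale_factors
        if (is.null(scale))
            scale <- stats::runif(n_runs, cfg$scale_range[1],
                                  cfg$scale_range[2])
        effect <- matrix(0, n, n_runs, dimnames = list(ids, run_ids))
        effect[biotin_ids, ] <- cfg$biotin_boost
        for (k in seq_len(nb)) {
            run <- paste0(baits[k], "_run")
            eff <- proximal[[baits[k]]]
            effect[names(eff), run] <- effect[names(eff), run] + eff
            effect[baits[k], run] <- effect[baits[k], run] +
                cfg$bait_self_effect
        }
        values <- matrix(NA_real_, n, n_runs,
                         dimnames = list(ids, run_ids))
        for (j in seq_len(n_runs)) {
            noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd)
                     else numeric(n)
            values[, j] <- 2^(base_log2 + effect[, j] + noise) * scale[j]
        }
        if (!is.null(cfg$missing_tau)) {
            for (j in seq_len(n_runs)) {
                p <- 1 / (1 + exp((log2(values[, j]) - cfg$missing_tau) /
                                      cfg$missing_s))
                u <- stats::runif(n)
                values[u < p, j] <- NA_real_
                if (all(is.na(values[, j])))
                    stop(sprintf("run '%s' lost every value to censoring",
                                 run_ids[j]))
            }
        }
        expected <- matrix(0, n, nb, dimnames = list(ids, baits))
        for (k in seq_len(nb)) {
            eff <- proximal[[baits[k]]]
            expected[names(eff), k] <- eff
            expected[baits[k], k] <- expected[baits[k], k] +
                cfg$bait_self_effect
        }
        list(values = values, proximal = proximal, expected = expected,
             scale = scale)
    })
    pe <- ProximityExperiment(out$values, run_meta,
                              endogenous_biotin = ids %in% biotin_ids)
    list(experiment = pe,
         truth = list(proximal = out$proximal,
                      expected_enrichment = out$expected,
                      scale_factors = stats::setNames(out$scale, run_ids),
                      seed = cfg$seed))
}

# Compact-support component templates over 20 fractions: free pool near the
# top, a 60S peak at fraction 9, 80S at 10-12, polysomes from 13 down.
# Supports are disjoint across the scored fraction groups so that each
# group's ratio reflects a single component.
defaultGradientTemplates <- function() {
    z <- numeric(20)
    free <- z; free[1:4] <- c(4, 8, 5, 2)
    s60 <- z; s60[7:9] <- c(2, 5, 8)
    s80 <- z; s80[10:12] <- c(10, 9, 4)
    poly <- z; poly[13:20] <- c(7, 7, 6, 5, 4, 3, 2, 1.5)
    list(free = free, s60 = s60, s80 = s80, poly = poly)
}

#' Configuration for the sucrose-gradient profile simulator
#'
#' The denominator protein (an obligatory subunit component) follows the
#' sum of the component templates; the numerator protein carries each
#' component scaled by its occupancy theta (fraction of denominator-bearing
#' particles that also carry the numerator). Polysomal occupancy defaults
#' to 1, the anchoring assumption of the normalization.
#'
#' Noise: one multiplicative log-normal draw of coefficient of variation
#' \code{cv} per (fraction, replicate), shared by the two profiles (lane-
#' level loading/recovery variation — both proteins are probed from the
#' same gradient-fraction lane), plus optional independent per-profile
#' detection noise of CV \code{detection_cv}.
#'
#' @param theta named occupancies in [0, 1] for free, s60, s80, poly.
#' @param cv lane-level noise CV (>= 0).
#' @param detection_cv per-profile detection noise CV (>= 0).
#' @param n_replicates replicate count.
#' @param templates component templates (named list of length-20
#'   non-negative vectors).
#' @param numerator,denominator protein ids used in the output profiles.
#' @param seed integer seed.
#' @return A list of class \code{"GradientSimConfig"}.
#' @export
gradientSimConfig <- function(theta = c(free = 1, s60 = 0.75, s80 = 0.75,
                                        poly = 1),
                              cv = 0.1, detection_cv = 0, n_replicates = 2,
                              templates = defaultGradientTemplates(),
                              numerator = "Rpl1", denominator = "Rpl4",
                              seed = 1L) {
    stopifnot(all(theta >= 0), all(theta <= 1), cv >= 0, detection_cv >= 0,
              n_replicates >= 1,
              all(vapply(templates, function(t)
                  length(t) == 20 && all(t >= 0), TRUE)))
    structure(list(theta = theta, cv = cv, detection_cv = detection_cv,
                   n_replicates = n_replicates, templates = templates,
                   numerator = numerator, denominator = denominator,
                   seed = as.integer(seed)),
              class = "GradientSimConfig")
}

#' Simulate gradient band-intensity profiles with known occupancy
#'
#' @param cfg a \code{\link{gradientSimConfig}}.
#' @return list(profiles = \linkS4class{GradientProfiles} with numerator
#'   and denominator rows per replicate, truth = list(theta, seed)).
#' @export
simulateGradient <- function(cfg) {
    tm <- cfg$templates
    den_clean <- Reduce(`+`, tm)
    num_clean <- Reduce(`+`, Map(function(th, t) th * t,
                                 as.list(cfg$theta[names(tm)]), tm))
    sd_lane <- sqrt(log(1 + cfg$cv^2))
    sd_det <- sqrt(log(1 + cfg$detection_cv^2))
    withSeed(cfg$seed, {
        rows <- list()
        for (r in seq_len(cfg$n_replicates)) {
            lane <- exp(stats::rnorm(20, -sd_lane^2 / 2, sd_lane))
            det_n <- if (sd_det > 0)
                exp(stats::rnorm(20, -sd_det^2 / 2, sd_det)) else rep(1, 20)
            det_d <- if (sd_det > 0)
                exp(stats::rnorm(20, -sd_det^2 / 2, sd_det)) else rep(1, 20)
            rep_id <- paste0("rep", r)
            rows[[length(rows) + 1]] <- list(cfg$numerator, rep_id,
                                             num_clean * lane * det_n)
            rows[[length(rows) + 1]] <- list(cfg$denominator, rep_id,
                                             den_clean * lane * det_d)
        }
        profiles <- GradientProfiles(
            vapply(rows, `[[`, "", 1),
            vapply(rows, `[[`, "", 2),
            do.call(rbind, lapply(rows, `[[`, 3)))
        list(profiles = profiles,
             truth = list(theta = cfg$theta, seed = cfg$seed))
    })
}
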