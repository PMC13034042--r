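# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Median by explicit sort (odd/even cases spelled out).
oracle_median <- function(x) {
    x <- sort(x)
    n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Linear-interpolation quantile between order statistics.
oracle_quantile <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exhaustive cNLS enumeration: every 4-window K-[KR]-x-[KR].
oracle_cnls <- function(seq) {
    res <- strsplit(seq, "")[[1]]
    starts <- integer()
    for (i in seq_len(max(0, length(res) - 3)))
        if (res[i] == "K" && res[i + 1] %in% c("K", "R") &&
            res[i + 3] %in% c("K", "R"))
            starts <- c(starts, i)
    starts
}

# Exhaustive bPY enumeration: returns data.frame(anchor, p_pos, phi_pos)
# for every [RKH]-x(2-5)-P-[Y,phi] with >= B basics in the W-window.
oracle_bpy <- function(seq, W, B) {
    res <- strsplit(seq, "")[[1]]
    n <- length(res)
    basic <- c("K", "R", "H")
    phi <- c("Y", "L", "I", "V", "F", "M", "W")
    out <- NULL
    for (i in seq_len(n)) for (g in 2:5) {
        pp <- i + g + 1; yp <- pp + 1
        if (yp > n || !res[i] %in% basic) next
        if (res[pp] != "P" || !res[yp] %in% phi) next
        win <- if (i > 1) res[max(1, i - W):(i - 1)] else character()
        if (sum(win %in% basic) >= B)
            out <- rbind(out, data.frame(anchor = i, p_pos = pp,
                                         phi_pos = yp))
    }
    out
}

# pH-grid zero-crossing scan for the isoelectric point.
oracle_pi_grid <- function(seq, pka = bjellqvistPkaSet(), step = 1e-4) {
    ph <- seq(0, 14, by = step)
    q <- netCharge(seq, ph, pka)
    i <- which(q <= 0)[1]           # charge decreasing in pH
    # linear interpolation between the bracketing grid points
    if (i == 1) return(ph[1])
    ph[i - 1] + (ph[i] - ph[i - 1]) * q[i - 1] / (q[i - 1] - q[i])
}

random_peptide <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]]) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Tiny ProximityExperiment straight from a values matrix.
make_pe <- function(values, roles = NULL) {
    if (is.null(roles))
        roles <- c(rep("bait", ncol(values) - 2), "control", "control")
    meta <- data.frame(run_id = colnames(values),
                       bait_name = colnames(values),
                       tag_terminus = "C", role = roles,
                       series_id = "S", replicate_index = 1L,
                       mode = "yeast")
    ProximityExperiment(values, meta)
}

# Synthetic stand-in for the C-terminal bPY-NLS segment described for the
# Bcl1 chaperone: 26 residues, eight lysines + three arginines, anchor R at
# local position 22 (residue 385 in full-length numbering), P at 25 (388),
# Y at 26 (389); positions 19-21 non-basic so the anchor is unique.
BPY_SEGMENT <- "SKKNKAKVRKKGKKTRQSASSRASPY"
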