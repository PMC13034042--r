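AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Average residue masses (Da), i.e. amino acid minus one water.
RESIDUE_MASS <- c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

HYDROPHOBIC <- c("L", "I", "V", "F", "M", "W")

checkProtein <- function(seq) {
    seq <- toupper(as.character(seq))
    res <- strsplit(seq, "")[[1]]
    if (!length(res))
        stop("empty sequence")
    bad <- setdiff(res, AA_ALPHABET)
    if (length(bad))
        stop("invalid residue(s): ", paste(unique(bad), collapse = ", "))
    res
}

#' The Bjellqvist pKa set
#'
#' The ionizable-group pKa values behind common protein pI/MW services;
#' the package default for \code{\link{netCharge}} and
#' \code{\link{isoelectricPoint}}. Free cysteine and tyrosine are treated
#' as ionizable.
#'
#' @return A \linkS4class{PkaSet}.
#' @export
bjellqvistPkaSet <- function() {
    new("PkaSet", n_term = 7.5, c_term = 3.55,
        side_chains = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
                        H = 5.98, K = 10.0, R = 12.0))
}

#' Henderson-Hasselbalch net charge of a protein at a given pH
#'
#' Positive groups (N-terminus, K, R, H) each contribute
#' 1 / (1 + 10^(pH - pKa)); negative groups (C-terminus, D, E, C, Y) each
#' contribute -1 / (1 + 10^(pKa - pH)). The result is the expected net
#' charge in elementary-charge units.
#'
#' @param seq protein sequence (character or AAString).
#' @param pH numeric pH (may be a vector).
#' @param pka a \linkS4class{PkaSet}; default \code{\link{bjellqvistPkaSet}}.
#' @return Numeric net charge, one value per pH.
#' @export
netCharge <- function(seq, pH, pka = bjellqvistPkaSet()) {
    res <- checkProtein(seq)
    counts <- table(factor(res, levels = AA_ALPHABET))
    pos <- function(pk, n) n / (1 + 10^(pH - pk))
    neg <- function(pk, n) -n / (1 + 10^(pk - pH))
    sc <- pka@side_chains
    unname(pos(pka@n_term, 1) + neg(pka@c_term, 1) +
        pos(sc[["K"]], counts[["K"]]) + pos(sc[["R"]], counts[["R"]]) +
        pos(sc[["H"]], counts[["H"]]) +
        neg(sc[["D"]], counts[["D"]]) + neg(sc[["E"]], counts[["E"]]) +
        neg(sc[["C"]], counts[["C"]]) + neg(sc[["Y"]], counts[["Y"]]))
}

#' Isoelectric point by bisection on the net-charge curve
#'
#' Bisects pH over [0, 14] (the net charge is strictly decreasing in pH)
#' until |charge| < 1e-6 or the bracketing interval is narrower than 1e-4.
#'
#' @inheritParams netCharge
#' @return The pI in pH units.
#' @export
isoelectricPoint <- function(seq, pka = bjellqvistPkaSet()) {
    res <- checkProtein(seq)
    # termini always ionize, but keep the guard generic for custom sets
    has_pos <- TRUE
    has_neg <- TRUE
    if (!has_pos || !has_neg)
        stop("pI undefined: need at least one positive and one negative group")
    lo <- 0; hi <- 14
    repeat {
        mid <- (lo + hi) / 2
        q <- netCharge(seq, mid, pka)
        if (abs(q) < 1e-6 || (hi - lo) < 1e-4)
            return(mid)
        if (q > 0) lo <- mid else hi <- mid
    }
}

#' Average molecular mass of a protein
#'
#' Sum of standard average residue masses plus one water (18.0153 Da).
#'
#' @param seq protein sequence (character or AAString).
#' @return Mass in Da.
#' @export
molecularWeight <- function(seq) {
    res <- checkProtein(seq)
    sum(RESIDUE_MASS[res]) + WATER_MASS
}

#' Scan for the classical monopartite NLS consensus K-K/R-x-K/R
#'
#' Reports every (overlapping) 4-residue window matching K, [KR], any,
#' [KR], in ascending start order. Coordinates are 1-based inclusive.
#'
#' @param seq protein sequence.
#' @return data.frame: kind, start, end, match.
#' @export
scanCNLS <- function(seq) {
    res <- checkProtein(seq)
    n <- length(res)
    hits <- list()
    if (n >= 4) for (i in seq_len(n - 3)) {
        if (res[i] == "K" && res[i + 1] %in% c("K", "R") &&
            res[i + 3] %in% c("K", "R"))
            hits[[length(hits) + 1]] <- data.frame(
                kind = "cNLS", start = i, end = i + 3,
                match = paste(res[i:(i + 3)], collapse = ""),
                stringsAsFactors = FALSE)
    }
    if (length(hits)) do.call(rbind, c(hits, list(make.row.names = FALSE)))
    else data.frame(kind = character(), start = integer(), end = integer(),
                    match = character())
}

#' Scan for the basic PY-NLS signature
#'
#' Reports every occurrence of [RKH] - x(2-5) - P - [Y or hydrophobic]
#' whose anchor ([RKH] position) is preceded, within the \code{window}
#' residues immediately upstream, by at least \code{min_basic} basic
#' residues (K/R/H). The hydrophobic class is \{L, I, V, F, M, W\} in
#' addition to Y. The hit spans the upstream window start through the
#' Y/hydrophobic position; \code{near_cterm} flags signatures ending
#' within 3 residues of the C-terminus (the configuration of a C-terminal
#' import signal). Coordinates are 1-based inclusive.
#'
#' @param seq protein sequence.
#' @param window W >= 1, upstream basic-enrichment window length.
#' @param min_basic B >= 0, minimum K/R/H count in the window.
#' @return data.frame: kind, start, end, match, anchor, p_pos, phi_pos,
#'   n_basic_upstream, cterm_distance, near_cterm.
#' @export
scanBPYNLS <- function(seq, window = 20L, min_basic = 4L) {
    stopifnot(window >= 1L, min_basic >= 0L)
    res <- checkProtein(seq)
    n <- length(res)
    basic <- c("K", "R", "H")
    phi <- c("Y", HYDROPHOBIC)
    hits <- list()
    for (i in seq_len(n)) {
        if (!res[i] %in% basic) next
        for (gap in 2:5) {
            p_pos <- i + gap + 1L
            y_pos <- p_pos + 1L
            if (y_pos > n) break
            if (res[p_pos] != "P" || !res[y_pos] %in% phi) next
            win_start <- max(1L, i - window)
            win <- if (i > 1L) res[win_start:(i - 1L)] else character()
            nb <- sum(win %in% basic)
            if (nb < min_basic) next
            hits[[length(hits) + 1]] <- data.frame(
                kind = "bPY", start = win_start, end = y_pos,
                match = paste(res[win_start:y_pos], collapse = ""),
                anchor = i, p_pos = p_pos, phi_pos = y_pos,
                n_basic_upstream = nb,
                cterm_distance = n - y_pos,
                near_cterm = (n - y_pos) <= 3L,
                stringsAsFactors = FALSE)
        }
    }
    if (length(hits)) do.call(rbind, c(hits, list(make.row.names = FALSE)))
    else data.frame(kind = character(), start = integer(), end = integer(),
                    match = character(), anchor = integer(),
                    p_pos = integer(), phi_pos = integer(),
                    n_basic_upstream = integer(), cterm_distance = integer(),
                    near_cterm = logical())
}

#' In-silico amplicon prediction by exact primer matching
#'
#' Finds every plus-strand occurrence of the forward primer and every
#' occurrence of the reverse complement of the reverse primer starting at
#' or after the forward match's 3' end + 1, and emits one amplicon per
#' pair, spanning the forward 5' end through the reverse-complement 3' end
#' inclusive (so both primers are part of the product). Matching is exact
#' and case-insensitive; the template is treated as a linear plus strand.
#'
#' @param template nucleotide sequence (character or DNAString), ACGT only.
#' @param forward,reverse primer sequences, written 5' to 3'.
#' @return data.frame sorted by length: start, end, length (bp). Empty
#'   (with a message) when either primer has no match.
#' @export
predictAmplicon <- function(template, forward, reverse) {
    tmpl <- Biostrings::DNAString(toupper(as.character(template)))
    fwd <- Biostrings::DNAString(toupper(as.character(forward)))
    rev_rc <- Biostrings::reverseComplement(
        Biostrings::DNAString(toupper(as.character(reverse))))
    f_hits <- Biostrings::matchPattern(fwd, tmpl)
    r_hits <- Biostrings::matchPattern(rev_rc, tmpl)
    empty <- data.frame(start = integer(), end = integer(),
                        length = integer())
    if (!length(f_hits) || !length(r_hits)) {
        message(sprintf("no amplicon: forward matches %d site(s), reverse %d",
                        length(f_hits), length(r_hits)))
        return(empty)
    }
    rows <- list()
    for (fi in seq_along(f_hits)) {
        f_start <- BiocGenerics::start(f_hits)[fi]
        f_end <- BiocGenerics::end(f_hits)[fi]
        for (ri in seq_along(r_hits)) {
            r_start <- BiocGenerics::start(r_hits)[ri]
            r_end <- BiocGenerics::end(r_hits)[ri]
            if (r_start >= f_end + 1L)
                rows[[length(rows) + 1]] <- data.frame(
                    start = f_start, end = r_end,
                    length = r_end - f_start + 1L)
        }
    }
    if (!length(rows)) {
        message("no amplicon: no reverse site downstream of a forward site")
        return(empty)
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out[order(out$length, out$start), , drop = FALSE]
}
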