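write_fixture <- function(df, dir = withr::local_tempdir(.local_envir =
                                                             parent.frame())) {
    path <- file.path(dir, "table.tsv")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

two_run_config <- function(cols = c("iBAQ run1", "iBAQ run2")) {
    list(runs = list(
        list(run_id = "run1", column = cols[1], bait_name = "B1",
             role = "bait", series_id = "S", replicate_index = 1),
        list(run_id = "run2", column = cols[2], bait_name = "GFP",
             role = "control", series_id = "S", replicate_index = 1)),
        endogenous_biotin_genes = list("ACC1"))
}

test_that("a hand-written fixture round-trips with flags and missing marks", {
    df <- data.frame(protein_id = c("P1", "P2", "P3"),
                     gene_name = c("ACC1", "GEN2", "GEN3"),
                     contaminant = c("", "+", ""),
                     reverse = c("", "", "+"),
                     `iBAQ run1` = c(10, 0, 3.5),
                     `iBAQ run2` = c(2, 5, 0),
                     check.names = FALSE)
    pe <- readIntensityTable(write_fixture(df), two_run_config())
    expect_equal(dim(pe), c(3L, 2L))
    v <- intensities(pe)
    expect_true(is.na(v["P2", "run1"]))   # recorded 0 == not detected
    expect_true(is.na(v["P3", "run2"]))
    expect_equal(v["P1", "run1"], 10)
    rd <- as.data.frame(SummarizedExperiment::rowData(pe))
    expect_equal(rd$contaminant, c(FALSE, TRUE, FALSE))
    expect_equal(rd$decoy, c(FALSE, FALSE, TRUE))
    expect_equal(rd$endogenous_biotin, c(TRUE, FALSE, FALSE))
})

test_that("validation errors name the offending cell or column", {
    df <- data.frame(protein_id = c("P1", "P2"), gene_name = c("a", "b"),
                     `iBAQ run1` = c(1, -5), `iBAQ run2` = c(1, 1),
                     check.names = FALSE)
    expect_error(readIntensityTable(write_fixture(df), two_run_config()),
                 "-5.*P2.*iBAQ run1")
    df2 <- data.frame(protein_id = c("P1", "P1"), gene_name = c("a", "b"),
                      `iBAQ run1` = c(1, 2), `iBAQ run2` = c(1, 1),
                      check.names = FALSE)
    expect_error(readIntensityTable(write_fixture(df2), two_run_config()),
                 "duplicate protein id 'P1'")
    df3 <- data.frame(protein_id = "P1", gene_name = "a",
                      `iBAQ run1` = 1, check.names = FALSE)
    expect_error(readIntensityTable(write_fixture(df3), two_run_config()),
                 "iBAQ run2")
})

test_that("read -> write -> read is the identity on 50 random fixtures", {
    dir <- withr::local_tempdir()
    for (k in 1:50) {
        set.seed(k)
        n <- sample(2:12, 1)
        m <- sample(2:5, 1)
        v <- matrix(round(rlnorm(n * m, 10, 2), 4), n, m,
                    dimnames = list(paste0("P", seq_len(n)),
                                    paste0("r", seq_len(m))))
        v[runif(n * m) < 0.2] <- NA
        if (any(colSums(!is.na(v)) == 0)) next
        meta <- data.frame(run_id = colnames(v), bait_name = colnames(v),
                           tag_terminus = "C",
                           role = c("control", rep("bait", m - 1)),
                           series_id = "S", replicate_index = 1L,
                           mode = "yeast")
        pe <- ProximityExperiment(v, meta,
                                  contaminant = runif(n) < 0.2,
                                  decoy = runif(n) < 0.1,
                                  endogenous_biotin = runif(n) < 0.1)
        path <- file.path(dir, sprintf("fx%02d.tsv", k))
        writeIntensityTable(pe, path)
        pe2 <- readIntensityTable(path, runConfig(pe))
        expect_equal(intensities(pe2), intensities(pe))
        expect_equal(as.data.frame(SummarizedExperiment::rowData(pe2)),
                     as.data.frame(SummarizedExperiment::rowData(pe)))
        expect_equal(runMeta(pe2), runMeta(pe))
    }
})

test_that("filterProteins drops exactly the selected flag classes", {
    v <- matrix(1:10, 5, 2,
                dimnames = list(paste0("P", 1:5), c("b", "c")))
    meta <- data.frame(run_id = c("b", "c"), bait_name = c("B", "G"),
                       role = c("bait", "control"), series_id = "S",
                       replicate_index = 1L)
    pe <- ProximityExperiment(v, meta,
                              contaminant = c(TRUE, TRUE, FALSE, FALSE,
                                              FALSE))
    out <- filterProteins(pe, drop_contaminants = TRUE)
    expect_equal(nrow(out), 3L)
    expect_equal(nrow(pe), 5L)                      # original untouched
    # all flags false, all drops requested -> identity
    pe0 <- ProximityExperiment(v, meta)
    out0 <- filterProteins(pe0, TRUE, TRUE, TRUE)
    expect_equal(intensities(out0), intensities(pe0))
})

test_that("random flag assignments match the brute-force surviving set", {
    meta <- data.frame(run_id = c("b", "c"), bait_name = c("B", "G"),
                       role = c("bait", "control"), series_id = "S",
                       replicate_index = 1L)
    for (k in 1:20) {
        set.seed(100 + k)
        n <- 30
        v <- matrix(rlnorm(n * 2), n, 2,
                    dimnames = list(paste0("P", 1:n), c("b", "c")))
        fl <- list(contaminant = runif(n) < 0.3, decoy = runif(n) < 0.3,
                   endogenous_biotin = runif(n) < 0.3)
        drops <- runif(3) < 0.5
        pe <- ProximityExperiment(v, meta, contaminant = fl$contaminant,
                                  decoy = fl$decoy,
                                  endogenous_biotin = fl$endogenous_biotin)
        out <- filterProteins(pe, drops[1], drops[2], drops[3])
        want <- rownames(v)[!((drops[1] & fl$contaminant) |
                              (drops[2] & fl$decoy) |
                              (drops[3] & fl$endogenous_biotin))]
        expect_identical(rownames(out), want)
        # surviving rows keep their values exactly
        expect_identical(intensities(out), intensities(pe)[want, ])
    }
})

test_that("enrichment tables write deterministically and read back", {
    rec <- data.frame(protein_id = c("P2", "P1", "P3"),
                      gene_name = c("g2", "g1", "g3"), bait = "B",
                      normalized_abundance = c(2, 1, 8),
                      log10_abundance = log10(c(2, 1, 8)),
                      log2_enrichment = c(3, 3, 5),
                      n_reference_runs = 2L,
                      any_imputed_reference = FALSE)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeEnrichmentTable(rec, path)
    back <- readEnrichmentTable(path)
    # descending enrichment; the two tied records ordered by protein id
    expect_equal(back$protein_id, c("P3", "P1", "P2"))
    expect_equal(back$log2_enrichment, c(5, 3, 3))
    expect_equal(back$normalized_abundance, c(8, 1, 2))

    writeEnrichmentTable(rec[0, ], path)
    empty <- readEnrichmentTable(path)
    expect_equal(nrow(empty), 0L)
    expect_equal(colnames(empty)[1], "protein_id")

    # round trip at 6 significant digits on random records
    set.seed(7)
    rnd <- data.frame(protein_id = paste0("P", 1:40),
                      gene_name = paste0("g", 1:40), bait = "B",
                      normalized_abundance = rlnorm(40),
                      log10_abundance = 0, log2_enrichment = rnorm(40),
                      n_reference_runs = 2L,
                      any_imputed_reference = sample(c(TRUE, FALSE), 40,
                                                     TRUE))
    rnd$log10_abundance <- log10(rnd$normalized_abundance)
    writeEnrichmentTable(rnd, path)
    back <- readEnrichmentTable(path)
    ord <- order(-rnd$log2_enrichment, rnd$protein_id)
    expect_equal(back$log2_enrichment, signif(rnd$log2_enrichment[ord], 6))
    expect_equal(back$normalized_abundance,
                 signif(rnd$normalized_abundance[ord], 6))
    expect_equal(back$any_imputed_reference, rnd$any_imputed_reference[ord])
})
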