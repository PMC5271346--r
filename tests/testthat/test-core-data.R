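test_that("TSV count tables round-trip and preserve taxa order", {
  m <- rbind(a = c(3L, 10L), b = c(0L, 7L), c = c(5L, 5L))
  colnames(m) <- c("Ureaplasma", "Staphylococcus")
  path <- write_tsv_fixture(m, tempfile(fileext = ".tsv"))
  tab <- read_count_table(path, format = "tsv")
  expect_s3_class(tab, "taxon_count_table")
  expect_equal(n_samples(tab), 3)
  expect_equal(n_taxa(tab), 2)
  expect_identical(colnames(tab$counts), c("Ureaplasma", "Staphylococcus"))
  expect_identical(unname(tab$counts), unname(m))

  path2 <- tempfile(fileext = ".tsv")
  write_count_table(tab, path2)
  expect_identical(read_count_table(path2)$counts, tab$counts)

  ## transposed layout only via the explicit flag
  tpath <- tempfile(fileext = ".tsv")
  tm <- t(m)
  utils::write.table(data.frame(taxon_id = rownames(tm), tm,
                                check.names = FALSE),
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  tab_t <- read_count_table(tpath, transposed = TRUE)
  expect_identical(tab_t$counts, tab$counts)
})

test_that("count table validation rejects malformed input", {
  m <- rbind(c(1L, 2L), c(3L, 4L))
  expect_error(taxon_count_table(m, sample_ids = c("a", "a")),
               "duplicated sample")
  expect_error(taxon_count_table(rbind(c(1, 2), c(0, 0)),
                                 sample_ids = c("s1", "s2")),
               "s2")
  expect_error(taxon_count_table(rbind(c(-1, 2), c(3, 4)),
                                 sample_ids = c("s1", "s2"),
                                 taxon_ids = c("t1", "t2")),
               "negative count.*s1.*t1")
  expect_error(taxon_count_table(rbind(c(1.5, 2), c(3, 4))), "non-integer")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB", "s1\t3\tx", "s2\t1\t2"), bad)
  expect_error(read_count_table(bad), "malformed.*B")
})

test_that("BIOM reader agrees with the TSV reader", {
  m <- rbind(s1 = c(5L, 2L, 0L), s2 = c(1L, 0L, 9L))
  colnames(m) <- c("A", "B", "C")
  bpath <- tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(t(m)), bpath)
  tab <- read_count_table(bpath, format = "biom")
  expect_equal(unname(tab$counts[rownames(m), colnames(m)]), unname(m))
})

test_that("relative abundance is percent of the sample total", {
  tab <- taxon_count_table(rbind(s1 = c(30L, 70L)))
  expect_equal(unname(relative_abundance(tab)[1, ]), c(30, 70))
  expect_equal(unname(relative_abundance(rbind(c(5, 0, 0)))[1, ]),
               c(100, 0, 0))
  expect_equal(unname(relative_abundance(rbind(c(1, 1, 2)))[1, ]),
               c(25, 25, 50))
  ## rows always sum to 100
  for (seed in 1:5) {
    ra <- relative_abundance(random_count_table(7, 11, seed))
    expect_equal(unname(rowSums(ra)), rep(100, 7), tolerance = 1e-9)
  }
  expect_error(relative_abundance(rbind(bad = c(0, 0))), "bad")
})

test_that("collapse_rare pools taxa rare in every sample and conserves totals", {
  ## T3 has max RA 0.5%; T4 is 0.5% in one sample but >1% elsewhere
  m <- rbind(s1 = c(600L, 389L, 5L, 6L),
             s2 = c(700L, 280L, 5L, 15L))
  colnames(m) <- c("T1", "T2", "T3", "T4")
  tab <- taxon_count_table(m)
  out <- collapse_rare(tab, threshold_pct = 1)
  expect_identical(colnames(out$counts), c("T1", "T2", "T4", "rare"))
  expect_identical(out$rare_taxon, "rare")
  expect_identical(unname(out$counts[, "rare"]), c(5L, 5L))
  expect_identical(rowSums(out$counts), rowSums(tab$counts))

  ## totals conserved exactly on random fixtures
  for (seed in 6:9) {
    tb <- random_count_table(6, 20, seed)
    cl <- collapse_rare(tb, threshold_pct = 5)
    expect_identical(rowSums(cl$counts), rowSums(tb$counts))
  }

  ## nothing rare: unchanged, no all-zero rare column appended
  tab2 <- taxon_count_table(rbind(s1 = c(50L, 50L)))
  out2 <- collapse_rare(tab2)
  expect_identical(colnames(out2$counts), colnames(tab2$counts))
})

test_that("subject series partition samples and sort by day", {
  m <- rbind(a1 = c(5L, 1L), a2 = c(2L, 2L), b1 = c(1L, 9L))
  tab <- taxon_count_table(m)
  md <- data.frame(sample_id = c("a1", "a2", "b1"),
                   subject_id = c("A", "A", "B"),
                   collection_day = c(14, 7, 3),
                   group = c("mild", "mild", "severe"))
  ser <- build_subject_series(tab, md, min_samples = 1)
  expect_named(ser, c("A", "B"))
  ## unsorted input days 14, 7 come out ordered 7, 14
  expect_equal(ser$A$days, c(7, 14))
  expect_identical(ser$A$sample_ids, c("a2", "a1"))
  ## partition: every sample in exactly one series
  all_ids <- unlist(lapply(ser, `[[`, "sample_ids"))
  expect_setequal(all_ids, rownames(m))
  expect_false(anyDuplicated(all_ids) > 0)
  ## min_samples filter drops singleton subjects
  ser2 <- build_subject_series(tab, md, min_samples = 2)
  expect_named(ser2, "A")

  md_orphan <- md[-1, ]
  expect_error(build_subject_series(tab, md_orphan), "a1")
  md_dup <- md
  md_dup$collection_day <- c(7, 7, 3)
  expect_error(build_subject_series(tab, md_dup), "ambiguous")
})

test_that("series partition holds on a simulated cohort", {
  coh <- generate_cohort(small_cohort_config(seed = 3))
  ser <- build_subject_series(coh$table, coh$metadata, min_samples = 2)
  ids <- unlist(lapply(ser, `[[`, "sample_ids"))
  expect_false(anyDuplicated(ids) > 0)
  kept_subjects <- names(which(table(coh$metadata$subject_id) >= 2))
  expect_setequal(names(ser), kept_subjects)
})
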