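test_that("matrix TSV round-trips preserve values, order and missing cells", {
  m <- make_expr(c("TP53", "PTEN", "AR"), n_samples = 3)
  m[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path)
  expect_equal(unclass(back)[, ], unclass(m)[, ], tolerance = 1e-12)
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))
  expect_true(is.na(back[2, 3]))

  cna <- cna_matrix(matrix(c(-2L, -1L, 0L, 1L, 2L, NA), 2,
                           dimnames = list(c("PTEN", "TP53"),
                                           c("S1", "S2", "S3"))))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_gistic_matrix(cna, path2)
  back2 <- read_gistic_matrix(path2)
  expect_identical(unclass(back2)[, ], unclass(cna)[, ])
})

test_that("expression parsing rejects malformed input and honours NA tokens", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS1", "A\t1\t2"), path)
  expect_error(read_expression(path), "S1")

  writeLines(c("gene\tS1\tS2", "A\t1\t2", "B\t3"), path)
  expect_error(read_expression(path), "ragged")

  writeLines(c("gene\tS1\tS2", "A\tNA\t2"), path)
  m <- read_expression(path)
  expect_true(is.na(m["A", "S1"]))
  expect_identical(m["A", "S2"], 2)

  writeLines(c("gene\tS1", "A\tfoo"), path)
  expect_error(read_expression(path), "non-numeric")
})

test_that("GISTIC reader enforces the discrete call range", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "PTEN\t-2\t-1", "MYC\t1\t2"), path)
  m <- read_gistic_matrix(path)
  expect_identical(m["PTEN", "S1"], -2L)  # deep loss call survives intact
  writeLines(c("gene\tS1", "PTEN\t3"), path)
  expect_error(read_gistic_matrix(path), "outside")
  writeLines(c("gene\tS1", "PTEN\t0.5"), path)
  expect_error(read_gistic_matrix(path), "non-integer")
})

test_that("MAF reader maps columns, preserves Silent, rejects bad schema", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "TP53\tS1\tMissense_Mutation",
               "SPOP\tS2\tSilent"), path)
  mt <- read_maf(path)
  expect_equal(nrow(mt), 2L)
  expect_identical(mt$variant_class[mt$gene_symbol == "SPOP"], "Silent")

  writeLines(c("Hugo_Symbol\tVariant_Classification", "TP53\tSilent"), path)
  expect_error(read_maf(path), "Tumor_Sample_Barcode")

  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "TP53\tS1\tIn_Frame_Del"), path)
  expect_warning(mt2 <- read_maf(path), "Other")
  expect_identical(mt2$variant_class, "Other")
})

test_that("clinical validation reports violations as data, not errors", {
  good <- make_clinical(c("S1", "S2"), grade = c("7", ">=8"),
                        time = c(10, 20), event = c(0L, 1L))
  expect_identical(nrow(validate_clinical(good)), 0L)

  bad <- good
  bad$bcr_event[1] <- 2L
  bad$sample_type[2] <- "Primary"
  rep <- validate_clinical(bad)
  expect_setequal(rep$field, c("bcr_event", "sample_type"))
  expect_match(rep$message[rep$field == "sample_type"], "did you mean 'primary'")

  dup <- good
  dup$sample_id <- c("S1", "S1")
  expect_true("unique" %in% validate_clinical(dup)$rule_violated)

  gl <- good
  gl$gleason_primary <- c(3L, 4L)
  gl$gleason_secondary <- c(4L, 4L)
  gl$gleason_sum <- c(7L, 9L)
  expect_true("gleason_consistency" %in% validate_clinical(gl)$rule_violated)
})

test_that("gene harmonization renames aliases, collapses and logs", {
  dict <- gene_dictionary(canonical = c("B", "C"), alias = c("B-ALT", "C-OLD"))
  m <- expression_matrix(matrix(c(1, 4, 3, 6), 2, byrow = FALSE,
                                dimnames = list(c("B", "B-ALT"),
                                                c("S1", "S2"))))
  # rows B=[1,3], B-ALT=[4,6]; mean collapse -> B=[2.5, 4.5]
  res <- harmonize_genes(m, dict, collapse_rule = "mean")
  expect_identical(rownames(res$matrix), "B")
  expect_equal(unname(unclass(res$matrix)["B", ]), c(2.5, 4.5))
  expect_true(any(res$log$action == "collapsed_mean"))

  # spec worked example: values [1,3] and [3,5] average to [2,4]
  m2 <- expression_matrix(matrix(c(1, 3, 3, 5), 2,
                                 dimnames = list(c("B", "B-ALT"),
                                                 c("S1", "S2"))))
  res2 <- harmonize_genes(m2, dict)
  expect_equal(unname(unclass(res2$matrix)["B", ]), c(2, 4))

  # identity dictionary: no-op, empty log
  iddict <- gene_dictionary(canonical = c("X", "Y"), alias = c("X", "Y"))
  m3 <- make_expr(c("X", "Y"))
  res3 <- harmonize_genes(m3, iddict)
  expect_equal(unclass(res3$matrix)[, ], unclass(m3)[, ], tolerance = 1e-12)
  expect_identical(nrow(res3$log), 0L)
  expect_identical(rownames(res3$matrix), rownames(m3))

  # ambiguous alias with no priority: dropped and logged
  amb <- gene_dictionary(canonical = c("A1", "A2"), alias = c("AX", "AX"))
  m4 <- make_expr(c("AX", "Y"))
  res4 <- harmonize_genes(m4, amb)
  expect_false("AX" %in% rownames(res4$matrix))
  expect_true(any(res4$log$action == "ambiguous_dropped"))

  # priority flag resolves the ambiguity instead
  pri <- gene_dictionary(canonical = c("A1", "A2"), alias = c("AX", "AX"),
                         priority = c(TRUE, FALSE))
  res5 <- harmonize_genes(m4, pri)
  expect_true("A1" %in% rownames(res5$matrix))

  # max_variance keeps the most variable duplicate row
  mv <- expression_matrix(matrix(c(1, 10, 1.1, 20, 0.9, 30), 2,
                                 dimnames = list(c("B", "B-ALT"),
                                                 c("S1", "S2", "S3"))))
  res6 <- harmonize_genes(mv, dict, collapse_rule = "max_variance")
  expect_equal(unname(unclass(res6$matrix)["B", ]), c(10, 20, 30))
})

test_that("harmonization is idempotent", {
  dict <- gene_dictionary(canonical = c("NKX3-1", "CDK1"),
                          alias = c("NKX3.1", "CDC2"))
  m <- make_expr(c("NKX3.1", "CDK1", "CDC2", "UNKNOWN1"), n_samples = 5)
  once <- harmonize_genes(m, dict)$matrix
  twice <- harmonize_genes(once, dict)$matrix
  expect_identical(rownames(once), rownames(twice))
  expect_equal(unclass(once)[, ], unclass(twice)[, ], tolerance = 1e-12)
})

test_that("Gleason mapping follows sum > primary+secondary > ISUP precedence", {
  expect_identical(map_gleason(primary = 3, secondary = 4), "7")
  expect_identical(map_gleason(isup = 5), ">=8")
  expect_identical(map_gleason(sum = 6), "<=6")
  expect_identical(map_gleason(isup = 1), "<=6")
  expect_identical(map_gleason(isup = 2), "7")
  expect_identical(map_gleason(isup = 3), "7")
  expect_identical(map_gleason(isup = 4), ">=8")
  # reported sum wins over components and ISUP
  expect_identical(map_gleason(primary = 4, secondary = 5, sum = 6, isup = 5),
                   "<=6")
  expect_identical(map_gleason(), NA_character_)
  expect_error(map_gleason(sum = 12), "2..10")
  # consistency: any decomposition of s agrees with sum = s
  for (p in 1:5) for (s in 1:5) {
    tot <- p + s
    if (tot >= 2 && tot <= 10)
      expect_identical(map_gleason(primary = p, secondary = s),
                       map_gleason(sum = tot))
  }
})

test_that("study bundles enforce sample containment and report counts", {
  clin <- make_clinical(paste0("S", 1:12))
  clin$sample_type <- c(rep("primary", 10), "normal", "normal")
  m <- make_expr(c("A", "B"), n_samples = 12)
  colnames(m) <- paste0("S", 1:12)
  b <- build_study("demo", expression = m, clinical = clin)
  cnt <- study_counts(b)
  expect_identical(cnt$gex, 12L)
  expect_identical(as.integer(cnt$primary), 10L)
  expect_identical(as.integer(cnt$normal), 2L)

  bad <- make_expr(c("A"), n_samples = 2)
  colnames(bad) <- c("S1", "S99")
  expect_error(build_study("demo", expression = bad, clinical = clin), "S99")
  expect_error(build_study("demo", clinical = clin), "at least one assay")
})

test_that("study bundle directory round-trip reproduces all assays", {
  cfg <- sim_config(n_studies = 1, n_samples = 20, n_genes = 50, seed = 3)
  st <- simulate_multistudy(cfg)[[1]]
  dir <- withr::local_tempdir()
  write_study_bundle(st, dir)
  back <- read_study_bundle(st$name, dir)
  expect_equal(unclass(back$expression)[, ], unclass(st$expression)[, ],
               tolerance = 1e-9)
  expect_identical(unclass(back$cna)[, ], unclass(st$cna)[, ])
  expect_identical(back$mutations$gene_symbol, st$mutations$gene_symbol)
  expect_identical(back$clinical$grade_group, st$clinical$grade_group)
  expect_identical(nrow(validate_clinical(back$clinical)), 0L)
})
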