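make_two_group_matrix <- function(genes = 40, nh = 6, nl = 6, seed = 1) {
  set.seed(seed)
  g <- sprintf("G%03d", seq_len(genes))
  samples <- c(paste0("H", seq_len(nh)), paste0("L", seq_len(nl)))
  m <- matrix(rnorm(genes * (nh + nl), 7, 1), genes,
              dimnames = list(g, samples))
  groups <- setNames(rep(c(">=8", "<=6"), c(nh, nl)), samples)
  list(matrix = expression_matrix(m), groups = groups)
}

test_that("symmetric groups give zero logFC and p = 1; means drive logFC", {
  fx <- make_two_group_matrix(nh = 4, nl = 4)
  X <- unclass(fx$matrix)
  X[, 5:8] <- X[, 1:4]  # low group duplicates high group
  de <- differential_expression(expression_matrix(X), groups = fx$groups)
  expect_true(all(abs(de$logFC) < 1e-12))
  expect_true(all(de$t == 0))
  expect_true(all(de$p == 1))

  Y <- unclass(fx$matrix)
  Y["G001", 1:4] <- c(5, 5, 5.2, 4.8)
  Y["G001", 5:8] <- c(3, 3, 3.2, 2.8)
  de2 <- differential_expression(expression_matrix(Y), groups = fx$groups)
  expect_equal(de2$logFC[de2$gene == "G001"], 2, tolerance = 1e-12)
})

test_that("moderated t matches a literal transcription of the recipe to 1e-10", {
  fx <- make_two_group_matrix(genes = 50, nh = 5, nl = 7, seed = 42)
  X <- unclass(fx$matrix)
  de <- differential_expression(fx$matrix, groups = fx$groups)
  orc <- oracle_moderated_t(X[, 1:5], X[, 6:12])
  expect_equal(attr(de, "prior")$d0, orc$d0, tolerance = 1e-10)
  expect_equal(attr(de, "prior")$s02, orc$s02, tolerance = 1e-10)
  expect_equal(de$logFC, unname(orc$logFC), tolerance = 1e-12)
  expect_equal(de$t, unname(orc$t), tolerance = 1e-10)
  expect_equal(de$p, unname(orc$p), tolerance = 1e-10)
})

test_that("variance shrinkage agrees with limma's empirical-Bayes machinery", {
  skip_if_not_installed("limma")
  fx <- make_two_group_matrix(genes = 200, nh = 6, nl = 6, seed = 8)
  de <- differential_expression(fx$matrix, groups = fx$groups)
  sq <- limma::squeezeVar(de$s2, df = de$df)
  expect_equal(attr(de, "prior")$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior")$s02, sq$var.prior, tolerance = 1e-6)
  post <- (attr(de, "prior")$d0 * attr(de, "prior")$s02 +
             de$df * de$s2) / (attr(de, "prior")$d0 + de$df)
  expect_equal(post, sq$var.post, tolerance = 1e-8)
})

test_that("moderated t recovers its classical limits", {
  fx <- make_two_group_matrix(genes = 30, nh = 5, nl = 5, seed = 6)
  X <- unclass(fx$matrix)
  # d0 = 0: ordinary pooled-variance two-sample t-test
  de0 <- differential_expression(fx$matrix, groups = fx$groups,
                                 d0_override = 0)
  classic <- vapply(seq_len(nrow(X)), function(i)
    t.test(X[i, 1:5], X[i, 6:10], var.equal = TRUE)$p.value, numeric(1))
  expect_equal(de0$p, classic, tolerance = 1e-10)
  # d0 = Inf: all variances shrunk to the prior, normal reference
  deInf <- differential_expression(fx$matrix, groups = fx$groups,
                                   d0_override = Inf)
  s02 <- attr(deInf, "prior")$s02
  z <- deInf$logFC / sqrt(s02 * (1 / 5 + 1 / 5))
  expect_equal(deInf$p, 2 * pnorm(abs(z), lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("posterior variance is a convex combination of s2 and the prior", {
  fx <- make_two_group_matrix(genes = 100, nh = 4, nl = 6, seed = 13)
  de <- differential_expression(fx$matrix, groups = fx$groups)
  pr <- attr(de, "prior")
  post <- (pr$d0 * pr$s02 + de$df * de$s2) / (pr$d0 + de$df)
  expect_true(all(post >= pmin(de$s2, pr$s02) - 1e-12))
  expect_true(all(post <= pmax(de$s2, pr$s02) + 1e-12))
})

test_that("Fisher's method matches its closed forms and validates input", {
  expect_equal(fisher_combine(c(1, 1, 1)),
               list(statistic = 0, p = 1))
  # k = 1: chi^2 with 2 df identity, combined p equals the input
  for (p in c(0.9, 0.5, 0.05, 1e-4))
    expect_equal(fisher_combine(p)$p, p, tolerance = 1e-12)
  # df = 4 closed form exp(-x/2) (1 + x/2)
  res <- fisher_combine(c(0.05, 0.05))
  expect_equal(res$statistic, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(res$statistic, 11.983, tolerance = 1e-4)
  expect_equal(res$p, exp(-res$statistic / 2) * (1 + res$statistic / 2),
               tolerance = 1e-12)
  expect_equal(res$p, 0.01747, tolerance = 1e-3)
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
  expect_error(fisher_combine(numeric(0)), "at least one")
})

test_that("Fisher combination is permutation-invariant and monotone", {
  set.seed(4)
  p <- runif(5)
  expect_equal(fisher_combine(p), fisher_combine(rev(p)))
  lower <- p; lower[3] <- lower[3] / 10
  expect_lt(fisher_combine(lower)$p, fisher_combine(p)$p)
})

test_that("BH adjustment matches the hand example and brute-force step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_true(max(bh_adjust(runif(100, 0.9, 1))) <= 1)
})

test_that("meta-DE enforces sign consistency and q-thresholding", {
  mk <- function(logfc, p, study) {
    structure(data.frame(gene = c("GA", "GB", "GC"), logFC = logfc,
                         s2 = 1, df = 10, t = 0, p = p, n_high = 6,
                         n_low = 6, stringsAsFactors = FALSE),
              study = study, prior = list(d0 = 4, s02 = 1),
              class = c("study_de", "data.frame"))
  }
  studies <- list(mk(c(1, 1, 1), c(1e-6, 1e-6, 1), "s1"),
                  mk(c(1, 1, 1), c(1e-6, 1e-6, 1), "s2"),
                  mk(c(1, 1, 1), c(1e-6, 1e-6, 1), "s3"),
                  mk(c(1, -1, 1), c(1e-6, 1e-6, 1), "s4"))
  res <- meta_de(studies, q_threshold = 0.01)
  sel <- attr(res, "selected")
  # GA: consistent and significant; GB: mixed sign, excluded regardless of q
  expect_identical(sel$up, "GA")
  expect_identical(res$sign_consistent[res$gene == "GB"], "mixed")
  expect_false(res$selected[res$gene == "GB"])
  # GC: p = 1 everywhere -> q = 1, excluded
  expect_equal(res$q[res$gene == "GC"], 1)
  expect_false(res$selected[res$gene == "GC"])

  disjoint <- list(mk(c(1, 1, 1), c(0.5, 0.5, 0.5), "a"),
                   mk(c(1, 1, 1), c(0.5, 0.5, 0.5), "b"))
  disjoint[[2]]$gene <- c("ZA", "ZB", "ZC")
  expect_error(meta_de(disjoint), "intersection")
})

test_that("meta-DE recovers planted genes across synthetic studies", {
  cfg <- sim_config(n_studies = 4, n_samples = 150, n_genes = 800,
                    de_genes = 40, de_logfc = 1, seed = 21)
  studies <- simulate_multistudy(cfg)
  planted <- attr(studies[[1]], "truth")$planted$gene
  des <- lapply(studies, differential_expression)
  res <- meta_de(des, q_threshold = 0.01)
  sel <- unlist(attr(res, "selected"))
  expect_gte(mean(planted %in% sel), 0.9)
  nulls <- setdiff(res$gene, planted)
  expect_lte(mean(nulls %in% sel), 0.01)
})

test_that("pairwise logFC correlation matches hand Pearson values", {
  mk <- function(genes, logfc, study)
    structure(data.frame(gene = genes, logFC = logfc, s2 = 1, df = 10,
                         t = 0, p = 0.5, n_high = 6, n_low = 6,
                         stringsAsFactors = FALSE),
              study = study, class = c("study_de", "data.frame"))
  a <- mk(c("A", "B", "C"), c(1, 2, 3), "a")
  expect_equal(pairwise_logfc_correlation(a, a)$r, 1, tolerance = 1e-12)
  b <- mk(c("A", "B", "C"), c(1, 2, 4), "b")
  res <- pairwise_logfc_correlation(a, b)
  expect_equal(res$r, 3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(res$r, 0.982, tolerance = 1e-3)
  expect_identical(res$n_common, 3L)
  d <- mk(c("X", "Y", "Z"), c(1, 2, 3), "d")
  expect_error(pairwise_logfc_correlation(a, d), "common genes")
})

test_that("anchor correlation profiles behave at the exact limits", {
  set.seed(3)
  base <- rnorm(8)
  X <- rbind(AR = base, SAME = base, NEG = -base, CONST = rep(1, 8),
             OTHER = rnorm(8))
  colnames(X) <- paste0("S", 1:8)
  expect_message(
    prof <- anchor_correlation_profile(expression_matrix(X), "AR"),
    "undefined")
  expect_false("AR" %in% names(prof))
  expect_equal(unname(prof["SAME"]), 1, tolerance = 1e-12)
  expect_equal(unname(prof["NEG"]), -1, tolerance = 1e-12)
  expect_true(is.na(prof["CONST"]))
  expect_error(anchor_correlation_profile(expression_matrix(X), "NOPE"),
               "anchor")
})

test_that("profile cross-correlation is rank-invariant with unit diagonal", {
  p1 <- setNames(c(0.9, 0.1, -0.5, 0.3), c("A", "B", "C", "D"))
  same <- p1
  mono <- tanh(2 * p1) + 5     # strictly monotone transform
  rev <- setNames(c(-0.9, -0.1, 0.5, -0.3), names(p1))
  m <- cross_study_profile_correlation(list(s1 = p1, s2 = same, s3 = mono,
                                            s4 = rev))
  expect_equal(diag(m), setNames(rep(1, 4), paste0("s", 1:4)))
  expect_equal(m["s1", "s2"], 1)
  expect_equal(m["s1", "s3"], 1)
  expect_equal(m["s1", "s4"], -1)
  expect_equal(m, t(m))
})
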