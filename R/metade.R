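# Cross-study differential expression: per-study empirical-Bayes moderated
# t between Gleason grade groups, Fisher's method across studies, BH
# correction, sign-consistency selection, and the pairwise logFC /
# anchor-correlation analyses.

# Newton inversion of trigamma(x) = y (y > 0), tolerance 1e-8
trigamma_inverse <- function(y) {
  if (y <= 0) stop("trigamma_inverse needs y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  repeat {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) return(x)
  }
}

# moment-matching of log s^2 against a scaled F / log-chi^2 model:
# e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2);
# var(e) - trigamma(d/2) = trigamma(d0/2)  =>  d0 by trigamma inversion;
# s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)).
# Non-positive moment estimate -> d0 = Inf, s0^2 = exp(mean(e)).
estimate_variance_prior <- function(s2, df) {
  s2 <- unname(s2); df <- unname(df)
  ok <- is.finite(s2) & s2 > 0
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(ebar)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Per-study moderated-t differential expression between grade groups
#'
#' Per gene: logFC = mean(log2 expression in the high group) - mean(low
#' group); pooled two-group variance with `n_high + n_low - 2` df; an
#' empirical-Bayes prior `(d0, s0^2)` estimated by moment-matching the
#' distribution of log variances (trigamma inversion by Newton iteration);
#' posterior variance `(d0 s0^2 + d s^2)/(d0 + d)`; moderated
#' `t = logFC / (s_tilde sqrt(1/n_h + 1/n_l))` with a two-sided p on
#' `d0 + d` df. Missing values are handled complete-case per gene per group.
#'
#' @param study a `study_bundle` with expression and grade groups, or an
#'   [expression_matrix()] when `groups` is supplied.
#' @param high_label,low_label grade groups contrasted (default `>=8` vs
#'   `<=6`).
#' @param groups optional per-sample group labels overriding the clinical
#'   table (named by sample).
#' @param d0_override force the prior df: `0` recovers the ordinary pooled
#'   t-test, `Inf` a normal test with variances fully shrunk to the prior.
#' @return `study_de`: per-gene data.frame `(gene, logFC, s2, df, t, p,
#'   n_high, n_low)` with the prior in `attr(, "prior")`.
#' @export
differential_expression <- function(study, high_label = ">=8",
                                    low_label = "<=6", groups = NULL,
                                    d0_override = NULL) {
  if (inherits(study, "study_bundle")) {
    if (is.null(study$expression)) stop("study has no expression assay")
    m <- study$expression
    if (is.null(groups)) {
      groups <- setNames(study$clinical$grade_group, study$clinical$sample_id)
      groups <- groups[colnames(m)]
    }
    study_name <- study$name
  } else {
    m <- study
    if (is.null(groups)) stop("groups required when passing a bare matrix")
    groups <- groups[colnames(m)]
    study_name <- "study"
  }
  hi <- names(groups)[!is.na(groups) & groups == high_label]
  lo <- names(groups)[!is.na(groups) & groups == low_label]
  if (length(hi) < 2L || length(lo) < 2L)
    stop("need >= 2 samples per group (high: ", length(hi),
         ", low: ", length(lo), ")")
  X <- unclass(m)
  xh <- X[, hi, drop = FALSE]
  xl <- X[, lo, drop = FALSE]
  nh <- rowSums(!is.na(xh))
  nl <- rowSums(!is.na(xl))
  usable <- nh >= 2L & nl >= 2L
  if (any(!usable))
    message(sum(!usable), " gene(s) excluded for insufficient non-missing values")
  xh <- xh[usable, , drop = FALSE]; xl <- xl[usable, , drop = FALSE]
  nh <- nh[usable]; nl <- nl[usable]
  mh <- rowMeans(xh, na.rm = TRUE)
  ml <- rowMeans(xl, na.rm = TRUE)
  logfc <- mh - ml
  ssh <- rowSums((xh - mh)^2, na.rm = TRUE)
  ssl <- rowSums((xl - ml)^2, na.rm = TRUE)
  df <- nh + nl - 2
  s2 <- (ssh + ssl) / df
  if (length(unique(df)) == 1L) {
    prior <- if (is.null(d0_override)) estimate_variance_prior(s2, df[1])
             else list(d0 = d0_override,
                       s02 = estimate_variance_prior(s2, df[1])$s02)
  } else {
    # unequal residual df across genes (missingness): moment-match at the
    # modal df, shrink each gene with its own df
    dmode <- as.numeric(names(sort(table(df), decreasing = TRUE))[1])
    sub <- s2[df == dmode]
    prior <- if (is.null(d0_override)) estimate_variance_prior(sub, dmode)
             else list(d0 = d0_override,
                       s02 = estimate_variance_prior(sub, dmode)$s02)
  }
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / nh + 1 / nl))
  tmod <- ifelse(se == 0, 0, logfc / se)
  df_total <- d0 + df
  p <- 2 * pt(abs(tmod), df = df_total, lower.tail = FALSE)
  p[tmod == 0] <- 1
  out <- data.frame(gene = rownames(xh), logFC = logfc, s2 = s2, df = df,
                    t = tmod, p = p, n_high = nh, n_low = nl,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, study = study_name,
            prior = list(d0 = d0, s02 = s02),
            contrast = c(high = high_label, low = low_label),
            class = c("study_de", "data.frame"))
}

#' Combine p-values with Fisher's method
#'
#' `statistic = -2 sum(log p_i)`, compared to a chi-square with `2k` df.
#'
#' @param pvals p-values in (0, 1].
#' @return list with `statistic` and `p`.
#' @export
fisher_combine <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) stop("need at least one p-value")
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(pvals))
  list(statistic = stat,
       p = pchisq(stat, df = 2 * length(pvals), lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin, named wrapper over `p.adjust(method = "BH")`.
#' @param pvals p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) p.adjust(pvals, method = "BH")

#' Cross-study meta-differential-expression
#'
#' Restricts to genes present in every study, combines per-study two-sided
#' p-values with Fisher's method, applies BH across genes, and labels each
#' gene's direction `up` (logFC > 0 in every study), `down` (< 0 in every
#' study) or `mixed`. The selected sets are the sign-consistent genes with
#' `q < q_threshold`.
#'
#' @param studies list of `study_de` results (>= 2).
#' @param q_threshold selection threshold on BH q (default 0.01).
#' @return `meta_de_result`: per-gene data.frame with per-study logFC and p
#'   columns, `fisher_stat`, `fisher_p`, `q`, `sign_consistent`,
#'   `n_studies`, `selected`; up/down gene sets in `attr(, "selected")`.
#' @export
meta_de <- function(studies, q_threshold = 0.01) {
  stopifnot(length(studies) >= 2L)
  names(studies) <- vapply(seq_along(studies), function(i)
    attr(studies[[i]], "study") %||% paste0("study", i), character(1))
  common <- Reduce(intersect, lapply(studies, `[[`, "gene"))
  if (!length(common)) stop("empty gene intersection across studies")
  logfc <- sapply(studies, function(s) s$logFC[match(common, s$gene)])
  pmat <- sapply(studies, function(s) s$p[match(common, s$gene)])
  fisher_stat <- -2 * rowSums(log(pmat))
  fisher_p <- pchisq(fisher_stat, df = 2 * ncol(pmat), lower.tail = FALSE)
  q <- bh_adjust(fisher_p)
  sign_consistent <- ifelse(rowSums(logfc > 0) == ncol(logfc), "up",
                     ifelse(rowSums(logfc < 0) == ncol(logfc), "down",
                            "mixed"))
  selected <- q < q_threshold & sign_consistent != "mixed"
  out <- data.frame(gene = common, stringsAsFactors = FALSE)
  for (s in names(studies)) {
    out[[paste0("logFC_", s)]] <- logfc[, s]
    out[[paste0("p_", s)]] <- pmat[, s]
  }
  out$fisher_stat <- fisher_stat
  out$fisher_p <- fisher_p
  out$q <- q
  out$sign_consistent <- sign_consistent
  out$n_studies <- length(studies)
  out$selected <- selected
  structure(out,
            selected = list(up = common[selected & sign_consistent == "up"],
                            down = common[selected & sign_consistent == "down"]),
            q_threshold = q_threshold,
            class = c("meta_de_result", "data.frame"))
}

#' @export
print.meta_de_result <- function(x, ...) {
  sel <- attr(x, "selected")
  cat("meta-DE over ", x$n_studies[1], " studies, ", nrow(x),
      " common genes; q < ", attr(x, "q_threshold"), ": ",
      length(sel$up), " up, ", length(sel$down), " down\n", sep = "")
  invisible(x)
}

#' Pearson correlation of logFC between two studies
#'
#' @param a,b `study_de` results.
#' @return list with `r`, `p` (two-sided) and `n_common`.
#' @export
pairwise_logfc_correlation <- function(a, b) {
  common <- intersect(a$gene, b$gene)
  if (length(common) < 3L) stop("need >= 3 common genes")
  x <- a$logFC[match(common, a$gene)]
  y <- b$logFC[match(common, b$gene)]
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_common = length(common))
}

#' Correlation profile of all genes against an anchor gene
#'
#' Pearson correlation of every other gene's expression with the anchor
#' (e.g. AR or ERG) across samples; constant genes yield `NA` and are
#' logged.
#'
#' @param matrix an [expression_matrix()].
#' @param anchor_gene gene symbol present in the matrix.
#' @return named numeric vector (anchor excluded).
#' @export
anchor_correlation_profile <- function(matrix, anchor_gene) {
  X <- unclass(matrix)
  if (!(anchor_gene %in% rownames(X)))
    stop("anchor gene '", anchor_gene, "' not in matrix")
  if (ncol(X) < 3L) stop("need >= 3 samples")
  anchor <- X[anchor_gene, ]
  others <- setdiff(rownames(X), anchor_gene)
  r <- suppressWarnings(
    as.numeric(cor(t(X[others, , drop = FALSE]), anchor,
                   use = "pairwise.complete.obs")))
  names(r) <- others
  if (anyNA(r))
    message(sum(is.na(r)),
            " gene(s) with undefined correlation recorded as missing")
  r
}

#' Spearman correlation matrix of per-study correlation profiles
#'
#' @param profiles named list of per-gene correlation vectors (one per
#'   study, named by gene).
#' @return symmetric matrix of Spearman correlations over each pair's common
#'   genes (unit diagonal; pairs with < 3 common genes are `NA` and logged).
#' @export
cross_study_profile_correlation <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  k <- length(profiles)
  nm <- names(profiles) %||% paste0("study", seq_len(k))
  out <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(out) <- 1
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    common <- intersect(names(profiles[[i]]), names(profiles[[j]]))
    xi <- profiles[[i]][common]; xj <- profiles[[j]][common]
    ok <- !is.na(xi) & !is.na(xj)
    if (sum(ok) < 3L) {
      message("insufficient overlap between ", nm[i], " and ", nm[j])
      next
    }
    out[i, j] <- out[j, i] <- cor(xi[ok], xj[ok], method = "spearman")
  }
  out
}
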