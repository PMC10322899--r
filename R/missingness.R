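# Simulated gene-dropout robustness benchmark: drop k signature genes at
# random, rescore, and correlate against the full-signature score.

# distinct k-subsets of 1..m: enumerate when the space is small, otherwise
# rejection-sample distinct combinations without replacement
sample_k_subsets <- function(m, k, n_combinations) {
  if (k == 0L) return(list(integer()))
  total <- choose(m, k)
  if (total <= n_combinations) {
    return(asplit(combn(m, k), 2L))
  }
  seen <- new.env(parent = emptyenv())
  out <- vector("list", n_combinations)
  got <- 0L
  while (got < n_combinations) {
    s <- sort(sample.int(m, k))
    key <- paste(s, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- s
    }
  }
  out
}

#' Benchmark a signature's robustness to missing genes
#'
#' For each dropout size `k`, samples distinct k-subsets of the signature's
#' genes (full enumeration when there are fewer than `n_combinations`
#' subsets), recomputes the score without those genes and correlates it with
#' the full-signature "ground truth" score across samples. Per-k RNG streams
#' are derived from the root seed, so adding a `k` does not perturb others.
#'
#' @param sig a [signature_model()] or built-in name.
#' @param matrix an [expression_matrix()] containing every signature gene.
#' @param k_min,k_max dropout range; `k_min = 0` is allowed as a sanity mode
#'   (all correlations exactly 1).
#' @param n_combinations subsets per k. The default follows the published
#'   benchmark: 100 combinations, except 50 for the 34-gene cell-cycle
#'   (`prolaris`) score.
#' @param seed root RNG seed.
#' @param method correlation type; Pearson matches the continuous scores.
#' @return `missingness_benchmark`: list of per-k results, each with
#'   `k`, `n_combinations`, `correlations`, `mean_corr`, `median_corr`,
#'   `seed`.
#' @export
benchmark_missingness <- function(sig, matrix, k_min = 1L, k_max = 5L,
                                  n_combinations = NULL, seed = 42L,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.character(sig)) sig <- builtin_signatures(sig)
  stopifnot(inherits(sig, "signature_model"))
  if (is.null(n_combinations))
    n_combinations <- if (identical(sig$name, "prolaris")) 50L else 100L
  m <- nrow(sig$components)
  if (!(k_min >= 0L && k_min <= k_max)) stop("need 0 <= k_min <= k_max")
  if (k_max >= m) stop("k_max must be smaller than the signature size (", m, ")")
  if (ncol(matrix) < 3L) stop("correlation undefined with < 3 samples")
  report <- classify_coverage(sig, matrix)
  if (attr(report, "totals")["n_single"] < m)
    stop("signature must be fully present (single matches) for the ",
         "ground-truth score; see coverage report")
  full <- score_signature(sig, matrix)$score
  results <- lapply(seq(k_min, k_max), function(k) {
    set.seed((as.integer(seed) %% 1000003L) * 1009L + k)
    subsets <- sample_k_subsets(m, k, n_combinations)
    cors <- vapply(subsets, function(drop) {
      if (!length(drop)) return(1)  # k = 0: score identical to itself
      sub_sig <- sig
      keep <- setdiff(seq_len(m), drop)
      sub_sig$components <- sig$components[keep, , drop = FALSE]
      s <- score_signature(sub_sig, matrix, min_fraction = 1e-9)$score
      cor(s, full, method = method)
    }, numeric(1))
    list(k = k, n_combinations = length(subsets), correlations = cors,
         mean_corr = mean(cors), median_corr = median(cors),
         seed = seed, method = method)
  })
  structure(results, signature = sig$name, method = method,
            class = "missingness_benchmark")
}

#' Summarize a missingness benchmark
#'
#' @param results a `missingness_benchmark`.
#' @return data.frame with one row per k: `k`, `n_combinations`,
#'   `mean_corr`, `median_corr`, `q05`, `q95`.
#' @export
summarize_missingness <- function(results) {
  stopifnot(inherits(results, "missingness_benchmark"), length(results) > 0)
  rows <- lapply(results, function(r) {
    stopifnot(length(r$correlations) == r$n_combinations,
              r$n_combinations > 0)
    data.frame(k = r$k, n_combinations = r$n_combinations,
               mean_corr = mean(r$correlations),
               median_corr = median(r$correlations),
               q05 = unname(quantile(r$correlations, 0.05)),
               q95 = unname(quantile(r$correlations, 0.95)))
  })
  do.call(rbind, rows)
}

#' @export
print.missingness_benchmark <- function(x, ...) {
  cat("gene-dropout benchmark for signature '", attr(x, "signature"),
      "' (", attr(x, "method"), " correlation)\n", sep = "")
  print(summarize_missingness(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.missingness_benchmark <- function(x, ...) {
  s <- summarize_missingness(x)
  plot(s$k, s$mean_corr, type = "b", ylim = c(min(s$q05, na.rm = TRUE), 1),
       xlab = "genes removed (k)", ylab = "correlation with full score",
       main = attr(x, "signature"), ...)
  graphics::segments(s$k, s$q05, s$k, s$q95, col = "grey50")
  invisible(x)
}
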