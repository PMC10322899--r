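# Signature scoring engine: signature models, coverage classification
# (1-to-1 / 1-to-many / missing), normalization and combination rules.

#' Construct a signature model
#'
#' A named gene signature: components (gene, aliases, direction, weight,
#' optional group), a per-gene normalization rule and a combination rule.
#' `grouped_linear` requires `group_weights` covering every component group.
#'
#' @param name signature name.
#' @param components data.frame with columns `gene`, `direction` (+1/-1),
#'   `weight`, optional `group`, and optionally a list-column `aliases`.
#' @param normalization `"zscore"`, `"percentile"` or `"center"`.
#' @param combination `"mean"`, `"weighted_sum"`, `"grouped_linear"` or
#'   `"signed_percentile_mean"`.
#' @param group_weights named numeric, required iff
#'   `combination == "grouped_linear"`.
#' @param min_fraction minimum fraction of signature genes with a single
#'   match required for scoring, in (0, 1].
#' @return list of class `signature_model`.
#' @export
signature_model <- function(name, components,
                            normalization = c("zscore", "percentile", "center"),
                            combination = c("mean", "weighted_sum",
                                            "grouped_linear",
                                            "signed_percentile_mean"),
                            group_weights = NULL, min_fraction = 0.5) {
  normalization <- match.arg(normalization)
  combination <- match.arg(combination)
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "direction", "weight") %in% names(components)))
  if (is.null(components$aliases))
    components$aliases <- replicate(nrow(components), character(),
                                    simplify = FALSE)
  if (is.null(components$group)) components$group <- NA_character_
  if (anyDuplicated(components$gene))
    stop("signature component genes must be unique")
  if (!all(components$direction %in% c(-1, 1)))
    stop("component directions must be +1 or -1")
  if (any(!is.finite(components$weight)))
    stop("component weights must be finite")
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must lie in (0, 1]")
  if (combination == "grouped_linear") {
    if (is.null(group_weights) || is.null(names(group_weights)))
      stop("grouped_linear requires named group_weights")
    missing_w <- setdiff(unique(components$group), names(group_weights))
    if (length(missing_w) || anyNA(components$group))
      stop("every component needs a group with a weight; missing: ",
           paste(missing_w, collapse = ", "))
  }
  structure(list(name = name, components = components,
                 normalization = normalization, combination = combination,
                 group_weights = group_weights,
                 min_fraction = min_fraction),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("signature '", x$name, "': ", nrow(x$components), " genes, ",
      x$normalization, " + ", x$combination, "\n", sep = "")
  invisible(x)
}

#' Read a signature model from a JSON definition file
#' @param path JSON file mirroring the [signature_model()] fields.
#' @return a `signature_model`.
#' @export
read_signature <- function(path) {
  def <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  comp <- def$components
  if (is.data.frame(comp) && !is.null(comp$aliases) &&
      !is.list(comp$aliases))
    comp$aliases <- as.list(comp$aliases)
  gw <- if (!is.null(def$group_weights)) unlist(def$group_weights)
  signature_model(name = def$name, components = comp,
                  normalization = def$normalization,
                  combination = def$combination,
                  group_weights = gw,
                  min_fraction = def$min_fraction %||% 0.5)
}

.signature_cache <- new.env(parent = emptyenv())

#' Built-in signature models
#'
#' Research transcriptions of four prostate-cancer expression signatures:
#' `"ar"` (20-gene androgen-receptor activity score, z-score + mean),
#' `"oncotype_dx"` (12 genes in 4 weighted modules), `"prolaris"` (34
#' cell-cycle genes, centered mean) and `"decipher"` (20 signed markers,
#' signed percentile mean). Gene lists and constants are transcriptions from
#' the original publications shipped as versioned package data; the scoring
#' engine, not the constants, is the contract. Scores are on research
#' (dimensionless) scales, not commercial report units.
#'
#' @param name optional single signature name; omit for the full list.
#' @return a `signature_model`, or a named list of all of them.
#' @export
builtin_signatures <- function(name = NULL) {
  if (is.null(.signature_cache$models)) {
    dir <- system.file("extdata", "signatures", package = "pcharm")
    files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
    models <- lapply(files, read_signature)
    names(models) <- vapply(models, `[[`, character(1), "name")
    .signature_cache$models <- models
  }
  models <- .signature_cache$models
  if (is.null(name)) return(models)
  if (!name %in% names(models))
    stop("unknown signature '", name, "'; available: ",
         paste(names(models), collapse = ", "))
  models[[name]]
}

# match each signature gene to matrix rows via its symbol, its own aliases,
# and dictionary aliases of the symbol
signature_matches <- function(sig, matrix, dict = NULL) {
  rows <- rownames(matrix)
  lapply(seq_len(nrow(sig$components)), function(i) {
    gene <- sig$components$gene[i]
    syn <- unique(c(gene, unlist(sig$components$aliases[[i]])))
    if (!is.null(dict)) {
      syn <- unique(c(syn, dict$alias[dict$canonical %in% syn],
                      dict$canonical[dict$alias %in% syn]))
    }
    which(rows %in% syn)
  })
}

#' Classify signature gene coverage in an expression matrix
#'
#' Buckets every signature gene as `single` (exactly one matrix row matches
#' the gene or an alias — a usable 1-to-1 match), `multiple` (1-to-many,
#' excluded from scoring) or `missing`.
#'
#' @param sig a [signature_model()].
#' @param matrix an [expression_matrix()] (ideally harmonized).
#' @param dict optional [gene_dictionary()] supplying extra aliases.
#' @return `match_report`: data.frame `(gene, category, n_matches)` with
#'   totals in `attr(, "totals")`.
#' @export
classify_coverage <- function(sig, matrix, dict = NULL) {
  matches <- signature_matches(sig, matrix, dict)
  n <- vapply(matches, length, integer(1))
  category <- ifelse(n == 1L, "single", ifelse(n > 1L, "multiple", "missing"))
  rep <- data.frame(gene = sig$components$gene, category = category,
                    n_matches = n, stringsAsFactors = FALSE)
  totals <- c(n_single = sum(n == 1L), n_multiple = sum(n > 1L),
              n_missing = sum(n == 0L))
  structure(rep, totals = totals,
            class = c("match_report", "data.frame"))
}

#' @export
print.match_report <- function(x, ...) {
  t <- attr(x, "totals")
  cat("signature coverage: ", t["n_single"], " single (1-to-1), ",
      t["n_multiple"], " multiple (1-to-many), ",
      t["n_missing"], " missing\n", sep = "")
  invisible(x)
}

normalize_rows <- function(m, rule) {
  switch(rule,
    zscore = {
      mu <- rowMeans(m, na.rm = TRUE)
      sdv <- apply(m, 1L, sd, na.rm = TRUE)
      zero <- !is.na(sdv) & sdv == 0
      if (any(zero))
        message("zero-variance gene(s) under zscore set to 0: ",
                paste(rownames(m)[zero], collapse = ", "))
      sdv[zero | is.na(sdv)] <- Inf  # -> z = 0
      (m - mu) / sdv
    },
    percentile = t(apply(m, 1L, function(x) {
      r <- rank(x, ties.method = "average", na.last = "keep")
      r / sum(!is.na(x))
    })),
    center = m - rowMeans(m, na.rm = TRUE))
}

#' Score samples with a signature
#'
#' Normalizes each usable (single-match) signature gene across samples and
#' combines genes by the model's rule: `mean` is `(1/m) sum d_i x_i`,
#' `weighted_sum` is `sum w_i d_i x_i`, `grouped_linear` averages within
#' groups and combines group means with the group weights, and
#' `signed_percentile_mean` is the mean percentile of up-markers minus the
#' mean percentile of down-markers. Genes with a 1-to-many match are
#' excluded; scoring proceeds on available genes provided coverage is at
#' least `min_fraction`.
#'
#' @param sig a [signature_model()] or a built-in name.
#' @param matrix an [expression_matrix()] (harmonized log-scale values).
#' @param dict optional [gene_dictionary()].
#' @param min_fraction override of the model's coverage floor.
#' @return `score_vector`: list with `score` (named per-sample numeric),
#'   `genes_used`, `n_genes_used`, `signature` and the `match_report`.
#' @export
score_signature <- function(sig, matrix, dict = NULL, min_fraction = NULL) {
  if (is.character(sig)) sig <- builtin_signatures(sig)
  stopifnot(inherits(sig, "signature_model"))
  min_fraction <- min_fraction %||% sig$min_fraction
  report <- classify_coverage(sig, matrix, dict)
  matches <- signature_matches(sig, matrix, dict)
  usable <- which(report$category == "single")
  frac <- length(usable) / nrow(sig$components)
  if (frac < min_fraction) {
    cond <- simpleError(sprintf(
      "signature coverage %.2f below min_fraction %.2f (%d/%d single matches)",
      frac, min_fraction, length(usable), nrow(sig$components)))
    cond$match_report <- report
    stop(cond)
  }
  if (!length(usable)) stop("no usable signature genes")
  needs_dist <- sig$normalization %in% c("zscore", "percentile")
  if (needs_dist && ncol(matrix) < 3L)
    stop("zscore/percentile normalization needs >= 3 samples")
  rows <- vapply(matches[usable], `[[`, integer(1), 1L)
  sub <- unclass(matrix)[rows, , drop = FALSE]
  rownames(sub) <- sig$components$gene[usable]
  norm_rule <- if (sig$combination == "signed_percentile_mean") "percentile"
               else sig$normalization
  xt <- normalize_rows(sub, norm_rule)
  d <- sig$components$direction[usable]
  w <- sig$components$weight[usable]
  grp <- sig$components$group[usable]
  scores <- switch(sig$combination,
    mean = colMeans(xt * d, na.rm = TRUE),
    weighted_sum = colSums(xt * (w * d), na.rm = TRUE),
    grouped_linear = {
      acc <- rep(0, ncol(xt))
      for (g in unique(grp)) {
        idx <- which(grp == g)
        acc <- acc + sig$group_weights[[g]] *
          colMeans(xt[idx, , drop = FALSE] * d[idx], na.rm = TRUE)
      }
      acc
    },
    signed_percentile_mean = {
      up <- which(d > 0); down <- which(d < 0)
      up_m <- if (length(up)) colMeans(xt[up, , drop = FALSE], na.rm = TRUE)
              else rep(0, ncol(xt))
      down_m <- if (length(down))
        colMeans(xt[down, , drop = FALSE], na.rm = TRUE) else rep(0, ncol(xt))
      up_m - down_m
    })
  scores <- setNames(as.numeric(scores), colnames(matrix))
  structure(list(score = scores,
                 genes_used = rownames(sub),
                 n_genes_used = length(usable),
                 signature = sig$name,
                 match_report = report),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat("signature '", x$signature, "' scores for ", length(x$score),
      " samples using ", x$n_genes_used, " genes\n", sep = "")
  print(head(x$score))
  invisible(x)
}

#' Score a generic marker-gene program
#'
#' A lightweight stand-in for per-sample cell-content or pathway estimates:
#' z-score + mean over whichever marker genes are present in the matrix
#' (e.g. an endothelial-like program feeding survival stratification).
#'
#' @param marker_genes character vector of marker symbols.
#' @param matrix an [expression_matrix()].
#' @return a `score_vector`.
#' @export
marker_score <- function(marker_genes, matrix) {
  marker_genes <- unique(as.character(marker_genes))
  comp <- data.frame(gene = marker_genes, direction = 1, weight = 1,
                     stringsAsFactors = FALSE)
  sig <- signature_model(name = "marker_program", components = comp,
                         normalization = "zscore", combination = "mean",
                         min_fraction = 1e-9)
  present <- sum(marker_genes %in% rownames(matrix))
  if (present == 0L) stop("none of the marker genes are present")
  score_signature(sig, matrix)
}
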