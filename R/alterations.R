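# Somatic alteration analysis: binarize CNA + non-silent mutations, per-gene
# frequencies, and pairwise co-occurrence / mutual-exclusivity statistics.

#' Binarize copy-number and mutation data into an alteration matrix
#'
#' A sample is altered in a gene iff its copy-number call is non-zero (any
#' gain or loss, shallow calls included) or it carries at least one
#' non-silent mutation. Samples lacking one assay contribute no alterations
#' from it and are flagged, so their alteration frequencies are an
#' acknowledged undercount.
#'
#' @param cna optional [cna_matrix()].
#' @param mut optional [mutation_table()].
#' @param gene_list genes to include; genes absent from both assays are
#'   excluded with a warning.
#' @param samples optional sample universe; defaults to the union of assay
#'   samples.
#' @return `alteration_matrix`: binary genes-by-samples matrix with
#'   `attr(, "provenance")` (character matrix in
#'   `{cna, mutation, both, none}`) and `attr(, "assays")` (per-sample
#'   logical availability flags).
#' @export
binarize_alterations <- function(cna = NULL, mut = NULL, gene_list,
                                 samples = NULL) {
  if (is.null(cna) && is.null(mut))
    stop("at least one of cna/mut is required")
  gene_list <- unique(as.character(gene_list))
  cna_samples <- if (!is.null(cna)) colnames(cna) else character()
  mut_samples <- if (!is.null(mut)) unique(mut$sample_id) else character()
  samples <- samples %||% union(cna_samples, mut_samples)
  in_cna <- if (!is.null(cna)) gene_list %in% rownames(cna)
            else rep(FALSE, length(gene_list))
  in_mut <- if (!is.null(mut)) gene_list %in% mut$gene_symbol
            else rep(FALSE, length(gene_list))
  absent <- !(in_cna | in_mut)
  if (any(absent)) {
    warning("gene(s) absent from both assays excluded: ",
            paste(gene_list[absent], collapse = ", "))
    gene_list <- gene_list[!absent]
  }
  if (!length(gene_list)) stop("no genes left to binarize")
  g <- length(gene_list); n <- length(samples)
  cna_alt <- matrix(FALSE, g, n, dimnames = list(gene_list, samples))
  mut_alt <- cna_alt
  if (!is.null(cna)) {
    common_g <- intersect(gene_list, rownames(cna))
    sub <- unclass(cna)[common_g, intersect(samples, cna_samples),
                        drop = FALSE]
    cna_alt[common_g, colnames(sub)] <- !is.na(sub) & sub != 0L
  }
  if (!is.null(mut)) {
    nonsilent <- mut[mut$variant_class != "Silent" &
                       mut$gene_symbol %in% gene_list &
                       mut$sample_id %in% samples, , drop = FALSE]
    if (nrow(nonsilent))
      mut_alt[cbind(nonsilent$gene_symbol, nonsilent$sample_id)] <- TRUE
  }
  alt <- (cna_alt | mut_alt) + 0L
  provenance <- matrix("none", g, n, dimnames = dimnames(alt))
  provenance[cna_alt & !mut_alt] <- "cna"
  provenance[!cna_alt & mut_alt] <- "mutation"
  provenance[cna_alt & mut_alt] <- "both"
  assays <- data.frame(sample_id = samples,
                       has_cna = samples %in% cna_samples,
                       has_mut = samples %in% mut_samples,
                       stringsAsFactors = FALSE)
  structure(alt, provenance = provenance, assays = assays,
            class = c("alteration_matrix", class(alt)))
}

#' Per-gene alteration frequency
#'
#' Fraction of samples altered, with per-assay availability counts attached
#' (frequencies that combine CNA and mutations are under-estimates for
#' samples missing an assay).
#'
#' @param am an `alteration_matrix`.
#' @return data.frame `(gene, n_altered, n_samples, frequency, n_cna_assayed,
#'   n_mut_assayed)`.
#' @export
alteration_frequency <- function(am) {
  stopifnot(inherits(am, "alteration_matrix"))
  assays <- attr(am, "assays")
  data.frame(gene = rownames(am),
             n_altered = rowSums(am),
             n_samples = ncol(am),
             frequency = rowMeans(am),
             n_cna_assayed = sum(assays$has_cna),
             n_mut_assayed = sum(assays$has_mut),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene copy-number gain and loss frequencies
#'
#' @param cna a [cna_matrix()].
#' @return data.frame `(gene, frac_gain, frac_loss, n_assayed)`; genes with
#'   all calls missing report `NA`.
#' @export
cna_gain_loss_frequency <- function(cna) {
  X <- unclass(cna)
  n_ok <- rowSums(!is.na(X))
  frac_gain <- ifelse(n_ok > 0, rowSums(X > 0, na.rm = TRUE) / n_ok, NA_real_)
  frac_loss <- ifelse(n_ok > 0, rowSums(X < 0, na.rm = TRUE) / n_ok, NA_real_)
  data.frame(gene = rownames(X), frac_gain = frac_gain,
             frac_loss = frac_loss, n_assayed = n_ok,
             stringsAsFactors = FALSE, row.names = NULL)
}

# two-sided Fisher exact p for the 2x2 alteration table (hypergeometric
# enumeration as implemented in stats::fisher.test)
fisher_exact_p <- function(both, a_only, b_only, neither) {
  tab <- matrix(c(both, b_only, a_only, neither), 2L)
  fisher.test(tab, alternative = "two.sided")$p.value
}

# sample odds ratio by the count formula OR = (both * neither)/(a_only * b_only)
count_odds_ratio <- function(both, a_only, b_only, neither) {
  if (a_only * b_only == 0) {
    if (both * neither == 0) return(NA_real_)  # undefined
    return(Inf)
  }
  (both * neither) / (a_only * b_only)
}

#' Test a gene pair for co-occurrence / mutual exclusivity
#'
#' Builds the 2x2 alteration table over samples, computes the odds ratio by
#' the count formula `(both * neither) / (a_only * b_only)` and a two-sided
#' Fisher exact p. OR > 1 labels the pair co-occurring, OR < 1 exclusive,
#' OR = 1 or undefined indeterminate; a zero discordant cell with altered
#' concordant cells yields OR = +Inf (a Haldane-corrected OR with 0.5 added
#' to every cell is reported alongside for plotting).
#'
#' @param am an `alteration_matrix`.
#' @param gene_a,gene_b genes in the matrix.
#' @return one-row data.frame of class `pair_test`.
#' @export
mutual_exclusivity <- function(am, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!(g %in% rownames(am))) stop("gene '", g, "' not in alteration matrix")
  a <- am[gene_a, ] == 1L
  b <- am[gene_b, ] == 1L
  both <- sum(a & b); a_only <- sum(a & !b)
  b_only <- sum(!a & b); neither <- sum(!a & !b)
  or <- count_odds_ratio(both, a_only, b_only, neither)
  p <- fisher_exact_p(both, a_only, b_only, neither)
  or_haldane <- ((both + 0.5) * (neither + 0.5)) /
    ((a_only + 0.5) * (b_only + 0.5))
  label <- if (is.na(or) || or == 1) "indeterminate"
           else if (or > 1) "co-occurring" else "exclusive"
  structure(data.frame(gene_a = gene_a, gene_b = gene_b, both = both,
                       a_only = a_only, b_only = b_only, neither = neither,
                       odds_ratio = or, odds_ratio_haldane = or_haldane,
                       p = p, label = label, stringsAsFactors = FALSE),
            class = c("pair_test", "data.frame"))
}

#' Screen all gene pairs for co-occurrence / mutual exclusivity
#'
#' Tests every unordered pair, applies BH across the screen, and stars pairs
#' at p < 0.05 following the oncoprint-panel convention.
#'
#' @param am an `alteration_matrix`.
#' @param genes >= 2 genes to screen (default: all matrix genes).
#' @return data.frame of class `mutex_screen` with one row per pair and
#'   columns of [mutual_exclusivity()] plus `q` and `star`.
#' @export
mutex_screen <- function(am, genes = rownames(am)) {
  genes <- unique(as.character(genes))
  if (length(genes) < 2L) stop("need >= 2 genes")
  pairs <- combn(genes, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i)
    mutual_exclusivity(am, pairs[1L, i], pairs[2L, i]))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$star <- out$p < 0.05
  structure(out, class = c("mutex_screen", "data.frame"))
}
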