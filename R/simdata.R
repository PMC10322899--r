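# Seeded synthetic multi-study generator. Emulates the structure of the
# harmonized resource — several studies with Gleason grade groups,
# biochemical-recurrence follow-up, partially overlapping gene universes,
# GISTIC-style CNA calls and MAF-like mutations — so every analysis module
# is testable without downloads. Gene variances are drawn from an
# inverse-gamma prior (the moderated-t model's own assumption); a latent
# "endothelial-like" program links expression to recurrence hazard.

#' Build a simulation configuration
#'
#' @param n_studies number of studies.
#' @param n_samples samples per study (recycled).
#' @param n_genes genes per study universe.
#' @param grade_probs probabilities of grade groups `<=6`, `7`, `>=8`.
#' @param de_genes number of planted differentially expressed genes.
#' @param de_logfc planted logFC (log2) between `>=8` and `<=6` samples.
#' @param de_up_fraction fraction of planted genes shifted upward.
#' @param d0,s02 inverse-gamma gene-variance prior: variances are
#'   `d0 * s02 / chisq(d0)` (i.e. scaled-inverse-chi-square with d0 df and
#'   scale s02).
#' @param variance_model `"inverse_gamma"` (correctly specified for the
#'   moderated t) or `"lognormal"` (misspecified robustness mode).
#' @param n_markers latent-program marker genes.
#' @param loading marker loading on the latent per-sample score.
#' @param beta log hazard ratio per unit latent score for recurrence.
#' @param censoring target censoring fraction in (0, 1).
#' @param overlap fraction of the gene universe shared by every study
#'   (remaining genes are study-specific draws).
#' @param cna_genes genes in the CNA/mutation block.
#' @param alt_prob marginal alteration probability of CNA-block genes.
#' @param target_or pairwise odds ratio planted between the first two
#'   CNA-block genes.
#' @param silent_fraction fraction of simulated mutations that are Silent.
#' @param mut_prob per-gene per-sample mutation probability.
#' @param seed root RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 4L, n_samples = 120L, n_genes = 1000L,
                       grade_probs = c(0.35, 0.40, 0.25), de_genes = 50L,
                       de_logfc = 1, de_up_fraction = 0.5, d0 = 8,
                       s02 = 0.25, variance_model = c("inverse_gamma",
                                                      "lognormal"),
                       n_markers = 20L, loading = 0.8, beta = log(2),
                       censoring = 0.3, overlap = 1, cna_genes = 8L,
                       alt_prob = 0.25, target_or = 5, silent_fraction = 0.2,
                       mut_prob = 0.1, seed = 1L) {
  variance_model <- match.arg(variance_model)
  if (length(grade_probs) != 3L || any(grade_probs < 0) ||
      abs(sum(grade_probs) - 1) > 1e-8)
    stop("grade_probs must be 3 nonnegative probabilities summing to 1")
  if (!(censoring >= 0 && censoring < 1))
    stop("infeasible censoring fraction (need 0 <= f < 1)")
  if (target_or <= 0) stop("target odds ratio must be positive")
  if (!(overlap > 0 && overlap <= 1)) stop("overlap must be in (0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Exact joint distribution of two Bernoullis with a target odds ratio
#'
#' Solves for `p11` such that the 2x2 cell probabilities implied by the
#' marginals and `p11` have the requested odds ratio, then draws `n` paired
#' binary observations from that joint distribution.
#'
#' @param p_a,p_b marginal alteration probabilities in (0, 1).
#' @param odds_ratio target OR (> 0).
#' @param n draws.
#' @param seed RNG seed.
#' @return list with `a`, `b` (binary vectors) and `p11`.
#' @export
correlated_bernoulli_pair <- function(p_a, p_b, odds_ratio, n, seed = 1L) {
  if (!(p_a > 0 && p_a < 1 && p_b > 0 && p_b < 1))
    stop("marginals must lie strictly in (0, 1)")
  if (odds_ratio <= 0) stop("odds ratio must be positive")
  p11 <- solve_p11(p_a, p_b, odds_ratio)
  p10 <- p_a - p11; p01 <- p_b - p11; p00 <- 1 - p_a - p_b + p11
  if (min(p10, p01, p00) < -1e-12)
    stop("infeasible (p_a, p_b, odds_ratio) triple")
  set.seed(seed)
  u <- runif(n)
  cell <- findInterval(u, cumsum(c(p11, p10, p01)))  # 0:both 1:a 2:b 3:none
  list(a = as.integer(cell <= 1L), b = as.integer(cell %in% c(0L, 2L)),
       p11 = p11)
}

# root of OR(p11) = theta on the feasible interval; OR is monotone
# increasing in p11, so uniroot on the log scale is safe
solve_p11 <- function(p_a, p_b, theta) {
  if (abs(theta - 1) < 1e-12) return(p_a * p_b)
  lo <- max(0, p_a + p_b - 1); hi <- min(p_a, p_b)
  f <- function(p11) {
    p10 <- p_a - p11; p01 <- p_b - p11; p00 <- 1 - p_a - p_b + p11
    log(p11) + log(p00) - log(p10) - log(p01) - log(theta)
  }
  eps <- (hi - lo) * 1e-12
  uniroot(f, c(lo + eps, hi - eps), tol = 1e-12)$root
}

#' Simulate a MAF-like mutation table
#'
#' Per-gene per-sample Bernoulli mutations; a configured fraction are
#' Silent, the rest draw uniformly from the non-silent variant classes.
#'
#' @param genes,samples character vectors.
#' @param mut_prob per-gene per-sample mutation probability.
#' @param silent_fraction fraction of mutations with class Silent.
#' @param seed RNG seed.
#' @return a [mutation_table()] (possibly zero rows).
#' @export
simulate_maf <- function(genes, samples, mut_prob = 0.1,
                         silent_fraction = 0.2, seed = 1L) {
  stopifnot(silent_fraction >= 0, silent_fraction <= 1)
  set.seed(seed)
  hit <- matrix(runif(length(genes) * length(samples)) < mut_prob,
                length(genes), dimnames = list(genes, samples))
  idx <- which(hit, arr.ind = TRUE)
  n <- nrow(idx)
  if (!n)
    return(mutation_table(character(), character(), character()))
  silent <- runif(n) < silent_fraction
  nonsilent_classes <- setdiff(VARIANT_CLASSES, c("Silent", "Other"))
  cls <- ifelse(silent, "Silent",
                sample(nonsilent_classes, n, replace = TRUE))
  mutation_table(sample_id = samples[idx[, 2L]],
                 gene_symbol = genes[idx[, 1L]],
                 variant_class = cls,
                 mutation_status = "matched_normal")
}

# uniform-cutoff censoring: C ~ U(0, tau) with tau solved so the realized
# censoring fraction matches the target for the drawn event times
censor_times <- function(t_event, fraction, u) {
  if (fraction == 0)
    return(list(time = t_event, event = rep(1L, length(t_event))))
  g <- function(tau) mean(u * tau < t_event) - fraction
  hi <- max(t_event) / min(u)
  tau <- uniroot(g, c(1e-9, hi), extendInt = "downX", tol = 1e-9)$root
  cens <- u * tau
  event <- as.integer(t_event <= cens)
  list(time = pmin(t_event, cens), event = event)
}

simulate_one_study <- function(cfg, study_idx, genes_all, planted, markers,
                               seed) {
  set.seed(seed)
  n <- cfg$n_samples[[min(study_idx, length(cfg$n_samples))]]
  # study gene universe: shared core plus study-specific subset of the rest
  core <- genes_all[seq_len(ceiling(cfg$overlap * cfg$n_genes))]
  extra <- setdiff(genes_all, core)
  genes <- sort(union(core, extra[runif(length(extra)) < 0.5]))
  g <- length(genes)
  samples <- sprintf("%s_S%03d", paste0("study", study_idx), seq_len(n))
  grade <- sample(GRADE_GROUPS, n, replace = TRUE, prob = cfg$grade_probs)
  latent <- rnorm(n)
  # scaled-inverse-chi-square: sigma^2 = d0 * s02 / chisq_d0
  sdv <- if (cfg$variance_model == "inverse_gamma")
    sqrt(cfg$d0 * cfg$s02 / rgamma(g, shape = cfg$d0 / 2, rate = 1 / 2))
  else sqrt(exp(rnorm(g, mean = log(cfg$s02), sd = 0.5)))
  baseline <- rnorm(g, mean = 7, sd = 1.5)
  X <- matrix(rnorm(g * n, sd = rep(sdv, n)), g, n,
              dimnames = list(genes, samples))
  X <- X + baseline
  shift <- c("<=6" = 0, "7" = 0.5, ">=8" = 1)[grade]
  planted_here <- intersect(planted$gene, genes)
  if (length(planted_here)) {
    dirs <- planted$direction[match(planted_here, planted$gene)]
    X[planted_here, ] <- X[planted_here, ] +
      outer(dirs * cfg$de_logfc, shift)
  }
  markers_here <- intersect(markers, genes)
  if (length(markers_here))
    X[markers_here, ] <- X[markers_here, ] +
      cfg$loading * matrix(latent, length(markers_here), n, byrow = TRUE)
  # recurrence: exponential hazard proportional to exp(beta * latent)
  t_event <- rexp(n, rate = 0.02 * exp(cfg$beta * latent))
  cens <- censor_times(t_event, cfg$censoring, runif(n))
  # CNA block with one planted correlated pair
  cna_genes <- genes[seq_len(min(cfg$cna_genes, g))]
  pair <- correlated_bernoulli_pair(cfg$alt_prob, cfg$alt_prob,
                                    cfg$target_or, n,
                                    seed = seed + 7L)
  set.seed(seed + 11L)
  alt <- matrix(runif(length(cna_genes) * n) < cfg$alt_prob,
                length(cna_genes), n,
                dimnames = list(cna_genes, samples))
  alt[1L, ] <- pair$a == 1L
  if (length(cna_genes) >= 2L) alt[2L, ] <- pair$b == 1L
  calls <- matrix(0L, length(cna_genes), n,
                  dimnames = list(cna_genes, samples))
  calls[alt] <- sample(c(-2L, -1L, 1L, 2L), sum(alt), replace = TRUE,
                       prob = c(0.15, 0.35, 0.35, 0.15))
  mut <- simulate_maf(cna_genes, samples, mut_prob = cfg$mut_prob,
                      silent_fraction = cfg$silent_fraction,
                      seed = seed + 13L)
  gp <- ifelse(grade == "<=6", 3L, ifelse(grade == "7", 3L, 4L))
  gs <- ifelse(grade == "<=6", 3L, ifelse(grade == "7", 4L, 5L))
  clin <- clinical_table(data.frame(
    sample_id = samples,
    patient_id = sub("_S", "_P", samples),
    sample_type = "primary",
    grade_group = grade,
    gleason_primary = gp,
    gleason_secondary = gs,
    gleason_sum = gp + gs,
    isup = c("<=6" = 1L, "7" = 2L, ">=8" = 4L)[grade],
    bcr_event = cens$event,
    time_to_bcr = round(cens$time, 4),
    os_event = NA_integer_,
    time_to_os = NA_real_,
    stringsAsFactors = FALSE))
  bundle <- build_study(name = paste0("study", study_idx),
                        expression = expression_matrix(round(X, 6)),
                        cna = cna_matrix(calls), mutations = mut,
                        clinical = clin)
  attr(bundle, "truth") <- list(latent = setNames(latent, samples),
                                planted = planted, markers = markers,
                                p11 = pair$p11)
  bundle
}

#' Simulate a harmonized multi-study resource
#'
#' Generates `n_studies` study bundles sharing (part of) a gene universe:
#' per-study gene variances from the configured prior, planted
#' grade-group-associated genes (full shift in `>=8`, half in `7`), a latent
#' program loading marker genes and driving exponential recurrence times,
#' uniform-cutoff censoring to the target fraction, a CNA/mutation block
#' with one pair planted at the target odds ratio, and fully
#' dictionary-conformant clinical tables. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return named list of `study_bundle`s; per-study ground truth (latent
#'   scores, planted genes, marker list, joint alteration cell) in
#'   `attr(bundle, "truth")`.
#' @export
simulate_multistudy <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  # the gene universe starts with the built-in signature genes (real studies
  # contain them, and it keeps built-in scores computable on simulated data),
  # padded with synthetic symbols
  sig_genes <- unique(unlist(lapply(builtin_signatures(),
                                    function(s) s$components$gene)))
  genes_all <- if (cfg$n_genes <= length(sig_genes))
    sig_genes[seq_len(cfg$n_genes)]
  else c(sig_genes,
         sprintf("G%05d", seq_len(cfg$n_genes - length(sig_genes))))
  n_de <- min(cfg$de_genes, cfg$n_genes)
  de_idx <- sample.int(cfg$n_genes, n_de)
  n_up <- round(cfg$de_up_fraction * n_de)
  planted <- data.frame(gene = genes_all[de_idx],
                        direction = rep(c(1, -1),
                                        c(n_up, n_de - n_up)),
                        stringsAsFactors = FALSE)
  marker_pool <- setdiff(genes_all, planted$gene)
  markers <- sample(marker_pool, min(cfg$n_markers, length(marker_pool)))
  cfg$n_samples <- rep_len(cfg$n_samples, cfg$n_studies)
  studies <- lapply(seq_len(cfg$n_studies), function(i)
    simulate_one_study(cfg, i, genes_all, planted, markers,
                       seed = (cfg$seed %% 100003L) * 131L + i))
  names(studies) <- vapply(studies, `[[`, character(1), "name")
  studies
}
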