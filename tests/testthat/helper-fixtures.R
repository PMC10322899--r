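# In-code fixtures and independent oracles shared across test files.

# small expression matrix with named genes
make_expr <- function(genes, n_samples = 4, seed = 1, mean = 7, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(length(genes) * n_samples, mean, sd), length(genes),
              dimnames = list(genes, paste0("S", seq_len(n_samples))))
  expression_matrix(m)
}

# minimal conformant clinical table for a set of sample ids
make_clinical <- function(samples, grade = NULL, time = NULL, event = NULL) {
  n <- length(samples)
  clinical_table(data.frame(
    sample_id = samples,
    patient_id = paste0("P", seq_len(n)),
    sample_type = "primary",
    grade_group = grade %||% rep(NA_character_, n),
    bcr_event = event %||% rep(NA_integer_, n),
    time_to_bcr = time %||% rep(NA_real_, n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent literal transcription of the moderated-t recipe, evaluated
# step by step. Uses uniroot (not Newton) to invert trigamma so the oracle
# shares no code path with the implementation.
oracle_moderated_t <- function(xh, xl) {
  nh <- ncol(xh); nl <- ncol(xl)
  mh <- rowMeans(xh); ml <- rowMeans(xl)
  logfc <- mh - ml
  d <- nh + nl - 2
  s2 <- (rowSums((xh - mh)^2) + rowSums((xl - ml)^2)) / d
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
    s2post <- rep(s02, length(s2))
  } else {
    half_d0 <- uniroot(function(x) trigamma(x) - evar,
                       interval = c(1e-8, 1e8), tol = 1e-14)$root
    d0 <- 2 * half_d0
    s02 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
    s2post <- (d0 * s02 + d * s2) / (d0 + d)
  }
  tmod <- logfc / sqrt(s2post * (1 / nh + 1 / nl))
  p <- 2 * pt(abs(tmod), df = d0 + d, lower.tail = FALSE)
  list(logFC = logfc, d0 = d0, s02 = s02, s2_post = s2post, t = tmod, p = p)
}

# brute-force BH step-up: q_(k) = min_{j >= k} p_(j) * n / j, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (k in seq_len(n)) q[k] <- min(1, min(ps[k:n] * n / (k:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# exhaustive two-sided Fisher exact p for a 2x2 table by hypergeometric
# enumeration over all tables with the observed margins
oracle_fisher_p <- function(both, a_only, b_only, neither) {
  m <- both + a_only        # altered in A
  n <- b_only + neither     # not altered in A
  k <- both + b_only        # altered in B (sampled)
  x_obs <- both
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# closed-form quadratic root for the joint Bernoulli cell p11 at a target OR
oracle_p11 <- function(pa, pb, theta) {
  if (abs(theta - 1) < 1e-12) return(pa * pb)
  a <- theta - 1
  b <- -(1 + (pa + pb) * (theta - 1))
  cc <- theta * pa * pb
  roots <- (-b + c(-1, 1) * sqrt(b^2 - 4 * a * cc)) / (2 * a)
  ok <- roots >= max(0, pa + pb - 1) - 1e-12 & roots <= min(pa, pb) + 1e-12
  roots[ok][1]
}

# deterministic exponential survival fixture with a binary group effect
make_surv_fixture <- function(n = 200, hr = 2, censor_frac = 0.3, seed = 1) {
  set.seed(seed)
  x <- rep(0:1, length.out = n)
  t_event <- rexp(n, rate = 0.05 * hr^x)
  cens <- runif(n, 0, quantile(t_event, 1 - censor_frac) * 2)
  data.frame(sample_id = paste0("S", seq_len(n)),
             time = pmin(t_event, cens),
             event = as.integer(t_event <= cens),
             covariate = x)
}
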