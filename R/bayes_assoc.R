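# Pairwise Bayesian association testing. The evidence for an association
# between two variables is a Jeffreys-Zellner-Siow (JZS) Bayes factor
# computed from the sample correlation; Spearman coefficients carry the
# direction of each association.

# log(1 + c * exp(u)) without overflow for large u (c > 0)
log1p_c_exp <- function(u, c = 1) {
  ifelse(u > 33, u + log(c + exp(-u)), log1p(c * exp(u)))
}

jzs_log_integrand <- function(u, n, r2, b) {
  # integrand of BF10 on the u = log(g) axis, including the inverse-gamma
  # prior on g (shape 1/2, scale b = n * rscale^2 / 2) and the jacobian
  (n - 2) / 2 * log1p_c_exp(u) -
    (n - 1) / 2 * log1p_c_exp(u, 1 - r2) +
    0.5 * log(b) - lgamma(0.5) - 0.5 * u - b * exp(-u)
}

jzs_regression_log10_bf <- function(n, r, rscale, rel_tol = 1e-8) {
  b <- n * rscale^2 / 2
  r2 <- r^2
  lv <- jzs_log_integrand(seq(-60, 60, length.out = 2001L), n, r2, b)
  M <- max(lv)
  f <- function(u) exp(jzs_log_integrand(u, n, r2, b) - M)
  I <- tryCatch(
    stats::integrate(f, -200, 200, rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e) NULL)
  if (is.null(I) || I$message != "OK")
    I <- stats::integrate(f, -200, 200, rel.tol = rel_tol, abs.tol = 0,
                          subdivisions = 5000L)
  if (I$message != "OK")
    stop(sprintf(
      "non-convergent quadrature (n=%d, r=%.4f, rscale=%.4f): %s",
      n, r, rscale, I$message))
  (M + log(I$value)) / log(10)
}

# Gauss hypergeometric 2F1(a, b; c; x) by power series; all terms are
# positive for the arguments used here (a, b, c > 0, 0 < x < 1) and the
# series converges since c - a - b > 0.
hyp2f1 <- function(a, b, c, x, tol = 1e-13, maxit = 200000L) {
  term <- 1; s <- 1; k <- 0L
  while (k < maxit) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * x
    s <- s + term
    k <- k + 1L
    if (abs(term) < tol * abs(s)) return(s)
  }
  stop("2F1 series did not converge")
}

stretched_beta_log10_bf <- function(n, r, rscale, rel_tol = 1e-8) {
  # Prior: rho scaled so that (rho + 1)/2 ~ Beta(1/rscale, 1/rscale).
  # BF10 integrates the exact sampling-density ratio of the observed
  # correlation r over this prior.
  al <- 1 / rscale
  log_den <- log(hyp2f1(0.5, 0.5, n - 0.5, 0.5))
  lik_ratio <- function(rho) {
    h <- vapply(rho, function(q) hyp2f1(0.5, 0.5, n - 0.5, (r * q + 1) / 2),
                numeric(1L))
    exp((n - 1) / 2 * log1p(-rho^2) +
          (3 - 2 * n) / 2 * log1p(-rho * r) + log(h) - log_den)
  }
  prior <- function(rho) {
    exp((al - 1) * log1p(-rho^2) - lbeta(al, al) - (2 * al - 1) * log(2))
  }
  I <- stats::integrate(function(rho) lik_ratio(rho) * prior(rho), -1, 1,
                        rel.tol = rel_tol, subdivisions = 500L)
  if (I$message != "OK")
    stop("non-convergent quadrature in stretched-beta Bayes factor")
  log10(I$value)
}

#' JZS Bayes factor for a correlation
#'
#' Computes `log10(BF10)` for the presence of an association given a sample
#' correlation `r` at sample size `n`, under a Jeffreys-Zellner-Siow prior
#' with width `rscale`. The default (`method = "regression"`) is the
#' single-covariate Zellner-Siow regression Bayes factor,
#' \deqn{BF_{10} = \int_0^\infty (1+g)^{(n-2)/2} (1 + g(1-r^2))^{-(n-1)/2}
#'   \pi(g)\, dg,}
#' with \eqn{\pi(g)} the inverse-gamma(1/2, \eqn{n\,rscale^2/2}) mixing
#' density that makes the implied effect-size prior a Cauchy of scale
#' `rscale`; 0.354 (close to \eqn{\sqrt 2 / 4}) is the conventional medium
#' width for one continuous covariate. `method = "stretched-beta"` instead
#' places a stretched Beta(1/rscale, 1/rscale) prior directly on the
#' population correlation and integrates the exact sampling density of `r`.
#' Both are evaluated by adaptive quadrature on a transformed axis to a
#' relative tolerance of 1e-8, and both depend on `r` only through `r^2`.
#'
#' @param n Number of observations (> 3).
#' @param r Sample correlation(s), each strictly inside (-1, 1).
#' @param rscale Prior scale (default 0.354).
#' @param method `"regression"` (default) or `"stretched-beta"`.
#' @return `log10(BF10)`, vectorised over `r`.
#' @seealso [jzs_log10_bf_mc()] for a Monte-Carlo estimate of the regression
#'   form used as an independent numerical cross-check.
#' @export
jzs_log10_bf_from_r <- function(n, r, rscale = 0.354,
                                method = c("regression", "stretched-beta")) {
  method <- match.arg(method)
  if (length(n) != 1L || !is.finite(n) || n <= 3)
    stop("'n' must be a single number > 3")
  if (rscale <= 0) stop("'rscale' must be positive")
  if (any(!is.finite(r)) || any(abs(r) >= 1 - 1e-12))
    stop("|r| must be < 1 - 1e-12")
  fun <- switch(method,
                regression = jzs_regression_log10_bf,
                `stretched-beta` = stretched_beta_log10_bf)
  vapply(r, function(ri) fun(n, ri, rscale), numeric(1L))
}

#' Monte-Carlo estimate of the regression-form JZS Bayes factor
#'
#' Estimates the same integral as [jzs_log10_bf_from_r()] (regression form)
#' by drawing `g` from its inverse-gamma prior and averaging the
#' likelihood-ratio term. Used as an independent simulation-based
#' cross-check of the quadrature; with `ndraws = 1e7` the two agree to about
#' three decimals. Uses the current RNG state; seed it for reproducibility.
#'
#' @inheritParams jzs_log10_bf_from_r
#' @param ndraws Number of prior draws (default 1e7).
#' @return An estimate of `log10(BF10)` (scalar `r` only).
#' @export
jzs_log10_bf_mc <- function(n, r, rscale = 0.354, ndraws = 1e7) {
  stopifnot(length(r) == 1L, abs(r) < 1, n > 3)
  b <- n * rscale^2 / 2
  g <- 1 / stats::rgamma(ndraws, shape = 0.5, rate = b)
  lw <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r^2))
  M <- max(lw)
  (M + log(mean(exp(lw - M)))) / log(10)
}

#' Pairwise Bayes factor for two aligned sample vectors
#'
#' Drops pairs with a missing value in either vector (pairwise-complete
#' observations), computes the Pearson correlation of the remainder, and
#' delegates to [jzs_log10_bf_from_r()].
#'
#' @param x,y Numeric vectors aligned by sample.
#' @param rscale,method Passed to [jzs_log10_bf_from_r()].
#' @param cap_degenerate If `TRUE`, a degenerate pair with `|r| = 1` is
#'   capped at `|r| = 1 - 1e-8` with a warning instead of erroring.
#' @return A list with `log10_bf`, `r` (Pearson) and `n_obs`.
#' @export
pair_log10_bf <- function(x, y, rscale = 0.354,
                          method = c("regression", "stretched-beta"),
                          cap_degenerate = FALSE) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("fewer than 4 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate pair: zero variance in one of the vectors")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    if (!cap_degenerate)
      stop("degenerate pair: |r| = 1 (perfectly collinear vectors)")
    warning("degenerate pair capped at |r| = 1 - 1e-8")
    r <- sign(r) * (1 - 1e-8)
  }
  list(log10_bf = jzs_log10_bf_from_r(n, r, rscale, method),
       r = r, n_obs = n)
}

#' Spearman rank correlation with midranks for ties
#'
#' The Pearson correlation of the average ranks of the pairwise-complete
#' observations. Used to assign a direction to each association.
#'
#' @param x,y Numeric vectors aligned by sample.
#' @return The Spearman coefficient, or `NA` (with a warning) when either
#'   vector is constant so that the direction is undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fewer than 3 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: direction undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Classify the strength of evidence of a Bayes factor
#'
#' Kass-Raftery style bands on the common logarithm of BF10:
#' `"none"` below 0.5, `"substantial"` in \[0.5, 1), `"strong"` in \[1, 2),
#' `"decisive"` at 2 or above.
#'
#' @param log10_bf Numeric vector of `log10(BF10)` values (finite).
#' @return Character vector of evidence classes.
#' @export
classify_evidence <- function(log10_bf) {
  if (any(!is.finite(log10_bf))) stop("log10_bf must be finite")
  out <- rep("none", length(log10_bf))
  out[log10_bf >= 0.5] <- "substantial"
  out[log10_bf >= 1.0] <- "strong"
  out[log10_bf >= 2.0] <- "decisive"
  out
}

#' Wrap a matrix of aligned variables as a network block
#'
#' @param values Numeric samples x variables matrix with dimnames.
#' @param modality `"T"` (taxa), `"M"` (modules) or `"PP"`
#'   (psychopathology scores).
#' @return A `node_block` object.
#' @export
node_block <- function(values, modality = c("T", "M", "PP")) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !is.null(rownames(values)))
  structure(list(values = values, modality = modality),
            class = "node_block")
}

as_node_block <- function(x) {
  if (inherits(x, "node_block")) return(x)
  if (inherits(x, "transformed_table"))
    return(node_block(x$values,
                      modality = c(taxon = "T", module = "M")[x$modality]))
  if (inherits(x, "abundance_table"))
    return(node_block(x$values,
                      modality = c(taxon = "T", module = "M")[x$modality]))
  stop("blocks must be node_block, transformed_table or abundance_table")
}

#' Joint pairwise association edges over multiple blocks
#'
#' Computes `log10(BF10)` and the Spearman direction for every unordered pair
#' of variables drawn from the given blocks (taxa, modules, psychopathology
#' scores). The underlying correlation matrix is symmetric, so only its upper
#' triangle is materialised. Degenerate pairs (zero variance or `|r| = 1`)
#' are skipped with a warning.
#'
#' @param blocks List of blocks sharing sample alignment: `node_block`,
#'   `transformed_table` or `abundance_table` objects.
#' @param rscale,method Passed to [jzs_log10_bf_from_r()].
#' @return A data frame of association edges: `node_a`, `node_b`,
#'   `modality_a`, `modality_b`, `n_obs`, `log10_bf`, `rho`, `evidence`.
#' @export
joint_edge_matrix <- function(blocks, rscale = 0.354,
                              method = c("regression", "stretched-beta")) {
  method <- match.arg(method)
  blocks <- lapply(blocks, as_node_block)
  ids <- lapply(blocks, function(b) rownames(b$values))
  for (i in seq_along(blocks)[-1L])
    if (!identical(ids[[i]], ids[[1L]]))
      stop("all blocks must share identical sample alignment")
  big <- do.call(cbind, lapply(blocks, `[[`, "values"))
  modal <- unlist(lapply(blocks, function(b)
    rep(b$modality, ncol(b$values))))
  nodes <- colnames(big)
  if (anyDuplicated(nodes))
    stop("duplicate node identifiers across blocks: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  p <- ncol(big)
  pairs <- utils::combn(p, 2L)
  rows <- vector("list", ncol(pairs))
  skipped <- character(0)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    frag <- tryCatch(
      pair_log10_bf(big[, i], big[, j], rscale = rscale, method = method),
      error = function(e) e)
    if (inherits(frag, "error")) {
      skipped <- c(skipped, paste0(nodes[i], " ~ ", nodes[j]))
      next
    }
    rows[[k]] <- data.frame(
      node_a = nodes[i], node_b = nodes[j],
      modality_a = modal[i], modality_b = modal[j],
      n_obs = frag$n_obs, log10_bf = frag$log10_bf,
      rho = spearman_rho(big[, i], big[, j]),
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L)
    warning("skipped ", length(skipped), " degenerate pair(s): ",
            paste(utils::head(skipped, 5L), collapse = "; "),
            if (length(skipped) > 5L) " ..." else "")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out$evidence <- classify_evidence(out$log10_bf)
  out
}

#' Write an association edge list to a tab-separated file
#'
#' @param edges Edge data frame as produced by [joint_edge_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
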