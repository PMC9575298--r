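# Sample QC, prevalence filtering, CLR transformation and nuisance-covariate
# adjustment. The residual matrices produced here feed every association test.

#' Construct a transformed table
#'
#' Holds a real-valued sample x feature matrix on the CLR or residual scale,
#' together with a provenance record of the filters and covariates applied.
#'
#' @param values Numeric matrix with sample row names and feature column
#'   names.
#' @param modality `"taxon"` or `"module"`.
#' @param stage `"clr"` or `"adjusted"`.
#' @param provenance A list recording how the matrix was produced.
#' @return An object of class `transformed_table`.
#' @export
transformed_table <- function(values, modality = c("taxon", "module"),
                              stage = c("clr", "adjusted"),
                              provenance = list()) {
  modality <- match.arg(modality)
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values)))
    stop("transformed values must be finite")
  if (stage == "clr" && any(abs(rowSums(values)) > 1e-9))
    stop("CLR rows must sum to 0 within 1e-9")
  structure(list(values = values, modality = modality, stage = stage,
                 provenance = provenance),
            class = "transformed_table")
}

#' @export
print.transformed_table <- function(x, ...) {
  cat(sprintf("transformed_table: %d samples x %d features [%s, stage=%s]\n",
              nrow(x$values), ncol(x$values), x$modality, x$stage))
  invisible(x)
}

#' Sample quality control by annotation richness
#'
#' Removes samples in which the number of annotated (nonzero) features falls
#' below `min_features` in either the taxonomic or the functional table; a
#' sample is retained only if it clears the bound in both.
#'
#' @param taxa,modules `abundance_table`s sharing a sample universe.
#' @param min_features Minimum nonzero-feature count per table (default 50).
#' @return Character vector of retained sample identifiers, in the order of
#'   the taxonomic table.
#' @export
qc_filter_samples <- function(taxa, modules, min_features = 50L) {
  stopifnot(inherits(taxa, "abundance_table"),
            inherits(modules, "abundance_table"))
  shared <- intersect(sample_ids(taxa), sample_ids(modules))
  if (length(shared) == 0L)
    stop("taxonomic and functional tables share no samples")
  rich_t <- rowSums(taxa$values[shared, , drop = FALSE] > 0)
  rich_m <- rowSums(modules$values[shared, , drop = FALSE] > 0)
  keep <- shared[rich_t >= min_features & rich_m >= min_features]
  sample_ids(taxa)[sample_ids(taxa) %in% keep]
}

#' Prevalence filtering
#'
#' Keeps features with a nonzero value in at least `min_prevalence` samples.
#' Apply after sample QC so that prevalence is counted on the retained
#' sample set.
#'
#' @param table An `abundance_table`.
#' @param min_prevalence Minimum number of samples a feature must be present
#'   in (default 15).
#' @return The filtered `abundance_table`.
#' @export
prevalence_filter <- function(table, min_prevalence = 15L) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table$values) < min_prevalence)
    stop(sprintf("table has %d samples, fewer than min_prevalence = %d",
                 nrow(table$values), min_prevalence))
  prev <- colSums(table$values > 0)
  keep <- prev >= min_prevalence
  if (!any(keep))
    stop(sprintf(
      "no feature is present in >= %d samples; reduce the threshold",
      min_prevalence))
  table[, keep]
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its row sum.
#'
#' @param table An `abundance_table` with `unit = "count"`.
#' @param on_relative What to do when the input is already relative:
#'   `"error"` (default) or `"pass"` (return unchanged).
#' @return An `abundance_table` with `unit = "relative"`; rows sum to 1
#'   within 1e-12.
#' @export
to_relative <- function(table, on_relative = c("error", "pass")) {
  stopifnot(inherits(table, "abundance_table"))
  on_relative <- match.arg(on_relative)
  if (table$unit == "relative") {
    if (on_relative == "pass") return(table)
    stop("table is already on the relative scale")
  }
  rs <- rowSums(table$values)
  if (any(rs == 0))
    stop("all-zero sample row(s): ",
         paste(rownames(table$values)[rs == 0], collapse = ", "))
  abundance_table(table$values / rs, modality = table$modality,
                  unit = "relative",
                  feature_annotation = table$feature_annotation)
}

#' Centred log-ratio transformation
#'
#' Maps each compositional sample to an unconstrained scale:
#' `clr(p)_j = ln(p'_j) - mean_k ln(p'_k)`, where `p'` is the zero-replaced,
#' re-closed composition over the features of the table. Because microbiome
#' compositions contain structural zeros, zeros are first replaced by a
#' strictly positive pseudo-abundance and rows are re-closed; the default
#' policy uses half the smallest nonzero relative abundance observed anywhere
#' in the table, a simple multiplicative replacement that keeps the transform
#' well defined without disturbing the nonzero part of the composition.
#'
#' @param table An `abundance_table` with `unit = "relative"` (run
#'   [to_relative()] first).
#' @param pseudocount `"half-min-nonzero"` (default) or a positive number to
#'   use as the replacement value directly.
#' @return A `transformed_table` with `stage = "clr"`; every row sums to 0
#'   within 1e-9.
#' @export
clr_transform <- function(table, pseudocount = "half-min-nonzero") {
  stopifnot(inherits(table, "abundance_table"))
  if (table$unit != "relative")
    stop("CLR is defined on relative abundances; run to_relative() first")
  v <- table$values
  if (any(rowSums(v) == 0))
    stop("all-zero sample row(s): ",
         paste(rownames(v)[rowSums(v) == 0], collapse = ", "))
  if (any(v == 0)) {
    repl <- if (identical(pseudocount, "half-min-nonzero")) {
      0.5 * min(v[v > 0])
    } else {
      if (!is.numeric(pseudocount) || pseudocount <= 0)
        stop("'pseudocount' must be 'half-min-nonzero' or a positive number")
      pseudocount
    }
    v[v == 0] <- repl
  }
  v <- v / rowSums(v)
  lv <- log(v)
  clr <- lv - rowMeans(lv)
  transformed_table(clr, modality = table$modality, stage = "clr",
                    provenance = list(pseudocount = pseudocount,
                                      n_features = ncol(v)))
}

# Build the numeric nuisance design matrix (without intercept) from metadata.
# diagnosis is coded 0 = CD, 1 = UC; sex and the medication flags are 0/1.
covariate_design <- function(meta, covariates) {
  stopifnot(inherits(meta, "sample_metadata"))
  missing_cols <- setdiff(covariates, colnames(meta))
  if (length(missing_cols) > 0L)
    stop("metadata lacks configured covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  if (length(covariates) == 0L)
    return(matrix(numeric(0), nrow(meta), 0L,
                  dimnames = list(meta$sample_id, NULL)))
  cols <- lapply(covariates, function(cv) {
    x <- meta[[cv]]
    if (cv == "diagnosis") as.numeric(x == "UC") else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  dimnames(X) <- list(meta$sample_id, covariates)
  X
}

fit_nuisance_qr <- function(t, meta, covariates) {
  stopifnot(inherits(t, "transformed_table"))
  Y <- t$values
  meta <- meta[match(rownames(Y), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("metadata is missing sample(s): ",
         paste(setdiff(rownames(Y), meta$sample_id), collapse = ", "))
  X <- covariate_design(meta, covariates)
  complete <- rowSums(is.na(X)) == 0L
  if (!all(complete)) {
    message(sum(!complete), " sample(s) dropped for missing covariates: ",
            paste(rownames(Y)[!complete], collapse = ", "))
    Y <- Y[complete, , drop = FALSE]
    X <- X[complete, , drop = FALSE]
  }
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df_resid <- nrow(D) - ncol(D)
  if (df_resid < 3L)
    stop(sprintf("residual degrees of freedom %d < 3", df_resid))
  list(Y = Y, D = D, qr = qrD, df_resid = df_resid,
       n_dropped = sum(!complete))
}

#' Adjust CLR abundances for nuisance covariates
#'
#' Fits, feature-wise, an ordinary least-squares regression of the
#' CLR-transformed abundance on the nuisance covariates (with intercept) and
#' returns the residuals. All downstream association tests operate on these
#' residuals. Samples missing any covariate are dropped with a message;
#' the residual degrees of freedom must be at least 3.
#'
#' @param t A `transformed_table` (stage `"clr"`).
#' @param meta A `sample_metadata` data frame covering the table's samples.
#' @param covariates Character vector of covariate column names; the default
#'   is the ten nuisance variables `age`, `sex`, `diagnosis`, `crp` and the
#'   six medication flags.
#' @return A `transformed_table` with `stage = "adjusted"`; residuals are
#'   orthogonal to every covariate column (and the intercept) within 1e-8.
#' @export
adjust_nuisance <- function(t, meta, covariates = default_covariates()) {
  fit <- fit_nuisance_qr(t, meta, covariates)
  res <- qr.resid(fit$qr, fit$Y)
  transformed_table(res, modality = t$modality, stage = "adjusted",
                    provenance = c(t$provenance,
                                   list(covariates = covariates,
                                        df_resid = fit$df_resid,
                                        n_dropped_samples = fit$n_dropped)))
}

#' The default nuisance covariate set
#'
#' Age, sex, diagnosis, CRP and the six medication classes (steroids,
#' mesalamine, immunosuppressants, hormonal contraceptives, antidepressants,
#' proton pump inhibitors) - ten variables in total.
#'
#' @return Character vector of length 10.
#' @export
default_covariates <- function() {
  c("age", "sex", "diagnosis", "crp", .meta_binary_flags)
}

#' Per-feature covariate effect report
#'
#' For every feature, reports the post-hoc t-statistic of each nuisance
#' covariate (coefficient over its standard error) and the variance
#' explanation (R squared) of the full nuisance regression.
#'
#' @inheritParams adjust_nuisance
#' @return A data frame with one row per feature: `feature`, `r_squared` and
#'   one `t_<covariate>` column per covariate.
#' @export
covariate_effect_report <- function(t, meta, covariates = default_covariates()) {
  fit <- fit_nuisance_qr(t, meta, covariates)
  coefs <- qr.coef(fit$qr, fit$Y)           # (p+1) x features
  res <- qr.resid(fit$qr, fit$Y)
  rss <- colSums(res^2)
  sigma2 <- rss / fit$df_resid
  xtx_inv <- chol2inv(qr.R(fit$qr))
  dimnames(xtx_inv) <- list(colnames(fit$D), colnames(fit$D))
  se <- sqrt(outer(diag(xtx_inv), sigma2))  # (p+1) x features
  tstat <- coefs / se
  tss <- colSums(scale(fit$Y, center = TRUE, scale = FALSE)^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  out <- data.frame(feature = colnames(fit$Y), r_squared = r2,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cv in covariates)
    out[[paste0("t_", cv)]] <- tstat[cv, ]
  out
}
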