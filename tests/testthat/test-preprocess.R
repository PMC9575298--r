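test_that("sample QC removes samples under-annotated in either table", {
  set.seed(1)
  mt <- matrix(rpois(3 * 60, 5) + 1, 3, 60,
               dimnames = list(c("s1", "s2", "s3"), sprintf("g%02d", 1:60)))
  mm <- matrix(rpois(3 * 200, 5) + 1, 3, 200,
               dimnames = list(c("s1", "s2", "s3"), sprintf("m%03d", 1:200)))
  mt["s2", 1:11] <- 0                       # 49 nonzero genera, boundary
  taxa <- abundance_table(mt + 0, "taxon", "count")
  mods <- abundance_table(mm + 0, "module", "count")
  expect_identical(qc_filter_samples(taxa, mods, 50L), c("s1", "s3"))
  expect_identical(qc_filter_samples(taxa, mods, 10L), c("s1", "s2", "s3"))
})

test_that("a 62-sample cohort with 5 planted low-richness samples keeps 57", {
  co <- generate_cohort(cohort_spec(low_richness_samples = 5L, seed = 2L))
  keep <- qc_filter_samples(co$taxa, co$modules, 50L)
  expect_false(any(sprintf("S%03d", 58:62) %in% keep))
  expect_equal(length(keep), 57L)
})

test_that("prevalence filter keeps features present in enough samples", {
  set.seed(3)
  m <- matrix(rpois(57 * 4, 8) + 1, 57, 4,
              dimnames = list(sprintf("s%02d", 1:57), paste0("f", 1:4)))
  m[15:57, 2] <- 0                          # present in 14 samples only
  m[, 4] <- 0
  tab <- abundance_table(m + 0, "taxon", "count")
  expect_identical(colnames(prevalence_filter(tab, 15L)$values),
                   c("f1", "f3"))
  expect_identical(colnames(prevalence_filter(tab, 1L)$values),
                   c("f1", "f2", "f3"))
  expect_error(prevalence_filter(tab, 58L), "fewer than")

  # brute-force enumeration on a small matrix
  m5 <- matrix(c(1, 0, 0, 0, 0,
                 1, 1, 0, 0, 0,
                 0, 1, 1, 0, 1), 5, 3,
               dimnames = list(paste0("s", 1:5), paste0("f", 1:3)))
  tab5 <- abundance_table(m5, "taxon", "count")
  expected <- names(which(colSums(m5 > 0) >= 2L))
  expect_identical(colnames(prevalence_filter(tab5, 2L)$values), expected)
})

test_that("relative transformation closes rows", {
  m <- matrix(c(2, 2, 4), 1, 3, dimnames = list("s1", paste0("f", 1:3)))
  rel <- to_relative(abundance_table(m, "taxon", "count"))
  expect_equal(unname(rel$values[1, ]), c(0.25, 0.25, 0.5))
  expect_error(to_relative(rel), "already")
  expect_identical(to_relative(rel, on_relative = "pass"), rel)

  tab <- toy_counts(6L, 5L)
  expect_equal(unname(rowSums(to_relative(tab)$values)), rep(1, 6),
               tolerance = 1e-12)
  m0 <- m; m0[1, ] <- 0
  expect_error(to_relative(abundance_table(m0, "taxon", "count")), "s1")
})

test_that("CLR matches hand evaluation and its invariances", {
  mk <- function(v) abundance_table(
    matrix(v, 1, 3, dimnames = list("s", paste0("f", 1:3))),
    "taxon", "relative")
  expect_equal(unname(clr_transform(mk(c(1, 1, 1) / 3))$values[1, ]),
               c(0, 0, 0), tolerance = 1e-12)
  # ln(p/gm): hand evaluation for (0.5, 0.25, 0.25)
  expect_equal(unname(clr_transform(mk(c(0.5, 0.25, 0.25)))$values[1, ]),
               c(0.462098, -0.231049, -0.231049), tolerance = 1e-5)

  # scale invariance: closure removes any sample-wise count rescaling
  tab <- toy_counts(8L, 6L, seed = 9L)
  scaled <- abundance_table(tab$values * 2, "taxon", "count")
  expect_equal(clr_transform(to_relative(tab))$values,
               clr_transform(to_relative(scaled))$values, tolerance = 1e-12)

  # rows sum to zero even with zero replacement in play
  set.seed(10)
  m <- matrix(rpois(20 * 12, 3), 20, 12,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("f%02d", 1:12)))
  m[, 1] <- m[, 1] + 1
  clr <- clr_transform(to_relative(abundance_table(m + 0, "taxon", "count")))
  expect_lt(max(abs(rowSums(clr$values))), 1e-9)
  expect_true(all(is.finite(clr$values)))
})

test_that("nuisance adjustment reproduces textbook least squares", {
  meta <- toy_metadata(6L)
  covs <- c("age", "crp")
  set.seed(11)
  Y <- matrix(rnorm(6 * 3), 6, 3,
              dimnames = list(meta$sample_id, paste0("f", 1:3)))
  Y <- Y - rowMeans(Y)  # a valid clr-stage matrix
  t_in <- transformed_table(Y, "taxon", "clr")
  adj <- adjust_nuisance(t_in, meta, covs)
  X <- cbind(meta$age, meta$crp)
  expect_equal(adj$values, normal_equations_residuals(Y, X),
               tolerance = 1e-10)
  # orthogonality to design incl. intercept
  expect_lt(max(abs(crossprod(cbind(1, X), adj$values))), 1e-8)

  # feature exactly linear in covariates -> zero residuals
  v <- 2 * meta$age - 0.5 * meta$crp + 3
  Yl <- cbind(f1 = v, f2 = -v)
  rownames(Yl) <- meta$sample_id
  adj_l <- adjust_nuisance(transformed_table(Yl, "taxon", "clr"), meta, covs)
  expect_lt(max(abs(adj_l$values)), 1e-9)

  # intercept-only model = centring
  adj_c <- adjust_nuisance(t_in, meta, character(0))
  expect_equal(adj_c$values, scale(Y, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("rank-deficient designs and low degrees of freedom are rejected", {
  meta <- toy_metadata(6L)
  meta$crp <- meta$age * 2                   # collinear
  Y <- matrix(rnorm(12), 6, 2, dimnames = list(meta$sample_id, c("a", "b")))
  Y <- Y - rowMeans(Y)
  t_in <- transformed_table(Y, "taxon", "clr")
  expect_error(adjust_nuisance(t_in, meta, c("age", "crp")), "collinear")
  expect_error(adjust_nuisance(t_in, meta, c("age", "sex", "weimus")),
               "degrees of freedom")
})

test_that("samples missing a covariate are dropped with a message", {
  meta <- toy_metadata(8L)
  meta$crp[2L] <- NA
  meta <- sample_metadata(meta)
  Y <- matrix(rnorm(16), 8, 2, dimnames = list(meta$sample_id, c("a", "b")))
  Y <- Y - rowMeans(Y)
  expect_message(
    adj <- adjust_nuisance(transformed_table(Y, "taxon", "clr"), meta,
                           c("age", "crp")),
    "missing covariates")
  expect_equal(nrow(adj$values), 7L)
  expect_false("S02" %in% rownames(adj$values))
})

test_that("covariate effect report matches per-feature lm fits", {
  co <- generate_cohort(cohort_spec(n_samples = 40L, n_taxa = 12L,
                                    n_modules = 20L, seed = 12L))
  clr <- clr_transform(to_relative(co$taxa))
  rep10 <- covariate_effect_report(clr, co$metadata)
  meta <- co$metadata
  X <- data.frame(age = meta$age, sex = meta$sex,
                  diagnosis = as.numeric(meta$diagnosis == "UC"),
                  crp = meta$crp, steroid = meta$steroid,
                  mesalamine = meta$mesalamine,
                  immunosuppressant = meta$immunosuppressant,
                  contraceptive = meta$contraceptive,
                  antidepressant = meta$antidepressant, ppi = meta$ppi)
  for (j in c(1L, 7L)) {
    fit <- lm(clr$values[, j] ~ ., data = X)
    sm <- summary(fit)
    expect_equal(unlist(rep10[j, paste0("t_", colnames(X))],
                        use.names = FALSE),
                 unname(sm$coefficients[-1L, "t value"]), tolerance = 1e-8)
    expect_equal(rep10$r_squared[j], sm$r.squared, tolerance = 1e-10)
  }
})

test_that("covariate effect report separates signal from noise", {
  set.seed(13)
  n <- 200L
  meta <- sample_metadata(data.frame(
    sample_id = sprintf("s%03d", 1:n),
    age = round(runif(n, 20, 70)), sex = rbinom(n, 1, 0.5),
    diagnosis = sample(c("CD", "UC"), n, replace = TRUE),
    crp = runif(n, 1, 50), fcal = runif(n, 50, 700),
    steroid = rbinom(n, 1, 0.4), mesalamine = rbinom(n, 1, 0.4),
    immunosuppressant = rbinom(n, 1, 0.3),
    contraceptive = rbinom(n, 1, 0.2), antidepressant = rbinom(n, 1, 0.2),
    ppi = rbinom(n, 1, 0.3), hads_d = rbinom(n, 21, 0.3),
    weimus = rbinom(n, 68, 0.45), stringsAsFactors = FALSE))
  mk <- function(v, name) {
    m <- cbind(v, -v)
    dimnames(m) <- list(meta$sample_id, c(name, paste0(name, "_mirror")))
    transformed_table(m, "taxon", "clr")
  }
  rep_null <- covariate_effect_report(mk(rnorm(n), "f_null"), meta)
  expect_lt(rep_null$r_squared[1L], 0.15)
  expect_lt(max(abs(rep_null[1L, grep("^t_", names(rep_null))])), 4)
  rep_sig <- covariate_effect_report(
    mk(2 * meta$age + rnorm(n, 0, 1e-4), "f_age"), meta)
  expect_gt(rep_sig$r_squared[1L], 0.999)
})

test_that("prevalence filtering commutes with closure", {
  tab <- toy_counts(20L, 15L, seed = 14L)
  v <- tab$values; v[v < 12] <- 0
  tab <- abundance_table(v, "taxon", "count")
  keep_before <- colnames(prevalence_filter(tab, 3L)$values)
  rel <- to_relative(abundance_table(
    v[rowSums(v) > 0, , drop = FALSE], "taxon", "count"))
  keep_after <- colnames(prevalence_filter(rel, 3L)$values)
  expect_identical(keep_before, keep_after)
})
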