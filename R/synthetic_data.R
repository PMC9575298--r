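# Synthetic cohort generator. Emulates the post-annotation data of an
# active-IBD faecal metagenomics cohort: compositional count tables with
# zeros for ~57 samples, ~59 prevalent genera and ~209 functional modules,
# nuisance-covariate effects on abundances, and planted
# taxon-module-symptom triangles induced by shared latent factors.

#' Specify a synthetic cohort
#'
#' The defaults mirror the cohort the analysis is designed for: 57 samples
#' (optionally plus a few low-richness samples that the QC step should
#' remove), 59 prevalent genera, 209 functional modules, compositional
#' counts with zero inflation, covariate effects on abundances, and planted
#' latent associations with target correlations in the 0.3-0.5 range.
#'
#' @param n_samples Number of regular samples (default 57, minimum 10).
#' @param n_taxa,n_modules Number of genus / module features (defaults 59
#'   and 209).
#' @param depth Mean total count per sample and table (default 1e5).
#' @param covariate_effects List of effects, each a list with elements
#'   `covariate` (metadata column), `modality` (`"taxon"`/`"module"`),
#'   `features` (indices) and `effect` (CLR-scale units per covariate
#'   unit). `NULL` for none; the default plants an antidepressant effect on
#'   three genera, a steroid effect on three modules and a weak age trend.
#' @param planted_motifs List of planted triangles, each a list with
#'   `taxon` (feature index), `module` (feature index), `symptom`
#'   (`"hads"` or `"weimus"`) and `rho` (target absolute pairwise
#'   correlation of all three planted pairs, in (0, 0.95)). `NULL` for a
#'   null cohort.
#' @param noise_sd Residual CLR-scale standard deviation per feature
#'   (default 1).
#' @param zero_inflation Mean dropout probability for module features
#'   (default 0.3); dropout rises with feature rarity, and the taxonomic
#'   table receives a twentieth of it so that regular samples keep the
#'   annotation richness of a QC-passing cohort.
#' @param low_richness_samples Number of extra samples with drastically
#'   reduced annotation richness, to exercise sample QC (default 0).
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 57L, n_taxa = 59L, n_modules = 209L,
                        depth = 1e5,
                        covariate_effects = default_covariate_effects(),
                        planted_motifs = NULL, noise_sd = 1,
                        zero_inflation = 0.3, low_richness_samples = 0L,
                        seed = 1L) {
  if (n_samples < 10L) stop("n_samples must be >= 10")
  if (depth <= 0) stop("depth must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (zero_inflation < 0 || zero_inflation > 0.6)
    stop("zero_inflation must be in [0, 0.6]")
  planted_motifs <- lapply(planted_motifs, function(pm) {
    stopifnot(is.list(pm),
              all(c("taxon", "module", "symptom", "rho") %in% names(pm)))
    if (!pm$symptom %in% c("hads", "weimus"))
      stop("planted symptom must be 'hads' or 'weimus'")
    if (pm$taxon < 1L || pm$taxon > n_taxa ||
        pm$module < 1L || pm$module > n_modules)
      stop("planted feature index out of range")
    if (abs(pm$rho) <= 0 || abs(pm$rho) >= 0.95)
      stop(sprintf(
        "infeasible target correlation %.3f: the latent-factor loading for noise_sd = %.2f requires |rho| in (0, 0.95)",
        pm$rho, noise_sd))
    pm
  })
  qsq <- vapply(c("hads", "weimus"), function(sy) {
    sum(vapply(planted_motifs,
               function(pm) if (pm$symptom == sy) abs(pm$rho) else 0, 0))
  }, 0)
  if (any(qsq > 0.95))
    stop("infeasible planted motifs: total latent variance share on one ",
         "symptom exceeds 0.95")
  structure(list(n_samples = as.integer(n_samples),
                 n_taxa = as.integer(n_taxa),
                 n_modules = as.integer(n_modules), depth = depth,
                 covariate_effects = covariate_effects,
                 planted_motifs = planted_motifs, noise_sd = noise_sd,
                 zero_inflation = zero_inflation,
                 low_richness_samples = as.integer(low_richness_samples),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default synthetic covariate effects
#'
#' Antidepressant use shifts three genera by 1 CLR unit, steroid use shifts
#' three modules by 0.8 CLR units, and age adds a weak trend to two genera -
#' enough structure for the nuisance adjustment to have visible work to do.
#'
#' @return A list of covariate-effect descriptors (see [cohort_spec()]).
#' @export
default_covariate_effects <- function() {
  list(list(covariate = "antidepressant", modality = "taxon",
            features = c(2L, 3L, 4L), effect = 1.0),
       list(covariate = "steroid", modality = "module",
            features = c(3L, 4L, 5L), effect = 0.8),
       list(covariate = "age", modality = "taxon",
            features = c(5L, 6L), effect = 0.03))
}

#' Expected motif list implied by a cohort specification
#'
#' Deterministically maps the planted motifs of a specification to the
#' (deduplicated) triangles the full pipeline is expected to recover.
#'
#' @param spec A `cohort_spec`.
#' @return A data frame with columns `taxon`, `module`, `pp` (node
#'   identifiers as emitted in the tables) and `target_rho`.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(spec$planted_motifs) == 0L)
    return(data.frame(taxon = character(0), module = character(0),
                      pp = character(0), target_rho = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(spec$planted_motifs, function(pm) {
    data.frame(taxon = taxon_name(pm$taxon),
               module = module_name(pm$module),
               pp = c(hads = "HADS_D", weimus = "WEIMuS")[pm$symptom],
               target_rho = abs(pm$rho), stringsAsFactors = FALSE)
  }))
  out <- out[!duplicated(out[, c("taxon", "module", "pp")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

taxon_name <- function(i) sprintf("genus_%03d", i)
module_name <- function(i) sprintf("mod_%03d", i)

# binary flag with guaranteed variation (>= 2 carriers and 2 non-carriers),
# so that the nuisance design stays full rank at realistic prevalences
rbinary_flag <- function(n, p) {
  x <- stats::rbinom(n, 1L, p)
  while (sum(x) < 2L) x[sample.int(n, 1L)] <- 1L
  while (sum(1 - x) < 2L) x[sample.int(n, 1L)] <- 0L
  x
}

rlnorm_match <- function(n, mean, sd) {
  # lognormal draws with the given arithmetic mean and sd
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic cohort
#'
#' Draws per-sample metadata with the demographic and clinical mix of an
#' active-IBD cohort, one standard-normal latent factor per planted motif,
#' CLR-scale feature signals (baseline + covariate effects + latent loading
#' + Gaussian noise) that are mapped to compositions by softmax and to
#' counts by multinomial sampling at the given depth with additional
#' rarity-weighted dropout, and symptom scores that share the planted latent
#' factors (rounded and clipped into their questionnaire ranges, 0-21 for
#' HADS-D and 0-68 for WEIMuS).
#'
#' A planted motif with target correlation `rho` gives its taxon, module and
#' (negated) symptom latent loadings of `sqrt(rho)` each so that all three
#' pairwise correlations equal `rho` on the latent scale; feature loadings
#' are scaled by `noise_sd` accordingly.
#'
#' @param spec A `cohort_spec`.
#' @return A list with elements `taxa` and `modules` (count
#'   `abundance_table`s), `metadata` (a `sample_metadata` data frame) and
#'   `truth` (a list with the expected motif data frame, the latent factor
#'   matrix `z` and the per-feature loading matrices).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_reg <- spec$n_samples
  n <- n_reg + spec$low_richness_samples
  ids <- sprintf("S%03d", seq_len(n))

  meta <- data.frame(
    sample_id = ids,
    age = pmin(80, pmax(18, round(stats::rnorm(n, 40, 16)))),
    sex = rbinary_flag(n, 36 / 62),
    diagnosis = ifelse(stats::rbinom(n, 1L, 11 / 62) == 1L, "UC", "CD"),
    crp = round(rlnorm_match(n, 21.2, 24.8), 1),
    fcal = round(rlnorm_match(n, 365, 282), 0),
    steroid = rbinary_flag(n, 21 / 62),
    mesalamine = rbinary_flag(n, 0.30),
    immunosuppressant = rbinary_flag(n, 13 / 62),
    contraceptive = rbinary_flag(n, 0.15),
    antidepressant = rbinary_flag(n, 0.10),
    ppi = rbinary_flag(n, 0.25),
    stringsAsFactors = FALSE)
  while (length(unique(meta$diagnosis)) < 2L)
    meta$diagnosis[sample.int(n, 1L)] <- "UC"
  meta$fcal[stats::runif(n) < 4 / 57] <- NA_real_

  motifs <- spec$planted_motifs
  K <- length(motifs)
  z <- matrix(stats::rnorm(n * max(K, 1L)), n, max(K, 1L))

  build_block <- function(n_feat, modality, namer, log_range) {
    baseline <- seq(0, -log_range, length.out = n_feat) +
      stats::rnorm(n_feat, 0, 0.4)
    eta <- matrix(rep(baseline, each = n), n, n_feat) +
      matrix(stats::rnorm(n * n_feat, 0, spec$noise_sd), n, n_feat)
    loadings <- numeric(n_feat)
    for (k in seq_along(motifs)) {
      pm <- motifs[[k]]
      idx <- if (modality == "taxon") pm$taxon else pm$module
      q <- sqrt(abs(pm$rho))
      lambda <- spec$noise_sd * q / sqrt(1 - q^2)
      loadings[idx] <- loadings[idx] + lambda
      eta[, idx] <- eta[, idx] + lambda * z[, k]
    }
    for (ce in spec$covariate_effects) {
      if (!identical(ce$modality, modality)) next
      x <- meta[[ce$covariate]]
      if (ce$covariate == "diagnosis") x <- as.numeric(x == "UC")
      eta[, ce$features] <- eta[, ce$features] + outer(x, rep(ce$effect,
        length(ce$features)))
    }
    dimnames(eta) <- list(ids, namer(seq_len(n_feat)))
    list(eta = eta, loadings = loadings)
  }

  # the genus table emulates a post-QC cohort: its baseline abundance range
  # is kept narrow enough (6 natural-log units) that regular samples retain
  # the annotation richness of QC-passing patients; module baselines span 8
  # units so that, with rarity-weighted dropout, roughly a tenth of modules
  # falls under the prevalence cut as in real functional profiles
  bt <- build_block(spec$n_taxa, "taxon", taxon_name, 6)
  bm <- build_block(spec$n_modules, "module", module_name, 8)

  draw_counts <- function(eta, dropout_mean) {
    n_feat <- ncol(eta)
    depth_i <- pmax(1000, round(stats::rnorm(n, spec$depth,
                                             0.15 * spec$depth)))
    counts <- matrix(0L, n, n_feat, dimnames = dimnames(eta))
    for (i in seq_len(n)) {
      pr <- exp(eta[i, ] - max(eta[i, ]))
      counts[i, ] <- stats::rmultinom(1L, depth_i[i], pr / sum(pr))
    }
    # rarity-weighted dropout: rare features (higher column index, lower
    # baseline) are missed in more samples
    p_drop <- pmin(0.95, 2 * dropout_mean *
                     (seq_len(n_feat) - 1L) / max(1L, n_feat - 1L))
    drop <- matrix(stats::runif(n * n_feat), n, n_feat) <
      matrix(rep(p_drop, each = n), n, n_feat)
    counts[drop] <- 0L
    if (spec$low_richness_samples > 0L) {
      lri <- seq.int(n_reg + 1L, n)
      sparse <- matrix(stats::runif(length(lri) * n_feat), length(lri),
                       n_feat) > 0.08
      counts[lri, ][sparse] <- 0L
    }
    counts
  }

  taxa_counts <- draw_counts(bt$eta, spec$zero_inflation / 20)
  module_counts <- draw_counts(bm$eta, spec$zero_inflation)

  score_latent <- function(symptom) {
    qs <- vapply(motifs, function(pm)
      if (pm$symptom == symptom) sqrt(abs(pm$rho)) else 0, 0)
    signal <- if (K > 0L) as.vector(z[, seq_len(K), drop = FALSE] %*%
                                      (-qs[seq_len(K)])) else numeric(n)
    share <- sum(qs^2)
    signal + sqrt(max(0, 1 - share)) * stats::rnorm(n)
  }
  meta$hads_d <- pmax(0, pmin(21, round(6.5 + 4.5 * score_latent("hads"))))
  meta$weimus <- pmax(0, pmin(68, round(31.5 + 14.7 *
                                          score_latent("weimus"))))
  meta <- sample_metadata(meta[, .meta_required_cols])

  list(taxa = abundance_table(taxa_counts + 0, modality = "taxon",
                              unit = "count"),
       modules = abundance_table(module_counts + 0, modality = "module",
                                 unit = "count"),
       metadata = meta,
       truth = list(motifs = planted_truth(spec),
                    z = z[, seq_len(max(K, 0L)), drop = FALSE],
                    taxa_loadings = bt$loadings,
                    module_loadings = bm$loadings))
}

#' Write a synthetic cohort to disk in the pipeline's file dialects
#'
#' Emits `taxa.tsv`, `modules.tsv` and `metadata.tsv` under `dir`, in
#' exactly the formats [read_abundance_table()] and [read_sample_metadata()]
#' consume, plus `truth.tsv` with the planted motif list.
#'
#' @param spec A `cohort_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list returned by [generate_cohort()].
#' @export
write_cohort_fixture <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- generate_cohort(spec)
  write_abundance_table(cohort$taxa, file.path(dir, "taxa.tsv"), digits = 10)
  write_abundance_table(cohort$modules, file.path(dir, "modules.tsv"),
                        digits = 10)
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(cohort$truth$motifs, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cohort)
}
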