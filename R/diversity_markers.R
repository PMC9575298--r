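# Shannon alpha diversity and the bivariate Bayesian associations between
# symptom scores and the clinical markers (CRP, faecal calprotectin) and
# diversity.

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` over the nonzero entries of a relative
#' abundance vector, in natural-log units. For a matrix the index is
#' computed per sample row.
#'
#' @param p Relative-abundance vector summing to 1 (within `tol`), or a
#'   samples x features matrix of such rows.
#' @param tol Tolerance on the row sums (default 1e-9).
#' @return A numeric value (or per-sample vector) in `[0, ln(m)]` where `m`
#'   is the number of nonzero entries.
#' @export
shannon_index <- function(p, tol = 1e-9) {
  if (is.matrix(p))
    return(apply(p, 1L, shannon_index, tol = tol))
  if (any(p < 0)) stop("negative abundance entries")
  if (abs(sum(p) - 1) > tol)
    stop("abundances must sum to 1 (use to_relative() first)")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Build a per-sample marker panel
#'
#' Collects, per sample, the Shannon diversity of the genus composition and
#' the raw clinical markers and symptom scores. Diversity is computed on
#' relative genus abundances of the QC-passed table before prevalence
#' filtering, so that the index reflects the full annotated composition
#' rather than the aggressively filtered feature set.
#'
#' @param taxa_relative An `abundance_table` with `unit = "relative"`.
#' @param meta A `sample_metadata` data frame covering the table's samples.
#' @return A data frame of class `marker_panel` with columns `sample_id`,
#'   `shannon`, `crp`, `fcal`, `hads_d`, `weimus`.
#' @export
marker_panel <- function(taxa_relative, meta) {
  stopifnot(inherits(taxa_relative, "abundance_table"),
            inherits(meta, "sample_metadata"))
  if (taxa_relative$unit != "relative")
    stop("diversity is computed on relative abundances")
  ids <- sample_ids(taxa_relative)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("metadata is missing sample(s): ",
         paste(ids[is.na(meta$sample_id)], collapse = ", "))
  out <- data.frame(sample_id = ids,
                    shannon = unname(shannon_index(taxa_relative$values)),
                    crp = meta$crp, fcal = meta$fcal,
                    hads_d = meta$hads_d, weimus = meta$weimus,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Marker-symptom Bayesian associations
#'
#' For each pairing of {CRP, faecal calprotectin, Shannon diversity} with
#' {HADS-D, WEIMuS} computes the JZS Bayes factor and Spearman direction via
#' the same engine as the network edges. Marker values enter raw (neither
#' CLR-transformed nor residualised); samples missing a marker are excluded
#' pairwise, so a missing calprotectin value affects only the calprotectin
#' edges' `n_obs`.
#'
#' @param panel A `marker_panel` data frame.
#' @param rscale,method Passed to [jzs_log10_bf_from_r()].
#' @return A data frame with one row per marker-symptom pair: `marker`,
#'   `symptom`, `n_obs`, `log10_bf`, `rho`, `evidence`.
#' @export
marker_associations <- function(panel, rscale = 0.354,
                                method = c("regression", "stretched-beta")) {
  stopifnot(inherits(panel, "marker_panel"))
  method <- match.arg(method)
  markers <- c("crp", "fcal", "shannon")
  symptoms <- c("hads_d", "weimus")
  rows <- list()
  for (mk in markers) for (sy in symptoms) {
    frag <- pair_log10_bf(panel[[mk]], panel[[sy]], rscale = rscale,
                          method = method)
    rows[[length(rows) + 1L]] <- data.frame(
      marker = mk, symptom = sy, n_obs = frag$n_obs,
      log10_bf = frag$log10_bf,
      rho = spearman_rho(panel[[mk]], panel[[sy]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$evidence <- classify_evidence(out$log10_bf)
  rownames(out) <- NULL
  out
}
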