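# Average-spectrum imaging-MS screening: cross-sample m/z alignment, TIC
# normalization, the strong-signal rule, the KW + Dunn-Bonferroni screen with
# FDR, multivariate summaries, and adduct-mass annotation. The working unit
# is a per-sample average peak list (pixel-averaged spectra), not raw pixels.

#' TIC-normalize intensities
#'
#' Divides intensities by their total ion current so the output sums to 1 and
#' samples acquired at different overall signal levels are comparable.
#' Idempotent; errors on an all-zero spectrum.
#'
#' @param intensity non-negative intensities of one spectrum.
#' @return Normalized intensities summing to 1.
#' @export
tic_normalize <- function(intensity) {
  if (any(intensity < 0)) stop("intensities must be >= 0")
  s <- sum(intensity)
  if (s <= 0) stop("cannot TIC-normalize an all-zero spectrum")
  intensity / s
}

#' Align peak lists across samples into a signal matrix
#'
#' Single-linkage clustering of all peak m/z values: sorted m/z are chained
#' into one bin while consecutive gaps stay within \code{tolerance_ppm};
#' the bin center is the intensity-weighted mean m/z. When a sample
#' contributes several peaks to one bin the most intense is kept and the
#' collision is counted (attribute \code{collisions}). Rows of the returned
#' matrix are TIC-normalized, so each row sums to 1 over the recorded range.
#'
#' @param peaks data.frame with columns \code{sample_id}, \code{group},
#'   \code{replicate}, \code{mz}, \code{intensity}.
#' @param tolerance_ppm alignment tolerance in ppm (default 10, matching the
#'   annotation tolerance).
#' @return Object of class \code{signal_matrix}: list with the samples x bins
#'   \code{matrix} (TIC-normalized), \code{mz} bin centers, \code{sum_intensity}
#'   (per-bin column sums), and per-sample \code{group}/\code{replicate}.
#' @export
align_mz <- function(peaks, tolerance_ppm = 10) {
  need <- c("sample_id", "group", "mz", "intensity")
  stopifnot(all(need %in% names(peaks)))
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  if (!nrow(peaks)) stop("empty peak table")
  o <- order(peaks$mz)
  p <- peaks[o, , drop = FALSE]
  gap_ppm <- diff(p$mz) / head(p$mz, -1) * 1e6
  bin <- cumsum(c(1L, as.integer(gap_ppm > tolerance_ppm)))
  centers <- tapply(p$mz * p$intensity, bin, sum) /
    tapply(p$intensity, bin, sum)
  # all-zero-intensity bin: fall back to the plain mean
  zero <- !is.finite(centers)
  if (any(zero)) {
    centers[zero] <- tapply(p$mz, bin, mean)[zero]
  }
  samples <- unique(peaks$sample_id)
  nb <- max(bin)
  M <- matrix(0, nrow = length(samples), ncol = nb,
              dimnames = list(samples, sprintf("mz_%.4f", centers)))
  collisions <- 0L
  for (si in seq_along(samples)) {
    sel <- p$sample_id == samples[si]
    bi <- bin[sel]; ii <- p$intensity[sel]
    if (anyDuplicated(bi)) {
      collisions <- collisions + sum(duplicated(bi))
      keep <- tapply(ii, bi, max)
      M[si, as.integer(names(keep))] <- keep
    } else {
      M[si, bi] <- ii
    }
  }
  M <- t(apply(M, 1, tic_normalize))
  meta <- unique(peaks[, intersect(c("sample_id", "group", "replicate"),
                                   names(peaks))])
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  structure(list(matrix = M, mz = unname(as.numeric(centers)),
                 sum_intensity = unname(colSums(M)),
                 group = meta$group,
                 replicate = if ("replicate" %in% names(meta)) meta$replicate
                             else rep(NA, length(samples))),
            class = "signal_matrix", collisions = collisions)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d samples x %d m/z bins (%.2f-%.2f Da)\n",
              nrow(x$matrix), ncol(x$matrix), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Select strong m/z signals
#'
#' Keeps the bins whose summed TIC-normalized intensity across all samples
#' exceeds \code{threshold_fraction} of the largest such sum (strict
#' inequality); default 5%.
#'
#' @param sm a [align_mz()] signal matrix.
#' @param threshold_fraction fraction of the largest per-bin sum, default 0.05.
#' @return Integer indices of the retained bins.
#' @export
select_strong_signals <- function(sm, threshold_fraction = 0.05) {
  stopifnot(inherits(sm, "signal_matrix"))
  s <- sm$sum_intensity
  which(s > threshold_fraction * max(s))
}

#' Significance screen over strong signals
#'
#' Per-bin Kruskal-Wallis across groups with Benjamini-Hochberg FDR over
#' bins, followed by pairwise Dunn tests (Bonferroni over pairs) within the
#' FDR-significant bins. The alternative ordering — FDR applied to the
#' pairwise Dunn p-values of all screened bins — is available via
#' \code{fdr_scope = "pairwise"}.
#'
#' Technical replicates can optionally be collapsed by averaging per
#' biological replicate first, since treating them as independent inflates n.
#'
#' @param sm signal matrix.
#' @param bins bin indices to screen (e.g. from [select_strong_signals()]).
#' @param alpha significance level, default 0.05.
#' @param fdr_scope \code{"omnibus"} (default) or \code{"pairwise"}.
#' @param collapse_technical average technical replicates per biological
#'   replicate before testing (requires \code{replicate} metadata of the form
#'   \code{"<biological>_<technical>"} or a two-column data.frame).
#' @return List with \code{omnibus} (per-bin H, raw and FDR-adjusted p) and
#'   \code{pairwise} (Dunn results for significant bins).
#' @export
screen_significance <- function(sm, bins = seq_along(sm$mz), alpha = 0.05,
                                fdr_scope = c("omnibus", "pairwise"),
                                collapse_technical = FALSE) {
  stopifnot(inherits(sm, "signal_matrix"))
  fdr_scope <- match.arg(fdr_scope)
  M <- sm$matrix[, bins, drop = FALSE]
  grp <- sm$group
  if (collapse_technical) {
    bio <- paste(grp, sub("_[^_]*$", "", as.character(sm$replicate)))
    M <- apply(M, 2, function(col) tapply(col, bio, mean))
    grp <- tapply(as.character(grp), bio, `[`, 1)
  }
  if (length(unique(grp)) < 2L) stop("need at least 2 groups")
  om <- do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
    kw <- kruskal_wallis(M[, j], grp)
    data.frame(bin = bins[j], mz = sm$mz[bins[j]],
               statistic = kw$statistic, df = kw$df, p_value = kw$p_value)
  }))
  pw_all <- lapply(seq_len(ncol(M)), function(j) {
    d <- dunn_bonferroni(M[, j], grp)
    d$bin <- bins[j]; d$mz <- sm$mz[bins[j]]
    d
  })
  if (fdr_scope == "omnibus") {
    om$p_fdr <- bh_fdr(om$p_value)
    om$significant <- om$p_fdr < alpha
    pw <- do.call(rbind, pw_all[om$significant])
    if (!is.null(pw)) pw$significant <- pw$p_adjusted < alpha
  } else {
    om$p_fdr <- bh_fdr(om$p_value)
    om$significant <- om$p_fdr < alpha
    pw <- do.call(rbind, pw_all)
    pw$p_fdr <- bh_fdr(pw$p_adjusted)
    pw$significant <- pw$p_fdr < alpha
  }
  list(omnibus = om, pairwise = pw)
}

#' PCA summary of a signal matrix
#'
#' Column-centered (optionally unit-variance scaled) principal component
#' analysis of the selected bins.
#'
#' @param sm signal matrix.
#' @param bins bin indices to use.
#' @param scale. scale columns to unit variance (default FALSE).
#' @return List with \code{scores}, \code{loadings} and
#'   \code{var_explained} (fractions, summing to <= 1); a constant matrix is
#'   flagged via \code{zero_variance}.
#' @export
pca_summary <- function(sm, bins = seq_along(sm$mz), scale. = FALSE) {
  stopifnot(inherits(sm, "signal_matrix"))
  M <- sm$matrix[, bins, drop = FALSE]
  if (nrow(M) < 2L) stop("need at least 2 samples")
  cv <- apply(M, 2, stats::var)
  if (all(cv == 0)) {
    return(list(scores = matrix(0, nrow(M), 1), loadings = NULL,
                var_explained = 0, zero_variance = TRUE))
  }
  if (scale.) M <- M[, cv > 0, drop = FALSE]
  pc <- stats::prcomp(M, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_explained = ve,
       zero_variance = FALSE)
}

#' Ward clustering of significant signals
#'
#' Z-scales each bin across samples, computes Euclidean distances, and
#' clusters rows (samples) and columns (bins) with Ward's method
#' (\code{ward.D2}). Output order is deterministic for fixed input.
#'
#' @param sm signal matrix.
#' @param bins bin indices (e.g. significant bins from the screen).
#' @param k number of sample clusters to cut (default 2).
#' @return List with \code{row_tree}, \code{col_tree} (hclust objects or NULL
#'   for single-column input), \code{row_clusters}, the scaled matrix and the
#'   leaf orders.
#' @export
ward_heatmap <- function(sm, bins = seq_along(sm$mz), k = 2) {
  stopifnot(inherits(sm, "signal_matrix"))
  M <- sm$matrix[, bins, drop = FALSE]
  if (nrow(M) < 2L) stop("need at least 2 samples")
  Z <- apply(M, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(Z) <- rownames(M)
  row_tree <- stats::hclust(stats::dist(Z), method = "ward.D2")
  col_tree <- if (ncol(Z) >= 2L) {
    stats::hclust(stats::dist(t(Z)), method = "ward.D2")
  } else NULL
  list(row_tree = row_tree, col_tree = col_tree,
       row_clusters = stats::cutree(row_tree, k = min(k, nrow(Z))),
       scaled = Z,
       row_order = row_tree$order,
       col_order = if (is.null(col_tree)) 1L else col_tree$order)
}

#' Annotate a query m/z against a formula table
#'
#' Computes theoretical adduct m/z values (monoisotopic mass plus cation mass
#' corrected for one electron) for every compound x adduct combination and
#' returns the hits within the ppm tolerance, sorted by absolute ppm error.
#' An unparsable formula is reported per entry and skipped; other entries are
#' still processed.
#'
#' @param query_mz the observed m/z (Da).
#' @param formula_table data.frame with columns \code{name} and
#'   \code{formula}; an optional \code{adducts} column (semicolon-separated)
#'   restricts the adducts tried per compound.
#' @param adducts adducts to try when the table has no per-compound list.
#' @param tolerance_ppm acceptance tolerance, default 10 ppm.
#' @return data.frame of hits: name, formula, adduct, theoretical m/z and ppm
#'   error.
#' @export
annotate_mass <- function(query_mz, formula_table,
                          adducts = c("M+H", "M+Na", "M+K", "M+2Na-H"),
                          tolerance_ppm = 10) {
  stopifnot(all(c("name", "formula") %in% names(formula_table)))
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  hits <- list()
  for (i in seq_len(nrow(formula_table))) {
    mono <- tryCatch(monoisotopic_mass(formula_table$formula[i]),
                     error = function(e) {
                       warning("entry '", formula_table$name[i], "': ",
                               conditionMessage(e))
                       NA_real_
                     })
    if (is.na(mono)) next
    add_i <- adducts
    if ("adducts" %in% names(formula_table) &&
        !is.na(formula_table$adducts[i]) && nzchar(formula_table$adducts[i])) {
      add_i <- trimws(strsplit(formula_table$adducts[i], ";")[[1]])
    }
    for (a in add_i) {
      theo <- mono + adduct_mass_shifts()[[a]]
      ppm <- (query_mz - theo) / theo * 1e6
      if (abs(ppm) <= tolerance_ppm) {
        hits[[length(hits) + 1L]] <- data.frame(
          query_mz = query_mz, name = formula_table$name[i],
          formula = formula_table$formula[i], adduct = a,
          theoretical_mz = theo, ppm_error = ppm)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(query_mz = numeric(0), name = character(0),
                      formula = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0)))
  }
  res <- do.call(rbind, hits)
  res[order(abs(res$ppm_error)), , drop = FALSE]
}

#' Bundled annotation table of screened muscle metabolites
#'
#' Loads the package's offline annotation table: tentative metabolite
#' identities (name, elemental formula, plausible cation adducts) for the
#' m/z signals screened in nuchal skeletal muscle, for use with
#' [annotate_mass()] without any live database query. The comment column
#' records known caveats (e.g. the xanthurenic acid 8-O-sulfate sodium
#' adduct computes roughly 40 ppm away from its commonly quoted m/z).
#'
#' @return data.frame with columns name, formula, adducts, reported_mz,
#'   comment.
#' @export
annotation_table <- function() {
  path <- system.file("extdata", "annotation_table.csv",
                      package = "metabodyn", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
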