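# Normalization recipes applied to count matrices before model fitting.
# Order matters and is fixed per recipe: filter -> (CPM) -> log1p -> scale.

.as_dense <- function(M) {
  if (methods::is(M, "Matrix")) as.matrix(M) else M
}

#' Drop features observed in too few cells
#'
#' Removes columns of one modality whose number of cells with a nonzero
#' value is strictly below `min_cells`. The threshold is inclusive: a
#' feature seen in exactly `min_cells` cells is kept. Cells are never
#' dropped and retained values are untouched.
#'
#' @param data a [paired_dataset].
#' @param modality `"x"` or `"y"`.
#' @param min_cells integer >= 1.
#' @return A [paired_dataset] with the filtered modality.
#' @export
filter_features <- function(data, modality = c("x", "y"), min_cells = 1) {
  modality <- match.arg(modality)
  stopifnot(inherits(data, "paired_dataset"))
  if (length(min_cells) != 1 || min_cells < 1)
    stop("min_cells must be a single integer >= 1")
  M <- if (modality == "x") data$X else data$Y
  nnz <- if (methods::is(M, "Matrix")) Matrix::colSums(M != 0) else colSums(M != 0)
  keep <- nnz >= min_cells
  if (!any(keep))
    stop("filter_features would remove every feature of modality ", modality,
         "; lower min_cells (currently ", min_cells, ")")
  if (sum(!keep) > 0)
    message("filter_features: dropped ", sum(!keep), " of ", length(keep),
            " features in modality ", modality)
  if (modality == "x") {
    data$X <- M[, keep, drop = FALSE]
    data$feature_ids_x <- data$feature_ids_x[keep]
  } else {
    data$Y <- M[, keep, drop = FALSE]
    data$feature_ids_y <- data$feature_ids_y[keep]
  }
  data
}

#' Counts-per-million row normalization
#'
#' Rescales each cell (row) so its entries sum to one million.
#'
#' @param M nonnegative matrix, cells x features.
#' @return Matrix of the same shape and storage kind.
#' @export
normalize_cpm <- function(M) {
  if (min(M) < 0) stop("normalize_cpm expects nonnegative counts")
  rs <- if (methods::is(M, "Matrix")) Matrix::rowSums(M) else rowSums(M)
  bad <- which(rs <= 0)
  if (length(bad) > 0) {
    ids <- rownames(M)[bad] %||% as.character(bad)
    stop("normalize_cpm: zero-total rows (cells): ",
         paste(utils::head(ids, 5), collapse = ", "))
  }
  if (methods::is(M, "Matrix")) Matrix::Diagonal(x = 1e6 / rs) %*% M
  else M * (1e6 / rs)
}

#' Elementwise log(1 + x) transform
#'
#' The pseudo-count of 1 avoids taking the logarithm of zeros.
#'
#' @param M nonnegative matrix (raw or CPM counts).
#' @return Transformed matrix.
#' @export
log1p_transform <- function(M) {
  if (min(M) < 0)
    stop("log1p_transform applies to counts/CPM; found negative entries")
  if (methods::is(M, "Matrix")) {
    M@x <- log1p(M@x)  # log1p(0) = 0, sparsity pattern preserved
    M
  } else log1p(M)
}

#' Column standardization to zero mean and unit variance
#'
#' Each feature is centered and divided by its sample standard deviation
#' (denominator n - 1). Constant features become all zeros rather than NaN,
#' keeping matrix shapes stable. The result is dense: centering destroys
#' sparsity, so this is the step where sparse inputs are materialized.
#'
#' @param M matrix with at least two rows.
#' @return Dense base matrix, columns with mean 0 and (where defined) sd 1.
#' @export
scale_unit <- function(M) {
  if (nrow(M) < 2) stop("scale_unit needs at least 2 cells")
  M <- .as_dense(M)
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  sdv[sdv == 0] <- Inf   # constant columns -> centered then zeroed
  sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
}

#' Apply a named preprocessing recipe to both modalities
#'
#' Presets mirror the per-protocol recipes used for the real datasets this
#' model targets:
#' \describe{
#'   \item{`multiome`}{RNA + ATAC peaks: filter both modalities at
#'     `min_cells = 1`, then log1p, then scale.}
#'   \item{`immune`}{RNA + a small antibody panel: filter RNA only at
#'     `min_cells = 1`; log1p and scale both.}
#'   \item{`citeseq`}{RNA: filter at `min_cells = 10`, CPM, log1p, scale.
#'     ADT: CPM, log1p, scale, no filtering.}
#'   \item{`none`}{identity.}
#' }
#'
#' @param data a [paired_dataset] of raw counts.
#' @param preset recipe name.
#' @return A [paired_dataset] whose matrices are dense and scaled (except
#'   `preset = "none"`).
#' @export
apply_preset <- function(data, preset = c("multiome", "immune", "citeseq", "none")) {
  preset <- match.arg(preset)
  if (preset == "none") return(data)
  if (preset == "multiome") {
    data <- filter_features(data, "x", 1)
    data <- filter_features(data, "y", 1)
    data$X <- scale_unit(log1p_transform(data$X))
    data$Y <- scale_unit(log1p_transform(data$Y))
  } else if (preset == "immune") {
    data <- filter_features(data, "x", 1)
    data$X <- scale_unit(log1p_transform(data$X))
    data$Y <- scale_unit(log1p_transform(data$Y))
  } else if (preset == "citeseq") {
    data <- filter_features(data, "x", 10)
    data$X <- scale_unit(log1p_transform(normalize_cpm(data$X)))
    data$Y <- scale_unit(log1p_transform(normalize_cpm(data$Y)))
  }
  data
}

#' Keep the top-k most variable features of one modality
#'
#' Optional helper for very wide modalities (e.g. millions of chromatin
#' peaks) where a variance-based cut makes dense scaling feasible. The
#' model itself accepts raw peak counts; this selector is a convenience,
#' not part of any preset.
#'
#' @param data a [paired_dataset].
#' @param modality `"x"` or `"y"`.
#' @param k number of features to retain.
#' @return A [paired_dataset] restricted to the top-k variance features.
#' @export
select_top_variance <- function(data, modality = c("x", "y"), k) {
  modality <- match.arg(modality)
  M <- if (modality == "x") data$X else data$Y
  if (k >= ncol(M)) return(data)
  v <- apply(.as_dense(M), 2, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(k)])
  if (modality == "x") {
    data$X <- M[, keep, drop = FALSE]
    data$feature_ids_x <- data$feature_ids_x[keep]
  } else {
    data$Y <- M[, keep, drop = FALSE]
    data$feature_ids_y <- data$feature_ids_y[keep]
  }
  data
}
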