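#' Paired two-modality single-cell dataset
#'
#' Container for two cell-by-feature matrices measured on the same cells:
#' modality X (gene expression) and modality Y (antibody-derived tags or
#' chromatin-accessibility peaks). Rows of `X` and `Y` are aligned: row `i`
#' of both matrices describes the same cell.
#'
#' @param X n x p matrix (cells x features) for modality 1; dense or a
#'   `Matrix` sparse matrix.
#' @param Y n x q matrix for modality 2, same cells in the same order.
#' @param cell_ids character vector of length n; unique cell barcodes.
#' @param feature_ids_x,feature_ids_y unique feature identifiers per modality.
#' @param labels optional length-n vector of reference annotations (used only
#'   for evaluation, never by the model).
#' @return An object of class `paired_dataset`.
#' @export
paired_dataset <- function(X, Y, cell_ids = rownames(X),
                           feature_ids_x = colnames(X),
                           feature_ids_y = colnames(Y),
                           labels = NULL) {
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(X)))
  if (is.null(feature_ids_x)) feature_ids_x <- paste0("fx_", seq_len(ncol(X)))
  if (is.null(feature_ids_y)) feature_ids_y <- paste0("fy_", seq_len(ncol(Y)))
  cell_ids <- as.character(cell_ids)
  feature_ids_x <- as.character(feature_ids_x)
  feature_ids_y <- as.character(feature_ids_y)
  if (nrow(X) != nrow(Y))
    stop("X and Y must describe the same cells: nrow(X) = ", nrow(X),
         ", nrow(Y) = ", nrow(Y))
  if (length(cell_ids) != nrow(X))
    stop("cell_ids length (", length(cell_ids), ") != number of cells (",
         nrow(X), ")")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell barcodes: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 5),
               collapse = ", "))
  if (anyDuplicated(feature_ids_x) || anyDuplicated(feature_ids_y))
    stop("feature ids must be unique within each modality")
  if (length(feature_ids_x) != ncol(X) || length(feature_ids_y) != ncol(Y))
    stop("feature id lengths do not match matrix dimensions")
  if (!is.null(labels)) {
    if (length(labels) != nrow(X))
      stop("labels length (", length(labels), ") != number of cells (",
           nrow(X), ")")
  }
  structure(list(X = X, Y = Y, cell_ids = cell_ids,
                 feature_ids_x = feature_ids_x,
                 feature_ids_y = feature_ids_y, labels = labels),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("paired_dataset:", nrow(x$X), "cells;",
      ncol(x$X), "features (X),", ncol(x$Y), "features (Y)",
      if (!is.null(x$labels)) sprintf("; %d label groups",
                                      length(unique(x$labels))) else "", "\n")
  invisible(x)
}

#' @export
dim.paired_dataset <- function(x) c(nrow(x$X), ncol(x$X), ncol(x$Y))

#' Read a paired dataset from two on-disk matrices
#'
#' Reads the two modalities from standard single-cell exports and aligns
#' them cell-by-cell using barcodes. Row order is taken from modality X;
#' cells absent from either modality are dropped (a message reports how
#' many).
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx`}{a directory holding a Matrix Market triplet:
#'     `matrix.mtx`, `features.tsv` (or `genes.tsv`), `barcodes.tsv`.
#'     Orientation (cells x features vs the 10x features x cells
#'     convention) is auto-detected by matching the barcode count.}
#'   \item{`csv`}{delimited text, header row = feature ids, first column =
#'     cell barcodes.}
#'   \item{`h5-10x`}{a 10x-style HDF5 feature-barcode container; both
#'     modalities live in one file, split by `feature_type` ("Gene
#'     Expression" goes to X, everything else to Y). Pass the same path as
#'     `path_x` and `path_y` (or leave `path_y` as `NULL`). Reading is
#'     delegated to the `h5py` Python library, which must be on the
#'     `python` found in `PATH`.}
#' }
#'
#' @param path_x,path_y paths (directories for `mtx`, files otherwise).
#' @param format one of `"mtx"`, `"csv"`, `"h5-10x"`.
#' @param labels optional path to a headerless text file of per-cell labels
#'   aligned to modality X's barcodes (two columns: barcode, label), or a
#'   vector recycled onto the aligned cells.
#' @return A [paired_dataset].
#' @export
read_paired <- function(path_x, path_y = NULL, format = c("mtx", "csv", "h5-10x"),
                        labels = NULL) {
  format <- match.arg(format)
  if (format == "h5-10x") {
    parts <- .read_10x_h5_pair(path_x)
    mx <- parts$X; my <- parts$Y
  } else {
    reader <- switch(format, mtx = .read_mtx_dir, csv = .read_csv_matrix)
    mx <- reader(path_x)
    my <- reader(path_y)
  }
  bx <- rownames(mx); by <- rownames(my)
  if (anyDuplicated(bx) || anyDuplicated(by))
    stop("duplicate cell barcodes within a modality; cannot align")
  keep <- bx[bx %in% by]
  if (length(keep) == 0)
    stop("no overlapping cell barcodes between the two modalities")
  dropped <- (length(bx) - length(keep)) + (length(by) - length(keep))
  if (dropped > 0)
    message("read_paired: dropped ", dropped,
            " cells absent from one modality")
  mx <- mx[keep, , drop = FALSE]
  my <- my[match(keep, by), , drop = FALSE]
  message("read_paired: n = ", length(keep), ", p = ", ncol(mx),
          ", q = ", ncol(my))
  lab <- NULL
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
      tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
      lab <- tab[[2]][match(keep, tab[[1]])]
    } else lab <- labels[match(keep, bx)]
  }
  paired_dataset(mx, my, cell_ids = keep, feature_ids_x = colnames(mx),
                 feature_ids_y = colnames(my), labels = lab)
}

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  readLines(path)
}

# Matrix Market triplet directory -> cells x features sparse matrix with
# barcode rownames.
.read_mtx_dir <- function(dir) {
  if (!dir.exists(dir)) stop("cannot read directory: ", dir)
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) {
    cand <- list.files(dir, pattern = "\\.mtx$", full.names = TRUE)
    if (length(cand) != 1) stop("no unique .mtx file in ", dir)
    mtx <- cand
  }
  feat_path <- file.path(dir, "features.tsv")
  if (!file.exists(feat_path)) feat_path <- file.path(dir, "genes.tsv")
  bc_path <- file.path(dir, "barcodes.tsv")
  m <- Matrix::readMM(mtx)
  feats <- vapply(strsplit(.read_lines_checked(feat_path), "\t"), `[[`, "", 1)
  bcs <- .read_lines_checked(bc_path)
  if (nrow(m) == length(feats) && ncol(m) == length(bcs)) {
    m <- Matrix::t(m)                       # 10x convention: features x cells
  } else if (!(nrow(m) == length(bcs) && ncol(m) == length(feats))) {
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither orientation of ", length(bcs), " barcodes x ",
         length(feats), " features")
  }
  dimnames(m) <- list(bcs, feats)
  m
}

.read_csv_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

# 10x-style HDF5 container. No R HDF5 binding ships with this toolchain, so
# the datasets are dumped to a temporary directory through python/h5py and
# reassembled into sparse matrices here.
.read_10x_h5_pair <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  py <- Sys.which("python")
  if (py == "") stop("reading h5-10x requires a `python` with h5py on PATH")
  tmp <- tempfile("h5dump")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  script <- file.path(tmp, "dump.py")
  writeLines(c(
    "import sys, h5py, numpy as np",
    "path, out = sys.argv[1], sys.argv[2]",
    "f = h5py.File(path, 'r')",
    "g = f['matrix']",
    "def dec(a):",
    "    return [x.decode() if isinstance(x, bytes) else str(x) for x in a]",
    "np.savetxt(out + '/data.txt', g['data'][:], fmt='%.17g')",
    "np.savetxt(out + '/indices.txt', g['indices'][:], fmt='%d')",
    "np.savetxt(out + '/indptr.txt', g['indptr'][:], fmt='%d')",
    "np.savetxt(out + '/shape.txt', g['shape'][:], fmt='%d')",
    "open(out + '/barcodes.txt', 'w').write('\\n'.join(dec(g['barcodes'][:])) + '\\n')",
    "open(out + '/features.txt', 'w').write('\\n'.join(dec(g['features/id'][:])) + '\\n')",
    "open(out + '/types.txt', 'w').write('\\n'.join(dec(g['features/feature_type'][:])) + '\\n')"
  ), script)
  status <- system2(py, c(script, shQuote(path), shQuote(tmp)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("h5py failed to read ", path)
  rd <- function(f) scan(file.path(tmp, f), what = double(), quiet = TRUE)
  shape <- rd("shape.txt")                  # features x cells (CSC by cell)
  m <- Matrix::sparseMatrix(
    i = rd("indices.txt") + 1, p = rd("indptr.txt"), x = rd("data.txt"),
    dims = shape, index1 = TRUE)
  bcs <- readLines(file.path(tmp, "barcodes.txt"))
  feats <- readLines(file.path(tmp, "features.txt"))
  types <- readLines(file.path(tmp, "types.txt"))
  dimnames(m) <- list(feats, bcs)
  m <- Matrix::t(m)                         # cells x features
  is_x <- types == "Gene Expression"
  if (!any(is_x) || all(is_x))
    stop("h5-10x container must carry Gene Expression plus a second feature_type")
  list(X = m[, is_x, drop = FALSE], Y = m[, !is_x, drop = FALSE])
}
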