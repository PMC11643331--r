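#' Representational dissimilarity matrices
#'
#' An `rdm` is a square, symmetric matrix of pairwise dissimilarities between
#' stimuli, labeled by stimulus id. It is the common currency passed between
#' every stage of the pipeline: model geometries, split-session neural
#' geometries, behavioral arrangement geometries, gaze geometries, and
#' semantic geometries are all `rdm` objects.
#'
#' Entries must be finite and symmetric up to `tol`; asymmetries within
#' tolerance are averaged away. The diagonal is retained (split-session RDMs
#' carry a meaningful nonzero diagonal) but never enters the vectorized form.
#'
#' @param mat numeric square matrix of dissimilarities.
#' @param stimulus_ids character vector of stimulus labels; defaults to
#'   `rownames(mat)` or `s1..sm`.
#' @param meta named list of construction metadata (source tag, parameters).
#' @param tol symmetry tolerance.
#' @return an object of class `rdm`: the symmetrized matrix with stimulus ids
#'   as dimnames and a `meta` attribute.
#' @examples
#' r <- rdm(as.matrix(dist(matrix(rnorm(20), 5))))
#' rdm_vectorize(r)
#' @export
rdm <- function(mat, stimulus_ids = NULL, meta = list(), tol = 1e-9) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop_arg("an RDM must be square")
  if (any(!is.finite(mat))) stop_arg("RDM entries must be finite")
  if (max(abs(mat - t(mat))) > tol) {
    stop_arg("RDM is asymmetric beyond tolerance (max |d_ij - d_ji| = ",
             format(max(abs(mat - t(mat)))), ")")
  }
  mat <- (mat + t(mat)) / 2
  if (is.null(stimulus_ids)) {
    stimulus_ids <- rownames(mat)
    if (is.null(stimulus_ids)) stimulus_ids <- paste0("s", seq_len(nrow(mat)))
  }
  if (length(stimulus_ids) != nrow(mat)) {
    stop_arg("stimulus_ids length does not match matrix size")
  }
  if (anyDuplicated(stimulus_ids)) stop_arg("stimulus_ids must be unique")
  dimnames(mat) <- list(stimulus_ids, stimulus_ids)
  structure(mat, class = c("rdm", "matrix", "array"), meta = meta)
}

#' @export
print.rdm <- function(x, ...) {
  m <- nrow(x)
  cat(sprintf("RDM over %d stimuli (%d pairs)\n", m, m * (m - 1) / 2))
  meta <- attr(x, "meta")
  if (length(meta)) {
    cat("  source:", if (!is.null(meta$source)) meta$source else "<unset>", "\n")
  }
  v <- rdm_vectorize(x)
  cat(sprintf("  dissimilarities: min %.4g / median %.4g / max %.4g\n",
              min(v), stats::median(v), max(v)))
  invisible(x)
}

#' Test whether an object is an RDM
#' @param x any object.
#' @export
is_rdm <- function(x) inherits(x, "rdm")

#' Stimulus ids of an RDM
#' @param x an `rdm`.
#' @export
rdm_ids <- function(x) rownames(x)

#' Vectorize an RDM
#'
#' Extracts the upper triangle (diagonal excluded) in fixed row-major pair
#' order: (1,2), (1,3), ..., (1,m), (2,3), ... This order is used for every
#' RDM comparison in the package.
#'
#' @param x an `rdm` or square matrix.
#' @return numeric vector of length `m(m-1)/2`.
#' @export
rdm_vectorize <- function(x) {
  tx <- t(unclass(x))
  tx[lower.tri(tx)]
}

#' Rebuild a square RDM from its vectorized upper triangle
#'
#' Inverse of [rdm_vectorize()]: entries are placed back in row-major pair
#' order and the diagonal is set to zero.
#'
#' @param v vector of length `m(m-1)/2`.
#' @param stimulus_ids optional stimulus labels (length `m`).
#' @param meta metadata list passed to [rdm()].
#' @export
rdm_devectorize <- function(v, stimulus_ids = NULL, meta = list()) {
  m <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(m - round(m)) > 1e-8) stop_arg("length of v is not m(m-1)/2 for integer m")
  m <- round(m)
  mat <- matrix(0, m, m)
  mat[lower.tri(mat)] <- v        # fills column-major lower = row-major upper of t
  mat <- t(mat)
  mat <- mat + t(mat)
  rdm(mat, stimulus_ids = stimulus_ids, meta = meta)
}

#' Pair order of the vectorized form
#'
#' @param m number of stimuli.
#' @return two-column integer matrix of (i, j) indices, row-major order.
#' @export
rdm_pair_index <- function(m) {
  i <- rep(seq_len(m - 1), times = (m - 1):1)
  j <- unlist(lapply(seq_len(m - 1), function(k) (k + 1):m))
  cbind(i = i, j = j)
}

#' Reorder or subset an RDM by stimulus id
#' @param x an `rdm`.
#' @param ids stimulus ids to keep, in the requested order.
#' @export
rdm_align <- function(x, ids) {
  missing_ids <- setdiff(ids, rdm_ids(x))
  if (length(missing_ids)) {
    stop_arg("stimuli absent from RDM: ", paste(missing_ids, collapse = ", "))
  }
  rdm(unclass(x)[ids, ids, drop = FALSE], stimulus_ids = ids,
      meta = attr(x, "meta"))
}

#' Read and write RDMs as plain text
#'
#' Two interchangeable formats are supported. The square format is a CSV with
#' a header row and first column of stimulus ids. The long format is
#' whitespace/tab-delimited with columns `stim_i`, `stim_j`, `dissimilarity`
#' (either triangle, in any row order); symmetry is validated on read.
#'
#' @param x an `rdm`.
#' @param path file path.
#' @param format `"square"` or `"long"`.
#' @return `write_rdm` returns `path` invisibly; `read_rdm` returns an `rdm`.
#' @export
write_rdm <- function(x, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(stimulus_id = rdm_ids(x), unclass(x), check.names = FALSE)
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    idx <- rdm_pair_index(nrow(x))
    ids <- rdm_ids(x)
    df <- data.frame(stim_i = ids[idx[, 1]], stim_j = ids[idx[, 2]],
                     dissimilarity = rdm_vectorize(x))
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  if (format == "auto") {
    hdr <- strsplit(readLines(path, n = 1), "[,\t]")[[1]]
    format <- if (identical(tolower(hdr[1:2]), c("stim_i", "stim_j"))) "long" else "square"
  }
  if (format == "square") {
    df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- as.character(df[[1]])
    return(rdm(mat, stimulus_ids = as.character(df[[1]])))
  }
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  ids <- unique(c(df$stim_i, df$stim_j))
  m <- length(ids)
  mat <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  diag(mat) <- 0
  for (k in seq_len(nrow(df))) {
    i <- df$stim_i[k]; j <- df$stim_j[k]; d <- df$dissimilarity[k]
    for (cur in list(c(i, j), c(j, i))) {
      prev <- mat[cur[1], cur[2]]
      if (!is.na(prev) && abs(prev - d) > 1e-9 && cur[1] != cur[2]) {
        stop_arg("inconsistent duplicate entries for pair ", i, " / ", j)
      }
      mat[cur[1], cur[2]] <- d
    }
  }
  if (any(is.na(mat))) stop_arg("long-format RDM file does not cover all pairs")
  rdm(mat, stimulus_ids = ids)
}
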