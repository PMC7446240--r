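#' Representational dissimilarity matrices
#'
#' An `rdm` is a square symmetric matrix of pairwise dissimilarities between
#' experimental conditions, with a zero diagonal and condition labels. Three
#' kinds are distinguished: `"model_1mr"` (1 - Pearson r model RDMs, entries
#' in \[0, 2\]), `"model_categorical"` (binary same/different-category RDMs),
#' and `"data_crossnobis"` (cross-validated Mahalanobis distance RDMs, whose
#' entries are unbiased under the null and may therefore be negative).
#'
#' @param values numeric square matrix of dissimilarities.
#' @param labels character vector of condition names; defaults to the row
#'   names of `values` or `cond1..condN`.
#' @param kind one of `"model_1mr"`, `"model_categorical"`,
#'   `"data_crossnobis"`.
#' @return an object of class `rdm`: the validated matrix with attributes
#'   `labels` and `kind`.
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2)
#' rdm(m, labels = c("a", "b"), kind = "model_categorical")
#' @export
rdm <- function(values, labels = NULL,
                kind = c("data_crossnobis", "model_1mr", "model_categorical")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("RDM must be square")
  if (anyNA(values) || any(!is.finite(values))) stop("RDM entries must be finite")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-9) {
    stop(sprintf("RDM is asymmetric (max |v - t(v)| = %.3g)", asym))
  }
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > 1e-9) stop("RDM diagonal must be zero")
  diag(values) <- 0
  if (is.null(labels)) labels <- rownames(values) %||% paste0("cond", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must match RDM size")
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  if (kind == "model_1mr" && (min(values) < -1e-9 || max(values) > 2 + 1e-9)) {
    stop("model_1mr entries must lie in [0, 2]")
  }
  if (kind == "model_categorical" && !all(values %in% c(0, 1))) {
    stop("model_categorical entries must be 0 or 1")
  }
  if (kind != "data_crossnobis" && min(values) < 0) {
    stop("model RDM entries must be nonnegative")
  }
  dimnames(values) <- list(labels, labels)
  structure(values, labels = labels, kind = kind, class = c("rdm", "matrix"))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions, kind = %s\n", nrow(x), attr(x, "kind")))
  v <- lower_tri(unclass(x))
  cat(sprintf("  dissimilarities: min %.4g, median %.4g, max %.4g\n",
              min(v), stats::median(v), max(v)))
  invisible(x)
}

#' @export
plot.rdm <- function(x, order = NULL, main = NULL, ...) {
  m <- unclass(x)
  if (!is.null(order)) m <- m[order, order]
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = main %||% attr(x, "kind"), ...)
  invisible(x)
}

rdm_labels <- function(x) attr(x, "labels")

# Reorder an RDM's conditions, preserving class and kind.
rdm_reorder <- function(x, labels) {
  stopifnot(inherits(x, "rdm"), setequal(labels, rdm_labels(x)))
  rdm(unclass(x)[labels, labels], labels = labels, kind = attr(x, "kind"))
}

check_same_labels <- function(a, b) {
  if (!identical(rdm_labels(a), rdm_labels(b))) {
    stop("RDMs have mismatching condition labels")
  }
}

#' Read and write RDMs as labelled CSV
#'
#' The on-disk format is a square CSV with condition labels as both header row
#' and first column. Round trips are lossless to better than 1e-12; symmetry
#' is validated on read and asymmetry beyond 1e-9 is rejected.
#'
#' @param path file path.
#' @param x an [rdm].
#' @param kind RDM kind to attach on read (the CSV stores values only).
#' @return `read_rdm` returns an [rdm]; `write_rdm` returns `path` invisibly.
#' @export
read_rdm <- function(path, kind = "data_crossnobis") {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("RDM file is not square: ", path)
  if (!identical(rownames(m), colnames(m))) {
    stop("RDM file row and column labels disagree: ", path)
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9) {
    stop(sprintf("RDM file asymmetric beyond tolerance (max asymmetry %.3g): %s",
                 asym, path))
  }
  rdm(m, labels = rownames(m), kind = kind)
}

#' @rdname read_rdm
#' @export
write_rdm <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  df <- as.data.frame(unclass(x))
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}
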