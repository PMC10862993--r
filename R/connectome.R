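#' Regress confound timecourses out of node timecourses
#'
#' Replaces every node timecourse by its residuals from a least-squares
#' regression on an intercept plus the supplied confound timecourses
#' (e.g. global signal, white-matter and CSF signals, or noise-component
#' timecourses).  With no confounds this reduces to per-node demeaning.
#'
#' @param tc Numeric timepoints-by-nodes matrix (column names are node
#'   labels).
#' @param confounds Optional numeric timepoints-by-k matrix of confound
#'   regressors; `NULL` means intercept only.
#' @return A matrix of the same shape as `tc` containing the residuals.
#' @export
regress_confounds <- function(tc, confounds = NULL) {
  tc <- as.matrix(tc)
  if (!is.numeric(tc) || anyNA(tc)) abort("`tc` must be numeric, no NAs.")
  t_len <- nrow(tc)
  x <- matrix(1, t_len, 1L, dimnames = list(NULL, "(intercept)"))
  if (!is.null(confounds) && NCOL(confounds) > 0L) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != t_len) {
      abort("`confounds` must have one row per timepoint.")
    }
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    }
    x <- cbind(x, confounds)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    abort(paste0("Confound design is rank deficient; offending columns: ",
                 paste(bad, collapse = ", ")))
  }
  res <- tc - x %*% qr.coef(qx, tc)
  dimnames(res) <- dimnames(tc)
  res
}

#' Compute a Fisher-z connectivity matrix from node timecourses
#'
#' Full connectivity is the pairwise Pearson correlation of the node
#' timecourses.  Partial connectivity is the correlation of each pair of
#' nodes after the timecourses of all remaining nodes are regressed out,
#' computed through the (pseudo-)inverse of the sample covariance:
#' \eqn{\rho_{ab} = -P_{ab} / \sqrt{P_{aa} P_{bb}}} for precision matrix
#' \eqn{P}.  Correlations are clipped to \eqn{\pm(1 - 10^{-12})} before
#' the variance-stabilizing Fisher transform \eqn{z = \mathrm{arctanh}(r)}.
#'
#' @param tc Numeric timepoints-by-nodes matrix.
#' @param method `"full"` (pairwise Pearson) or `"partial"`.
#' @param gsr_applied Flag recorded on the result: whether global signal
#'   regression was applied upstream (see [regress_confounds()]).
#' @return A symmetric node-by-node matrix of Fisher-z values of class
#'   `connectivity_matrix`, with `NA` on the diagonal and attributes
#'   `method` and `gsr_applied`.
#' @export
compute_rsfc <- function(tc, method = c("full", "partial"),
                         gsr_applied = FALSE) {
  method <- match.arg(method)
  tc <- as.matrix(tc)
  v <- ncol(tc)
  t_len <- nrow(tc)
  if (t_len < 3L) abort("Need at least 3 timepoints.")
  sds <- apply(tc, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(tc)[sds == 0] %||% which(sds == 0)
    abort(paste0("Constant node timecourse(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (method == "full") {
    r <- cor(tc)
  } else {
    if (t_len <= v + 1L) {
      abort(sprintf(
        "Partial correlation needs timepoints > nodes + 1 (have %d, %d).",
        t_len, v))
    }
    s <- cov(tc)
    p <- tryCatch(solve(s), error = function(e) MASS::ginv(s))
    d <- sqrt(diag(p))
    r <- -p / outer(d, d)
    diag(r) <- 1
    r <- (r + t(r)) / 2
  }
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  diag(z) <- NA_real_
  dimnames(z) <- list(colnames(tc), colnames(tc))
  structure(z, class = c("connectivity_matrix", "matrix", "array"),
            method = method, gsr_applied = isTRUE(gsr_applied))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d nodes, method = %s\n",
              nrow(x), attr(x, "method")))
  print(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x)))])
  invisible(x)
}

#' Unwrap the strict upper triangle of a connectivity matrix
#'
#' Vectorizes a symmetric connectivity matrix into its row-major strict
#' upper triangle — edge order (1,2), (1,3), ..., (1,N), (2,3), ... — so
#' an N-node matrix yields N(N-1)/2 edge features.  Only one triangle is
#' needed because the matrix is symmetric about the diagonal.
#'
#' @param cm Symmetric numeric matrix (a `connectivity_matrix` or plain
#'   matrix); the diagonal is ignored.
#' @param node_labels,network_labels Optional per-node labels used to
#'   annotate edges; node labels default to the matrix dimnames.
#' @return A tibble with one row per edge: `feature_id`, `node_a`,
#'   `node_b`, `network_a`, `network_b` (when networks are given) and
#'   `value`.
#' @export
vectorize_upper <- function(cm, node_labels = NULL, network_labels = NULL) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("`cm` must be square.")
  off <- !diag(nrow(m))
  if (any(abs(m[off] - t(m)[off]) > 1e-10, na.rm = TRUE)) {
    abort("`cm` is asymmetric beyond tolerance 1e-10.")
  }
  n <- nrow(m)
  node_labels <- node_labels %||% rownames(m) %||%
    sprintf("node%03d", seq_len(n))
  idx <- upper_pairs(n)
  out <- tibble::tibble(
    feature_id = if (nrow(idx)) sprintf("e%05d", seq_len(nrow(idx)))
                 else character(),
    node_a = node_labels[idx[, 1]],
    node_b = node_labels[idx[, 2]],
    value = m[idx])
  if (!is.null(network_labels)) {
    if (length(network_labels) != n) {
      abort("`network_labels` must have one entry per node.")
    }
    out$network_a <- network_labels[idx[, 1]]
    out$network_b <- network_labels[idx[, 2]]
    out <- out[c("feature_id", "node_a", "node_b",
                 "network_a", "network_b", "value")]
  }
  out
}

#' Rebuild a symmetric matrix from an unwrapped edge table
#'
#' Inverse of [vectorize_upper()] on the strict upper triangle.
#'
#' @param edges Tibble from [vectorize_upper()].
#' @param diag_value Value placed on the diagonal (default `NA`).
#' @return Symmetric numeric matrix.
#' @export
edges_to_matrix <- function(edges, diag_value = NA_real_) {
  labels <- unique(c(edges$node_a, edges$node_b))
  n <- length(labels)
  if (nrow(edges) != n * (n - 1) / 2) {
    abort("`edges` does not cover a full strict upper triangle.")
  }
  m <- matrix(diag_value, n, n, dimnames = list(labels, labels))
  ia <- match(edges$node_a, labels)
  ib <- match(edges$node_b, labels)
  m[cbind(ia, ib)] <- edges$value
  m[cbind(ib, ia)] <- edges$value
  m
}

#' Motion quality-control exclusion rule
#'
#' Flags a scan for exclusion when the mean framewise displacement
#' exceeds 0.25 mm or when more than 50% of frames individually exceed
#' 0.25 mm.  Both comparisons are strict, so a scan exactly at a
#' threshold is kept.
#'
#' @param fd_mean Mean framewise displacement in mm (vectorized).
#' @param fd_pct_above Percent of frames with FD > 0.25 mm (vectorized).
#' @param fd_mean_max,pct_max Exclusion thresholds.
#' @return Logical vector: `TRUE` = exclude.
#' @export
qc_exclude <- function(fd_mean, fd_pct_above,
                       fd_mean_max = 0.25, pct_max = 50) {
  if (any(fd_mean < 0) || any(fd_pct_above < 0) || any(fd_pct_above > 100)) {
    abort("`fd_mean` must be >= 0 and `fd_pct_above` within [0, 100].")
  }
  fd_mean > fd_mean_max | fd_pct_above > pct_max
}

#' Smooth vertexwise values on a mesh
#'
#' Approximates Gaussian surface smoothing by iterative neighbor
#' averaging: each iteration replaces a vertex value by the mean of
#' itself and its neighbors.  The iteration count k is calibrated to the
#' requested kernel through the diffusion approximation
#' \eqn{FWHM \approx L\sqrt{8\ln(2)\,k/3}} for mean edge length L, i.e.
#' \eqn{k = \lceil 3\,(FWHM/L)^2 / (8\ln 2) \rceil}.  The global mean of
#' the values is preserved exactly by re-centering after smoothing.
#' Vertices with no neighbors are left unchanged (with a warning).
#'
#' @param values Numeric per-vertex vector.
#' @param adjacency List of integer neighbor-index vectors, one per
#'   vertex; must be symmetric.
#' @param fwhm Kernel full-width at half-maximum in mm; 0 is identity.
#' @param edge_len Mean mesh edge length in mm.
#' @return Smoothed numeric vector, same length and mean as `values`.
#' @export
smooth_on_mesh <- function(values, adjacency, fwhm, edge_len = 1) {
  if (length(adjacency) != length(values)) {
    abort("`adjacency` must have one entry per vertex.")
  }
  if (fwhm < 0) abort("`fwhm` must be >= 0.")
  if (fwhm == 0) return(values)
  isolated <- lengths(adjacency) == 0L
  if (any(isolated)) {
    warn(sprintf("%d isolated vertices left unsmoothed.", sum(isolated)))
  }
  k <- max(1L, ceiling(3 * (fwhm / edge_len)^2 / (8 * log(2))))
  v0_mean <- mean(values)
  v <- values
  for (it in seq_len(k)) {
    nb_mean <- vapply(seq_along(v), function(i) {
      nb <- adjacency[[i]]
      if (length(nb) == 0L) v[i] else mean(c(v[i], v[nb]))
    }, numeric(1))
    v <- ifelse(isolated, v, nb_mean)
  }
  # restore the global mean without touching isolated vertices
  n_active <- sum(!isolated)
  v[!isolated] <- v[!isolated] +
    (v0_mean - mean(v)) * length(v) / n_active
  v
}
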