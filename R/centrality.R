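#' Normalized eigenvector centrality
#'
#' Solves `A x = lambda x` for the leading eigenpair of a symmetric
#' nonnegative connectivity matrix and returns the Perron-Frobenius
#' eigenvector, sign-fixed to the all-nonnegative orientation and
#' normalized so the squared scores sum to 1 (unit Euclidean length).
#' A node's score therefore grows with the scores of its neighbours:
#' connections to central regions count more than connections to
#' peripheral ones.
#'
#' The diagonal is forced to zero before solving (self-coupling is
#' undefined for phase-based connectivity). For `N <= dense_limit` a dense
#' symmetric eigendecomposition is used; larger problems fall back to power
#' iteration with tolerance `tol`.
#'
#' @param A Square symmetric nonnegative matrix (a `conn_matrix` or plain
#'   matrix); at least one nonzero off-diagonal entry.
#' @param method `"auto"` (dense below `dense_limit`, else power),
#'   `"dense"`, or `"power"`.
#' @param tol Power-iteration convergence tolerance (default 1e-12).
#' @param max_iter Power-iteration cap (default 10000).
#' @param dense_limit Size cutoff for the dense path (default 256).
#' @return A `centrality_vector`: list with `scores` (named, nonnegative,
#'   unit sum of squares), `lambda` (leading eigenvalue), `band`.
#' @examples
#' A <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3)  # 3-node star
#' eigenvector_centrality(A)$scores               # (0.707, 0.5, 0.5)
#' @export
eigenvector_centrality <- function(A, method = c("auto", "dense", "power"),
                                   tol = 1e-12, max_iter = 10000,
                                   dense_limit = 256) {
  method <- match.arg(method)
  band <- attr(A, "band") %||% NA_character_
  labels <- rownames(A)
  A <- unclass(as.matrix(A))
  attr(A, "band") <- NULL
  if (nrow(A) != ncol(A)) stop_invalid("matrix must be square")
  assert_finite(A, "connectivity matrix")
  if (max(abs(A - t(A))) > 1e-10) stop_invalid("matrix must be symmetric")
  if (any(A < 0)) stop_invalid("matrix must be nonnegative")
  diag(A) <- 0
  if (all(A == 0)) stop_invalid("all-zero matrix has no defined centrality")

  if (method == "auto") {
    method <- if (nrow(A) <= dense_limit) "dense" else "power"
  }
  res <- switch(method,
    dense = ec_dense(A),
    power = ec_power(A, tol = tol, max_iter = max_iter)
  )
  x <- fix_sign(res$x)
  x <- x / sqrt(sum(x^2))
  if (any(x < -1e-12)) {
    stop_invalid(paste0(
      "leading eigenvector has a genuinely negative component; ",
      "the matrix is likely disconnected with an ambiguous leading eigenspace"))
  }
  x[x < 0] <- 0
  x <- x / sqrt(sum(x^2))
  names(x) <- labels
  structure(list(scores = x, lambda = res$lambda, band = band),
            class = "centrality_vector")
}

ec_dense <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  list(x = e$vectors[, 1], lambda = e$values[1])
}

ec_power <- function(A, tol, max_iter) {
  n <- nrow(A)
  # Deterministic strictly positive start: converges to the Perron vector
  # for any irreducible nonnegative A.
  x <- rep(1 / sqrt(n), n)
  # Diagonal shift keeps the iteration convergent when the spectrum has
  # lambda_min = -lambda_max (e.g. bipartite structures).
  shift <- max(rowSums(abs(A))) * 1e-3 + 1e-8
  lambda <- 0
  for (it in seq_len(max_iter)) {
    y <- as.vector(A %*% x) + shift * x
    ny <- sqrt(sum(y^2))
    if (ny == 0) stop_invalid("power iteration collapsed to zero vector")
    y <- y / ny
    delta <- sqrt(sum((y - x)^2))
    x <- y
    lambda <- ny - shift
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop_invalid(paste0(
      "power iteration did not converge in %d iterations; the leading ",
      "eigenspace may be ambiguous (disconnected graph)"), max_iter)
  }
  list(x = x, lambda = lambda)
}

fix_sign <- function(x) {
  k <- which.max(abs(x))
  if (x[k] < 0) -x else x
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat(sprintf("<centrality_vector> %d regions, lambda = %.6g, band = %s\n",
              length(x$scores), x$lambda, x$band))
  invisible(x)
}

#' Average centrality within lobes
#'
#' Arithmetic mean of the region scores inside each of the six partition
#' groups. Collapsing 90 regional values to six lobe values trades spatial
#' detail for statistical power: the group comparison then runs on six
#' tests per band instead of ninety.
#'
#' @param ec A `centrality_vector` (or named numeric vector of scores).
#' @param partition Partition data.frame (`region_label`, `group`), e.g.
#'   [default_lobe_partition()].
#' @return Named numeric vector, one mean per group present in the
#'   partition, in canonical lobe order.
#' @export
lobe_average <- function(ec, partition) {
  scores <- if (inherits(ec, "centrality_vector")) ec$scores else ec
  if (is.null(names(scores))) stop_invalid("centrality scores must be named")
  partition <- validate_partition(partition)
  missing <- setdiff(names(scores), partition$region_label)
  if (length(missing) > 0) {
    stop_invalid("region(s) missing from partition: %s",
                 paste(missing, collapse = ", "))
  }
  grp <- partition$group[match(names(scores), partition$region_label)]
  m <- tapply(scores, grp, mean)
  present <- lobe_names()[lobe_names() %in% names(m)]
  as.numeric(m[present]) |> stats::setNames(present)
}
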