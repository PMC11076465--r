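#' Pearson correlation matrix of adjusted measures
#'
#' Computed on complete cases across the requested measure subset (the
#' same subset rule the composites use).
#'
#' @param adjusted a `cb_adjusted`.
#' @param measures measure ids (default all columns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(adjusted, measures = NULL) {
  measures <- measures %n% colnames(adjusted$scores)
  x <- adjusted$scores[, measures, drop = FALSE]
  cc <- stats::complete.cases(x)
  if (sum(cc) < 3) {
    cb_abort(sprintf("only %d complete cases; need at least 3", sum(cc)),
             "cb_factor_error")
  }
  stats::cor(x[cc, , drop = FALSE])
}

#' Kaiser retention rule
#'
#' Number of correlation-matrix eigenvalues strictly greater than 1.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @return Integer count.
#' @export
#' @examples
#' kaiser_n_factors(c(2.5, 1.2, 0.9, 0.4))  # 2
kaiser_n_factors <- function(eigenvalues) {
  sum(eigenvalues > 1)
}

# Principal-axis factoring with iterated communalities. Returns loadings
# (columns ordered by explained variance), communalities, iteration count
# and whether a Heywood case was clipped.
paf_extract <- function(R, n_factors, max_iter = 5000, tol = 1e-6) {
  p <- ncol(R)
  h2 <- tryCatch(1 - 1 / diag(solve(R)),
                 error = function(e) rep(0.9, p))  # SMC start; fall back if singular
  h2 <- pmin(pmax(h2, 0), 0.995)
  heywood <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    k <- seq_len(n_factors)
    lam <- e$vectors[, k, drop = FALSE] %*%
      diag(sqrt(pmax(e$values[k], 0)), n_factors)
    h2_new <- rowSums(lam^2)
    if (any(h2_new > 0.995)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 0.995)
    }
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) break
    if (iter >= max_iter) {
      cb_abort(sprintf(
        "principal-axis factoring did not converge in %d iterations", iter),
        "cb_factor_error", iterations = iter)
    }
  }
  dimnames(lam) <- list(rownames(R), paste0("F", seq_len(n_factors)))
  list(loadings = lam, communalities = h2, iterations = iter,
       heywood = heywood)
}

#' Exploratory factor analysis with optional varimax rotation
#'
#' Extraction is principal-axis factoring with iterated communalities
#' (maximum likelihood available via `extraction = "ml"`); rotation is
#' orthogonal varimax with Kaiser row-normalization. Loadings are
#' sign-fixed so each factor's largest-magnitude loading is positive and
#' columns are ordered by explained variance. Factor scores use the
#' regression (Thurstone) method when a data matrix is supplied.
#'
#' @param corr correlation matrix.
#' @param n_factors number of factors to extract (< dimension).
#' @param rotation `"varimax"` or `"none"`.
#' @param data optional numeric matrix (rows = participants, columns
#'   matching `corr`) used to compute factor scores; rows with missing
#'   values receive `NA` scores.
#' @param extraction `"paf"` or `"ml"`.
#' @return A `cb_factor_solution`: `eigenvalues` (of `corr`),
#'   `n_factors`, `loadings` (rotated if requested), `unrotated`,
#'   `rotation_matrix`, `communalities`, `scores`, `heywood`.
#' @export
fit_efa <- function(corr, n_factors, rotation = c("varimax", "none"),
                    data = NULL, extraction = c("paf", "ml")) {
  rotation <- match.arg(rotation)
  extraction <- match.arg(extraction)
  if (n_factors >= ncol(corr)) {
    cb_abort("n_factors must be smaller than the number of measures",
             "cb_factor_error")
  }
  eigenvalues <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (extraction == "paf") {
    ext <- paf_extract(corr, n_factors)
  } else {
    fa <- stats::factanal(covmat = corr, factors = n_factors,
                          rotation = "none")
    lam <- matrix(fa$loadings, ncol = n_factors,
                  dimnames = list(rownames(corr),
                                  paste0("F", seq_len(n_factors))))
    ext <- list(loadings = lam, communalities = rowSums(lam^2),
                iterations = NA_integer_, heywood = FALSE)
  }
  if (ext$heywood) {
    warn("Heywood case: communalities clipped at 0.995")
  }
  unrot <- ext$loadings
  if (rotation == "varimax" && n_factors > 1) {
    vm <- stats::varimax(unrot, normalize = TRUE, eps = 1e-10)
    rot <- vm$loadings[, , drop = FALSE]
    class(rot) <- NULL
    rotmat <- vm$rotmat
  } else {
    rot <- unrot
    rotmat <- diag(n_factors)
  }
  # order by explained variance, then sign-fix each column
  ord <- order(colSums(rot^2), decreasing = TRUE)
  rot <- rot[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, 0)
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  rotmat <- sweep(rotmat, 2, flip, `*`)
  colnames(rot) <- paste0("F", seq_len(ncol(rot)))

  scores <- NULL
  if (!is.null(data)) {
    data <- data[, rownames(corr), drop = FALSE]
    cc <- stats::complete.cases(data)
    z <- scale(data[cc, , drop = FALSE])
    w <- solve_weights(corr, rot)
    sc <- matrix(NA_real_, nrow(data), n_factors,
                 dimnames = list(rownames(data), colnames(rot)))
    sc[cc, ] <- z %*% w
    scores <- sc
  }
  structure(list(
    eigenvalues = eigenvalues,
    n_factors = n_factors,
    loadings = rot,
    unrotated = unrot,
    rotation = rotation,
    rotation_matrix = rotmat,
    communalities = ext$communalities,
    scores = scores,
    extraction = extraction,
    heywood = ext$heywood,
    iterations = ext$iterations), class = "cb_factor_solution")
}

solve_weights <- function(R, lam) {
  tryCatch(solve(R, lam), error = function(e) MASS::ginv(R) %*% lam)
}

#' @export
print.cb_factor_solution <- function(x, ...) {
  cat(sprintf("<cb_factor_solution> %d measures, %d factors (%s, %s)\n",
              nrow(x$loadings), x$n_factors, x$extraction, x$rotation))
  invisible(x)
}

#' One-factor global composite scores
#'
#' Global performance estimated as the first (unrotated) factor of the
#' requested measures, for participants who completed all of them. Scores
#' are standardized to mean 0, SD 1 on the scored subset, and sign-fixed
#' so the mean loading is positive (inputs are oriented high = good, so
#' high composite = good performance).
#'
#' @param adjusted a `cb_adjusted`.
#' @param measures measure ids entering the composite.
#' @param label tag recorded with the scores (e.g. `"accuracy"`).
#' @return A `cb_composites` tibble: participant_id, group, score; the
#'   loadings, measure set and label are attached as attributes.
#' @export
global_composite <- function(adjusted, measures = NULL, label = "global") {
  measures <- measures %n% colnames(adjusted$scores)
  x <- adjusted$scores[, measures, drop = FALSE]
  cc <- stats::complete.cases(x)
  if (sum(cc) < length(measures) + 1) {
    cb_abort(sprintf(
      "only %d complete cases for %d measures; need more cases than measures",
      sum(cc), length(measures)), "cb_factor_error")
  }
  R <- stats::cor(x[cc, , drop = FALSE])
  sol <- fit_efa(R, 1, rotation = "none", data = x)
  lam <- sol$loadings[, 1]
  sc <- sol$scores[, 1]
  if (mean(lam) < 0) {
    lam <- -lam
    sc <- -sc
  }
  sc <- (sc - mean(sc, na.rm = TRUE)) / stats::sd(sc, na.rm = TRUE)
  out <- tibble::tibble(
    participant_id = adjusted$participants$participant_id,
    group = adjusted$participants$group,
    score = sc)[cc, ]
  attr(out, "loadings") <- lam
  attr(out, "measures") <- measures
  attr(out, "label") <- label
  class(out) <- c("cb_composites", class(out))
  out
}

#' Dominant factor and loading discreteness for a measure
#'
#' @param solution a rotated `cb_factor_solution`.
#' @param measure_id row of the loading matrix.
#' @param threshold discreteness threshold below which the loading
#'   pattern is flagged non-discrete.
#' @return List: `factor` (column name with the largest absolute
#'   loading), `discreteness` (gap between the top two absolute
#'   loadings), `discrete` (logical).
#' @export
dominant_factor <- function(solution, measure_id, threshold = 0.1) {
  lam <- abs(solution$loadings[measure_id, ])
  ord <- order(lam, decreasing = TRUE)
  gap <- lam[ord[1]] - lam[ord[2]]
  list(factor = colnames(solution$loadings)[ord[1]],
       discreteness = unname(gap),
       discrete = unname(gap) >= threshold)
}

#' Tucker congruence between loading vectors
#'
#' Cosine similarity between columns; used to match recovered factors to
#' generating factors.
#'
#' @param a,b loading vectors or matrices with the same number of rows.
#' @return Scalar (vectors) or matrix of congruences (columns of `a` x
#'   columns of `b`).
#' @export
tucker_congruence <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  num <- crossprod(a, b)
  den <- outer(sqrt(colSums(a^2)), sqrt(colSums(b^2)))
  out <- num / den
  if (ncol(a) == 1 && ncol(b) == 1) as.numeric(out) else out
}

#' Match estimated factors to reference factors
#'
#' Resolves rotation indeterminacy before a recovery comparison: greedy
#' assignment maximizing absolute Tucker congruence, with sign alignment.
#'
#' @param estimated,reference loading matrices (same rows).
#' @return List: `order` (columns of `estimated` matched to each
#'   reference column), `signs`, `congruence` (absolute congruence per
#'   reference factor), `loadings` (estimated matrix permuted and
#'   sign-aligned).
#' @export
match_factors <- function(estimated, reference) {
  cg <- tucker_congruence(estimated, reference)
  k <- ncol(reference)
  ord <- integer(k)
  remaining <- seq_len(ncol(estimated))
  for (step in order(apply(abs(cg), 2, max), decreasing = TRUE)) {
    best <- remaining[which.max(abs(cg[remaining, step]))]
    ord[step] <- best
    remaining <- setdiff(remaining, best)
  }
  signs <- sign(cg[cbind(ord, seq_len(k))])
  signs[signs == 0] <- 1
  matched <- sweep(estimated[, ord, drop = FALSE], 2, signs, `*`)
  colnames(matched) <- colnames(reference)
  list(order = ord, signs = signs,
       congruence = abs(cg[cbind(ord, seq_len(k))]),
       loadings = matched)
}
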