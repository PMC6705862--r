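#' Factor-analysis configuration
#'
#' Retention and reporting rules for the correlation-matrix PCA: keep
#' components with eigenvalues above 1.0, expect the retained set to explain
#' at least 60% of total variance (warn otherwise), and flag rotated
#' loadings at or above 0.60 in absolute value as practically significant.
#' Rotation is varimax with Kaiser row normalization.
#'
#' @param eigen_threshold retain eigenvalues strictly greater than this;
#'   default 1.0.
#' @param cumvar_threshold expected cumulative percent variance of the
#'   retained set; default 60.
#' @param loading_threshold practical-significance cutoff on rotated
#'   loadings; default 0.60.
#' @param max_iter,tol varimax iteration cap and convergence tolerance.
#' @return An object of class `fa_config`.
#' @export
fa_config <- function(eigen_threshold = 1.0, cumvar_threshold = 60,
                      loading_threshold = 0.60, max_iter = 1000L,
                      tol = 1e-8) {
  stopifnot(eigen_threshold > 0, cumvar_threshold > 0, loading_threshold > 0)
  structure(list(eigen_threshold = eigen_threshold,
                 cumvar_threshold = cumvar_threshold,
                 loading_threshold = loading_threshold,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "fa_config")
}

check_corr <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8)
    stop_usage("R must be a symmetric correlation matrix")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop_usage("R must have a unit diagonal")
  R
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix departs from the identity (i.e. the
#' variables share enough correlation for factoring):
#' `chi^2 = -(n - 1 - (2p + 5)/6) * ln det R`, `df = p(p-1)/2`.
#'
#' @param R correlation matrix (symmetric, unit diagonal, positive
#'   determinant).
#' @param n sample size behind `R`.
#' @return List with `chisq`, `df`, `p`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- check_corr(R)
  p <- nrow(R)
  if (p < 2L) stop_usage("Bartlett sphericity needs at least 2 variables")
  detR <- det(R)
  if (detR <= 0) stop_usage("singular correlation matrix (det <= 0)")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Contrasts raw correlations with anti-image partial correlations (from the
#' inverse of `R`): overall KMO is `sum r^2 / (sum r^2 + sum q^2)` over the
#' off-diagonal, with per-variable analogues per row. Values above .50
#' indicate the matrix is appropriate for factoring. A diagonal `R` makes the
#' measure 0/0; it is then reported as `NA` (flagged), not an error.
#'
#' @param R invertible correlation matrix.
#' @return List with `overall` and named `per_variable`.
#' @export
kmo <- function(R) {
  R <- check_corr(R)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop_usage("singular correlation matrix"))
  s <- diag(Rinv)
  Q <- -Rinv / sqrt(outer(s, s))      # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  denom <- sum(r2) + sum(q2)
  overall <- if (denom == 0) structure(NA_real_, undefined = TRUE) else
    sum(r2) / denom
  pv_den <- rowSums(r2) + rowSums(q2)
  per <- ifelse(pv_den == 0, NA_real_, rowSums(r2) / pv_den)
  names(per) <- rownames(R) %||% paste0("V", seq_len(nrow(R)))
  list(overall = overall, per_variable = per)
}

#' Component retention rule
#'
#' Retains the components whose eigenvalues are strictly greater than
#' `eigen_threshold` (Kaiser rule); warns when their cumulative percent
#' variance falls short of `cumvar_threshold`.
#'
#' @param eigenvalues eigenvalues of the correlation matrix, sorted
#'   descending.
#' @param config an [fa_config()].
#' @return Integer count of retained components.
#' @examples
#' retain_components(c(3.29, 2.854, 1.721, 1.52, 1.447, 0.9, 0.5))  # 5
#' @export
retain_components <- function(eigenvalues, config = fa_config()) {
  stopifnot(!is.unsorted(rev(eigenvalues)))
  k <- sum(eigenvalues > config$eigen_threshold)
  cumvar <- 100 * sum(eigenvalues[seq_len(k)]) / sum(eigenvalues)
  if (k > 0L && cumvar < config$cumvar_threshold)
    warning(sprintf(
      "retained %d components explain %.1f%% of variance, below %.0f%%",
      k, cumvar, config$cumvar_threshold))
  k
}

#' Correlation-matrix PCA with varimax rotation
#'
#' Eigendecomposition of the correlation matrix of the complete-case rows;
#' loadings are eigenvectors scaled by the square root of their eigenvalues;
#' components retained by [retain_components()] are varimax-rotated with
#' Kaiser row normalization. Orthogonal rotation preserves per-variable
#' communalities. Deterministic conventions: each rotated component's
#' largest-magnitude loading is made positive, and components are ordered by
#' rotated variance (sum of squared loadings), descending.
#'
#' @param x numeric data matrix or data frame (rows = possessions, columns
#'   = variables); non-numeric columns are rejected.
#' @param config an [fa_config()].
#' @return An object of class `factor_model`: variable names, eigenvalues
#'   with percent and cumulative variance, rotated loadings, practical-
#'   significance flags, communalities, rotated variance per component,
#'   Bartlett test, KMO measures, `n` (complete cases) and `n_dropped`.
#' @export
pca_varimax <- function(x, config = fa_config()) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  if (!all(num))
    stop_usage("non-numeric column(s): ",
               paste(names(x)[!num], collapse = ", "))
  x <- as.matrix(x)
  cc <- stats::complete.cases(x)
  n_dropped <- sum(!cc)
  x <- x[cc, , drop = FALSE]
  p <- ncol(x)
  if (nrow(x) < p + 1L)
    stop_usage("need at least variables + 1 complete rows")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop_usage("constant column(s): ",
               paste(colnames(x)[sds == 0], collapse = ", "))
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  k <- retain_components(ev, config)
  if (k < 1L) stop_usage("no component passes the eigenvalue threshold")
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rownames(L) <- colnames(x)
  Lr <- L
  if (k > 1L) {
    # restart the rotation until it reaches a true fixed point: a single
    # varimax call can stop on a criterion plateau short of the optimum
    converged <- FALSE
    vcrit <- function(M) sum(apply(M^2, 2L, stats::var))
    last <- vcrit(Lr)
    for (it in seq_len(1000L)) {
      rot <- stats::varimax(Lr, normalize = TRUE, eps = config$tol)
      Lr <- Lr %*% rot$rotmat
      now <- vcrit(Lr)
      if (max(abs(rot$rotmat - diag(k))) < 1e-7 ||
          now - last < 1e-7 * max(1, now)) { converged <- TRUE; break }
      last <- now
    }
    if (!converged) warning("varimax rotation did not fully converge; ",
                            "returning the last iterate")
  }
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(Lr))) {
    if (Lr[which.max(abs(Lr[, j])), j] < 0) Lr[, j] <- -Lr[, j]
  }
  ssl <- colSums(Lr^2)
  ord <- order(ssl, decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  ssl <- ssl[ord]
  colnames(Lr) <- paste0("PC", seq_len(k))
  structure(list(
    variables = colnames(x),
    eigenvalues = ev,
    pct_variance = 100 * ev / p,
    cum_variance = cumsum(100 * ev / p),
    n_retained = k,
    loadings = Lr,
    flags = abs(Lr) >= config$loading_threshold,
    communalities = rowSums(Lr^2),
    rotated_ssl = ssl,
    rotated_pct = 100 * ssl / p,
    bartlett = tryCatch(bartlett_sphericity(R, nrow(x)), error = function(e) {
      # exactly collinear variables (e.g. a metric defined as an affine
      # function of another) make det(R) = 0; the PCA itself is unaffected
      warning("Bartlett test unavailable: ", conditionMessage(e))
      list(chisq = NA_real_, df = p * (p - 1) / 2, p = NA_real_)
    }),
    kmo = tryCatch(kmo(R), error = function(e) {
      warning("KMO unavailable: ", conditionMessage(e))
      list(overall = NA_real_,
           per_variable = stats::setNames(rep(NA_real_, p), colnames(x)))
    }),
    n = nrow(x), n_dropped = n_dropped,
    config = config), class = "factor_model")
}

#' @export
print.factor_model <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<factor_model> %d variables, %d complete cases, %d components retained\n",
    length(x$variables), x$n, x$n_retained))
  L <- round(x$loadings, digits)
  disp <- matrix(sprintf(paste0("%.", digits, "f%s"), x$loadings,
                         ifelse(x$flags, "*", " ")),
                 nrow = nrow(L), dimnames = dimnames(L))
  print(as.data.frame(disp))
  k <- x$n_retained
  cat("Eigenvalues:", paste(round(x$eigenvalues[seq_len(k)], 3),
                            collapse = "  "), "\n")
  cat(sprintf("Cumulative %% variance (retained): %.1f\n",
              x$cum_variance[k]))
  cat(sprintf("Bartlett chi^2 = %.1f (df = %d), p %s\n", x$bartlett$chisq,
              x$bartlett$df,
              format.pval(x$bartlett$p, digits = 2, eps = .001)))
  cat(sprintf("KMO overall = %.2f\n", as.numeric(x$kmo$overall)))
  cat("(*) |loading| >=", x$config$loading_threshold, "\n")
  invisible(x)
}

#' @export
summary.factor_model <- function(object, ...) {
  print(object, ...)
  cat("Per-variable KMO:\n")
  print(round(object$kmo$per_variable, 2))
  invisible(object)
}

#' Write a factor model as a loadings CSV
#'
#' Variables x components plus eigenvalue, percent-variance, cumulative,
#' Bartlett and KMO rows, shaped like a published loadings table.
#'
#' @param model a `factor_model`.
#' @param path destination CSV.
#' @export
write_factor_csv <- function(model, path) {
  k <- model$n_retained
  L <- format(round(model$loadings, 3), nsmall = 3)
  body <- data.frame(variable = model$variables, L, check.names = FALSE,
                     stringsAsFactors = FALSE)
  extra <- rbind(
    c("eigenvalue", format(round(model$eigenvalues[seq_len(k)], 3))),
    c("pct_variance", format(round(model$pct_variance[seq_len(k)], 1))),
    c("cumulative_pct", format(round(model$cum_variance[seq_len(k)], 1))),
    c("bartlett_chisq", format(round(model$bartlett$chisq, 1)),
      rep("", k - 1)),
    c("bartlett_p", format.pval(model$bartlett$p, digits = 3, eps = 1e-12),
      rep("", k - 1)),
    c("kmo_overall", format(round(as.numeric(model$kmo$overall), 3)),
      rep("", k - 1)))
  colnames(extra) <- colnames(body)
  utils::write.csv(rbind(body, extra), path, row.names = FALSE)
  invisible(path)
}
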