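#' Pinball (check) loss
#'
#' Mean asymmetric absolute loss `(tau - 1{y < q}) * (y - q)` underlying all
#' quantile-regression fits in the package. Nonnegative, and zero exactly
#' when `y == q` elementwise.
#'
#' @param y Observed values.
#' @param q Predicted quantiles, same length as `y`.
#' @param tau Target probability, strictly inside (0, 1).
#' @return A single nonnegative number.
#' @export
#' @examples
#' pinball_loss(c(0, 1), c(0.5, 0.5), 0.5) # 0.25
pinball_loss <- function(y, q, tau) {
  if (length(y) != length(q))
    stop("y and q must have equal length", call. = FALSE)
  if (tau <= 0 || tau >= 1)
    stop("tau must lie strictly inside (0, 1)", call. = FALSE)
  mean((tau - (y < q)) * (y - q))
}

validate_taus <- function(taus) {
  if (any(taus <= 0 | taus >= 1) || is.unsorted(taus, strictly = TRUE))
    stop("taus must be strictly increasing probabilities inside (0, 1)",
         call. = FALSE)
  taus
}

#' Linear quantile regression of IMMAX on age
#'
#' Fits, for every `tau`, the line `intercept + slope * age` minimizing the
#' pinball loss. The solver runs an asymmetric-weight iteratively
#' reweighted least-squares pass to near-optimality and then polishes to an
#' exact basic solution by enumerating candidate lines through the data
#' points with the smallest absolute residuals (the optimal quantile line
#' interpolates at least two observations).
#'
#' @param age Ages in years.
#' @param y Responses in \[0, 1\], same length.
#' @param taus Strictly increasing probabilities (default the five
#'   reference centiles P03/P15/P50/P85/P97).
#' @param intercept_only Fit a constant per tau (the sample tau-quantile);
#'   required when all ages coincide.
#' @return A `centile_model` with `algorithm = "LQR"`, a 2 x length(taus)
#'   coefficient matrix, and per-tau empirical coverage diagnostics.
#' @export
fit_lqr <- function(age, y, taus = c(0.03, 0.15, 0.50, 0.85, 0.97),
                    intercept_only = FALSE) {
  validate_taus(taus)
  if (length(age) != length(y)) stop("age and y must have equal length", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  if (!intercept_only && length(unique(age)) == 1L)
    stop("all ages identical: the slope is unidentifiable; ",
         "refit with intercept_only = TRUE for a constant quantile",
         call. = FALSE)
  coef <- vapply(taus, function(tau) {
    if (intercept_only) c(lqr_intercept_only(y, tau), 0)
    else lqr_exact(age, y, tau)
  }, numeric(2))
  dimnames(coef) <- list(c("intercept", "slope"), paste0("tau_", taus))
  fitted <- t(coef[1, ] + outer(coef[2, ], age))
  model <- list(algorithm = "LQR", taus = taus, age_range = range(age),
                coef = coef,
                diagnostics = coverage_diagnostics(y, fitted, taus))
  class(model) <- "centile_model"
  model
}

# exact tau-quantile line: IRLS warm start + basic-solution polishing
lqr_exact <- function(x, y, tau, pool = 40L, rounds = 5L) {
  X <- cbind(1, x)
  beta <- tryCatch(qr.solve(X, y), error = function(e) c(stats::median(y), 0))
  for (it in 1:60) {
    r <- as.numeric(y - X %*% beta)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), 1e-7)
    beta_new <- tryCatch(solve(crossprod(X, X * w), crossprod(X, y * w)),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < 1e-11) { beta <- as.numeric(beta_new); break }
    beta <- as.numeric(beta_new)
  }
  best <- as.numeric(beta)
  bestloss <- pinball_loss(y, X %*% best, tau)
  n <- length(y)
  for (round in seq_len(rounds)) {
    r <- as.numeric(y - X %*% best)
    idx <- order(abs(r))[seq_len(min(n, pool))]
    improved <- FALSE
    for (i in seq_along(idx)) {
      for (j in seq_len(i - 1L)) {
        a <- idx[i]; b <- idx[j]
        if (x[a] == x[b]) next
        sl <- (y[a] - y[b]) / (x[a] - x[b])
        ic <- y[a] - sl * x[a]
        l <- pinball_loss(y, ic + sl * x, tau)
        if (l < bestloss - 1e-14) {
          bestloss <- l; best <- c(ic, sl); improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best
}

# constant minimizing pinball loss; averages adjacent tied minimizers so the
# tau = 0.5 fit equals the sample median
lqr_intercept_only <- function(y, tau) {
  ys <- sort(unique(y))
  loss <- vapply(ys, function(c) pinball_loss(y, rep(c, length(y)), tau), 0)
  i <- which.min(loss)
  out <- ys[i]
  if (i < length(ys) && abs(loss[i + 1L] - loss[i]) < 1e-14)
    out <- (ys[i] + ys[i + 1L]) / 2
  out
}

#' Penalized-spline nonparametric quantile regression
#'
#' Fits, for every `tau`, a cubic B-spline curve on an equally spaced knot
#' grid minimizing `pinball loss + penalty * ||second differences of the
#' coefficients||^2` (a quantile P-spline). When `penalty` is `NULL` it is
#' chosen per tau by minimizing a Schwarz-type criterion
#' `log(mean pinball) + log(n)/(2n) * edf` over a log-spaced grid. The
#' spline basis is only defined over the observed age range: evaluating the
#' fitted curves outside it is an error, so these models cannot be
#' extrapolated.
#'
#' @inheritParams fit_lqr
#' @param penalty Nonnegative smoothing penalty shared by all taus, or
#'   `NULL` for per-tau Schwarz selection.
#' @param basis_size Number of B-spline coefficients (>= 4; default 10).
#' @return A `centile_model` with `algorithm = "NQR"`, knots and per-tau
#'   coefficients, selected penalties, and coverage diagnostics.
#' @export
fit_nqr <- function(age, y, taus = c(0.03, 0.15, 0.50, 0.85, 0.97),
                    penalty = NULL, basis_size = 10L) {
  validate_taus(taus)
  if (length(age) != length(y)) stop("age and y must have equal length", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  if (basis_size < 4L) stop("basis_size must be at least 4", call. = FALSE)
  if (!is.null(penalty) && (length(penalty) != 1L || penalty < 0))
    stop("penalty must be a single nonnegative number", call. = FALSE)
  rng <- range(age)
  B <- pspline_basis(age, rng[1], rng[2], basis_size)
  D <- diff(diag(ncol(B)), differences = 2L)
  DtD <- crossprod(D)
  lam_grid <- if (is.null(penalty)) 10^seq(-2, 5, length.out = 8) else penalty
  fit_one <- function(tau) {
    picks <- lapply(lam_grid, function(lam) nqr_irls(B, y, tau, lam, DtD))
    if (length(picks) > 1L) {
      n <- length(y)
      sic <- vapply(picks, function(f) log(max(f$loss, 1e-12)) +
                      log(n) / (2 * n) * f$edf, 0)
      picks[[which.min(sic)]]
    } else picks[[1L]]
  }
  fits <- lapply(taus, fit_one)
  theta <- vapply(fits, `[[`, numeric(ncol(B)), "theta")
  colnames(theta) <- paste0("tau_", taus)
  fitted <- B %*% theta
  model <- list(algorithm = "NQR", taus = taus, age_range = rng,
                basis_size = as.integer(basis_size),
                theta = theta,
                penalty = vapply(fits, `[[`, 0, "lambda"),
                diagnostics = coverage_diagnostics(y, fitted, taus))
  class(model) <- "centile_model"
  model
}

# asymmetric-weight IRLS for the penalized pinball objective
nqr_irls <- function(B, y, tau, lambda, DtD) {
  th <- tryCatch(qr.solve(B, y), error = function(e) rep(mean(y), ncol(B)))
  w <- rep(1, length(y))
  for (it in 1:60) {
    A <- crossprod(B, B * w) + lambda * DtD
    th_new <- tryCatch(as.numeric(solve(A, crossprod(B, y * w))),
                       error = function(e) th)
    conv <- max(abs(th_new - th)) < 1e-9
    th <- th_new
    r <- as.numeric(y - B %*% th)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), 1e-6)
    if (conv && it > 2L) break
  }
  A <- crossprod(B, B * w) + lambda * DtD
  edf <- tryCatch(sum(diag(solve(A, crossprod(B, B * w)))),
                  error = function(e) ncol(B))
  list(theta = th, lambda = lambda, edf = edf,
       loss = pinball_loss(y, as.numeric(B %*% th), tau))
}

# cubic B-spline basis on equally spaced knots spanning [a0, a1]
pspline_basis <- function(x, a0, a1, K) {
  pad <- 1e-6 * (a1 - a0)
  lo <- a0 - pad; hi <- a1 + pad
  nseg <- K - 3L
  h <- (hi - lo) / nseg
  knots <- lo + h * (-3:(nseg + 3))
  splines::splineDesign(knots, x, ord = 4L)
}

coverage_diagnostics <- function(y, fitted, taus) {
  data.frame(tau = taus,
             coverage_strict = colMeans(fitted > y),
             coverage_weak = colMeans(fitted >= y))
}

#' @export
print.centile_model <- function(x, ...) {
  cat(sprintf("%s centile model, taus: %s, age range [%.1f, %.1f]\n",
              x$algorithm, paste(x$taus, collapse = "/"),
              x$age_range[1], x$age_range[2]))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}
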