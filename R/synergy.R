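# Bliss and ZIP synergy scoring of dose-response checkerboards. Responses
# are inhibition fractions (1 - relative viability); deltas are reported in
# percentage points as observed minus the reference-model expectation, so
# positive deltas mean synergy and negative antagonism.

#' Dose-response checkerboard matrix
#'
#' @param response numeric matrix of inhibition fractions in [0, 1]; rows =
#'   doses of drug A, columns = doses of drug B.
#' @param doses_a,doses_b ascending dose grids; the first entry of each must
#'   be 0 (monotherapy axes live in row 1 / column 1).
#' @param drug_a,drug_b drug names.
#' @param replicates number of replicates averaged into `response`.
#' @return A `dose_response_matrix` list.
#' @export
dose_response_matrix <- function(response, doses_a, doses_b,
                                 drug_a = "drugA", drug_b = "drugB",
                                 replicates = 1L) {
  response <- as.matrix(response)
  doses_a <- as.numeric(doses_a)
  doses_b <- as.numeric(doses_b)
  if (nrow(response) != length(doses_a) || ncol(response) != length(doses_b)) {
    stop("response dimensions must match the dose grids")
  }
  if (doses_a[1L] != 0 || doses_b[1L] != 0) {
    stop("each dose grid must start at 0 (monotherapy axis)")
  }
  if (is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE)) {
    stop("dose grids must be strictly ascending")
  }
  if (any(!is.finite(response))) stop("responses must be finite")
  if (abs(response[1L, 1L]) > 0.05) {
    warning("untreated (0, 0) well has inhibition far from 0; check scale")
  }
  structure(list(response = response, doses_a = doses_a, doses_b = doses_b,
                 drug_a = drug_a, drug_b = drug_b,
                 replicates = as.integer(replicates)),
            class = "dose_response_matrix")
}

#' @export
print.dose_response_matrix <- function(x, ...) {
  cat(sprintf("Dose matrix %s x %s: %d x %d doses (incl. monotherapy axes)\n",
              x$drug_a, x$drug_b, length(x$doses_a), length(x$doses_b)))
  invisible(x)
}

# Scale guard shared by both reference models: hard error outside
# [-0.2, 1.2] (wrong scale, e.g. percent), soft clip to [0, 1] inside it.
check_responses <- function(resp) {
  if (any(resp < -0.2 | resp > 1.2)) {
    stop("responses outside [-0.2, 1.2]; expected inhibition fractions")
  }
  if (any(resp < 0 | resp > 1)) {
    warning("responses outside [0, 1] clipped")
    resp <- pmin(pmax(resp, 0), 1)
  }
  resp
}

new_synergy_result <- function(model, delta, fit = NULL) {
  structure(list(model = model, delta = delta,
                 synergy_score = mean(delta),
                 most_synergistic_area = most_synergistic_area(delta),
                 fit = fit),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("%s synergy: score = %.2f, most synergistic area = %.2f (percentage points, %d x %d combination cells)\n",
              toupper(x$model), x$synergy_score, x$most_synergistic_area,
              nrow(x$delta), ncol(x$delta)))
  invisible(x)
}

#' Bliss-independence synergy delta
#'
#' For each combination cell the Bliss expectation is
#' `y_A + y_B - y_A * y_B` from the observed monotherapy inhibition
#' fractions; the delta is `100 * (observed - expected)` percentage points.
#' The overall synergy score is the mean delta over the combination cells
#' (the monotherapy row/column is excluded: its deltas are 0 by
#' construction), and the most-synergistic-area score the maximum 3x3-window
#' mean of the delta surface.
#'
#' @param matrix a [dose_response_matrix()] with monotherapy row and column.
#' @return A `synergy_result`: `model`, `delta` surface (combination cells),
#'   `synergy_score`, `most_synergistic_area`.
#' @export
bliss_delta <- function(matrix) {
  stopifnot(inherits(matrix, "dose_response_matrix"))
  resp <- check_responses(matrix$response)
  if (nrow(resp) < 2L || ncol(resp) < 2L) {
    stop("need at least one non-zero dose per drug")
  }
  y_a <- resp[, 1L][-1L]
  y_b <- resp[1L, ][-1L]
  expected <- outer(y_a, y_b, function(a, b) a + b - a * b)
  observed <- resp[-1L, -1L, drop = FALSE]
  delta <- 100 * (observed - expected)
  dimnames(delta) <- list(matrix$doses_a[-1L], matrix$doses_b[-1L])
  new_synergy_result("bliss", delta)
}

# Four-parameter logistic on inhibition fractions:
# y(c) = ymin + (ymax - ymin) / (1 + (ec50 / c)^slope), y(0) = ymin.
pl4 <- function(conc, ymin, ymax, ec50, slope) {
  ifelse(conc == 0, ymin, ymin + (ymax - ymin) / (1 + (ec50 / conc)^slope))
}

# Bounded 4PL fit (ymin in [0, 0.3], ymax in [0.7, 1], slope and ec50 > 0)
# by Levenberg-Marquardt least squares. Returns the coefficient vector, or
# NULL on non-convergence.
fit_4pl <- function(doses, y) {
  mid <- (max(y) + min(y)) / 2
  start <- list(ymin = min(max(min(y), 0), 0.3),
                ymax = max(min(max(y), 1), 0.7),
                ec50 = doses[which.min(abs(y - mid))],
                slope = 1)
  if (start$ec50 <= 0) start$ec50 <- stats::median(doses[doses > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ pl4(doses, ymin, ymax, ec50, slope),
                      data = data.frame(doses = doses, y = y),
                      start = start,
                      lower = c(ymin = 0, ymax = 0.7, ec50 = 1e-9,
                                slope = 1e-3),
                      upper = c(ymin = 0.3, ymax = 1,
                                ec50 = max(doses) * 1e3, slope = 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) NULL else as.list(stats::coef(fit))
}

# Two-parameter potency-shift fit used by ZIP along one axis: the minimum is
# fixed at the partner's fitted monotherapy effect and the maximum at full
# inhibition. Falls back to the observed responses on non-convergence.
fit_shift <- function(doses, y, floor_y) {
  start <- list(ec50 = stats::median(doses), slope = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (floor_y + (doses / ec50)^slope) / (1 + (doses / ec50)^slope),
      data = data.frame(doses = doses, y = y),
      start = start,
      lower = c(ec50 = 1e-9, slope = 1e-3),
      upper = c(ec50 = max(doses) * 1e3, slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  u <- (doses / cf[["ec50"]])^cf[["slope"]]
  (floor_y + u) / (1 + u)
}

#' Zero-interaction-potency (ZIP) synergy delta
#'
#' Fits a four-parameter logistic to each monotherapy axis, then captures
#' the potency shift each drug induces on the other: along every row and
#' column of the checkerboard the conditional response curve is refit with
#' the partner's fitted monotherapy effect as its fixed baseline and full
#' inhibition as its maximum. The fitted conditional values from the two
#' axes are averaged and compared with the Bliss expectation of the fitted
#' monotherapies; deltas are in percentage points and summarized as in
#' [bliss_delta()]. Non-convergent conditional fits fall back to the
#' observed responses with a warning.
#'
#' @param matrix a [dose_response_matrix()] with >= 4 non-zero doses per
#'   monotherapy axis.
#' @return A `synergy_result` with `fit` holding the two monotherapy 4PL
#'   parameter sets.
#' @export
zip_delta <- function(matrix) {
  stopifnot(inherits(matrix, "dose_response_matrix"))
  resp <- check_responses(matrix$response)
  da <- matrix$doses_a
  db <- matrix$doses_b
  if (sum(da > 0) < 4L || sum(db > 0) < 4L) {
    stop("ZIP needs at least 4 non-zero doses per monotherapy axis")
  }
  fa <- fit_4pl(da, resp[, 1L])
  fb <- fit_4pl(db, resp[1L, ])
  fallback_mono <- FALSE
  ya <- if (is.null(fa)) { fallback_mono <- TRUE; resp[-1L, 1L] }
        else pl4(da[-1L], fa$ymin, fa$ymax, fa$ec50, fa$slope)
  yb <- if (is.null(fb)) { fallback_mono <- TRUE; resp[1L, -1L] }
        else pl4(db[-1L], fb$ymin, fb$ymax, fb$ec50, fb$slope)
  if (fallback_mono) {
    warning("monotherapy 4PL fit did not converge; using observed monotherapy responses")
  }

  obs <- resp[-1L, -1L, drop = FALSE]
  n_a <- nrow(obs); n_b <- ncol(obs)
  fell_back <- FALSE

  # conditional fits along A (one per B dose) ...
  fit_a <- obs
  for (j in seq_len(n_b)) {
    v <- fit_shift(da[-1L], obs[, j], yb[j])
    if (is.null(v)) fell_back <- TRUE else fit_a[, j] <- v
  }
  # ... and along B (one per A dose)
  fit_b <- obs
  for (i in seq_len(n_a)) {
    v <- fit_shift(db[-1L], obs[i, ], ya[i])
    if (is.null(v)) fell_back <- TRUE else fit_b[i, ] <- v
  }
  if (fell_back) {
    warning("some conditional ZIP fits did not converge; observed responses used for those slices")
  }

  expected <- outer(ya, yb, function(a, b) a + b - a * b)
  delta <- 100 * ((fit_a + fit_b) / 2 - expected)
  dimnames(delta) <- list(da[-1L], db[-1L])
  new_synergy_result("zip", delta, fit = list(drug_a = fa, drug_b = fb))
}

#' Most synergistic area of a delta surface
#'
#' Maximum mean delta over all contiguous 3x3 windows of the surface
#' (SynergyFinder convention). Surfaces smaller than 3x3 use the largest
#' available window; ties resolve to the first window in row-major order.
#'
#' @param delta numeric matrix of synergy deltas (percentage points).
#' @return The maximum window mean.
#' @export
most_synergistic_area <- function(delta) {
  delta <- as.matrix(delta)
  if (length(delta) == 0L) stop("empty delta surface")
  wr <- min(3L, nrow(delta))
  wc <- min(3L, ncol(delta))
  best <- -Inf
  for (i in seq_len(nrow(delta) - wr + 1L)) {
    for (j in seq_len(ncol(delta) - wc + 1L)) {
      m <- mean(delta[i:(i + wr - 1L), j:(j + wc - 1L)])
      if (m > best) best <- m
    }
  }
  best
}
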