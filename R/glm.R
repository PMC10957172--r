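# Gaussian GLM of firing rate on trajectory x position and speed
# polynomials plus trial covariates:
#
#   FR = b0 + sum_k b_TPk T*P^k + sum_k b_Sk S^k + b_TN TN + b_R R
#        + b_A0 A0 + b_A1 A-1 + eps,          k = 1..order (default 6)
#
# One observation per (trial, bin) with occupancy > 0; FR is the raw
# (unsmoothed) per-trial-bin rate.  T is coded 1 for left and 2 for right;
# P is normalized position in (0, 1]; S is speed; TN the trial number; R
# the cumulative correct rate; A0 / A-1 current / previous trial accuracy
# (1 correct, 0 error; A-1 of the first trial set to 1).  The polynomial
# blocks are fitted on an orthonormalized basis (QR of the scaled monomial
# columns) for conditioning, with coefficients mapped back to the monomial
# basis — the two parameterizations span exactly the same model, so
# predictions are identical.

glm_predictors <- c("T", "S", "TN", "R", "A0", "A1")

# Orthonormal basis for the span of {v, v^2, ..., v^order} (no constant),
# with the transform back to monomial coefficients on the original scale.
poly_basis <- function(v, order, scale = max(abs(v))) {
  vs <- v / scale
  raw <- outer(vs, seq_len(order), `^`)
  qr_ <- qr(raw)
  list(Q = qr.Q(qr_), R = qr.R(qr_), scale = scale, order = order)
}

poly_eval <- function(basis, v) {
  raw <- outer(v / basis$scale, seq_len(basis$order), `^`)
  raw %*% solve(basis$R)
}

# gamma (orthonormal-basis coefs) -> beta (monomial coefs, original scale)
poly_back <- function(basis, gamma) {
  beta_scaled <- solve(basis$R, gamma)
  beta_scaled / basis$scale^seq_len(basis$order)
}

#' Build the firing-rate regression design for one unit
#'
#' @param lin A `lin_session` tibble restricted to (or containing) the unit
#'   of interest.
#' @param unit Unit id; may be omitted when `lin` holds a single unit.
#' @param order Polynomial order for the position and speed blocks.
#' @param task Task(s) whose trials enter the design (error trials are
#'   retained: accuracy enters as a covariate).
#' @return A list of class `rate_glm_design`: `frame` (tibble of
#'   observations and raw predictors), `X` (orthonormalized design
#'   matrix), `terms` (monomial term names), bases and bookkeeping.
#' @export
build_design <- function(lin, unit = NULL, order = 6, task = "memory") {
  n_bins <- attr(lin, "n_bins") %||% max(lin$bin)
  if (!is.null(unit)) lin <- lin[lin$unit_id == unit, ]
  if (length(unique(lin$unit_id)) != 1) {
    abort("design needs exactly one unit; pass `unit`")
  }
  lin <- lin[lin$task %in% task, ]
  trials <- dplyr::distinct(lin[, c("trial_index", "trajectory",
                                    "accuracy")]) |>
    dplyr::arrange(.data$trial_index)
  if (nrow(trials) < 20) abort("need at least 20 trials to fit the model")
  if (length(unique(trials$trajectory)) < 2) {
    abort("rank-deficient design: all trials have the same trajectory")
  }
  trials$tn <- seq_len(nrow(trials))
  trials$r <- cumsum(trials$accuracy == "correct") / trials$tn
  trials$a0 <- as.numeric(trials$accuracy == "correct")
  trials$a1 <- dplyr::lag(trials$a0, default = 1)  # trained animals
  trials$t_code <- ifelse(trials$trajectory == "left", 1, 2)

  obs <- lin[lin$occupancy_s > 0, ]
  obs <- dplyr::left_join(
    obs, trials[, c("trial_index", "tn", "r", "a0", "a1", "t_code")],
    by = "trial_index")
  frame <- tibble::tibble(
    trial_index = obs$trial_index,
    bin = obs$bin,
    fr = obs$n_spikes / obs$occupancy_s,
    T = obs$t_code,
    P = obs$bin / n_bins,
    S = obs$speed_cms,
    TN = obs$tn, R = obs$r, A0 = obs$a0, A1 = obs$a1)
  if (any(!is.finite(frame$fr))) abort("non-finite response values")

  bp <- poly_basis(frame$P, order, scale = 1)
  bs <- poly_basis(frame$S, order)
  Qp <- poly_eval(bp, frame$P)
  Qs <- bs$Q
  X <- cbind(1, frame$T * Qp, Qs, frame$TN, frame$R, frame$A0, frame$A1)
  terms <- c("(Intercept)",
             paste0("T:P^", seq_len(order)),
             paste0("S^", seq_len(order)),
             "TN", "R", "A0", "A1")
  colnames(X) <- terms
  structure(list(frame = frame, X = X, terms = terms, order = order,
                 basis_p = bp, basis_s = bs, trials = trials,
                 n_bins = n_bins),
            class = "rate_glm_design")
}

# Minimum-norm least squares via SVD.  Bin speed is width / occupancy and
# occupancy is built from whole tracking intervals, so the speed
# polynomial block can be numerically collinear with the intercept; the
# model stays identifiable in its predictions, and the minimum-norm
# solution is the stable representative.
ols_minnorm <- function(X, y, rtol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * rtol
  gamma <- drop(sv$v[, pos, drop = FALSE] %*%
                  ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
  list(gamma = gamma, fitted = drop(X %*% gamma), rank = sum(pos))
}

# Tolerant solve for the (possibly near-singular) normal equations.
solve_psd <- function(A, b, rtol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > max(e$values) * rtol
  drop(e$vectors[, pos, drop = FALSE] %*%
         ((t(e$vectors[, pos, drop = FALSE]) %*% b) / e$values[pos]))
}

#' Fit the firing-rate GLM
#'
#' Ordinary least squares (Gaussian noise, identity link) on the design
#' from [build_design()], with the Bayesian information criterion computed
#' from the Gaussian log-likelihood.  The solution is the minimum-norm
#' least-squares fit (SVD with relative tolerance 1e-10), which is robust
#' to the near-collinearity of high-order speed polynomials on
#' discretely sampled occupancy.
#'
#' @param design A `rate_glm_design`.
#' @return An object of class `rate_glm` with monomial-basis
#'   `coefficients`, orthonormal-basis `gamma`, `sigma2`, `bic`, `n`,
#'   `rank`, and the design (kept for the shuffle test).
#' @export
fit_glm <- function(design) {
  stopifnot(inherits(design, "rate_glm_design"))
  y <- design$frame$fr
  fit <- ols_minnorm(design$X, y)
  gamma <- fit$gamma
  n <- length(y)
  rss <- sum((y - fit$fitted)^2)
  sigma2 <- rss / n
  p <- ncol(design$X)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  bic <- -2 * loglik + (p + 1) * log(n)
  ord <- design$order
  beta <- c(gamma[1],
            poly_back(design$basis_p, gamma[1 + seq_len(ord)]),
            poly_back(design$basis_s, gamma[1 + ord + seq_len(ord)]),
            gamma[(2 + 2 * ord):(5 + 2 * ord)])
  names(beta) <- design$terms
  structure(list(coefficients = beta, gamma = gamma, sigma2 = sigma2,
                 bic = bic, n = n, fitted = fit$fitted,
                 rank = fit$rank,
                 design = design),
            class = "rate_glm")
}

#' @export
print.rate_glm <- function(x, ...) {
  cat(sprintf("<rate_glm> %d obs, %d coefficients, BIC %.1f\n",
              x$n, length(x$coefficients), x$bic))
  invisible(x)
}

#' @export
predict.rate_glm <- function(object, ...) {
  drop(object$design$X %*% object$gamma)
}

#' @export
tidy.rate_glm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.rate_glm <- function(x, ...) {
  tibble::tibble(n = x$n, n_coef = length(x$coefficients),
                 sigma2 = x$sigma2, bic = x$bic)
}

#' Choose the polynomial order by BIC
#'
#' Fits the model at each candidate order and returns the BIC table with
#' the minimizing order flagged.
#'
#' @param lin,unit,task As in [build_design()].
#' @param orders Candidate polynomial orders.
#' @return Tibble (`order`, `n_coef`, `bic`, `chosen`); the chosen order is
#'   also in the `chosen_order` attribute.
#' @export
select_order <- function(lin, unit = NULL, orders = 1:6, task = "memory") {
  if (length(orders) < 2) abort("need at least two candidate orders")
  bics <- vapply(orders, function(o) {
    fit_glm(build_design(lin, unit, order = o, task = task))$bic
  }, numeric(1))
  out <- tibble::tibble(order = orders, n_coef = 5 + 2 * orders,
                        bic = bics, chosen = bics == min(bics))
  attr(out, "chosen_order") <- orders[which.min(bics)]
  out
}

# The mean predicted left-right difference over a region is linear in the
# predicted values: D = sum_i w_i * pred_i, with weights +-1 / (n_common *
# cell count) for rows whose (side, bin) cell lies in the region and whose
# bin is observed on both sides.  Precomputing w makes every shuffle's D a
# couple of small cross-products.
pred_diff_weights <- function(is_left, bin, region_bins, n_bins) {
  keep <- bin %in% region_bins
  common <- intersect(unique(bin[keep & is_left]),
                      unique(bin[keep & !is_left]))
  if (length(common) == 0) {
    abort("no region bin is observed on both trajectories")
  }
  w <- numeric(length(bin))
  sel <- keep & bin %in% common
  code <- bin[sel] + n_bins * (!is_left[sel])
  cnt <- tabulate(code, nbins = 2L * n_bins)
  w[sel] <- ifelse(is_left[sel], 1, -1) / (length(common) * cnt[code])
  w
}

#' Simulate a response from the firing-rate model
#'
#' Generates `FR = X beta + eps` on the covariates of an existing design,
#' with `beta` given in the monomial basis (the 17 terms of
#' [build_design()], in order).  Useful for parameter-recovery and
#' operating-characteristic studies on real covariate structure.
#'
#' @param design A `rate_glm_design`.
#' @param beta Coefficient vector, length `5 + 2 * order`, monomial basis.
#' @param sigma Residual standard deviation.
#' @param seed Seed (optional).
#' @return Numeric response vector aligned with `design$frame`.
#' @export
simulate_glm_response <- function(design, beta, sigma = 1, seed = NULL) {
  stopifnot(inherits(design, "rate_glm_design"),
            length(beta) == length(design$terms))
  if (!is.null(seed)) set.seed(seed)
  fr <- design$frame
  ord <- design$order
  Xm <- cbind(1, fr$T * outer(fr$P, seq_len(ord), `^`),
              outer(fr$S, seq_len(ord), `^`), fr$TN, fr$R, fr$A0, fr$A1)
  drop(Xm %*% beta) + rnorm(nrow(fr), 0, sigma)
}

#' Shuffle-calibrated predictor significance
#'
#' For the unshuffled fit, computes the mean predicted left-right firing
#' rate difference over the bins of the maze region under test (D0).  For
#' each tested predictor, the predictor's trial assignment is shuffled
#' across trials `n_shuffles` times (speed is shuffled as whole trial
#' profiles; the other predictors' labels stay intact), the model refitted
#' and the predicted difference recomputed (Dj).  The predictor is flagged
#' significant when `|D0|` exceeds the `1 - alpha/m` quantile of `|Dj|`
#' (Bonferroni over the `m` tested predictors).
#'
#' @param fit A `rate_glm` from [fit_glm()].
#' @param predictors Predictors to test, among
#'   `c("T", "S", "TN", "R", "A0", "A1")`.
#' @param n_shuffles Number of shuffles (default 500).
#' @param alpha Significance level before Bonferroni.
#' @param m Bonferroni divisor (defaults to the number of tested
#'   predictors).
#' @param region Maze region under test (default `"delay"`) or `"all"`.
#' @param seed Seed.
#' @param boundaries,track_length Section geometry.
#' @return Tibble with one row per predictor: `d0_hat`, `threshold`,
#'   `null_mean`, `significant`, `degenerate` (constant predictors are
#'   untestable).
#' @export
shuffle_significance <- function(fit, predictors = glm_predictors,
                                 n_shuffles = 500, alpha = 0.05,
                                 m = length(predictors), region = "delay",
                                 seed = 1L,
                                 boundaries = c(50, 80, 120, 150),
                                 track_length = 150) {
  stopifnot(inherits(fit, "rate_glm"))
  if (n_shuffles < 20 / (alpha * m)) {
    abort("insufficient resolution: increase n_shuffles")
  }
  design <- fit$design
  frame <- design$frame
  ord <- design$order
  n_bins <- design$n_bins
  region_bins <- section_bins(region, boundaries, track_length, n_bins)
  is_left <- frame$T == 1

  X <- design$X
  y <- frame$fr
  w <- pred_diff_weights(is_left, frame$bin, region_bins, n_bins)
  d0_hat <- drop(crossprod(w, X %*% fit$gamma))

  trial_of_row <- match(frame$trial_index, design$trials$trial_index)
  n_trials <- nrow(design$trials)
  # speed profiles per trial (bins x trials), NA bins interpolated
  smat <- matrix(NA_real_, n_bins, n_trials)
  smat[cbind(frame$bin, trial_of_row)] <- frame$S
  for (j in seq_len(n_trials)) smat[, j] <- interp_na(smat[, j])

  col_block <- function(pred) {
    switch(pred,
           T = 1 + seq_len(ord),
           S = 1 + ord + seq_len(ord),
           TN = 2L + 2L * ord, R = 3L + 2L * ord,
           A0 = 4L + 2L * ord, A1 = 5L + 2L * ord)
  }
  trial_value <- function(pred) {
    switch(pred,
           T = design$trials$t_code, TN = design$trials$tn,
           R = design$trials$r, A0 = design$trials$a0,
           A1 = design$trials$a1, S = NULL)
  }
  shuffled_cols <- function(pred, perm) {
    if (pred == "S") {
      s_new <- smat[cbind(frame$bin, perm[trial_of_row])]
      poly_eval(design$basis_s, s_new)
    } else if (pred == "T") {
      t_new <- trial_value("T")[perm][trial_of_row]
      t_new * poly_eval(design$basis_p, frame$P)
    } else {
      matrix(trial_value(pred)[perm][trial_of_row], ncol = 1)
    }
  }

  set.seed(seed)
  out <- vector("list", length(predictors))
  for (pi in seq_along(predictors)) {
    pred <- predictors[pi]
    tv <- trial_value(pred)
    degen <- if (pred == "S") all(apply(smat, 1, var) == 0) else
      var(tv) == 0
    if (isTRUE(degen)) {
      out[[pi]] <- tibble::tibble(
        predictor = pred, d0_hat = d0_hat, threshold = NA_real_,
        null_mean = NA_real_, null_sd = NA_real_, significant = NA,
        degenerate = TRUE)
      next
    }
    cb <- col_block(pred)
    Fmat <- X[, -cb, drop = FALSE]
    FtF <- crossprod(Fmat)
    Fty <- crossprod(Fmat, y)
    wF <- crossprod(Fmat, w)
    nf <- ncol(Fmat)
    dj <- numeric(n_shuffles)
    for (j in seq_len(n_shuffles)) {
      perm <- sample.int(n_trials)
      C <- shuffled_cols(pred, perm)
      FtC <- crossprod(Fmat, C)
      XtX <- rbind(cbind(FtF, FtC), cbind(t(FtC), crossprod(C)))
      Xty <- rbind(Fty, crossprod(C, y))
      beta <- solve_psd(XtX, Xty)
      if (pred == "T") {
        # the model's trajectory variable IS the shuffled assignment, so
        # the predicted left/right means are grouped by it; this keeps
        # D_j exchangeable with D_0 under the null
        wj <- pred_diff_weights(trial_value("T")[perm][trial_of_row] == 1,
                                frame$bin, region_bins, n_bins)
        dj[j] <- sum(crossprod(Fmat, wj) * beta[seq_len(nf)]) +
          sum(crossprod(C, wj) * beta[-seq_len(nf)])
      } else {
        dj[j] <- sum(wF * beta[seq_len(nf)]) +
          sum(crossprod(C, w) * beta[-seq_len(nf)])
      }
    }
    dj <- dj[is.finite(dj)]
    thr <- quantile(abs(dj), 1 - alpha / m, names = FALSE)
    out[[pi]] <- tibble::tibble(
      predictor = pred, d0_hat = d0_hat, threshold = thr,
      null_mean = mean(dj), null_sd = sd(dj),
      significant = abs(d0_hat) > thr, degenerate = FALSE)
  }
  dplyr::bind_rows(out)
}
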