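# RBF-kernel support vector machine: SMO dual solver with a deterministic
# working-set heuristic, plus Platt sigmoid scaling for probabilities.
# Training sets in this package are small (tens to a few hundred rows,
# three features), so a pure-R solver is adequate and keeps the whole
# pipeline free of external ML dependencies.

rbf_kernel <- function(X, Y, gamma) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Median heuristic: gamma = 1 / median non-zero squared pairwise distance.
median_gamma <- function(X) {
  X <- as.matrix(X)
  d2 <- as.vector(stats::dist(X)^2)
  d2 <- d2[d2 > 0]
  if (length(d2) == 0) return(1 / max(1, ncol(X)))
  1 / median(d2)
}

#' Fit a binary RBF-kernel SVM
#'
#' Solves the C-SVM dual with sequential minimal optimization. The working
#' set selection is Platt's second-choice heuristic with deterministic
#' tie-breaks, so fits are exactly reproducible. Class probabilities come
#' from a Platt sigmoid fitted on the training decision values.
#'
#' @param X numeric matrix (rows = examples).
#' @param y labels coded +1 / -1 (or logical / 0-1, recoded internally).
#' @param cost soft-margin cost C (default 1).
#' @param gamma RBF width; NULL = median heuristic on the training rows.
#' @param tol KKT violation tolerance.
#' @param max_iter cap on SMO outer sweeps.
#' @return an `npm_svm` model object.
#' @export
svm_fit <- function(X, y, cost = 1, gamma = NULL, tol = 1e-3,
                    max_iter = 200L) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  y[y == 0] <- -1
  if (length(unique(y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  n <- nrow(X)
  if (is.null(gamma)) gamma <- median_gamma(X)
  K <- rbf_kernel(X, X, gamma)
  C <- cost

  alpha <- numeric(n)
  b <- 0
  # error cache: E_i = f(x_i) - y_i; with alpha = 0, f = b = 0
  E <- -y

  take_step <- function(i1, i2) {
    if (i1 == i2) return(FALSE)
    a1 <- alpha[i1]; a2 <- alpha[i2]
    y1 <- y[i1]; y2 <- y[i2]
    E1 <- E[i1]; E2 <- E[i2]
    s <- y1 * y2
    if (s > 0) {
      L <- max(0, a1 + a2 - C); H <- min(C, a1 + a2)
    } else {
      L <- max(0, a2 - a1); H <- min(C, C + a2 - a1)
    }
    if (L >= H) return(FALSE)
    k11 <- K[i1, i1]; k12 <- K[i1, i2]; k22 <- K[i2, i2]
    eta <- k11 + k22 - 2 * k12
    if (eta > 1e-12) {
      a2_new <- a2 + y2 * (E1 - E2) / eta
      a2_new <- min(H, max(L, a2_new))
    } else {
      # objective at the clipped ends
      f1 <- y1 * (E1 + b) - a1 * k11 - s * a2 * k12
      f2 <- y2 * (E2 + b) - s * a1 * k12 - a2 * k22
      L1 <- a1 + s * (a2 - L); H1 <- a1 + s * (a2 - H)
      obj_L <- L1 * f1 + L * f2 + 0.5 * L1^2 * k11 + 0.5 * L^2 * k22 +
        s * L * L1 * k12
      obj_H <- H1 * f1 + H * f2 + 0.5 * H1^2 * k11 + 0.5 * H^2 * k22 +
        s * H * H1 * k12
      a2_new <- if (obj_L < obj_H - 1e-12) L else if (obj_L > obj_H + 1e-12) H else a2
    }
    if (abs(a2_new - a2) < 1e-12 * (a2_new + a2 + 1e-12)) return(FALSE)
    a1_new <- a1 + s * (a2 - a2_new)

    b1 <- E1 + y1 * (a1_new - a1) * k11 + y2 * (a2_new - a2) * k12 + b
    b2 <- E2 + y1 * (a1_new - a1) * k12 + y2 * (a2_new - a2) * k22 + b
    b_new <- if (a1_new > 0 && a1_new < C) b1
             else if (a2_new > 0 && a2_new < C) b2
             else (b1 + b2) / 2

    E <<- E + y1 * (a1_new - a1) * K[, i1] + y2 * (a2_new - a2) * K[, i2] -
      (b_new - b)
    alpha[i1] <<- a1_new
    alpha[i2] <<- a2_new
    b <<- b_new
    TRUE
  }

  examine <- function(i2) {
    y2 <- y[i2]; a2 <- alpha[i2]; E2 <- E[i2]
    r2 <- E2 * y2
    if ((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0)) {
      nb <- which(alpha > 0 & alpha < C)
      if (length(nb) > 1) {
        i1 <- nb[which.max(abs(E[nb] - E2))]
        if (take_step(i1, i2)) return(TRUE)
      }
      for (i1 in nb) if (take_step(i1, i2)) return(TRUE)
      for (i1 in seq_len(n)) if (take_step(i1, i2)) return(TRUE)
    }
    FALSE
  }

  examine_all <- TRUE
  num_changed <- 0L
  sweeps <- 0L
  repeat {
    num_changed <- 0L
    idx <- if (examine_all) seq_len(n) else which(alpha > 0 & alpha < C)
    for (i2 in idx) num_changed <- num_changed + examine(i2)
    sweeps <- sweeps + 1L
    if (examine_all) {
      examine_all <- FALSE
    } else if (num_changed == 0L) {
      examine_all <- TRUE
    }
    if ((examine_all && num_changed == 0L && sweeps > 1L) ||
        sweeps >= max_iter) {
      break
    }
  }

  sv <- which(alpha > 1e-12)
  decision <- as.numeric(K %*% (alpha * y) - b)
  platt <- platt_fit(decision, y)
  structure(
    list(sv_X = X[sv, , drop = FALSE], sv_coef = (alpha * y)[sv], b = b,
         gamma = gamma, cost = cost, platt = platt, n_sv = length(sv)),
    class = "npm_svm"
  )
}

# Platt sigmoid P(y = 1 | f) = 1 / (1 + exp(A f + B)), fitted by the
# regularized Newton method of Lin, Lin & Weng (2007).
platt_fit <- function(decision, y) {
  t_pos <- sum(y > 0); t_neg <- sum(y < 0)
  hi <- (t_pos + 1) / (t_pos + 2)
  lo <- 1 / (t_neg + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0
  B <- log((t_neg + 1) / (t_pos + 1))
  f <- decision
  obj <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(A, B)
  for (iter in 1:100) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p
    d2 <- p * (1 - p)
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      A_new <- A + step * dA
      B_new <- B + step * dB
      val_new <- obj(A_new, B_new)
      if (val_new < val + 1e-4 * step * (g1 * dA + g2 * dB) || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA
    B <- B + step * dB
    val <- obj(A, B)
  }
  c(A = A, B = B)
}

#' Decision values and probabilities from a fitted SVM
#'
#' @param model an `npm_svm`.
#' @param X numeric matrix of rows to score.
#' @return list with `decision` and `probability` (P(positive class)).
#' @export
svm_decision <- function(model, X) {
  X <- as.matrix(X)
  dec <- if (model$n_sv > 0) {
    as.numeric(rbf_kernel(X, model$sv_X, model$gamma) %*% model$sv_coef) - model$b
  } else {
    rep(-model$b, nrow(X))
  }
  z <- model$platt["A"] * dec + model$platt["B"]
  prob <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
  list(decision = dec, probability = unname(prob))
}
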