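# The behavioural feature-compound model: logistic regression of hunting
# response probability on binary stimulus features, with stepwise term
# selection and rate-level cross-validation.
#
# The published best model is
#   logit(R) = b0 + b1*size + b2*polarity + b3*speed*size*polarity
# with b0 = -6.51, b1 = 1.33, b2 = 1.87, b3 = 0.90; odds ratios exp(b).

FEATURE_BITS <- c("direction", "speed", "size", "polarity")

# Evaluate product terms like "speed:size:polarity" on a data frame of bits.
term_columns <- function(data, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    bad <- setdiff(parts, FEATURE_BITS)
    if (length(bad)) stopf("unknown feature(s) in term '%s'", tm)
    Reduce(`*`, data[parts])
  })
  names(cols) <- terms
  as.data.frame(cols, optional = TRUE, check.names = FALSE)
}

#' All candidate feature terms up to fourth order
#' @return Character vector of the 4 main effects and 11 product interactions.
#' @export
candidate_terms <- function() {
  unlist(lapply(1:4, function(k) {
    apply(utils::combn(FEATURE_BITS, k), 2, paste, collapse = ":")
  }))
}

#' Simulate Bernoulli hunting-response trials from a logistic model
#'
#' Generates `n_per_stim` trials for each of the 16 moving-spot stimuli with
#' response probability given by the logistic feature-compound model.
#'
#' @param n_per_stim Trials per stimulus.
#' @param coef Named coefficients as in [behavior_params()]`$coef`.
#' @param seed Integer seed.
#' @return Data frame with the four feature bits and `responded` (0/1).
#' @export
simulate_response_trials <- function(n_per_stim,
                                     coef = behavior_params()$coef,
                                     seed = NULL) {
  st <- stimulus_table()[1:16, FEATURE_BITS]
  trials <- st[rep(seq_len(16), each = n_per_stim), ]
  eta <- coef[["intercept"]] + coef[["size"]] * trials$size +
    coef[["polarity"]] * trials$polarity +
    coef[["speed_size_polarity"]] * trials$speed * trials$size * trials$polarity
  p <- stats::plogis(eta)
  trials$responded <- with_seed(seed, as.integer(stats::runif(nrow(trials)) < p))
  rownames(trials) <- NULL
  trials
}

#' Fit the behavioural logistic model
#'
#' Maximum-likelihood logistic regression of per-trial hunting responses on
#' product terms of the four binary stimulus features, with Wald 95%
#' confidence intervals and odds ratios.
#'
#' @param trials Data frame with the four feature bits and `responded` (0/1),
#'   or a [response_rate_table()] result (expanded using trial counts).
#' @param terms Character vector of model terms, e.g.
#'   `c("size", "polarity", "speed:size:polarity")`.
#' @return Object of class `hunt_logit` with elements `coefficients`, `se`,
#'   `ci` (2-column matrix), `odds_ratio`, `terms`, `n`, `deviance`,
#'   `separation` (logical), `cv_r2` (`NA` until computed).
#' @export
fit_logistic_model <- function(trials, terms = c("size", "polarity",
                                                 "speed:size:polarity")) {
  if (!"responded" %in% names(trials)) {
    if (all(c("n_trials", "n_responses") %in% names(trials))) {
      idx <- rep(seq_len(nrow(trials)), trials$n_trials)
      resp <- unlist(lapply(seq_len(nrow(trials)), function(i) {
        c(rep(1L, trials$n_responses[i]),
          rep(0L, trials$n_trials[i] - trials$n_responses[i]))
      }))
      trials <- cbind(trials[idx, FEATURE_BITS], responded = resp)
    } else stopf("`trials` must contain a `responded` column")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(term_columns(trials, terms)))
  fit <- suppressWarnings(
    stats::glm.fit(X, trials$responded, family = stats::binomial()))
  beta <- fit$coefficients
  separation <- !fit$converged || any(abs(beta) > 15)
  if (separation) {
    warning("possible separation or non-convergence; coefficients unreliable")
  }
  # Wald standard errors from the Fisher information at the MLE
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  structure(list(coefficients = beta, se = se, ci = ci,
                 odds_ratio = exp(beta), terms = terms, n = nrow(trials),
                 deviance = fit$deviance, separation = separation,
                 cv_r2 = NA_real_),
            class = "hunt_logit")
}

#' @export
coef.hunt_logit <- function(object, ...) object$coefficients

#' @export
print.hunt_logit <- function(x, ...) {
  cat("Hunting-response logistic model\n")
  cat("  logit(R) ~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1", "\n")
  if (is.null(x$se)) {
    print(round(x$coefficients, 3))
  } else {
    tab <- data.frame(coef = x$coefficients, se = x$se,
                      ci_lo = x$ci[, 1], ci_hi = x$ci[, 2],
                      odds_ratio = x$odds_ratio)
    print(round(tab, 3))
  }
  if (!is.na(x$cv_r2)) cat(sprintf("  cross-validated R^2 (rates): %.3f\n", x$cv_r2))
  if (x$separation) cat("  WARNING: possible separation\n")
  invisible(x)
}

#' @export
summary.hunt_logit <- function(object, ...) {
  z <- object$coefficients / object$se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(coef = object$coefficients, se = object$se, z = z,
                    p_value = p, odds_ratio = object$odds_ratio)
  out
}

#' Predicted hunting-response probability
#'
#' Inverse-logit of the model's linear predictor for one or more stimulus
#' feature codes.
#'
#' @param model A `hunt_logit`, or a named coefficient vector whose names are
#'   `(Intercept)` plus product terms.
#' @param feature_code Length-4 numeric vector
#'   `(direction, speed, size, polarity)` or a data frame of bit columns.
#' @return Numeric vector of probabilities.
#' @export
predict_response_rate <- function(model, feature_code) {
  beta <- if (inherits(model, "hunt_logit")) model$coefficients else model
  if (is.numeric(feature_code) && is.null(dim(feature_code))) {
    feature_code <- as.data.frame(as.list(stats::setNames(feature_code,
                                                          FEATURE_BITS)))
  }
  terms <- setdiff(names(beta), "(Intercept)")
  eta <- rep(beta[["(Intercept)"]], nrow(feature_code))
  if (length(terms)) {
    tc <- term_columns(feature_code, terms)
    eta <- eta + as.matrix(tc) %*% beta[terms]
  }
  as.numeric(stats::plogis(eta))
}

#' @export
predict.hunt_logit <- function(object, newdata, ...) {
  predict_response_rate(object, newdata)
}

#' Cross-validated R-squared on per-stimulus response rates
#'
#' Splits trials into random halves, fits the model on the training half, and
#' scores the squared correlation-free R^2 (1 - SS_res/SS_tot) between the
#' model-predicted and observed per-stimulus response rates on the held-out
#' half, averaged over `n_splits` seeded halvings.
#'
#' @param trials Trial data frame (bits + `responded`).
#' @param terms Model terms.
#' @param n_splits Number of random halvings.
#' @param seed Integer seed.
#' @return Mean cross-validated R^2.
#' @export
cv_r2_rates <- function(trials, terms, n_splits = 10, seed = NULL) {
  if (n_splits < 1) stopf("n_splits must be >= 1")
  st <- stimulus_table()[1:16, FEATURE_BITS]
  code_of <- function(d) d$direction * 8 + d$speed * 4 + d$size * 2 + d$polarity
  trial_code <- code_of(trials)
  with_seed(seed, {
    r2 <- vapply(seq_len(n_splits), function(s) {
      train <- sample(c(TRUE, FALSE), nrow(trials), replace = TRUE)
      fit <- tryCatch(fit_logistic_model(trials[train, ], terms),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      test <- trials[!train, ]
      obs <- tapply(test$responded, factor(trial_code[!train], levels = 0:15),
                    mean)
      pred <- predict_response_rate(fit, st)
      ok <- !is.na(obs)
      1 - sum((obs[ok] - pred[ok])^2) / sum((obs[ok] - mean(obs[ok]))^2)
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  })
}

#' Stepwise selection of the behavioural model
#'
#' Bidirectional stepwise search over product terms of the four stimulus
#' features (main effects and all interactions up to fourth order), scored by
#' BIC on the per-trial binomial likelihood; BIC's consistency lets the
#' search drop redundant interaction terms once main effects enter. The
#' winning model is refit on all trials and annotated with its
#' cross-validated R^2 on per-stimulus rates (see [cv_r2_rates()]).
#'
#' @param trials Trial data frame (bits + `responded`).
#' @param candidates Candidate term set (default [candidate_terms()]).
#' @param n_splits Halvings for the cross-validated R^2 of the winner.
#' @param seed Integer seed for the cross-validation splits.
#' @return A `hunt_logit` for the selected model (possibly intercept-only),
#'   with `cv_r2` filled in.
#' @export
stepwise_select <- function(trials, candidates = candidate_terms(),
                            n_splits = 10, seed = NULL) {
  if (n_splits < 1) stopf("n_splits must be >= 1")
  n <- nrow(trials)
  # aggregate per stimulus cell: identical binomial likelihood (up to a
  # model-independent constant), so BIC comparisons are exact but fits are
  # on at most 16 rows
  code <- trials$direction * 8 + trials$speed * 4 + trials$size * 2 +
    trials$polarity
  agg_n <- as.numeric(table(factor(code, levels = 0:15)))
  agg_k <- as.numeric(tapply(trials$responded, factor(code, levels = 0:15),
                             sum, default = 0))
  keep <- agg_n > 0
  st16 <- stimulus_table()[1:16, FEATURE_BITS][keep, ]
  agg_n <- agg_n[keep]; agg_k <- agg_k[keep]
  bic_of <- function(terms) {
    X <- cbind(rep(1, nrow(st16)),
               if (length(terms)) as.matrix(term_columns(st16, terms)))
    fit <- suppressWarnings(stats::glm.fit(X, agg_k / agg_n, weights = agg_n,
                                           family = stats::binomial()))
    fit$deviance + log(n) * ncol(X)
  }
  current <- character(0)
  best <- bic_of(current)
  repeat {
    moves <- c(lapply(setdiff(candidates, current), function(tm) c(current, tm)),
               lapply(current, function(tm) setdiff(current, tm)))
    if (!length(moves)) break
    scores <- vapply(moves, bic_of, numeric(1))
    if (min(scores) < best - 1e-8) {
      best <- min(scores)
      current <- moves[[which.min(scores)]]
    } else break
  }
  model <- if (length(current)) fit_logistic_model(trials, current) else {
    m <- fit_logistic_model(trials, "size")  # placeholder to reuse machinery
    m$coefficients <- c(`(Intercept)` =
                          stats::qlogis(max(mean(trials$responded), 1e-12)))
    m$se <- m$ci <- m$odds_ratio <- NULL
    m$terms <- character(0)
    m
  }
  model$cv_r2 <- if (length(current)) {
    cv_r2_rates(trials, current, n_splits, seed)
  } else 0
  model
}
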