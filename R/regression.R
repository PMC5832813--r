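#' Ordinary least-squares fit with a tidy result
#'
#' Fits `formula` by OLS and collects everything one column of a
#' regression summary table needs: per-term estimates with t-based 95%
#' CIs and p-values, n, R2 and adjusted R2, the overall F statistic, and
#' AIC under the Gaussian log-likelihood convention
#' `-2 logLik + 2 (p + 1)` (the residual variance counts as a
#' parameter, as in [stats::AIC()]).
#'
#' @param data data.frame holding the response and predictors.
#' @param formula model formula; the intercept is always included.
#' @return an object of class `bturb_fit`: list with elements
#'   `coefficients` (data.frame term/estimate/ci_low/ci_high/p_value),
#'   `n`, `r_squared`, `adj_r_squared`, `f_statistic`, `aic`,
#'   `residuals`, `fitted`, `sigma`, `formula` and the underlying `lm`.
#' @examples
#' fit_linear_model(flume_treatments(), Rtot_g_m2 ~ Itot_mW_m2)
#' @export
fit_linear_model <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X)
  p <- ncol(X)
  if (!all(is.finite(X))) {
    stop("fit_linear_model: non-finite predictor values", call. = FALSE)
  }
  if (n < p + 1) {
    stop("fit_linear_model: need at least ", p + 1, " observations for ",
      p, " coefficient(s)",
      call. = FALSE
    )
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("fit_linear_model: design is rank deficient; collinear term(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    p_value = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  fstat <- if (is.null(sm$fstatistic)) NA_real_ else unname(sm$fstatistic["value"])
  r2 <- sm$r.squared
  adj_r2 <- sm$adj.r.squared
  if (stats::var(stats::model.response(mf)) == 0) {
    # degenerate constant response: no variance to explain
    r2 <- 0
    adj_r2 <- 0
  }
  structure(
    list(
      formula = formula,
      coefficients = coefs,
      n = n,
      r_squared = r2,
      adj_r_squared = adj_r2,
      f_statistic = fstat,
      aic = stats::AIC(fit),
      sigma = sm$sigma,
      residuals = stats::residuals(fit),
      fitted = stats::fitted(fit),
      lm = fit
    ),
    class = "bturb_fit"
  )
}

#' @export
print.bturb_fit <- function(x, digits = 4, ...) {
  cat("OLS fit:", deparse(x$formula), "\n")
  co <- x$coefficients
  co[, -1] <- signif(co[, -1], digits)
  print(co, row.names = FALSE)
  cat(
    "n =", x$n,
    " R2 =", signif(x$r_squared, digits),
    " adj R2 =", signif(x$adj_r_squared, digits),
    " F =", signif(x$f_statistic, digits),
    " AIC =", signif(x$aic, 6), "\n"
  )
  invisible(x)
}

#' Bidirectional AIC stepwise model selection
#'
#' Starts from the full model and alternates drop/add moves, each step
#' taking the single move that most lowers AIC, until no move improves
#' it. The candidate scope is the lattice of models nested in the full
#' formula; marginality is respected (an interaction is dropped before
#' its main effects). Deterministic: ties go to the first candidate in
#' scope order.
#'
#' @param data data.frame.
#' @param formula the full model formula defining the scope.
#' @return an object of class `stepwise_trace`: `steps` (data.frame of
#'   the accepted path: step, action, formula, AIC), `visited` (every
#'   candidate model evaluated, with AIC), `selected` (formula) and
#'   `fit` (the selected model as a [fit_linear_model()] result).
#' @examples
#' stepwise_select(flume_treatments(), Rtot_g_m2 ~ functional_group * Itot_mW_m2)
#' @export
stepwise_select <- function(data, formula) {
  current <- formula
  cur_fit <- fit_linear_model(data, current)
  steps <- data.frame(
    step = 0L, action = "start",
    formula = deparse(current), aic = cur_fit$aic,
    stringsAsFactors = FALSE
  )
  visited <- data.frame(
    formula = deparse(current), aic = cur_fit$aic,
    stringsAsFactors = FALSE
  )
  repeat {
    drops <- stats::drop.scope(current)
    adds <- stats::add.scope(current, formula)
    cands <- c(
      lapply(drops, function(tm) list(action = paste("-", tm), term = tm, dir = "drop")),
      lapply(adds, function(tm) list(action = paste("+", tm), term = tm, dir = "add"))
    )
    if (!length(cands)) break
    cand_aic <- rep(NA_real_, length(cands))
    cand_formula <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      op <- if (cands[[i]]$dir == "drop") "-" else "+"
      f <- stats::update.formula(
        current,
        stats::as.formula(paste(". ~ .", op, cands[[i]]$term))
      )
      environment(f) <- environment(formula)
      cand_formula[[i]] <- f
      cand_aic[i] <- fit_linear_model(data, f)$aic
      visited <- rbind(visited, data.frame(
        formula = deparse(f), aic = cand_aic[i], stringsAsFactors = FALSE
      ))
    }
    best <- which.min(cand_aic)
    if (cand_aic[best] >= cur_fit$aic) break
    current <- cand_formula[[best]]
    cur_fit <- fit_linear_model(data, current)
    steps <- rbind(steps, data.frame(
      step = nrow(steps), action = cands[[best]]$action,
      formula = deparse(current), aic = cur_fit$aic,
      stringsAsFactors = FALSE
    ))
  }
  visited <- visited[!duplicated(visited$formula), , drop = FALSE]
  rownames(visited) <- NULL
  structure(
    list(steps = steps, visited = visited, selected = current, fit = cur_fit),
    class = "stepwise_trace"
  )
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("Bidirectional AIC stepwise selection\n")
  st <- x$steps
  st$aic <- round(st$aic, 3)
  print(st, row.names = FALSE)
  cat("selected:", deparse(x$selected), "\n")
  invisible(x)
}

#' Spearman rank correlation with a large-sample p-value
#'
#' Rank-based correlation using average ranks for ties; the p-value uses
#' the standard large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, at least 3, neither
#'   constant.
#' @return list with `rho`, `p_value` and `n`.
#' @examples
#' spearman_correlation(c(1, 2, 3), c(3, 1, 2))
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("spearman_correlation: need equal-length vectors of length >= 3",
      call. = FALSE
    )
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman_correlation: correlation is undefined for a constant vector",
      call. = FALSE
    )
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Correlations of resuspension with metabolism and density
#'
#' Rank (Spearman) and product-moment (Pearson) correlations of the
#' observed resuspension `Rtot_g_m2` with population metabolic rate
#' `Itot_mW_m2` and with density `density_ind_m2`. Both flavours are
#' reported because on strongly skewed predictors they can differ
#' materially; see the methods vignette.
#'
#' @param table treatment table (standard schema).
#' @return data.frame with columns predictor, method, estimate, p_value.
#' @export
correlation_report <- function(table) {
  preds <- c(metabolism = "Itot_mW_m2", density = "density_ind_m2")
  out <- do.call(rbind, lapply(names(preds), function(nm) {
    x <- table[[preds[[nm]]]]
    y <- table$Rtot_g_m2
    sp <- spearman_correlation(x, y)
    pe <- stats::cor.test(x, y)
    data.frame(
      predictor = nm,
      method = c("spearman", "pearson"),
      estimate = c(sp$rho, unname(pe$estimate)),
      p_value = c(sp$p_value, pe$p.value),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Refit after excluding the highest-leverage treatments
#'
#' Sensitivity check: drops the `k` treatments with the largest
#' population metabolic rate and refits the simple model
#' `Rtot_g_m2 ~ Itot_mW_m2`. All rows tied with the k-th largest value
#' are excluded, and the effective number of exclusions is reported.
#'
#' @param table treatment table.
#' @param k number of highest-`Itot` rows to drop; must satisfy
#'   `k < n - 2`.
#' @return list with `fit` (a `bturb_fit`), `excluded` (row indices),
#'   and `effective_k`.
#' @export
leverage_exclusion_refit <- function(table, k) {
  n <- nrow(table)
  if (k < 0 || k >= n - 2) {
    stop("leverage_exclusion_refit: need 0 <= k < n - 2", call. = FALSE)
  }
  if (k == 0) {
    fit <- fit_linear_model(table, Rtot_g_m2 ~ Itot_mW_m2)
    return(list(fit = fit, excluded = integer(0), effective_k = 0L))
  }
  cutoff <- sort(table$Itot_mW_m2, decreasing = TRUE)[k]
  excluded <- which(table$Itot_mW_m2 >= cutoff)
  fit <- fit_linear_model(table[-excluded, , drop = FALSE], Rtot_g_m2 ~ Itot_mW_m2)
  list(fit = fit, excluded = excluded, effective_k = length(excluded))
}

#' Models of the per-milliwatt biotic effect
#'
#' Tests whether the sediment resuspended per unit of population
#' metabolic power depends on density or individual size (body mass, mg
#' AFDW): bidirectional AIC stepwise selection starting from
#' `R_BIO ~ density * mass`, down to the intercept-only model whose
#' estimate is the mean `R_BIO`.
#'
#' @param table treatment table with an `R_BIO` column (see
#'   [assemble_treatment_table()]).
#' @return list with `trace` (a `stepwise_trace`), `fit` (selected
#'   model) and `mean_rbio`.
#' @export
rbio_models <- function(table) {
  if (is.null(table$R_BIO)) {
    stop("rbio_models: table has no R_BIO column; run assemble_treatment_table()",
      call. = FALSE
    )
  }
  trace <- stepwise_select(table, R_BIO ~ density_ind_m2 * mass_mg_afdw)
  list(trace = trace, fit = trace$fit, mean_rbio = mean(table$R_BIO))
}
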