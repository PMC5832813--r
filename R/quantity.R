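#' Quantity with a 95% confidence half-width
#'
#' The currency of the measurement-conversion chain: a numeric value
#' together with the half-width of its symmetric 95% confidence interval
#' (same units). Half-widths are treated as 1.96 standard deviations when
#' propagated, and inputs to a propagation step are assumed independent.
#'
#' @param value numeric vector of values (finite).
#' @param ci95 numeric vector of non-negative 95% CI half-widths, recycled
#'   against `value`.
#' @return an object of class `qci`.
#' @examples
#' qci(32.25, 1.73)
#' @export
qci <- function(value, ci95 = 0) {
  value <- as.numeric(value)
  ci95 <- as.numeric(ci95)
  if (!all(is.finite(value))) stop("qci: 'value' must be finite", call. = FALSE)
  if (any(is.na(ci95)) || any(ci95 < 0)) {
    stop("qci: 'ci95' must be non-negative", call. = FALSE)
  }
  n <- max(length(value), length(ci95))
  structure(
    list(value = rep_len(value, n), ci95 = rep_len(ci95, n)),
    class = "qci"
  )
}

#' @export
print.qci <- function(x, digits = 4, ...) {
  cat(
    paste0(
      signif(x$value, digits), " ± ", signif(x$ci95, digits),
      collapse = ", "
    ),
    "(95% CI half-width)\n"
  )
  invisible(x)
}

#' @export
length.qci <- function(x) length(x$value)

is_qci <- function(x) inherits(x, "qci")

#' Run code with a local, restorable random seed
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' First-order (delta-method) error propagation
#'
#' Propagates 95% CI half-widths through a differentiable scalar map
#' using the first-order approximation
#' `ci_out = sqrt(sum((df/dx_i * ci_i)^2))`. Half-widths scale like
#' standard deviations, so no rescaling by 1.96 is needed. Derivatives
#' are evaluated numerically by central differences; inputs are treated
#' as independent. `f` must be vectorized elementwise when the inputs
#' hold more than one element.
#'
#' @param f a function of as many numeric arguments as there are inputs.
#' @param ... one or more [qci] inputs (equal length or length one).
#' @param step optional finite-difference step; defaults to
#'   `max(|x|, 1) * eps^(1/3)` per element.
#' @return a [qci] with `f(values)` and the propagated half-width.
#' @examples
#' propagate_delta(function(x, y) x * y, qci(2, 0.2), qci(3, 0.3))
#' @seealso [propagate_monte_carlo()] for the simulation-based audit.
#' @export
propagate_delta <- function(f, ..., step = NULL) {
  inputs <- list(...)
  if (!length(inputs) || !all(vapply(inputs, is_qci, logical(1)))) {
    stop("propagate_delta: all inputs must be 'qci' objects", call. = FALSE)
  }
  n <- max(vapply(inputs, length, integer(1)))
  vals <- lapply(inputs, function(q) rep_len(q$value, n))
  cis <- lapply(inputs, function(q) rep_len(q$ci95, n))
  value <- do.call(f, vals)
  if (!all(is.finite(value))) {
    stop("propagate_delta: f is not finite at the input values", call. = FALSE)
  }
  var_out <- rep(0, n)
  for (i in seq_along(inputs)) {
    x <- vals[[i]]
    # relative step keeps x - h inside the domain of positive-argument maps
    h <- if (is.null(step)) {
      pmax(abs(x), 1.5e-8) * .Machine$double.eps^(1 / 3)
    } else {
      step
    }
    up <- vals
    dn <- vals
    up[[i]] <- x + h
    dn[[i]] <- x - h
    g <- (do.call(f, up) - do.call(f, dn)) / (2 * h)
    if (!all(is.finite(g))) {
      stop("propagate_delta: non-finite derivative at the evaluation point",
        call. = FALSE
      )
    }
    var_out <- var_out + (g * cis[[i]])^2
  }
  qci(value, sqrt(var_out))
}

#' Monte Carlo error propagation
#'
#' Simulation-based audit of [propagate_delta()]: each input is drawn as
#' an independent Gaussian with mean `value` and standard deviation
#' `ci95 / 1.96`; the result is the mean of `f` over the draws with a
#' half-width of 1.96 times its standard deviation. Deterministic for a
#' fixed seed; the global random-number state is left untouched.
#'
#' @inheritParams propagate_delta
#' @param n_draws number of draws, at least 1000.
#' @param seed integer seed (mandatory).
#' @return a [qci].
#' @examples
#' propagate_monte_carlo(function(x, y) x * y,
#'   qci(2, 0.2), qci(3, 0.3),
#'   n_draws = 5000, seed = 1
#' )
#' @export
propagate_monte_carlo <- function(f, ..., n_draws = 10000, seed) {
  inputs <- list(...)
  if (!length(inputs) || !all(vapply(inputs, is_qci, logical(1)))) {
    stop("propagate_monte_carlo: all inputs must be 'qci' objects", call. = FALSE)
  }
  if (n_draws < 1000) {
    stop("propagate_monte_carlo: n_draws must be at least 1000", call. = FALSE)
  }
  n <- max(vapply(inputs, length, integer(1)))
  vals <- lapply(inputs, function(q) rep_len(q$value, n))
  cis <- lapply(inputs, function(q) rep_len(q$ci95, n))
  with_seed(seed, {
    value <- numeric(n)
    ci <- numeric(n)
    for (j in seq_len(n)) {
      draws <- lapply(seq_along(inputs), function(i) {
        stats::rnorm(n_draws, mean = vals[[i]][j], sd = cis[[i]][j] / 1.96)
      })
      out <- do.call(f, draws)
      value[j] <- mean(out)
      ci[j] <- 1.96 * stats::sd(out)
    }
    qci(value, ci)
  })
}
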