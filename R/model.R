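# Core predictions of the dual-memory model: recall in the test condition
# arises through two retrieval routes (study memory and test memory).  Under
# route independence the probability of recall is the inclusive-or of the two
# route probabilities; with identically distributed strengths both routes
# share the restudy recall probability, giving PC_T = 2*PC_R - PC_R^2.  The
# correlated-strengths extension replaces independence with a bivariate
# standard-normal strength pair with correlation rho (a Gaussian copula with
# identical marginals), which nests the independent model at rho = 0 and
# collapses to a single route at rho = 1.

#' Validate a probability argument
#'
#' @param p numeric vector.
#' @param arg name used in error messages.
#' @return `p`, invisibly checked.
#' @noRd
check_prob <- function(p, arg = deparse(substitute(p))) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p)) {
    stop(sprintf("'%s' must be a non-empty numeric vector without NA", arg),
         call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]; got value(s) outside range", arg),
         call. = FALSE)
  }
  invisible(p)
}

#' Validate a strength-correlation argument
#'
#' Only non-negative correlations are in the model space: the extension is
#' motivated by shared semantic features, which can only align the two
#' routes' strengths.
#'
#' @param rho scalar in \[0, 1\].
#' @noRd
check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho > 1) {
    stop("'rho' must be a single number in [0, 1]", call. = FALSE)
  }
  invisible(rho)
}

# Gauss-Legendre nodes on [-1, 1], computed once per process and rescaled to
# the integration interval at call time.
.gl_cache <- new.env(parent = emptyenv())

gl_unit_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .gl_cache[[key]]
}

#' Inclusive-or recall probability for two independent retrieval routes
#'
#' Probability that retrieval succeeds through at least one of two
#' stochastically independent routes with success probabilities `p_s`
#' (study memory) and `p_t` (test memory).
#'
#' @param p_s,p_t probabilities of correct retrieval through each route;
#'   vectors are recycled to a common length.
#' @return `p_s + p_t - p_s * p_t`.
#' @examples
#' inclusive_or(0.5, 0.5)  # 0.75
#' @export
inclusive_or <- function(p_s, p_t) {
  check_prob(p_s)
  check_prob(p_t)
  p_s + p_t - p_s * p_t
}

#' Predicted test-condition performance under route independence
#'
#' The parameter-free prediction of final-test proportion correct in the
#' test condition from restudy proportion correct: with both routes equal
#' in strength to the restudy route and independent,
#' `PC_T = 2 * PC_R - PC_R^2`.
#'
#' @param pc_r restudy proportion correct (vectorised).
#' @return predicted test-condition proportion correct.
#' @seealso [predict_te()], [pt_correlated()]
#' @examples
#' predict_pt(0.3)  # 0.51
#' @export
predict_pt <- function(pc_r) {
  check_prob(pc_r)
  2 * pc_r - pc_r^2
}

#' Predicted testing-effect magnitude under route independence
#'
#' The predicted advantage of the test condition over restudy,
#' `TE = PC_R - PC_R^2`.  The prediction is quadratic in `PC_R`: it is 0 at
#' the floor and ceiling and maximal (0.25) at `PC_R = 0.5`, so equal
#' testing efficacy does not imply equal TE magnitudes across conditions
#' that differ in restudy performance.
#'
#' @inheritParams predict_pt
#' @return predicted testing effect, in \[0, 0.25\].
#' @examples
#' predict_te(0.3)  # 0.21
#' predict_te(0.7)  # 0.21
#' @export
predict_te <- function(pc_r) {
  check_prob(pc_r)
  pc_r - pc_r^2
}

#' Test-condition performance under correlated memory strengths
#'
#' One-parameter extension of the independent-routes prediction: study and
#' test memory strengths for an item are standard bivariate normal with
#' correlation `rho`, and retrieval succeeds if either strength exceeds the
#' threshold `z = qnorm(1 - pc_r)` that individually yields recall
#' probability `pc_r`.  The returned value is
#' `1 - P(S <= z, T <= z; rho) = 2*pc_r - P(S > z, T > z; rho)`.
#'
#' `rho = 0` reproduces [predict_pt()] exactly; `rho = 1` collapses the two
#' routes into one, returning `pc_r`; the prediction decreases continuously
#' in `rho` between those limits.
#'
#' The upper-orthant probability is evaluated through Plackett's identity,
#' reducing it to a one-dimensional integral over the correlation
#' \deqn{P(S > z, T > z; \rho) = \bar\Phi(z)^2 +
#'   \frac{1}{2\pi}\int_0^{\arcsin\rho} e^{-z^2/(1+\sin\theta)}\,d\theta,}
#' which is smooth on the whole rho range and is integrated by fixed
#' Gauss-Legendre quadrature (converged well below 1e-8 at the default
#' node count).
#'
#' @inheritParams predict_pt
#' @param rho correlation between study and test memory strengths, in
#'   \[0, 1\].
#' @param nodes number of quadrature nodes.
#' @return predicted test-condition proportion correct (vectorised over
#'   `pc_r`).
#' @examples
#' pt_correlated(0.47, 0)      # 0.7191, the independence limit
#' pt_correlated(0.47, 0.334)  # 0.6652, shrunk toward pc_r
#' @export
pt_correlated <- function(pc_r, rho, nodes = 32L) {
  check_prob(pc_r)
  check_rho(rho)
  if (rho == 0) return(predict_pt(pc_r))
  if (rho == 1) return(pc_r)
  out <- pc_r  # boundary cases 0 and 1 are exact fixed points
  inner <- pc_r > 0 & pc_r < 1
  if (any(inner)) {
    p <- pc_r[inner]
    z <- stats::qnorm(1 - p)
    gl <- gl_unit_nodes(nodes)
    half <- asin(rho) / 2
    theta <- half * (gl$x + 1)
    w <- gl$w * half
    # len(p) x nodes matrix of exp(-z^2 / (1 + sin theta))
    m <- exp(-outer(z^2, 1 + sin(theta), "/"))
    upper <- p^2 + as.vector(m %*% w) / (2 * pi)
    out[inner] <- 2 * p - upper
  }
  out
}

#' Testing effect under correlated memory strengths
#'
#' @inheritParams pt_correlated
#' @return `pt_correlated(pc_r, rho) - pc_r`.
#' @export
te_correlated <- function(pc_r, rho, nodes = 32L) {
  pt_correlated(pc_r, rho, nodes) - pc_r
}

#' Monte-Carlo estimate of the correlated-strengths prediction
#'
#' Simulates `n_draws` bivariate standard-normal strength pairs with
#' correlation `rho` and scores recall as either component exceeding
#' `qnorm(1 - pc_r)`.  Provided for validation of [pt_correlated()] and for
#' direct simulation of the extended model; the closed-form route is used
#' everywhere performance matters.
#'
#' @param pc_r restudy proportion correct (a single probability).
#' @param rho correlation between the two strengths, in \[0, 1\].
#' @param n_draws number of simulated items.
#' @param seed optional integer; when supplied the caller's RNG state is
#'   left untouched.
#' @return the simulated proportion recalled.
#' @export
pt_correlated_mc <- function(pc_r, rho, n_draws = 1e6, seed = NULL) {
  if (length(pc_r) != 1L) stop("'pc_r' must be a single probability",
                               call. = FALSE)
  check_prob(pc_r)
  check_rho(rho)
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1) {
    stop("'n_draws' must be a positive integer", call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  if (pc_r == 0) return(0)
  if (pc_r == 1) return(1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  z <- stats::qnorm(1 - pc_r)
  s <- stats::rnorm(n_draws)
  t <- rho * s + sqrt(1 - rho^2) * stats::rnorm(n_draws)
  mean(s > z | t > z)
}

# RNG bookkeeping: seeds are always explicit arguments, never global state
# mutated behind the caller's back.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
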