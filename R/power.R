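#' Specification for repeated-measures interaction power analysis
#'
#' Bundles the parameters of an a-priori power computation for the
#' within-between interaction of a mixed-design (split-plot) ANOVA:
#' `g` independent groups each measured on `m` repeated levels.
#'
#' @param f Cohen's effect size f (0.10/0.25/0.40 are the conventional
#'   small/medium/large benchmarks).
#' @param alpha Type-I error rate.
#' @param target_power Desired power (1 - beta).
#' @param g Number of between-subject groups.
#' @param m Number of repeated measures.
#' @param rho Assumed population correlation among the repeated measures.
#' @param epsilon Non-sphericity correction (Greenhouse-Geisser style), in
#'   `[1/(m-1), 1]`.
#' @return A `power_spec` list.
#' @export
#' @examples
#' power_spec() # the default is the validation study's preregistered spec
power_spec <- function(f = 0.25, alpha = 0.01, target_power = 0.90,
                       g = 10, m = 5, rho = 0.5, epsilon = 1) {
  stopifnot(f >= 0, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1,
            g >= 2, m >= 2, rho >= 0, rho < 1,
            epsilon >= 1 / (m - 1), epsilon <= 1)
  structure(list(f = f, alpha = alpha, target_power = target_power,
                 g = g, m = m, rho = rho, epsilon = epsilon),
            class = "power_spec")
}

#' Power of the within-between interaction F test
#'
#' Noncentral-F power for the group-by-measure interaction of a
#' mixed-design repeated-measures ANOVA at total sample size `N`:
#' numerator df `(g-1)(m-1)·epsilon`, denominator df `(N-g)(m-1)·epsilon`,
#' and noncentrality `lambda = f^2 · N · m · epsilon / (1 - rho)` under
#' the G*Power convention in which f is defined on the raw effect scale
#' and the repeated-measures multiplier `m·epsilon/(1-rho)` is applied
#' internally. Under the `"spss"` convention f is assumed to already
#' absorb that multiplier, so `lambda = f^2 · N`.
#'
#' @param spec A [power_spec()].
#' @param N Total sample size across all groups (> g).
#' @param convention `"gpower3"` (default) or `"spss"`.
#' @return Achieved power, a probability.
#' @export
#' @examples
#' interaction_power(power_spec(), N = 80)
interaction_power <- function(spec, N, convention = c("gpower3", "spss")) {
  convention <- match.arg(convention)
  stopifnot(inherits(spec, "power_spec"))
  if (N <= spec$g) {
    stop("N (", N, ") must exceed the number of groups (", spec$g,
         ") to leave error degrees of freedom.", call. = FALSE)
  }
  df1 <- (spec$g - 1) * (spec$m - 1) * spec$epsilon
  df2 <- (N - spec$g) * (spec$m - 1) * spec$epsilon
  lambda <- switch(
    convention,
    gpower3 = spec$f^2 * N * spec$m * spec$epsilon / (1 - spec$rho),
    spss = spec$f^2 * N
  )
  pf(qf(1 - spec$alpha, df1, df2), df1, df2, ncp = lambda,
     lower.tail = FALSE)
}

#' Minimal sample size for the interaction test
#'
#' Searches upward over total sample sizes divisible by `granularity`
#' (by default whole groups, so per-group sizes stay equal) for the
#' smallest `N` whose interaction power reaches the target.
#'
#' @param spec A [power_spec()].
#' @param granularity Step and divisibility constraint for `N`; defaults
#'   to the number of groups.
#' @param convention Passed to [interaction_power()].
#' @return A list with `N`, `per_group` and `power` (the achieved power
#'   at `N`).
#' @export
#' @examples
#' minimal_sample_size(power_spec()) # N = 80, 8 per group
minimal_sample_size <- function(spec, granularity = spec$g,
                                convention = c("gpower3", "spss")) {
  convention <- match.arg(convention)
  stopifnot(inherits(spec, "power_spec"), granularity >= 1)
  n <- granularity * ceiling((spec$g + 1) / granularity)
  repeat {
    pw <- interaction_power(spec, n, convention)
    if (pw >= spec$target_power) break
    n <- n + granularity
    if (n > 1e7) stop("Sample-size search did not converge.", call. = FALSE)
  }
  list(N = n, per_group = n / spec$g, power = pw)
}
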