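#' Cumulative probability of detecting a rare taxon in a clone library
#'
#' In a clone library of `n` independently sampled clones, a non-target taxon
#' present at per-capsule incidence `q` appears at least once with cumulative
#' probability `P = 1 - (1 - q)^n`. This assumes equal incidence of the
#' non-target taxon among all samples and no amplification bias during PCR,
#' so clones are i.i.d. Bernoulli draws. Computed via
#' `-expm1(n * log1p(-q))`, which is stable for small `q` and large `n`
#' where the naive power form underflows.
#'
#' @param q Incidence (proportion) of the non-target taxon, in \[0, 1\].
#' @param n Number of sequenced clones, positive integer. Vectorised over
#'   both arguments.
#' @return Detection probability in \[0, 1\]; monotone non-decreasing in both
#'   arguments.
#' @seealso [max_incidence()] for the inversion in `q`, [required_clones()]
#'   for the inversion in `n`, [mc_detection_probability()] for a Monte Carlo
#'   check.
#' @examples
#' detection_probability(q = 0.036, n = 126)
#' @export
detection_probability <- function(q, n) {
  check_q(q)
  check_n(n)
  -expm1(n * log1p(-q))
}

#' Maximum incidence compatible with detection at a given probability
#'
#' Inverts the detection model in `q`: the largest incidence a non-target
#' taxon can have and still be missed in `n` clones with probability at least
#' `1 - P`; equivalently `q = 1 - (1 - P)^(1/n)`. With zero non-target
#' detections among `n` clones, incidences above this value are excluded at
#' cumulative probability `P`.
#'
#' @param P Cumulative detection probability threshold, in (0, 1).
#' @param n Number of sequenced clones, positive integer. Vectorised.
#' @return Incidence in (0, 1); strictly decreasing in `n`. The round trip
#'   `detection_probability(max_incidence(P, n), n)` recovers `P` to 1e-12.
#' @examples
#' max_incidence(P = 0.99, n = 126)  # combined survey bound
#' @export
max_incidence <- function(P, n) {
  check_P(P)
  check_n(n)
  -expm1(log1p(-P) / n)
}

#' Smallest clone library size achieving a detection probability
#'
#' The smallest integer `n` with `1 - (1 - q)^n >= P`, i.e.
#' `ceiling(log(1 - P) / log(1 - q))`.
#'
#' @param P Target cumulative detection probability, in (0, 1).
#' @param q Incidence of the non-target taxon, in (0, 1\]. `q = 0` is an
#'   error (the target is unreachable); `q = 1` returns 1.
#' @return Positive integer `n` with
#'   `detection_probability(q, n - 1) < P <= detection_probability(q, n)`.
#' @examples
#' required_clones(P = 0.99, q = 0.01)
#' @export
required_clones <- function(P, q) {
  check_P(P)
  if (any(q <= 0 | q > 1)) {
    abort("q must be in (0, 1]: a zero-incidence taxon can never be detected")
  }
  out <- ifelse(q == 1, 1, ceiling(log1p(-P) / log1p(-q)))
  # settle knife-edge cases against the model definition itself (the plain
  # power form, exact at these magnitudes), so n is the true smallest integer
  for (k in seq_along(out)) {
    qk <- if (length(q) > 1) q[k] else q
    Pk <- if (length(P) > 1) P[k] else P
    if (qk == 1) next
    while (out[k] > 1 && 1 - (1 - qk)^(out[k] - 1) >= Pk) out[k] <- out[k] - 1
    while (1 - (1 - qk)^out[k] < Pk) out[k] <- out[k] + 1
  }
  as.integer(out)
}

#' Expected number of clones sequenced until first detection
#'
#' The waiting time to the first non-target clone is geometric with success
#' probability `q`, so its expectation is `1/q`: at incidence 1%, one hundred
#' clones on average must be sequenced to observe the taxon once.
#'
#' @param q Incidence in (0, 1\].
#' @return Expected clone count `1/q`.
#' @examples
#' expected_clones_to_detection(0.01)
#' @export
expected_clones_to_detection <- function(q) {
  if (any(q <= 0 | q > 1)) abort("q must be in (0, 1]")
  1 / q
}

#' Per-host and pooled maximum-incidence table
#'
#' For each host the maximum non-target incidence compatible with zero
#' detections among that host's `n` clones at cumulative probability `P`
#' ([max_incidence()]), plus a pooled row using `n_total = sum(n)`. Pooling
#' assumes equal incidence of non-target taxa among all samples and no
#' amplification bias, so clones pool as i.i.d. draws. Rounded values use
#' round-half-away-from-zero at `digits` decimals; full-precision values are
#' always carried alongside.
#'
#' @param per_host_n Named numeric vector (names are hosts) or a data frame
#'   with columns `host` and `n` of per-host clone counts.
#' @param P Cumulative detection probability threshold, in (0, 1).
#' @param digits Decimals for the rounded display column.
#' @param pooled_label Label of the pooled row.
#' @return A tibble of class `incidence_table` with columns `host`, `n`,
#'   `q_max` (full precision) and `q_max_rounded`; the last row is the pooled
#'   row. Attributes `P` and `digits` record the settings.
#' @examples
#' incidence_table(c("A. gracile" = 27, "L. aurora" = 5), P = 0.99)
#' @export
incidence_table <- function(per_host_n, P = 0.99, digits = 3,
                            pooled_label = "combined") {
  if (is.data.frame(per_host_n)) {
    per_host_n <- setNames(per_host_n$n, per_host_n$host)
  }
  if (length(per_host_n) == 0) abort("per_host_n is empty")
  if (is.null(names(per_host_n)) || any(!nzchar(names(per_host_n)))) {
    abort("per_host_n must be named by host")
  }
  check_P(P)
  check_n(per_host_n)
  n_total <- sum(per_host_n)
  out <- tibble(
    host = c(names(per_host_n), pooled_label),
    n = as.integer(unname(c(per_host_n, n_total))),
    q_max = unname(max_incidence(P, c(per_host_n, n_total)))
  )
  out$q_max_rounded <- round_half_away(out$q_max, digits)
  attr(out, "P") <- P
  attr(out, "digits") <- digits
  attr(out, "pooled_label") <- pooled_label
  class(out) <- c("incidence_table", class(out))
  out
}

#' @method tidy incidence_table
#' @export
tidy.incidence_table <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "incidence_table")
  out$pooled <- out$host == attr(x, "pooled_label")
  out
}

#' One-row summary of an incidence table
#'
#' @param x An `incidence_table`.
#' @param ... Unused.
#' @return Tibble with `P`, `n_hosts`, `n_total`, `q_max_combined`.
#' @method glance incidence_table
#' @export
glance.incidence_table <- function(x, ...) {
  pooled <- x[x$host == attr(x, "pooled_label"), ]
  tibble(
    P = attr(x, "P"),
    n_hosts = nrow(x) - 1L,
    n_total = pooled$n,
    q_max_combined = pooled$q_max
  )
}

#' Detection-power curve with per-host bounds
#'
#' Plots the maximum undetected incidence as a function of library size at
#' the table's probability threshold, with each host (and the pooled survey)
#' marked at its clone count.
#'
#' @param object An `incidence_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot incidence_table
#' @export
autoplot.incidence_table <- function(object, ...) {
  P <- attr(object, "P")
  grid <- tibble(n = seq_len(max(object$n) * 1.2))
  grid$q_max <- max_incidence(P, grid$n)
  df <- tidy(object)
  ggplot2::ggplot(grid, ggplot2::aes(.data$n, .data$q_max)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = df, ggplot2::aes(colour = .data$host),
                        size = 2.5) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.2f", v)) +
    ggplot2::labs(
      x = "clones sequenced (n)",
      y = sprintf("max undetected incidence at P = %.2f", P),
      colour = "host"
    ) +
    ggplot2::theme_minimal()
}

#' Monte Carlo estimate of the detection probability
#'
#' Simulates `reps` clone libraries of `n` i.i.d. Bernoulli(`q`) clones and
#' estimates the probability that at least one is non-target, with its
#' binomial standard error. Serves as an independent stochastic check of
#' [detection_probability()].
#'
#' @param q Incidence in \[0, 1\].
#' @param n Library size, positive integer.
#' @param reps Number of simulated libraries, at least 1000 (smaller values
#'   are too noisy to act as an oracle and are rejected).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List with `estimate` and `std_error`.
#' @examples
#' mc_detection_probability(q = 0.036, n = 126, reps = 1e4, seed = 1)
#' @export
mc_detection_probability <- function(q, n, reps = 1e4, seed = 1) {
  check_q(q)
  check_n(n)
  if (reps < 1e3) abort("reps must be at least 1000")
  est <- with_seed_(seed, mean(rbinom(reps, size = n, prob = q) >= 1))
  list(estimate = est, std_error = sqrt(est * (1 - est) / reps))
}

check_q <- function(q) {
  if (any(!is.finite(q) | q < 0 | q > 1)) abort("q must be in [0, 1]")
}

check_P <- function(P) {
  if (any(!is.finite(P) | P <= 0 | P >= 1)) abort("P must be in (0, 1)")
}

check_n <- function(n) {
  if (any(!is.finite(n) | n < 1 | n != floor(n))) {
    abort("n must be a positive integer")
  }
}
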