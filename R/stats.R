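# Clone-picking probability chain, interval estimates and library diversity.

#' Clone-picking probability chain
#'
#' Computes the probability of recovering at least one usable clone (a
#' full-length assembly with no deleterious mutation in any unit) when
#' screening `n` colonies of a `k`-unit array:
#'
#' \deqn{p(G) = 1 - p(M), \quad p(A) = p(G)^k, \quad p(C) = p(A)\,p(F),
#'       \quad p(U) = 1 - (1 - p(C))^n}
#'
#' where `p(M)` is the per-unit deleterious mutation proportion and `p(F)` the
#' probability that an assembly is full length. Units are assumed to mutate
#' independently (they are synthesised separately) and colonies are assumed
#' to be independent transformation events.
#'
#' @param p_M Per-unit deleterious mutation proportion, in `[0, 1]`.
#' @param p_F Full-length assembly probability, in `[0, 1]`.
#' @param k Units per array (`>= 1`).
#' @param n Colonies screened (`>= 0`).
#' @return A `picking_model` with fields `p_M`, `p_G`, `p_A`, `p_F`, `p_C`,
#'   `p_U`, `k`, `n`. `tidy()` returns the chain as a long tibble, `glance()`
#'   as one row.
#' @export
#' @examples
#' picking_probability(p_M = 0.075, p_F = 0.81, k = 10, n = 4)
picking_probability <- function(p_M, p_F, k, n) {
  if (p_M < 0 || p_M > 1 || p_F < 0 || p_F > 1) {
    abort("p_M and p_F must lie in [0, 1]", class = "guidearray_validation_error")
  }
  k <- as.integer(k); n <- as.integer(n)
  if (is.na(k) || k < 1L) abort("k must be >= 1",
                                class = "guidearray_validation_error")
  if (is.na(n) || n < 0L) abort("n must be >= 0",
                                class = "guidearray_validation_error")
  p_G <- 1 - p_M
  p_A <- p_G^k
  p_C <- p_A * p_F
  p_U <- 1 - (1 - p_C)^n
  structure(list(p_M = p_M, p_G = p_G, p_A = p_A, p_F = p_F, p_C = p_C,
                 p_U = p_U, k = k, n = n),
            class = "picking_model")
}

#' @export
print.picking_model <- function(x, ...) {
  cat(sprintf("<clone-picking model: k = %d units, n = %d colonies>\n", x$k, x$n))
  cat(sprintf("  p(M) = %.4f  p(G) = %.4f  p(A) = %.4f  p(F) = %.4f\n",
              x$p_M, x$p_G, x$p_A, x$p_F))
  cat(sprintf("  p(C) = %.4f  p(U) = %.4f\n", x$p_C, x$p_U))
  invisible(x)
}

#' @export
tidy.picking_model <- function(x, ...) {
  tibble(
    quantity = c("p_M", "p_G", "p_A", "p_F", "p_C", "p_U"),
    description = c("per-unit deleterious mutation proportion",
                    "per-unit probability of no mutation",
                    "probability an array of k units has no mutation",
                    "full-length assembly probability",
                    "probability a picked clone is usable",
                    "probability of at least one usable clone in n"),
    value = c(x$p_M, x$p_G, x$p_A, x$p_F, x$p_C, x$p_U)
  )
}

#' @export
glance.picking_model <- function(x, ...) {
  tibble(p_M = x$p_M, p_G = x$p_G, p_A = x$p_A, p_F = x$p_F, p_C = x$p_C,
         p_U = x$p_U, k = x$k, n = x$n)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (`> 0`).
#' @param conf Confidence level.
#' @return A tibble with `estimate`, `conf_low`, `conf_high`, `x`, `n`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n <= 0) abort("n must be positive", class = "guidearray_validation_error")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(estimate = p, conf_low = max(0, centre - half),
         conf_high = min(1, centre + half), x = x, n = n)
}

#' Estimate p(M) and p(F) from QC outputs
#'
#' Point estimates are the observed fractions (deleterious-mutated units over
#' units profiled; full-length inserts over binned inserts), with Wilson
#' score confidence intervals.
#'
#' @param profile A `mutation_profile`, or `NULL`.
#' @param histogram A `gg_length_histogram`, or `NULL`.
#' @param conf Confidence level.
#' @return A tibble with one row per available quantity (`p_M`, `p_F`):
#'   `quantity`, `estimate`, `conf_low`, `conf_high`, `x`, `n`.
#' @export
estimate_proportions <- function(profile = NULL, histogram = NULL,
                                 conf = 0.95) {
  rows <- list()
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "mutation_profile"))
    g <- glance(profile)
    if (g$n_units == 0) {
      abort("no units profiled: cannot estimate p_M",
            class = "guidearray_validation_error")
    }
    rows$p_M <- bind_cols(tibble(quantity = "p_M"),
                          wilson_ci(g$n_deleterious_units, g$n_units, conf))
  }
  if (!is.null(histogram)) {
    stopifnot(inherits(histogram, "gg_length_histogram"))
    h <- glance(histogram)
    if (h$n_binned == 0) {
      abort("no binned inserts: cannot estimate p_F",
            class = "guidearray_validation_error")
    }
    rows$p_F <- bind_cols(tibble(quantity = "p_F"),
                          wilson_ci(h$full_length_count, h$n_binned, conf))
  }
  if (length(rows) == 0) {
    abort("supply a mutation profile and/or a length histogram",
          class = "guidearray_validation_error")
  }
  list_rbind(unname(rows))
}

# exact big-integer product of positive integers, schoolbook, base 1e4
.exact_product <- function(values) {
  digits <- 1L          # little-endian base-1e4 "digit" vector
  for (v in values) {
    carry <- 0
    for (i in seq_along(digits)) {
      x <- digits[i] * v + carry
      digits[i] <- x %% 10000
      carry <- x %/% 10000
    }
    while (carry > 0) {
      digits <- c(digits, carry %% 10000)
      carry <- carry %/% 10000
    }
  }
  n <- length(digits)
  parts <- c(format(digits[n], scientific = FALSE),
             if (n > 1) sprintf("%04d", rev(digits[-n])))
  paste(parts, collapse = "")
}

#' Number of distinct full-length arrays a pooled library can produce
#'
#' The diversity of a library with independent per-position spacer pools is
#' the product of the pool sizes, computed in exact integer arithmetic (no
#' floating point), so counts such as ten pools of ten — ten billion distinct
#' arrays — are exact.
#'
#' @param pool_sizes Integer vector of per-position pool sizes (all `>= 1`).
#' @return A `library_diversity` object: the exact count as a character
#'   string of digits, with attribute `numeric` (lossy for very large
#'   counts).
#' @export
#' @examples
#' library_diversity(rep(10, 10))
library_diversity <- function(pool_sizes) {
  if (length(pool_sizes) == 0) {
    abort("pool_sizes must be nonempty", class = "guidearray_validation_error")
  }
  sizes <- as.integer(pool_sizes)
  if (any(is.na(sizes) | sizes < 1L)) {
    abort("all pool sizes must be integers >= 1",
          class = "guidearray_validation_error")
  }
  exact <- .exact_product(sizes)
  structure(exact, numeric = as.numeric(exact), class = "library_diversity")
}

#' @export
print.library_diversity <- function(x, ...) {
  cat(sprintf("<library diversity: %s distinct full-length arrays>\n",
              format(unclass(x), big.mark = ",")))
  invisible(x)
}
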