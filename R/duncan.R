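#' Studentized range quantile
#'
#' Upper quantile of the studentized range distribution for `k` means and
#' `df` error degrees of freedom, the critical value underlying multiple
#' range tests. Thin wrapper over the numerically inverted CDF in base R;
#' monotone increasing in `k` and decreasing in `df`.
#'
#' @param k Number of means spanned (>= 2).
#' @param df Error degrees of freedom (>= 1).
#' @param prob Cumulative probability in (0, 1); e.g. `0.95` gives the 5%
#'   critical value.
#' @return The quantile `q` with `P(Q <= q) = prob`.
#' @examples
#' studentized_range_quantile(2, 10, 0.95) # ~3.15
#' @export
studentized_range_quantile <- function(k, df, prob) {
  if (any(k < 2) || any(k != round(k))) {
    abort("`k` must be an integer >= 2.", class = "pegscreen_invalid_input")
  }
  if (any(df < 1)) {
    abort("`df` must be >= 1.", class = "pegscreen_invalid_input")
  }
  if (any(prob <= 0) || any(prob >= 1)) {
    abort("`prob` must lie in (0, 1).", class = "pegscreen_invalid_input")
  }
  qtukey(prob, nmeans = k, df = df)
}

#' Duncan's new multiple range test with compact letter display
#'
#' Implements the protected stepwise procedure: means are ordered, and a pair
#' of means `p` positions apart in the ordering is compared against the least
#' significant range `LSR_p = q_p * sqrt(MSE / n)`, where `q_p` is the
#' studentized range quantile at Duncan's protection level
#' `gamma_p = 1 - (1 - alpha)^(p - 1)`. The protection rule applies: no pair
#' inside a range already declared non-significant can be declared
#' significant. Letters are assigned by a left-to-right sweep over the
#' maximal non-significant stretches of the ordered means, so that two levels
#' share a letter exactly when they do not differ significantly.
#'
#' With unequal group sizes `n` is replaced by the harmonic mean of the
#' sizes. Ties in the means are ordered stably by level name and always fall
#' inside a common letter group. A zero error mean square is degenerate:
#' distinct means get distinct letters and the result is flagged.
#'
#' @param means Named numeric vector of level means.
#' @param n_per_mean Replicate count behind each mean; scalar or per-level
#'   vector (harmonic mean is used if unequal).
#' @param mse Error mean square from the ANOVA protecting the test.
#' @param error_df Error degrees of freedom.
#' @param alpha Significance level; default `0.01`, the level conventionally
#'   used for letter displays in germination screens.
#' @return A `peg_duncan` object: a list with `alpha`, `error_df`, `mse`,
#'   `n_harmonic`, `lsr` (tibble of spans and least significant ranges),
#'   `groups` (tibble `level`, `mean`, `letters` in descending mean order)
#'   and `degenerate`.
#' @examples
#' m <- c(a = 10, b = 9.8, c = 5)
#' duncan_letters(m, n_per_mean = 5, mse = 0.25, error_df = 12)
#' @export
duncan_letters <- function(means, n_per_mean, mse, error_df, alpha = 0.01) {
  if (is.null(names(means)) || anyNA(names(means)) || any(names(means) == "")) {
    abort("`means` must be a fully named numeric vector.",
          class = "pegscreen_invalid_input")
  }
  k <- length(means)
  if (k < 2) {
    abort("Need at least two level means.", class = "pegscreen_invalid_input")
  }
  if (error_df < 1) {
    abort("`error_df` must be >= 1.", class = "pegscreen_invalid_input")
  }
  if (mse < 0) {
    abort("`mse` must be non-negative.", class = "pegscreen_invalid_input")
  }
  if (length(n_per_mean) == 1) n_per_mean <- rep(n_per_mean, k)
  if (any(n_per_mean <= 0)) {
    abort("`n_per_mean` must be positive.", class = "pegscreen_invalid_input")
  }
  n_h <- length(n_per_mean) / sum(1 / n_per_mean)

  ord <- order(-means, names(means))
  m <- as.numeric(means)[ord]
  lev <- names(means)[ord]

  degenerate <- mse == 0
  if (degenerate) {
    # no error variance: any numeric difference is taken at face value
    grp <- cumsum(c(TRUE, diff(m) != 0))
    letters_per <- make_letter_codes(max(grp))[grp]
    lsr_tbl <- tibble::tibble(span = integer(), lsr = numeric())
    ns <- outer(grp, grp, "==")
  } else {
    spans <- 2:k
    qcrit <- vapply(spans, function(p) {
      qtukey((1 - alpha)^(p - 1), nmeans = p, df = error_df)
    }, numeric(1))
    lsr <- qcrit * sqrt(mse / n_h)
    lsr_tbl <- tibble::tibble(span = spans, lsr = lsr)

    # ns[i, j]: levels i..j (sorted order) not significantly different.
    # Sweep spans from widest to narrowest; once a range is declared
    # non-significant every pair inside it is protected.
    ns <- diag(k) > 0
    if (k >= 2) {
      for (p in rev(spans)) {
        for (i in seq_len(k - p + 1)) {
          j <- i + p - 1
          if (ns[i, j]) next
          if ((m[i] - m[j]) < lsr[p - 1]) {
            ns[i:j, i:j] <- TRUE
          }
        }
      }
    }
    letters_per <- letters_from_ns(ns)
  }

  groups <- tibble::tibble(level = lev, mean = m, letters = letters_per)
  structure(
    list(alpha = alpha, error_df = error_df, mse = mse, n_harmonic = n_h,
         lsr = lsr_tbl, groups = groups, degenerate = degenerate),
    class = "peg_duncan"
  )
}

# letters a, b, ..., z, aa, ab, ... for arbitrarily many groups
make_letter_codes <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, paste0)))[seq_len(n)]
}

# compact letter display from an interval-closed non-significance matrix
letters_from_ns <- function(ns) {
  k <- nrow(ns)
  reach <- vapply(seq_len(k), function(i) max(which(ns[i, ])), integer(1))
  # maximal non-significant stretches: [i, reach(i)] not nested in a prior one
  starts <- integer(0)
  ends <- integer(0)
  max_end <- 0L
  for (i in seq_len(k)) {
    if (reach[i] > max_end) {
      starts <- c(starts, i)
      ends <- c(ends, reach[i])
      max_end <- reach[i]
    }
  }
  codes <- make_letter_codes(length(starts))
  vapply(seq_len(k), function(i) {
    covering <- which(starts <= i & ends >= i)
    paste0(codes[covering], collapse = "")
  }, character(1))
}

#' @export
print.peg_duncan <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, error df = %d, MSE = %g)\n",
              x$alpha, x$error_df, x$mse))
  if (x$degenerate) cat("  [degenerate: zero error mean square]\n")
  print(x$groups, ...)
  invisible(x)
}

#' @export
tidy.peg_duncan <- function(x, ...) x$groups

#' @export
glance.peg_duncan <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, error_df = x$error_df, mse = x$mse,
    n_harmonic = x$n_harmonic,
    n_groups = length(unique(x$groups$letters)),
    degenerate = x$degenerate
  )
}
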