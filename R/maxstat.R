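#' Maximally selected cutpoint statistic with permutation p-value
#'
#' Searches all admissible cutpoints of a continuous covariate (midpoints
#' between sorted unique values leaving at least `min_prop` of the data on
#' each side) for the two-group split that maximizes the standardized
#' mean-difference statistic
#' \deqn{T(c) = |S_c - E(S_c)| / \sqrt{Var(S_c)}}
#' where \eqn{S_c} is the sum of the response below the cutpoint and the
#' moments are the permutation moments of that sum. `T_max` is the maximum
#' over cutpoints (ties broken toward the smaller cutpoint) and its
#' significance is assessed by permuting the response (`n_perm` draws,
#' plus-one correction), which accounts for the cutpoint selection.
#'
#' @param data Data frame holding the variables, or `NULL` if `x`/`y` are
#'   vectors.
#' @param x,y Column names (tidy-select style strings) or numeric vectors:
#'   covariate and response.
#' @param min_prop Minimum proportion of observations on each side of an
#'   admissible cutpoint.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Optional integer seed for the permutations.
#' @return A `maxstat_cutpoint` object: `cutpoint`, `t_max`, `p_perm`,
#'   `group_means` (below/above), `candidates` (per-cutpoint statistics),
#'   `n`, `n_perm`.
#' @export
maxstat_cutpoint <- function(data = NULL, x, y, min_prop = 0.1,
                             n_perm = 10000, seed = NULL) {
  if (!is.null(data)) {
    xv <- data[[x]]
    yv <- data[[y]]
  } else {
    xv <- x
    yv <- y
  }
  .assert(length(xv) == length(yv), "x and y must have the same length")
  ok <- complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  .assert(n >= 10, "need at least 10 observations")
  .assert(min_prop > 0 && min_prop < 0.5, "min_prop must be in (0, 0.5)")

  o <- order(xv)
  xs <- xv[o]
  ys <- yv[o]
  ux <- unique(xs)
  cuts <- (head(ux, -1) + tail(ux, -1)) / 2
  n_below <- vapply(cuts, function(cc) sum(xs <= cc), integer(1))
  lo <- ceiling(min_prop * n)
  keep <- n_below >= lo & (n - n_below) >= lo
  .assert(any(keep), "no admissible cutpoint under min_prop")
  cuts <- cuts[keep]
  n_below <- n_below[keep]

  tmax_of <- function(yy) {
    # standardized sum-below statistic at every candidate, vectorized
    cs <- cumsum(yy)
    S <- cs[n_below]
    mu <- mean(yy)
    sig2 <- sum((yy - mu)^2) / n
    ES <- n_below * mu
    VS <- n_below * (n - n_below) / (n - 1) * sig2
    if (sig2 == 0) return(list(t = rep(0, length(cuts)), tmax = 0))
    t <- abs(S - ES) / sqrt(VS)
    list(t = t, tmax = max(t))
  }
  obs <- tmax_of(ys)
  i_best <- which.max(obs$t) # first maximum = smaller cutpoint on ties
  cutpoint <- cuts[i_best]

  p_perm <- if (obs$tmax == 0) {
    1
  } else {
    if (!is.null(seed)) {
      exceed <- .with_seed(seed, {
        sum(vapply(seq_len(n_perm),
                   function(i) tmax_of(sample(ys))$tmax, numeric(1)) >= obs$tmax - 1e-12)
      })
    } else {
      exceed <- sum(vapply(seq_len(n_perm),
                           function(i) tmax_of(sample(ys))$tmax, numeric(1)) >= obs$tmax - 1e-12)
    }
    (1 + exceed) / (n_perm + 1)
  }

  below <- xs <= cutpoint
  structure(
    list(
      cutpoint = cutpoint,
      t_max = obs$tmax,
      p_perm = p_perm,
      group_means = c(below = mean(ys[below]), above = mean(ys[!below])),
      group_n = c(below = sum(below), above = sum(!below)),
      candidates = tibble::tibble(cutpoint = cuts, statistic = obs$t),
      n = n,
      n_perm = n_perm
    ),
    class = "maxstat_cutpoint"
  )
}

#' @export
print.maxstat_cutpoint <- function(x, ...) {
  cat("Maximally selected cutpoint\n")
  cat(sprintf(
    "  cutpoint %.4g, T_max = %.4f, permutation p = %.4g (%d permutations)\n",
    x$cutpoint, x$t_max, x$p_perm, x$n_perm
  ))
  cat(sprintf(
    "  mean below = %.3f (n = %d), mean above = %.3f (n = %d)\n",
    x$group_means[["below"]], x$group_n[["below"]],
    x$group_means[["above"]], x$group_n[["above"]]
  ))
  invisible(x)
}
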