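#' Assemble grouped activity curves on a common dense grid
#'
#' Each subject's per-minute scores (knots at minutes `1..m`) are interpolated
#' by a natural cubic spline and evaluated on a uniform dense grid, following
#' the functional-data convention of interpolating, smoothing and
#' differentiating discretized activity records before comparing groups.
#'
#' @param scores matrix `n_subjects x n_minutes` (rownames used as subject
#'   ids) or long data.frame with columns `subject_id`, `minute`, `qar_score`.
#' @param labels data.frame with columns `subject_id`, `group` (exactly two
#'   groups, each with >= 2 subjects).
#' @param dense_n number of dense-grid points over \[first knot, last knot\]
#'   (default 221).
#' @return an object of class `grouped_curves`: knot grid and values, dense
#'   grid and values, per-subject spline functions, group factor.
#' @export
build_curves <- function(scores, labels, dense_n = 221L) {
  if (is.data.frame(scores)) {
    wide <- tapply(scores$qar_score,
                   list(scores$subject_id, scores$minute), identity)
    scores <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
                     dimnames = dimnames(wide))
  }
  if (any(!is.finite(scores)) || is.null(rownames(scores)))
    stop_qar("scores must be a finite matrix with subject ids as rownames (or long data.frame); ragged input is not allowed",
             "qar_shape_error")
  ids <- rownames(scores)
  grp <- labels$group[match(ids, labels$subject_id)]
  if (any(is.na(grp)))
    stop_qar("labels missing for some subjects", "qar_shape_error")
  grp <- factor(grp)
  if (nlevels(grp) != 2 || any(table(grp) < 2))
    stop_qar("need exactly 2 groups with >= 2 subjects each", "qar_shape_error")
  knots <- suppressWarnings(as.numeric(colnames(scores)))
  if (length(knots) != ncol(scores) || any(is.na(knots)))
    knots <- seq_len(ncol(scores))
  splines <- apply(scores, 1L, function(v) splinefun(knots, v, method = "natural"))
  dense_grid <- seq(min(knots), max(knots), length.out = dense_n)
  dense <- t(vapply(splines, function(f) f(dense_grid), numeric(dense_n)))
  rownames(dense) <- ids
  structure(list(subject_id = ids, group = grp, knots = knots,
                 values = scores, dense_grid = dense_grid,
                 dense_values = dense, splines = splines,
                 curve_type = "activity"),
            class = "grouped_curves")
}

#' @export
print.grouped_curves <- function(x, ...) {
  cat(sprintf("<grouped_curves> (%s) %d curves (%s), %d knots, dense grid %d points on [%g, %g]\n",
              x$curve_type, length(x$subject_id),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", "),
              length(x$knots), length(x$dense_grid),
              min(x$dense_grid), max(x$dense_grid)))
  invisible(x)
}

# Pointwise two-group one-way ANOVA F over the columns of V (subjects in
# rows), for group-1 row indices idx1. Precomputable pieces are passed in so
# the permutation loop touches only one colSums per replicate.
fstat_columns <- function(V, idx1, n1, n2, S1, TSS, gmean) {
  s1 <- colSums(V[idx1, , drop = FALSE])
  m1 <- s1 / n1
  m2 <- (S1 - s1) / n2
  SSB <- n1 * (m1 - gmean)^2 + n2 * (m2 - gmean)^2
  SSW <- pmax(TSS - SSB, 0)
  N <- n1 + n2
  FF <- SSB / (SSW / (N - 2))
  FF[SSW == 0 & SSB > 0] <- Inf
  FF[SSW == 0 & SSB == 0] <- 0
  FF
}

fstat_setup <- function(V) {
  S1 <- colSums(V)
  N <- nrow(V)
  gmean <- S1 / N
  TSS <- colSums(V^2) - N * gmean^2
  list(S1 = S1, gmean = gmean, TSS = pmax(TSS, 0), N = N)
}

#' Pointwise one-way ANOVA F statistic
#'
#' Classical two-group F statistic (between-group mean square over
#' within-group mean square, df 1 and N-2) of the smoothed curve values at
#' each requested time. Times not on the dense grid are evaluated through the
#' stored splines. A time point where all curves coincide within a group but
#' group means differ yields an infinite statistic, flagged downstream.
#'
#' @param grouped a [build_curves()] result.
#' @param t times (minutes) at which to evaluate; default the dense grid.
#' @return numeric vector of F values.
#' @export
pointwise_F <- function(grouped, t = grouped$dense_grid) {
  on_grid <- match(t, grouped$dense_grid)
  if (anyNA(on_grid)) {
    V <- t(vapply(grouped$splines, function(f) f(t), numeric(length(t))))
    if (length(t) == 1L) V <- matrix(V, ncol = 1L)
  } else {
    V <- grouped$dense_values[, on_grid, drop = FALSE]
  }
  idx1 <- which(grouped$group == levels(grouped$group)[1])
  n1 <- length(idx1)
  n2 <- nrow(V) - n1
  st <- fstat_setup(V)
  fstat_columns(V, idx1, n1, n2, st$S1, st$TSS, st$gmean)
}

# Shared permutation machinery: returns observed GPF and Fmax statistics plus
# their permutation null draws, from one resampling stream.
fanova_permute <- function(grouped, n_resamples, seed) {
  if (n_resamples < 99)
    warning("fewer than 99 resamples: permutation p-values will be coarse")
  V <- grouped$dense_values
  grid <- grouped$dense_grid
  # canonicalize on the smaller group: F is symmetric in the two groups, and
  # sampling the smaller index set makes statistics and p-values exactly
  # invariant to swapping the group labels
  sizes <- table(grouped$group)
  lev1 <- levels(grouped$group)[which.min(sizes)]
  idx1 <- which(grouped$group == lev1)
  n1 <- length(idx1)
  N <- nrow(V)
  n2 <- N - n1
  st <- fstat_setup(V)
  span <- diff(range(grid))

  summarize <- function(FF) {
    bad <- !is.finite(FF)
    if (any(bad)) {
      warning(sprintf("%d grid point(s) with degenerate within-group variance excluded from the integral",
                      sum(bad)))
    }
    gpf <- pracma::trapz(grid[!bad], FF[!bad]) / span
    c(gpf = gpf, fmax = max(FF[is.finite(FF)], if (any(bad)) Inf))
  }

  obs_F <- fstat_columns(V, idx1, n1, n2, st$S1, st$TSS, st$gmean)
  obs <- suppressWarnings(summarize(obs_F))
  if (any(!is.finite(obs_F)))
    warning(sprintf("%d observed grid point(s) had degenerate within-group variance",
                    sum(!is.finite(obs_F))))

  null_draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(N, n1)
      suppressWarnings(
        summarize(fstat_columns(V, idx, n1, n2, st$S1, st$TSS, st$gmean)))
    }, numeric(2))
  })
  list(obs = obs, null = null_draws, pointwise_F = obs_F,
       n_resamples = n_resamples)
}

new_fanova_result <- function(method, statistic, p_value, n_resamples,
                              pointwise_F, curve_type) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_resamples = n_resamples, pointwise_F = pointwise_F,
                 curve_type = curve_type),
            class = "fanova_result")
}

#' @export
print.fanova_result <- function(x, ...) {
  cat(sprintf("%s test (%s curves): statistic = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$curve_type, x$statistic, x$p_value, x$n_resamples))
  invisible(x)
}

#' Globalized pointwise F-test and F-max test, sharing one resampling stream
#'
#' The globalized pointwise F (GPF) statistic is the time-average of the
#' pointwise F statistic, `(1/|T|) * integral of F(t) dt`, by trapezoidal
#' quadrature on the dense grid; the F-max statistic is its supremum over the
#' grid. Both p-values come from the same group-label permutation of whole
#' curves with the add-one rule `p = (1 + #{stat* >= stat}) / (B + 1)`, which
#' keeps the preassigned level exactly under exchangeability without
#' distributional assumptions -- preferable to asymptotic nulls at the small
#' group sizes these tests target.
#'
#' @param grouped a [build_curves()] result (or [velocity()] output).
#' @param n_resamples number of permutations B (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list with elements `gpf` and `fmax`, each a `fanova_result`.
#' @export
fanova_tests <- function(grouped, n_resamples = 1000L, seed = 1L) {
  pr <- fanova_permute(grouped, n_resamples, seed)
  p <- (1 + rowSums(pr$null >= pr$obs)) / (n_resamples + 1)
  list(
    gpf = new_fanova_result("GPF", unname(pr$obs["gpf"]), unname(p["gpf"]),
                            n_resamples, pr$pointwise_F, grouped$curve_type),
    fmax = new_fanova_result("Fmax", unname(pr$obs["fmax"]), unname(p["fmax"]),
                             n_resamples, pr$pointwise_F, grouped$curve_type)
  )
}

#' @rdname fanova_tests
#' @export
gpf_test <- function(grouped, n_resamples = 1000L, seed = 1L) {
  fanova_tests(grouped, n_resamples, seed)$gpf
}

#' @rdname fanova_tests
#' @export
fmax_test <- function(grouped, n_resamples = 1000L, seed = 1L) {
  fanova_tests(grouped, n_resamples, seed)$fmax
}

#' Velocity curves: first derivative of the smoothed activity curves
#'
#' Analytic derivative of each subject's interpolating spline, in score units
#' per minute, evaluated on the same dense grid. The result is again a
#' `grouped_curves` object, so the same functional tests apply to the rate of
#' change of movement.
#'
#' @param grouped a [build_curves()] result.
#' @return a `grouped_curves` object with `curve_type = "velocity"`.
#' @export
velocity <- function(grouped) {
  if (length(grouped$dense_grid) < 2)
    stop_qar("need >= 2 grid points", "qar_shape_error")
  dense <- t(vapply(grouped$splines,
                    function(f) f(grouped$dense_grid, deriv = 1),
                    numeric(length(grouped$dense_grid))))
  rownames(dense) <- grouped$subject_id
  out <- grouped
  out$dense_values <- dense
  out$values <- t(vapply(grouped$splines,
                         function(f) f(grouped$knots, deriv = 1),
                         numeric(length(grouped$knots))))
  rownames(out$values) <- grouped$subject_id
  out$splines <- lapply(grouped$splines, function(f) {
    force(f); function(x, deriv = 0) f(x, deriv = deriv + 1)
  })
  out$curve_type <- "velocity"
  out
}

#' Per-group values and means at selected times
#'
#' Evaluates each subject's smoothed curve at the requested times and returns
#' the per-group values and arithmetic means -- the numbers behind pointwise
#' density comparisons at a handful of clinically interesting minutes.
#'
#' @param grouped a [build_curves()] result.
#' @param times minutes at which to evaluate (default `c(3, 7, 9, 11, 22)`).
#' @return list with `values` (long data.frame: `time`, `subject_id`, `group`,
#'   `value`) and `means` (data.frame: `time`, `group`, `mean`).
#' @export
pointwise_distribution <- function(grouped, times = c(3, 7, 9, 11, 22)) {
  rng <- range(grouped$knots)
  if (any(times < rng[1] - 1e-9) || any(times > rng[2] + 1e-9))
    stop_qar("requested times outside the curve domain", "qar_range_error")
  vals <- do.call(rbind, lapply(times, function(tm) {
    data.frame(time = tm, subject_id = grouped$subject_id,
               group = as.character(grouped$group),
               value = vapply(grouped$splines, function(f) f(tm), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(vals) <- NULL
  means <- aggregate(value ~ time + group, data = vals, FUN = mean)
  names(means)[names(means) == "value"] <- "mean"
  list(values = vals, means = means[order(means$time, means$group), ])
}

#' Spearman rank correlation with midrank ties
#'
#' @param x,y equal-length numeric vectors (length >= 3, neither constant).
#' @return list with `rho` and two-sided `p` (t approximation, as appropriate
#'   with ties).
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_qar("need equal lengths >= 3", "qar_contract_error")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_qar("rank correlation undefined for a constant vector",
             "qar_contract_error")
  rho <- cor(rank(x), rank(y))
  p <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  list(rho = rho, p = p)
}

#' Area under a smoothed activity curve
#'
#' Trapezoidal area under the dense-grid evaluation over
#' \[first knot, last knot\]; the scalar "total movement" used for
#' correlations with clinical scores.
#'
#' @param grouped a [build_curves()] result.
#' @param subject optional subject id; default all subjects.
#' @return named numeric vector of areas.
#' @export
curve_total <- function(grouped, subject = NULL) {
  ids <- if (is.null(subject)) grouped$subject_id else subject
  vapply(ids, function(id) {
    pracma::trapz(grouped$dense_grid, grouped$dense_values[id, ])
  }, numeric(1))
}

#' Scalar two-group comparison
#'
#' Wilcoxon rank-sum test for continuous variables (exact enumeration when the
#' pooled sample is small and untied, normal approximation otherwise) or
#' Pearson chi-square for categorical variables.
#'
#' @param values numeric vector (continuous) or factor/character (categorical).
#' @param labels group labels, exactly two non-empty groups.
#' @param kind `"ranksum"` or `"chisq"`.
#' @return two-sided p-value.
#' @export
scalar_group_compare <- function(values, labels, kind = c("ranksum", "chisq")) {
  kind <- match.arg(kind)
  labels <- factor(labels)
  if (nlevels(labels) != 2 || any(table(labels) == 0))
    stop_qar("need exactly 2 non-empty groups", "qar_contract_error")
  if (kind == "ranksum") {
    x <- values[labels == levels(labels)[1]]
    y <- values[labels == levels(labels)[2]]
    exact <- (length(x) + length(y) <= 12) && !any(duplicated(c(x, y)))
    suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
  } else {
    suppressWarnings(chisq.test(table(values, labels), correct = FALSE)$p.value)
  }
}
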