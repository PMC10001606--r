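#' Configuration for grey relational analysis
#'
#' @param epsilon resolution coefficient in (0, 1]. Damps the influence of
#'   the maximum deviation in the grey relational coefficient; the
#'   conventional middle value 0.5 is the default.
#' @param theta weight in \[0, 1\] mixing the absolute and relative degrees
#'   into the synthetic degree (SDGRA); default 0.5 (plain average).
#' @param rounding decimal places used when *reporting* degrees and when
#'   detecting rank ties; all internal arithmetic stays at full precision.
#' @return list of class `grey_config`.
#' @export
grey_config <- function(epsilon = 0.5, theta = 0.5, rounding = 3L) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L)
  if (!(epsilon > 0 && epsilon <= 1)) {
    stop("grey_config: epsilon must lie in (0, 1]", call. = FALSE)
  }
  if (!(theta >= 0 && theta <= 1)) {
    stop("grey_config: theta must lie in [0, 1]", call. = FALSE)
  }
  rounding <- as.integer(rounding)
  if (rounding < 0L) stop("grey_config: rounding must be >= 0", call. = FALSE)
  structure(list(epsilon = epsilon, theta = theta, rounding = rounding),
            class = "grey_config")
}

#' Grey relational coefficients
#'
#' Pointwise similarity between the mean images of a reference sequence
#' x0 and comparison sequences xi:
#' \deqn{\gamma_i(k) = \frac{\min_i \min_k |\Delta_i(k)| +
#'   \varepsilon \max_i \max_k |\Delta_i(k)|}{|\Delta_i(k)| +
#'   \varepsilon \max_i \max_k |\Delta_i(k)|}}
#' where \eqn{\Delta_i(k) = x_0'(k) - x_i'(k)} on the mean images
#' \eqn{x'(k) = x(k)/\bar x}. The two-level min/max runs over all
#' observations *and* all comparison sequences supplied in the call (the
#' classical global scope); with a single comparison the two scopes
#' coincide.
#'
#' If every comparison image coincides with the reference image the
#' deviations are identically zero and all coefficients are defined as 1
#' (the perfect-incidence limit of the 0/0 form).
#'
#' @param reference [grey_seq] or numeric: the outcome series.
#' @param comparisons a [grey_seq], numeric vector, or (named) list of them.
#' @param epsilon resolution coefficient in (0, 1].
#' @return numeric matrix, one row per observation, one column per
#'   comparison; every entry in (0, 1].
#' @examples
#' grey_coefficients(c(1, 2, 3), c(3, 2, 1))  # 1/3, 1, 1/3
#' @export
grey_coefficients <- function(reference, comparisons, epsilon = 0.5) {
  if (!(epsilon > 0 && epsilon <= 1)) {
    stop("grey_coefficients: epsilon must lie in (0, 1]", call. = FALSE)
  }
  reference <- as_grey_seq(reference, "reference")
  comparisons <- as_comparison_list(comparisons)
  m <- length(reference$values)
  bad <- vapply(comparisons, function(s) length(s$values) != m, logical(1L))
  if (any(bad)) {
    stop("grey_coefficients: comparison '", names(comparisons)[bad][1L],
         "' has length ", length(comparisons[[which(bad)[1L]]]$values),
         ", reference has ", m, call. = FALSE)
  }
  r <- mean_image(reference)$values
  delta <- vapply(comparisons,
                  function(s) abs(r - mean_image(s)$values),
                  numeric(m))
  delta <- matrix(delta, nrow = m,
                  dimnames = list(reference$years, names(comparisons)))
  dmin <- min(delta)
  dmax <- max(delta)
  # Mean images have mean exactly 1, so deviations are O(1); a max deviation
  # at rounding-noise level means the images coincide (perfect incidence),
  # and the 0/0 limit of the coefficient is 1.
  if (dmax <= 1e-12) {
    delta[] <- 1
    return(delta)
  }
  (dmin + epsilon * dmax) / (delta + epsilon * dmax)
}

#' Deng's degree of grey incidence
#'
#' The arithmetic mean over observations of the grey relational
#' coefficients ([grey_coefficients]). Lies in (0, 1]; equals 1 exactly
#' when the mean images of reference and comparison coincide, so it is
#' invariant under positive rescaling of either series.
#'
#' When several comparisons are supplied, the coefficient min/max
#' normalisation is shared across all of them (global scope) before
#' averaging per factor.
#'
#' @inheritParams grey_coefficients
#' @param config a [grey_config]; only `epsilon` is used here.
#' @return named numeric vector, one degree per comparison.
#' @examples
#' deng_degree(c(1, 2, 3), c(3, 2, 1))  # 5/9
#' deng_degree(c(1, 2, 3), c(2, 4, 6))  # 1: proportional series
#' @export
deng_degree <- function(reference, comparisons, config = grey_config()) {
  gam <- grey_coefficients(reference, comparisons, config$epsilon)
  colMeans(gam)
}

# Area term of the Liu absolute-degree construction: on the zero-start
# image X0 of a length-m sequence, s = sum_{k=2}^{m-1} X0(k) + X0(m)/2.
zero_start_area <- function(s) {
  v <- zero_start_image(s)$values
  m <- length(v)
  sum(v[seq.int(2L, m - 1L)]) + v[m] / 2
}

#' Absolute degree of grey incidence
#'
#' Area-based similarity of two sequences: each series is reduced to its
#' zero-start image, the signed area \eqn{s = \sum_{k=2}^{m-1} X^0(k) +
#' \tfrac12 X^0(m)} is accumulated, and the degree is
#' \deqn{(1 + |s_0| + |s_i|) / (1 + |s_0| + |s_i| + |s_i - s_0|).}
#' It equals 1 when the zero-start images coincide (the two series differ
#' by a constant shift) and decays towards 1/2 as the areas diverge with
#' opposite signs. Unlike Deng's and the relative degree it is *not*
#' invariant under rescaling — magnitude of change matters.
#'
#' @param reference [grey_seq] or numeric.
#' @param comparisons a [grey_seq], numeric vector, or (named) list of them.
#' @return named numeric vector of degrees in (0, 1].
#' @examples
#' absolute_degree(c(1, 2, 3), c(2, 3, 4))  # 1: same shape, shifted
#' absolute_degree(c(1, 2, 3), c(7, 7, 7))  # 0.6: flat comparison
#' @export
absolute_degree <- function(reference, comparisons) {
  reference <- as_grey_seq(reference, "reference")
  comparisons <- as_comparison_list(comparisons)
  m <- length(reference$values)
  if (m < 3L) stop("absolute_degree: need length >= 3", call. = FALSE)
  s0 <- zero_start_area(reference)
  vapply(comparisons, function(s) {
    if (length(s$values) != m) {
      stop("absolute_degree: length mismatch for '", s$name, "'",
           call. = FALSE)
    }
    si <- zero_start_area(s)
    (1 + abs(s0) + abs(si)) / (1 + abs(s0) + abs(si) + abs(si - s0))
  }, numeric(1L))
}

#' Relative degree of grey incidence
#'
#' The absolute-degree area construction applied to the initial-value
#' images of the raw sequences: both series are divided by their first
#' value before comparing zero-start areas. The result is scale-free and
#' measures closeness of *rates of change*; it equals 1 for proportional
#' sequences.
#'
#' @inheritParams absolute_degree
#' @return named numeric vector of degrees in (0, 1].
#' @examples
#' relative_degree(c(2, 4, 6), c(1, 2, 3))  # 1: proportional
#' @export
relative_degree <- function(reference, comparisons) {
  reference <- as_grey_seq(reference, "reference")
  comparisons <- as_comparison_list(comparisons)
  ref_im <- initial_image(reference)
  vapply(comparisons, function(s) {
    absolute_degree(ref_im, initial_image(s))
  }, numeric(1L))
}

#' Synthetic degrees of grey incidence
#'
#' Two composite scores:
#' * `sdgra()` — weighted mean of the absolute and relative degrees,
#'   \eqn{\theta \cdot \rho_{abs} + (1-\theta) \cdot \rho_{rel}};
#'   balances magnitude-of-change and rate-of-change similarity.
#' * `ssgra()` — plain mean of Deng's and the absolute degree,
#'   \eqn{(\beta + \rho_{abs})/2}; mixes pointwise and integral closeness.
#'
#' @param absolute,relative,deng degree values in (0, 1] (vectorised).
#' @param theta weight in \[0, 1\]; default 0.5.
#' @return numeric vector of composite degrees.
#' @examples
#' sdgra(0.599, 0.893)   # 0.746
#' ssgra(0.941, 0.599)   # 0.770
#' @export
sdgra <- function(absolute, relative, theta = 0.5) {
  check_degree(absolute, "absolute")
  check_degree(relative, "relative")
  if (!(length(theta) == 1L && theta >= 0 && theta <= 1)) {
    stop("sdgra: theta must lie in [0, 1]", call. = FALSE)
  }
  theta * absolute + (1 - theta) * relative
}

#' @rdname sdgra
#' @export
ssgra <- function(deng, absolute) {
  check_degree(deng, "deng")
  check_degree(absolute, "absolute")
  (deng + absolute) / 2
}

check_degree <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    stop(what, " degree out of range: values must lie in (0, 1]",
         call. = FALSE)
  }
  invisible(x)
}

#' Rank factors by degree with shared-rank tie notation
#'
#' Sorts degrees in descending order (higher incidence = more important) and
#' assigns ranks 1..n on the *unrounded* values. Factors whose degrees
#' coincide after rounding to `rounding` decimals share a rank, reported in
#' the convention `"3(4)"`: both tied factors occupy sorted positions 3 and
#' 4 and carry the same label.
#'
#' @param degrees named numeric vector of degrees.
#' @param rounding decimals at which ties are detected (reporting
#'   precision); default 3.
#' @return data.frame with columns `factor`, `degree`, `rank` (integer,
#'   smallest position of the tie group) and `rank_label` (character).
#' @examples
#' rank_factors(c(income = 0.566, physician = 0.859, smoking = 0.941))
#' @export
rank_factors <- function(degrees, rounding = 3L) {
  n <- length(degrees)
  if (n < 1L) stop("rank_factors: need at least one degree", call. = FALSE)
  if (is.null(names(degrees))) {
    names(degrees) <- paste0("factor", seq_len(n))
  }
  ord <- order(degrees, decreasing = TRUE)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  rounded <- round(degrees, rounding)
  # Tie groups are contiguous in sorted position (rounding preserves order).
  grp <- match(rounded, unique(rounded[ord]))
  rank_int <- integer(n)
  rank_label <- character(n)
  for (g in unique(grp)) {
    members <- which(grp == g)
    p <- sort(pos[members])
    rank_int[members] <- p[1L]
    rank_label[members] <- paste0(p[1L],
      if (length(p) > 1L) paste0("(", p[-1L], ")", collapse = "") else "")
  }
  data.frame(factor = names(degrees), degree = unname(degrees),
             rank = rank_int, rank_label = rank_label,
             stringsAsFactors = FALSE)
}

#' Run all five grey incidence models and rank the factors
#'
#' Computes, for every comparison factor against the reference outcome:
#' Deng's degree (on mean images, shared min/max scope across factors), the
#' absolute degree (on mean images — the uniform unit-removing
#' standardisation — via zero-start areas), the relative degree (on
#' initial-value images of the raw data), and the two synthetic degrees
#' SDGRA and SSGRA; then ranks the factors under each model. The composite
#' identities `sdgra = theta*absolute + (1-theta)*relative` and
#' `ssgra = (deng + absolute)/2` hold exactly on the unrounded values.
#'
#' With `lag > 0` the outcome at year *t* is related to factor levels at
#' year *t − lag* via [lag_align] before any degree is computed.
#'
#' @param reference [grey_seq] outcome series.
#' @param comparisons named list of [grey_seq] factors (or numeric vectors).
#' @param config a [grey_config].
#' @param lag non-negative integer lag applied to all factors.
#' @return A `gra_table`: data.frame with one row per factor and, per model
#'   (`deng`, `sdgra`, `ssgra`, `absolute`, `relative`), the unrounded
#'   degree plus `<model>_rank` (integer) and `<model>_rank_label`
#'   (character, tie notation). Attributes record the config and lag used.
#' @examples
#' r <- grey_seq(c(90, 88, 85, 80, 76), years = 2001:2005, name = "mortality")
#' f <- list(smoking   = grey_seq(c(18, 17, 16, 14, 13), years = 2001:2005),
#'           physician = grey_seq(c(2.1, 2.2, 2.2, 2.3, 2.4), years = 2001:2005))
#' gra_table(r, f)
#' @export
gra_table <- function(reference, comparisons, config = grey_config(),
                      lag = 0L) {
  reference <- as_grey_seq(reference, "reference")
  comparisons <- as_comparison_list(comparisons)
  if (length(comparisons) < 1L) {
    stop("gra_table: need at least one comparison factor", call. = FALSE)
  }
  if (lag > 0L) {
    aligned <- lag_align(reference, comparisons, lag)
    reference <- aligned$reference
    comparisons <- aligned$comparisons
  }
  deng <- deng_degree(reference, comparisons, config)
  absolute <- absolute_degree(mean_image(reference),
                              lapply(comparisons, mean_image))
  relative <- relative_degree(reference, comparisons)
  sd_deg <- sdgra(absolute, relative, config$theta)
  ss_deg <- ssgra(deng, absolute)
  degrees <- list(deng = deng, sdgra = sd_deg, ssgra = ss_deg,
                  absolute = absolute, relative = relative)
  out <- data.frame(factor = names(comparisons), stringsAsFactors = FALSE)
  for (model in names(degrees)) {
    rk <- rank_factors(degrees[[model]], config$rounding)
    out[[model]] <- rk$degree
    out[[paste0(model, "_rank")]] <- rk$rank
    out[[paste0(model, "_rank_label")]] <- rk$rank_label
  }
  structure(out, class = c("gra_table", "data.frame"),
            config = config, lag = as.integer(lag),
            years = reference$years)
}

#' @export
print.gra_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Degrees of grey incidence (epsilon = ", cfg$epsilon,
      ", theta = ", cfg$theta,
      if (attr(x, "lag") > 0L) paste0(", lag = ", attr(x, "lag")) else "",
      ")\n\n", sep = "")
  models <- c("deng", "sdgra", "ssgra", "absolute", "relative")
  disp <- data.frame(factor = x$factor, stringsAsFactors = FALSE)
  for (model in models) {
    disp[[model]] <- formatC(round(x[[model]], cfg$rounding),
                             format = "f", digits = cfg$rounding)
    disp[[paste0(model, "_rk")]] <- x[[paste0(model, "_rank_label")]]
  }
  names(disp) <- c("factor", rbind(models, rep("rank", 5L)))
  print(disp, row.names = FALSE)
  invisible(x)
}

as_comparison_list <- function(comparisons) {
  if (inherits(comparisons, "grey_seq") || is.numeric(comparisons)) {
    comparisons <- list(comparisons)
  }
  out <- lapply(seq_along(comparisons), function(i) {
    nm <- names(comparisons)[i]
    s <- as_grey_seq(comparisons[[i]], if (is.null(nm) || !nzchar(nm))
      paste0("x", i) else nm)
    if (!is.null(nm) && nzchar(nm)) s$name <- nm
    s
  })
  names(out) <- vapply(out, `[[`, character(1L), "name")
  out
}
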